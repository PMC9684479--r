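test_that("nnls matches brute-force support enumeration and an independent solver", {
  set.seed(21)
  for (rep in 1:5) {
    A <- matrix(rnorm(9), 3, 3) + diag(3)  # well-conditioned
    y <- rnorm(3)
    f <- nnls(A, y)
    expect_true(all(f >= 0))
    f_brute <- brute_nnls(A, y)
    expect_equal(sum((A %*% f - y)^2), sum((A %*% f_brute - y)^2),
                 tolerance = 1e-8)
    expect_equal(f, f_brute, tolerance = 1e-4)
    skip_if_not_installed("pracma")
    expect_equal(f, as.vector(pracma::lsqnonneg(A, y)$x), tolerance = 1e-6)
  }
})

test_that("nnls recovers a noiseless spike and returns zero for zero data", {
  A <- small_kernel()
  grid <- kernel_t2_grid_pub(A)
  f_true <- numeric(grid$n); f_true[25] <- 1 / grid$delta
  y <- synthesize_signal(A, f_true)
  f <- nnls(A, y)
  expect_lt(sqrt(sum((unclass(A) %*% f - y)^2)), 1e-8)
  expect_equal(which.max(f), 25L, tolerance = 1)
  expect_equal(nnls(A, rep(0, nrow(A))), rep(0, grid$n))
})

test_that("Tikhonov-NNLS matches its augmented-system form, a dense grid oracle, and shrinks with lambda", {
  set.seed(22)
  A <- matrix(c(1, 0.3, 0.2, 1), 2, 2)
  y <- c(1, 0.5)
  lam <- 1
  f <- nnls_tikhonov(A, y, lam)
  # augmented-system equivalence (internal consistency)
  f_aug <- nnls(rbind(A, lam * diag(2)), c(y, 0, 0))
  expect_equal(f, f_aug, tolerance = 1e-10)
  # dense 400 x 400 grid oracle
  g <- grid_tikhonov_2d(A, y, lam, upper = 1.5, steps = 400)
  obj_f <- sum((A %*% f - y)^2) + lam^2 * sum(f^2)
  expect_lte(obj_f, g$obj + 1e-6)
  expect_equal(f, g$x, tolerance = 1e-2)  # grid resolution limited

  expect_equal(nnls_tikhonov(A, y, 0), nnls(A, y))
  expect_error(nnls_tikhonov(A, y, -1))
  # huge lambda wipes the solution out
  expect_lt(sum(nnls_tikhonov(A, y, 1e6 * norm(A, "2"))), 1e-10)
})

test_that("regularised families keep Tikhonov path monotonicity", {
  A <- small_kernel()
  grid <- kernel_t2_grid_pub(A)
  f_true <- two_gaussian_df(phantom_spec(35, 6, 100, 12), grid)
  y <- add_noise(synthesize_signal(A, f_true), snr = 500, seed = 3)
  lad <- lambda_ladder(16)
  fam <- regularized_family(A, y, lad)
  expect_equal(dim(fam$f), c(grid$n, 16L))
  expect_true(all(fam$f >= 0))
  expect_true(all(diff(fam$residual_norm) >= -1e-9))
  expect_true(all(diff(fam$solution_norm) <= 1e-9))
  # length-1 ladder degenerates to a single Tikhonov solve
  fam1 <- regularized_family(A, y, 0.01)
  expect_equal(fam1$f[, 1], nnls_tikhonov(A, y, 0.01))
  expect_error(regularized_family(A, y, c(2, 1)))
})

test_that("discrepancy principle hits its residual target and flags unreachable ones", {
  A <- small_kernel()
  grid <- kernel_t2_grid_pub(A)
  f_true <- two_gaussian_df(phantom_spec(35, 6, 100, 12), grid)
  y <- add_noise(synthesize_signal(A, f_true), snr = 500, seed = 4)
  sigma <- attr(y, "sigma")
  dp <- dp_select_lambda(A, y, sigma = sigma, nu = 1.05)
  expect_identical(dp$flag, "ok")
  expect_equal(dp$residual / dp$target, 1, tolerance = 1e-3)

  # bisection agrees with a dense log-lambda scan of |residual - target|
  lams <- exp(seq(log(1e-8), log(1e3), length.out = 200))
  res <- vapply(lams, function(l)
    sqrt(sum((unclass(A) %*% nnls_tikhonov(A, y, l) - y)^2)), numeric(1))
  l_scan <- lams[which.min(abs(res - dp$target))]
  expect_lt(abs(log(dp$lambda) - log(l_scan)), diff(log(lams[1:2])) * 1.5)

  # sigma far too large -> even the most regularised residual is below target
  dp_big <- dp_select_lambda(A, y, sigma = 10 * max(abs(y)))
  expect_identical(dp_big$flag, "lambda_max")
  # noiseless data -> target below the minimum achievable residual
  y0 <- synthesize_signal(A, f_true)
  dp_small <- dp_select_lambda(A, y0, sigma = 1e-14)
  expect_identical(dp_small$flag, "lambda_min")
  expect_error(dp_select_lambda(A, y, sigma = 0))
})

test_that("oracle lambda scans the ladder and breaks ties towards more regularisation", {
  A <- small_kernel()
  grid <- kernel_t2_grid_pub(A)
  f_true <- two_gaussian_df(phantom_spec(35, 6, 100, 12), grid)
  y <- add_noise(synthesize_signal(A, f_true), snr = 500, seed = 5)
  lad <- lambda_ladder(12)
  orc <- oracle_lambda(A, y, f_true, lad)
  # independent exhaustive evaluation
  errs <- vapply(lad, function(l)
    sqrt(sum((nnls_tikhonov(A, y, l) - f_true)^2)), numeric(1))
  expect_equal(orc$errors, errs, tolerance = 1e-10)
  expect_equal(orc$lambda, lad[which.min(errs)])

  # noiseless data: the error grows with lambda, so the smallest wins
  y0 <- synthesize_signal(A, f_true)
  orc0 <- oracle_lambda(A, y0, f_true, lambda_ladder(8, 1e-4, 10))
  expect_equal(orc0$index, 1L)
  # exact ties break towards the larger lambda
  tied <- oracle_lambda(A, rep(0, nrow(A)), rep(0, grid$n), c(0.1, 1))
  expect_equal(tied$lambda, 1)
})

test_that("simplex-constrained solver satisfies constraints exactly and matches a barycentric grid oracle", {
  # B = 0: any feasible point is optimal; constraints must still hold
  s0 <- simplex_nnls(matrix(0, 4, 5), 2, 3)
  expect_true(all(s0 >= 0))
  expect_equal(sum(s0[3:5]), 1, tolerance = 1e-12)

  # pure simplex, columns scaled (1, 2): minimise s1^2 + 4 s2^2 on the
  # simplex; the stationary point is (4/5, 1/5)
  s1 <- simplex_nnls(diag(c(1, 2)), 0, 2)
  expect_equal(as.vector(s1), c(0.8, 0.2), tolerance = 1e-10)

  set.seed(23)
  for (rep in 1:3) {
    B <- matrix(rnorm(8 * 5), 8, 5)
    s <- simplex_nnls(B, 2, 3)
    expect_true(all(s >= 0))
    expect_equal(sum(s[3:5]), 1, tolerance = 1e-8)
    obj <- attr(s, "objective")
    # oracle: barycentric grid over the simplex (step 0.01); for each c the
    # optimal free block solves a 2-variable NNLS by support enumeration
    cs <- seq(0, 1, by = 0.01)
    best <- Inf
    Bf <- B[, 1:2]; Bc <- B[, 3:5]
    for (c1 in cs) for (c2 in seq(0, 1 - c1, by = 0.01)) {
      v <- Bc %*% c(c1, c2, 1 - c1 - c2)
      ab <- brute_nnls(Bf, -as.vector(v))
      r <- sum((Bf %*% ab + v)^2)
      if (r < best) best <- r
    }
    expect_lte(obj^2, best + 1e-6)
    # penalty fallback agrees with the exact QP
    s_pen <- simplex_nnls(B, 2, 3, method = "penalty")
    expect_equal(as.vector(s), as.vector(s_pen), tolerance = 1e-4)
  }
})
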