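# Small configurations keep the ensemble computations fast; the
# full-scale study configuration is exercised in test-acceptance.R.

test_that("offline basis has consistent shapes, signs, and is seed-reproducible", {
  A <- small_kernel(40, 30)
  grid <- kernel_t2_grid_pub(A)
  D <- small_dictionary(grid, count = 6, sd = 8)
  lad <- lambda_ladder(3, 1e-4, 1)
  b1 <- offline_basis(A, D, lad, sigma = 0.002, n_run = 4, seed = 9)
  expect_s3_class(b1, "offline_basis")
  expect_equal(dim(b1$g_bar), c(40L, 6L, 3L))
  expect_equal(dim(b1$beta_bar), c(6L, 3L))
  expect_true(all(b1$g_bar >= 0))
  expect_true(all(b1$beta_bar >= 0))
  b2 <- offline_basis(A, D, lad, sigma = 0.002, n_run = 4, seed = 9)
  expect_identical(b1$g_bar, b2$g_bar)
  expect_identical(b1$beta_bar, b2$beta_bar)
  expect_error(offline_basis(A, D, lad, sigma = 0.002, n_run = 0))
  expect_error(offline_basis(A, D, lad, sigma = -1))
})

test_that("noiseless unregularised limit reproduces atoms with beta = 1", {
  # on a coarse grid the kernel is numerically full-rank, so the noiseless
  # lambda -> 0 inversion is unique and the identity limit is exact; at fine
  # discretisation the zero-residual set is a polytope and the active-set
  # solver returns a sparse vertex instead of the smooth atom
  A <- build_kernel(time_grid(150, 0.3, 400), t2_grid(8, 1, 200))
  grid <- kernel_t2_grid_pub(A)
  D <- build_dictionary(grid, list(gaussian_family(5, 30)))
  b <- offline_basis(A, D, 1e-12, sigma = 0, n_run = 1)
  for (i in seq_len(D$M)) {
    expect_lt(max(abs(b$g_bar[, i, 1] - D$G[, i])), 1e-4)
    expect_equal(b$beta_bar[i, 1], 1, tolerance = 1e-3)
  }
})

test_that("ensemble-average variance decays like 1/n_run", {
  A <- small_kernel(30, 25)
  grid <- kernel_t2_grid_pub(A)
  D <- small_dictionary(grid, count = 3, sd = 12)
  lad <- c(0.01)
  n_runs <- c(4L, 16L, 64L)
  n_rep <- 12L
  v <- vapply(seq_along(n_runs), function(q) {
    entry <- vapply(seq_len(n_rep), function(r) {
      b <- offline_basis(A, D, lad, sigma = 0.01, n_run = n_runs[q],
                         seed = 1000 * q + r)
      b$g_bar[15, 2, 1]
    }, numeric(1))
    stats::var(entry)
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(v) ~ log(n_runs)))[2]
  expect_lt(abs(slope + 1), 0.4)
})

test_that("online coefficients reproduce basis columns and reject mismatched ladders", {
  A <- small_kernel(40, 30)
  grid <- kernel_t2_grid_pub(A)
  D <- small_dictionary(grid, count = 6, sd = 8)
  lad <- lambda_ladder(3, 1e-4, 1)
  b <- offline_basis(A, D, lad, sigma = 0.002, n_run = 6, seed = 10)
  # a family equal to basis columns must be fit exactly
  fam <- structure(list(f = b$g_bar[, 4, ], lambda = lad),
                   class = "regularized_family")
  x <- online_coefficients(fam, b)
  for (j in seq_along(lad)) {
    fit <- b$g_bar[, , j] %*% x[, j]
    expect_lt(sqrt(sum((fit - b$g_bar[, 4, j])^2)), 1e-8)
  }
  # zero family -> zero coefficients
  fam0 <- structure(list(f = matrix(0, grid$n, 3), lambda = lad),
                    class = "regularized_family")
  expect_equal(online_coefficients(fam0, b), matrix(0, 6, 3))
  fam_bad <- structure(list(f = matrix(0, grid$n, 3),
                            lambda = lad * 2),
                       class = "regularized_family")
  expect_error(online_coefficients(fam_bad, b), "ladder")
})

test_that("online expansion matches a dense grid oracle on a 3-atom toy", {
  set.seed(31)
  A <- small_kernel(30, 25)
  grid <- kernel_t2_grid_pub(A)
  D <- small_dictionary(grid, count = 3, sd = 15)
  lad <- c(0.01)
  b <- offline_basis(A, D, lad, sigma = 0.005, n_run = 8, seed = 12)
  f_target <- 0.4 * b$g_bar[, 1, 1] + 0.6 * b$g_bar[, 3, 1]
  fam <- structure(list(f = matrix(f_target), lambda = lad),
                   class = "regularized_family")
  x <- online_coefficients(fam, b)[, 1]
  # dense non-negative grid search over the 3 coefficients
  G1 <- b$g_bar[, , 1]
  xs <- seq(0, 1, by = 0.01)
  best <- Inf
  for (x1 in xs) for (x2 in xs) {
    r2 <- f_target - G1[, 1] * x1 - G1[, 2] * x2
    # optimal x3 in closed form, clipped at 0
    x3 <- max(0, sum(G1[, 3] * r2) / sum(G1[, 3]^2))
    obj <- sum((r2 - G1[, 3] * x3)^2)
    if (obj < best) best <- obj
  }
  obj_x <- sum((f_target - G1 %*% x)^2)
  expect_lte(obj_x, best + 1e-4)
})

test_that("the stacked system carries the Kronecker replication structure", {
  A <- small_kernel(40, 30)
  grid <- kernel_t2_grid_pub(A)
  D <- small_dictionary(grid, count = 4, sd = 10)
  lad <- lambda_ladder(3, 1e-3, 1)
  b <- offline_basis(A, D, lad, sigma = 0.002, n_run = 3, seed = 13)
  M <- 4L; N <- 3L
  x <- matrix(runif(M * N), M, N)
  sys <- assemble_system(b, x)
  expect_equal(dim(sys$TT_alpha), c(M * N, N + M))
  expect_equal(dim(sys$TT_c), c(M * N, N + M))
  expect_true(all(sys$TT_alpha %in% c(0, 1)))
  s <- c(runif(N), runif(M))
  av <- sys$TT_alpha %*% s
  cv <- sys$TT_c %*% s
  # alpha_j replicated M times in lambda-major order
  expect_equal(as.vector(av), rep(s[1:N], each = M))
  # c_i replicated N times in atom-major order
  expect_equal(as.vector(cv), rep(s[N + 1:M], each = N))

  # B s equals the direct double-sum difference f_alpha - f_c
  f_alpha_direct <- rowSums(vapply(seq_len(N), function(j)
    s[j] * (b$g_bar[, , j] %*% x[, j]), numeric(grid$n)))
  f_c_direct <- rowSums(vapply(seq_len(M), function(i)
    s[N + i] * (b$g_bar[, i, ] %*% b$beta_bar[i, ]), numeric(grid$n)))
  expect_equal(as.vector(sys$B %*% s), f_alpha_direct - f_c_direct,
               tolerance = 1e-12)
})

test_that("spanreg self-consistently recovers a dictionary atom from noiseless data", {
  # coarse grid: reconstruction fidelity is then limited by the algorithm,
  # not by the (ill-posed) fine-grid inversion of the noiseless signal
  A <- build_kernel(time_grid(150, 0.3, 400), t2_grid(12, 1, 200))
  grid <- kernel_t2_grid_pub(A)
  D <- build_dictionary(grid, list(gaussian_family(6, 30)))
  lad <- lambda_ladder(8, 1e-6, 1)
  b <- offline_basis(A, D, lad, sigma = 0, n_run = 1)
  i0 <- 4L
  y <- synthesize_signal(A, D$G[, i0])
  fit <- spanreg(y, A, b, check_sigma = FALSE)
  expect_gte(fit$c[i0], 0.9)
  expect_lte(relative_error(fit$f_alpha, D$G[, i0]), 0.05)
  expect_true(all(fit$alpha >= 0))
  expect_equal(sum(fit$c), 1, tolerance = 1e-8)
  # f_alpha is the alpha-combination of the family by construction
  expect_equal(fit$f_alpha, as.vector(fit$family$f %*% fit$alpha),
               tolerance = 1e-12)
})

test_that("spanreg warns on basis/noise mismatch and keeps calls independent", {
  A <- small_kernel(60, 120)     # long, decayed tail for the estimator
  grid <- kernel_t2_grid_pub(A)
  D <- small_dictionary(grid, count = 6, sd = 8)
  lad <- lambda_ladder(4, 1e-4, 1)
  f <- two_gaussian_df(phantom_spec(30, 5, 60, 10), grid)
  b <- offline_basis(A, D, lad, sigma = 1e-4, n_run = 3, seed = 14)
  y <- add_noise(synthesize_signal(A, f), sigma = 2e-3, seed = 15)
  expect_warning(spanreg(y, A, b), "2x")
  # same basis, different signals: results must not leak between calls
  y1 <- add_noise(synthesize_signal(A, f), sigma = 1e-4, seed = 16)
  y2 <- add_noise(synthesize_signal(A, f), sigma = 1e-4, seed = 17)
  fit1a <- spanreg(y1, A, b, check_sigma = FALSE)
  invisible(spanreg(y2, A, b, check_sigma = FALSE))
  fit1b <- spanreg(y1, A, b, check_sigma = FALSE)
  expect_identical(fit1a$f_alpha, fit1b$f_alpha)
})

test_that("basis bank builds one basis per SNR bin", {
  A <- small_kernel(30, 25)
  grid <- kernel_t2_grid_pub(A)
  D <- small_dictionary(grid, count = 3, sd = 12)
  centers <- snr_bins(3, c(50, 800))
  bank <- basis_bank(A, D, lambda_ladder(2, 1e-3, 1), centers,
                     n_run = 2, seed = 18)
  expect_length(bank$bases, 3L)
  expect_equal(bank$bases[[2]]$sigma, 1 / centers[2])
})
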