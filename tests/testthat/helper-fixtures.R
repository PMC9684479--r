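# Shared small-scale fixtures. Everything is generated in code; the
# full-scale (200 x 150, M = 220) configuration is only built where a test
# genuinely needs it, and cached for the session.

small_grid <- function(n = 60) t2_grid(n, 1, 200)

small_kernel <- function(n = 60, m = 50) {
  build_kernel(time_grid(m, 0.3, 400), small_grid(n))
}

small_dictionary <- function(grid = small_grid(), count = 15, sd = 6) {
  build_dictionary(grid, list(gaussian_family(count, sd)))
}

default_sim_kernel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_kernel(time_grid(150, 0.3, 400), t2_grid(200, 1, 200))
    cache
  }
})

# Full-scale SNR-500 offline basis shared by the acceptance-level tests.
# Built once per test run (a few minutes). Unit-area phantoms have peak
# signal ~1 at the first sampling time, so sigma = 1/500 is the SNR-500
# noise level for all of them.
snr500_basis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      A <- default_sim_kernel()
      D <- build_dictionary(kernel_t2_grid_pub(A))
      cache <<- offline_basis(A, D, lambda_ladder(),
                              sigma = 1 / 500, n_run = 10, seed = 101)
    }
    cache
  }
})

# grid accessors are internal; tests reach them via the attributes
kernel_t2_grid_pub <- function(A) attr(A, "t2_grid")
kernel_time_grid_pub <- function(A) attr(A, "time_grid")$times

# brute-force NNLS for tiny systems: enumerate all sign supports, solve the
# unconstrained LS on each support, keep feasible candidates
brute_nnls <- function(A, y) {
  n <- ncol(A)
  best <- rep(0, n)
  best_obj <- sum(y^2)
  for (mask in seq_len(2^n) - 1L) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(S) == 0) next
    As <- A[, S, drop = FALSE]
    coef <- tryCatch(qr.solve(As, y), error = function(e) NULL)
    if (is.null(coef) || any(coef < 0)) next
    obj <- sum((As %*% coef - y)^2)
    if (obj < best_obj - 1e-14) {
      best <- rep(0, n); best[S] <- coef; best_obj <- obj
    }
  }
  best
}

# dense non-negative grid search for 2-variable Tikhonov problems
grid_tikhonov_2d <- function(A, y, lam, upper, steps = 400) {
  xs <- seq(0, upper, length.out = steps + 1)
  best <- c(0, 0); best_obj <- Inf
  for (x1 in xs) {
    r1 <- y - A[, 1] * x1
    for (x2 in xs) {
      obj <- sum((r1 - A[, 2] * x2)^2) + lam^2 * (x1^2 + x2^2)
      if (obj < best_obj) { best_obj <- obj; best <- c(x1, x2) }
    }
  }
  list(x = best, obj = best_obj)
}
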