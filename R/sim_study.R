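#' Two-Gaussian phantom specification
#'
#' The simulation phantoms are sums of two Gaussian components with means
#' (mu1, mu2) and SDs (sigma1, sigma2); the ratio of peak separation
#' RPS = mu2 / mu1 controls how hard the components are to resolve.
#'
#' @param mu1,mu2 Component means in ms, \code{mu1 <= mu2}.
#' @param sigma1,sigma2 Component SDs in ms (> 0).
#' @param normalize Rescale the sampled DF to unit discrete area (default
#'   TRUE): the summed density integrates to 2, while SpanReg's simplex
#'   constraint assumes a unit-area DF.
#' @return Class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(mu1, sigma1, mu2, sigma2, normalize = TRUE) {
  if (mu1 > mu2) stop("mu1 must not exceed mu2")
  if (sigma1 <= 0 || sigma2 <= 0) stop("sigmas must be positive")
  structure(list(mu1 = mu1, mu2 = mu2, sigma1 = sigma1, sigma2 = sigma2,
                 rps = mu2 / mu1, normalize = normalize),
            class = "phantom_spec")
}

#' Sample a two-Gaussian phantom DF on a grid
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param grid A \code{\link{t2_grid}} whose range contains both means.
#' @return Non-negative density vector on the grid (unit discrete area if
#'   \code{spec$normalize}).
#' @export
two_gaussian_df <- function(spec, grid) {
  if (spec$mu1 < grid$bounds[1] || spec$mu2 > grid$bounds[2])
    stop("phantom means must lie inside the grid range")
  f <- gaussian_density(spec$mu1, spec$sigma1, grid) +
    gaussian_density(spec$mu2, spec$sigma2, grid)
  if (isTRUE(spec$normalize)) f <- f / df_area(f, grid)
  f
}

#' The 5 x 5 simulation phantom grid
#'
#' sigma1 in \{2 + 0.75 k\} ms and RPS in \{1 + 0.75 k\}, k = 0..4, with
#' mu1 = 35 ms, mu2 = RPS * mu1 and sigma2 = 3 sigma1: 25 phantoms spanning
#' narrow-to-broad components at increasing separations.
#'
#' @param mu1 Centre of the left component (default 35 ms).
#' @return List of 25 \code{\link{phantom_spec}} objects, RPS-major within
#'   each sigma1.
#' @export
phantom_grid <- function(mu1 = 35) {
  sig1 <- 2 + 0.75 * 0:4
  rps <- 1 + 0.75 * 0:4
  specs <- list()
  for (s in sig1) for (r in rps)
    specs[[length(specs) + 1L]] <- phantom_spec(mu1, s, r * mu1, 3 * s)
  specs
}

#' Relative L2 reconstruction error
#'
#' \eqn{\|f_{rec} - f_{true}\|_2 / \|f_{true}\|_2}.
#'
#' @param f_rec,f_true Density vectors on the same grid.
#' @return Non-negative scalar.
#' @export
relative_error <- function(f_rec, f_true) {
  if (length(f_rec) != length(f_true)) stop("grids differ")
  denom <- sqrt(sum(f_true^2))
  if (denom == 0) stop("f_true must be non-zero")
  sqrt(sum((f_rec - f_true)^2)) / denom
}

#' Head-to-head comparison of SpanReg and the discrepancy principle
#'
#' For every phantom and seed: sample the phantom, synthesise its decay,
#' add noise at the requested SNR, reconstruct with SpanReg (using the
#' supplied basis) and with DP-selected Tikhonov-NNLS, and record the
#' relative errors. Errors are averaged over seeds; negative
#' \code{eps_diff} means SpanReg beat DP in that cell.
#'
#' @param A Kernel (its T2 grid is used for the phantoms).
#' @param basis Offline basis built at \code{sigma = peak / snr} for the
#'   unit-area phantoms (their peak signal is ~1 at t near 0).
#' @param specs List of \code{\link{phantom_spec}}s (default
#'   \code{\link{phantom_grid}()}).
#' @param snr Signal-to-noise ratio (default 500).
#' @param seeds Vector of master seeds (default 1:3); the per-cell seed is
#'   \code{master * 1000 + cell} for reproducibility.
#' @param nu DP safety factor (default 1.05).
#' @return Data frame with one row per cell: phantom parameters,
#'   \code{eps_spanreg}, \code{eps_dp}, \code{eps_diff}.
#' @export
run_comparison <- function(A, basis, specs = phantom_grid(), snr = 500,
                           seeds = 1:3, nu = 1.05) {
  grid <- kernel_t2_grid(A)
  out <- vector("list", length(specs))
  for (cell in seq_along(specs)) {
    spec <- specs[[cell]]
    f_true <- two_gaussian_df(spec, grid)
    y0 <- synthesize_signal(A, f_true)
    e_sr <- e_dp <- numeric(length(seeds))
    for (si in seq_along(seeds)) {
      y <- add_noise(y0, snr = snr, seed = seeds[si] * 1000 + cell)
      sigma <- attr(y, "sigma")
      fit <- spanreg(y, A, basis, check_sigma = FALSE)
      dp <- dp_select_lambda(A, y, sigma = sigma, nu = nu)
      e_sr[si] <- relative_error(fit$f_alpha, f_true)
      e_dp[si] <- relative_error(dp$f, f_true)
    }
    out[[cell]] <- data.frame(
      mu1 = spec$mu1, mu2 = spec$mu2, sigma1 = spec$sigma1,
      sigma2 = spec$sigma2, rps = spec$rps,
      eps_spanreg = mean(e_sr), eps_dp = mean(e_dp),
      eps_diff = mean(e_sr) - mean(e_dp))
  }
  do.call(rbind, out)
}

#' Stability of the reconstruction under mis-selected regularisation
#'
#' Finds the oracle lambda (minimiser of the true L2 error over the
#' ladder), then measures how much the reconstruction moves when lambda is
#' shifted by factors of two away from it. The Tikhonov branch compares
#' single solutions \eqn{f_{\lambda_{opt} 2^j}} against
#' \eqn{f_{\lambda_{opt}}}; the SpanReg branch compares reconstructions
#' built from shifted adjacent lambda triplets (lambda/2, lambda, 2 lambda,
#' with weights from running SpanReg restricted to that three-lambda
#' ladder) against the triplet centred on the oracle value. Smaller
#' difference norms mean greater stability.
#'
#' @param y Observed signal.
#' @param A Kernel.
#' @param f_true Known ground-truth DF (simulation only).
#' @param dictionary Dictionary for the triplet bases.
#' @param sigma Noise RMS of y.
#' @param ladder Ladder used to locate the oracle lambda (default
#'   \code{\link{lambda_ladder}()}).
#' @param shifts Integer shifts j to evaluate (default -2:2; 0 is the
#'   reference and has difference 0 by construction).
#' @param n_run,seed Passed to the per-triplet \code{\link{offline_basis}}.
#' @return Data frame with columns \code{shift}, \code{tikhonov_norm},
#'   \code{spanreg_norm}; attribute \code{"lambda_opt"} records the oracle
#'   value, and attribute \code{"boundary"} flags an oracle at the ladder
#'   edge.
#' @export
stability_analysis <- function(y, A, f_true, dictionary, sigma,
                               ladder = lambda_ladder(), shifts = -2:2,
                               n_run = 10L, seed = NULL) {
  orc <- oracle_lambda(A, y, f_true, ladder)
  lam0 <- orc$lambda
  boundary <- orc$index %in% c(1L, length(ladder))
  if (boundary)
    warning("oracle lambda lies at the ladder boundary")
  span_at <- function(j) {
    lam_c <- lam0 * 2^j
    lad3 <- lam_c * c(0.5, 1, 2)
    b3 <- offline_basis(A, dictionary, lad3, sigma, n_run = n_run,
                        seed = if (is.null(seed)) NULL else seed + j + 100L)
    spanreg(y, A, b3, check_sigma = FALSE)$f_alpha
  }
  f_tik0 <- nnls_tikhonov(A, y, lam0)
  f_span0 <- span_at(0L)
  rows <- lapply(shifts, function(j) {
    if (j == 0L)
      return(data.frame(shift = 0L, tikhonov_norm = 0, spanreg_norm = 0))
    f_tik <- nnls_tikhonov(A, y, lam0 * 2^j)
    f_span <- span_at(j)
    data.frame(shift = j,
               tikhonov_norm = sqrt(sum((f_tik0 - f_tik)^2)),
               spanreg_norm = sqrt(sum((f_span0 - f_span)^2)))
  })
  out <- do.call(rbind, rows)
  attr(out, "lambda_opt") <- lam0
  attr(out, "boundary") <- boundary
  out
}

#' Count resolved peaks of a distribution function
#'
#' A component counts as resolved when it is a local maximum with
#' topographic prominence of at least \code{prominence} times the global
#' maximum and at least \code{min_separation} grid points away from any
#' higher retained peak.
#'
#' @param f Non-negative density vector.
#' @param prominence Relative prominence threshold (default 0.05).
#' @param min_separation Minimum index separation between peaks (default 3).
#' @return Integer peak count.
#' @export
count_peaks <- function(f, prominence = 0.05, min_separation = 3L) {
  n <- length(f)
  if (n < 3 || max(f) <= 0) return(0L)
  # local maxima (plateau-aware: first index of a plateau that steps down)
  idx <- which(diff(sign(diff(f))) < 0) + 1L
  if (length(idx) == 0) {
    # monotone or boundary-peaked profiles: treat interior plateaus only
    return(if (which.max(f) %in% c(1L, n)) 0L else 1L)
  }
  prom <- vapply(idx, function(i) {
    left <- if (i > 1) {
      stop_at <- which(f[seq_len(i - 1)] > f[i])
      lo <- if (length(stop_at)) max(stop_at) + 1L else 1L
      min(f[lo:(i - 1L)])
    } else f[i]
    right <- if (i < n) {
      seg <- f[(i + 1L):n]
      stop_at <- which(seg > f[i])
      hi <- if (length(stop_at)) min(stop_at) - 1L else length(seg)
      if (hi >= 1) min(seg[seq_len(hi)]) else f[i]
    } else f[i]
    f[i] - max(left, right)
  }, numeric(1))
  keep <- idx[prom >= prominence * max(f)]
  if (length(keep) <= 1) return(length(keep))
  # greedy suppression: keep highest first, drop closer than min_separation
  keep <- keep[order(f[keep], decreasing = TRUE)]
  kept <- integer(0)
  for (i in keep)
    if (all(abs(i - kept) >= min_separation)) kept <- c(kept, i)
  length(kept)
}
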