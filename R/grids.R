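#' Uniform T2 grid
#'
#' Construct the discretisation of the T2 axis on which distribution
#' functions (DFs) live. The grid is uniform by default; the kernel carries
#' the grid spacing so that DF values are densities (per ms) and areas are
#' computed as \code{sum(f) * delta}.
#'
#' @param n Number of grid points (>= 2).
#' @param lo,hi Grid bounds in ms, \code{0 < lo < hi}.
#' @param spacing Either \code{"linear"} (default) or \code{"log"}.
#' @return An object of class \code{"t2_grid"}: a list with \code{values}
#'   (length-n vector, ms), \code{delta} (spacing, ms; for log spacing the
#'   vector of local cell widths), and \code{bounds}.
#' @examples
#' g <- t2_grid(200, 1, 200)
#' g$delta  # 1 ms
#' @export
t2_grid <- function(n, lo, hi, spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("n must be a single count >= 2")
  if (!(lo > 0)) stop("lo must be positive")
  if (!(hi > lo)) stop("hi must exceed lo")
  n <- as.integer(n)
  if (spacing == "linear") {
    values <- seq(lo, hi, length.out = n)
    delta <- (hi - lo) / (n - 1)
  } else {
    values <- exp(seq(log(lo), log(hi), length.out = n))
    # local cell widths by centred differences (trapezoidal weights)
    delta <- c(diff(values)[1], (values[-1:-2] - values[1:(n - 2)]) / 2,
               diff(values)[n - 1])
  }
  structure(list(values = values, delta = delta, bounds = c(lo, hi),
                 n = n, spacing = spacing),
            class = "t2_grid")
}

#' @export
print.t2_grid <- function(x, ...) {
  cat(sprintf("T2 grid: %d points in [%g, %g] ms (%s spacing)\n",
              x$n, x$bounds[1], x$bounds[2], x$spacing))
  invisible(x)
}

#' Measurement time grid
#'
#' Sampling times of the decay experiment. \code{time_grid} gives evenly
#' spaced times; \code{echo_times} gives the multi-echo convention
#' TE_i = i * TE.
#'
#' @param m Number of sampling times (>= 2).
#' @param lo,hi Time range in ms, \code{0 <= lo < hi}.
#' @return Class \code{"time_grid"}: list with \code{times} (ms).
#' @examples
#' tg <- time_grid(150, 0.3, 400)
#' te <- echo_times(32, 11.3)  # 11.3, 22.6, ..., 361.6 ms
#' @export
time_grid <- function(m, lo, hi) {
  if (!is.numeric(m) || length(m) != 1L || m < 2)
    stop("m must be a single count >= 2")
  if (lo < 0) stop("lo must be non-negative")
  if (!(hi > lo)) stop("hi must exceed lo")
  structure(list(times = seq(lo, hi, length.out = as.integer(m)),
                 m = as.integer(m)),
            class = "time_grid")
}

#' @rdname time_grid
#' @param n_echo Number of echoes.
#' @param te Echo spacing TE in ms.
#' @export
echo_times <- function(n_echo, te) {
  if (n_echo < 2) stop("n_echo must be >= 2")
  if (te <= 0) stop("te must be positive")
  structure(list(times = te * seq_len(n_echo), m = as.integer(n_echo)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time grid: %d samples in [%g, %g] ms\n",
              x$m, min(x$times), max(x$times)))
  invisible(x)
}

as_time_grid <- function(t) {
  if (inherits(t, "time_grid")) return(t)
  if (is.numeric(t) && length(t) >= 2 && all(diff(t) > 0) && t[1] >= 0)
    return(structure(list(times = as.numeric(t), m = length(t)),
                     class = "time_grid"))
  stop("not a valid time grid: need >= 2 strictly increasing non-negative times")
}

#' Discretised Laplace kernel
#'
#' Builds the m x n kernel matrix with entries
#' \eqn{A_{ij} = \exp(-t_i / \tau_j)\,\Delta\tau}, so that \code{A \%*\% f}
#' is the midpoint discretisation of the Laplace transform of the density f.
#'
#' @param t A \code{time_grid} (or numeric vector of increasing times, ms).
#' @param tau A \code{t2_grid}.
#' @return An m x n matrix of class \code{"relax_kernel"} with the grids
#'   attached as attributes \code{"time_grid"} and \code{"t2_grid"}.
#' @examples
#' A <- build_kernel(time_grid(150, 0.3, 400), t2_grid(200, 1, 200))
#' dim(A)  # 150 200
#' @export
build_kernel <- function(t, tau) {
  t <- as_time_grid(t)
  if (!inherits(tau, "t2_grid")) stop("tau must be a t2_grid")
  if (any(tau$values <= 0)) stop("T2 values must be strictly positive")
  A <- exp(-outer(t$times, 1 / tau$values))
  A <- sweep(A, 2, rep_len(tau$delta, tau$n), `*`)
  structure(A, class = c("relax_kernel", class(A)),
            time_grid = t, t2_grid = tau)
}

kernel_t2_grid <- function(A) {
  g <- attr(A, "t2_grid")
  if (is.null(g)) stop("kernel has no attached t2_grid; use build_kernel()")
  g
}

kernel_time_grid <- function(A) {
  g <- attr(A, "time_grid")
  if (is.null(g)) stop("kernel has no attached time_grid; use build_kernel()")
  g
}

#' Discrete area of a distribution function
#'
#' @param f Non-negative density values on \code{grid}.
#' @param grid A \code{t2_grid}.
#' @return \code{sum(f * delta)}.
#' @export
df_area <- function(f, grid) {
  sum(f * rep_len(grid$delta, grid$n))
}

#' Synthesise a noiseless decay signal
#'
#' Computes \code{y = A f}, the forward model of the discretised Fredholm
#' problem.
#'
#' @param A Kernel from \code{\link{build_kernel}}.
#' @param f Distribution function (density) on the kernel's T2 grid.
#' @return Numeric signal of length \code{nrow(A)}.
#' @export
synthesize_signal <- function(A, f) {
  if (length(f) != ncol(A))
    stop(sprintf("f has length %d but the kernel has %d T2 bins",
                 length(f), ncol(A)))
  as.vector(unclass(A) %*% f)
}

#' Add i.i.d. Gaussian noise at a prescribed SNR
#'
#' SNR is defined as \code{max(abs(y)) / sigma} with sigma the RMS noise
#' amplitude; real additive Gaussian noise approximates high-SNR magnitude
#' data.
#'
#' @param y Noiseless signal.
#' @param snr Target SNR (> 0). Ignored when \code{sigma} is given.
#' @param sigma RMS noise amplitude; overrides \code{snr}.
#' @param seed Optional integer seed for reproducibility.
#' @return Noisy signal with attribute \code{"sigma"} recording the RMS
#'   amplitude used.
#' @examples
#' y <- exp(-(1:32) * 11.3 / 80)
#' yn <- add_noise(y, snr = 500, seed = 1)
#' attr(yn, "sigma")  # max|y|/500
#' @export
add_noise <- function(y, snr = NULL, sigma = NULL, seed = NULL) {
  if (is.null(sigma)) {
    if (is.null(snr)) stop("give either snr or sigma")
    if (snr <= 0) stop("snr must be positive")
    peak <- max(abs(y))
    if (peak == 0) stop("cannot set sigma from snr for an all-zero signal")
    sigma <- peak / snr
  }
  if (sigma < 0) stop("sigma must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  out <- if (sigma == 0) y else y + stats::rnorm(length(y), 0, sigma)
  attr(out, "sigma") <- sigma
  out
}

#' Estimate the noise RMS from the signal tail
#'
#' For decaying signals the late-time samples are noise-dominated; sigma is
#' estimated as the standard deviation of the last
#' \code{ceiling(tail_fraction * m)} samples after mean removal. The result
#' is flagged when the tail is evidently not noise-dominated (tail mean
#' exceeding 5x the tail SD).
#'
#' @param y Observed signal.
#' @param tail_fraction Fraction of samples in the tail, in (0, 0.5].
#' @return List with \code{sigma} and logical \code{flagged}.
#' @export
estimate_noise_sigma <- function(y, tail_fraction = 0.2) {
  if (tail_fraction <= 0 || tail_fraction > 0.5)
    stop("tail_fraction must be in (0, 0.5]")
  m <- length(y)
  k <- ceiling(tail_fraction * m)
  tail <- y[(m - k + 1):m]
  s <- stats::sd(tail)
  if (is.na(s)) s <- 0
  flagged <- is.finite(s) && abs(mean(tail)) > 5 * s
  list(sigma = s, flagged = flagged)
}
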