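#' Offline SpanReg basis: ensemble-averaged noise-corrupted inversions
#'
#' For each dictionary atom g_i, each noise realisation k draws one fresh
#' Gaussian noise vector omega (shared across the whole lambda ladder for
#' that atom and realisation) and computes the Tikhonov-NNLS inversion of
#' \code{A g_i + omega} at every ladder value. The ensemble averages
#' \eqn{\langle g_{i,\lambda_j}\rangle} over realisations form the offline
#' basis; the coefficients \eqn{\langle\beta_{ij}\rangle} are obtained by
#' fitting each atom non-negatively against its own per-realisation
#' inversions and averaging the fits. In the noiseless, unregularised limit
#' the beta coefficients collapse to the identity pattern.
#'
#' This computation depends only on the kernel, the dictionary, the ladder
#' and the noise level sigma — never on observed data — so one basis serves
#' any number of reconstructions at that noise level.
#'
#' @param A Kernel from \code{\link{build_kernel}}.
#' @param dictionary A \code{\link{build_dictionary}} result on the
#'   kernel's T2 grid.
#' @param ladder Lambda ladder (see \code{\link{lambda_ladder}}).
#' @param sigma Noise RMS amplitude the basis is built for (>= 0).
#' @param n_run Number of noise realisations averaged (default 50). A
#'   sigma of exactly 0 needs no averaging and uses a single run.
#' @param seed Optional integer seed; fixed seeds give bit-identical bases.
#' @return Class \code{"offline_basis"}: list with \code{g_bar} (n x M x N
#'   array), \code{beta_bar} (M x N), \code{sigma}, \code{n_run},
#'   \code{ladder}, \code{dictionary}, \code{seed}.
#' @export
offline_basis <- function(A, dictionary, ladder, sigma, n_run = 50L,
                          seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (n_run < 1) stop("n_run must be >= 1")
  if (any(ladder <= 0)) stop("ladder must be positive")
  Au <- unclass(A)
  G <- dictionary$G
  if (nrow(G) != ncol(Au)) stop("dictionary grid does not match the kernel")
  n <- ncol(Au); M <- dictionary$M; N <- length(ladder)
  m <- nrow(Au)
  if (!is.null(seed)) set.seed(seed)
  n_eff <- if (sigma == 0) 1L else as.integer(n_run)

  At <- t(Au)
  AtA <- crossprod(Au)
  AtAG <- AtA %*% G                       # A'(A g_i) for every atom
  Qs <- lapply(ladder, function(l) { Q <- AtA; diag(Q) <- diag(Q) + l^2; Q })

  g_bar <- array(0, dim = c(n, M, N))
  beta_bar <- matrix(0, M, N)
  gk <- matrix(0, n, N)                   # per-(k,i) inversions across lambdas
  for (k in seq_len(n_eff)) {
    for (i in seq_len(M)) {
      b0 <- AtAG[, i]
      if (sigma > 0) b0 <- b0 + as.vector(At %*% stats::rnorm(m, 0, sigma))
      for (j in seq_len(N)) {
        g <- fnnls_cpp(Qs[[j]], b0)
        gk[, j] <- g
        g_bar[, i, j] <- g_bar[, i, j] + g
      }
      beta_bar[i, ] <- beta_bar[i, ] +
        fnnls_cpp(crossprod(gk), as.vector(crossprod(gk, G[, i])))
    }
  }
  structure(list(g_bar = g_bar / n_eff, beta_bar = beta_bar / n_eff,
                 sigma = sigma, n_run = n_eff, ladder = ladder,
                 dictionary = dictionary, seed = seed),
            class = "offline_basis")
}

#' @export
print.offline_basis <- function(x, ...) {
  cat(sprintf("offline SpanReg basis: M = %d atoms x N = %d lambdas, sigma = %.3g, %d runs\n",
              dim(x$g_bar)[2], dim(x$g_bar)[3], x$sigma, x$n_run))
  invisible(x)
}

#' Online expansion of regularised solutions in the offline basis
#'
#' For each ladder entry j independently, fits the data-derived solution
#' f_lambda_j non-negatively against the averaged basis columns
#' \eqn{\{\langle g_{i,\lambda_j}\rangle\}_i}, giving the M x N coefficient
#' matrix x.
#'
#' @param family A \code{\link{regularized_family}} computed on the same
#'   ladder as the basis.
#' @param basis An \code{\link{offline_basis}}.
#' @param nonneg Fit with non-negativity (default TRUE); set FALSE for a
#'   plain least-squares variant.
#' @return M x N matrix of expansion coefficients.
#' @export
online_coefficients <- function(family, basis, nonneg = TRUE) {
  if (length(family$lambda) != length(basis$ladder) ||
      any(abs(family$lambda - basis$ladder) >
          1e-12 * pmax(1, basis$ladder)))
    stop("family ladder does not match the basis ladder")
  M <- dim(basis$g_bar)[2]; N <- dim(basis$g_bar)[3]
  x <- matrix(0, M, N)
  for (j in seq_len(N)) {
    Gj <- basis$g_bar[, , j]
    if (nonneg) {
      x[, j] <- fnnls_cpp(crossprod(Gj), as.vector(crossprod(Gj, family$f[, j])))
    } else {
      x[, j] <- stats::lsfit(Gj, family$f[, j], intercept = FALSE)$coefficients
    }
  }
  x
}

#' Assemble the stacked SpanReg least-squares system
#'
#' Builds the blocks of the stacked problem: L_alpha groups basis columns
#' by lambda (lambda-major), L_c by dictionary atom (atom-major); the
#' replication matrices TT_alpha and TT_c carry the Kronecker structure
#' that maps the stacked unknown s = (alpha, c) onto the MN expanded
#' coefficients; and
#' \deqn{B = L_\alpha\,diag(x)\,TT_\alpha - L_c\,diag(\beta)\,TT_c.}
#' Minimising \eqn{\|B s\|} over the feasible set matches the two
#' representations f_alpha and f_c of the unknown DF.
#'
#' @param basis An \code{\link{offline_basis}}.
#' @param x M x N coefficients from \code{\link{online_coefficients}}.
#' @return List with \code{L_alpha}, \code{L_c}, \code{x_vec},
#'   \code{beta_vec}, \code{TT_alpha}, \code{TT_c}, \code{B}, \code{N},
#'   \code{M}.
#' @export
assemble_system <- function(basis, x) {
  dm <- dim(basis$g_bar)
  n <- dm[1]; M <- dm[2]; N <- dm[3]
  if (!all(dim(x) == c(M, N))) stop("x must be M x N")
  # lambda-major: column (j-1)*M + i  <->  <g_{i,lambda_j}>
  L_alpha <- matrix(basis$g_bar, n, M * N)
  x_vec <- as.vector(x)
  # atom-major: column (i-1)*N + j
  perm <- as.vector(t(matrix(seq_len(M * N), M, N)))  # maps (i,j) -> i-major
  L_c <- L_alpha[, perm, drop = FALSE]
  beta_vec <- as.vector(t(basis$beta_bar))
  TT_alpha <- kronecker(diag(N), matrix(1, M, 1)) %*%
    cbind(diag(N), matrix(0, N, M))
  TT_c <- kronecker(diag(M), matrix(1, N, 1)) %*%
    cbind(matrix(0, M, N), diag(M))
  B <- L_alpha %*% (x_vec * TT_alpha) - L_c %*% (beta_vec * TT_c)
  list(L_alpha = L_alpha, L_c = L_c, x_vec = x_vec, beta_vec = beta_vec,
       TT_alpha = TT_alpha, TT_c = TT_c, B = B, N = N, M = M)
}

#' SpanReg reconstruction of a distribution function
#'
#' The online step: computes the Tikhonov-NNLS family of the observed
#' signal over the basis ladder, expands each family member in the offline
#' basis, assembles the stacked system and solves the simplex-constrained
#' least-squares problem for the weights. The primary reconstruction is
#' \eqn{f^*_\alpha = \sum_j \alpha^*_j f_{\lambda_j}}, a non-negative
#' combination of differently regularised solutions of the data itself;
#' the dictionary-side reconstruction f*_c is returned as well.
#'
#' The signal is assumed normalised so that the underlying DF has unit
#' area (simulation phantoms are generated that way; for imaging data use
#' \code{\link{normalize_decay}} first).
#'
#' @param y Observed (normalised) signal.
#' @param A Kernel from \code{\link{build_kernel}}.
#' @param basis An \code{\link{offline_basis}} built for this kernel at the
#'   signal's noise level.
#' @param check_sigma Warn when an unflagged tail estimate of the signal's
#'   noise differs from the basis sigma by more than 2x (default TRUE).
#' @return Class \code{"spanreg_fit"}: list with \code{alpha} (N weights),
#'   \code{c} (M simplex weights), \code{x}, \code{f_alpha}, \code{f_c},
#'   \code{family}, \code{objective}.
#' @examples
#' \donttest{
#' grid <- t2_grid(60, 1, 200)
#' A <- build_kernel(time_grid(50, 0.3, 400), grid)
#' D <- build_dictionary(grid, list(gaussian_family(20, 4)))
#' f <- two_gaussian_df(phantom_spec(40, 3.5, 120, 10), grid)
#' y <- add_noise(synthesize_signal(A, f), snr = 500, seed = 1)
#' basis <- offline_basis(A, D, lambda_ladder(6), sigma = attr(y, "sigma"),
#'                        n_run = 5, seed = 2)
#' fit <- spanreg(y, A, basis)
#' relative_error(fit$f_alpha, f)
#' }
#' @export
spanreg <- function(y, A, basis, check_sigma = TRUE) {
  if (check_sigma && basis$sigma > 0) {
    est <- estimate_noise_sigma(y)
    if (!est$flagged && est$sigma > 0) {
      ratio <- est$sigma / basis$sigma
      if (ratio > 2 || ratio < 0.5)
        warning(sprintf(
          "basis sigma (%.3g) differs from the signal's tail estimate (%.3g) by more than 2x",
          basis$sigma, est$sigma))
    }
  }
  family <- regularized_family(A, y, basis$ladder)
  x <- online_coefficients(family, basis)
  sys <- assemble_system(basis, x)
  s <- simplex_nnls(sys$B, n_free = sys$N, n_simplex = sys$M)
  alpha <- s[seq_len(sys$N)]
  cc <- s[sys$N + seq_len(sys$M)]
  f_alpha <- as.vector(family$f %*% alpha)
  f_c <- as.vector(sys$L_c %*% (sys$beta_vec * as.vector(sys$TT_c %*% s)))
  structure(list(alpha = alpha, c = cc, x = x, f_alpha = f_alpha,
                 f_c = f_c, family = family,
                 objective = attr(s, "objective")),
            class = "spanreg_fit")
}

#' @export
print.spanreg_fit <- function(x, ...) {
  cat(sprintf("SpanReg fit: %d lambda weights (%d active), %d dictionary weights (%d active)\n",
              length(x$alpha), sum(x$alpha > 1e-10),
              length(x$c), sum(x$c > 1e-10)))
  invisible(x)
}

#' Bank of offline bases keyed by SNR bin
#'
#' Imaging data spans a wide SNR range; the bank precomputes one offline
#' basis per SNR bin centre (noise level sigma = peak / SNR for a
#' unit-peak normalised decay) so per-pixel reconstruction just looks its
#' bin up.
#'
#' @param A Kernel.
#' @param dictionary Dictionary.
#' @param ladder Lambda ladder.
#' @param snr_centers Representative SNR per bin (see
#'   \code{\link{snr_bins}}).
#' @param peak Signal peak the sigmas refer to (default 1: normalised
#'   decays).
#' @param n_run,seed Passed to \code{\link{offline_basis}}; each bin uses
#'   \code{seed + bin index}.
#' @return Class \code{"basis_bank"}: list of bases plus \code{snr_centers}.
#' @export
basis_bank <- function(A, dictionary, ladder, snr_centers, peak = 1,
                       n_run = 50L, seed = NULL) {
  bases <- lapply(seq_along(snr_centers), function(b)
    offline_basis(A, dictionary, ladder, sigma = peak / snr_centers[b],
                  n_run = n_run,
                  seed = if (is.null(seed)) NULL else seed + b))
  structure(list(bases = bases, snr_centers = snr_centers),
            class = "basis_bank")
}

#' @export
print.basis_bank <- function(x, ...) {
  cat(sprintf("basis bank: %d SNR bins in [%.3g, %.3g]\n",
              length(x$snr_centers), min(x$snr_centers), max(x$snr_centers)))
  invisible(x)
}
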