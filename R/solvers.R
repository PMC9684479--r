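#' Non-negative least squares
#'
#' Solves \eqn{\min_{f \ge 0} \|A f - y\|_2^2} by an active-set method on
#' the normal equations (FNNLS). This is the unregularised inversion of the
#' discretised Fredholm problem; for the exponential kernel it is severely
#' ill-conditioned and noise-sensitive, which is the motivation for the
#' regularised variants below.
#'
#' @param A Design matrix (m x n), typically a \code{\link{build_kernel}}
#'   result.
#' @param y Right-hand side of length m.
#' @return Non-negative solution vector of length n.
#' @export
nnls <- function(A, y) {
  A <- unclass(A)
  if (length(y) != nrow(A)) stop("length(y) must equal nrow(A)")
  fnnls_cpp(crossprod(A), as.vector(crossprod(A, y)))
}

#' Tikhonov-regularised non-negative least squares
#'
#' Solves \eqn{\min_{f \ge 0} \|A f - y\|_2^2 + \lambda^2 \|f\|_2^2},
#' equivalent to NNLS on the augmented system \code{rbind(A, lambda * I)}
#' versus \code{c(y, 0)}. Implemented on the normal equations
#' \code{(A'A + lambda^2 I) f = A'y}, so a precomputed Gram matrix can be
#' supplied when solving many right-hand sides.
#'
#' @inheritParams nnls
#' @param lambda Regularisation weight, >= 0.
#' @param AtA Optional precomputed \code{crossprod(A)}.
#' @param Aty Optional precomputed \code{crossprod(A, y)}.
#' @return Non-negative solution vector of length n.
#' @export
nnls_tikhonov <- function(A, y, lambda, AtA = NULL, Aty = NULL) {
  if (lambda < 0) stop("lambda must be non-negative")
  A <- unclass(A)
  if (is.null(AtA)) AtA <- crossprod(A)
  if (is.null(Aty)) Aty <- as.vector(crossprod(A, y))
  Q <- AtA
  if (lambda > 0) diag(Q) <- diag(Q) + lambda^2
  fnnls_cpp(Q, as.vector(Aty))
}

#' Logarithmically spaced regularisation ladder
#'
#' @param n Number of lambdas (default 16).
#' @param lo,hi Range of lambdas (defaults 1e-6 and 10).
#' @return Strictly increasing positive numeric vector.
#' @export
lambda_ladder <- function(n = 16L, lo = 1e-6, hi = 10) {
  if (n < 1) stop("n must be >= 1")
  if (lo <= 0 || hi < lo) stop("need 0 < lo <= hi")
  if (n == 1L) return(lo)
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Family of Tikhonov-NNLS solutions over a lambda ladder
#'
#' One \code{\link{nnls_tikhonov}} solve per ladder entry, with residual and
#' solution norms recorded. Residual norms are non-decreasing and solution
#' norms non-increasing along the ladder.
#'
#' @inheritParams nnls
#' @param ladder Strictly increasing positive lambdas.
#' @return Class \code{"regularized_family"}: list with \code{f} (n x N
#'   matrix of solutions), \code{lambda}, \code{residual_norm},
#'   \code{solution_norm}.
#' @export
regularized_family <- function(A, y, ladder) {
  if (any(ladder <= 0) || is.unsorted(ladder, strictly = TRUE))
    stop("ladder must be strictly increasing and positive")
  Au <- unclass(A)
  AtA <- crossprod(Au)
  Aty <- as.vector(crossprod(Au, y))
  N <- length(ladder)
  f <- matrix(0, ncol(Au), N)
  for (j in seq_len(N))
    f[, j] <- nnls_tikhonov(Au, y, ladder[j], AtA = AtA, Aty = Aty)
  structure(list(f = f,
                 lambda = ladder,
                 residual_norm = sqrt(colSums((Au %*% f - y)^2)),
                 solution_norm = sqrt(colSums(f^2))),
            class = "regularized_family")
}

#' @export
print.regularized_family <- function(x, ...) {
  cat(sprintf("regularised family: %d solutions, lambda in [%.3g, %.3g]\n",
              length(x$lambda), min(x$lambda), max(x$lambda)))
  invisible(x)
}

#' Discrepancy-principle selection of lambda
#'
#' Chooses lambda so that the fit residual matches the expected noise norm,
#' \eqn{\|A f_\lambda - y\|_2 = \nu \sqrt{m}\,\sigma}, by bisection on
#' log-lambda (the Tikhonov residual is monotone non-decreasing in lambda).
#' When the target residual lies below the residual of the least-regularised
#' solution, or above that of the most-regularised one, the corresponding
#' bracket endpoint is returned with a flag.
#'
#' @inheritParams nnls
#' @param sigma Noise RMS amplitude (> 0): the known simulation value, or a
#'   tail estimate from \code{\link{estimate_noise_sigma}} for real data.
#' @param nu Safety factor >= 1 (default 1.05).
#' @param bracket Bisection bracket for lambda; defaults to
#'   \code{c(1e-10, 1e4)} times the spectral norm of A, which spans the
#'   whole useful regularisation range of the exponential kernel.
#' @param tol Relative tolerance on the achieved residual (default 1e-3).
#' @param maxit Maximum bisection iterations.
#' @return List with \code{lambda}, \code{f}, \code{residual},
#'   \code{target}, and \code{flag} (\code{"ok"}, \code{"lambda_min"} or
#'   \code{"lambda_max"}).
#' @export
dp_select_lambda <- function(A, y, sigma, nu = 1.05, bracket = NULL,
                             tol = 1e-3, maxit = 200L) {
  if (sigma <= 0) stop("sigma must be positive")
  if (nu < 1) stop("nu must be >= 1")
  Au <- unclass(A)
  m <- nrow(Au)
  AtA <- crossprod(Au)
  Aty <- as.vector(crossprod(Au, y))
  target <- nu * sqrt(m) * sigma
  if (is.null(bracket)) {
    scale <- sqrt(max(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values))
    bracket <- c(1e-10, 1e4) * scale
  }
  resid_at <- function(lam) {
    f <- nnls_tikhonov(Au, y, lam, AtA = AtA, Aty = Aty)
    list(f = f, r = sqrt(sum((Au %*% f - y)^2)))
  }
  lo <- resid_at(bracket[1])
  if (lo$r >= target) {
    return(list(lambda = bracket[1], f = lo$f, residual = lo$r,
                target = target, flag = "lambda_min"))
  }
  hi <- resid_at(bracket[2])
  if (hi$r <= target) {
    return(list(lambda = bracket[2], f = hi$f, residual = hi$r,
                target = target, flag = "lambda_max"))
  }
  llo <- log(bracket[1]); lhi <- log(bracket[2])
  mid <- NULL
  for (it in seq_len(maxit)) {
    lmid <- (llo + lhi) / 2
    mid <- resid_at(exp(lmid))
    if (abs(mid$r - target) <= tol * target) break
    if (mid$r < target) llo <- lmid else lhi <- lmid
  }
  list(lambda = exp((llo + lhi) / 2), f = mid$f, residual = mid$r,
       target = target, flag = "ok")
}

#' Oracle lambda: minimiser of the true reconstruction error
#'
#' Simulation-only selector: scans the ladder for the lambda minimising
#' \eqn{\|f_\lambda - f_{true}\|_2}. Ties are broken towards the larger
#' lambda (more regularisation preferred at equal error).
#'
#' @inheritParams regularized_family
#' @param f_true Known ground-truth DF.
#' @return List with \code{lambda}, \code{index}, \code{errors}.
#' @export
oracle_lambda <- function(A, y, f_true, ladder) {
  fam <- regularized_family(A, y, ladder)
  errs <- sqrt(colSums((fam$f - f_true)^2))
  best <- max(which(errs <= min(errs) + 1e-15 * max(1, min(errs))))
  list(lambda = ladder[best], index = best, errors = errs, family = fam)
}

#' Simplex-constrained least squares
#'
#' Solves \eqn{\min_s \|B s\|_2} subject to \eqn{s \ge 0} and the last
#' \code{n_simplex} entries summing to one. This is the stacked SpanReg
#' weight problem: the first \code{n_free} entries are the non-negative
#' weights over the lambda ladder, the rest the simplex weights over the
#' dictionary. The default solver is a primal active-set quadratic program
#' that keeps the equality in every working set (exact to machine
#' precision); \code{method = "penalty"} instead appends a heavily weighted
#' constraint row to an NNLS solve, useful as an independent cross-check.
#'
#' @param B Matrix with \code{n_free + n_simplex} columns.
#' @param n_free Number of unconstrained non-negative variables (may be 0).
#' @param n_simplex Number of simplex variables (>= 1).
#' @param method \code{"qp"} (default) or \code{"penalty"}.
#' @param ridge Ridge added to the Gram matrix for uniqueness when it is
#'   singular; 0 disables, \code{NULL} (default) enables the automatic value
#'   \code{1e-12 * trace(B'B) / ncol(B)} only on singular working sets.
#' @param tol Feasibility/optimality tolerance.
#' @param maxit Maximum active-set iterations.
#' @return Non-negative vector s of length \code{n_free + n_simplex} whose
#'   trailing block sums to 1 (to 1e-8 or better), with attribute
#'   \code{"objective"} = \eqn{\|B s\|_2}.
#' @export
simplex_nnls <- function(B, n_free, n_simplex,
                         method = c("qp", "penalty"),
                         ridge = NULL, tol = 1e-12, maxit = NULL) {
  method <- match.arg(method)
  p <- n_free + n_simplex
  if (ncol(B) != p) stop("ncol(B) must equal n_free + n_simplex")
  if (n_simplex < 1) stop("n_simplex must be >= 1")
  Q <- crossprod(B)
  auto_ridge <- if (is.null(ridge)) 1e-12 * sum(diag(Q)) / p else ridge
  a <- c(rep(0, n_free), rep(1, n_simplex))

  s <- if (method == "penalty") {
    # penalty weight: large enough that the constraint violation before
    # renormalisation is negligible, small enough that the B block is not
    # lost to roundoff in the (squared) normal equations
    w2 <- (1e3 * max(sqrt(sum(B^2)), .Machine$double.eps))^2
    # default FNNLS tolerance scales with the penalty row; tie it to the
    # unpenalised gradient scale instead so the B block is resolved
    tol_pen <- 1e-6 * max(diag(Q), .Machine$double.xmin)
    s0 <- fnnls_cpp(Q + w2 * tcrossprod(a), w2 * a, tol = tol_pen)
    # the penalty row dominates the gradient scale, so polish the support
    # it found with one exact equality-constrained solve
    P <- s0 > 0
    if (any(P & a > 0)) {
      z <- eqp_solve(Q, a, P, auto_ridge)
      if (!is.null(z) && all(z$z >= -1e-10)) {
        s0 <- numeric(p); s0[P] <- pmax(z$z, 0)
      }
    }
    s0
  } else {
    simplex_qp_active_set(Q, a, n_free, n_simplex, auto_ridge, tol,
                          maxit %||% 100L * p)
  }
  # exact renormalisation of the simplex block (guards rounding)
  tot <- sum(s[n_free + seq_len(n_simplex)])
  if (tot > 0) s[n_free + seq_len(n_simplex)] <-
      s[n_free + seq_len(n_simplex)] / tot
  attr(s, "objective") <- sqrt(sum(as.vector(B %*% s)^2))
  s
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Equality-constrained subproblem: minimise 1/2 z'Q[P,P]z subject to
# a[P]'z = 1, via the KKT system. Returns z and the (sign-flipped)
# multiplier, or NULL when even the ridged/pseudo-inverse solve fails.
eqp_solve <- function(Q, a, Pset, auto_ridge) {
  k <- sum(Pset)
  Qpp <- Q[Pset, Pset, drop = FALSE]
  ap <- a[Pset]
  K <- rbind(cbind(Qpp, ap), c(ap, 0))
  rhs <- c(numeric(k), 1)
  sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) {
    K[seq_len(k), seq_len(k)] <- Qpp + diag(auto_ridge + 1e-300, k)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol)))
      sol <- tryCatch(c(MASS_ginv_solve(K, rhs)), error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol))) return(NULL)
  }
  list(z = sol[seq_len(k)], mu = sol[k + 1])
}

# Primal active-set QP for min 1/2 s'Qs  s.t. s >= 0, a's = 1, where a is
# the 0/1 indicator of the simplex block. The equality stays in every
# working set; bound constraints are handled Lawson-Hanson style.
simplex_qp_active_set <- function(Q, a, n_free, n_simplex, auto_ridge,
                                  tol, maxit) {
  p <- length(a)
  simplex_idx <- n_free + seq_len(n_simplex)
  # feasible start: best single simplex vertex
  i0 <- simplex_idx[which.min(diag(Q)[simplex_idx])]
  s <- numeric(p); s[i0] <- 1
  P <- logical(p); P[i0] <- TRUE
  gscale <- max(diag(Q), .Machine$double.xmin)
  for (it in seq_len(maxit)) {
    sol <- eqp_solve(Q, a, P, auto_ridge)
    if (is.null(sol)) break
    k <- sum(P)
    z <- numeric(p); z[P] <- sol$z
    mu <- sol$mu
    if (all(z[P] >= -tol * max(1, sum(abs(z[P]))))) {
      z[z < 0] <- 0
      s <- z
      g <- as.vector(Q %*% s)
      # KKT block gives Qz + mu*a = 0 on P, i.e. mu = -(true multiplier)
      r <- g + mu * a
      r[P] <- 0
      jmin <- which.min(r)
      if (r[jmin] >= -1e-9 * gscale) break
      P[jmin] <- TRUE
    } else {
      neg <- P & (z < 0)
      theta <- min(s[neg] / (s[neg] - z[neg]))
      s <- s + theta * (z - s)
      drop_i <- neg & (s <= tol)
      s[drop_i] <- 0
      P[drop_i] <- FALSE
      if (!any(P[simplex_idx])) {  # numerical guard; cannot happen exactly
        j <- simplex_idx[which.max(s[simplex_idx])]
        P[j] <- TRUE
      }
    }
  }
  s
}

# minimal pseudo-inverse solve without importing MASS
MASS_ginv_solve <- function(K, rhs) {
  sv <- svd(K)
  pos <- sv$d > max(sv$d) * 1e-12
  sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
}
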