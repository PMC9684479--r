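#' Gaussian density sampled on a T2 grid
#'
#' Evaluates the normal density
#' \eqn{(2\pi\sigma^2)^{-1/2} \exp(-(T_2-\mu)^2 / 2\sigma^2)} on the grid.
#' This is the atom shape used both for the dictionary and for the
#' simulation phantoms.
#'
#' @param mu Mean in ms.
#' @param sd Standard deviation in ms (> 0).
#' @param grid A \code{\link{t2_grid}}.
#' @return Density values (per ms) on the grid.
#' @export
gaussian_density <- function(mu, sd, grid) {
  if (sd <= 0) stop("sd must be positive")
  stats::dnorm(grid$values, mean = mu, sd = sd)
}

#' Specification of one Gaussian dictionary family
#'
#' A family is a set of atoms sharing one SD with means equally spaced
#' across the T2 range (endpoints included).
#'
#' @param count Number of members (>= 1).
#' @param sd Standard deviation in ms (> 0).
#' @return List of class \code{"gaussian_family"}.
#' @export
gaussian_family <- function(count, sd) {
  if (count < 1) stop("count must be >= 1")
  if (sd <= 0) stop("sd must be positive")
  structure(list(count = as.integer(count), sd = sd),
            class = "gaussian_family")
}

#' Default dictionary specification
#'
#' Three families: 160 members at SD 2 ms, 40 at SD 3 ms and 20 at SD 4 ms,
#' for M = 220 atoms in total.
#'
#' @return List of \code{\link{gaussian_family}} objects.
#' @export
default_families <- function() {
  list(gaussian_family(160, 2), gaussian_family(40, 3), gaussian_family(20, 4))
}

#' Build a Gaussian dictionary
#'
#' For each family, atom means are placed at \code{count} equally spaced
#' positions spanning the grid bounds inclusively. Each column is the
#' Gaussian density sampled on the grid and then renormalised to unit
#' discrete area, so that the simplex constraint on dictionary weights
#' keeps its probability interpretation even for edge-truncated atoms.
#'
#' @param grid A \code{\link{t2_grid}}.
#' @param families List of \code{\link{gaussian_family}} specs; defaults to
#'   \code{\link{default_families}}.
#' @return Class \code{"gaussian_dictionary"}: list with \code{G} (n x M
#'   matrix, unit-area non-negative columns), \code{mu}, \code{sd}
#'   (length-M vectors), \code{M}, \code{grid}.
#' @examples
#' D <- build_dictionary(t2_grid(200, 1, 200))
#' D$M  # 220
#' @export
build_dictionary <- function(grid, families = default_families()) {
  if (!inherits(grid, "t2_grid")) stop("grid must be a t2_grid")
  if (length(families) == 0) stop("families must be non-empty")
  delta <- rep_len(grid$delta, grid$n)
  mu <- numeric(0); sd <- numeric(0)
  for (fam in families) {
    if (!inherits(fam, "gaussian_family")) fam <- do.call(gaussian_family, fam)
    if (fam$sd < min(delta) / 2)
      warning(sprintf("family SD %.3g ms is under-resolved on a grid with spacing %.3g ms",
                      fam$sd, min(delta)))
    means <- if (fam$count == 1L) mean(grid$bounds) else
      seq(grid$bounds[1], grid$bounds[2], length.out = fam$count)
    mu <- c(mu, means)
    sd <- c(sd, rep(fam$sd, fam$count))
  }
  G <- vapply(seq_along(mu),
              function(i) gaussian_density(mu[i], sd[i], grid),
              numeric(grid$n))
  area <- colSums(G * delta)
  if (any(area <= 0)) stop("dictionary contains an all-zero column")
  G <- sweep(G, 2, area, `/`)
  structure(list(G = G, mu = mu, sd = sd, M = length(mu), grid = grid),
            class = "gaussian_dictionary")
}

#' @export
print.gaussian_dictionary <- function(x, ...) {
  cat(sprintf("Gaussian dictionary: M = %d atoms, SDs {%s} ms, on %d-point grid\n",
              x$M, paste(sort(unique(x$sd)), collapse = ", "), x$grid$n))
  invisible(x)
}

#' Minimum (mu, sd) distance between a Gaussian component and the dictionary
#'
#' Simulation phantoms must not coincide with dictionary atoms (that would
#' make recovery trivial); this returns
#' \code{min_i (|mu - mu_i| + |sd - sd_i|)} for checking.
#'
#' @param mu,sd Component parameters in ms.
#' @param dictionary A \code{\link{build_dictionary}} result.
#' @return Non-negative scalar; 0 means exact coincidence.
#' @export
dictionary_distance <- function(mu, sd, dictionary) {
  min(abs(mu - dictionary$mu) + abs(sd - dictionary$sd))
}
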