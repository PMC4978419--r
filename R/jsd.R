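# Jensen-Shannon distances between spectral density profiles.

#' Jensen-Shannon divergence between two discrete distributions
#'
#' `JSD(p, q) = H(m) - (H(p) + H(q))/2` with `m = (p + q)/2` and Shannon
#' entropy in nats, so the divergence is symmetric and bounded by `ln 2`.
#' Inputs are renormalized to sum 1.
#'
#' @param p,q nonnegative numeric vectors of equal length.
#' @return a scalar in `[0, log(2)]`.
#' @export
#' @examples
#' js_divergence(c(0.5, 0.5), c(0.9, 0.1))
js_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) stop("negative probabilities")
  sp <- sum(p); sq <- sum(q)
  if (sp <= 0 || sq <= 0) stop("empty (all-zero) density")
  p <- p / sp; q <- q / sq
  m <- (p + q) / 2
  shannon_entropy(m) - (shannon_entropy(p) + shannon_entropy(q)) / 2
}

# Evaluate a profile's stored density on an arbitrary grid (linear
# interpolation, zero outside the stored support).
profile_density_on <- function(profile, grid) {
  d <- profile$density
  if (is.null(d) || length(d$x) == 0) stop("profile carries no density grid")
  stats::approx(d$x, d$y, xout = grid, yleft = 0, yright = 0)$y
}

# Shared evaluation grid spanning the union of supports of a profile list.
shared_grid <- function(profiles, n_grid = 1024L) {
  lo <- min(vapply(profiles, function(p) min(p$density$x), 0))
  hi <- max(vapply(profiles, function(p) max(p$density$x), 0))
  seq(lo, hi, length.out = n_grid)
}

# Row-normalized matrix of profile densities on the shared grid.
profile_density_matrix <- function(profiles, n_grid = 1024L) {
  grid <- shared_grid(profiles, n_grid)
  g <- t(vapply(profiles, profile_density_on, numeric(n_grid), grid = grid))
  rs <- rowSums(g)
  if (any(rs <= 0)) stop("empty density in at least one profile")
  g / rs
}

#' Jensen-Shannon distance between two spectral profiles
#'
#' Both densities are re-evaluated on a shared uniform grid spanning the
#' union of their supports, renormalized, and compared with
#' [js_divergence()].
#'
#' @param p,q objects of class `"spectral_profile"` (or any list carrying a
#'   `density` element with `x` and `y`).
#' @param n_grid number of shared grid points.
#' @return a scalar in `[0, log(2)]`.
#' @export
js_distance <- function(p, q, n_grid = 1024L) {
  g <- profile_density_matrix(list(p, q), n_grid)
  js_divergence(g[1L, ], g[2L, ])
}

# All-pairs JSD between rows of a row-stochastic matrix; vectorized over
# the second index.
jsd_pairwise <- function(g) {
  n <- nrow(g)
  h <- apply(g, 1L, shannon_entropy)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    m <- (g[rest, , drop = FALSE] +
            matrix(g[i, ], length(rest), ncol(g), byrow = TRUE)) / 2
    lm <- m; lm[m > 0] <- log(m[m > 0]); lm[m == 0] <- 0
    hm <- -rowSums(m * lm)
    d[i, rest] <- d[rest, i] <- pmax(0, hm - (h[i] + h[rest]) / 2)
  }
  d
}

#' Pairwise Jensen-Shannon distance matrix of a profile list
#'
#' @param profiles a list of `"spectral_profile"` objects.
#' @param labels optional character labels (defaults to profile labels or
#'   an index); must be unique.
#' @param n_grid number of shared grid points.
#' @return an object of class `"profile_dist"`: a list with `labels` and
#'   the symmetric `distances` matrix.
#' @export
profile_distance_matrix <- function(profiles, labels = NULL, n_grid = 1024L) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  if (is.null(labels)) {
    labels <- vapply(profiles, function(p)
      if (!is.null(p$label) && !is.na(p$label)) p$label else NA_character_,
      character(1))
    if (anyNA(labels)) labels <- as.character(seq_along(profiles))
  }
  if (anyDuplicated(labels)) stop("duplicate profile labels")
  g <- profile_density_matrix(profiles, n_grid)
  d <- jsd_pairwise(g)
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, distances = d, grid_densities = g),
            class = "profile_dist")
}

#' @export
print.profile_dist <- function(x, ...) {
  cat(sprintf("profile_dist: %d profiles, JSD range [%.4g, %.4g]\n",
              length(x$labels), min(x$distances[upper.tri(x$distances)]),
              max(x$distances)))
  invisible(x)
}
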