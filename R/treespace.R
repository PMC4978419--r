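# Phylogenetic space: mapping profiles to (lambda*, psi, eta) points,
# trade-off regressions between the statistics, bounding-box volumes, and
# per-type convex-hull regions.

#' Map spectral profiles into phylogenetic space
#'
#' One point per profile, with coordinates `lambda_star`, `psi`, `eta`
#' copied verbatim from the profiles.
#'
#' @param profiles list of `"spectral_profile"` objects.
#' @param labels optional character labels (default: profile labels or
#'   indices).
#' @param cluster optional cluster ids aligned with profiles.
#' @param taxon_class optional class labels aligned with profiles.
#' @return a data.frame with columns `label`, `lambda_star`, `psi`, `eta`,
#'   and optionally `cluster` and `taxon_class`.
#' @export
map_points <- function(profiles, labels = NULL, cluster = NULL,
                       taxon_class = NULL) {
  if (is.null(labels)) {
    labels <- vapply(profiles, function(p)
      if (!is.null(p$label) && !is.na(p$label)) p$label else NA_character_,
      character(1))
    if (anyNA(labels)) labels <- as.character(seq_along(profiles))
  }
  pts <- data.frame(
    label = labels,
    lambda_star = vapply(profiles, `[[`, 0, "lambda_star"),
    psi = vapply(profiles, `[[`, 0, "psi"),
    eta = vapply(profiles, `[[`, 0, "eta"),
    stringsAsFactors = FALSE)
  bad <- !stats::complete.cases(pts[, c("lambda_star", "psi", "eta")]) |
    !is.finite(pts$lambda_star) | !is.finite(pts$psi) | !is.finite(pts$eta)
  if (any(bad))
    stop("non-finite summary statistic for tree(s): ",
         paste(labels[bad], collapse = ", "))
  if (!is.null(cluster)) pts$cluster <- cluster
  if (!is.null(taxon_class)) pts$taxon_class <- taxon_class
  pts
}

# Extract the numeric coordinate matrix from a map_points() data.frame or a
# bare matrix.
space_coords <- function(points) {
  if (is.data.frame(points)) {
    cols <- intersect(c("lambda_star", "psi", "eta"), names(points))
    if (length(cols) >= 2L) return(as.matrix(points[, cols]))
    return(as.matrix(points[vapply(points, is.numeric, TRUE)]))
  }
  as.matrix(points)
}

#' Pairwise trade-off regressions between space coordinates
#'
#' For every ordered pair of summary statistics, fits the candidate forms
#' linear, logarithmic (skipped when the predictor takes non-positive
#' values), quadratic and cubic, and keeps the form with the lowest AIC.
#' An intercept-only null model competes as well; the selected form is
#' flagged significant only when it beats the null on AIC *and* its F-test
#' p-value clears `alpha` after Bonferroni correction for the number of
#' candidate forms tried.
#'
#' @param points a [map_points()] data.frame (or coordinate matrix).
#' @param alpha significance level before the multiple-form correction.
#' @return a data.frame with one row per ordered pair: selected form,
#'   coefficients (as a formatted string), `r_squared`, `p_value`,
#'   `significant`.
#' @export
tradeoff_regressions <- function(points, alpha = 0.05) {
  x <- space_coords(points)
  if (nrow(x) < 10L) stop("need at least 10 points")
  vars <- colnames(x)
  out <- list()
  for (resp in vars) for (pred in setdiff(vars, resp)) {
    fit <- select_form(x[, pred], x[, resp], alpha = alpha)
    out[[length(out) + 1L]] <- data.frame(
      response = resp, predictor = pred, form = fit$form,
      coefficients = fit$coef_string, r_squared = fit$r_squared,
      p_value = fit$p_value, significant = fit$significant,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Candidate-form selection by AIC with an intercept-only null; shared by
# the trade-off and trajectory regressions.
select_form <- function(x, y, alpha = 0.05, forms = c("linear", "logarithmic",
                                                      "quadratic", "cubic")) {
  if (stats::sd(y) == 0)
    return(list(form = "none", coef_string = "", r_squared = 0, p_value = 1,
                significant = FALSE, model = NULL))
  d <- data.frame(x = x, y = y)
  models <- list(null = stats::lm(y ~ 1, data = d))
  if ("linear" %in% forms) models$linear <- stats::lm(y ~ x, data = d)
  if ("logarithmic" %in% forms && all(x > 0))
    models$logarithmic <- stats::lm(y ~ log(x), data = d)
  if ("quadratic" %in% forms)
    models$quadratic <- stats::lm(y ~ x + I(x^2), data = d)
  if ("cubic" %in% forms)
    models$cubic <- stats::lm(y ~ x + I(x^2) + I(x^3), data = d)
  aics <- vapply(models, stats::AIC, 0)
  best <- names(which.min(aics))
  n_forms <- length(models) - 1L
  if (best == "null")
    return(list(form = "none", coef_string = "", r_squared = 0, p_value = 1,
                significant = FALSE, model = models$null))
  m <- models[[best]]
  sm <- summary(m)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  list(form = best,
       coef_string = paste(sprintf("%s=%.4g", names(stats::coef(m)),
                                   stats::coef(m)), collapse = ", "),
       coefficients = stats::coef(m),
       r_squared = sm$r.squared,
       p_value = unname(p),
       significant = unname(p) < alpha / n_forms,
       model = m)
}

#' Bounding-box occupancy and overlap of two point sets
#'
#' `occupancy_pct` is the volume of the axis-aligned bounding box of `setA`
#' as a percentage of the bounding-box volume of `setB` (e.g. empirical
#' trees inside the space charted by simulated trees).  `overlap_pct` is
#' the intersection volume of the two boxes over their union volume, as a
#' percentage.
#'
#' @param setA,setB coordinate matrices/data.frames (same dimension).
#' @return list with `occupancy_pct` and `overlap_pct`.
#' @export
volume_stats <- function(setA, setB) {
  a <- space_coords(setA); b <- space_coords(setB)
  stopifnot(ncol(a) == ncol(b))
  box <- function(x) list(lo = apply(x, 2L, min), hi = apply(x, 2L, max))
  vol <- function(bx) prod(bx$hi - bx$lo)
  ba <- box(a); bb <- box(b)
  va <- vol(ba); vb <- vol(bb)
  if (va <= 0 || vb <= 0)
    stop("degenerate (zero-volume) bounding box along at least one axis")
  ilo <- pmax(ba$lo, bb$lo); ihi <- pmin(ba$hi, bb$hi)
  vi <- if (all(ihi > ilo)) prod(ihi - ilo) else 0
  list(occupancy_pct = 100 * va / vb,
       overlap_pct = 100 * vi / (va + vb - vi))
}

#' Convex-hull regions for each diversification type
#'
#' Builds a 3-D convex hull around the points of each cluster; clusters
#' with fewer than 4 points (or degenerate geometry) are flagged and
#' skipped.
#'
#' @param points a [map_points()] data.frame carrying a `cluster` column.
#' @return an object of class `"type_hulls"`: list of per-cluster hulls
#'   plus `skipped` (cluster ids without a hull).
#' @export
type_hulls <- function(points) {
  stopifnot(is.data.frame(points), "cluster" %in% names(points))
  x <- space_coords(points)
  hulls <- list(); skipped <- character(0)
  for (cl in sort(unique(points$cluster))) {
    xi <- x[points$cluster == cl, , drop = FALSE]
    h <- if (nrow(xi) >= 4L)
      tryCatch(convex_hull_3d(xi), error = function(e) NULL) else NULL
    if (is.null(h)) skipped <- c(skipped, as.character(cl))
    else hulls[[as.character(cl)]] <- h
  }
  structure(list(hulls = hulls, skipped = skipped), class = "type_hulls")
}

#' Assign points to diversification-type regions
#'
#' A query point inside exactly one hull takes that type; inside several,
#' the type with the nearest hull centroid; inside none, `NA`.
#'
#' @param hulls a [type_hulls()] result.
#' @param query a matrix/data.frame of 3-D query points.
#' @param tol membership tolerance passed to the hull test.
#' @return character vector of type ids (or `NA`).
#' @export
assign_to_hulls <- function(hulls, query, tol = 1e-8) {
  q <- space_coords(query)
  ids <- names(hulls$hulls)
  inside <- vapply(ids, function(id)
    hull_contains(hulls$hulls[[id]], q, tol = tol), logical(nrow(q)))
  inside <- matrix(inside, nrow = nrow(q))
  out <- rep(NA_character_, nrow(q))
  for (i in seq_len(nrow(q))) {
    hit <- ids[inside[i, ]]
    if (length(hit) == 1L) out[i] <- hit
    else if (length(hit) > 1L) {
      cd <- vapply(hit, function(id)
        sum((q[i, ] - hulls$hulls[[id]]$centroid)^2), 0)
      out[i] <- hit[which.min(cd)]
    }
  }
  out
}
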