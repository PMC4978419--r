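# Average trajectories through phylogenetic space over crown age: trees are
# binned by age with Fisher-Jenks natural breaks, each bin contributes the
# arithmetic mean of (lambda*, psi, eta), bins are assigned to
# diversification-type regions, and per-statistic age regressions are
# selected by AIC among polynomial forms.

#' Fisher-Jenks natural breaks of a numeric vector
#'
#' Exact dynamic-programming optimization of the within-class sum of
#' squared deviations (the natural-breaks criterion).  With `k = NULL` the
#' number of classes is chosen automatically: the smallest `k` whose
#' goodness-of-variance fit (1 - SSD_k / SSD_1) reaches `gvf_min`, capped
#' at `k_max`.
#'
#' @param values numeric vector.
#' @param k number of classes, or `NULL` for automatic selection.
#' @param gvf_min goodness-of-variance-fit threshold for automatic `k`.
#' @param k_max cap on the automatic class count (default 7).
#' @return a list with `breaks` (boundary values: min, k-1 cut points,
#'   max), `assignment` (class index per input value, in input order), `k`,
#'   and `gvf`.
#' @export
#' @examples
#' jenks_breaks(c(1, 2, 3, 100, 101, 102), k = 2)
jenks_breaks <- function(values, k = NULL, gvf_min = 0.9, k_max = 7L) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (!is.null(k)) {
    if (k > length(unique(values)))
      stop("k exceeds the number of distinct values")
    res <- jenks_dp(values, k)
    res$gvf <- jenks_gvf(values, res$assignment)
    return(res)
  }
  kk <- 1L
  repeat {
    res <- jenks_dp(values, kk)
    gvf <- jenks_gvf(values, res$assignment)
    if (gvf >= gvf_min || kk >= min(k_max, length(unique(values)))) {
      res$gvf <- gvf
      return(res)
    }
    kk <- kk + 1L
  }
}

# Exact DP over sorted values: cost(i, j) = SSD of values i..j via prefix
# sums; classes are contiguous runs of the sorted order.
jenks_dp <- function(values, k) {
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssd <- function(i, j) {  # 1-based inclusive
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  cost <- matrix(Inf, k, n)   # cost[c, j]: best SSD for x[1..j] in c classes
  back <- matrix(0L, k, n)
  for (j in seq_len(n)) cost[1L, j] <- ssd(1L, j)
  if (k > 1L) for (cc in 2:k) for (j in cc:n) {
    for (i in cc:j) {  # class cc covers x[i..j]
      v <- cost[cc - 1L, i - 1L] + ssd(i, j)
      if (v < cost[cc, j]) { cost[cc, j] <- v; back[cc, j] <- i }
    }
  }
  # recover boundaries
  bounds <- integer(k + 1L); bounds[k + 1L] <- n
  j <- n
  if (k > 1L) for (cc in k:2) {
    i <- back[cc, j]
    bounds[cc] <- i - 1L
    j <- i - 1L
  }
  bounds[1L] <- 0L
  cls_sorted <- integer(n)
  for (cc in seq_len(k)) cls_sorted[(bounds[cc] + 1L):bounds[cc + 1L]] <- cc
  assignment <- integer(n)
  assignment[ord] <- cls_sorted
  breaks <- c(x[1L], x[bounds[2:(k + 1L)]])
  list(breaks = breaks, assignment = assignment, k = k,
       within_ssd = cost[k, n])
}

jenks_gvf <- function(values, assignment) {
  ssd_tot <- sum((values - mean(values))^2)
  if (ssd_tot == 0) return(1)
  ssd_w <- sum(unlist(lapply(split(values, assignment),
                             function(v) sum((v - mean(v))^2))))
  1 - ssd_w / ssd_tot
}

#' Average trajectory through phylogenetic space over crown age
#'
#' Bins trees by crown age (natural breaks), computes per-bin arithmetic
#' means of the three summary statistics, assigns each bin mean to a
#' diversification-type region (hull membership, or nearest hull centroid
#' when the mean falls in no hull), and reports the median tree of each bin
#' (the tree nearest the bin mean in min-max-normalized coordinates; ties
#' break by label order).
#'
#' @param points a [map_points()] data.frame.
#' @param ages numeric crown ages aligned with `points` rows.
#' @param hulls optional [type_hulls()] result for type assignment.
#' @param k,gvf_min,k_max passed to [jenks_breaks()].
#' @return a list with `bins` (data.frame: bin, age range, n, mean
#'   coordinates, assigned type, median tree label), `assignment` (bin per
#'   tree), `breaks`, `k`, `gvf`.
#' @export
trajectory_through_space <- function(points, ages, hulls = NULL, k = NULL,
                                     gvf_min = 0.9, k_max = 7L) {
  stopifnot(nrow(points) == length(ages))
  jb <- jenks_breaks(ages, k = k, gvf_min = gvf_min, k_max = k_max)
  x <- space_coords(points)
  xn <- normalize_minmax(x)
  bins <- list()
  for (bb in seq_len(jb$k)) {
    idx <- which(jb$assignment == bb)
    if (length(idx) == 0L) stop("empty age bin ", bb)
    mu <- colMeans(x[idx, , drop = FALSE])
    mun <- colMeans(xn[idx, , drop = FALSE])
    dist_n <- sqrt(rowSums(sweep(xn[idx, , drop = FALSE], 2L, mun, "-")^2))
    med_label <- points$label[idx[order(dist_n, points$label[idx])[1L]]]
    type <- NA_character_
    if (!is.null(hulls)) {
      type <- assign_to_hulls(hulls, matrix(mu, 1L))
      if (is.na(type) && length(hulls$hulls)) {
        cd <- vapply(hulls$hulls, function(h) sum((mu - h$centroid)^2), 0)
        type <- names(hulls$hulls)[which.min(cd)]
      }
    }
    bins[[bb]] <- data.frame(
      bin = bb, age_min = min(ages[idx]), age_max = max(ages[idx]),
      mean_age = mean(ages[idx]), n = length(idx),
      lambda_star = unname(mu[1L]), psi = unname(mu[2L]),
      eta = unname(mu[3L]),
      type = type, median_tree = med_label, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, bins)
  rownames(out) <- NULL
  list(bins = out, assignment = jb$assignment,
       breaks = jb$breaks, k = jb$k, gvf = jb$gvf)
}

#' Per-statistic regressions of space coordinates on crown age
#'
#' For each of the three summary statistics, fits polynomials in age up to
#' cubic plus an intercept-only null, selects by AIC, and reports the
#' selected form with its fit statistics.  A statistic whose best model is
#' the null (or whose F-test does not clear the Bonferroni-adjusted level)
#' is reported as having no significant trend.
#'
#' @param points a [map_points()] data.frame.
#' @param ages numeric crown ages aligned with `points`.
#' @param alpha significance level before the multiple-form correction.
#' @return a data.frame, one row per statistic: form, coefficients,
#'   `r_squared`, `p_value`, `significant`.
#' @export
trajectory_regressions <- function(points, ages, alpha = 0.05) {
  x <- space_coords(points)
  if (nrow(x) < 10L) stop("need at least 10 trees")
  out <- list()
  for (v in colnames(x)) {
    fit <- select_form(ages, x[, v], alpha = alpha,
                       forms = c("linear", "quadratic", "cubic"))
    out[[length(out) + 1L]] <- data.frame(
      statistic = v, form = fit$form, coefficients = fit$coef_string,
      r_squared = fit$r_squared, p_value = fit$p_value,
      significant = fit$significant, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
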