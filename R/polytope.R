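# Archetypal (polytope) analysis of phylogenetic space.
#
# The geometry of the point cloud in (lambda*, psi, eta) space is described
# by the polytope with the fewest vertices (archetypes) that explains most
# of the variance.  Fitting is archetypal-analysis-style alternating
# optimization (archetypes constrained to convex combinations of the data,
# points approximated by convex combinations of archetypes), followed by a
# minimal inflation step so the selected polytope encloses the data --
# "vertices enclose (approximately) all points with minimal volume" is the
# contract, not a specific published algorithm.  Significance of a k-vertex
# fit is assessed with a t-ratio test (hull volume over polytope volume)
# against axis-shuffled null data.

# --- simplex tools --------------------------------------------------------

# Euclidean projection of each row of x onto the probability simplex
# (Duchi et al. thresholding), vectorized across rows: one global order()
# sorts all rows at once, and the cumulative sums loop over the (small)
# number of columns.
project_simplex_rows <- function(x) {
  n <- nrow(x); k <- ncol(x)
  if (k == 1L) return(matrix(1, n, 1L))
  u <- matrix(x[order(row(x), -x)], n, k, byrow = TRUE)
  css <- u
  for (j in 2:k) css[, j] <- css[, j - 1L] + u[, j]
  jj <- matrix(seq_len(k), n, k, byrow = TRUE)
  rho <- rowSums(u - (css - 1) / jj > 0)
  theta <- (css[cbind(seq_len(n), rho)] - 1) / rho
  pmax(x - theta, 0)
}

# Greedy row matching: reorder the rows of `a` so row i is the one nearest
# row i of `ref` (keeps archetype labels stable when the enclosing
# refinement replaces the fitted vertices).
reorder_like <- function(a, ref) {
  k <- nrow(a)
  out <- matrix(NA_real_, k, ncol(a))
  used <- rep(FALSE, k)
  for (i in seq_len(k)) {
    d <- rowSums(sweep(a, 2L, ref[i, ], "-")^2)
    d[used] <- Inf
    j <- which.min(d)
    out[i, ] <- a[j, ]
    used[j] <- TRUE
  }
  out
}

# Indices of the extreme points (convex hull vertices) of a point cloud;
# archetypes constrained to conv(data) can restrict their weights to these
# without changing the feasible set.
extreme_point_ids <- function(x) {
  d <- ncol(x)
  ids <- tryCatch({
    if (d == 2L) grDevices::chull(x[, 1L], x[, 2L])
    else if (d == 3L) convex_hull_3d(x)$vertex_ids
    else seq_len(nrow(x))
  }, error = function(e) seq_len(nrow(x)))
  sort(unique(ids))
}

# min ||X - S Z||^2 over row-stochastic S via projected gradient.
solve_stochastic <- function(x, z, s = NULL, steps = 12L) {
  n <- nrow(x); k <- nrow(z)
  if (is.null(s)) s <- matrix(1 / k, n, k)
  g <- z %*% t(z)
  lip <- 2 * max(eigen(g, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  xz <- x %*% t(z)
  for (i in seq_len(steps)) {
    grad <- 2 * (s %*% g - xz)
    s <- project_simplex_rows(s - grad / lip)
  }
  s
}

# --- archetypal fit -------------------------------------------------------

# Furthest-sum initialization: greedy selection of k mutually distant points.
furthest_init <- function(x, k, seed) {
  n <- nrow(x)
  with_seed(seed, {
    idx <- sample.int(n, 1L)
    for (i in seq_len(k - 1L)) {
      d <- rowSums((x - matrix(colMeans(x[idx, , drop = FALSE]), n, ncol(x),
                               byrow = TRUE))^2)
      dmin <- apply(vapply(idx, function(j)
        rowSums(sweep(x, 2L, x[j, ], "-")^2), numeric(n)), 1L, min)
      dmin[idx] <- -Inf
      idx <- c(idx, which.max(dmin))
    }
  })
  idx
}

# Alternating archetypal analysis with archetypes Z = B Xc (B
# row-stochastic over the extreme points Xc of the data, which span the
# same convex hull as the full cloud) and point weights S (row-stochastic
# over archetypes).  Returns archetypes, weights, SSE, and explained
# variance.
archetypal_fit <- function(x, k, seed = 1L, outer = 40L, pg_steps = 10L,
                           init_b = NULL, cand = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1L || n < k + 1L) stop("need at least k + 1 points")
  sstot <- sum(sweep(x, 2L, colMeans(x), "-")^2)
  if (k == 1L) {
    z <- matrix(colMeans(x), 1L, ncol(x))
    return(list(archetypes = z, weights = matrix(1, n, 1L),
                sse = sstot, explained_variance = 0, cand = cand))
  }
  if (is.null(cand)) cand <- extreme_point_ids(x)
  if (length(cand) < k) cand <- seq_len(n)
  xc <- x[cand, , drop = FALSE]
  m <- nrow(xc)
  if (is.null(init_b)) {
    idx <- furthest_init(xc, min(k, m), seed)
    b <- matrix(1e-6, k, m)
    b[cbind(seq_len(k), idx[((seq_len(k) - 1L) %% length(idx)) + 1L])] <- 1
    b <- b / rowSums(b)
  } else b <- init_b
  s <- NULL
  sig1c2 <- svd(xc, nu = 0, nv = 0)$d[1L]^2
  for (it in seq_len(outer)) {
    z <- b %*% xc
    s <- solve_stochastic(x, z, s, steps = pg_steps)
    # B-update: projected gradient of ||X - S B Xc||^2 wrt B
    sts <- crossprod(s)
    lip <- 2 * max(eigen(sts, symmetric = TRUE, only.values = TRUE)$values,
                   1e-12) * max(sig1c2, 1e-12)
    grad <- 2 * (sts %*% b %*% xc - crossprod(s, x)) %*% t(xc)
    b <- project_simplex_rows(b - grad / lip)
  }
  z <- b %*% xc
  s <- solve_stochastic(x, z, s, steps = 4L * pg_steps)
  sse <- sum((x - s %*% z)^2)
  list(archetypes = z, weights = s, sse = sse,
       explained_variance = 1 - sse / sstot, b = b, cand = cand)
}

# Minimal-volume enclosing simplex refinement for k <= d + 1 vertices:
# work in affine (generalized barycentric) coordinates w of the points with
# respect to the vertex set; points off the simplex's affine span only
# contribute their in-span component (relevant when a triangle is fitted to
# near-planar 3-D data).  Step 1 inflates the simplex about its centroid by
# the smallest factor enclosing every point (coordinate map w -> w/f +
# (1 - 1/f)/k gives the closed form f = max(1, 1 - k min(w))).  Step 2
# repeatedly shrinks each vertex toward the centroid of the others as far
# as the coordinates allow (shrinking vertex i by s maps w_i -> w_i/s and
# w_j -> w_j - w_i (1-s)/(s (k-1)), so feasibility requires
# s >= w_i / ((k-1) w_j + w_i) over all points and j != i), which
# monotonically reduces the volume while keeping every point enclosed.
enclose_simplex <- function(x, z, sweeps = 30L, slack = 1e-9) {
  k <- nrow(z); d <- ncol(z)
  n <- nrow(x)
  stopifnot(k <= d + 1L)
  amat <- rbind(t(z), rep(1, k))
  rhs <- rbind(t(x), rep(1, n))
  w <- solve(crossprod(amat), crossprod(amat, rhs))  # k x n affine coords
  f <- max(1, 1 - k * min(w)) * (1 + slack)
  cen <- colMeans(z)
  z <- sweep(sweep(z, 2L, cen, "-") * f, 2L, cen, "+")
  w <- w / f + (1 - 1 / f) / k
  w <- pmax(w, 0)
  for (sw in seq_len(sweeps)) {
    for (i in seq_len(k)) {
      wi <- w[i, ]
      wj <- w[-i, , drop = FALSE]
      s_req <- matrix(wi, k - 1L, n, byrow = TRUE) /
        ((k - 1L) * wj + matrix(wi, k - 1L, n, byrow = TRUE))
      s_req[!is.finite(s_req)] <- 0
      s <- min(1, max(0, max(s_req)) * (1 + slack) + slack)
      if (s >= 1) next
      ci <- colMeans(z[-i, , drop = FALSE])
      z[i, ] <- ci + s * (z[i, ] - ci)
      w[-i, ] <- pmax(wj - matrix(wi * (1 - s) / (s * (k - 1L)),
                                  k - 1L, n, byrow = TRUE), 0)
      w[i, ] <- wi / s
    }
  }
  z
}

# Minimal-area enclosing triangle in 2-D via support-line angles.  A
# triangle of outward support lines (direction theta_i: the line
# n_i . x = max over hull points of n_i . p) always contains the data, and
# the minimal enclosing triangle has at least one side flush with a hull
# edge, so the search fixes one angle at each hull-edge normal in turn and
# optimizes the other two numerically; a final free optimization over all
# three angles polishes the best start.
min_enclosing_triangle <- function(pts, starts_cap = 16L, maxit = 200L,
                                   tol = 1e-9) {
  hp <- pts[grDevices::chull(pts[, 1L], pts[, 2L]), , drop = FALSE]
  h <- nrow(hp)
  scale <- max(1, max(abs(hp)))
  tri_from <- function(th) {
    nm <- cbind(cos(th), sin(th))
    cv <- vapply(1:3, function(i) max(hp %*% nm[i, ]), 0)
    v <- matrix(NA_real_, 3L, 2L)
    pair <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))
    for (e in 1:3) {
      i <- pair[e, 1L]; j <- pair[e, 2L]
      dd <- nm[i, 1L] * nm[j, 2L] - nm[j, 1L] * nm[i, 2L]
      if (abs(dd) < 1e-12) return(NULL)
      v[e, ] <- c(cv[i] * nm[j, 2L] - cv[j] * nm[i, 2L],
                  nm[i, 1L] * cv[j] - nm[j, 1L] * cv[i]) / dd
    }
    # the half-plane intersection is this triangle only if every computed
    # vertex satisfies the remaining constraint
    third <- c(3L, 1L, 2L)
    for (e in 1:3)
      if (sum(nm[third[e], ] * v[e, ]) > cv[third[e]] + tol * scale)
        return(NULL)
    v
  }
  area_of <- function(th) {
    v <- tri_from(th)
    if (is.null(v)) return(.Machine$double.xmax)
    polygon_area(v)
  }
  # outward normal angle of each hull edge (chull order is clockwise)
  nxt <- c(seq_len(h)[-1L], 1L)
  edges <- atan2(hp[nxt, 1L] - hp[, 1L], -(hp[nxt, 2L] - hp[, 2L]))
  # make sure the normal points away from the hull interior
  cen <- colMeans(hp)
  flip <- (cos(edges) * (hp[, 1L] - cen[1L]) +
             sin(edges) * (hp[, 2L] - cen[2L])) < 0
  edges[flip] <- edges[flip] + pi
  if (length(edges) > starts_cap)
    edges <- edges[round(seq(1L, length(edges), length.out = starts_cap))]
  best_th <- NULL; best_area <- Inf
  for (te in edges) {
    opt <- stats::optim(c(te + 2 * pi / 3, te - 2 * pi / 3),
                        function(t23) area_of(c(te, t23)),
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (opt$value < best_area) {
      best_area <- opt$value
      best_th <- c(te, opt$par)
    }
  }
  opt <- stats::optim(best_th, area_of, method = "Nelder-Mead",
                      control = list(maxit = 2L * maxit, reltol = 1e-12))
  if (opt$value < best_area) best_th <- opt$par
  tri_from(best_th)
}

# Inflate vertices about their centroid by the smallest factor that brings
# every point inside the polytope (within tol); used for vertex counts
# beyond d + 1, where the simplex refinement above does not apply.
# Bisection on the factor with membership tested by simplex-constrained
# projection.
inflate_to_enclose <- function(x, z, tol = 1e-3, f_max = 5) {
  centroid <- colMeans(z)
  inflate <- function(f) sweep(sweep(z, 2L, centroid, "-") * f, 2L, centroid, "+")
  k <- nrow(z); d <- ncol(z)
  if (k == 3L) {
    # triangles: refine in the plane (the data's leading principal plane
    # when d > 2), where per-vertex linear programs reach a local
    # minimal-area enclosing triangle, including rotations
    zz <- tryCatch({
      if (d == 2L) {
        reorder_like(min_enclosing_triangle(x), z)
      } else {
        pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
        x2 <- pc$x[, 1:2, drop = FALSE]
        z2 <- sweep(z, 2L, pc$center, "-") %*% pc$rotation[, 1:2]
        z2 <- reorder_like(min_enclosing_triangle(x2), z2)
        sweep(z2 %*% t(pc$rotation[, 1:2]), 2L, pc$center, "+")
      }
    }, error = function(e) NULL)
    if (!is.null(zz)) return(zz)
  }
  if (k <= d + 1L) {
    zz <- tryCatch(enclose_simplex(x, z), error = function(e) NULL)
    if (!is.null(zz)) return(zz)
  }
  enclosed <- function(f) {
    zf <- inflate(f)
    s <- solve_stochastic(x, zf, steps = 100L)
    resid <- sqrt(rowSums((x - s %*% zf)^2))
    max(resid) <= tol * max(1, max(abs(x)))
  }
  if (enclosed(1)) return(z)
  lo <- 1; hi <- f_max
  if (!enclosed(hi)) return(inflate(hi))
  for (i in seq_len(25L)) {
    mid <- (lo + hi) / 2
    if (enclosed(mid)) hi <- mid else lo <- mid
  }
  inflate(hi)
}

#' Fit enclosing polytopes (archetypes) to points in phylogenetic space
#'
#' Coordinates are min-max normalized per statistic, then an archetypal
#' decomposition is fitted for each `k = 1..k_max` (each fit warm-started
#' from the previous one so explained variance is non-decreasing in `k`).
#' The selected `k` is the elbow: the largest `k` whose marginal gain in
#' explained variance is still at least `gain_threshold`.  The selected
#' vertex set is inflated about its centroid by the smallest factor that
#' encloses all points ("minimal-volume enclosing" behavior).
#'
#' @param points a matrix or data.frame whose columns are the space
#'   coordinates (e.g. `lambda_star`, `psi`, `eta`), or the result of
#'   [map_points()].
#' @param k_max maximum number of archetypes considered (default 6).
#' @param seed integer seed for initialization.
#' @param gain_threshold marginal explained-variance gain below which an
#'   extra vertex is judged unnecessary (default 0.05).
#' @param enclose if `TRUE` (default), inflate the selected vertices to
#'   enclose all points.
#' @return an object of class `"polytope_fit"`: list with `k`, `vertices`
#'   (k x d, normalized coordinates), `vertices_raw` (original scale),
#'   `explained_variance` (per candidate k), `ranges` (per-axis min/max used
#'   for normalization), `contributions` (see [archetype_contributions()]).
#' @export
fit_polytope <- function(points, k_max = 6L, seed = 1L,
                         gain_threshold = 0.05, enclose = TRUE) {
  x_raw <- space_coords(points)
  if (nrow(x_raw) < k_max + 1L) stop("need at least k_max + 1 points")
  xn <- normalize_minmax(x_raw)
  ranges <- attr(xn, "ranges")
  evs <- numeric(k_max)
  fits <- vector("list", k_max)
  cand <- extreme_point_ids(xn)
  prev_b <- NULL
  for (k in seq_len(k_max)) {
    init_b <- NULL
    if (!is.null(prev_b) && ncol(prev_b) == length(cand) &&
        length(cand) >= k) {
      # warm start: previous archetypes plus one new extreme point
      xc <- xn[cand, , drop = FALSE]
      idx_new <- furthest_init(xc, min(k, nrow(xc)), derive_seed(seed, k))
      newrow <- rep(1e-6, nrow(xc)); newrow[idx_new[length(idx_new)]] <- 1
      init_b <- rbind(prev_b, newrow / sum(newrow))
    }
    f <- archetypal_fit(xn, k, seed = derive_seed(seed, k), init_b = init_b,
                        cand = if (length(cand) >= k) cand else NULL)
    # keep monotone: if a cold restart beats the warm start, take it
    if (k > 1L) {
      f2 <- archetypal_fit(xn, k, seed = derive_seed(seed, 100L + k))
      if (f2$sse < f$sse) f <- f2
    }
    fits[[k]] <- f
    evs[k] <- f$explained_variance
    prev_b <- f$b
  }
  evs <- cummax(evs)
  gains <- c(evs[1L], diff(evs))
  drop_k <- which(gains < gain_threshold)
  drop_k <- drop_k[drop_k >= 3L]  # never select below k = 2
  k_sel <- if (length(drop_k) == 0L) k_max else min(drop_k) - 1L
  z <- fits[[k_sel]]$archetypes
  if (enclose) z <- inflate_to_enclose(xn, z)
  z_raw <- sweep(sweep(z, 2L, ranges$hi - ranges$lo, "*"), 2L, ranges$lo, "+")
  colnames(z) <- colnames(z_raw) <- colnames(x_raw)
  fit <- structure(list(
    k = k_sel, vertices = z, vertices_raw = z_raw,
    explained_variance = evs, ranges = ranges,
    weights = fits[[k_sel]]$weights, points = xn,
    seed = seed, gain_threshold = gain_threshold),
    class = "polytope_fit")
  # a vertex at the normalized origin has no defined contribution split;
  # leave contributions NULL rather than fail the whole fit
  fit$contributions <- tryCatch(archetype_contributions(fit),
                                error = function(e) NULL)
  fit
}

#' @export
print.polytope_fit <- function(x, ...) {
  cat(sprintf("polytope_fit: k = %d archetypes, explained variance %s\n",
              x$k, paste(sprintf("%.3f", x$explained_variance), collapse = " ")))
  if (!is.null(x$contributions)) print(round(x$contributions, 1))
  else cat("(contributions undefined: a vertex sits at the normalized origin)\n")
  invisible(x)
}

#' Per-archetype contributions of each summary statistic
#'
#' Each archetype's contribution vector is its min-max-normalized
#' coordinates divided by their sum, times 100, so the three percentages sum
#' to 100 (the convention used to describe archetypes such as "(10%, 89%,
#' 1%)").
#'
#' @param fit a `"polytope_fit"` (or a matrix of normalized vertices).
#' @return a k x d matrix of percentages, rows summing to 100.
#' @export
archetype_contributions <- function(fit) {
  z <- if (inherits(fit, "polytope_fit")) fit$vertices else as.matrix(fit)
  z <- pmax(z, 0)
  rs <- rowSums(z)
  if (any(rs <= 0)) stop("archetype with all-zero normalized coordinates")
  100 * z / rs
}

#' t-ratio test for a k-vertex polytope fit
#'
#' The t-ratio is the volume of the convex hull of the points divided by
#' the volume of the best-fit enclosing k-polytope (so it lies in (0, 1];
#' values near 1 mean the polytope is filled).  Significance is assessed by
#' permutation: each coordinate axis is shuffled independently, the polytope
#' refitted, and the p-value is the fraction of permuted datasets whose
#' t-ratio is at least the observed one.  When the polytope is a simplex of
#' fewer vertices than `d + 1` (e.g. a triangle in 3-D), points are first
#' projected onto the principal subspace of dimension `k - 1`.
#'
#' @param points coordinates (matrix/data.frame or [map_points()] result).
#' @param k number of polytope vertices (>= 3).
#' @param n_perm number of axis-shuffled null datasets.
#' @param seed integer seed.
#' @param fit_args list of extra arguments for the internal archetypal fits
#'   (e.g. `outer`) -- smaller values speed up permutations.
#' @return a list with `t_ratio`, `p_value`, and the null `t_null` vector.
#' @export
t_ratio_test <- function(points, k = 3L, n_perm = 200L, seed = 1L,
                         fit_args = list()) {
  if (k < 3L) stop("t-ratio test requires k >= 3")
  if (n_perm < 100L) warning("n_perm < 100 gives coarse p-values")
  x <- normalize_minmax(space_coords(points))
  d <- ncol(x)
  if (k <= d) {
    # project onto the leading (k-1)-dim principal subspace
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    x <- pc$x[, seq_len(k - 1L), drop = FALSE]
  }
  tr_obs <- polytope_t_ratio(x, k, seed, fit_args)
  t_null <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      xp <- apply(x, 2L, sample)
      t_null[b] <- polytope_t_ratio(xp, k, derive_seed(seed, b), fit_args)
    }
  })
  list(t_ratio = tr_obs,
       p_value = mean(t_null >= tr_obs),
       t_null = t_null)
}

# Hull volume over enclosing-k-polytope volume for a point matrix already in
# its fitting dimension.
polytope_t_ratio <- function(x, k, seed, fit_args = list()) {
  if (k == 3L && ncol(x) == 2L) {
    # the minimal enclosing triangle does not depend on the archetypal
    # decomposition; fit it directly (permutation loops use reduced
    # optimizer settings for speed; observed and null fits share them)
    z <- min_enclosing_triangle(x,
                                starts_cap = fit_args$tri_starts %||% 8L,
                                maxit = fit_args$tri_maxit %||% 100L)
  } else {
    args <- c(list(x = x, k = k, seed = seed), fit_args)
    f <- do.call(archetypal_fit, args)
    z <- inflate_to_enclose(x, f$archetypes)
  }
  vol_z <- if (nrow(z) == ncol(z) + 1L) simplex_volume(z) else hull_volume(z)
  vol_h <- hull_volume(x)
  if (vol_z <= 0) return(NA_real_)
  min(1, vol_h / vol_z)
}

#' Rarefaction of archetype coordinates
#'
#' For each sample size, draws bootstrap samples of the points, refits the
#' polytope at fixed `k`, and records for each axis the maximum coordinate
#' over the fitted vertices.  A logarithmic saturation curve
#' `max_coord ~ a + b log(n)` is fitted per axis; a flat curve indicates
#' that the corpus already saturates the space.
#'
#' @param points coordinates (matrix/data.frame or [map_points()] result).
#' @param sample_sizes integer vector of bootstrap sample sizes (each `<=`
#'   number of points).
#' @param replicates bootstrap replicates per size (default 50).
#' @param k fixed number of archetypes (default 3).
#' @param seed integer seed.
#' @return a list with `summary` (per size and axis: mean and sd of the max
#'   vertex coordinate) and `curves` (per axis: intercept, slope on log n,
#'   p-value of the slope).
#' @export
rarefaction_saturation <- function(points, sample_sizes, replicates = 50L,
                                   k = 3L, seed = 1L) {
  x <- space_coords(points)
  n <- nrow(x)
  if (any(sample_sizes > n)) stop("sample sizes exceed the number of points")
  if (any(sample_sizes < k + 1L)) stop("sample sizes must exceed k")
  axes <- colnames(x) %||% paste0("axis", seq_len(ncol(x)))
  rows <- list(); raw <- list()
  for (m in sample_sizes) {
    mx <- matrix(NA_real_, replicates, ncol(x))
    for (r in seq_len(replicates)) {
      s <- derive_seed(seed, m * 1000 + r)
      idx <- with_seed(s, sample.int(n, m, replace = TRUE))
      f <- tryCatch(
        archetypal_fit(normalize_minmax(x[idx, , drop = FALSE]), k,
                       seed = s, outer = 25L),
        error = function(e) NULL)
      if (is.null(f)) next
      # vertices back on the full-data normalized scale
      zn <- normalize_minmax(
        sweep(sweep(f$archetypes, 2L,
                    apply(x[idx, , drop = FALSE], 2L, max) -
                      apply(x[idx, , drop = FALSE], 2L, min), "*"),
              2L, apply(x[idx, , drop = FALSE], 2L, min), "+"),
        ranges = list(lo = apply(x, 2L, min), hi = apply(x, 2L, max)))
      mx[r, ] <- apply(zn, 2L, max)
    }
    raw[[as.character(m)]] <- mx
    rows[[length(rows) + 1L]] <- data.frame(
      n = m, axis = axes,
      mean_max = colMeans(mx, na.rm = TRUE),
      sd_max = apply(mx, 2L, stats::sd, na.rm = TRUE))
  }
  summary <- do.call(rbind, rows)
  curves <- do.call(rbind, lapply(seq_along(axes), function(j) {
    sub <- summary[summary$axis == axes[j], ]
    fit <- stats::lm(mean_max ~ log(n), data = sub)
    co <- summary(fit)$coefficients
    data.frame(axis = axes[j], intercept = co[1L, 1L], slope = co[2L, 1L],
               p_value = co[2L, 4L])
  }))
  list(summary = summary, curves = curves, replicates = replicates, k = k)
}
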