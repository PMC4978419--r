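# Convex hull utilities in 2-D and 3-D.
#
# The 3-D hull is an incremental quickhull over triangular facets with
# outward-oriented normals; it supports volume computation and point
# membership.  2-D hulls go through grDevices::chull.  Only desk-scale
# point sets (hundreds of points) are ever processed here.

# --- 2-D ------------------------------------------------------------------

# Area of the convex hull of 2-D points (shoelace on chull order).
hull_area_2d <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) return(0)
  idx <- grDevices::chull(pts[, 1L], pts[, 2L])
  polygon_area(pts[idx, , drop = FALSE])
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L])) / 2
}

# --- 3-D ------------------------------------------------------------------

# Incremental convex hull of 3-D points.  Returns a list with `vertices`
# (the input points), `faces` (m x 3 index matrix, outward-oriented),
# `normals`, `offsets` (so a point q is inside iff normals %*% q <= offsets
# + tol for all faces), `volume`, `centroid`.
convex_hull_3d <- function(pts, tol = 1e-10) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3L)
  n <- nrow(pts)
  if (n < 4L) stop("need at least 4 points for a 3-D hull")
  scale <- max(1, max(abs(pts)))
  eps <- tol * scale

  # initial simplex: two extreme points, farthest from their line, farthest
  # from that plane
  i1 <- which.min(pts[, 1L]); i2 <- which.max(pts[, 1L])
  if (isTRUE(all.equal(pts[i1, ], pts[i2, ]))) {
    dd <- as.matrix(stats::dist(pts))
    w <- which(dd == max(dd), arr.ind = TRUE)[1L, ]
    i1 <- w[1L]; i2 <- w[2L]
  }
  ab <- pts[i2, ] - pts[i1, ]
  if (sqrt(sum(ab^2)) <= eps) stop("degenerate point set (all points equal)")
  dline <- apply(pts, 1L, function(p) {
    v <- p - pts[i1, ]
    sqrt(max(0, sum(v^2) - sum(v * ab)^2 / sum(ab^2)))
  })
  i3 <- which.max(dline)
  if (dline[i3] <= eps) stop("degenerate point set (collinear)")
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  dplane <- abs(as.vector(pts %*% nrm) - sum(nrm * pts[i1, ])) / sqrt(sum(nrm^2))
  i4 <- which.max(dplane)
  if (dplane[i4] <= eps) stop("degenerate point set (coplanar)")

  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  centroid0 <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- t(apply(faces, 1L, orient_face, pts = pts, inside = centroid0))

  face_list <- split(faces, row(faces))
  alive <- rep(TRUE, length(face_list))

  repeat {
    np <- face_normals(face_list, alive, pts)
    # farthest outside point over all faces
    sd_mat <- pts %*% t(np$normals) -
      matrix(np$offsets, n, length(np$offsets), byrow = TRUE)
    best <- which(sd_mat == max(sd_mat), arr.ind = TRUE)[1L, ]
    if (sd_mat[best[1L], best[2L]] <= eps) break
    p <- best[1L]
    # visible faces
    vis_local <- which(as.vector(np$normals %*% pts[p, ]) - np$offsets > eps)
    vis <- np$face_ids[vis_local]
    # horizon: edges of visible faces shared with exactly one visible face
    edges <- do.call(rbind, lapply(vis, function(fi) {
      f <- face_list[[fi]]
      rbind(sort(c(f[1L], f[2L])), sort(c(f[2L], f[3L])), sort(c(f[1L], f[3L])))
    }))
    key <- paste(edges[, 1L], edges[, 2L])
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    alive[vis] <- FALSE
    inner <- colMeans(pts[unique(unlist(face_list[alive])), , drop = FALSE])
    for (e in seq_len(nrow(horizon))) {
      newf <- orient_face(c(horizon[e, ], p), pts, inner)
      face_list[[length(face_list) + 1L]] <- newf
      alive <- c(alive, TRUE)
    }
  }

  faces <- do.call(rbind, face_list[alive])
  np <- face_normals(face_list, alive, pts)
  hull_pts <- sort(unique(as.vector(faces)))
  centroid <- colMeans(pts[hull_pts, , drop = FALSE])
  vol <- sum(vapply(seq_len(nrow(faces)), function(i) {
    v <- pts[faces[i, ], , drop = FALSE]
    abs(det(rbind(v[1L, ] - centroid, v[2L, ] - centroid, v[3L, ] - centroid))) / 6
  }, 0))
  structure(list(vertices = pts, vertex_ids = hull_pts, faces = faces,
                 normals = np$normals, offsets = np$offsets,
                 volume = vol, centroid = centroid, eps = eps),
            class = "hull3d")
}

cross3 <- function(a, b) c(a[2L] * b[3L] - a[3L] * b[2L],
                           a[3L] * b[1L] - a[1L] * b[3L],
                           a[1L] * b[2L] - a[2L] * b[1L])

# Orient a face index triple so its normal points away from `inside`.
orient_face <- function(f, pts, inside) {
  nrm <- cross3(pts[f[2L], ] - pts[f[1L], ], pts[f[3L], ] - pts[f[1L], ])
  if (sum(nrm * (inside - pts[f[1L], ])) > 0) f[c(1L, 3L, 2L)] else f
}

# Unit normals and offsets for the live faces.
face_normals <- function(face_list, alive, pts) {
  ids <- which(alive)
  normals <- t(vapply(ids, function(fi) {
    f <- face_list[[fi]]
    v <- cross3(pts[f[2L], ] - pts[f[1L], ], pts[f[3L], ] - pts[f[1L], ])
    nv <- sqrt(sum(v^2))
    if (nv > 0) v / nv else v
  }, numeric(3L)))
  offsets <- vapply(seq_along(ids), function(k)
    sum(normals[k, ] * pts[face_list[[ids[k]]][1L], ]), 0)
  list(normals = normals, offsets = offsets, face_ids = ids)
}

# Is each query point inside the hull (within tolerance)?  Normals are unit
# length, so the comparison is a signed distance in coordinate units.
hull_contains <- function(hull, q, tol = 1e-8) {
  q <- matrix(q, ncol = 3L)
  scale <- max(1, max(abs(hull$vertices[hull$vertex_ids, , drop = FALSE])))
  sd_mat <- q %*% t(hull$normals) -
    matrix(hull$offsets, nrow(q), length(hull$offsets), byrow = TRUE)
  apply(sd_mat <= tol * scale, 1L, all)
}

# Volume of the simplex with vertex matrix v ((d+1) x d).
simplex_volume <- function(v) {
  v <- as.matrix(v)
  d <- ncol(v)
  abs(det(v[-1L, , drop = FALSE] -
            matrix(v[1L, ], nrow(v) - 1L, d, byrow = TRUE))) / factorial(d)
}

# Volume (area/volume) of the convex hull of points in 2-D or 3-D.
hull_volume <- function(pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) == 2L) hull_area_2d(pts)
  else if (ncol(pts) == 3L) convex_hull_3d(pts)$volume
  else stop("hull_volume supports 2-D and 3-D points only")
}
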