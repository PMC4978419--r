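# Shared fixture builders: random trees, toy profiles, small oracles.

# Random binary ultrametric tree via a quick coalescent-style construction
# (rcoal), wrapped as a tree_record.
random_ultrametric_tree <- function(n, seed, scale = 1) {
  with_seed(seed, {
    phy <- ape::rcoal(n)
    phy$edge.length <- phy$edge.length * scale
    tree_record(phy)
  })
}

# Random tree with arbitrary (non-ultrametric) branch lengths.
random_rough_tree <- function(n, seed) {
  with_seed(seed, {
    phy <- ape::rtree(n)
    tree_record(phy)
  })
}

with_seed <- phylospace:::with_seed

# A synthetic profile carrying an explicit density grid (for JSD tests).
toy_profile <- function(x, y, lambda_star = 1, psi = 0, eta = max(y)) {
  area <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  list(density = list(x = x, y = y / area, bw = NA_real_),
       lambda_star = lambda_star, psi = psi, eta = eta,
       label = NA_character_)
}

# Gaussian-bump profile centered at mu.
gaussian_profile <- function(mu, sd = 0.3, lambda_star = mu) {
  x <- seq(mu - 4 * sd, mu + 4 * sd, length.out = 301)
  toy_profile(x, stats::dnorm(x, mu, sd), lambda_star = lambda_star)
}

# Independent shortest-path oracle (Floyd-Warshall over the edge graph).
floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- w
  d[d == 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n))
    d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  d
}

# Adjacency (edge-weight) matrix of a phylo over all nodes.
tree_edge_weights <- function(phy) {
  ntot <- length(phy$tip.label) + phy$Nnode
  w <- matrix(0, ntot, ntot)
  for (e in seq_len(nrow(phy$edge))) {
    i <- phy$edge[e, 1L]; j <- phy$edge[e, 2L]
    w[i, j] <- w[j, i] <- phy$edge.length[e]
  }
  w
}

# Brute-force Jenks oracle: enumerate all contiguous partitions of the
# sorted values into k classes, return the minimal within-class SSD.
jenks_brute_force <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf
  splits <- utils::combn(n - 1L, k - 1L)
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0L, splits[, j], n)
    tot <- 0
    for (c2 in seq_len(k))
      tot <- tot + ssd(x[(cuts[c2] + 1L):cuts[c2 + 1L]])
    best <- min(best, tot)
  }
  best
}

# Independent convex-hull oracle (scipy.spatial.ConvexHull through the
# system python): returns the hull volume and half-space membership of the
# query points.
scipy_hull_oracle <- function(p, q, tol = 1e-7) {
  pf <- tempfile(fileext = ".csv"); qf <- tempfile(fileext = ".csv")
  of <- tempfile(fileext = ".csv")
  utils::write.table(p, pf, sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(q, qf, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- sprintf(paste0(
    "import numpy as np\n",
    "from scipy.spatial import ConvexHull\n",
    "p = np.loadtxt(%s, delimiter=',')\n",
    "q = np.loadtxt(%s, delimiter=',', ndmin=2)\n",
    "h = ConvexHull(p)\n",
    "A, b = h.equations[:, :-1], h.equations[:, -1]\n",
    "inside = np.all(q @ A.T + b <= %.3g, axis=1)\n",
    "out = np.column_stack([np.full(len(q), h.volume), inside])\n",
    "np.savetxt(%s, out, delimiter=',')\n"),
    deparse(pf), deparse(qf), tol, deparse(of))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  out <- utils::read.csv(of, header = FALSE)
  list(volume = out[1, 1], inside = out[, 2] > 0.5)
}
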