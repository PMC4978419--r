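# Modified graph Laplacian (MGL) of a phylogeny and its spectral density
# profile.
#
# The MGL is D - A, where A is the all-pairs path-length distance matrix
# over every node of the tree and D is the diagonal "degree" matrix with
# D_ii = sum_j A_ij.  Rows sum to zero, the matrix is symmetric positive
# semidefinite, and its eigenvalue spectrum is the tree-shape fingerprint:
# the spectral density profile is a Gaussian kernel density of the
# ln-transformed nonzero eigenvalues, summarized by
#   lambda_star  ln of the principal eigenvalue ("phylogenetic expansion"),
#   psi          skewness of the nonzero eigenvalue distribution
#                (stem-to-tip distribution: low = stemmy, high = tippy),
#   eta          peak height of the unit-integral density (regularity),
#   modality     position of the largest eigengap in the ranked spectrum.

#' Build the modified graph Laplacian of a tree
#'
#' Returns `M = D - A` where `A` is [node_distance_matrix()] over all nodes
#' and `D` is diagonal with `D[i,i] = sum_j A[i,j]`.  `M` is symmetric
#' positive semidefinite with zero row sums, so its smallest eigenvalue is
#' structurally zero.
#'
#' @param t a [tree_record()] or `"phylo"` with at least 2 tips.
#' @return a symmetric numeric matrix of size (number of nodes)^2.
#' @export
#' @examples
#' build_mgl(parse_newick("(A:1,B:1);"))  # eigenvalues 5, 3, 0
build_mgl <- function(t) {
  phy <- as_phylo_tree(t)
  if (length(phy$tip.label) < 2L)
    stop("the MGL requires a tree with at least 2 tips")
  a <- node_distance_matrix(phy)
  m <- -a
  diag(m) <- rowSums(a)
  m
}

#' Eigengap modality of a ranked spectrum
#'
#' The number of modes of division in a tree, read off as the position of
#' the largest difference between consecutive descending-ranked eigenvalues
#' (the eigengap heuristic).  Ties break toward the smaller index.
#'
#' @param eigenvalues numeric vector of eigenvalues (sorted internally).
#' @param max_modes cap on the number of gaps examined.
#' @return a positive integer.
#' @export
#' @examples
#' eigengap_modality(c(10, 1, 0.9, 0.8, 0))   # 1
#' eigengap_modality(c(10, 9.5, 1, 0.9, 0))   # 2
eigengap_modality <- function(eigenvalues, max_modes = Inf) {
  ev <- sort(as.numeric(eigenvalues), decreasing = TRUE)
  if (length(ev) < 2L)
    stop("eigengap modality needs at least 2 eigenvalues")
  gaps <- -diff(ev)
  kmax <- min(max_modes, length(gaps))
  which.max(gaps[seq_len(kmax)])  # which.max ties break to smaller index
}

#' Spectral density profile of a tree
#'
#' Dense symmetric eigendecomposition of the MGL, followed by a Gaussian
#' kernel density estimate of the ln-transformed eigenvalues.  Structural
#' zero eigenvalues (those with `|lambda| <= zero_tol * lambda_max`) are
#' excluded before the ln-transform; optionally all eigenvalues below
#' `drop_below` can be excluded instead.  The density uses Silverman's
#' rule-of-thumb bandwidth on a uniform grid of `grid_size` points spanning
#' the ln-eigenvalue range plus three bandwidths on each side, and is
#' renormalized to unit integral.
#'
#' @param t a [tree_record()] or `"phylo"` with at least 2 tips.
#' @param grid_size number of grid points for the kernel density.
#' @param zero_tol relative tolerance below which an eigenvalue is treated
#'   as a structural zero.
#' @param drop_below optional absolute threshold: eigenvalues `<= drop_below`
#'   are excluded from the ln-transform (default `NULL`, drop structural
#'   zeros only).
#' @return an object of class `"spectral_profile"`: a list with
#'   `eigenvalues` (descending), `ln_eigenvalues`, `density` (list with `x`,
#'   `y`, `bw`), `lambda_star` (log principal eigenvalue), `psi` (skewness
#'   of the nonzero eigenvalue distribution), `eta` (peak height of the
#'   unit-integral ln-eigenvalue density), `modality`, `n_tips`, `label`.
#' @export
#' @examples
#' p <- spectral_profile(parse_newick("(A:1,B:1);"))
#' p$lambda_star  # log(5)
spectral_profile <- function(t, grid_size = 512L, zero_tol = 1e-8,
                             drop_below = NULL) {
  phy <- as_phylo_tree(t)
  m <- build_mgl(phy)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)))
    stop("non-finite eigenvalues in the MGL spectrum")
  ev <- sort(ev, decreasing = TRUE)
  lmax <- ev[1L]
  if (lmax <= 0)
    stop("degenerate tree: all MGL eigenvalues are (numerically) zero")
  keep <- if (is.null(drop_below)) abs(ev) > zero_tol * lmax else ev > drop_below
  lnev <- log(ev[keep])
  if (length(lnev) < 1L)
    stop("no eigenvalues left after excluding structural zeros")
  dens <- ln_spectrum_density(lnev, grid_size)
  label <- if (inherits(t, "tree_record") && !is.na(t$family)) t$family
           else NA_character_
  structure(
    list(eigenvalues = ev,
         ln_eigenvalues = lnev,
         density = dens,
         lambda_star = log(lmax),
         # skewness of the (raw) nonzero eigenvalue distribution: low for
         # early-burst (stemmy) trees, high for tip-ward (tippy) ones; the
         # ln scale is reserved for the density and its peak height
         psi = moment_skewness(ev[abs(ev) > zero_tol * lmax]),
         eta = max(dens$y),
         # the structural zero is excluded from the gap scan: the terminal
         # drop to zero is a graph-theoretic artifact, not a division mode
         modality = eigengap_modality(ev[abs(ev) > zero_tol * lmax]),
         n_tips = length(phy$tip.label),
         label = label),
    class = "spectral_profile")
}

# Gaussian KDE of ln-eigenvalues on a uniform grid with Silverman bandwidth,
# renormalized to unit (trapezoid) integral.  Degenerate spectra (a single
# value, or zero spread) fall back to a small fixed bandwidth so the profile
# remains a proper density.
ln_spectrum_density <- function(lnev, grid_size = 512L) {
  bw <- tryCatch(stats::bw.nrd0(lnev), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- 1e-3
  d <- stats::density(lnev, bw = bw, n = grid_size, kernel = "gaussian")
  area <- trapezoid_integral(d$x, d$y)
  list(x = d$x, y = d$y / area, bw = bw)
}

trapezoid_integral <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Moment (type-1) sample skewness; 0 for spectra with fewer than 3 values
# or zero spread.
moment_skewness <- function(x) {
  if (length(x) < 3L) return(0)
  s <- e1071::skewness(x, type = 1)
  if (!is.finite(s)) 0 else s
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf(
    "spectral_profile: %d tips | lambda* = %.4f, psi = %.4f, eta = %.4f, modality = %d\n",
    x$n_tips, x$lambda_star, x$psi, x$eta, x$modality))
  invisible(x)
}

#' Plot a spectral density profile
#'
#' @param x a `"spectral_profile"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spectral_profile <- function(x, ...) {
  graphics::plot(x$density$x, x$density$y, type = "l",
                 xlab = "ln eigenvalue", ylab = "density", ...)
  graphics::rug(x$ln_eigenvalues)
  invisible(x)
}
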