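# Random "phylogeny-type networks": bifurcating, ultrametric, rooted trees
# derived from random constrained graph Laplacians.  These chart the space
# of trees available at a given phylogenetic expansion (lambda*): a random
# symmetric positive-semidefinite M-matrix with zero row sums defines a
# weighted graph; Dijkstra shortest paths give a distance matrix; complete
# linkage turns it into a dendrogram; mean-path-length ultrametricization
# and polytomy resolution yield a proper tree, whose branch lengths are
# finally rescaled so its own profile lambda* hits the drawn target.

#' Sampler configuration for phylogeny-type networks
#'
#' @param n_nodes integer range (length-2) of graph node counts; each node
#'   becomes a tip of the reconstructed tree.  The desk-scale default is
#'   20--100; the empirical corpus spans 20--700 tips.
#' @param target_lambda_star numeric pool of target `lambda*` values
#'   (typically the empirical distribution); one is drawn per tree.
#' @param off_diagonal_law function(m) returning m positive weights; the
#'   negated draws populate the Laplacian off-diagonals.  Default
#'   `Exponential(1)` on every pair (dense complete graph).
#' @param n_trees number of trees to generate.
#' @param seed integer master seed.
#' @param constrain_after if `TRUE` (default) the `lambda*` constraint is
#'   enforced on the final tree by linear branch rescaling; if `FALSE` only
#'   the initial matrix is rescaled.
#' @return an object of class `"sampler_config"`.
#' @export
sampler_config <- function(n_nodes = c(20L, 100L),
                           target_lambda_star = log(5),
                           off_diagonal_law = function(m) stats::rexp(m, 1),
                           n_trees = 100L, seed = 1L,
                           constrain_after = TRUE) {
  stopifnot(length(n_nodes) == 2L, n_nodes[1L] >= 3L,
            n_nodes[2L] >= n_nodes[1L], n_trees >= 1L,
            length(target_lambda_star) >= 1L)
  structure(list(n_nodes = as.integer(n_nodes),
                 target_lambda_star = target_lambda_star,
                 off_diagonal_law = off_diagonal_law,
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 constrain_after = isTRUE(constrain_after)),
            class = "sampler_config")
}

#' Sample a random constrained graph Laplacian
#'
#' Populates a symmetric M-matrix with negative off-diagonals drawn from
#' the configured law and diagonal entries equal to minus the off-diagonal
#' row sums (zero row sums), then rescales it so the log of the largest
#' eigenvalue equals `target_lambda_star` exactly (eigenvalues are linear
#' in the matrix scale).
#'
#' @param n number of nodes (>= 3).
#' @param target_lambda_star target log principal eigenvalue.
#' @param seed integer seed.
#' @param law function(m) returning m positive off-diagonal weights.
#' @param max_retries resampling attempts if the implied weighted graph is
#'   disconnected (cannot happen under the dense default law).
#' @return a symmetric PSD matrix with zero row sums.
#' @export
sample_mgl_matrix <- function(n, target_lambda_star, seed = 1L,
                              law = function(m) stats::rexp(m, 1),
                              max_retries = 10L) {
  stopifnot(n >= 3L, is.finite(target_lambda_star))
  for (try in seq_len(max_retries)) {
    w <- with_seed(derive_seed(seed, try), law(n * (n - 1L) / 2L))
    if (any(w < 0)) stop("off-diagonal law must return positive weights")
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- w
    a <- a + t(a)
    g <- igraph::graph_from_adjacency_matrix(a > 0, mode = "undirected")
    if (igraph::is_connected(g)) {
      m <- -a
      diag(m) <- rowSums(a)
      lmax <- max(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
      return(m * exp(target_lambda_star) / lmax)
    }
  }
  stop("disconnected weighted graph after ", max_retries, " attempts")
}

#' Reconstruct an ultrametric tree from a Laplacian-like matrix
#'
#' Edge weights are the magnitudes of the off-diagonal entries; all-pairs
#' shortest paths (Dijkstra) give a distance matrix; complete-linkage
#' clustering converts it to a rooted dendrogram whose branch lengths come
#' from the merge heights; mean-path-length ultrametricization and random
#' polytomy resolution produce a binary, rooted, ultrametric tree.
#'
#' @param L symmetric matrix with non-positive off-diagonals (a weighted
#'   graph Laplacian).
#' @param seed integer seed for polytomy resolution.
#' @return a [tree_record()].
#' @export
matrix_to_tree <- function(L, seed = 1L) {
  L <- as.matrix(L)
  if (!isSymmetric(unname(L), tol = 1e-8)) stop("input matrix must be symmetric")
  w <- abs(L); diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  if (any(!is.finite(d))) stop("implied weighted graph is disconnected")
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  phy <- ape::as.phylo(hc)
  phy$tip.label <- paste0("t", seq_len(nrow(d)))
  t <- tree_record(phy)
  t <- mpl_ultrametricize(t)
  t <- resolve_polytomies(t, seed = seed)
  t
}

#' Generate a corpus of phylogeny-type networks
#'
#' Draws a node count and a target `lambda*` per tree, samples the
#' constrained Laplacian, reconstructs the tree, and (by default) rescales
#' its branch lengths so the final spectral profile's `lambda*` equals the
#' target exactly.  Per-tree failures are skipped with a count in the
#' result.
#'
#' @param cfg a [sampler_config()].
#' @return a list with `trees` (list of tree_records), `profiles` (list of
#'   spectral profiles), `targets` (numeric vector), `failures` (count).
#' @export
generate_network_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "sampler_config"))
  trees <- list(); profiles <- list(); targets <- numeric(0)
  failures <- 0L
  for (i in seq_len(cfg$n_trees)) {
    s <- derive_seed(cfg$seed, i)
    res <- tryCatch({
      draw <- with_seed(s, list(
        n = sample(seq(cfg$n_nodes[1L], cfg$n_nodes[2L]), 1L),
        tgt = cfg$target_lambda_star[sample.int(length(cfg$target_lambda_star), 1L)]))
      m <- sample_mgl_matrix(draw$n, draw$tgt, seed = derive_seed(s, 1L),
                             law = cfg$off_diagonal_law)
      t <- matrix_to_tree(m, seed = derive_seed(s, 2L))
      if (cfg$constrain_after) {
        p0 <- spectral_profile(t)
        t$phy$edge.length <- t$phy$edge.length * exp(draw$tgt - p0$lambda_star)
      }
      p <- spectral_profile(t)
      t$family <- sprintf("net%04d", i)
      p$label <- t$family
      list(t = t, p = p, tgt = draw$tgt)
    }, error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    trees[[length(trees) + 1L]] <- res$t
    profiles[[length(profiles) + 1L]] <- res$p
    targets <- c(targets, res$tgt)
  }
  list(trees = trees, profiles = profiles, targets = targets,
       failures = failures)
}
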