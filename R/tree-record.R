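# Tree records: rooted (usually ultrametric) phylogenies plus study metadata.
#
# A tree_record wraps an ape "phylo" object together with the per-family
# metadata used throughout the analysis (taxonomic class, sampling fraction).
# Node ordering follows ape's convention: tips 1..n in input order, then the
# root (n+1), then internal nodes cladewise.  The MGL spectrum is invariant
# under node permutation, so this choice is cosmetic but fixed.

#' Construct a tree record
#'
#' Bundles a rooted phylogeny with the metadata carried through the analysis
#' pipeline (family name, taxonomic class, sampling fraction).  Crown age is
#' derived from the tree, not stored.
#'
#' @param phy an object of class `"phylo"` (see [ape::read.tree()]), rooted,
#'   with branch lengths.
#' @param family optional family (clade) name.
#' @param taxon_class optional taxonomic class label (e.g. `"Aves"`).
#' @param sampling_fraction optional proportion of extant species sampled,
#'   in `[0, 1]`.
#' @param regime optional generative regime label (used by the synthetic
#'   corpus generators; `NA` for empirical trees).
#'
#' @return an object of class `"tree_record"`: a list with elements `phy`,
#'   `family`, `taxon_class`, `sampling_fraction` and `regime`.
#' @export
#' @examples
#' tr <- tree_record(ape::read.tree(text = "((A:1,B:1):1,C:2);"),
#'                   family = "Example")
#' tree_metrics(tr)
tree_record <- function(phy, family = NA_character_, taxon_class = NA_character_,
                        sampling_fraction = NA_real_, regime = NA_character_) {
  if (!inherits(phy, "phylo"))
    stop("'phy' must be a \"phylo\" object")
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(phy$edge.length))
    stop("tree has missing branch lengths")
  if (any(phy$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (anyDuplicated(phy$tip.label))
    stop("tip labels must be unique")
  # a basal multifurcation is treated as a rooted polytomy (resolvable via
  # resolve_polytomies), so ape::is.rooted (root degree <= 2) is not
  # enforced here; phylo objects structurally have a single root
  if (phy$Nnode < 1L)
    stop("tree must have a root node")
  if (!is.na(sampling_fraction) &&
      (sampling_fraction < 0 || sampling_fraction > 1))
    stop("'sampling_fraction' must lie in [0, 1]")
  structure(
    list(phy = phy, family = as.character(family),
         taxon_class = as.character(taxon_class),
         sampling_fraction = as.numeric(sampling_fraction),
         regime = as.character(regime)),
    class = "tree_record")
}

#' @export
print.tree_record <- function(x, ...) {
  m <- tree_metrics(x)
  cat(sprintf("tree_record: %d tips, crown age %.4g%s%s\n",
              m$n_tips, m$crown_age,
              if (m$is_ultrametric) ", ultrametric" else ", NOT ultrametric",
              if (!is.na(x$family)) paste0(" [", x$family, "]") else ""))
  invisible(x)
}

#' Extract the underlying phylo object
#'
#' @param x a [tree_record()].
#' @param ... ignored.
#' @return the wrapped `"phylo"` object.
#' @method as.phylo tree_record
#' @export
#' @importFrom ape as.phylo
as.phylo.tree_record <- function(x, ...) x$phy

# Accept either a tree_record or a bare phylo everywhere.
as_phylo_tree <- function(t) {
  if (inherits(t, "tree_record")) return(t$phy)
  if (inherits(t, "phylo")) return(t)
  stop("expected a \"tree_record\" or \"phylo\" object")
}

# Carry metadata over to a transformed topology/branch set.
rewrap <- function(t, phy) {
  if (inherits(t, "tree_record")) {
    t$phy <- phy
    t
  } else phy
}

#' Parse a Newick string into a tree record
#'
#' Thin validating wrapper around [ape::read.tree()].  Parenthesis balance is
#' checked first so that malformed input is reported with the character
#' offset of the first imbalance; trees without (or with partial) branch
#' lengths are rejected, since every downstream quantity is built from
#' path-length distances.
#'
#' @param text a single Newick string (terminating `;` optional on read).
#' @inheritParams tree_record
#' @return a [tree_record()].
#' @export
#' @examples
#' parse_newick("((A:1,B:1):1,C:2);")
parse_newick <- function(text, family = NA_character_,
                         taxon_class = NA_character_,
                         sampling_fraction = NA_real_,
                         regime = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at character %d",
                 depth, length(chars)))
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("malformed Newick: ape failed to parse the string")
  if (is.null(phy$edge.length) || anyNA(phy$edge.length) ||
      length(phy$edge.length) != nrow(phy$edge))
    stop("Newick string lacks branch lengths on one or more edges")
  tree_record(phy, family = family, taxon_class = taxon_class,
              sampling_fraction = sampling_fraction, regime = regime)
}

#' Write a tree record as a Newick string
#'
#' @param t a [tree_record()] or `"phylo"` object.
#' @param digits number of significant digits for branch lengths.
#' @return a Newick string (with trailing `;`).
#' @export
write_newick <- function(t, digits = 12) {
  ape::write.tree(as_phylo_tree(t), digits = digits)
}

# Root-to-node path lengths, one per node (tips + internals), in ape order.
node_depths <- function(phy) ape::node.depth.edgelength(phy)

#' Basic shape measurements of a tree
#'
#' Crown age is the maximum root-to-tip path length measured from the first
#' split (any stem/root edge is ignored).  A tree is flagged ultrametric when
#' root-to-tip spans differ by at most `tol` relative to tree height.
#'
#' @param t a [tree_record()] or `"phylo"`.
#' @param tol relative tolerance for the ultrametricity check.
#' @return a list with `n_tips`, `crown_age`, `is_ultrametric`, `is_binary`.
#' @export
tree_metrics <- function(t, tol = 1e-8) {
  phy <- as_phylo_tree(t)
  n <- length(phy$tip.label)
  depths <- node_depths(phy)[seq_len(n)]
  crown <- max(depths)
  ultra <- if (crown == 0) TRUE else (max(depths) - min(depths)) <= tol * crown
  # rooted sense: every internal node (including the root) has exactly two
  # children; ape::is.binary treats a basal trifurcation as unrooted-binary
  kids <- tabulate(phy$edge[, 1L], nbins = n + phy$Nnode)
  list(n_tips = n,
       crown_age = crown,
       is_ultrametric = ultra,
       is_binary = all(kids[(n + 1L):(n + phy$Nnode)] == 2L))
}

#' All-pairs path-length distance matrix over all nodes
#'
#' Entry (i, j) is the sum of branch lengths on the unique path between nodes
#' i and j, over tips, internal nodes and the root (ape node numbering).  For
#' a binary tree of n tips the matrix is (2n-1) x (2n-1).  This is the
#' distance matrix from which the modified graph Laplacian is built.
#'
#' @param t a [tree_record()] or `"phylo"`.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
#' @examples
#' node_distance_matrix(parse_newick("(A:1,B:1);"))
node_distance_matrix <- function(t) {
  phy <- as_phylo_tree(t)
  d <- ape::dist.nodes(phy)
  lab <- c(phy$tip.label,
           paste0("node", seq_len(phy$Nnode) + length(phy$tip.label)))
  dimnames(d) <- list(lab, lab)
  d
}

#' Resolve polytomies into a binary tree
#'
#' Multifurcations are replaced by sequences of bifurcations joined by
#' zero-length edges (via [ape::multi2di()]), so every tip-to-tip distance is
#' preserved exactly.  The resolution is randomized; a fixed `seed` makes it
#' reproducible.  Already-binary trees are returned unchanged.
#'
#' @param t a [tree_record()] or `"phylo"`.
#' @param seed integer seed for the (randomized) resolution.
#' @return object of the same class as `t`, strictly bifurcating.
#' @export
resolve_polytomies <- function(t, seed = 1L) {
  phy <- as_phylo_tree(t)
  if (tree_metrics(phy)$is_binary) return(t)
  phy2 <- with_seed(seed, ape::multi2di(phy, random = TRUE))
  rewrap(t, phy2)
}

#' Make a tree ultrametric by mean path lengths
#'
#' Each internal node's age is set to the mean of its path lengths to all
#' descendant tips; tips are placed at age 0.  Where this would make a child
#' older than its parent, the child age is clamped to the parent age
#' (yielding a zero-length edge); such inversions are rare on near-clocklike
#' input.  Ultrametric input is a fixed point of the transformation.
#'
#' @param t a [tree_record()] or `"phylo"`.
#' @return object of the same class as `t`, ultrametric.
#' @export
#' @examples
#' mpl_ultrametricize(parse_newick("((A:1,B:3):1,C:4);"))
mpl_ultrametricize <- function(t) {
  phy <- as_phylo_tree(t)
  n <- length(phy$tip.label)
  nnode <- phy$Nnode
  ntot <- n + nnode
  root <- n + 1L
  # mean path length from each internal node to its descendant tips,
  # accumulated in one postorder sweep: track (sum of tip path lengths,
  # number of descendant tips) per node
  tipsum <- numeric(ntot)
  tipcnt <- integer(ntot)
  tipcnt[seq_len(n)] <- 1L
  eo <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1L]; child <- eo$edge[k, 2L]; len <- eo$edge.length[k]
    tipsum[par] <- tipsum[par] + tipsum[child] + len * tipcnt[child]
    tipcnt[par] <- tipcnt[par] + tipcnt[child]
  }
  age <- numeric(ntot)                      # tips at 0
  age[(n + 1L):ntot] <- tipsum[(n + 1L):ntot] / tipcnt[(n + 1L):ntot]
  # clamp child ages to parent ages in a preorder sweep
  pre <- eo$edge[rev(seq_len(nrow(eo$edge))), , drop = FALSE]
  for (k in seq_len(nrow(pre))) {
    par <- pre[k, 1L]; child <- pre[k, 2L]
    if (age[child] > age[par]) age[child] <- age[par]
  }
  newlen <- age[phy$edge[, 1L]] - age[phy$edge[, 2L]]
  if (any(newlen < 0))
    stop("negative implied branch length after clamping")
  phy$edge.length <- newlen
  rewrap(t, phy)
}
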