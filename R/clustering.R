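# Clustering trees into diversification types from their spectral density
# profiles: hierarchical clustering with bootstrap support, PAM k-medoids
# with silhouette-based selection of k, stability across resampled corpora,
# and a per-class null test of cluster composition.

#' Hierarchical clustering of profiles with bootstrap support
#'
#' Agglomerative clustering of the Jensen-Shannon distance matrix.  Support
#' for each internal node is the fraction of `B` bootstrap resamples (grid
#' columns of the density matrix resampled with replacement, distances and
#' dendrogram recomputed) in which the same tip set forms a clade.  Clades
#' with probability `>= alpha` are flagged significant.
#'
#' @param profiles a list of `"spectral_profile"` objects (>= 3).
#' @param linkage linkage method for [stats::hclust()].
#' @param B number of bootstrap resamples.
#' @param alpha support threshold for significance.
#' @param seed integer seed.
#' @param n_grid number of shared grid points for the densities.
#' @return a list with the observed `hclust` object, `labels`, and a
#'   data.frame `clades` (one row per internal node: members, bootstrap
#'   probability, significance flag).
#' @export
hierarchical_cluster_bootstrap <- function(profiles, linkage = "average",
                                           B = 1000L, alpha = 0.95,
                                           seed = 1L, n_grid = 1024L) {
  if (length(profiles) < 3L) stop("need at least 3 profiles")
  if (B < 2L) stop("B must be at least 2")
  if (B < 100L) warning("B < 100 gives unstable bootstrap probabilities")
  dm <- profile_distance_matrix(profiles, n_grid = n_grid)
  g <- dm$grid_densities
  hc <- stats::hclust(stats::as.dist(dm$distances), method = linkage)
  obs_clades <- clade_sets(hc)
  counts <- integer(length(obs_clades))
  with_seed(seed, {
    for (b in seq_len(B)) {
      cols <- sample.int(ncol(g), replace = TRUE)
      gb <- g[, cols, drop = FALSE]
      rs <- rowSums(gb)
      if (any(rs <= 0)) next
      db <- jsd_pairwise(gb / rs)
      dimnames(db) <- list(dm$labels, dm$labels)
      hb <- stats::hclust(stats::as.dist(db), method = linkage)
      keys <- vapply(clade_sets(hb), paste, character(1), collapse = "\r")
      okeys <- vapply(obs_clades, paste, character(1), collapse = "\r")
      counts <- counts + as.integer(okeys %in% keys)
    }
  })
  prob <- counts / B
  clades <- data.frame(
    members = vapply(obs_clades, paste, character(1), collapse = ","),
    size = lengths(obs_clades),
    bootstrap_prob = prob,
    significant = prob >= alpha,
    stringsAsFactors = FALSE)
  list(hclust = hc, labels = dm$labels, clades = clades,
       B = B, alpha = alpha, linkage = linkage)
}

# Sorted label sets of every internal node of an hclust tree.
clade_sets <- function(hc) {
  n <- length(hc$labels %||% hc$order)
  labs <- hc$labels %||% as.character(seq_len(n))
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) labs[-j] else sets[[j]]
    sets[[i]] <- sort(c(pick(hc$merge[i, 1L]), pick(hc$merge[i, 2L])))
  }
  sets
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' k-medoids clustering with silhouette-based selection of k
#'
#' Runs PAM for each candidate `k` on the profile distance matrix and keeps
#' the `k` maximizing the overall mean silhouette width; average widths
#' above 0.5 are treated as supported cluster structure.
#'
#' @param dm a `"profile_dist"` (or symmetric distance matrix).
#' @param k_range integer vector of candidate cluster counts (within
#'   `[2, n - 1]`).
#' @param seed integer seed (PAM's build/swap phases are deterministic; the
#'   seed guards any medoid sampling in degenerate inputs).
#' @return an object of class `"tree_clusters"`: a list with `assignments`
#'   (named integer vector), `k`, `silhouette` (per-tree widths), per-cluster
#'   and overall `mean_silhouette`, `medoids`, `supported`, and the per-k
#'   silhouette trace `k_trace`.
#' @export
kmedoids_select_k <- function(dm, k_range = 2:10, seed = 1L) {
  d <- if (inherits(dm, "profile_dist")) dm$distances else as.matrix(dm)
  labels <- if (inherits(dm, "profile_dist")) dm$labels
            else (rownames(d) %||% as.character(seq_len(nrow(d))))
  n <- nrow(d)
  if (n < 4L) stop("need at least 4 trees to select k")
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (length(k_range) == 0L) stop("empty k_range after clipping to [2, n-1]")
  if (max(d) == 0) {
    # all points identical: silhouettes are undefined, no supported k
    return(structure(list(assignments = NULL, k = NA_integer_,
                          silhouette = NULL, mean_silhouette = NA_real_,
                          cluster_silhouette = NULL, medoids = NULL,
                          supported = FALSE,
                          k_trace = data.frame(k = k_range,
                                               avg_silhouette = NA_real_)),
                     class = "tree_clusters"))
  }
  fits <- list(); avg <- rep(NA_real_, length(k_range))
  with_seed(seed, {
    for (i in seq_along(k_range)) {
      f <- cluster::pam(stats::as.dist(d), k = k_range[i], diss = TRUE)
      fits[[i]] <- f
      avg[i] <- f$silinfo$avg.width
    }
  })
  if (all(!is.finite(avg))) {
    return(structure(list(assignments = NULL, k = NA_integer_,
                          silhouette = NULL, mean_silhouette = NA_real_,
                          cluster_silhouette = NULL, medoids = NULL,
                          supported = FALSE,
                          k_trace = data.frame(k = k_range, avg_silhouette = avg)),
                     class = "tree_clusters"))
  }
  best <- which.max(avg)
  f <- fits[[best]]
  asg <- f$clustering
  names(asg) <- labels
  sil <- f$silinfo$widths
  rn <- rownames(sil)
  pos <- if (all(rn %in% labels)) match(labels, rn)
         else match(as.character(seq_len(n)), rn)
  sil_w <- sil[pos, "sil_width"]
  names(sil_w) <- labels
  structure(list(
    assignments = asg,
    k = k_range[best],
    silhouette = sil_w,
    mean_silhouette = avg[best],
    cluster_silhouette = f$silinfo$clus.avg.widths,
    medoids = labels[f$id.med],
    supported = is.finite(avg[best]) && avg[best] > 0.5,
    k_trace = data.frame(k = k_range, avg_silhouette = avg)),
    class = "tree_clusters")
}

#' @export
print.tree_clusters <- function(x, ...) {
  if (is.na(x$k)) {
    cat("tree_clusters: no supported k (degenerate distances)\n")
  } else {
    cat(sprintf("tree_clusters: k = %d, mean silhouette %.3f (%s)\n",
                x$k, x$mean_silhouette,
                if (x$supported) "supported" else "not supported"))
    print(table(cluster = x$assignments))
  }
  invisible(x)
}

# Maximum-agreement matching of two partitions (labels aligned by name):
# number of items on which the partitions agree after the best relabeling
# of b's clusters onto a's.  Exhaustive over permutations for small k,
# greedy otherwise.
max_agreement <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  ka <- max(a); kb <- max(b)
  tab <- table(factor(a, levels = seq_len(ka)), factor(b, levels = seq_len(kb)))
  k <- max(ka, kb)
  m <- matrix(0, k, k)
  m[seq_len(ka), seq_len(kb)] <- tab
  if (k <= 7L) {
    perms <- all_permutations(k)
    best <- 0
    for (p in perms) best <- max(best, sum(m[cbind(seq_len(k), p)]))
  } else {
    best <- 0; mm <- m
    for (i in seq_len(k)) {
      idx <- which(mm == max(mm), arr.ind = TRUE)[1L, ]
      best <- best + mm[idx[1L], idx[2L]]
      mm[idx[1L], ] <- -1; mm[, idx[2L]] <- -1
    }
  }
  best
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L))
    for (pos in 0:(k - 1L))
      out[[length(out) + 1L]] <- append(p, k, after = pos)
  out
}

#' Clustering stability across resampled corpora
#'
#' Reruns [kmedoids_select_k()] on each corpus (e.g. profiles recomputed
#' from posterior samples of the source trees) and compares the result with
#' a reference clustering: the fraction of corpora recovering the same `k`,
#' the fraction whose assignment is identical up to cluster relabeling
#' (maximum-agreement matching), and the worst-case fraction of trees placed
#' differently.
#'
#' @param corpora a list; each element is either a list of profiles or a
#'   `"profile_dist"` covering the same tree labels as the reference.
#' @param reference a `"tree_clusters"` result.
#' @param k_range,seed passed to [kmedoids_select_k()].
#' @return a list with `pct_same_k`, `pct_identical_assignment`,
#'   `max_pct_mismatched` (all percentages) and the per-corpus detail table.
#' @export
cluster_stability <- function(corpora, reference, k_range = 2:10, seed = 1L) {
  ref <- reference$assignments
  n <- length(ref)
  same_k <- logical(length(corpora))
  mism <- numeric(length(corpora))
  for (i in seq_along(corpora)) {
    ci <- corpora[[i]]
    dm <- if (inherits(ci, "profile_dist")) ci else profile_distance_matrix(ci)
    if (!setequal(dm$labels, names(ref)))
      stop("corpus ", i, " does not cover the reference tree labels")
    cl <- kmedoids_select_k(dm, k_range = k_range,
                            seed = derive_seed(seed, i))
    same_k[i] <- identical(cl$k, reference$k)
    asg <- cl$assignments[names(ref)]
    mism[i] <- 1 - max_agreement(ref, asg) / n
  }
  list(pct_same_k = 100 * mean(same_k),
       pct_identical_assignment = 100 * mean(same_k & mism == 0),
       max_pct_mismatched = 100 * max(mism),
       detail = data.frame(corpus = seq_along(corpora), same_k = same_k,
                           pct_mismatched = 100 * mism))
}

#' Null test of class composition across clusters
#'
#' For each taxonomic class of `x` trees, draws `x` trees into clusters with
#' probabilities proportional to observed cluster sizes, `n_iter` times,
#' yielding a null distribution of per-cluster counts.  An observed count is
#' flagged significant when it falls in the lower or upper `tail` of its
#' null distribution.
#'
#' @param assignments named integer vector of cluster ids.
#' @param class_labels character vector of class labels, aligned with
#'   `assignments`.
#' @param n_iter number of null draws.
#' @param seed integer seed.
#' @param tail one-sided tail probability threshold (default 0.05).
#' @return a data.frame with one row per (class, cluster): observed count,
#'   null mean, lower/upper empirical tail probabilities, significance flag.
#' @export
class_composition_null <- function(assignments, class_labels, n_iter = 500L,
                                   seed = 1L, tail = 0.05) {
  stopifnot(length(assignments) == length(class_labels))
  if (anyNA(assignments) || anyNA(class_labels))
    stop("every tree needs a class label and a cluster assignment")
  if (n_iter < 100L) warning("n_iter < 100 gives coarse tail probabilities")
  clusters <- sort(unique(assignments))
  sizes <- as.numeric(table(factor(assignments, levels = clusters)))
  probs <- sizes / sum(sizes)
  out <- list()
  with_seed(seed, {
    for (cl in unique(class_labels)) {
      x <- sum(class_labels == cl)
      draws <- stats::rmultinom(n_iter, size = x, prob = probs)  # k x n_iter
      obs <- as.numeric(table(factor(assignments[class_labels == cl],
                                     levels = clusters)))
      for (j in seq_along(clusters)) {
        p_lo <- mean(draws[j, ] <= obs[j])
        p_hi <- mean(draws[j, ] >= obs[j])
        out[[length(out) + 1L]] <- data.frame(
          class = cl, cluster = clusters[j], observed = obs[j],
          expected = x * probs[j], p_lower = p_lo, p_upper = p_hi,
          significant = (p_lo < tail) || (p_hi < tail),
          stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, out)
}
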