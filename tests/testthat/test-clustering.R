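# Hierarchical bootstrap, k-medoids selection, stability, and the
# class-composition null test.

# Two planted groups of well-separated Gaussian-bump profiles.
two_group_profiles <- function(n_per = 5, gap = 6, seed = 1) {
  with_seed(seed, {
    mus <- c(rnorm(n_per, 0, 0.2), rnorm(n_per, gap, 0.2))
  })
  profs <- lapply(mus, gaussian_profile)
  labels <- c(paste0("a", seq_len(n_per)), paste0("b", seq_len(n_per)))
  list(profiles = profs, labels = labels,
       truth = rep(c("a", "b"), each = n_per))
}

test_that("bootstrap recovers well-separated planted clades with high support", {
  g <- two_group_profiles(5, gap = 6, seed = 3)
  for (i in seq_along(g$profiles)) g$profiles[[i]]$label <- g$labels[i]
  hb <- hierarchical_cluster_bootstrap(g$profiles, B = 200, seed = 11)
  for (side in c("a", "b")) {
    want <- paste(sort(g$labels[g$truth == side]), collapse = ",")
    row <- hb$clades[hb$clades$members == want, ]
    expect_equal(nrow(row), 1L)
    expect_gte(row$bootstrap_prob, 0.95)
    expect_true(row$significant)
  }
})

test_that("bootstrap probabilities are deterministic under a fixed seed", {
  g <- two_group_profiles(4, gap = 3, seed = 5)
  h1 <- hierarchical_cluster_bootstrap(g$profiles, B = 150, seed = 42)
  h2 <- hierarchical_cluster_bootstrap(g$profiles, B = 150, seed = 42)
  expect_identical(h1$clades$bootstrap_prob, h2$clades$bootstrap_prob)
  expect_error(hierarchical_cluster_bootstrap(g$profiles, B = 1), "at least 2")
  expect_warning(hierarchical_cluster_bootstrap(g$profiles, B = 50, seed = 1),
                 "B < 100")
})

test_that("k-medoids selects k = 2 for two tight blobs with high silhouette", {
  d <- as.matrix(stats::dist(c(0, 0.1, 0.05, 10, 10.1, 10.05)))
  rownames(d) <- colnames(d) <- paste0("t", 1:6)
  km <- kmedoids_select_k(d, k_range = 2:5, seed = 1)
  expect_equal(km$k, 2L)
  expect_gt(km$mean_silhouette, 0.9)
  expect_true(km$supported)
  expect_equal(unname(km$assignments[1:3]), rep(km$assignments[[1]], 3))
  # silhouette widths computed per tree and bounded
  expect_true(all(km$silhouette >= -1 & km$silhouette <= 1))
})

test_that("identical points yield no supported k", {
  d <- matrix(0, 5, 5)
  km <- kmedoids_select_k(d, k_range = 2:4, seed = 1)
  expect_false(km$supported)
  expect_true(is.na(km$k))
})

test_that("k-medoids objective is non-increasing over pam's build/swap", {
  # swap phase cannot worsen the build objective
  with_seed(9, d <- as.matrix(stats::dist(runif(20))))
  for (k in 2:4) {
    f_build <- cluster::pam(stats::as.dist(d), k, diss = TRUE, do.swap = FALSE)
    f_swap <- cluster::pam(stats::as.dist(d), k, diss = TRUE)
    obj <- function(f) sum(vapply(seq_len(20), function(i)
      d[i, f$id.med[f$clustering[i]]], 0))
    expect_lte(obj(f_swap), obj(f_build) + 1e-12)
  }
})

test_that("cluster_stability reports identity for identical corpora and flags a swap", {
  g <- two_group_profiles(5, gap = 6, seed = 7)
  for (i in seq_along(g$profiles)) g$profiles[[i]]$label <- g$labels[i]
  dm <- profile_distance_matrix(g$profiles)
  ref <- kmedoids_select_k(dm, k_range = 2:5, seed = 1)
  st <- cluster_stability(list(dm, dm, dm), ref, k_range = 2:5, seed = 1)
  expect_equal(st$pct_same_k, 100)
  expect_equal(st$pct_identical_assignment, 100)
  expect_equal(st$max_pct_mismatched, 0)

  # swap one tree's profile to the other cluster's medoid: exactly one
  # tree lands in the wrong cluster
  profs2 <- g$profiles
  med_b <- which(g$labels == setdiff(ref$medoids, g$labels[1:5]))[1]
  if (length(med_b) == 0 || is.na(med_b)) med_b <- 10L
  profs2[[1]] <- profs2[[med_b]]
  profs2[[1]]$label <- g$labels[1]
  dm2 <- profile_distance_matrix(profs2, labels = g$labels)
  st2 <- cluster_stability(list(dm2), ref, k_range = 2:2, seed = 1)
  expect_equal(st2$max_pct_mismatched, 10, tolerance = 1e-9)  # 1 of 10 trees
})

test_that("class composition null matches binomial tail oracles", {
  # 2 clusters of equal size; a class of 3 all in one cluster has
  # exceedance probability 0.5^3 = 0.125 (not significant); a class of 10
  # all in one cluster has 0.5^10 ~ 0.001 (significant)
  assignments <- c(rep(1L, 20), rep(2L, 20))
  classes <- rep("other", 40)
  classes[1:3] <- "tiny"
  out <- class_composition_null(assignments, classes, n_iter = 50000, seed = 2)
  row <- out[out$class == "tiny" & out$cluster == 1, ]
  expect_equal(row$p_upper, 0.125, tolerance = 0.03)
  expect_false(row$significant)

  classes2 <- rep("other", 40)
  classes2[1:10] <- "big"
  # keep cluster sizes equal so the null stays at p = 1/2
  out2 <- class_composition_null(assignments, classes2, n_iter = 50000, seed = 3)
  row2 <- out2[out2$class == "big" & out2$cluster == 1, ]
  expect_equal(row2$p_upper, 0.5^10, tolerance = 5e-3)
  expect_true(row2$significant)
})

test_that("a class matching the global composition is never flagged", {
  assignments <- rep(1:5, each = 20)
  classes <- rep(rep(c("x", "y"), each = 10), 5)  # both classes evenly spread
  out <- class_composition_null(assignments, classes, n_iter = 500, seed = 4)
  expect_false(any(out$significant))
})

test_that("max_agreement matches partitions up to relabeling", {
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(3, 3, 1, 1, 2, 2)  # same partition, relabeled
  expect_equal(phylospace:::max_agreement(a, b), 6)
  b2 <- c(3, 3, 1, 2, 2, 2)
  expect_equal(phylospace:::max_agreement(a, b2), 5)
})
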