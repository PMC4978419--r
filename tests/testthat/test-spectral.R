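# MGL construction and spectral density profiles.

test_that("cherry MGL matches the hand-computed matrix and spectrum", {
  m <- build_mgl(parse_newick("(A:1,B:1);"))
  expect_equal(unname(m[c("node3", "A", "B"), c("node3", "A", "B")]),
               rbind(c(2, -1, -1), c(-1, 3, -2), c(-1, -2, 3)))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev, decreasing = TRUE), c(5, 3, 0), tolerance = 1e-12)
  p <- spectral_profile(parse_newick("(A:1,B:1);"))
  expect_equal(p$lambda_star, log(5), tolerance = 1e-12)
})

test_that("MGL structure: zero row sums, PSD, trace identity, svd oracle", {
  for (seed in 1:25) {
    tr <- random_rough_tree(sample(3:6, 1), seed)
    m <- build_mgl(tr)
    expect_lt(max(abs(rowSums(m))), 1e-10 * max(1, max(abs(m))))
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    lmax <- max(ev)
    expect_gt(min(ev), -1e-8 * lmax)             # PSD
    expect_lt(abs(min(abs(ev))), 1e-8 * lmax)    # structural zero
    d <- node_distance_matrix(tr)
    expect_equal(sum(diag(m)), sum(d), tolerance = 1e-10)  # trace = 2 * pairs
    # independent solver: singular values of a PSD matrix are its eigenvalues
    sv <- svd(m, nu = 0, nv = 0)$d
    expect_equal(sort(ev, decreasing = TRUE), sort(sv, decreasing = TRUE),
                 tolerance = 1e-8)
  }
  expect_error(build_mgl(ape::read.tree(text = "(A:1);")), "2 tips")
})

test_that("spectrum scales linearly with branch lengths; psi and eta invariant", {
  tr <- random_ultrametric_tree(12, 3)
  p0 <- spectral_profile(tr)
  ev0 <- p0$eigenvalues
  for (cc in c(0.1, 2, 10)) {
    trc <- tr
    trc$phy$edge.length <- trc$phy$edge.length * cc
    pc <- spectral_profile(trc)
    expect_equal(pc$eigenvalues, cc * ev0, tolerance = 1e-10)
    expect_equal(pc$lambda_star, p0$lambda_star + log(cc), tolerance = 1e-10)
    expect_equal(pc$psi, p0$psi, tolerance = 1e-6)
    expect_equal(pc$eta, p0$eta, tolerance = 1e-6)
  }
})

test_that("spectrum is invariant under tip relabeling and rotation", {
  tr <- random_ultrametric_tree(10, 9)
  p1 <- spectral_profile(tr)
  phy2 <- ape::rotateConstr(tr$phy, rev(tr$phy$tip.label))
  phy2$tip.label <- phy2$tip.label[sample(length(phy2$tip.label))]
  p2 <- spectral_profile(tree_record(phy2))
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-8)
})

test_that("lambda* strictly increases when a tip is attached", {
  for (seed in 1:5) {
    tr <- random_ultrametric_tree(sample(4:8, 1), seed + 30)
    p0 <- spectral_profile(tr)
    phy2 <- with_seed(seed, ape::bind.tree(
      tr$phy, ape::read.tree(text = "(new:0.5);"),
      where = sample(length(tr$phy$tip.label), 1)))
    p1 <- spectral_profile(tree_record(phy2))
    expect_gt(p1$lambda_star, p0$lambda_star)
  }
})

test_that("density integrates to one and eta is its maximum", {
  tr <- random_ultrametric_tree(30, 11)
  p <- spectral_profile(tr)
  area <- sum(diff(p$density$x) *
                (head(p$density$y, -1) + tail(p$density$y, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-6)
  expect_equal(p$eta, max(p$density$y))
  expect_equal(p$lambda_star, log(max(p$eigenvalues)))
})

test_that("psi is zero for a perfectly symmetric spectrum", {
  # symmetric toy spectra pushed through the same skewness estimator
  expect_equal(phylospace:::moment_skewness(c(-2, -1, 0, 1, 2)), 0)
  expect_equal(phylospace:::moment_skewness(c(2, 4, 6)), 0, tolerance = 1e-12)
  # two-eigenvalue spectra (e.g. the cherry) report zero by convention
  expect_equal(spectral_profile(parse_newick("(A:1,B:1);"))$psi, 0)
})

test_that("eigengap modality reads the largest gap, ties to the left", {
  expect_equal(eigengap_modality(c(10, 1, 0.9, 0.8, 0)), 1L)
  expect_equal(eigengap_modality(c(10, 9.5, 1, 0.9, 0)), 2L)
  expect_equal(eigengap_modality(c(10, 7, 4, 1)), 1L)  # tie -> smaller index
  expect_error(eigengap_modality(5), "at least 2")
})

test_that("profile modality scans gaps of the nonzero spectrum", {
  # two tight 2-tip clusters far apart: the 7x7 MGL spectrum is
  # {1308.7, 711, 711, 707, 706.3, 704, 0}; with the structural zero
  # excluded the dominant gap sits after the first eigenvalue
  tr <- parse_newick("((A:1,B:1):100,(C:1,D:1):100);")
  m <- build_mgl(tr)
  ev <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  expect_equal(eigengap_modality(ev[ev > 1e-8 * max(ev)]), 1L)
  expect_equal(spectral_profile(tr)$modality, 1L)
  # including the structural zero would let the terminal drop dominate
  expect_equal(eigengap_modality(ev), 6L)
})

test_that("drop_below threshold excludes small eigenvalues from the ln-transform", {
  tr <- random_ultrametric_tree(8, 21)
  p0 <- spectral_profile(tr)
  p1 <- spectral_profile(tr, drop_below = 1)
  expect_true(all(exp(p1$ln_eigenvalues) > 1))
  expect_lte(length(p1$ln_eigenvalues), length(p0$ln_eigenvalues))
})
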