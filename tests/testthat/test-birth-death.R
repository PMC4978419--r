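# Birth-death simulator: Yule moments, conditioning, rejection behavior,
# and the planted five-regime corpus.

test_that("pure-birth mean tip count matches the Yule expectation", {
  p <- bd_params("constant", b = 0.1, d = 0, age = 20)
  tips <- vapply(1:400, function(s) {
    tr <- simulate_bd_tree(p, seed = s)
    if (is_bd_rejection(tr)) NA_real_ else length(tr$phy$tip.label)
  }, 0)
  tips <- tips[!is.na(tips)]
  # crown process: E[N] = 2 exp(bT); pure birth never rejects for richness
  expect_gt(length(tips), 390)
  se <- stats::sd(tips) / sqrt(length(tips))
  expect_lt(abs(mean(tips) - 2 * exp(2)), 3 * se)
})

test_that("accepted trees are ultrametric with exact crown age", {
  for (seed in 1:20) {
    p <- bd_params("constant", b = 0.15, d = 0.05, age = 15)
    tr <- simulate_bd_tree(p, seed = seed)
    if (is_bd_rejection(tr)) next
    m <- tree_metrics(tr, tol = 1e-8)
    expect_true(m$is_ultrametric)
    expect_true(m$is_binary)
    expect_equal(m$crown_age, 15, tolerance = 1e-8)
    expect_gte(m$n_tips, 2L)
  }
})

test_that("zero extinction never yields crown-extinct rejections", {
  p <- bd_params("constant", b = 0.2, d = 0, age = 10)
  for (seed in 1:50) {
    tr <- simulate_bd_tree(p, seed = seed)
    expect_false(is_bd_rejection(tr))
  }
})

test_that("beta = 0 in the decreasing form reduces to a constant rate", {
  pc <- bd_params("constant", b = 0.12, d = 0, age = 15)
  pd <- bd_params("decreasing", alpha = 0.12, beta = 0, d = 0, age = 15)
  tips_c <- vapply(1:300, function(s)
    length(simulate_bd_tree(pc, seed = s)$phy$tip.label), 0)
  tips_d <- vapply(1:300, function(s)
    length(simulate_bd_tree(pd, seed = s + 10000)$phy$tip.label), 0)
  ks <- suppressWarnings(stats::ks.test(tips_c, tips_d))
  expect_gt(ks$p.value, 0.01)
})

test_that("richness bounds reject out-of-range trees with a reason", {
  p <- bd_params("constant", b = 0.05, d = 0, age = 10,
                 richness_bounds = c(50L, 700L))
  rejected <- 0
  for (seed in 1:20) {
    tr <- simulate_bd_tree(p, seed = seed)
    if (is_bd_rejection(tr)) {
      rejected <- rejected + 1
      expect_true(attr(tr, "reason") %in% c("richness", "crown_extinct"))
    }
  }
  expect_gt(rejected, 15)  # E[N] ~ 3.3, well under the lower bound
})

test_that("early-burst trees are less skewed than late-burst trees at matched size", {
  # stemmy (decreasing-rate) versus tippy (increasing-rate) trees, matched
  # in crown age and richness window: the profile skewness separates them
  psi_of <- function(form, alpha, seeds) {
    out <- c()
    for (s in seeds) {
      p <- bd_params(form, alpha = alpha, beta = 0.12, d = 0, age = 40,
                     richness_bounds = c(30L, 100L))
      tr <- simulate_bd_tree(p, seed = s, max_lineages = 1000L)
      if (is_bd_rejection(tr)) next
      out <- c(out, spectral_profile(tr)$psi)
    }
    out
  }
  stemmy <- psi_of("decreasing", 0.4, 1:30)
  tippy <- psi_of("increasing", 0.0035, 1:30)
  expect_gte(length(stemmy), 10)
  expect_gte(length(tippy), 10)
  expect_lt(mean(stemmy), mean(tippy))
})

test_that("simulate_model_corpus enforces the richness filter and provenance", {
  grid <- data.frame(rate_form = c("constant", "decreasing"),
                     b = c(0.25, NA), alpha = c(NA, 0.5),
                     beta = c(NA, 0.1), d = 0, age = c(20, 30))
  corp <- simulate_model_corpus(grid, n_per_cell = 5, seed = 3,
                                richness_bounds = c(20L, 700L))
  tips <- vapply(corp$trees, function(t) length(t$phy$tip.label), 0)
  expect_true(all(tips >= 20 & tips <= 700))
  expect_equal(nrow(corp$provenance), length(corp$trees))
  expect_true(all(c("cell", "rate_form", "n_tips") %in%
                    names(corp$provenance)))
  # determinism
  corp2 <- simulate_model_corpus(grid, n_per_cell = 5, seed = 3,
                                 richness_bounds = c(20L, 700L))
  expect_identical(vapply(corp$trees, write_newick, ""),
                   vapply(corp2$trees, write_newick, ""))
})

test_that("planted corpus has five labeled regimes within its richness bounds", {
  corpus <- planted_type_corpus(n_per_type = 10, seed = 77)
  expect_length(corpus, 50L)
  regimes <- vapply(corpus, `[[`, "", "regime")
  expect_equal(sort(unique(regimes)), sort(names(phylospace:::planted_regimes())))
  tips <- vapply(corpus, function(t) length(t$phy$tip.label), 0)
  expect_true(all(tips >= 20 & tips <= 700))
  ages <- vapply(corpus, function(t) tree_metrics(t)$crown_age, 0)
  expect_gt(max(ages), 95)
  expect_lt(min(ages), 15)
  for (tr in corpus[seq(1, 50, by = 7)])
    expect_true(tree_metrics(tr, tol = 1e-8)$is_ultrametric)
})

test_that("planted regimes separate in profile space (between > within JSD)", {
  corpus <- planted_type_corpus(n_per_type = 10, seed = 13)
  profs <- lapply(corpus, spectral_profile)
  truth <- vapply(corpus, `[[`, "", "regime")
  dm <- profile_distance_matrix(profs, labels = paste0(truth, seq_along(profs)))
  d <- dm$distances
  same <- outer(truth, truth, "==") & upper.tri(d)
  diff_ <- !outer(truth, truth, "==") & upper.tri(d)
  expect_gt(mean(d[diff_]), mean(d[same]))
})
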