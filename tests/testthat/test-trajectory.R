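# Natural-breaks binning and trajectories through phylogenetic space.

test_that("jenks splits an obvious gap and handles edge cases", {
  jb <- jenks_breaks(c(1, 2, 3, 100, 101, 102), k = 2)
  expect_equal(jb$assignment, c(1, 1, 1, 2, 2, 2))
  # k = n: every value its own class, zero within-class variance
  v <- c(4, 9, 1, 7)
  jb2 <- jenks_breaks(v, k = 4)
  expect_equal(jb2$within_ssd, 0)
  expect_equal(length(unique(jb2$assignment)), 4L)
  expect_error(jenks_breaks(c(1, 1, 2), k = 3), "distinct")
})

test_that("jenks matches the brute-force partition oracle", {
  with_seed(55, {
    for (case in 1:60) {
      n <- sample(4:12, 1)
      k <- sample(2:4, 1)
      if (k > n) next
      vals <- round(runif(n, 0, 100), 2)
      dp <- jenks_breaks(vals, k = k)
      expect_equal(dp$within_ssd, jenks_brute_force(vals, k),
                   tolerance = 1e-9)
    }
  })
})

test_that("jenks is order-invariant and deterministic", {
  with_seed(56, v <- runif(30, 0, 50))
  a <- jenks_breaks(v, k = 3)
  b <- jenks_breaks(rev(v), k = 3)
  expect_equal(sort(a$breaks), sort(b$breaks))
  expect_equal(a$within_ssd, b$within_ssd)
})

test_that("automatic k stops at the smallest class count reaching the GVF", {
  v <- c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1))
  jb <- jenks_breaks(v)
  expect_equal(jb$k, 2L)
  expect_gte(jb$gvf, 0.9)
})

test_that("trajectory bins order by age, pool to the grand mean, and pick median trees", {
  n <- 60
  with_seed(61, {
    ages <- runif(n, 5, 100)
    pts <- data.frame(label = sprintf("t%02d", 1:n),
                      lambda_star = runif(n, 6, 12),
                      psi = rnorm(n), eta = runif(n, 1, 8))
  })
  tj <- trajectory_through_space(pts, ages, k = 4)
  expect_equal(nrow(tj$bins), 4L)
  expect_true(all(diff(tj$bins$mean_age) > 0))
  # weighted pooling of bin means reproduces the grand mean
  expect_equal(sum(tj$bins$lambda_star * tj$bins$n) / n,
               mean(pts$lambda_star), tolerance = 1e-9)
  expect_true(all(tj$bins$median_tree %in% pts$label))
  # identical trees: median tree tie broken by label order
  pts2 <- pts; pts2[, 2:4] <- 1
  tj2 <- trajectory_through_space(pts2, ages, k = 2)
  for (bb in 1:2) {
    idx <- which(tj2$assignment == bb)
    expect_equal(tj2$bins$median_tree[bb], sort(pts2$label[idx])[1])
  }
})

test_that("bin means land in their planted type regions", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  pts <- data.frame(label = as.character(1:16),
                    lambda_star = c(cube[, 1], cube[, 1] + 5),
                    psi = c(cube[, 2], cube[, 2] + 5),
                    eta = c(cube[, 3], cube[, 3] + 5),
                    cluster = rep(c(1L, 2L), each = 8))
  th <- type_hulls(pts)
  ages <- c(rep(10, 8), rep(50, 8))  # young trees in hull 1, old in hull 2
  tj <- trajectory_through_space(pts, ages, hulls = th, k = 2)
  expect_equal(tj$bins$type, c("1", "2"))
})

test_that("trajectory regressions recover a linear age trend and stay quiet on noise", {
  n <- 80
  with_seed(62, {
    ages <- runif(n, 5, 100)
    psi <- 0.6 * ages + rnorm(n, sd = 4)
    eta <- rnorm(n)
    ls <- 8 + 0.001 * ages + rnorm(n, sd = 2)
  })
  pts <- data.frame(label = as.character(1:n), lambda_star = ls,
                    psi = psi, eta = eta)
  tr <- trajectory_regressions(pts, ages)
  psi_row <- tr[tr$statistic == "psi", ]
  expect_equal(psi_row$form, "linear")
  expect_true(psi_row$significant)
  expect_gt(psi_row$r_squared, 0.5)
  # slope close to the planted 0.6
  fit <- phylospace:::select_form(ages, psi)
  expect_equal(unname(fit$coefficients["x"]), 0.6, tolerance = 0.05)
})

test_that("cubic age trends retain cubic terms", {
  n <- 120
  with_seed(63, {
    ages <- runif(n, 1, 10)
    y <- -0.42 * ages + 0.41 * ages^2 - 0.02 * ages^3 + rnorm(n, sd = 0.5)
  })
  fit <- phylospace:::select_form(ages, y, forms = c("linear", "quadratic",
                                                     "cubic"))
  expect_equal(fit$form, "cubic")
  expect_true(fit$significant)
})

test_that("constant response reports no trend", {
  pts <- data.frame(label = as.character(1:20), lambda_star = rep(1, 20),
                    psi = rep(2, 20), eta = rep(3, 20))
  tr <- trajectory_regressions(pts, ages = 1:20)
  expect_true(all(tr$form == "none"))
  expect_false(any(tr$significant))
})

test_that("noise-only trajectories are rarely significant", {
  hits <- 0
  for (seed in 1:100) {
    with_seed(seed + 900, {
      ages <- runif(40, 5, 100)
      y <- rnorm(40)
    })
    fit <- phylospace:::select_form(ages, y, forms = c("linear", "quadratic",
                                                       "cubic"))
    if (fit$significant) hits <- hits + 1
  }
  expect_lte(hits, 10)
})
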