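# Birth-death tree simulation with constant or exponentially time-varying
# speciation, conditioned on the crown: the process starts from two crown
# lineages at time 0 (time runs from the crown toward the present) and runs
# for `age` time units.  Speciation events are generated by thinning
# against the envelope max of the rate over the remaining interval, which
# is exact for the bounded rate forms used here.  Extinct lineages are
# pruned; a simulation is rejected (reported, not silently retried) when
# either crown lineage leaves no extant descendant or the surviving tip
# count falls outside the richness bounds.

#' Birth-death simulation parameters
#'
#' Speciation rate forms: `"constant"` uses rate `b`; `"decreasing"` uses
#' `alpha * exp(-beta * t)` (high early rates: stemmy trees);
#' `"increasing"` uses `alpha * exp(beta * t)` (high late rates: tippy
#' trees); `"shift"` is a two-epoch form with rate `b` before
#' `shift_time` and `b2` after.  Extinction rate `d` is constant.  Time
#' `t` is measured from the crown toward the present.
#'
#' @param rate_form one of `"constant"`, `"decreasing"`, `"increasing"`,
#'   `"shift"`.
#' @param b constant speciation rate (events/lineage/My; used by
#'   `"constant"` and as the first-epoch rate of `"shift"`).
#' @param alpha initial speciation scale for the exponential forms.
#' @param beta exponential rate coefficient (1/My).
#' @param b2 second-epoch speciation rate for `"shift"`.
#' @param shift_time epoch boundary for `"shift"` (My after the crown).
#' @param d constant extinction rate.
#' @param age crown age (My).
#' @param richness_bounds length-2 integer vector; surviving trees with a
#'   tip count outside this range are rejected.
#' @return an object of class `"bd_params"`.
#' @export
bd_params <- function(rate_form = c("constant", "decreasing", "increasing",
                                    "shift"),
                      b = 0.1, alpha = 0.5, beta = 0.1, b2 = b,
                      shift_time = Inf, d = 0, age = 20,
                      richness_bounds = c(2L, Inf)) {
  rate_form <- match.arg(rate_form)
  stopifnot(b >= 0, alpha >= 0, beta >= 0, b2 >= 0, d >= 0, age > 0,
            length(richness_bounds) == 2L, richness_bounds[1L] >= 2L)
  structure(list(rate_form = rate_form, b = b, alpha = alpha, beta = beta,
                 b2 = b2, shift_time = shift_time, d = d, age = age,
                 richness_bounds = richness_bounds),
            class = "bd_params")
}

# Speciation rate at time t (vectorized).
bd_rate <- function(p, t) {
  switch(p$rate_form,
         constant = rep(p$b, length(t)),
         decreasing = p$alpha * exp(-p$beta * t),
         increasing = p$alpha * exp(p$beta * t),
         shift = ifelse(t < p$shift_time, p$b, p$b2))
}

# Upper envelope of the speciation rate over [0, age].
bd_rate_max <- function(p) {
  r <- max(bd_rate(p, c(0, p$age, min(p$shift_time, p$age))))
  if (!is.finite(r)) stop("speciation rate is non-finite on [0, age]")
  r
}

#' Simulate one crown-conditioned birth-death tree
#'
#' @param p a [bd_params()].
#' @param seed integer seed.
#' @param max_lineages simulations exceeding this many simultaneously
#'   extant lineages are abandoned as a richness rejection.
#' @return a [tree_record()] (ultrametric, crown age exactly `p$age`), or
#'   a `"bd_rejection"` object with attribute `reason` (`"crown_extinct"`
#'   or `"richness"`) when the simulation is rejected; see
#'   [is_bd_rejection()].
#' @export
#' @examples
#' t <- simulate_bd_tree(bd_params("constant", b = 0.1, age = 20), seed = 1)
#' if (!is_bd_rejection(t)) tree_metrics(t)
simulate_bd_tree <- function(p, seed = 1L, max_lineages = 20000L) {
  stopifnot(inherits(p, "bd_params"))
  lmax <- bd_rate_max(p)
  with_seed(seed, bd_simulate_core(p, lmax, max_lineages))
}

# Simulation body; assumes the RNG state is already set by the caller.
bd_simulate_core <- function(p, lmax, max_lineages) {
  reject <- function(reason)
    structure(list(), class = "bd_rejection", reason = reason)
  # lineage ledger: parent, birth time, death time (NA while alive),
  # children ids (0 = none, -1 = extinct marker)
  parent <- c(0L, 0L); birth <- c(0, 0); death <- c(NA_real_, NA_real_)
  child1 <- c(0L, 0L); child2 <- c(0L, 0L)
  alive <- c(1L, 2L)
  tnow <- 0
  total_rate_unit <- lmax + p$d
  repeat {
    n_alive <- length(alive)
    if (n_alive == 0L) break
    if (n_alive > max_lineages) return(reject("richness"))
    dt <- stats::rexp(1L, n_alive * total_rate_unit)
    tnow <- tnow + dt
    if (tnow >= p$age) break
    u <- stats::runif(1L)
    rate_now <- bd_rate(p, tnow)
    if (u < rate_now / total_rate_unit) {
      # speciation of a uniformly chosen extant lineage
      li <- alive[sample.int(n_alive, 1L)]
      id1 <- length(parent) + 1L; id2 <- id1 + 1L
      parent <- c(parent, li, li); birth <- c(birth, tnow, tnow)
      death <- c(death, NA_real_, NA_real_)
      child1 <- c(child1, 0L, 0L); child2 <- c(child2, 0L, 0L)
      child1[li] <- id1; child2[li] <- id2
      death[li] <- tnow
      alive <- c(alive[alive != li], id1, id2)
    } else if (u < (rate_now + p$d) / total_rate_unit) {
      li <- alive[sample.int(n_alive, 1L)]
      death[li] <- tnow
      child1[li] <- -1L
      alive <- alive[alive != li]
    } # else: thinned proposal, no event
  }
  death[is.na(death)] <- p$age  # survivors reach the present
  extant <- child1 == 0L & child2 == 0L & death >= p$age
  if (!has_extant(1L, child1, child2, extant) ||
      !has_extant(2L, child1, child2, extant))
    return(reject("crown_extinct"))
  n_tips <- sum(extant)
  if (n_tips < p$richness_bounds[1L] || n_tips > p$richness_bounds[2L])
    return(reject("richness"))
  nwk <- sprintf("(%s,%s);",
                 prune_newick(1L, birth, death, child1, child2, extant),
                 prune_newick(2L, birth, death, child1, child2, extant))
  tr <- parse_newick(nwk)
  tr$regime <- p$rate_form
  tr
}

#' Test whether a simulation result is a rejection
#'
#' @param x result of [simulate_bd_tree()].
#' @return `TRUE` for a rejected simulation; the rejection reason is in
#'   `attr(x, "reason")`.
#' @export
is_bd_rejection <- function(x) inherits(x, "bd_rejection")

# Does lineage id have at least one extant descendant (itself included)?
has_extant <- function(id, child1, child2, extant) {
  stack <- id
  while (length(stack)) {
    i <- stack[[1L]]; stack <- stack[-1L]
    if (extant[i]) return(TRUE)
    if (child1[i] > 0L) stack <- c(stack, child1[i], child2[i])
  }
  FALSE
}

# Newick string of the extant part of the subtree rooted at lineage `id`,
# with branch lengths accumulated through pruned (single-survivor) nodes.
# Returns NA when the subtree has no extant descendant.
prune_newick <- function(id, birth, death, child1, child2, extant,
                         extra = 0) {
  len <- death[id] - birth[id] + extra
  if (child1[id] <= 0L) {  # leaf of the full process
    if (!extant[id]) return(NA_character_)
    return(sprintf("s%d:%.10g", id, len))
  }
  s1 <- prune_newick(child1[id], birth, death, child1, child2, extant)
  s2 <- prune_newick(child2[id], birth, death, child1, child2, extant)
  if (is.na(s1) && is.na(s2)) return(NA_character_)
  if (is.na(s1) || is.na(s2)) {
    # single surviving side: splice this node out, extending the branch
    keep <- if (is.na(s1)) child2[id] else child1[id]
    return(prune_newick(keep, birth, death, child1, child2, extant,
                        extra = len))
  }
  sprintf("(%s,%s):%.10g", s1, s2, len)
}

#' Simulate a corpus over a grid of birth-death parameters
#'
#' @param grid a data.frame with one row per cell; columns are
#'   [bd_params()] arguments (missing columns take the defaults).
#' @param n_per_cell accepted trees per cell.
#' @param seed integer master seed.
#' @param richness_bounds global richness filter (default 20--700, the
#'   inclusion range of the empirical corpus).
#' @param max_attempts_per_tree attempts allowed per accepted tree before a
#'   cell is flagged.
#' @return list with `trees`, `provenance` (data.frame: cell, seed,
#'   n_tips), and `rejections` (per-cell counts, with a `flagged` column
#'   for cells with > 99% rejection).
#' @export
simulate_model_corpus <- function(grid, n_per_cell = 10L, seed = 1L,
                                  richness_bounds = c(20L, 700L),
                                  max_attempts_per_tree = 200L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  trees <- list(); prov <- list(); rej <- list()
  for (ci in seq_len(nrow(grid))) {
    args <- as.list(grid[ci, , drop = FALSE])
    args <- args[!vapply(args, function(v) is.na(v) || is.null(v), TRUE)]
    args$richness_bounds <- richness_bounds
    p <- do.call(bd_params, args)
    got <- 0L; tried <- 0L
    while (got < n_per_cell && tried < n_per_cell * max_attempts_per_tree) {
      tried <- tried + 1L
      tr <- simulate_bd_tree(p, seed = derive_seed(seed, ci * 100000 + tried))
      if (is_bd_rejection(tr)) next
      got <- got + 1L
      tr$family <- sprintf("cell%02d_%03d", ci, got)
      trees[[length(trees) + 1L]] <- tr
      prov[[length(prov) + 1L]] <- data.frame(
        cell = ci, rate_form = p$rate_form, age = p$age,
        tree = tr$family, n_tips = length(tr$phy$tip.label))
    }
    rej[[ci]] <- data.frame(cell = ci, attempts = tried, accepted = got,
                            flagged = got < tried * 0.01)
  }
  list(trees = trees, provenance = do.call(rbind, prov),
       rejections = do.call(rbind, rej))
}

# The five generative regimes used for the planted synthetic corpus.  The
# regimes are deliberately well separated in crown age, size and rate shape
# (small young constant-rate; large old constant-rate; strong early burst;
# strong late acceleration; two-epoch shift), spanning crown ages ~5-110 My
# with tip counts inside the 20-700 inclusion range of the family-level
# corpus the package emulates.  Each regime additionally conditions on its
# own richness window (as a family category of a given size class), which
# keeps the within-regime spread of the profile statistics well below the
# between-regime separation.
planted_regimes <- function() {
  list(
    const_small = list(rate_form = "constant", b = 0.3, d = 0,
                       age_range = c(11, 13), richness = c(30, 45)),
    const_large = list(rate_form = "constant", b = 0.12, d = 0,
                       age_range = c(35, 40), richness = c(40, 55)),
    decreasing = list(rate_form = "decreasing", alpha = 0.55, beta = 0.15,
                      d = 0, age_range = c(70, 80), richness = c(70, 100)),
    increasing = list(rate_form = "increasing", alpha = 0.012, beta = 0.1,
                      d = 0, age_range = c(36, 40), richness = c(260, 340)),
    shift = list(rate_form = "shift", b = 0.015, b2 = 0.32, d = 0,
                 age_range = c(100, 110), shift_offset = 12,
                 richness = c(320, 420)))
}

#' Planted five-regime synthetic corpus
#'
#' Generates `n_per_type` accepted trees under each of five well-separated
#' diversification regimes (constant-rate small and large, strongly
#' decreasing speciation, strongly increasing speciation, and a two-epoch
#' rate shift), with crown ages spread over roughly 5--110 My and tip
#' counts within `richness_bounds`.  Regime labels are retained as ground
#' truth for planted-recovery tests.
#'
#' @param n_per_type accepted trees per regime (>= 10).
#' @param seed integer master seed.
#' @param richness_bounds tip-count filter (default 20--700).
#' @param max_attempts_per_tree attempts per accepted tree.
#' @return a list of [tree_record()]s (length `5 * n_per_type`) with
#'   `regime` set; families are labeled `"<regime>_<i>"`.
#' @export
planted_type_corpus <- function(n_per_type = 30L, seed = 1L,
                                richness_bounds = c(20L, 700L),
                                max_attempts_per_tree = 500L) {
  stopifnot(n_per_type >= 10L)
  regimes <- planted_regimes()
  out <- list()
  for (ri in seq_along(regimes)) {
    reg <- regimes[[ri]]
    rname <- names(regimes)[ri]
    got <- 0L; tried <- 0L
    while (got < n_per_type) {
      tried <- tried + 1L
      if (tried > n_per_type * max_attempts_per_tree)
        stop("regime ", rname, " rejected too many simulations")
      s <- derive_seed(seed, ri * 1000000 + tried)
      age <- with_seed(derive_seed(s, 7L),
                       stats::runif(1L, reg$age_range[1L], reg$age_range[2L]))
      args <- reg[setdiff(names(reg), c("age_range", "shift_offset",
                                        "richness"))]
      args$age <- age
      if (!is.null(reg$shift_offset)) args$shift_time <- age - reg$shift_offset
      args$richness_bounds <- c(max(reg$richness[1L], richness_bounds[1L]),
                                min(reg$richness[2L], richness_bounds[2L]))
      p <- do.call(bd_params, args)
      # abandon runs that outgrow the richness window with margin
      tr <- simulate_bd_tree(p, seed = s,
                             max_lineages = 3L * p$richness_bounds[2L])
      if (is_bd_rejection(tr)) next
      got <- got + 1L
      tr$regime <- rname
      tr$family <- sprintf("%s_%02d", rname, got)
      out[[length(out) + 1L]] <- tr
    }
  }
  out
}
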