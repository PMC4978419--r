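# End-to-end orchestration: profile -> cluster -> space -> (optional)
# sampler comparison -> trajectory, with one master seed fanned out to
# deterministic per-stage seeds, CSV/JSON outputs and a run manifest.

#' Pipeline configuration
#'
#' @param trees_dir directory of Newick files (one tree per file) named in
#'   the metadata table.
#' @param metadata_csv CSV with columns `family`, `class`, `crown_age`,
#'   `sampling_fraction`, `newick_path` (paths relative to `trees_dir`);
#'   an optional `regime` column carries generative ground truth.
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed; per-stage seeds are derived
#'   deterministically from it.
#' @param k_range candidate cluster counts for k-medoids.
#' @param bootstrap_B hierarchical-clustering bootstrap resamples.
#' @param k_max_polytope maximum archetype count.
#' @param n_perm permutations for the t-ratio test.
#' @param grid_size spectral density grid size.
#' @param run_sampler if `TRUE`, generate a phylogeny-type network corpus
#'   matched to the empirical lambda* distribution and report bounding-box
#'   occupancy/overlap.
#' @param n_sampler_trees size of that corpus.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(trees_dir, metadata_csv,
                            out_dir = file.path(trees_dir, "results"),
                            seed = 1L, k_range = 2:10, bootstrap_B = 200L,
                            k_max_polytope = 6L, n_perm = 200L,
                            grid_size = 512L, run_sampler = FALSE,
                            n_sampler_trees = 100L) {
  structure(list(trees_dir = trees_dir, metadata_csv = metadata_csv,
                 out_dir = out_dir, seed = as.integer(seed),
                 k_range = k_range, bootstrap_B = as.integer(bootstrap_B),
                 k_max_polytope = as.integer(k_max_polytope),
                 n_perm = as.integer(n_perm),
                 grid_size = as.integer(grid_size),
                 run_sampler = isTRUE(run_sampler),
                 n_sampler_trees = as.integer(n_sampler_trees)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) parse and profile every tree; (2) Jensen-Shannon distances,
#' k-medoids clustering with silhouette-selected k, per-class composition
#' null test; (3) phylogenetic-space mapping, polytope/archetype fit,
#' t-ratio test, trade-off regressions; (4) optional phylogeny-type
#' network comparison (bounding-box occupancy and overlap); (5) crown-age
#' trajectory and age regressions.  All tabular outputs are written as CSV
#' under `cfg$out_dir`, the polytope as JSON, plus `manifest.json`
#' recording seeds, stage timings and package version.  Any stage failure
#' aborts with the stage name (and the offending tree label where known);
#' partial outputs are retained.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list with all stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("phylospace")),
                   seed = cfg$seed, stages = list())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), st, units = "secs")),
      seed = derive_seed(cfg$seed, match(name, c("profile", "cluster",
                                                 "space", "sampler",
                                                 "trajectory"))))
    res
  }

  meta <- stage("profile", {
    m <- utils::read.csv(cfg$metadata_csv, stringsAsFactors = FALSE)
    need <- c("family", "class", "crown_age", "newick_path")
    if (!all(need %in% names(m)))
      stop("metadata must carry columns ", paste(need, collapse = ", "))
    m
  })
  trees <- list(); profiles <- list()
  for (i in seq_len(nrow(meta))) {
    path <- file.path(cfg$trees_dir, meta$newick_path[i])
    tr <- tryCatch(
      parse_newick(paste(readLines(path, warn = FALSE), collapse = ""),
                   family = meta$family[i], taxon_class = meta$class[i],
                   sampling_fraction = if ("sampling_fraction" %in% names(meta))
                     meta$sampling_fraction[i] else NA_real_),
      error = function(e)
        stop("pipeline stage 'profile' failed on tree '", meta$family[i],
             "': ", conditionMessage(e), call. = FALSE))
    trees[[i]] <- tr
    profiles[[i]] <- spectral_profile(tr, grid_size = cfg$grid_size)
  }
  prof_df <- data.frame(
    family = meta$family, class = meta$class,
    n_tips = vapply(profiles, `[[`, 0, "n_tips"),
    crown_age = vapply(trees, function(t) tree_metrics(t)$crown_age, 0),
    lambda_star = vapply(profiles, `[[`, 0, "lambda_star"),
    psi = vapply(profiles, `[[`, 0, "psi"),
    eta = vapply(profiles, `[[`, 0, "eta"),
    modality = vapply(profiles, function(p) as.integer(p$modality), 0L))
  write_csv_stable(prof_df, file.path(cfg$out_dir, "profiles.csv"))

  clus <- stage("cluster", {
    dm <- profile_distance_matrix(profiles, labels = meta$family)
    km <- kmedoids_select_k(dm, k_range = cfg$k_range,
                            seed = derive_seed(cfg$seed, 2L))
    hb <- hierarchical_cluster_bootstrap(profiles, B = cfg$bootstrap_B,
                                         seed = derive_seed(cfg$seed, 2L))
    comp <- class_composition_null(km$assignments, meta$class,
                                   seed = derive_seed(cfg$seed, 2L))
    list(dm = dm, km = km, hb = hb, comp = comp)
  })
  write_csv_stable(data.frame(family = meta$family,
                              cluster = clus$km$assignments,
                              silhouette = clus$km$silhouette),
                   file.path(cfg$out_dir, "clusters.csv"))
  write_csv_stable(clus$hb$clades, file.path(cfg$out_dir, "dendrogram_support.csv"))
  write_csv_stable(clus$comp, file.path(cfg$out_dir, "class_composition.csv"))

  space <- stage("space", {
    pts <- map_points(profiles, labels = meta$family,
                      cluster = clus$km$assignments,
                      taxon_class = meta$class)
    pfit <- fit_polytope(pts, k_max = cfg$k_max_polytope,
                         seed = derive_seed(cfg$seed, 3L))
    tt <- t_ratio_test(pts, k = pfit$k, n_perm = cfg$n_perm,
                       seed = derive_seed(cfg$seed, 3L),
                       fit_args = list(outer = 20L))
    to <- tradeoff_regressions(pts)
    hulls <- type_hulls(pts)
    list(points = pts, polytope = pfit, t_test = tt, tradeoffs = to,
         hulls = hulls)
  })
  write_csv_stable(space$points, file.path(cfg$out_dir, "points.csv"))
  write_csv_stable(space$tradeoffs, file.path(cfg$out_dir, "tradeoffs.csv"))
  jsonlite::write_json(
    list(k = space$polytope$k,
         explained_variance = space$polytope$explained_variance,
         vertices_normalized = space$polytope$vertices,
         vertices_raw = space$polytope$vertices_raw,
         contributions = space$polytope$contributions,
         t_ratio = space$t_test$t_ratio, p_value = space$t_test$p_value),
    file.path(cfg$out_dir, "polytope.json"), auto_unbox = TRUE, digits = NA)

  sampler <- NULL
  if (cfg$run_sampler) {
    sampler <- stage("sampler", {
      # networks are matched to the corpus: node counts span the corpus
      # tip-count range and lambda* targets are the corpus values
      scfg <- sampler_config(
        n_nodes = range(prof_df$n_tips),
        target_lambda_star = space$points$lambda_star,
        n_trees = cfg$n_sampler_trees, seed = derive_seed(cfg$seed, 4L))
      corpus <- generate_network_corpus(scfg)
      spts <- map_points(corpus$profiles)
      vs <- volume_stats(space$points, spts)
      list(corpus = corpus, points = spts, volumes = vs)
    })
    write_csv_stable(sampler$points, file.path(cfg$out_dir, "network_points.csv"))
    jsonlite::write_json(sampler$volumes,
                         file.path(cfg$out_dir, "volumes.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  traj <- stage("trajectory", {
    ages <- vapply(trees, function(t) tree_metrics(t)$crown_age, 0)
    tj <- trajectory_through_space(space$points, ages, hulls = space$hulls)
    tr <- trajectory_regressions(space$points, ages)
    list(trajectory = tj, regressions = tr, ages = ages)
  })
  write_csv_stable(traj$trajectory$bins, file.path(cfg$out_dir, "trajectory.csv"))
  write_csv_stable(traj$regressions,
                   file.path(cfg$out_dir, "trajectory_regressions.csv"))

  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$n_trees <- length(trees)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(meta = meta, trees = trees, profiles = profiles,
                 clusters = clus, space = space, sampler = sampler,
                 trajectory = traj, manifest = manifest))
}

# CSV writer with stable numeric formatting so identical runs are
# byte-identical.
write_csv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- formatC(df[[j]], digits = 12,
                                           format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}

#' Generate a synthetic study directory
#'
#' Writes a planted five-regime corpus (trees as Newick files plus a
#' metadata CSV with fabricated family names, round-robin class labels and
#' the true regime of every tree) laid out the way [run_pipeline()] expects
#' an empirical study.
#'
#' @param dir target directory (created).
#' @param seed integer seed.
#' @param n_per_type accepted trees per regime.
#' @return the path of the metadata CSV (invisibly, with attribute
#'   `trees`).
#' @export
make_synthetic_study <- function(dir, seed = 1L, n_per_type = 30L) {
  dir.create(file.path(dir, "trees"), recursive = TRUE, showWarnings = FALSE)
  corpus <- planted_type_corpus(n_per_type = n_per_type, seed = seed)
  classes <- c("Mammalia", "Aves", "Squamata", "Amphibia", "Actinopterygii")
  rows <- list()
  for (i in seq_along(corpus)) {
    tr <- corpus[[i]]
    fam <- tr$family
    path <- file.path("trees", paste0(fam, ".nwk"))
    writeLines(write_newick(tr), file.path(dir, path))
    rows[[i]] <- data.frame(
      family = fam, class = classes[(i - 1L) %% length(classes) + 1L],
      crown_age = tree_metrics(tr)$crown_age,
      sampling_fraction = 1, newick_path = path, regime = tr$regime,
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, rows)
  csv <- file.path(dir, "metadata.csv")
  write_csv_stable(meta, csv)
  out <- csv
  attr(out, "trees") <- length(corpus)
  invisible(out)
}
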