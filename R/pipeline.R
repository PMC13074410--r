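#' Default run configuration for the end-to-end pipeline
#'
#' Bundles every stage's parameters with a single seed. All clustering and
#' thinning constants default to the documented reference parameterization
#' (adaptive-radius table, retention ladder and factor caps).
#'
#' @param n_trees Number of synthetic trees to simulate.
#' @param canopy A [canopy_config] (per-tree seed derived from `seed`).
#' @param eps An [eps_params].
#' @param s1,s2 [s1_params] / [s2_params].
#' @param yield A [yield_config].
#' @param lasso List with `alpha`, `top_k`.
#' @param models Panel subset to evaluate.
#' @param nfolds CV folds.
#' @param seed Integer master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_trees = 20,
                       canopy = canopy_config(image_size = c(512, 512),
                                              n_clusters = 3,
                                              flowers_per_cluster = c(2, 16),
                                              cluster_spread_px = 20,
                                              flower_area_sd = 250,
                                              n_isolated_flowers = 2),
                       eps = eps_params(), s1 = s1_params(),
                       s2 = s2_params(), yield = yield_config(),
                       lasso = list(alpha = 0.01, top_k = 8L),
                       models = c("smr", "rf", "xgb"), nfolds = 5L,
                       seed = 1L) {
  structure(list(n_trees = n_trees, canopy = canopy, eps = eps, s1 = s1,
                 s2 = s2, yield = yield, lasso = lasso, models = models,
                 nfolds = nfolds, seed = as.integer(seed)),
            class = "run_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(strip_classes(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# jsonlite has no methods for the package's parameter classes; serialize
# them as plain named lists (data frames keep their class).
strip_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), strip_classes)
  } else {
    x
  }
}

clustering_to_list <- function(cl) {
  list(tree_id = cl$tree_id, n_points = cl$n_points,
       noise_pixel_count = cl$noise_pixel_count,
       clusters = cl$clusters, flowers = cl$flowers,
       cluster_pixels = lapply(cl$cluster_pixels, as.integer),
       flower_pixels = lapply(cl$flower_pixels, as.integer))
}

thinning_to_list <- function(th) {
  list(strategy = th$strategy,
       overall_retention = th$overall_retention,
       per_cluster_ratio = as.list(th$per_cluster_ratio),
       removed_cluster_labels = as.integer(th$removed_cluster_labels),
       retained_flower_ids = as.integer(th$retained_flower_ids),
       n_retained_pixels = length(th$retained_rows))
}

#' Run the full pipeline on synthetic canopies
#'
#' Simulate -> cluster -> thin -> featurize -> generate yields -> Lasso
#' selection -> cross-validated evaluation, writing every stage's artifact
#' before the next stage starts:
#' `masks/*.png`, `truth/*.json`, `clusters/*.json`, `thinning/*.json`,
#' `features.csv`, `yield.csv`, `selected.json`, `report.json` and a
#' `manifest.json` recording the package version, seed and a config hash.
#' Rerunning with the same config reproduces the CSV/JSON artifacts
#' byte-identically.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [run_config].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("masks", "truth", "clusters", "thinning")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  tree_ids <- sprintf("tree-%03d", seq_len(config$n_trees))

  # stage 1: simulate
  truths <- vector("list", config$n_trees)
  for (i in seq_len(config$n_trees)) {
    cfg <- config$canopy
    cfg$seed <- as.integer(config$seed + i)
    tr <- generate_canopy(cfg)
    tr$mask$tree_id <- tree_ids[i]
    truths[[i]] <- tr
    write_mask(tr$mask, file.path(out_dir, "masks", paste0(tree_ids[i], ".png")))
    write_json_file(list(tree_id = tree_ids[i],
                         flower_centers = tr$flower_centers,
                         flower_areas = tr$flower_areas,
                         cluster_labels = tr$cluster_labels,
                         n_pixels = tr$n_pixels),
                    file.path(out_dir, "truth", paste0(tree_ids[i], ".json")))
  }

  # stage 2 + 3: cluster and thin
  feats <- vector("list", config$n_trees)
  for (i in seq_len(config$n_trees)) {
    cl <- cluster_image(truths[[i]]$mask, config$eps)
    write_json_file(clustering_to_list(cl),
                    file.path(out_dir, "clusters", paste0(tree_ids[i], ".json")))
    r1 <- s1_thin(cl, config$s1)
    r2 <- s2_thin(cl, config$s2)
    write_json_file(list(s1 = thinning_to_list(r1), s2 = thinning_to_list(r2)),
                    file.path(out_dir, "thinning", paste0(tree_ids[i], ".json")))
    fv <- extract_features(cl, r1, r2)
    feats[[i]] <- data.frame(tree_id = tree_ids[i], t(fv),
                             stringsAsFactors = FALSE, check.names = FALSE)
  }
  features <- do.call(rbind, feats)
  write_feature_table(features, file.path(out_dir, "features.csv"))

  # stage 4: yields
  ycfg <- config$yield
  ycfg$seed <- as.integer(config$seed + 10000L)
  yields <- generate_yield(features, ycfg)
  write_yield_table(yields, file.path(out_dir, "yield.csv"))
  features$yield_kg <- yields$yield_kg

  # stage 5: selection
  gn <- feature_group_names()
  sel <- lasso_select(as.matrix(features[, gn$mixed_all]),
                      features$yield_kg,
                      alpha = config$lasso$alpha, top_k = config$lasso$top_k)
  write_json_file(sel, file.path(out_dir, "selected.json"))

  # stage 6: evaluation
  ev <- evaluate_models(features, groups = "mixed_all",
                        models = config$models, seed = config$seed,
                        nfolds = config$nfolds)
  write_json_file(list(seed = ev$seed, nfolds = ev$nfolds,
                       summary = ev$summary),
                  file.path(out_dir, "report.json"))

  cfg_path <- file.path(out_dir, "config.json")
  write_json_file(config, cfg_path)
  manifest <- list(
    package = "bloomthin",
    version = as.character(utils::packageVersion("bloomthin")),
    seed = config$seed,
    n_trees = config$n_trees,
    config_md5 = unname(tools::md5sum(cfg_path)),
    artifacts = c("masks/", "truth/", "clusters/", "thinning/",
                  "features.csv", "yield.csv", "selected.json",
                  "report.json", "config.json"))
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
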