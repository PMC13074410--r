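#' The 50-feature flowering phenotype schema
#'
#' The phenotype vector has three fixed blocks: 23 features from the
#' original (un-thinned) clustering, 13 from thinning strategy 1 and 14
#' from strategy 2, 50 in total. The block contents cover seven trait
#' categories: cluster counts (overall and per size grade), cluster areas,
#' single-flower counts, cluster morphology (roundness, compactness),
#' spatial distribution (area variance, positional dispersion, uniformity),
#' post-thinning counts/areas, and within-cluster flower density. "Dense"
#' clusters are clusters holding at least `dense_min_flowers` single
#' flowers (default 8). The uniformity score is the coefficient of
#' variation of flower nearest-neighbour distances (lower = more uniform).
#'
#' @return Named list of character vectors `original` (23), `strategy1`
#'   (13), `strategy2` (14).
#' @export
feature_schema <- function() {
  list(
    original = c(
      "n_clusters_total", "small_counts", "medium_counts", "large_counts",
      "supersized_counts", "dense_counts", "total_flower_area", "small_area",
      "medium_area", "large_area", "supersized_area", "dense_area",
      "n_single_total", "n_isolated_singles", "avg_flowers_per_cluster",
      "max_flowers_per_cluster", "mean_circularity", "mean_compactness",
      "cluster_area_variance", "single_position_dispersion",
      "uniformity_score", "mean_cluster_area", "median_single_area"),
    strategy1 = c(
      "s1_n_clusters_retained", "s1_total_retained_area", "avg_dynamic_ratio",
      "s1_small_area", "s1_medium_area", "s1_large_area", "s1_supersized_area",
      "s1_dense_area", "s1_n_removed_noise_clusters",
      "s1_retained_pixel_fraction", "s1_n_fully_retained_clusters",
      "s1_retained_area_variance", "s1_mean_retained_cluster_area"),
    strategy2 = c(
      "retained_flowers_s2_total", "s2_n_clusters_retained",
      "s2_total_retained_area", "s2_small_area", "s2_medium_area",
      "s2_large_area", "s2_supersized_area", "s2_dense_area",
      "s2_n_merged_clusters", "s2_retained_pixel_fraction",
      "s2_mean_retained_flowers_per_cluster", "s2_mean_nn_distance_retained",
      "s2_uniformity_retained", "s2_mean_retained_flower_area"))
}

sum_by_grade <- function(values, grades) {
  vapply(c("small", "medium", "large", "supersized"),
         function(g) sum(values[grades == g]), numeric(1))
}

mean0 <- function(x) if (length(x) == 0) 0 else mean(x)
var0 <- function(x) if (length(x) < 2) 0 else stats::var(x)

#' Extract the 50-feature phenotype vector of one tree
#'
#' All three inputs must come from the same mask (same pixel universe).
#' Statistics over empty sets (e.g. no cluster survives thinning) are
#' reported as 0.
#'
#' @param clustering A `bloom_clustering` from [cluster_image()].
#' @param s1,s2 `bloom_thinning` results of the two strategies for the same
#'   clustering.
#' @param dense_min_flowers Minimum single-flower count for a cluster to
#'   count as dense (default 8).
#' @return Named numeric vector of length 50, ordered per
#'   [feature_schema()].
#' @export
extract_features <- function(clustering, s1, s2, dense_min_flowers = 8L) {
  stopifnot(inherits(clustering, "bloom_clustering"),
            inherits(s1, "bloom_thinning"), inherits(s2, "bloom_thinning"))
  if (s1$strategy != "s1" || s2$strategy != "s2") {
    stop("`s1`/`s2` must be results of strategies s1 and s2 respectively")
  }
  if (s1$n_points != clustering$n_points || s2$n_points != clustering$n_points) {
    stop("thinning results and clustering refer to different pixel universes")
  }
  cls <- clustering$clusters
  fl <- clustering$flowers
  dense <- if (nrow(cls)) cls$n_flowers >= dense_min_flowers else logical(0)
  fc <- cbind(fl$centroid_row, fl$centroid_col)

  orig <- c(
    n_clusters_total = nrow(cls),
    setNames(vapply(c("small", "medium", "large", "supersized"),
                    function(g) sum(cls$grade == g), numeric(1)),
             c("small_counts", "medium_counts", "large_counts",
               "supersized_counts")),
    dense_counts = sum(dense),
    total_flower_area = sum(cls$area),
    setNames(sum_by_grade(cls$area, cls$grade),
             c("small_area", "medium_area", "large_area", "supersized_area")),
    dense_area = sum(cls$area[dense]),
    n_single_total = nrow(fl),
    n_isolated_singles = sum(cls$n_flowers == 1),
    avg_flowers_per_cluster = mean0(cls$n_flowers),
    max_flowers_per_cluster = if (nrow(cls)) max(cls$n_flowers) else 0,
    mean_circularity = mean0(cls$circularity),
    mean_compactness = mean0(cls$compactness),
    cluster_area_variance = var0(cls$area),
    single_position_dispersion = if (nrow(fl) > 0) {
      ctr <- colMeans(fc)
      mean(sqrt((fc[, 1] - ctr[1])^2 + (fc[, 2] - ctr[2])^2))
    } else 0,
    uniformity_score = cv_of(nn_dists(fc)),
    mean_cluster_area = mean0(cls$area),
    median_single_area = if (nrow(fl)) median(fl$area) else 0)

  k1 <- s1$per_cluster_kept
  if (length(k1) == 0) k1 <- setNames(numeric(nrow(cls)), cls$label)
  r1 <- s1$assigned_ratio
  if (is.null(r1)) r1 <- s1$per_cluster_ratio
  strat1 <- c(
    s1_n_clusters_retained = sum(k1 > 0),
    s1_total_retained_area = sum(k1),
    avg_dynamic_ratio = mean0(r1),
    setNames(sum_by_grade(k1, cls$grade),
             c("s1_small_area", "s1_medium_area", "s1_large_area",
               "s1_supersized_area")),
    s1_dense_area = sum(k1[dense]),
    s1_n_removed_noise_clusters = length(s1$removed_cluster_labels),
    s1_retained_pixel_fraction = s1$overall_retention,
    s1_n_fully_retained_clusters = sum(s1$per_cluster_ratio == 1),
    s1_retained_area_variance = var0(k1[k1 > 0]),
    s1_mean_retained_cluster_area = mean0(k1[k1 > 0]))

  rf <- fl[fl$flower_id %in% s2$retained_flower_ids, , drop = FALSE]
  kept2 <- table(factor(rf$parent_label, levels = cls$label))
  area2 <- vapply(cls$label, function(lab) {
    sum(rf$area[rf$parent_label == lab])
  }, numeric(1))
  rfc <- cbind(rf$centroid_row, rf$centroid_col)
  strat2 <- c(
    retained_flowers_s2_total = nrow(rf),
    s2_n_clusters_retained = sum(kept2 > 0),
    s2_total_retained_area = length(s2$retained_rows),
    setNames(sum_by_grade(area2, cls$grade),
             c("s2_small_area", "s2_medium_area", "s2_large_area",
               "s2_supersized_area")),
    s2_dense_area = sum(area2[dense]),
    s2_n_merged_clusters = length(s2$merged_away_labels),
    s2_retained_pixel_fraction = s2$overall_retention,
    s2_mean_retained_flowers_per_cluster = mean0(as.numeric(kept2[kept2 > 0])),
    s2_mean_nn_distance_retained = mean0(nn_dists(rfc)),
    s2_uniformity_retained = cv_of(nn_dists(rfc)),
    s2_mean_retained_flower_area = mean0(rf$area))

  out <- c(orig, strat1, strat2)
  sch <- feature_schema()
  stopifnot(identical(names(out), unname(unlist(sch))))
  out
}

#' Split a feature table into the named feature groups
#'
#' The five groups mirror the phenotype blocks: `original` (23 features),
#' `strategy1` (13), `strategy2` (14), `mixed_strategy` (the union of the
#' two strategy blocks, 27) and `mixed_all` (everything, 50).
#'
#' @param table Feature table (data frame with `tree_id`, the 50 schema
#'   columns and optionally `yield_kg`).
#' @return Named list of data frames, each keeping `tree_id` (and
#'   `yield_kg` when present) plus the group's feature columns.
#' @export
feature_groups <- function(table) {
  stopifnot(is.data.frame(table))
  sch <- feature_schema()
  missing_cols <- setdiff(unlist(sch), names(table))
  if (length(missing_cols) > 0) {
    stop("feature table lacks schema columns: ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  groups <- list(original = sch$original,
                 strategy1 = sch$strategy1,
                 strategy2 = sch$strategy2,
                 mixed_strategy = c(sch$strategy1, sch$strategy2),
                 mixed_all = unlist(sch, use.names = FALSE))
  keep <- intersect(c("tree_id", "yield_kg"), names(table))
  lapply(groups, function(cols) table[, c(keep, cols), drop = FALSE])
}

#' @rdname feature_groups
#' @export
feature_group_names <- function() {
  sch <- feature_schema()
  list(original = sch$original, strategy1 = sch$strategy1,
       strategy2 = sch$strategy2,
       mixed_strategy = c(sch$strategy1, sch$strategy2),
       mixed_all = unname(unlist(sch)))
}
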