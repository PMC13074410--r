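#' Parameters of thinning strategy 1 (density-graded dynamic retention)
#'
#' Strategy 1 assigns every flower cluster a retention ratio
#' `r = clip(r_base * A_single * A_round * A_compact, r_min, r_max)` and
#' keeps the pixels nearest the cluster centroid. The base ratio follows a
#' graded area ladder referenced to the 1200 px^2 single-flower area:
#' clusters below 300 px^2 are treated as noise and removed; below 500 px^2
#' fully retained; below 1000 px^2 ratio 0.7; below 5000 px^2 ratio 0.5;
#' below 10,000 px^2 ratio 0.3; 0.2 otherwise. The multiplicative factors
#' adjust for flower count (`1 - min(n_single/20, 0.3)`), roundness
#' (`1 + min(2 * circularity, 0.2)`) and compactness
#' (`1 - 0.2 * min(compactness/50000, 1)`).
#'
#' @param ladder_breaks,ladder_ratios Area breakpoints (px^2) and the base
#'   ratio on each rung; `ladder_ratios[i]` applies to areas in
#'   `[ladder_breaks[i], ladder_breaks[i+1])`.
#' @param single_divisor,single_cap Flower-count penalty: divisor 20, cap 0.3.
#' @param round_mult,round_cap Roundness bonus: multiplier 2, cap 0.2.
#' @param compact_norm,compact_scale Compactness penalty: normalizer 50,000,
#'   scale 0.2.
#' @param r_min,r_max Retention clip, default \[0.1, 1\].
#' @return A list of class `s1_params`.
#' @export
s1_params <- function(ladder_breaks = c(0, 300, 500, 1000, 5000, 10000, Inf),
                      ladder_ratios = c(0, 1.0, 0.7, 0.5, 0.3, 0.2),
                      single_divisor = 20, single_cap = 0.3,
                      round_mult = 2, round_cap = 0.2,
                      compact_norm = 50000, compact_scale = 0.2,
                      r_min = 0.1, r_max = 1.0) {
  stopifnot(length(ladder_ratios) == length(ladder_breaks) - 1,
            !is.unsorted(ladder_breaks),
            all(diff(ladder_ratios[-1]) <= 0),  # non-increasing above removal
            r_min >= 0, r_min <= r_max, r_max <= 1)
  structure(list(ladder_breaks = ladder_breaks, ladder_ratios = ladder_ratios,
                 single_divisor = single_divisor, single_cap = single_cap,
                 round_mult = round_mult, round_cap = round_cap,
                 compact_norm = compact_norm, compact_scale = compact_scale,
                 r_min = r_min, r_max = r_max),
            class = "s1_params")
}

#' Parameters of thinning strategy 2 (spatially uniform flower retention)
#'
#' Strategy 2 first merges flower clusters whose centroids are closer than
#' `merge_distance` (keeping the larger cluster), then greedily retains
#' `T = max(1, round(retain_fraction * n_flowers))` flowers per cluster by
#' a score that favours large, round flowers near the cluster centre first
#' and spatial dispersion from already-selected flowers afterwards.
#'
#' @param retain_fraction Fraction of flowers kept per cluster (default
#'   0.2, matching the ~19% average pixel retention this strategy targets).
#' @param merge_distance Centroid merge threshold, px (default 30,
#'   about 1.5 x the maximum macro radius).
#' @param w_center Weight of the centre-proximity term once flowers have
#'   been selected (the rest weighs dispersion), default 0.5.
#' @return A list of class `s2_params`.
#' @export
s2_params <- function(retain_fraction = 0.2, merge_distance = 30,
                      w_center = 0.5) {
  stopifnot(retain_fraction > 0, retain_fraction <= 1, merge_distance > 0,
            w_center >= 0, w_center <= 1)
  structure(list(retain_fraction = retain_fraction,
                 merge_distance = merge_distance, w_center = w_center),
            class = "s2_params")
}

#' Strategy-1 retention ratio of one cluster
#'
#' @param cluster One-row slice of a clustering's `clusters` table (needs
#'   `area`, `circularity`, `compactness`).
#' @param n_single Number of single flowers in the cluster.
#' @param params An [s1_params] object.
#' @return Retention ratio in `{0} U [r_min, r_max]`. Clusters below the
#'   removal breakpoint return 0; clusters below the full-retention
#'   breakpoint return exactly 1.
#' @examples
#' cl <- data.frame(area = 800, circularity = 0, compactness = 0)
#' s1_retention_ratio(cl, n_single = 0)  # 0.7
#' @export
s1_retention_ratio <- function(cluster, n_single, params = s1_params()) {
  stopifnot(n_single >= 0)
  area <- cluster$area
  rung <- findInterval(area, params$ladder_breaks, rightmost.closed = FALSE)
  r_base <- params$ladder_ratios[rung]
  if (r_base == 0) return(0)    # below the removal breakpoint: noise
  if (r_base == 1) return(1)    # small clusters are always fully kept
  a_single <- 1 - min(n_single / params$single_divisor, params$single_cap)
  a_round <- 1 + min(params$round_mult * cluster$circularity, params$round_cap)
  a_compact <- 1 - params$compact_scale *
    min(cluster$compactness / params$compact_norm, 1)
  clip01(r_base * a_single * a_round * a_compact, params$r_min, params$r_max)
}

new_thinning_result <- function(strategy, retained_rows, per_cluster_ratio,
                                removed, overall, n_points,
                                retained_flower_ids = integer(0),
                                merged_away_labels = integer(0),
                                per_cluster_kept = numeric(0)) {
  structure(list(strategy = strategy,
                 retained_rows = retained_rows,
                 per_cluster_ratio = per_cluster_ratio,
                 per_cluster_kept = per_cluster_kept,
                 removed_cluster_labels = removed,
                 overall_retention = overall,
                 retained_flower_ids = retained_flower_ids,
                 merged_away_labels = merged_away_labels,
                 n_points = n_points),
            class = "bloom_thinning")
}

#' @export
print.bloom_thinning <- function(x, ...) {
  cat(sprintf("<bloom_thinning> strategy %s: %d/%d pixels retained (%.1f%%)\n",
              x$strategy, length(x$retained_rows), x$n_points,
              100 * x$overall_retention))
  invisible(x)
}

#' Apply thinning strategy 1 to a clustering result
#'
#' Per cluster the retention ratio from [s1_retention_ratio()] is realized
#' by keeping the `ceiling(r * area)` pixels nearest (Euclidean) to the
#' cluster centroid, ties broken in row-major pixel order; the ceiling
#' guarantees the achieved fraction never drops below `r_min`. Removed
#' clusters (ratio 0) contribute nothing.
#'
#' @param clustering A `bloom_clustering` from [cluster_image()].
#' @param params An [s1_params] object.
#' @return A `bloom_thinning` object: `retained_rows` (indices into the
#'   clustering's coordinate matrix), `per_cluster_ratio` (achieved pixel
#'   fraction, named by cluster label), `removed_cluster_labels`,
#'   `overall_retention` = retained / total pixels.
#' @export
s1_thin <- function(clustering, params = s1_params()) {
  stopifnot(inherits(clustering, "bloom_clustering"))
  cls <- clustering$clusters
  if (nrow(cls) == 0) {
    return(new_thinning_result("s1", integer(0), numeric(0), integer(0), 0,
                               clustering$n_points))
  }
  retained <- integer(0)
  ratio <- numeric(nrow(cls))
  kept_n <- numeric(nrow(cls))
  assigned <- numeric(nrow(cls))
  removed <- integer(0)
  for (i in seq_len(nrow(cls))) {
    r <- s1_retention_ratio(cls[i, ], cls$n_flowers[i], params)
    assigned[i] <- r
    if (r == 0) {
      removed <- c(removed, cls$label[i])
      next
    }
    ix <- clustering$cluster_pixels[[i]]
    k <- min(ceiling(r * cls$area[i]), length(ix))
    d <- sqrt((clustering$coords[ix, 1] - cls$centroid_row[i])^2 +
                (clustering$coords[ix, 2] - cls$centroid_col[i])^2)
    keep <- ix[order(d, ix)[seq_len(k)]]
    retained <- c(retained, keep)
    ratio[i] <- k / cls$area[i]
    kept_n[i] <- k
  }
  names(ratio) <- cls$label
  names(assigned) <- cls$label
  names(kept_n) <- cls$label
  res <- new_thinning_result("s1", sort(retained), ratio, removed,
                             if (clustering$n_points > 0)
                               length(retained) / clustering$n_points else 0,
                             clustering$n_points,
                             per_cluster_kept = kept_n)
  res$assigned_ratio <- assigned
  res
}

#' Merge flower clusters that crowd each other (strategy 2 pre-step)
#'
#' Greedy by descending area (ties by label): a cluster is dropped when its
#' centroid lies within `merge_distance` of an already-kept cluster's
#' centroid, so the kept set is pairwise separated by at least
#' `merge_distance`.
#'
#' @param clusters Macro cluster table.
#' @param params An [s2_params] object.
#' @return List with `kept` (labels) and `dropped` (labels).
#' @export
s2_merge_close_clusters <- function(clusters, params = s2_params()) {
  if (nrow(clusters) == 0) return(list(kept = integer(0), dropped = integer(0)))
  ord <- order(-clusters$area, clusters$label)
  kept <- integer(0)
  dropped <- integer(0)
  kc <- matrix(numeric(0), 0, 2)
  for (i in ord) {
    ctr <- c(clusters$centroid_row[i], clusters$centroid_col[i])
    if (nrow(kc) > 0 &&
        min(sqrt((kc[, 1] - ctr[1])^2 + (kc[, 2] - ctr[2])^2)) <
          params$merge_distance) {
      dropped <- c(dropped, clusters$label[i])
    } else {
      kept <- c(kept, clusters$label[i])
      kc <- rbind(kc, ctr)
    }
  }
  list(kept = sort(kept), dropped = sort(dropped))
}

#' Strategy-2 selection scores for candidate flowers
#'
#' `S_total = S_base * S_spatial`. The base score rewards large, round
#' flowers: `(area / median cluster flower area) * (1 + circularity) / 2`.
#' The spatial score starts centre-first — `1 / (1 + d_center / eps_used)`
#' when nothing is selected yet — and once flowers are selected balances
#' centre proximity against dispersion:
#' `w_center / (1 + d_center/eps_used) + (1 - w_center) * mean distance to
#' selected / cluster radius` (cluster radius = max centroid-to-pixel
#' distance).
#'
#' @param cluster One-row macro cluster slice (needs centroid, `eps_used`).
#' @param flowers Flower table of that cluster.
#' @param selected Integer indices (into `flowers`) already selected.
#' @param cluster_radius Max centroid-to-pixel distance of the cluster.
#' @param params An [s2_params] object.
#' @return Numeric vector of `S_total`, one per flower row.
#' @export
s2_scores <- function(cluster, flowers, selected = integer(0),
                      cluster_radius = NULL, params = s2_params()) {
  if (nrow(flowers) == 0) return(numeric(0))
  med <- median(flowers$area)
  if (med == 0) med <- 1
  s_base <- (flowers$area / med) * (1 + flowers$circularity) / 2
  d_center <- sqrt((flowers$centroid_row - cluster$centroid_row)^2 +
                     (flowers$centroid_col - cluster$centroid_col)^2)
  center_term <- 1 / (1 + d_center / cluster$eps_used)
  if (length(selected) == 0) {
    s_spatial <- center_term
  } else {
    if (is.null(cluster_radius) || cluster_radius <= 0) cluster_radius <- 1
    sel <- flowers[selected, , drop = FALSE]
    mean_d <- vapply(seq_len(nrow(flowers)), function(i) {
      mean(sqrt((sel$centroid_row - flowers$centroid_row[i])^2 +
                  (sel$centroid_col - flowers$centroid_col[i])^2))
    }, numeric(1))
    s_spatial <- params$w_center * center_term +
      (1 - params$w_center) * mean_d / cluster_radius
  }
  s_base * s_spatial
}

#' Apply thinning strategy 2 to a clustering result
#'
#' After merging crowded clusters, each kept cluster retains
#' `T = max(1, round(retain_fraction * n_flowers))` flowers, selected
#' greedily by [s2_scores()] with the spatial score recomputed after every
#' pick (ties broken by flower index). Retained pixels are the pixels of
#' the retained flowers. Kept clusters without any micro-level flower are
#' skipped.
#'
#' @inheritParams s1_thin
#' @param params An [s2_params] object.
#' @return A `bloom_thinning` object; additionally carries
#'   `retained_flower_ids` and `merged_away_labels`.
#' @export
s2_thin <- function(clustering, params = s2_params()) {
  stopifnot(inherits(clustering, "bloom_clustering"))
  cls <- clustering$clusters
  if (nrow(cls) == 0) {
    return(new_thinning_result("s2", integer(0), numeric(0), integer(0), 0,
                               clustering$n_points))
  }
  mg <- s2_merge_close_clusters(cls, params)
  retained <- integer(0)
  flower_ids <- integer(0)
  ratio <- setNames(numeric(nrow(cls)), cls$label)
  for (lab in mg$kept) {
    i <- which(cls$label == lab)
    fl <- clustering$flowers[clustering$flowers$parent_label == lab, ,
                             drop = FALSE]
    if (nrow(fl) == 0) next  # no micro flowers: nothing to retain
    ix <- clustering$cluster_pixels[[i]]
    rad <- max(sqrt((clustering$coords[ix, 1] - cls$centroid_row[i])^2 +
                      (clustering$coords[ix, 2] - cls$centroid_col[i])^2))
    T_keep <- max(1L, round(params$retain_fraction * nrow(fl)))
    T_keep <- min(T_keep, nrow(fl))
    sel <- integer(0)
    while (length(sel) < T_keep) {
      sc <- s2_scores(cls[i, ], fl, sel, rad, params)
      sc[sel] <- -Inf
      pick <- which(sc == max(sc))[1]
      sel <- c(sel, pick)
    }
    ids <- fl$flower_id[sel]
    flower_ids <- c(flower_ids, ids)
    px <- unlist(clustering$flower_pixels[ids], use.names = FALSE)
    retained <- c(retained, px)
    ratio[as.character(lab)] <- length(px) / cls$area[i]
  }
  new_thinning_result("s2", sort(retained), ratio, mg$dropped,
                      if (clustering$n_points > 0)
                        length(retained) / clustering$n_points else 0,
                      clustering$n_points,
                      retained_flower_ids = sort(flower_ids),
                      merged_away_labels = mg$dropped)
}

#' Mean retention summary over a cohort of thinning results
#'
#' @param results List of `bloom_thinning` objects (one or both strategies).
#' @return Data frame with one row per strategy: `strategy`, `n`,
#'   `mean_retention`, and `in_band` flagging whether the mean lies in the
#'   20–40% range that orchard practice considers a reasonable thinning
#'   intensity.
#' @export
retention_report <- function(results) {
  if (length(results) == 0) stop("no thinning results supplied")
  stopifnot(all(vapply(results, inherits, logical(1), "bloom_thinning")))
  strat <- vapply(results, `[[`, character(1), "strategy")
  ret <- vapply(results, `[[`, numeric(1), "overall_retention")
  out <- do.call(rbind, lapply(unique(strat), function(s) {
    m <- mean(ret[strat == s])
    data.frame(strategy = s, n = sum(strat == s), mean_retention = m,
               in_band = m >= 0.2 && m <= 0.4, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
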