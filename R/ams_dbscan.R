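#' Parameters of the adaptive multi-scale clustering
#'
#' Controls the double-level adaptive neighbourhood radius. At both levels
#' the radius grows logarithmically with the area of the region being
#' clustered: the area ratio `R = area / area_target` is floored at 1
#' before the log (regions at or below the target area keep the base
#' radius), and `eps = eps_base + beta * log(R)` is clipped to the level's
#' admissible interval, whose cap — not the ratio — stabilises the radius
#' for extreme areas. The macro level (flower clusters) uses base radius 10 px,
#' `beta = 1.8` and a 20 px cap; the micro level (single flowers inside a
#' cluster) uses base radius 7 px with a deliberately weaker adjustment
#' (`beta_micro = 0.5`, cap 10 px) because its working range is much
#' narrower. `area_target` = 1200 px^2 is the reference single-flower area.
#'
#' `min_samples` (the DBSCAN core-point threshold, self included) defaults
#' to 5 at the macro level and 4 at the micro level: small enough that an
#' isolated ~1200 px^2 flower is never written off as noise, large enough
#' to suppress speckle.
#'
#' @param eps_base Macro base radius, px.
#' @param beta Macro area-adjustment coefficient.
#' @param area_target Reference flower area, px^2.
#' @param eps_min Lower clip of the adapted radius, px.
#' @param eps_max Macro upper clip, px.
#' @param initial_eps Radius of the provisional (first) macro pass, px.
#' @param min_samples_macro,min_samples_micro DBSCAN core thresholds.
#' @param eps_base_micro Micro base radius, px.
#' @param beta_micro Micro area-adjustment coefficient.
#' @param eps_max_micro Micro upper clip, px.
#' @return A list of class `eps_params`.
#' @export
eps_params <- function(eps_base = 10, beta = 1.8, area_target = 1200,
                       eps_min = 5, eps_max = 20, initial_eps = 10,
                       min_samples_macro = 5L, min_samples_micro = 4L,
                       eps_base_micro = 7, beta_micro = 0.5,
                       eps_max_micro = 10) {
  stopifnot(eps_min > 0, eps_min <= eps_base, eps_base <= eps_max,
            beta > 0, beta_micro > 0, area_target > 0, initial_eps > 0,
            min_samples_macro >= 1, min_samples_micro >= 1,
            eps_min <= eps_base_micro, eps_base_micro <= eps_max_micro)
  structure(list(eps_base = eps_base, beta = beta, area_target = area_target,
                 eps_min = eps_min, eps_max = eps_max,
                 initial_eps = initial_eps,
                 min_samples_macro = as.integer(min_samples_macro),
                 min_samples_micro = as.integer(min_samples_micro),
                 eps_base_micro = eps_base_micro, beta_micro = beta_micro,
                 eps_max_micro = eps_max_micro),
            class = "eps_params")
}

#' Area-adaptive neighbourhood radius
#'
#' @param area_cluster Region area(s), px^2; must be positive.
#' @param level `"macro"` (flower-cluster level) or `"micro"` (single-flower
#'   level).
#' @param params An [eps_params] object.
#' @return Adapted radius in px, same length as `area_cluster`. Equals the
#'   level's base radius when `area_cluster <= area_target` (the area ratio
#'   clamps to 1) and saturates at the level's cap for very large regions.
#' @examples
#' adaptive_eps(1200, "macro")  # base radius 10
#' adaptive_eps(1e9, "macro")   # capped at 20
#' @export
adaptive_eps <- function(area_cluster, level = c("macro", "micro"),
                         params = eps_params()) {
  level <- match.arg(level)
  if (any(!is.finite(area_cluster)) || any(area_cluster <= 0)) {
    stop("`area_cluster` must be positive")
  }
  R <- pmax(area_cluster / params$area_target, 1)
  if (level == "macro") {
    clip01(params$eps_base + params$beta * log(R),
           params$eps_min, params$eps_max)
  } else {
    clip01(params$eps_base_micro + params$beta_micro * log(R),
           params$eps_min, params$eps_max_micro)
  }
}

#' DBSCAN on pixel coordinates
#'
#' Density-based clustering of a (row, col) coordinate matrix with standard
#' DBSCAN semantics: a point is *core* when at least `min_samples` points
#' (itself included) lie within Euclidean distance `eps`; clusters are
#' maximal density-reachable sets; border points attach to the first core
#' point that discovers them. Labelling is deterministic (row order, no
#' randomness). Neighbourhood queries run through a 2-D kd-tree by default;
#' `method = "brute"` uses a linear scan and returns identical labels.
#'
#' @param points N x 2 numeric matrix of (row, col) coordinates.
#' @param eps Neighbourhood radius, px.
#' @param min_samples Core-point threshold (neighbours within `eps`,
#'   inclusive of the point itself).
#' @param method `"kdtree"` (default) or `"brute"`.
#' @return Integer vector of length N: cluster labels starting at 1, or -1
#'   for noise. Empty input gives a zero-length vector.
#' @export
dbscan_cluster <- function(points, eps, min_samples,
                           method = c("kdtree", "brute")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  if (nrow(points) == 0) return(integer(0))
  if (ncol(points) != 2) stop("`points` must have two columns (row, col)")
  storage.mode(points) <- "double"
  dbscan_labels_cpp(points, as.numeric(eps), as.integer(min_samples),
                    method == "kdtree")
}

#' Macro-level clustering of flower pixels
#'
#' Two-pass procedure: a provisional DBSCAN at the fixed initial radius
#' (default 10 px) estimates cluster areas; each provisional cluster is then
#' re-clustered on its own pixels with the area-adapted radius from
#' [adaptive_eps()]. Provisional clusters are refined independently and are
#' never re-merged across provisional boundaries. Shape statistics
#' (centroid, marching-squares perimeter, circularity, compactness = squared
#' perimeter) and a size grade are computed for every final cluster.
#'
#' @inheritParams dbscan_cluster
#' @param params An [eps_params] object.
#' @return List with `clusters` (data frame: `label`, `area`,
#'   `centroid_row`, `centroid_col`, `perimeter`, `circularity`,
#'   `compactness`, `eps_used`, `grade`), `pixels` (list of row-index
#'   vectors into `points`, one per cluster) and `labels` (per-point final
#'   labels, -1 = noise).
#' @export
macro_cluster <- function(points, params = eps_params(),
                          method = c("kdtree", "brute")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("`points` must be non-empty")

  lab1 <- dbscan_cluster(points, params$initial_eps,
                         params$min_samples_macro, method)
  final <- rep(-1L, nrow(points))
  eps_used <- numeric(0)
  nxt <- 0L
  for (p in sort(unique(lab1[lab1 > 0]))) {
    idx <- which(lab1 == p)
    eps2 <- adaptive_eps(length(idx), "macro", params)
    lab2 <- dbscan_cluster(points[idx, , drop = FALSE], eps2,
                           params$min_samples_macro, method)
    for (q in sort(unique(lab2[lab2 > 0]))) {
      nxt <- nxt + 1L
      final[idx[lab2 == q]] <- nxt
      eps_used[nxt] <- eps2
    }
  }
  if (nxt == 0L) {
    warning("all points classified as noise at the macro level")
    return(list(clusters = empty_cluster_df(), pixels = list(),
                labels = final))
  }

  pixels <- split(seq_len(nrow(points)), factor(final, levels = seq_len(nxt)))
  pixels <- unname(pixels)
  stats_list <- lapply(pixels, function(ix) {
    region_shape(points[ix, 1], points[ix, 2])
  })
  clusters <- data.frame(
    label = seq_len(nxt),
    area = vapply(stats_list, `[[`, numeric(1), "area"),
    centroid_row = vapply(stats_list, function(s) s$centroid[1], numeric(1)),
    centroid_col = vapply(stats_list, function(s) s$centroid[2], numeric(1)),
    perimeter = vapply(stats_list, `[[`, numeric(1), "perimeter"),
    circularity = vapply(stats_list, `[[`, numeric(1), "circularity"),
    compactness = vapply(stats_list, `[[`, numeric(1), "compactness"),
    eps_used = eps_used,
    stringsAsFactors = FALSE)
  clusters$grade <- as.character(area_grade(clusters$area))
  list(clusters = clusters, pixels = pixels, labels = final)
}

empty_cluster_df <- function() {
  data.frame(label = integer(0), area = numeric(0),
             centroid_row = numeric(0), centroid_col = numeric(0),
             perimeter = numeric(0), circularity = numeric(0),
             compactness = numeric(0), eps_used = numeric(0),
             grade = character(0), stringsAsFactors = FALSE)
}

empty_flower_df <- function() {
  data.frame(flower_id = integer(0), parent_label = integer(0),
             centroid_row = numeric(0), centroid_col = numeric(0),
             area = numeric(0), circularity = numeric(0),
             stringsAsFactors = FALSE)
}

#' Micro-level clustering: single flowers inside one macro cluster
#'
#' Re-clusters the pixels of one macro cluster with the micro-level adapted
#' radius (base 7 px, weak area adjustment) to separate the individual
#' flowers it contains. Micro-level noise pixels remain part of the macro
#' cluster but yield no flower record.
#'
#' @param cluster One-row slice of the macro `clusters` data frame.
#' @param pixel_idx Row indices (into `points`) of the cluster's pixels.
#' @param points Full coordinate matrix.
#' @param params An [eps_params] object.
#' @inheritParams dbscan_cluster
#' @return List with `flowers` (data frame: `parent_label`,
#'   `centroid_row`, `centroid_col`, `area`, `circularity`) and `pixels`
#'   (list of row-index vectors, one per flower).
#' @export
micro_cluster <- function(cluster, pixel_idx, points, params = eps_params(),
                          method = c("kdtree", "brute")) {
  method <- match.arg(method)
  if (length(pixel_idx) == 0) {
    return(list(flowers = empty_flower_df(), pixels = list()))
  }
  eps_m <- adaptive_eps(length(pixel_idx), "micro", params)
  lab <- dbscan_cluster(points[pixel_idx, , drop = FALSE], eps_m,
                        params$min_samples_micro, method)
  labs <- sort(unique(lab[lab > 0]))
  if (length(labs) == 0) {
    return(list(flowers = empty_flower_df(), pixels = list()))
  }
  pix <- lapply(labs, function(q) pixel_idx[lab == q])
  st <- lapply(pix, function(ix) region_shape(points[ix, 1], points[ix, 2]))
  flowers <- data.frame(
    flower_id = NA_integer_,
    parent_label = cluster$label,
    centroid_row = vapply(st, function(s) s$centroid[1], numeric(1)),
    centroid_col = vapply(st, function(s) s$centroid[2], numeric(1)),
    area = vapply(st, `[[`, numeric(1), "area"),
    circularity = vapply(st, `[[`, numeric(1), "circularity"),
    stringsAsFactors = FALSE)
  list(flowers = flowers, pixels = pix)
}

#' Cluster a flower mask into flower clusters and single flowers
#'
#' Full adaptive multi-scale clustering of one mask: coordinate extraction,
#' two-pass macro clustering with the area-adaptive radius, then micro
#' clustering of every macro cluster into single flowers. Deterministic for
#' a fixed input.
#'
#' @param mask A [flower_mask].
#' @param params An [eps_params] object.
#' @inheritParams dbscan_cluster
#' @inheritParams extract_coords
#' @return An object of class `bloom_clustering`: list with
#'   \describe{
#'     \item{clusters}{macro cluster table (see [macro_cluster()]) plus an
#'       `n_flowers` column,}
#'     \item{cluster_pixels}{list of per-cluster pixel row indices,}
#'     \item{flowers}{single-flower table,}
#'     \item{flower_pixels}{list of per-flower pixel row indices,}
#'     \item{point_labels}{per-coordinate macro label (-1 = noise),}
#'     \item{noise_pixel_count, n_points, coords, params, method.}{}
#'   }
#'   Cluster pixel sets are pairwise disjoint and
#'   `sum(clusters$area) + noise_pixel_count == n_points`.
#' @export
cluster_image <- function(mask, params = eps_params(),
                          method = c("kdtree", "brute"), stride = 1L) {
  method <- match.arg(method)
  coords <- extract_coords(mask, stride = stride)
  n <- nrow(coords)
  if (n == 0) {
    res <- list(clusters = transform(empty_cluster_df(), n_flowers = integer(0)),
                cluster_pixels = list(), flowers = empty_flower_df(),
                flower_pixels = list(), point_labels = integer(0),
                noise_pixel_count = 0L, n_points = 0L, coords = coords,
                params = params, method = method, tree_id = mask$tree_id)
    class(res) <- "bloom_clustering"
    return(res)
  }
  mac <- macro_cluster(coords, params, method)
  flowers <- empty_flower_df()
  flower_pixels <- list()
  n_flowers <- integer(nrow(mac$clusters))
  for (i in seq_len(nrow(mac$clusters))) {
    mic <- micro_cluster(mac$clusters[i, ], mac$pixels[[i]], coords,
                         params, method)
    n_flowers[i] <- nrow(mic$flowers)
    if (nrow(mic$flowers) > 0) {
      flowers <- rbind(flowers, mic$flowers)
      flower_pixels <- c(flower_pixels, mic$pixels)
    }
  }
  if (nrow(flowers) > 0) flowers$flower_id <- seq_len(nrow(flowers))
  clusters <- mac$clusters
  clusters$n_flowers <- n_flowers
  res <- list(clusters = clusters, cluster_pixels = mac$pixels,
              flowers = flowers, flower_pixels = flower_pixels,
              point_labels = mac$labels,
              noise_pixel_count = sum(mac$labels == -1L),
              n_points = n, coords = coords, params = params,
              method = method, tree_id = mask$tree_id)
  class(res) <- "bloom_clustering"
  res
}

#' @export
print.bloom_clustering <- function(x, ...) {
  cat(sprintf(paste0("<bloom_clustering> tree '%s': %d pixels, %d clusters, ",
                     "%d flowers, %d noise pixels\n"),
              x$tree_id, x$n_points, nrow(x$clusters), nrow(x$flowers),
              x$noise_pixel_count))
  invisible(x)
}
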