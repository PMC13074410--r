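#' Configuration of the synthetic canopy generator
#'
#' The generator emulates the structure of flowering-stage canopy masks: a
#' parent–offspring (Neyman–Scott style) point process places flower-cluster
#' parents uniformly with a minimum separation, draws Gaussian offspring
#' flower centres around each parent, and adds isolated single flowers away
#' from any cluster. Each flower is rendered as a filled ellipse whose area
#' is drawn from a truncated normal (default mean 1200 px^2, the reference
#' single-flower area) with axis ratio ~ Uniform(0.7, 1) and random
#' orientation, so circularity varies and the roundness-based rules are
#' exercised. Flowers inside a cluster may overlap ("severe overlap" is a
#' property of real canopies); ground-truth bookkeeping assigns a shared
#' pixel to the later-drawn flower.
#'
#' @param image_size `(rows, cols)` in px; default 1024 x 1024, the working
#'   crop size of the imaging protocol the generator emulates.
#' @param n_clusters Number of flower clusters.
#' @param flowers_per_cluster Integer range `c(min, max)` of flowers per
#'   cluster.
#' @param cluster_spread_px SD of the offspring displacement, px.
#' @param flower_area_mean,flower_area_sd Flower area distribution, px^2.
#' @param n_isolated_flowers Isolated single flowers outside any cluster.
#' @param min_separation Minimum parent-centre separation, px. The default
#'   `5 * cluster_spread_px + 6 * sqrt(flower_area_mean / pi)` keeps the
#'   rendered clusters pixel-separated (two flower diameters of clearance on
#'   top of the 5-sigma centre rule), i.e. the well-separated regime.
#' @param isolated_min_sep Minimum separation between isolated flowers, px.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A list of class `canopy_config`.
#' @export
canopy_config <- function(image_size = c(1024, 1024), n_clusters = 5,
                          flowers_per_cluster = c(5, 12),
                          cluster_spread_px = 25,
                          flower_area_mean = 1200, flower_area_sd = 300,
                          n_isolated_flowers = 3,
                          min_separation = NULL, isolated_min_sep = 80,
                          seed = 1L) {
  if (is.null(min_separation)) {
    min_separation <- 5 * cluster_spread_px + 6 * sqrt(flower_area_mean / pi)
  }
  stopifnot(length(image_size) == 2, all(image_size >= 32),
            n_clusters >= 0, n_isolated_flowers >= 0,
            length(flowers_per_cluster) == 2,
            flowers_per_cluster[1] >= 1,
            flowers_per_cluster[2] >= flowers_per_cluster[1],
            cluster_spread_px > 0, flower_area_mean > 0, flower_area_sd >= 0,
            min_separation > 0, isolated_min_sep > 0)
  structure(list(image_size = as.integer(image_size),
                 n_clusters = as.integer(n_clusters),
                 flowers_per_cluster = as.integer(flowers_per_cluster),
                 cluster_spread_px = cluster_spread_px,
                 flower_area_mean = flower_area_mean,
                 flower_area_sd = flower_area_sd,
                 n_isolated_flowers = as.integer(n_isolated_flowers),
                 min_separation = min_separation,
                 isolated_min_sep = isolated_min_sep,
                 seed = as.integer(seed)),
            class = "canopy_config")
}

# Rejection-sample `n` points uniform on [lo, hi]^2 with pairwise separation
# >= sep from `existing` and among themselves. A stuck layout (earlier points
# boxing out the rest) is discarded and redrawn from scratch a bounded number
# of times before giving up.
place_points <- function(n, lo_r, hi_r, lo_c, hi_c, sep,
                         existing = matrix(numeric(0), 0, 2),
                         max_tries = 400L, restarts = 60L, what = "parent") {
  for (attempt in seq_len(restarts)) {
    pts <- existing
    placed <- matrix(numeric(0), 0, 2)
    stuck <- FALSE
    for (i in seq_len(n)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        cand <- c(runif(1, lo_r, hi_r), runif(1, lo_c, hi_c))
        if (nrow(pts) == 0 ||
            min(sqrt((pts[, 1] - cand[1])^2 +
                       (pts[, 2] - cand[2])^2)) >= sep) {
          pts <- rbind(pts, cand)
          placed <- rbind(placed, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stuck <- TRUE
        break
      }
    }
    if (!stuck) return(placed)
  }
  stop("could not place ", n, " ", what, "(s) with separation ", round(sep),
       " px; image too small for the requested layout")
}

# Pixel set of a filled ellipse at centre (cr, cc), semi-axes a >= b,
# orientation theta, evaluated at integer pixel centres.
ellipse_pixels <- function(cr, cc, a, b, theta, nr, nc) {
  ext <- ceiling(a) + 1L
  rr <- max(1L, floor(cr - ext)):min(nr, ceiling(cr + ext))
  cc_ <- max(1L, floor(cc - ext)):min(nc, ceiling(cc + ext))
  gr <- expand.grid(row = rr, col = cc_)
  dr <- gr$row - cr
  dc <- gr$col - cc
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  gr[keep, , drop = FALSE]
}

#' Generate a synthetic canopy mask with ground truth
#'
#' @param config A [canopy_config].
#' @return An object of class `canopy_truth` with elements
#'   \describe{
#'     \item{mask}{a [flower_mask],}
#'     \item{flower_centers}{matrix of (row, col) flower centres,}
#'     \item{flower_areas}{owned pixel count per flower (overlapping pixels
#'       belong to the later-drawn flower),}
#'     \item{cluster_labels}{per-flower cluster id, -1 for isolated flowers,}
#'     \item{owner}{integer matrix mapping every flower pixel to the flower
#'       that owns it (0 = background),}
#'     \item{n_pixels}{total flower pixel count.}
#'   }
#' @examples
#' truth <- generate_canopy(canopy_config(image_size = c(256, 256),
#'                                        n_clusters = 1,
#'                                        flowers_per_cluster = c(3, 3),
#'                                        n_isolated_flowers = 1, seed = 7))
#' truth$cluster_labels
#' @export
generate_canopy <- function(config = canopy_config()) {
  stopifnot(inherits(config, "canopy_config"))
  nr <- config$image_size[1]
  nc <- config$image_size[2]
  with_seed(config$seed, {
    margin <- ceiling(sqrt((config$flower_area_mean +
                              4 * config$flower_area_sd) / pi)) + 2
    pad <- margin + 2 * config$cluster_spread_px
    lo_r <- min(pad, nr / 4); hi_r <- max(nr - pad, nr * 3 / 4)
    lo_c <- min(pad, nc / 4); hi_c <- max(nc - pad, nc * 3 / 4)

    parents <- place_points(config$n_clusters, lo_r, hi_r, lo_c, hi_c,
                            config$min_separation, what = "cluster parent")

    centers <- matrix(numeric(0), 0, 2)
    labels <- integer(0)
    for (k in seq_len(config$n_clusters)) {
      nf <- if (config$flowers_per_cluster[1] == config$flowers_per_cluster[2])
        config$flowers_per_cluster[1]
      else sample(config$flowers_per_cluster[1]:config$flowers_per_cluster[2], 1)
      off <- matrix(rnorm(2 * nf, 0, config$cluster_spread_px), ncol = 2)
      ctr <- sweep(off, 2, parents[k, ], "+")
      centers <- rbind(centers, ctr)
      labels <- c(labels, rep(k, nf))
    }
    if (config$n_isolated_flowers > 0) {
      clearance <- 2 * config$cluster_spread_px +
        4 * sqrt(config$flower_area_mean / pi) + 20
      iso <- place_points(config$n_isolated_flowers, margin, nr - margin,
                          margin, nc - margin,
                          sep = max(clearance, config$isolated_min_sep),
                          existing = parents, what = "isolated flower")
      # separation from parents uses `clearance`; among isolated flowers the
      # stricter of the two radii applies, which place_points enforced above
      centers <- rbind(centers, iso)
      labels <- c(labels, rep(-1L, config$n_isolated_flowers))
    }

    n_fl <- nrow(centers)
    owner <- matrix(0L, nr, nc)
    for (f in seq_len(n_fl)) {
      area <- 0
      for (t in 1:100) {
        area <- rnorm(1, config$flower_area_mean, config$flower_area_sd)
        if (area > 0) break
      }
      area <- max(area, 9)
      q <- runif(1, 0.7, 1)
      a <- sqrt(area / (pi * q))
      b <- q * a
      theta <- runif(1, 0, pi)
      # clamp the centre so the whole ellipse fits inside the raster
      ext <- ceiling(a) + 1
      centers[f, 1] <- clip01(centers[f, 1], ext + 1, nr - ext - 1)
      centers[f, 2] <- clip01(centers[f, 2], ext + 1, nc - ext - 1)
      px <- ellipse_pixels(centers[f, 1], centers[f, 2], a, b, theta, nr, nc)
      owner[cbind(px$row, px$col)] <- f
    }

    areas <- tabulate(owner[owner > 0], nbins = n_fl)
    mask <- flower_mask(owner != 0L, sprintf("synthetic-%d", config$seed))
    structure(list(mask = mask,
                   flower_centers = unname(centers),
                   flower_areas = areas,
                   cluster_labels = labels,
                   owner = owner,
                   n_pixels = sum(owner > 0L),
                   config = config),
              class = "canopy_truth")
  })
}

#' @export
print.canopy_truth <- function(x, ...) {
  cat(sprintf(paste0("<canopy_truth> %d x %d px, %d clusters, %d flowers ",
                     "(%d isolated), %d flower pixels\n"),
              nrow(x$mask$grid), ncol(x$mask$grid), x$config$n_clusters,
              length(x$cluster_labels), sum(x$cluster_labels == -1L),
              x$n_pixels))
  invisible(x)
}

#' Synthetic yield model configuration
#'
#' Yields are generated as a linear model on z-scored phenotype features plus
#' Gaussian noise, clipped to a plausible per-tree range:
#' `yield_i = intercept + sum_f w_f * z(feature_f)_i + eps_i`.
#' The defaults place weight on five features spanning distinct phenotype
#' axes (total flower area, flowers per cluster, strategy-1 dynamic
#' retention, strategy-2 spacing, cluster circularity); `noise_sd = 1.25` kg
#' is about a quarter of the resulting signal SD (amplitude signal-to-noise
#' around 4). The intercept and clip range match a realistic orchard cohort
#' (mean 18.45 kg, range 4.6–35.9 kg).
#'
#' @param weights Named numeric vector: feature name -> weight (kg per SD).
#' @param noise_sd Noise SD, kg.
#' @param intercept Mean yield, kg.
#' @param yield_clip `(min, max)` clip, kg.
#' @param seed Integer seed.
#' @return A list of class `yield_config`.
#' @export
yield_config <- function(weights = default_yield_weights(), noise_sd = 1.25,
                         intercept = 18.45, yield_clip = c(4.6, 35.9),
                         seed = 1L) {
  stopifnot(is.numeric(weights), length(weights) >= 1,
            !is.null(names(weights)), any(weights != 0),
            noise_sd >= 0, length(yield_clip) == 2,
            yield_clip[1] < yield_clip[2])
  structure(list(weights = weights, noise_sd = noise_sd,
                 intercept = intercept, yield_clip = yield_clip,
                 seed = as.integer(seed)),
            class = "yield_config")
}

#' @rdname yield_config
#' @export
default_yield_weights <- function() {
  c(total_flower_area = 3, avg_flowers_per_cluster = 2,
    avg_dynamic_ratio = -2, s2_mean_nn_distance_retained = 1.5,
    mean_circularity = 1.5)
}

#' Generate synthetic yields from a feature table
#'
#' @param features Feature table (data frame with `tree_id` and numeric
#'   feature columns) whose columns include every name in
#'   `config$weights`.
#' @param config A [yield_config].
#' @return Data frame with `tree_id` and `yield_kg`.
#' @export
generate_yield <- function(features, config = yield_config()) {
  stopifnot(is.data.frame(features), inherits(config, "yield_config"))
  miss <- setdiff(names(config$weights), names(features))
  if (length(miss) > 0) {
    stop("weighted features missing from table: ", paste(miss, collapse = ", "))
  }
  n <- nrow(features)
  z <- vapply(names(config$weights), function(nm) {
    x <- features[[nm]]
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, n) else (x - mean(x)) / s
  }, numeric(n))
  z <- matrix(z, nrow = n)
  signal <- drop(z %*% config$weights)
  y <- with_seed(config$seed,
                 config$intercept + signal + rnorm(n, 0, config$noise_sd))
  y <- clip01(y, config$yield_clip[1], config$yield_clip[2])
  data.frame(tree_id = as.character(features$tree_id), yield_kg = y,
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of trees and build its feature table
#'
#' Runs the full mask -> clustering -> thinning -> features chain on
#' `n_trees` independently generated canopies. The default per-tree canopy
#' (512 x 512 px, 3 clusters of 2–16 flowers, 2 isolated flowers) is a
#' scaled-down version of the default 1024 x 1024 canopy that keeps the full
#' multi-scale structure — isolated ~1200 px^2 flowers up to clusters beyond
#' 10,000 px^2 — while staying fast enough for cohort-scale simulation.
#'
#' @param n_trees Number of trees.
#' @param canopy Base [canopy_config]; the per-tree seed is derived from
#'   `seed + tree index`.
#' @param params [eps_params] for clustering.
#' @param s1,s2 Thinning parameter objects ([s1_params], [s2_params]).
#' @param seed Integer seed.
#' @param method Neighbour-search method, see [dbscan_cluster()].
#' @return Feature table (data frame: `tree_id` + 50 features).
#' @export
simulate_cohort <- function(n_trees = 50,
                            canopy = canopy_config(image_size = c(512, 512),
                                                   n_clusters = 3,
                                                   flowers_per_cluster = c(2, 16),
                                                   cluster_spread_px = 20,
                                                   flower_area_sd = 250,
                                                   n_isolated_flowers = 2),
                            params = eps_params(),
                            s1 = s1_params(), s2 = s2_params(),
                            seed = 1L, method = "kdtree") {
  rows <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    cfg <- canopy
    cfg$seed <- as.integer(seed + i)
    truth <- generate_canopy(cfg)
    truth$mask$tree_id <- sprintf("tree-%03d", i)
    cl <- cluster_image(truth$mask, params, method)
    r1 <- s1_thin(cl, s1)
    r2 <- s2_thin(cl, s2)
    fv <- extract_features(cl, r1, r2)
    rows[[i]] <- data.frame(tree_id = truth$mask$tree_id, t(fv),
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  do.call(rbind, rows)
}
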