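neutral_cluster <- function(area, circ = 0, compact = 0) {
  data.frame(area = area, circularity = circ, compactness = compact)
}

test_that("strategy-1 retention follows the graded ladder and factor caps", {
  # ladder rows with neutral adjustment factors
  expect_equal(s1_retention_ratio(neutral_cluster(800), 0), 0.7)
  expect_equal(s1_retention_ratio(neutral_cluster(3000), 0), 0.5)
  expect_equal(s1_retention_ratio(neutral_cluster(7000), 0), 0.3)
  expect_equal(s1_retention_ratio(neutral_cluster(250), 0), 0)    # removed
  expect_equal(s1_retention_ratio(neutral_cluster(400), 5), 1)    # fully kept

  # direct evaluation of the factor product: 0.2 * 0.7 * 1.2 * 0.8 = 0.1344,
  # inside [0.1, 1] so the clip is inactive
  r <- s1_retention_ratio(neutral_cluster(20000, circ = 1, compact = 1e6), 40)
  expect_equal(r, 0.2 * 0.7 * 1.2 * 0.8)

  # factor caps: flower-count penalty saturates at 30%, roundness bonus at
  # 20%, compactness penalty at 20%
  expect_equal(s1_retention_ratio(neutral_cluster(800), 1000),
               0.7 * 0.7)
  expect_equal(s1_retention_ratio(neutral_cluster(800, circ = 0.05), 0),
               0.7 * 1.1)
  expect_equal(s1_retention_ratio(neutral_cluster(800, compact = 25000), 0),
               0.7 * (1 - 0.2 * 0.5))

  # with default caps the factor product cannot fall below 0.2*0.7*0.8 =
  # 0.112, so the 0.1 floor is a safety net; it engages once the
  # flower-count cap is relaxed
  r_lo <- s1_retention_ratio(neutral_cluster(20000, compact = 1e6), 1000,
                             s1_params(single_cap = 0.5))
  expect_equal(r_lo, 0.1)
})

test_that("strategy 1 keeps the pixels nearest the centroid", {
  truth <- generate_canopy(canopy_config(image_size = c(360, 360),
                                         n_clusters = 2,
                                         flowers_per_cluster = c(5, 9),
                                         cluster_spread_px = 14,
                                         n_isolated_flowers = 1, seed = 17))
  cl <- cluster_image(truth$mask)
  res <- s1_thin(cl)

  expect_true(all(res$retained_rows %in% seq_len(cl$n_points)))
  for (i in seq_len(nrow(cl$clusters))) {
    ix <- cl$cluster_pixels[[i]]
    kept <- intersect(res$retained_rows, ix)
    ratio <- res$per_cluster_ratio[[as.character(cl$clusters$label[i])]]
    expect_equal(length(kept) / length(ix), ratio)
    # achieved ratio in {0} U [r_min, 1]
    expect_true(ratio == 0 || (ratio >= 0.1 && ratio <= 1))
    if (length(kept) > 0 && length(kept) < length(ix)) {
      # sort-by-distance oracle: kept = k nearest to centroid
      d <- sqrt((cl$coords[ix, 1] - cl$clusters$centroid_row[i])^2 +
                  (cl$coords[ix, 2] - cl$clusters$centroid_col[i])^2)
      oracle <- ix[order(d, ix)[seq_along(kept)]]
      expect_setequal(kept, oracle)
    }
  }
  expect_equal(res$overall_retention,
               length(res$retained_rows) / cl$n_points)

  # clusters under 500 px^2 are always fully kept, under 300 always removed
  small <- disk_mask(cbind(40, 40), 10.5, c(80, 80))        # ~350 px
  cls <- cluster_image(small)
  r1 <- s1_thin(cls)
  expect_equal(unname(r1$per_cluster_ratio[1]), 1)

  # empty clustering
  empty <- cluster_image(flower_mask(matrix(0L, 8, 8)))
  r0 <- s1_thin(empty)
  expect_equal(r0$overall_retention, 0)
  expect_equal(length(r0$retained_rows), 0)
})

test_that("tiny clusters are removed as noise by strategy 1", {
  # one real cluster plus one sub-300 px speckle
  big <- disk_mask(cbind(60, 60), 19.5, c(160, 160))
  tiny <- disk_mask(cbind(130, 130), 8, c(160, 160))  # ~200 px
  m <- flower_mask(pmax(big$grid, tiny$grid))
  cl <- cluster_image(m)
  expect_equal(nrow(cl$clusters), 2)
  res <- s1_thin(cl)
  tiny_label <- cl$clusters$label[which.min(cl$clusters$area)]
  expect_true(tiny_label %in% res$removed_cluster_labels)
  expect_equal(unname(res$per_cluster_ratio[as.character(tiny_label)]), 0)
})

test_that("crowded clusters merge greedily by area", {
  mk <- function(label, area, r, c) {
    data.frame(label = label, area = area, centroid_row = r, centroid_col = c)
  }
  # two clusters 10 px apart: only the larger survives
  cls <- rbind(mk(1, 5000, 50, 50), mk(2, 800, 50, 60))
  mg <- s2_merge_close_clusters(cls, s2_params(merge_distance = 30))
  expect_equal(mg$kept, 1)
  expect_equal(mg$dropped, 2)

  # all far apart: identity
  cls <- rbind(mk(1, 5000, 50, 50), mk(2, 800, 50, 150), mk(3, 600, 150, 50))
  mg <- s2_merge_close_clusters(cls, s2_params(merge_distance = 30))
  expect_equal(mg$kept, c(1, 2, 3))

  # chain A-B-C with d(A,B) = d(B,C) = 20, d(A,C) = 40, areas 3000 > 2000 >
  # 1000: greedy keeps A, drops B (too close to A), keeps C
  cls <- rbind(mk(1, 3000, 50, 50), mk(2, 2000, 50, 70), mk(3, 1000, 50, 90))
  mg <- s2_merge_close_clusters(cls, s2_params(merge_distance = 30))
  expect_equal(mg$kept, c(1, 3))
  expect_equal(mg$dropped, 2)
})

test_that("strategy-2 scores favour the centre first, then dispersion", {
  cl <- data.frame(label = 1, centroid_row = 50, centroid_col = 50,
                   eps_used = 10)
  fl <- data.frame(flower_id = 1:2, parent_label = 1,
                   centroid_row = c(50, 50), centroid_col = c(50, 70),
                   area = c(400, 400), circularity = c(0.8, 0.8))
  sc <- s2_scores(cl, fl, integer(0))
  # candidate at the exact centroid maximises the spatial score at 1
  expect_equal(sc[1], (400 / 400) * (1 + 0.8) / 2 * 1)
  expect_gt(sc[1], sc[2])

  # 5 flowers on a line, 2 selected at one end: at equal base score the
  # far-end candidate outscores the one adjacent to the selected pair
  fl5 <- data.frame(flower_id = 1:5, parent_label = 1,
                    centroid_row = 50, centroid_col = c(10, 30, 50, 70, 90),
                    area = 400, circularity = 0.5)
  sc5 <- s2_scores(cl, fl5, selected = c(1, 2), cluster_radius = 40)
  # candidate 5 (far end) vs candidate 3 (middle, adjacent to selection):
  # hand evaluation of w/(1 + d/eps) + (1-w) * meandist/radius
  hand <- function(i) {
    d_ctr <- abs(fl5$centroid_col[i] - 50)
    mean_d <- mean(abs(fl5$centroid_col[c(1, 2)] - fl5$centroid_col[i]))
    base <- (1 + 0.5) / 2
    base * (0.5 / (1 + d_ctr / 10) + 0.5 * mean_d / 40)
  }
  expect_equal(sc5[5], hand(5))
  expect_equal(sc5[3], hand(3))
  expect_gt(sc5[5], sc5[3])
})

test_that("strategy 2 retains T flowers per kept cluster, deterministically", {
  # ten separable flowers in one cluster (9 px gaps)
  centers <- cbind(rep(c(40, 67), each = 5),
                   rep(c(30, 57, 84, 111, 138), 2))
  m <- disk_mask(centers, rep(9.8, 10), c(110, 170))
  cl <- cluster_image(m)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(nrow(cl$flowers), 10)

  res <- s2_thin(cl, s2_params(retain_fraction = 0.2))
  expect_equal(length(res$retained_flower_ids), 2)   # T = round(0.2 * 10)
  expect_true(all(res$retained_rows %in% unlist(cl$flower_pixels)))

  # single-flower cluster keeps its flower (T >= 1)
  one <- cluster_image(disk_mask(cbind(40, 40), 19.5, c(80, 80)))
  r_one <- s2_thin(one)
  expect_equal(length(r_one$retained_flower_ids), 1)

  # determinism
  expect_identical(res, s2_thin(cl, s2_params(retain_fraction = 0.2)))
})

test_that("strategy-2 retained flowers are more dispersed than random subsets", {
  # 20-flower ring cluster; compare the 4 retained flowers against random
  # 4-subsets over 100 draws (mean pairwise distance, higher = more spread)
  ang <- seq(0, 2 * pi, length.out = 21)[-21]
  centers <- cbind(120 + 88 * sin(ang), 120 + 88 * cos(ang))
  m <- disk_mask(centers, rep(9.8, 20), c(240, 240))
  cl <- cluster_image(m)
  expect_equal(nrow(cl$flowers), 20)
  res <- s2_thin(cl, s2_params(retain_fraction = 0.2))
  expect_equal(length(res$retained_flower_ids), 4)

  fc <- cbind(cl$flowers$centroid_row, cl$flowers$centroid_col)
  sel <- match(res$retained_flower_ids, cl$flowers$flower_id)
  mpd <- function(ix) mean(dist(fc[ix, ]))
  mpd_sel <- mpd(sel)
  mpd_rand <- withr::with_seed(77, {
    mean(replicate(100, mpd(sample(20, 4))))
  })
  expect_gt(mpd_sel, mpd_rand)

  # nearest-neighbour CV of the retained set beats size-matched random sets
  cv <- function(x) sd(x) / mean(x)
  nn_of <- function(ix) {
    d <- as.matrix(dist(fc[ix, ])); diag(d) <- Inf
    apply(d, 1, min)
  }
  cv_sel <- cv(nn_of(sel))
  cv_rand <- withr::with_seed(78, {
    replicate(100, cv(nn_of(sample(20, 4))))
  })
  expect_lte(cv_sel, mean(cv_rand))
})

test_that("retention summaries average per strategy and flag the agronomic band", {
  mk <- function(strategy, ret) {
    r <- s1_thin(cluster_image(flower_mask(matrix(0L, 4, 4))))
    r$strategy <- strategy
    r$overall_retention <- ret
    r
  }
  rep <- retention_report(list(mk("s1", 0.2), mk("s1", 0.3), mk("s2", 0.5)))
  expect_equal(rep$mean_retention[rep$strategy == "s1"], 0.25)
  expect_true(rep$in_band[rep$strategy == "s1"])
  expect_false(rep$in_band[rep$strategy == "s2"])
  expect_equal(rep$mean_retention[rep$strategy == "s2"], 0.5)
  expect_error(retention_report(list()), "no thinning results")
})

test_that("both strategies only ever keep subsets of the input pixels", {
  truth <- generate_canopy(canopy_config(image_size = c(360, 360),
                                         n_clusters = 2,
                                         flowers_per_cluster = c(3, 10),
                                         cluster_spread_px = 18,
                                         n_isolated_flowers = 1, seed = 23))
  cl <- cluster_image(truth$mask)
  for (res in list(s1_thin(cl), s2_thin(cl))) {
    expect_true(all(res$retained_rows %in% seq_len(cl$n_points)))
    expect_false(any(duplicated(res$retained_rows)))
    expect_true(all(res$per_cluster_ratio >= 0 & res$per_cluster_ratio <= 1))
    expect_equal(res$overall_retention,
                 length(res$retained_rows) / cl$n_points)
  }
})
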