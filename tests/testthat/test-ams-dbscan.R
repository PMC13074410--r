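test_that("adaptive radius reproduces the reference parameter table", {
  p <- eps_params()
  # at the target area the log term vanishes: base radii
  expect_equal(adaptive_eps(1200, "macro", p), 10)
  expect_equal(adaptive_eps(1200, "micro", p), 7)
  # upper clip for extreme areas
  expect_equal(adaptive_eps(1e9, "macro", p), 20)
  expect_equal(adaptive_eps(1e9, "micro", p), 10)
  # areas below target clamp the ratio to 1: base radius exactly
  expect_equal(adaptive_eps(120, "macro", p), 10)
  expect_equal(adaptive_eps(120, "micro", p), 7)
  expect_error(adaptive_eps(0, "macro", p), "positive")
  expect_error(adaptive_eps(-5, "micro", p), "positive")
})

test_that("adaptive radius is monotone, continuous and bounded in area", {
  p <- eps_params()
  areas <- exp(seq(log(1), log(1200 * 100), length.out = 400))
  for (lev in c("macro", "micro")) {
    e <- adaptive_eps(areas, lev, p)
    expect_true(all(diff(e) >= 0))
    cap <- if (lev == "macro") p$eps_max else p$eps_max_micro
    expect_true(all(e >= p$eps_min & e <= cap))
    # continuity: small area steps give small eps steps
    expect_lt(max(abs(diff(e))), 0.1)
  }
  # hand evaluation of the formula at area ratio 50 (macro)
  expect_equal(adaptive_eps(1200 * 50, "macro", p), 10 + 1.8 * log(50))
})

test_that("DBSCAN handles the textbook cases deterministically", {
  # 5 collinear points spaced 1 px, eps 1.5, min_samples 2: one cluster
  pts <- cbind(1:5, rep(1, 5))
  expect_equal(dbscan_cluster(pts, 1.5, 2), rep(1L, 5))

  # two 10-point blobs 100 px apart: two clusters
  blob <- function(r0) cbind(r0 + rep(0:1, 5), rep(1:5, each = 2))
  pts <- rbind(blob(0), blob(100))
  lab <- dbscan_cluster(pts, 5, 3)
  expect_equal(lab, rep(c(1L, 2L), each = 10))

  # empty input
  expect_equal(dbscan_cluster(matrix(numeric(0), 0, 2), 5, 3), integer(0))

  # lone point below min_samples is noise
  expect_equal(dbscan_cluster(cbind(1, 1), 2, 2), -1L)
})

test_that("kd-tree DBSCAN equals the brute-force oracle on random points", {
  withr::with_seed(20, {
    for (case in 1:8) {
      n <- sample(50:400, 1)
      pts <- cbind(runif(n, 0, 120), runif(n, 0, 120))
      eps <- runif(1, 2, 12)
      ms <- sample(2:8, 1)
      lab_kd <- dbscan_cluster(pts, eps, ms, method = "kdtree")
      lab_br <- dbscan_cluster(pts, eps, ms, method = "brute")
      lab_or <- brute_dbscan_oracle(pts, eps, ms)
      expect_identical(lab_kd, lab_br)
      expect_true(same_partition(lab_kd, lab_or))
    }
  })
})

test_that("macro clustering adapts the radius to provisional cluster area", {
  # one cluster at roughly the target area keeps the base radius
  m1 <- disk_mask(cbind(60, 60), 19.5, c(120, 120))  # ~1195 px
  cl1 <- cluster_image(m1)
  expect_equal(nrow(cl1$clusters), 1)
  expect_equal(cl1$clusters$eps_used, 10)

  # two well-separated clusters, areas ~1200 and ~60000: the larger one
  # gets the larger adapted radius, matching the formula evaluated by hand
  grid <- matrix(0L, 500, 500)
  m_small <- disk_mask(cbind(60, 60), 19.5, c(500, 500))
  m_big <- disk_mask(cbind(350, 350), 138, c(500, 500))  # ~59800 px
  grid <- pmax(m_small$grid, m_big$grid)
  cl <- cluster_image(flower_mask(grid))
  expect_equal(nrow(cl$clusters), 2)
  ord <- order(cl$clusters$area)
  expect_equal(cl$clusters$eps_used[ord[1]], 10)
  big_area <- cl$clusters$area[ord[2]]
  expect_equal(cl$clusters$eps_used[ord[2]],
               min(10 + 1.8 * log(big_area / 1200), 20))
  expect_gt(cl$clusters$eps_used[ord[2]], cl$clusters$eps_used[ord[1]])
})

test_that("second macro pass is a refinement: no merging across provisional clusters", {
  truth <- generate_canopy(canopy_config(image_size = c(400, 400),
                                         n_clusters = 2,
                                         flowers_per_cluster = c(6, 6),
                                         cluster_spread_px = 12,
                                         n_isolated_flowers = 0, seed = 9))
  co <- extract_coords(truth$mask)
  p <- eps_params()
  lab1 <- dbscan_cluster(co, p$initial_eps, p$min_samples_macro)
  mac <- macro_cluster(co, p)
  # every final cluster sits inside exactly one provisional cluster
  for (ix in mac$pixels) {
    expect_equal(length(unique(lab1[ix])), 1)
  }
})

test_that("micro level separates flowers across narrow gaps and keeps centroids", {
  # single rendered flower: one micro flower at the rendered centre
  m <- disk_mask(cbind(60, 60), 19.5, c(120, 120))
  cl <- cluster_image(m)
  expect_equal(nrow(cl$flowers), 1)
  expect_lt(sqrt((cl$flowers$centroid_row - 60)^2 +
                   (cl$flowers$centroid_col - 60)^2), 2)

  # four disks with ~9 px pixel gaps: gaps below the macro radius (10) so
  # one flower cluster, above the micro radius (7) so four single flowers
  centers <- cbind(60, c(30, 57, 84, 111))
  m4 <- disk_mask(centers, rep(9.8, 4), c(120, 150))
  cl4 <- cluster_image(m4)
  expect_equal(nrow(cl4$clusters), 1)
  expect_equal(nrow(cl4$flowers), 4)
  expect_equal(cl4$clusters$n_flowers, 4)

  # micro noise stays inside the macro cluster: flower pixels never exceed
  # the parent's pixels
  expect_lte(sum(cl4$flowers$area), cl4$clusters$area)

  # empty pixel list
  mic <- micro_cluster(cl4$clusters[1, ], integer(0), cl4$coords)
  expect_equal(nrow(mic$flowers), 0)
})

test_that("clustering partitions pixels and is deterministic", {
  truth <- generate_canopy(canopy_config(image_size = c(300, 300),
                                         n_clusters = 2,
                                         flowers_per_cluster = c(4, 8),
                                         cluster_spread_px = 15,
                                         n_isolated_flowers = 1, seed = 21))
  cl <- cluster_image(truth$mask)
  # partition property
  expect_equal(sum(cl$clusters$area) + cl$noise_pixel_count, cl$n_points)
  all_px <- unlist(cl$cluster_pixels)
  expect_false(any(duplicated(all_px)))
  expect_setequal(c(all_px, which(cl$point_labels == -1L)),
                  seq_len(cl$n_points))
  # flower pixel sets nest inside their parent cluster
  for (i in seq_len(nrow(cl$flowers))) {
    parent <- match(cl$flowers$parent_label[i], cl$clusters$label)
    expect_true(all(cl$flower_pixels[[i]] %in% cl$cluster_pixels[[parent]]))
  }
  # rerun gives an identical result
  cl2 <- cluster_image(truth$mask)
  expect_identical(cl, cl2)
  # brute-force neighbour search gives the identical result
  cl3 <- cluster_image(truth$mask, method = "brute")
  cl3$method <- cl$method
  expect_identical(cl, cl3)
})

test_that("degenerate masks are handled", {
  empty <- cluster_image(flower_mask(matrix(0L, 10, 10)))
  expect_equal(nrow(empty$clusters), 0)
  expect_equal(empty$noise_pixel_count, 0)
  expect_equal(empty$n_points, 0)

  # a few scattered pixels are all noise
  g <- matrix(0L, 50, 50)
  g[cbind(c(5, 25, 45), c(5, 25, 45))] <- 1L
  expect_warning(cl <- cluster_image(flower_mask(g)), "noise")
  expect_equal(nrow(cl$clusters), 0)
  expect_equal(cl$noise_pixel_count, 3)
})
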