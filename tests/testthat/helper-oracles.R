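# Independent oracles used by the tests. These deliberately avoid the
# package's code paths: the DBSCAN oracle works from a full distance
# matrix, connected components come from a BFS flood fill, dilation from
# shifted matrices.

# O(n^2) textbook DBSCAN on a precomputed distance matrix.
brute_dbscan_oracle <- function(points, eps, min_samples) {
  n <- nrow(points)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(points))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_samples
  labels <- rep(0L, n)  # 0 = unseen
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    if (!core[i]) {
      labels[i] <- -1L
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbrs[[i]], i)
    while (length(queue) > 0) {
      q <- queue[1]
      queue <- queue[-1]
      if (labels[q] == -1L) labels[q] <- cl
      if (labels[q] != 0L) next
      labels[q] <- cl
      if (core[q]) queue <- c(queue, nbrs[[q]])
    }
  }
  labels
}

# Map cluster ids to 1, 2, ... in order of first appearance (noise stays -1)
# so label vectors can be compared up to renaming.
canonical_labels <- function(labels) {
  out <- labels
  seen <- integer(0)
  for (i in seq_along(labels)) {
    l <- labels[i]
    if (l == -1L) next
    pos <- match(l, seen)
    if (is.na(pos)) {
      seen <- c(seen, l)
      pos <- length(seen)
    }
    out[i] <- pos
  }
  out
}

# Same-partition check that ignores labelling entirely (noise must match
# exactly; clusters must induce identical co-membership).
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  identical(canonical_labels(a), canonical_labels(b))
}

# Binary dilation with a square structuring element of half-width `r`,
# built from shifted copies of the matrix.
dilate_mask <- function(grid, r) {
  nr <- nrow(grid); nc <- ncol(grid)
  out <- matrix(0L, nr, nc)
  for (dr in -r:r) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    shifted <- matrix(0L, nr, nc)
    shifted[rt, ] <- grid[rs, ]
    out <- pmax(out, shifted)
  }
  grid2 <- out
  out <- matrix(0L, nr, nc)
  for (dc in -r:r) {
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    ct <- max(1, 1 - dc):min(nc, nc - dc)
    shifted <- matrix(0L, nr, nc)
    shifted[, ct] <- grid2[, cs]
    out <- pmax(out, shifted)
  }
  out
}

# 4-connected component count via BFS flood fill on the frontier.
count_components <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  ncomp <- 0L
  todo <- which(grid != 0L & lab == 0L)
  while (length(todo) > 0) {
    ncomp <- ncomp + 1L
    frontier <- todo[1]
    lab[frontier] <- ncomp
    while (length(frontier) > 0) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      cand <- c(ifelse(r > 1, frontier - 1L, NA),
                ifelse(r < nr, frontier + 1L, NA),
                ifelse(c > 1, frontier - nr, NA),
                ifelse(c < nc, frontier + nr, NA))
      cand <- cand[!is.na(cand)]
      cand <- unique(cand[grid[cand] != 0L & lab[cand] == 0L])
      lab[cand] <- ncomp
      frontier <- cand
    }
    todo <- which(grid != 0L & lab == 0L)
  }
  ncomp
}

# Build a mask from filled disks; returns a flower_mask.
disk_mask <- function(centers, radii, size = c(128, 128), tree_id = "disk") {
  grid <- matrix(0L, size[1], size[2])
  for (i in seq_len(nrow(centers))) {
    rr <- round(centers[i, 1]); cc <- round(centers[i, 2]); rad <- radii[i]
    rs <- max(1, rr - rad):min(size[1], rr + rad)
    cs <- max(1, cc - rad):min(size[2], cc + rad)
    g <- expand.grid(r = rs, c = cs)
    keep <- (g$r - centers[i, 1])^2 + (g$c - centers[i, 2])^2 <= rad^2
    grid[cbind(g$r[keep], g$c[keep])] <- 1L
  }
  flower_mask(grid, tree_id)
}

# Shared fixtures, built once per test session.
.fixture_env <- new.env(parent = emptyenv())

# The n = 200 synthetic cohort used by the contract and recovery checks.
cohort_table <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(n_trees = 200, seed = 1)
  }
  .fixture_env$cohort
}

# A small random feature table (not from the pipeline) for model tests.
random_feature_table <- function(n = 200, seed = 42) {
  sch <- unlist(feature_schema(), use.names = FALSE)
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * length(sch)), n)
    colnames(x) <- sch
    data.frame(tree_id = sprintf("t%03d", seq_len(n)), x,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
}
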