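# Region shape descriptors computed on a pixel set.
#
# The boundary length is a marching-squares contour estimate: the padded
# binary grid is scanned in 2x2 windows and each window contributes the
# length of the iso-contour segment(s) it contains (0, sqrt(2)/2, 1 or
# sqrt(2)). Circularity is the usual 4*pi*A/P^2, clipped to [0, 1] because
# the rasterized estimate can nudge past 1 for small near-circular regions.
# Compactness is the squared boundary length P^2 (px^2): a ragged outline
# inflates P^2 much faster than the area it encloses.

boundary_length <- function(grid) {
  nr <- nrow(grid) + 2L
  nc <- ncol(grid) + 2L
  g <- matrix(0L, nr, nc)
  g[2L:(nr - 1L), 2L:(nc - 1L)] <- grid
  tl <- g[-nr, -nc]
  tr <- g[-nr, -1L]
  bl <- g[-1L, -nc]
  br <- g[-1L, -1L]
  cases <- tl + 2L * tr + 4L * bl + 8L * br
  s <- sqrt(2) / 2
  lut <- c(0, s, s, 1, s, 1, 2 * s, s, s, 2 * s, 1, s, 1, s, s, 0)
  sum(lut[cases + 1L])
}

# Shape statistics for a region given by its pixel coordinates (row, col).
region_shape <- function(rows, cols) {
  area <- length(rows)
  if (area == 0) {
    return(list(area = 0, centroid = c(NA_real_, NA_real_), perimeter = 0,
                circularity = 0, compactness = 0))
  }
  r0 <- min(rows) - 1L
  c0 <- min(cols) - 1L
  g <- matrix(0L, max(rows) - r0, max(cols) - c0)
  g[cbind(rows - r0, cols - c0)] <- 1L
  per <- boundary_length(g)
  circ <- if (per > 0) clip01(4 * pi * area / per^2, 0, 1) else 0
  list(area = area,
       centroid = c(mean(rows), mean(cols)),
       perimeter = per,
       circularity = circ,
       compactness = per^2)
}

# Categorical cluster-size grade used by the thinning ladder and the
# phenotype features: tiny < 300, small [300, 1000), medium [1000, 5000),
# large [5000, 10000), supersized >= 10000 px^2.
grade_levels <- c("tiny", "small", "medium", "large", "supersized")

area_grade <- function(area) {
  cut(area, breaks = c(0, 300, 1000, 5000, 10000, Inf),
      labels = grade_levels, right = FALSE, include.lowest = TRUE)
}
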