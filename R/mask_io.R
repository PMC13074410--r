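#' Flower mask objects
#'
#' A flower mask is the binary raster produced by segmenting a flowering-stage
#' canopy photograph: non-zero pixels are flower, zero pixels are background.
#' `flower_mask()` wraps an integer 0/1 matrix together with a tree identifier.
#'
#' @param grid Matrix of 0/1 values (rows x cols, pixel units). Any non-zero
#'   entry is coerced to 1.
#' @param tree_id Character scalar naming the tree the mask belongs to.
#' @return An object of class `flower_mask` with elements `grid` and `tree_id`.
#' @examples
#' m <- flower_mask(matrix(c(0, 1, 0, 0), 2, 2), "tree-1")
#' sum(m$grid)
#' @export
flower_mask <- function(grid, tree_id = "tree") {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  if (nrow(grid) < 1 || ncol(grid) < 1) stop("`grid` must be non-empty")
  if (anyNA(grid)) stop("`grid` must not contain NA")
  g <- matrix(as.integer(grid != 0), nrow(grid), ncol(grid))
  structure(list(grid = g, tree_id = as.character(tree_id)[1]),
            class = "flower_mask")
}

#' @export
print.flower_mask <- function(x, ...) {
  cat(sprintf("<flower_mask> tree '%s': %d x %d px, %d flower pixels\n",
              x$tree_id, nrow(x$grid), ncol(x$grid), sum(x$grid)))
  invisible(x)
}

#' Read a flower mask from a PNG file
#'
#' Any pixel with a non-zero intensity in any channel counts as flower; there
#' is no grayscale threshold because the inputs are segmentation masks, not
#' photographs. An all-background image is accepted (downstream operations
#' decide what to do with it).
#'
#' @param path Path to an 8-bit PNG (grayscale, RGB or RGBA).
#' @param tree_id Tree identifier; defaults to the file name without extension.
#' @return A [flower_mask].
#' @export
read_mask <- function(path, tree_id = NULL) {
  if (!file.exists(path)) stop("mask file does not exist: ", path)
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("could not read PNG '", path, "': ",
                                           conditionMessage(e)))
  if (length(dim(img)) == 3) {
    nch <- min(dim(img)[3], 3)  # ignore alpha
    g <- apply(img[, , seq_len(nch), drop = FALSE], c(1, 2), max)
  } else {
    g <- img
  }
  if (length(g) == 0) stop("empty image: ", path)
  if (is.null(tree_id)) tree_id <- sub("\\.[Pp][Nn][Gg]$", "", basename(path))
  flower_mask(g != 0, tree_id)
}

#' Write a flower mask to an 8-bit PNG file
#'
#' @param mask A [flower_mask].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "flower_mask"))
  png::writePNG(mask$grid * 1.0, path)
  invisible(path)
}

#' Extract flower-pixel coordinates from a mask
#'
#' Returns the N x 2 matrix of (row, col) coordinates of all non-zero mask
#' pixels — the feature space in which the density clustering operates.
#' Coordinates are 1-based with the origin at the top-left; rows are ordered
#' row-major (by row, then column).
#'
#' @param mask A [flower_mask].
#' @param stride Optional integer subsampling stride (default 1 = every
#'   pixel). Values above 1 keep only pixels on a `stride`-spaced lattice;
#'   note that the area-graded constants of the thinning rules assume full
#'   resolution.
#' @return Numeric matrix with columns `row`, `col`; zero rows for an empty
#'   mask.
#' @export
extract_coords <- function(mask, stride = 1L) {
  stopifnot(inherits(mask, "flower_mask"))
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1) stop("`stride` must be a positive integer")
  w <- which(mask$grid != 0L, arr.ind = TRUE)
  if (nrow(w) == 0) {
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  if (stride > 1) {
    keep <- ((w[, 1] - 1L) %% stride == 0L) & ((w[, 2] - 1L) %% stride == 0L)
    w <- w[keep, , drop = FALSE]
  }
  w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
  out <- cbind(row = as.numeric(w[, 1]), col = as.numeric(w[, 2]))
  out
}

#' Write and read per-tree feature tables
#'
#' Feature tables are written as plain CSV with a header row, one row per
#' tree: `tree_id`, the 50 phenotype features in schema order (see
#' [feature_schema()]), and optionally `yield_kg`. Numeric values are
#' serialized with 17 significant digits so a write/read round trip is
#' bit-exact.
#'
#' @param table Data frame with a `tree_id` column and numeric feature
#'   columns.
#' @param path CSV path.
#' @return `path` invisibly (write); the table as a data frame (read).
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (!"tree_id" %in% names(table)) stop("table must have a `tree_id` column")
  if (anyDuplicated(table$tree_id)) stop("duplicate tree_id in feature table")
  out <- table
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table does not exist: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!"tree_id" %in% names(tab)) stop("feature table lacks `tree_id` column")
  if (anyDuplicated(tab$tree_id)) stop("duplicate tree_id in feature table")
  for (nm in setdiff(names(tab), "tree_id")) {
    val <- suppressWarnings(as.numeric(tab[[nm]]))
    if (nrow(tab) > 0 && anyNA(val)) {
      stop("non-numeric values in column `", nm, "` of ", path)
    }
    tab[[nm]] <- val
  }
  tab
}

#' Read a per-tree yield table
#'
#' @param path CSV with columns `tree_id` and `yield_kg` (kilograms per tree).
#' @return Data frame with character `tree_id` and numeric `yield_kg`.
#' @export
read_yield_table <- function(path) {
  if (!file.exists(path)) stop("yield table does not exist: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("tree_id", "yield_kg") %in% names(tab))) {
    stop("yield table must have columns tree_id, yield_kg")
  }
  if (anyDuplicated(tab$tree_id)) stop("duplicate tree_id in yield table")
  y <- suppressWarnings(as.numeric(tab$yield_kg))
  if (nrow(tab) > 0 && anyNA(y)) stop("non-numeric yield_kg in ", path)
  data.frame(tree_id = as.character(tab$tree_id), yield_kg = y,
             stringsAsFactors = FALSE)
}

#' @rdname read_yield_table
#' @param table Data frame with `tree_id` and `yield_kg` columns.
#' @export
write_yield_table <- function(table, path) {
  stopifnot(is.data.frame(table), all(c("tree_id", "yield_kg") %in% names(table)))
  if (anyDuplicated(table$tree_id)) stop("duplicate tree_id in yield table")
  out <- data.frame(tree_id = table$tree_id,
                    yield_kg = sprintf("%.17g", table$yield_kg))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
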