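# Region-of-interest extraction: mean-threshold binarization of a saliency
# map, largest connected component, minimal enclosing rectangle, crop.

#' Construct a binary mask
#'
#' @param values Matrix over \{0, 1\} (logical or numeric).
#' @param threshold_used The threshold that produced the mask, or `NA`.
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(values, threshold_used = NA_real_) {
  values <- as.matrix(values)
  if (is.logical(values)) values <- values + 0L
  if (!all(values %in% c(0, 1))) abort_invalid("mask values must be strictly binary")
  storage.mode(values) <- "integer"
  structure(list(values = values, threshold_used = threshold_used),
            class = "binary_mask")
}

#' Binarize a saliency map at its mean value
#'
#' The threshold is the arithmetic mean of all map values; a pixel is set to 1
#' iff its value is strictly greater than the mean. A constant map therefore
#' yields an all-zero mask (handled downstream by the full-image fallback).
#' The rule is invariant to multiplying the map by any positive constant.
#'
#' @param map A `saliency_map` or numeric matrix.
#' @return A `binary_mask` with `threshold_used` set to the mean.
#' @export
binarize_by_mean <- function(map) {
  v <- as_saliency(map)$values
  if (length(v) == 0L) abort_invalid("saliency map must be non-empty")
  thr <- mean(v)
  binary_mask(v > thr, threshold_used = thr)
}

# BFS connected-component labeling. Components are numbered in the order of
# their lexicographically smallest (row, col) pixel, which makes the
# equal-size tie-break in largest_connected_region deterministic.
label_components <- function(m, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) abort_invalid("connectivity must be 4 or 8")
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L)
    dc <- c(0L, -1L, 1L, 0L)
  }
  nlab <- 0L
  stack <- integer(h * w)
  for (r in seq_len(h)) for (cl in seq_len(w)) {
    if (m[r, cl] != 0L && lab[r, cl] == 0L) {
      nlab <- nlab + 1L
      lab[r, cl] <- nlab
      top <- 1L
      stack[1L] <- (cl - 1L) * h + r
      while (top > 0L) {
        idx <- stack[top]; top <- top - 1L
        rr <- ((idx - 1L) %% h) + 1L
        cc <- ((idx - 1L) %/% h) + 1L
        for (k in seq_along(dr)) {
          r2 <- rr + dr[k]; c2 <- cc + dc[k]
          if (r2 >= 1L && r2 <= h && c2 >= 1L && c2 <= w &&
              m[r2, c2] != 0L && lab[r2, c2] == 0L) {
            lab[r2, c2] <- nlab
            top <- top + 1L
            stack[top] <- (c2 - 1L) * h + r2
          }
        }
      }
    }
  }
  attr(lab, "n_components") <- nlab
  lab
}

#' Keep only the largest connected region of a binary mask
#'
#' Ties between equal-size components are broken toward the component
#' containing the lexicographically smallest (row, col) pixel. An empty mask
#' returns an empty mask.
#'
#' @param mask A `binary_mask` (or binary matrix).
#' @param connectivity 4 or 8 (default 8: diagonally touching pixels connect).
#' @return A `binary_mask` containing the selected component only.
#' @export
largest_connected_region <- function(mask, connectivity = 8L) {
  bm <- if (inherits(mask, "binary_mask")) mask else binary_mask(mask)
  lab <- label_components(bm$values, as.integer(connectivity))
  n <- attr(lab, "n_components")
  if (n == 0L) return(binary_mask(bm$values * 0L, threshold_used = bm$threshold_used))
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  best <- which.max(sizes)  # first maximum = lexicographically first component
  binary_mask((lab == best) + 0L, threshold_used = bm$threshold_used)
}

#' Construct a bounding box
#'
#' Coordinates are 0-based with half-open intervals: rows
#' `[row_start, row_end)`, columns `[col_start, col_end)`.
#'
#' @param row_start,col_start Inclusive starts (0-based).
#' @param row_end,col_end Exclusive ends.
#' @return Object of class `bounding_box`.
#' @export
bounding_box <- function(row_start, col_start, row_end, col_end) {
  if (row_start < 0 || col_start < 0 || row_end <= row_start || col_end <= col_start) {
    abort_invalid("bounding box must satisfy 0 <= start < end")
  }
  structure(list(row_start = as.integer(row_start), col_start = as.integer(col_start),
                 row_end = as.integer(row_end), col_end = as.integer(col_end)),
            class = "bounding_box")
}

#' Minimal enclosing rectangle of a binary component
#'
#' @param component A `binary_mask` (or binary matrix) with at least one
#'   1-pixel; otherwise an empty-region error is signalled (the ROI pipeline
#'   catches it and applies the full-image fallback).
#' @return A `bounding_box`.
#' @export
min_enclosing_box <- function(component) {
  v <- if (inherits(component, "binary_mask")) component$values else binary_mask(component)$values
  on <- which(v != 0L, arr.ind = TRUE)
  if (nrow(on) == 0L) abort_empty_region("component has no 1-pixels")
  bounding_box(min(on[, 1L]) - 1L, min(on[, 2L]) - 1L, max(on[, 1L]), max(on[, 2L]))
}

#' Attention-guided ROI extraction
#'
#' Composes the pipeline: binarize the saliency map at its mean, keep the
#' largest connected above-threshold region, take its minimal enclosing
#' rectangle and crop it from the image. If the mask is empty (constant map)
#' or the box covers less than `min_box_fraction` of the image area, the full
#' image is substituted and `fallback = TRUE` is set.
#'
#' @param image `(h, w, 3)` array (values in `[0, 1]`).
#' @param map `saliency_map` or matrix with the same height/width as `image`.
#' @param connectivity 4 or 8.
#' @param min_box_fraction Minimum box area as a fraction of image area below
#'   which the fallback triggers (default 0.01).
#' @param output_size Optional integer: resize the crop to
#'   `output_size x output_size` (bilinear).
#' @return Object of class `roi_result`: `mask`, `component_mask`, `box`,
#'   `crop`, `crop_raw_size` (box dimensions before resizing), `fallback`.
#' @export
extract_roi <- function(image, map, connectivity = 8L, min_box_fraction = 0.01,
                        output_size = NULL) {
  image <- ensure_rgb(image)
  v <- as_saliency(map)$values
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (nrow(v) != h || ncol(v) != w) {
    abort_invalid(sprintf("saliency map (%d x %d) does not match image (%d x %d)",
                          nrow(v), ncol(v), h, w))
  }
  mask <- binarize_by_mean(v)
  comp <- largest_connected_region(mask, connectivity = connectivity)
  fallback <- FALSE
  box <- NULL
  if (sum(comp$values) == 0L) {
    fallback <- TRUE
  } else {
    box <- min_enclosing_box(comp)
    area <- (box$row_end - box$row_start) * (box$col_end - box$col_start)
    if (area < min_box_fraction * h * w) fallback <- TRUE
  }
  if (fallback) {
    box <- bounding_box(0L, 0L, h, w)
    crop <- image
  } else {
    crop <- image[(box$row_start + 1L):box$row_end,
                  (box$col_start + 1L):box$col_end, , drop = FALSE]
  }
  crop_raw_size <- dim(crop)[1:2]
  if (!is.null(output_size)) crop <- resize_image(crop, output_size, output_size)
  structure(list(mask = mask, component_mask = comp, box = box, crop = crop,
                 crop_raw_size = crop_raw_size, fallback = fallback),
            class = "roi_result")
}
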