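# Image primitives. Images are base-R numeric arrays with dim (height, width,
# 3) and channel values in [0, 1]; this matches the layout used by png::readPNG
# so no axis shuffling happens at I/O boundaries.

#' Read an RGB image from a PNG file
#'
#' @param path Path to a PNG file.
#' @return Numeric array of dim `(height, width, 3)` with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("image file not found: %s", path))
  ensure_rgb(png::readPNG(path))
}

#' Write an RGB image to a PNG file
#'
#' @param image Numeric array `(height, width, 3)` in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- ensure_rgb(image)
  png::writePNG(clip01(image), path)
  invisible(path)
}

# Coerce grayscale / RGBA / matrix input to an (h, w, 3) array.
ensure_rgb <- function(image) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (length(dim(image)) != 3L) abort_invalid("image must be a (height, width, channels) array")
  nc <- dim(image)[3L]
  if (nc == 3L) return(image)
  if (nc == 1L) return(array(image[, , 1L], dim = c(dim(image)[1:2], 3L)))
  if (nc >= 3L) return(image[, , 1:3, drop = FALSE])
  abort_invalid(sprintf("unsupported channel count: %d", nc))
}

rgb_to_gray <- function(image) {
  image <- ensure_rgb(image)
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

#' Bilinear resize of a matrix
#'
#' Uses the half-pixel-center convention: output pixel `i` (0-based) samples
#' source coordinate `(i + 0.5) * n_in / n_out - 0.5`, clamped to the valid
#' range. Output values are convex combinations of input values, so the global
#' min/max bounds of the input are preserved.
#'
#' @param mat Numeric matrix.
#' @param out_h,out_w Positive output dimensions.
#' @return `out_h` x `out_w` numeric matrix.
#' @export
resize_bilinear <- function(mat, out_h, out_w) {
  if (!is.matrix(mat) || nrow(mat) < 1L || ncol(mat) < 1L) {
    abort_invalid("`mat` must be a non-empty matrix")
  }
  if (!is_count(out_h) || !is_count(out_w) || out_h < 1 || out_w < 1) {
    abort_invalid("target dimensions must be positive integers")
  }
  in_h <- nrow(mat); in_w <- ncol(mat)
  sy <- pmin(pmax((seq_len(out_h) - 0.5) * in_h / out_h - 0.5, 0), in_h - 1)
  sx <- pmin(pmax((seq_len(out_w) - 0.5) * in_w / out_w - 0.5, 0), in_w - 1)
  y0 <- floor(sy); x0 <- floor(sx)
  y1 <- pmin(y0 + 1, in_h - 1); x1 <- pmin(x0 + 1, in_w - 1)
  wy <- sy - y0; wx <- sx - x0
  m00 <- mat[y0 + 1, x0 + 1, drop = FALSE]
  m01 <- mat[y0 + 1, x1 + 1, drop = FALSE]
  m10 <- mat[y1 + 1, x0 + 1, drop = FALSE]
  m11 <- mat[y1 + 1, x1 + 1, drop = FALSE]
  outer(1 - wy, 1 - wx) * m00 + outer(1 - wy, wx) * m01 +
    outer(wy, 1 - wx) * m10 + outer(wy, wx) * m11
}

#' Bilinear resize of an RGB image
#'
#' @param image `(h, w, 3)` array.
#' @param out_h,out_w Positive output dimensions.
#' @return `(out_h, out_w, 3)` array.
#' @export
resize_image <- function(image, out_h, out_w) {
  image <- ensure_rgb(image)
  out <- array(0, dim = c(out_h, out_w, 3L))
  for (ch in 1:3) out[, , ch] <- resize_bilinear(image[, , ch], out_h, out_w)
  out
}

# Reflect a vector/matrix of 1-based integer indices into [1, n]
# (boundary pixels are not repeated; period 2n - 2).
reflect_index <- function(i, n) {
  if (n == 1L) return(i * 0L + 1L)
  period <- 2L * n - 2L
  m <- (i - 1) %% period
  m <- ifelse(m > n - 1, period - m, m)
  m + 1
}

# Inverse-mapped affine warp (rotation in degrees about the image centre,
# translation in pixels, isotropic zoom) with bilinear sampling and reflect
# padding. Reflect padding avoids the dark corners a constant fill would
# create, which would otherwise plant spurious saliency minima.
warp_affine <- function(image, angle_deg = 0, shift_rc = c(0, 0), zoom = 1) {
  image <- ensure_rgb(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (zoom <= 0) abort_invalid("zoom must be positive")
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  a <- angle_deg * pi / 180
  co <- cos(a); si <- sin(a)
  rr <- matrix(seq_len(h), h, w) - cr - shift_rc[1L]
  cc_m <- matrix(seq_len(w), h, w, byrow = TRUE) - cc - shift_rc[2L]
  # inverse rotation and zoom
  src_c <- ( co * cc_m + si * rr) / zoom + cc
  src_r <- (-si * cc_m + co * rr) / zoom + cr
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  r0i <- reflect_index(r0, h); r1i <- reflect_index(r0 + 1, h)
  c0i <- reflect_index(c0, w); c1i <- reflect_index(c0 + 1, w)
  out <- array(0, dim = dim(image))
  for (ch in 1:3) {
    plane <- image[, , ch]
    g <- function(ri, ci) matrix(plane[(ci - 1) * h + ri], h, w)
    out[, , ch] <- (1 - fr) * (1 - fc) * g(r0i, c0i) + (1 - fr) * fc * g(r0i, c1i) +
      fr * (1 - fc) * g(r1i, c0i) + fr * fc * g(r1i, c1i)
  }
  out
}
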