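# Frozen spectral feature extractor ("backbone"). Each branch of the
# classifier sees the same fixed transform: the input is resized to a square,
# converted to luminance, and summarized by the radial power spectrum of its
# 2-D FFT (log band energies over concentric frequency annuli) plus simple
# per-channel intensity statistics. Radial pooling makes the features
# invariant to texture orientation; band position encodes texture frequency,
# the fine-grained signal the ROI branch is meant to amplify.

#' Backbone specification
#'
#' @param name Backbone identifier; `"spectral-tiny"` is the built-in frozen
#'   spectral extractor.
#' @param input_size Square input size in pixels (default 48).
#' @param n_bands Number of radial frequency bands (default 12).
#' @param pretrained Ignored by `"spectral-tiny"` (it has no trainable
#'   weights); kept for interface compatibility with learned backbones.
#' @return Object of class `backbone_spec` with computed `feature_dim`.
#' @export
backbone_spec <- function(name = "spectral-tiny", input_size = 48L,
                          n_bands = 12L, pretrained = FALSE) {
  if (!identical(name, "spectral-tiny")) {
    abort_config(sprintf("unknown backbone name: %s", name))
  }
  if (!is_count(input_size) || input_size < 8) abort_invalid("input_size must be an integer >= 8")
  if (!is_count(n_bands) || n_bands < 2) abort_invalid("n_bands must be an integer >= 2")
  structure(list(name = name, input_size = as.integer(input_size),
                 n_bands = as.integer(n_bands),
                 feature_dim = as.integer(n_bands + 6L),
                 pretrained = isTRUE(pretrained)),
            class = "backbone_spec")
}

#' Extract frozen backbone features from one image
#'
#' @param spec A [backbone_spec()].
#' @param image `(h, w, 3)` array in `[0, 1]` (any size; resized internally).
#' @return Numeric feature vector of length `spec$feature_dim`.
#' @export
extract_features <- function(spec, image) {
  if (!inherits(spec, "backbone_spec")) abort_invalid("spec must be a backbone_spec")
  image <- ensure_rgb(image)
  s <- spec$input_size
  img <- resize_image(image, s, s)
  gray <- rgb_to_gray(img)
  gray <- gray - mean(gray)
  pw <- Mod(stats::fft(gray))^2 / length(gray)
  fy <- pmin(0:(s - 1), s - (0:(s - 1)))
  rad <- sqrt(outer(fy^2, fy^2, `+`))
  edges <- seq(0.5, s / 2, length.out = spec$n_bands + 1L)
  band <- findInterval(rad, edges, rightmost.closed = TRUE)
  bands <- vapply(seq_len(spec$n_bands), function(b) sum(pw[band == b]), numeric(1))
  stats <- c(vapply(1:3, function(ch) mean(img[, , ch]), numeric(1)),
             vapply(1:3, function(ch) stats::sd(img[, , ch]), numeric(1)))
  out <- c(log1p(bands * 1e4), stats)
  names(out) <- c(paste0("band", seq_len(spec$n_bands)),
                  paste0("mean_", c("r", "g", "b")), paste0("sd_", c("r", "g", "b")))
  out
}
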