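# Synthetic dermoscopy-like images: a textured elliptical blob (the "lesion")
# on a skin-toned background. The class signal is the spatial frequency of a
# sinusoidal texture confined to the blob, never color, so global color
# statistics cannot solve the task and the ROI branch is genuinely
# informative. Ground-truth masks/boxes and an oracle saliency map make every
# downstream module testable without any external dataset.

#' Parameters of the synthetic lesion-image generator
#'
#' @param image_size Square image edge length in pixels.
#' @param num_classes Number of classes (3 by default; 7 mirrors the standard
#'   dermoscopy label set, see [synth_preset()]).
#' @param blob_area_fraction Fraction of image area covered by the elliptical
#'   blob (default 0.15: a compact discriminative region).
#' @param blob_eccentricity Range of the ellipse axis ratio a/b.
#' @param background_tone List of per-channel (r, g, b) ranges for the
#'   skin-toned background.
#' @param lesion_darkening Range of the multiplicative darkening applied to
#'   the background tone inside the blob (identical distribution across
#'   classes, so tone carries no class signal).
#' @param texture_frequency Numeric vector, one spatial frequency
#'   (cycles/pixel) per class, pairwise distinct. Defaults to an arithmetic
#'   progression starting at 0.06 with step 0.06 (3 classes) or 0.04 with
#'   step 0.04 (more classes), keeping all classes below the Nyquist limit of
#'   downstream feature extraction.
#' @param texture_amplitude Amplitude of the sinusoidal class texture.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param oracle_noise Amplitude of the uniform background noise added to
#'   oracle saliency maps.
#' @param oracle_smooth_sd Gaussian smoothing sd (pixels) for oracle saliency
#'   maps; 0 (default) keeps the raw blob indicator so mean-thresholding
#'   recovers the blob support exactly.
#' @param class_names Optional character vector of class names.
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(image_size = 96L,
                         num_classes = 3L,
                         blob_area_fraction = 0.15,
                         blob_eccentricity = c(1.2, 2.0),
                         background_tone = list(r = c(0.75, 0.85),
                                                g = c(0.55, 0.65),
                                                b = c(0.45, 0.55)),
                         lesion_darkening = c(0.55, 0.70),
                         texture_frequency = NULL,
                         texture_amplitude = 0.15,
                         noise_sd = 0.05,
                         oracle_noise = 0.02,
                         oracle_smooth_sd = 0,
                         class_names = NULL) {
  if (!is_count(image_size) || image_size < 16) abort_invalid("image_size must be an integer >= 16")
  if (!is_count(num_classes) || num_classes < 2) abort_invalid("num_classes must be an integer >= 2")
  if (blob_area_fraction <= 0 || blob_area_fraction >= 1) {
    abort_invalid("blob_area_fraction must be in (0, 1)")
  }
  if (is.null(texture_frequency)) {
    step <- if (num_classes <= 3) 0.06 else 0.04
    texture_frequency <- step * seq_len(num_classes)
  }
  if (length(texture_frequency) != num_classes ||
      anyDuplicated(texture_frequency) > 0L) {
    abort_invalid("texture_frequency must give one distinct frequency per class")
  }
  if (is.null(class_names)) class_names <- paste0("C", seq_len(num_classes))
  if (length(class_names) != num_classes) abort_invalid("class_names length mismatch")
  structure(list(image_size = as.integer(image_size),
                 num_classes = as.integer(num_classes),
                 blob_area_fraction = blob_area_fraction,
                 blob_eccentricity = blob_eccentricity,
                 background_tone = background_tone,
                 lesion_darkening = lesion_darkening,
                 texture_frequency = texture_frequency,
                 texture_amplitude = texture_amplitude,
                 noise_sd = noise_sd,
                 oracle_noise = oracle_noise,
                 oracle_smooth_sd = oracle_smooth_sd,
                 class_names = class_names),
            class = "synth_params")
}

#' Generate one synthetic lesion image with ground truth
#'
#' Renders an elliptical blob at a seeded random position/orientation on a
#' skin-toned background, plants the class-specific sinusoidal texture
#' strictly inside the blob (random stripe orientation and phase), and adds
#' Gaussian pixel noise. Fully deterministic given `(params, label, seed)`.
#'
#' @param params A [synth_params()].
#' @param label Integer class label in `1..num_classes`.
#' @param seed Integer seed.
#' @return Object of class `synth_record`: `image`, `label`, `class_name`,
#'   `truth_mask` (a `binary_mask`), `truth_box` (its minimal enclosing
#'   `bounding_box`).
#' @export
generate_record <- function(params, label, seed) {
  if (!inherits(params, "synth_params")) abort_invalid("params must be synth_params")
  if (!is_count(label) || label < 1 || label > params$num_classes) {
    abort_invalid(sprintf("label must be in 1..%d", params$num_classes))
  }
  s <- params$image_size
  area <- params$blob_area_fraction * s^2
  max_ecc <- max(params$blob_eccentricity)
  a_max <- max_ecc * sqrt(area / (pi * max_ecc))  # widest possible semi-axis
  if (2 * a_max >= s - 2) {
    abort_config("blob_area_fraction too large: blob cannot fit inside the image")
  }
  with_seed(seed, {
    ecc <- stats::runif(1, params$blob_eccentricity[1], params$blob_eccentricity[2])
    b <- sqrt(area / (pi * ecc)); a <- ecc * b
    alpha <- stats::runif(1, 0, pi)
    cy <- stats::runif(1, a + 1, s - a - 1)
    cx <- stats::runif(1, a + 1, s - a - 1)
    X <- matrix(seq_len(s), s, s, byrow = TRUE)
    Y <- matrix(seq_len(s), s, s)
    u <- (X - cx) * cos(alpha) + (Y - cy) * sin(alpha)
    v <- -(X - cx) * sin(alpha) + (Y - cy) * cos(alpha)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    tone <- c(stats::runif(1, params$background_tone$r[1], params$background_tone$r[2]),
              stats::runif(1, params$background_tone$g[1], params$background_tone$g[2]),
              stats::runif(1, params$background_tone$b[1], params$background_tone$b[2]))
    dark <- stats::runif(1, params$lesion_darkening[1], params$lesion_darkening[2])
    f <- params$texture_frequency[label]
    phi <- stats::runif(1, 0, pi)
    phase <- stats::runif(1, 0, 2 * pi)
    tex <- params$texture_amplitude *
      sin(2 * pi * f * (X * cos(phi) + Y * sin(phi)) + phase)
    img <- array(0, dim = c(s, s, 3L))
    for (ch in 1:3) {
      plane <- matrix(tone[ch], s, s)
      plane[inside] <- plane[inside] * dark + tex[inside]
      img[, , ch] <- plane
    }
    if (params$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim = dim(img))
    }
    img <- clip01(img)
    truth_mask <- binary_mask(inside + 0L)
    structure(list(image = img, label = as.integer(label),
                   class_name = params$class_names[label],
                   truth_mask = truth_mask,
                   truth_box = min_enclosing_box(truth_mask)),
              class = "synth_record")
  })
}

#' Generate a balanced synthetic dataset with manifest and ground truth
#'
#' @param params A [synth_params()].
#' @param n_per_class Images per class.
#' @param seed Integer seed; each record gets a derived child seed.
#' @param duplicate_groups Images sharing each synthetic lesion group id
#'   (default 1). Values > 1 exercise lesion-group deduplication.
#' @param dir Optional directory; when given, images are written there as PNG
#'   and the manifest `path` column points at them.
#' @return List with `manifest` (data.frame: image_id, group_id, label, path,
#'   origin, parent_id), `images` (named list of arrays), `truth` (data.frame
#'   of truth boxes), `masks` (named list of `binary_mask`), `params`.
#' @export
generate_dataset <- function(params, n_per_class, seed, duplicate_groups = 1L,
                             dir = NULL) {
  if (!is_count(n_per_class) || n_per_class < 1) abort_invalid("n_per_class must be >= 1")
  if (!is_count(duplicate_groups) || duplicate_groups < 1) {
    abort_invalid("duplicate_groups must be >= 1")
  }
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list(); images <- list(); masks <- list(); truth <- list()
  idx <- 0L
  for (k in seq_len(params$num_classes)) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      rec <- generate_record(params, k, child_seed(seed, idx))
      image_id <- sprintf("syn_%s_%04d", tolower(params$class_names[k]), i)
      group_no <- (i - 1L) %/% duplicate_groups + 1L
      group_id <- sprintf("grp_%s_%04d", tolower(params$class_names[k]), group_no)
      path <- NA_character_
      if (!is.null(dir)) {
        path <- file.path(dir, paste0(image_id, ".png"))
        write_image(rec$image, path)
      }
      rows[[idx]] <- data.frame(image_id = image_id, group_id = group_id,
                                label = rec$class_name, path = path,
                                origin = "original", parent_id = NA_character_,
                                stringsAsFactors = FALSE)
      images[[image_id]] <- rec$image
      masks[[image_id]] <- rec$truth_mask
      truth[[idx]] <- data.frame(image_id = image_id,
                                 row_start = rec$truth_box$row_start,
                                 col_start = rec$truth_box$col_start,
                                 row_end = rec$truth_box$row_end,
                                 col_end = rec$truth_box$col_end,
                                 stringsAsFactors = FALSE)
    }
  }
  list(manifest = do.call(rbind, rows), images = images,
       truth = do.call(rbind, truth), masks = masks, params = params)
}

#' Oracle saliency map for a synthetic record
#'
#' The map is the (optionally Gaussian-smoothed) indicator of the true blob
#' mask plus low-amplitude uniform background noise, standing in for a
#' pretrained attention backbone in tests: mean-thresholding it recovers the
#' blob support (exactly, at the default smoothing of 0).
#'
#' @param record A `synth_record`, or a `binary_mask` truth mask.
#' @param params A [synth_params()].
#' @param seed Integer seed for the background noise.
#' @return A `saliency_map`.
#' @export
oracle_saliency <- function(record, params, seed = 0L) {
  mask <- if (inherits(record, "synth_record")) record$truth_mask
          else if (inherits(record, "binary_mask")) record
          else abort_invalid("record must be a synth_record or binary_mask")
  v <- mask$values + 0
  if (params$oracle_smooth_sd > 0) v <- gaussian_blur(v, params$oracle_smooth_sd)
  if (params$oracle_noise > 0) {
    v <- v + with_seed(seed, {
      matrix(stats::runif(length(v), 0, params$oracle_noise), nrow(v), ncol(v))
    })
  }
  saliency_map(v)
}

# Separable Gaussian blur with reflect boundary handling.
gaussian_blur <- function(m, sd) {
  r <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  conv1 <- function(mat, kern) {
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(kern)) {
      off <- j - r - 1L
      idx <- reflect_index(seq_len(n) + off, n)
      out <- out + kern[j] * mat[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m, k)), k))
}

#' Synthetic dataset presets
#'
#' `"tiny"`: 15 images (3 classes x 5) for smoke tests; `"smoke"`: 300 images
#' (3 classes x 100) sized for the single-branch vs dual-branch ablation.
#'
#' @param name `"tiny"` or `"smoke"`.
#' @param seed Integer seed.
#' @param duplicate_groups Passed to [generate_dataset()].
#' @param dir Optional output directory for PNGs.
#' @param params Optional [synth_params()] override.
#' @return See [generate_dataset()].
#' @export
synth_preset <- function(name = c("tiny", "smoke"), seed = 1L,
                         duplicate_groups = 1L, dir = NULL, params = NULL) {
  name <- match.arg(name)
  if (is.null(params)) params <- synth_params()
  n_per_class <- switch(name, tiny = 5L, smoke = 100L)
  generate_dataset(params, n_per_class, seed = seed,
                   duplicate_groups = duplicate_groups, dir = dir)
}

#' Dermoscopy-style 7-class synthetic parameters
#'
#' Mirrors the standard 7-label dermoscopy set (AKIEC, BCC, BKL, DF, MEL, NV,
#' VASC) for report-format tests; the images remain synthetic.
#'
#' @param ... Overrides forwarded to [synth_params()].
#' @return A [synth_params()] with 7 classes and dermoscopy class names.
#' @export
synth_params_derm7 <- function(...) {
  synth_params(num_classes = 7L,
               class_names = c("AKIEC", "BCC", "BKL", "DF", "MEL", "NV", "VASC"),
               ...)
}
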