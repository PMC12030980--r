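# Manifest-level data preparation: lesion-group deduplication, stratified
# train/test splitting, augmentation-based class rebalancing, and pixel-level
# augmentation. All randomized operations are pure functions of
# (input, config, seed).

manifest_cols <- c("image_id", "group_id", "label", "path", "origin", "parent_id")

#' Coerce a data frame to a dataset manifest
#'
#' A manifest has one row per image: `image_id` (unique), `group_id` (lesion
#' id), `label` (class), `path` (file location or `NA` for in-memory images),
#' `origin` (`"original"` or `"augmented"`) and `parent_id` (source image of
#' an augmented row, else `NA`).
#'
#' @param df Data frame with at least `image_id`, `group_id`, `label`.
#' @return The validated manifest data frame.
#' @export
as_manifest <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("image_id", "group_id", "label")) {
    if (!col %in% names(df)) abort_invalid(sprintf("manifest is missing column `%s`", col))
  }
  if (!"path" %in% names(df)) df$path <- NA_character_
  if (!"origin" %in% names(df)) df$origin <- "original"
  if (!"parent_id" %in% names(df)) df$parent_id <- NA_character_
  if (anyDuplicated(df$image_id) > 0L) abort_invalid("image_id values must be unique")
  aug <- df$origin == "augmented"
  if (any(aug) && !all(df$parent_id[aug] %in% df$image_id)) {
    abort_invalid("every augmented row's parent_id must exist in the manifest")
  }
  df[, manifest_cols]
}

#' Keep one representative image per lesion group
#'
#' Retains, within each `group_id`, the row with the lexicographically
#' smallest `image_id` (deterministic and auditable); all other rows are
#' dropped. Run before splitting so the same lesion can never appear on both
#' sides of a split.
#'
#' @param manifest A dataset manifest.
#' @return The deduplicated manifest (original row order preserved).
#' @export
deduplicate_by_group <- function(manifest) {
  manifest <- as_manifest(manifest)
  g <- manifest$group_id
  if (any(is.na(g) | !nzchar(g))) abort_invalid("group_id must be populated for every row")
  o <- order(g, manifest$image_id)
  keep_ids <- manifest$image_id[o][!duplicated(g[o])]
  manifest[manifest$image_id %in% keep_ids, , drop = FALSE]
}

#' Stratified train/test split
#'
#' Per class, `round(test_fraction * class_count)` rows (round-half-up) are
#' drawn into the test set, randomized within class by `seed`. Requires a
#' deduplicated manifest; after the split it is re-asserted that no
#' `group_id` spans both sides.
#'
#' @param manifest A deduplicated manifest.
#' @param test_fraction Fraction in `[0, 1)` (default 0.15).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
stratified_split <- function(manifest, test_fraction = 0.15, seed = 1L) {
  manifest <- as_manifest(manifest)
  if (test_fraction < 0 || test_fraction >= 1) {
    abort_invalid("test_fraction must be in [0, 1)")
  }
  if (anyDuplicated(manifest$group_id) > 0L) {
    abort_invalid("manifest must be deduplicated by group before splitting")
  }
  counts <- table(manifest$label)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    abort_invalid(sprintf("class(es) with fewer than 2 rows: %s",
                          paste(small, collapse = ", ")))
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(manifest$label == cl)
      n_test <- round_half_up(test_fraction * length(idx))
      if (n_test == 0L) integer(0) else sample(idx, n_test)
    }), use.names = FALSE)
  })
  train <- manifest[setdiff(seq_len(nrow(manifest)), test_idx), , drop = FALSE]
  test <- manifest[sort(test_idx), , drop = FALSE]
  stopifnot(length(intersect(train$group_id, test$group_id)) == 0L)
  list(train = train, test = test)
}

#' Augmentation configuration
#'
#' Geometric and photometric augmentation ranges used for class rebalancing.
#' Flip fields are probabilities in `[0, 1]`; logical values are accepted
#' (`TRUE` maps to 0.5, `FALSE` to 0).
#'
#' @param rotation_max_deg Maximum absolute rotation (degrees, default 180).
#' @param shift_fraction Maximum width/height shift as a fraction (default 0.10).
#' @param zoom_fraction Maximum zoom deviation from 1 (default 0.10).
#' @param horizontal_flip,vertical_flip Flip probabilities.
#' @param saturation,contrast,brightness Photometric jitter half-ranges
#'   (default 0.10, matching the spirit of the 10% geometric ranges).
#' @param seed Default seed for seeded augmentation draws.
#' @return Object of class `augment_config`.
#' @export
augment_config <- function(rotation_max_deg = 180, shift_fraction = 0.10,
                           zoom_fraction = 0.10, horizontal_flip = 0.5,
                           vertical_flip = 0.5, saturation = 0.10,
                           contrast = 0.10, brightness = 0.10, seed = 1L) {
  pflip <- function(x) {
    if (is.logical(x)) x <- if (x) 0.5 else 0
    x
  }
  horizontal_flip <- pflip(horizontal_flip); vertical_flip <- pflip(vertical_flip)
  if (rotation_max_deg < 0 || rotation_max_deg > 360) {
    abort_invalid("rotation_max_deg must be in [0, 360]")
  }
  for (v in c(shift_fraction, zoom_fraction, horizontal_flip, vertical_flip)) {
    if (v < 0 || v > 1) abort_invalid("fractions and flip probabilities must be in [0, 1]")
  }
  structure(list(rotation_max_deg = rotation_max_deg,
                 shift_fraction = shift_fraction,
                 zoom_fraction = zoom_fraction,
                 horizontal_flip = horizontal_flip,
                 vertical_flip = vertical_flip,
                 saturation = saturation, contrast = contrast,
                 brightness = brightness, seed = as.integer(seed)),
            class = "augment_config")
}

#' Pixel-level augmentation
#'
#' Seeded random horizontal/vertical flips followed by saturation, contrast
#' and brightness jitter (each drawn uniformly from the configured
#' half-range). Output has the same dimensions as the input and is clipped to
#' `[0, 1]`; identical seeds give identical output.
#'
#' @param image `(h, w, 3)` RGB array.
#' @param cfg An [augment_config()].
#' @param seed Integer seed (default `cfg$seed`).
#' @return Augmented `(h, w, 3)` array.
#' @export
pixel_augment <- function(image, cfg, seed = cfg$seed) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    abort_invalid("pixel_augment requires an RGB (h, w, 3) image")
  }
  with_seed(seed, {
    if (stats::runif(1) < cfg$horizontal_flip) image <- image[, rev(seq_len(dim(image)[2L])), , drop = FALSE]
    if (stats::runif(1) < cfg$vertical_flip) image <- image[rev(seq_len(dim(image)[1L])), , , drop = FALSE]
    ds <- stats::runif(1, -cfg$saturation, cfg$saturation)
    dc <- stats::runif(1, -cfg$contrast, cfg$contrast)
    db <- stats::runif(1, -cfg$brightness, cfg$brightness)
    if (ds != 0) {
      gray <- rgb_to_gray(image)
      for (ch in 1:3) image[, , ch] <- gray + (image[, , ch] - gray) * (1 + ds)
    }
    if (dc != 0) {
      m <- mean(image)
      image <- m + (image - m) * (1 + dc)
    }
    image <- image + db
    clip01(image)
  })
}

#' Full augmentation: geometric warp plus pixel-level jitter
#'
#' Draws a rotation in `[-rotation_max_deg, rotation_max_deg]`, row/column
#' shifts up to `shift_fraction` of each dimension, a zoom factor within
#' `1 +/- zoom_fraction` (reflect padding throughout), then applies
#' [pixel_augment()].
#'
#' @inheritParams pixel_augment
#' @return Augmented `(h, w, 3)` array.
#' @export
augment_image <- function(image, cfg, seed = cfg$seed) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    abort_invalid("augment_image requires an RGB (h, w, 3) image")
  }
  geo <- with_seed(seed, {
    list(angle = stats::runif(1, -cfg$rotation_max_deg, cfg$rotation_max_deg),
         shift = c(stats::runif(1, -cfg$shift_fraction, cfg$shift_fraction) * dim(image)[1L],
                   stats::runif(1, -cfg$shift_fraction, cfg$shift_fraction) * dim(image)[2L]),
         zoom = 1 + stats::runif(1, -cfg$zoom_fraction, cfg$zoom_fraction))
  })
  image <- warp_affine(image, angle_deg = geo$angle, shift_rc = geo$shift,
                       zoom = geo$zoom)
  pixel_augment(image, cfg, seed = child_seed(seed, 1L))
}

#' Rebalance class counts by augmentation-based oversampling
#'
#' Brings every class up to exactly `target_per_class` rows by adding
#' augmented copies of uniformly sampled (with replacement, seeded) original
#' rows of the same class. Original rows are never removed. Augmented images
#' are generated once here (not per epoch), so training sees a fixed
#' expanded set.
#'
#' @param manifest Training manifest.
#' @param cfg An [augment_config()].
#' @param target_per_class Integer target, or `"max"` for the largest current
#'   class count.
#' @param images Optional named list of in-memory images (by `image_id`);
#'   when absent, parents are read from `path`.
#' @param out_dir Optional directory where augmented PNGs are written (their
#'   `path` is filled in).
#' @param seed Integer seed (default `cfg$seed`).
#' @return List with `manifest` (original + augmented rows) and `images`
#'   (input list extended with augmented images, or `NULL` when images were
#'   written to disk only).
#' @export
rebalance_oversample <- function(manifest, cfg, target_per_class = "max",
                                 images = NULL, out_dir = NULL,
                                 seed = cfg$seed) {
  manifest <- as_manifest(manifest)
  if (nrow(manifest) == 0L) abort_invalid("manifest is empty")
  counts <- table(manifest$label)
  if (any(counts == 0L)) {
    abort_invalid(sprintf("empty class(es): %s",
                          paste(names(counts)[counts == 0L], collapse = ", ")))
  }
  if (identical(target_per_class, "max")) target_per_class <- max(counts)
  if (!is_count(target_per_class) || target_per_class < max(counts)) {
    abort_invalid("target_per_class must be >= the largest current class count")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  load_parent <- function(id) {
    if (!is.null(images) && id %in% names(images)) return(images[[id]])
    p <- manifest$path[manifest$image_id == id]
    if (is.na(p)) abort_invalid(sprintf("no image available for parent `%s`", id))
    read_image(p)
  }
  new_rows <- list(); counter <- 0L
  for (cl in names(counts)) {
    need <- target_per_class - counts[[cl]]
    if (need == 0L) next
    class_rows <- manifest[manifest$label == cl, , drop = FALSE]
    parents <- with_seed(child_seed(seed, match(cl, names(counts))), {
      sample(class_rows$image_id, need, replace = TRUE)
    })
    for (i in seq_len(need)) {
      counter <- counter + 1L
      pid <- parents[i]
      new_id <- sprintf("%s_aug%04d", pid, sum(new_rows_parent_count(new_rows, pid)) + 1L)
      aug <- augment_image(load_parent(pid), cfg, seed = child_seed(seed, 1000L + counter))
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(new_id, ".png"))
        write_image(aug, path)
      }
      if (!is.null(images)) images[[new_id]] <- aug
      new_rows[[counter]] <- data.frame(image_id = new_id,
                                        group_id = class_rows$group_id[class_rows$image_id == pid],
                                        label = cl, path = path,
                                        origin = "augmented", parent_id = pid,
                                        stringsAsFactors = FALSE)
    }
  }
  out <- if (counter > 0L) rbind(manifest, do.call(rbind, new_rows)) else manifest
  list(manifest = out, images = images)
}

new_rows_parent_count <- function(rows, pid) {
  if (length(rows) == 0L) return(0L)
  vapply(rows, function(r) identical(r$parent_id, pid), logical(1))
}

#' Read / write a manifest CSV
#'
#' @param path CSV path.
#' @param manifest Manifest data frame (for writing).
#' @return `read_manifest`: the manifest; `write_manifest`: `path`, invisibly.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("path", "parent_id")) {
    if (col %in% names(df)) df[[col]][!nzchar(df[[col]])] <- NA_character_
  }
  as_manifest(df)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as_manifest(manifest), path, row.names = FALSE, na = "")
  invisible(path)
}
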