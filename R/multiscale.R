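# Dual-branch multi-scale classifier. The full image and the attention-guided
# ROI crop pass through two parallel identical (frozen) feature extractors;
# each branch has a trainable linear adapter with ReLU, the adapter outputs
# are concatenated at a flatten layer, and an MLP head with softmax performs
# classification. Training uses Adam with cosine-annealed learning rate,
# categorical cross-entropy, a stratified validation split and early stopping
# on validation accuracy.

#' Training configuration
#'
#' @param epochs Maximum epochs (default 200).
#' @param learning_rate Initial Adam learning rate (default 1e-4), annealed
#'   with a cosine schedule over `epochs`.
#' @param batch_size Minibatch size (default 8).
#' @param early_stopping_patience Epochs without validation-accuracy
#'   improvement before stopping (default 10).
#' @param validation_fraction Fraction of the training set held out for
#'   validation (default 0.10), stratified by class.
#' @param seed Integer seed controlling the validation split and shuffling.
#' @return Object of class `train_config`. Optimizer is Adam and the loss is
#'   categorical cross-entropy; both are fixed.
#' @export
train_config <- function(epochs = 200L, learning_rate = 1e-4, batch_size = 8L,
                         early_stopping_patience = 10L,
                         validation_fraction = 0.10, seed = 1L) {
  if (!is_count(epochs) || epochs < 1) abort_invalid("epochs must be >= 1")
  if (learning_rate <= 0) abort_invalid("learning_rate must be positive")
  if (!is_count(batch_size) || batch_size < 1) abort_invalid("batch_size must be >= 1")
  if (!is_count(early_stopping_patience) || early_stopping_patience < 1) {
    abort_invalid("early_stopping_patience must be >= 1")
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort_invalid("validation_fraction must be in (0, 1)")
  }
  structure(list(epochs = as.integer(epochs), optimizer = "adam",
                 learning_rate = learning_rate, schedule = "cosine",
                 batch_size = as.integer(batch_size),
                 loss = "categorical_cross_entropy",
                 early_stopping_patience = as.integer(early_stopping_patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

init_dense <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

#' Build the dual-branch (global + ROI) classifier
#'
#' Both branches use the identical frozen backbone; each has a trainable
#' linear adapter (width `feature_dim`, ReLU). Adapter outputs are
#' concatenated (flatten layer of width `2 * feature_dim`) and classified by
#' an MLP head: one hidden layer of width `2 * feature_dim` with ReLU, then
#' a linear layer and softmax.
#'
#' @param spec A [backbone_spec()].
#' @param num_classes Number of classes (>= 2).
#' @param weight_sharing `"independent"` (default: two adapters trained in
#'   parallel) or `"tied"` (one adapter shared by both branches).
#' @param init_seed Seed for weight initialization.
#' @return Object of class `dual_branch_model`.
#' @export
build_dual_branch <- function(spec, num_classes,
                              weight_sharing = c("independent", "tied"),
                              init_seed = 1L) {
  weight_sharing <- match.arg(weight_sharing)
  new_branch_model(spec, num_classes, n_branches = 2L,
                   weight_sharing = weight_sharing, init_seed = init_seed)
}

#' Build the matched single-branch (global only) classifier
#'
#' Identical to [build_dual_branch()] but with one branch: the ablation
#' baseline for measuring the multi-scale booster's gain.
#'
#' @inheritParams build_dual_branch
#' @return Object of class `dual_branch_model` with `n_branches = 1`.
#' @export
build_single_branch <- function(spec, num_classes, init_seed = 1L) {
  new_branch_model(spec, num_classes, n_branches = 1L,
                   weight_sharing = "independent", init_seed = init_seed)
}

new_branch_model <- function(spec, num_classes, n_branches, weight_sharing,
                             init_seed) {
  if (!inherits(spec, "backbone_spec")) abort_invalid("spec must be a backbone_spec")
  if (!is_count(num_classes) || num_classes < 2) abort_invalid("num_classes must be >= 2")
  f <- spec$feature_dim
  hidden <- n_branches * f
  params <- with_seed(init_seed, {
    p <- list(Wg = init_dense(f, f), bg = numeric(f))
    if (n_branches == 2L && weight_sharing == "independent") {
      p$Wr <- init_dense(f, f); p$br <- numeric(f)
    }
    p$W1 <- init_dense(n_branches * f, hidden)
    p$b1 <- numeric(hidden)
    p$W2 <- init_dense(hidden, num_classes)
    p$b2 <- numeric(num_classes)
    p
  })
  structure(list(spec = spec, num_classes = as.integer(num_classes),
                 n_branches = as.integer(n_branches),
                 weight_sharing = weight_sharing,
                 params = params, scaler = NULL, classes = NULL,
                 init_seed = as.integer(init_seed), history = NULL),
            class = "dual_branch_model")
}

scale_features <- function(model, X) {
  if (is.null(model$scaler)) return(X)
  sweep(sweep(X, 2L, model$scaler$mean), 2L, model$scaler$sd, `/`)
}

# Forward pass on feature matrices (rows = instances). Returns the
# intermediates needed for backprop.
forward_internal <- function(model, Xg, Xr = NULL) {
  p <- model$params
  zg <- relu(Xg %*% p$Wg + matrix(p$bg, nrow(Xg), length(p$bg), byrow = TRUE))
  if (model$n_branches == 2L) {
    Wr <- if (model$weight_sharing == "tied") p$Wg else p$Wr
    br <- if (model$weight_sharing == "tied") p$bg else p$br
    zr <- relu(Xr %*% Wr + matrix(br, nrow(Xr), length(br), byrow = TRUE))
    Z <- cbind(zg, zr)
  } else {
    zr <- NULL; Z <- zg
  }
  h <- relu(Z %*% p$W1 + matrix(p$b1, nrow(Z), length(p$b1), byrow = TRUE))
  logits <- h %*% p$W2 + matrix(p$b2, nrow(h), length(p$b2), byrow = TRUE)
  list(zg = zg, zr = zr, Z = Z, h = h, probs = softmax_rows(logits))
}

#' Forward pass: probability vector for one (global, ROI) image pair
#'
#' Deterministic given fixed parameters and inputs. Both images must already
#' be at the backbone input size.
#'
#' @param model A `dual_branch_model`.
#' @param global_image `(s, s, 3)` array with `s = spec$input_size`.
#' @param roi_image ROI crop, same size; required for dual-branch models.
#' @return Named probability vector over classes (sums to 1).
#' @export
forward <- function(model, global_image, roi_image = NULL) {
  s <- model$spec$input_size
  check_size <- function(img, what) {
    img <- ensure_rgb(img)
    if (dim(img)[1L] != s || dim(img)[2L] != s) {
      abort_invalid(sprintf("%s must be %d x %d (backbone input size)", what, s, s))
    }
    img
  }
  global_image <- check_size(global_image, "global_image")
  Xg <- matrix(extract_features(model$spec, global_image), 1L)
  Xr <- NULL
  if (model$n_branches == 2L) {
    if (is.null(roi_image)) abort_invalid("dual-branch model requires roi_image")
    roi_image <- check_size(roi_image, "roi_image")
    Xr <- matrix(extract_features(model$spec, roi_image), 1L)
    Xr <- scale_features(model, Xr)
  }
  Xg <- scale_features(model, Xg)
  probs <- forward_internal(model, Xg, Xr)$probs[1L, ]
  names(probs) <- model$classes %||% paste0("class", seq_len(model$num_classes))
  probs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gradients of mean cross-entropy wrt all trainable parameters.
backward_internal <- function(model, fw, Xg, Xr, y_onehot) {
  p <- model$params
  n <- nrow(y_onehot)
  g <- list()
  dlogits <- (fw$probs - y_onehot) / n
  g$W2 <- t(fw$h) %*% dlogits
  g$b2 <- colSums(dlogits)
  dh <- dlogits %*% t(p$W2)
  dh[fw$h <= 0] <- 0
  g$W1 <- t(fw$Z) %*% dh
  g$b1 <- colSums(dh)
  dZ <- dh %*% t(p$W1)
  f <- ncol(fw$zg)
  dzg <- dZ[, seq_len(f), drop = FALSE]
  dzg[fw$zg <= 0] <- 0
  g$Wg <- t(Xg) %*% dzg
  g$bg <- colSums(dzg)
  if (model$n_branches == 2L) {
    dzr <- dZ[, f + seq_len(f), drop = FALSE]
    dzr[fw$zr <= 0] <- 0
    if (model$weight_sharing == "tied") {
      g$Wg <- g$Wg + t(Xr) %*% dzr
      g$bg <- g$bg + colSums(dzr)
    } else {
      g$Wr <- t(Xr) %*% dzr
      g$br <- colSums(dzr)
    }
  }
  g
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# Resolve images for manifest rows and compute branch feature matrices.
branch_feature_matrices <- function(model, manifest, images, roi_provider) {
  s <- model$spec$input_size
  n <- nrow(manifest)
  f <- model$spec$feature_dim
  Xg <- matrix(0, n, f)
  Xr <- if (model$n_branches == 2L) matrix(0, n, f) else NULL
  errors <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      img <- load_manifest_image(manifest[i, ], images)
      Xg[i, ] <- extract_features(model$spec, img)
      if (model$n_branches == 2L) {
        if (is.null(roi_provider)) abort_invalid("dual-branch model requires a roi_provider")
        crop <- roi_provider(img, manifest$image_id[i])
        Xr[i, ] <- extract_features(model$spec, crop)
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors[i] <- res
  }
  list(Xg = Xg, Xr = Xr, errors = errors)
}

load_manifest_image <- function(row, images) {
  id <- row$image_id
  if (!is.null(images) && id %in% names(images)) return(images[[id]])
  if (is.na(row$path) || !nzchar(row$path)) {
    abort_invalid(sprintf("image `%s` is neither in memory nor on disk", id))
  }
  read_image(row$path)
}

#' Train a dual- or single-branch classifier
#'
#' Adam with cosine-annealed learning rate, categorical cross-entropy, a
#' stratified validation split (`validation_fraction`) and early stopping on
#' validation accuracy (`early_stopping_patience`); returns the
#' best-validation-accuracy checkpoint. Reproducible given `cfg$seed` and the
#' model's `init_seed`.
#'
#' @param model A model from [build_dual_branch()] or [build_single_branch()].
#' @param manifest Dataset manifest (>= 2 classes).
#' @param cfg A [train_config()].
#' @param images Optional named list of in-memory images.
#' @param roi_provider Function `(image, image_id) -> cropped image`; required
#'   for dual-branch models. See [make_oracle_roi_provider()].
#' @return The trained model, with `history` (one row per epoch: lr,
#'   train/validation loss and accuracy) and `classes` filled in.
#' @export
train <- function(model, manifest, cfg, images = NULL, roi_provider = NULL) {
  if (!inherits(model, "dual_branch_model")) abort_invalid("model must be a dual_branch_model")
  if (!inherits(cfg, "train_config")) abort_invalid("cfg must be a train_config")
  manifest <- as_manifest(manifest)
  if (nrow(manifest) == 0L) abort_invalid("manifest is empty")
  classes <- sort(unique(manifest$label))
  if (length(classes) < 2L) abort_invalid("manifest must contain at least 2 classes")
  if (length(classes) != model$num_classes) {
    abort_config(sprintf("model has %d classes but manifest has %d",
                         model$num_classes, length(classes)))
  }
  feats <- branch_feature_matrices(model, manifest, images, roi_provider)
  bad <- which(!is.na(feats$errors))
  if (length(bad) > 0L) {
    abort_invalid(sprintf("unreadable training image(s): %s",
                          paste(manifest$image_id[bad], collapse = ", ")))
  }
  mu <- colMeans(feats$Xg)
  sd0 <- apply(feats$Xg, 2L, stats::sd)
  if (model$n_branches == 2L) {
    both <- rbind(feats$Xg, feats$Xr)
    mu <- colMeans(both); sd0 <- apply(both, 2L, stats::sd)
  }
  sd0[sd0 < 1e-8] <- 1
  model$scaler <- list(mean = mu, sd = sd0)
  model$classes <- classes
  Xg <- scale_features(model, feats$Xg)
  Xr <- if (is.null(feats$Xr)) NULL else scale_features(model, feats$Xr)
  y <- match(manifest$label, classes)
  n <- length(y)
  val_idx <- with_seed(cfg$seed, {
    idx <- unlist(lapply(classes, function(cl) {
      cidx <- which(manifest$label == cl)
      k <- round_half_up(cfg$validation_fraction * length(cidx))
      if (k == 0L) integer(0) else sample(cidx, k)
    }), use.names = FALSE)
    if (length(idx) == 0L) idx <- sample(n, 1L)
    idx
  })
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0L) abort_invalid("validation split leaves no training rows")
  onehot <- diag(model$num_classes)[y, , drop = FALSE]

  state <- list(t = 0L,
                m = lapply(model$params, function(p) p * 0),
                v = lapply(model$params, function(p) p * 0))
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  hist <- vector("list", cfg$epochs)
  stalled <- 0L
  with_seed(child_seed(cfg$seed, 17L), {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate * 0.5 * (1 + cos(pi * (epoch - 1) / cfg$epochs))
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        b <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        fw <- forward_internal(model, Xg[b, , drop = FALSE],
                               if (is.null(Xr)) NULL else Xr[b, , drop = FALSE])
        pb <- pmax(fw$probs[cbind(seq_along(b), y[b])], 1e-12)
        ep_loss <- ep_loss - sum(log(pb))
        ep_correct <- ep_correct + sum(max.col(fw$probs, ties.method = "first") == y[b])
        grads <- backward_internal(model, fw, Xg[b, , drop = FALSE],
                                   if (is.null(Xr)) NULL else Xr[b, , drop = FALSE],
                                   onehot[b, , drop = FALSE])
        upd <- adam_update(model$params, grads, state, lr)
        model$params <- upd$params
        state <- upd$state
      }
      vw <- forward_internal(model, Xg[val_idx, , drop = FALSE],
                             if (is.null(Xr)) NULL else Xr[val_idx, , drop = FALSE])
      val_pb <- pmax(vw$probs[cbind(seq_along(val_idx), y[val_idx])], 1e-12)
      val_loss <- -mean(log(val_pb))
      val_acc <- mean(max.col(vw$probs, ties.method = "first") == y[val_idx])
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  train_loss = ep_loss / length(ord),
                                  train_acc = ep_correct / length(ord),
                                  val_loss = val_loss, val_acc = val_acc)
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, params = model$params, epoch = epoch)
        stalled <- 0L
      } else {
        stalled <- stalled + 1L
        if (stalled >= cfg$early_stopping_patience) break
      }
    }
  })
  model$params <- best$params
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$best_epoch <- best$epoch
  model$best_val_acc <- best$acc
  model
}

#' Predict labels and probabilities for every manifest image
#'
#' Unreadable images produce a per-row error record (label `NA`) and the run
#' continues. Argmax ties break toward the lowest class index.
#'
#' @param model A trained model.
#' @param manifest Dataset manifest.
#' @param images Optional named list of in-memory images.
#' @param roi_provider Required for dual-branch models.
#' @return Data frame: `image_id`, `true_label` (if present), `pred_label`,
#'   one `prob_<class>` column per class, `error`.
#' @export
predict_dataset <- function(model, manifest, images = NULL, roi_provider = NULL) {
  manifest <- as_manifest(manifest)
  classes <- model$classes %||% abort_invalid("model has not been trained")
  n <- nrow(manifest)
  probs <- matrix(NA_real_, n, length(classes),
                  dimnames = list(NULL, classes))
  pred <- rep(NA_character_, n)
  errors <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      img <- load_manifest_image(manifest[i, ], images)
      Xg <- scale_features(model, matrix(extract_features(model$spec, img), 1L))
      Xr <- NULL
      if (model$n_branches == 2L) {
        if (is.null(roi_provider)) abort_invalid("dual-branch model requires a roi_provider")
        crop <- roi_provider(img, manifest$image_id[i])
        Xr <- scale_features(model, matrix(extract_features(model$spec, crop), 1L))
      }
      p <- forward_internal(model, Xg, Xr)$probs[1L, ]
      probs[i, ] <- p
      pred[i] <- classes[which.max(p)]
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors[i] <- res
  }
  out <- data.frame(image_id = manifest$image_id,
                    true_label = manifest$label,
                    pred_label = pred, stringsAsFactors = FALSE)
  colnames(probs) <- paste0("prob_", classes)
  out <- cbind(out, as.data.frame(probs))
  out$error <- errors
  out
}

#' ROI providers for training and prediction
#'
#' `make_oracle_roi_provider` crops using the synthetic generator's oracle
#' saliency (ground-truth blob mask) for images it knows, falling back to
#' [contrast_saliency()] for unknown (e.g. augmented) images.
#' `make_saliency_roi_provider` crops using a caller-supplied saliency
#' function `(image, image_id) -> saliency_map`. Both resize crops to the
#' backbone input size and memoize by `image_id`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param output_size Crop output size in pixels.
#' @param params Synthetic parameters (defaults to the dataset's).
#' @param saliency_fn Function `(image, image_id) -> saliency_map` or matrix.
#' @param ... Extra arguments passed to [extract_roi()].
#' @return Function `(image, image_id) -> cropped image`.
#' @export
make_oracle_roi_provider <- function(dataset, output_size = 48L,
                                     params = dataset$params, ...) {
  cache <- new.env(parent = emptyenv())
  ids <- names(dataset$masks)
  function(image, image_id) {
    if (!is.null(cache[[image_id]])) return(cache[[image_id]])
    map <- if (image_id %in% ids) {
      oracle_saliency(dataset$masks[[image_id]], params,
                      seed = child_seed(211L, match(image_id, ids)))
    } else {
      contrast_saliency(image)
    }
    crop <- extract_roi(image, map, output_size = output_size, ...)$crop
    cache[[image_id]] <- crop
    crop
  }
}

#' @rdname make_oracle_roi_provider
#' @export
make_saliency_roi_provider <- function(saliency_fn, output_size = 48L, ...) {
  cache <- new.env(parent = emptyenv())
  function(image, image_id) {
    if (!is.null(cache[[image_id]])) return(cache[[image_id]])
    crop <- extract_roi(image, saliency_fn(image, image_id),
                        output_size = output_size, ...)$crop
    cache[[image_id]] <- crop
    crop
  }
}

#' Self-contained tone/texture-contrast saliency
#'
#' Gaussian-smoothed absolute deviation of luminance from its image-wide
#' median: a simple saliency source for images whose region of interest
#' differs from the background in tone or texture. Useful when no attention
#' backbone is available.
#'
#' @param image `(h, w, 3)` array.
#' @param smooth_sd Gaussian smoothing sd in pixels (default 2).
#' @return A `saliency_map`.
#' @export
contrast_saliency <- function(image, smooth_sd = 2) {
  g <- rgb_to_gray(ensure_rgb(image))
  saliency_map(gaussian_blur(abs(g - stats::median(g)), smooth_sd))
}

#' Serialize / restore a model checkpoint as JSON
#'
#' Checkpoints embed the backbone spec, class set, scaler and all weights as
#' plain JSON, portable across platforms.
#'
#' @param model A `dual_branch_model`.
#' @param path Output path.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(spec = unclass(model$spec), num_classes = model$num_classes,
              n_branches = model$n_branches, weight_sharing = model$weight_sharing,
              params = lapply(model$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                else list(dim = NULL, data = as.numeric(p))
              }),
              scaler = model$scaler, classes = model$classes,
              init_seed = model$init_seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- backbone_spec(obj$spec$name, obj$spec$input_size, obj$spec$n_bands,
                        obj$spec$pretrained)
  model <- new_branch_model(spec, obj$num_classes, obj$n_branches,
                            obj$weight_sharing, obj$init_seed)
  model$params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2L) matrix(p$data, p$dim[1L], p$dim[2L])
    else as.numeric(p$data)
  })
  if (!is.null(obj$scaler)) {
    model$scaler <- list(mean = as.numeric(obj$scaler$mean),
                         sd = as.numeric(obj$scaler$sd))
  }
  model$classes <- obj$classes
  model
}
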