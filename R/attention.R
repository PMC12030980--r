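# Transformer self-attention utilities: scaled-dot-product attention weights,
# aggregation of per-head/per-layer weights into a patch-grid saliency map,
# and upsampling of that grid to image resolution.

#' Attention configuration
#'
#' Describes the attention geometry of a transformer backbone and how its
#' weights are turned into a saliency map.
#'
#' @param num_heads Number of attention heads `H` (positive integer).
#' @param model_dim Model embedding dimension `D`; must be divisible by
#'   `num_heads`. Per-head query/key dimension is `D / H`.
#' @param num_layers Number of encoder layers `L`.
#' @param patch_size Patch edge length in pixels.
#' @param aggregation How per-layer, per-head weights are combined:
#'   `"sum_heads_mean_layers"` sums the head matrices within each layer and
#'   averages the sums across layers; `"rollout"` averages heads per layer,
#'   adds the identity (residual path), renormalizes rows and multiplies the
#'   layer matrices in order.
#' @param source_token Which attention row becomes the map: the class-token
#'   row (`"cls_row"`, the default; the class token aggregates the image for
#'   classification) or the mean over all token rows (`"mean_rows"`).
#' @return An object of class `attention_config`.
#' @export
attention_config <- function(num_heads, model_dim, num_layers,
                             patch_size = 16L,
                             aggregation = c("sum_heads_mean_layers", "rollout"),
                             source_token = c("cls_row", "mean_rows")) {
  aggregation <- match.arg(aggregation)
  source_token <- match.arg(source_token)
  if (!is_count(num_heads) || num_heads < 1) abort_invalid("num_heads must be a positive integer")
  if (!is_count(model_dim) || model_dim < 1) abort_invalid("model_dim must be a positive integer")
  if (!is_count(num_layers) || num_layers < 1) abort_invalid("num_layers must be a positive integer")
  if (!is_count(patch_size) || patch_size < 1) abort_invalid("patch_size must be a positive integer")
  if (model_dim %% num_heads != 0) {
    abort_invalid(sprintf("model_dim (%d) must be divisible by num_heads (%d)",
                          model_dim, num_heads))
  }
  structure(list(num_heads = as.integer(num_heads),
                 model_dim = as.integer(model_dim),
                 num_layers = as.integer(num_layers),
                 patch_size = as.integer(patch_size),
                 aggregation = aggregation,
                 source_token = source_token),
            class = "attention_config")
}

#' Bundle per-layer, per-head attention weight matrices
#'
#' @param weights Array of dim `(L, H, T + 1, T + 1)` where `T` is the number
#'   of image patches and the extra token is the class token, stored first
#'   (row/column 1). Every row of every matrix must be a probability vector.
#' @param grid_rows,grid_cols Patch grid shape with `grid_rows * grid_cols = T`.
#' @param tol Row-sum tolerance.
#' @return An object of class `attention_stack`.
#' @export
attention_stack <- function(weights, grid_rows, grid_cols, tol = 1e-5) {
  d <- dim(weights)
  if (length(d) != 4L || d[3L] != d[4L]) {
    abort_invalid("weights must be an (L, H, T+1, T+1) array")
  }
  t_tok <- d[3L]
  if (!is_count(grid_rows) || !is_count(grid_cols) ||
      grid_rows < 1 || grid_cols < 1 ||
      grid_rows * grid_cols != t_tok - 1L) {
    abort_invalid(sprintf(
      "grid (%s x %s) does not factor the %d patch tokens",
      grid_rows, grid_cols, t_tok - 1L))
  }
  if (any(weights < -tol)) abort_invalid("attention weights must be non-negative")
  rs <- apply(weights, c(1L, 2L, 3L), sum)
  if (any(abs(rs - 1) > tol)) {
    abort_invalid("every attention row must sum to 1 (row-stochastic)")
  }
  structure(list(weights = weights,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols)),
            class = "attention_stack")
}

#' Scaled dot-product attention weights
#'
#' Computes `softmax(Q %*% t(K) / sqrt(D / H))` row by row, the attention
#' weight matrix of one head: each row is the distribution of one query
#' token's attention over all key tokens.
#'
#' @param Q,K Query and key matrices, each `T' x d` with `d = model_dim /
#'   num_heads` from `cfg`.
#' @param cfg An [attention_config()].
#' @return A `T' x T'` row-stochastic matrix.
#' @export
scaled_dot_attention <- function(Q, K, cfg) {
  if (!inherits(cfg, "attention_config")) abort_invalid("cfg must be an attention_config")
  Q <- as.matrix(Q); K <- as.matrix(K)
  d_head <- cfg$model_dim / cfg$num_heads
  if (ncol(Q) != ncol(K) || nrow(Q) != nrow(K)) {
    abort_invalid("Q and K must have identical dimensions")
  }
  if (ncol(Q) != d_head) {
    abort_invalid(sprintf("Q/K width %d does not match model_dim/num_heads = %g",
                          ncol(Q), d_head))
  }
  if (nrow(Q) < 1L) abort_invalid("Q must have at least one row")
  logits <- Q %*% t(K) / sqrt(d_head)
  softmax_rows(logits)
}

#' Aggregate an attention stack into a patch-grid saliency
#'
#' Under `sum_heads_mean_layers` the head matrices are summed within each
#' layer and the per-layer sums are averaged across layers; under `rollout`
#' heads are averaged per layer, the identity is added for the residual path,
#' rows are renormalized and the layer matrices are multiplied in order
#' (later layers on the left). The configured source-token row, restricted to
#' the patch columns, is reshaped to the patch grid (row-major).
#'
#' @param stack An [attention_stack()].
#' @param cfg An [attention_config()].
#' @return `grid_rows` x `grid_cols` non-negative matrix.
#' @export
aggregate_attention <- function(stack, cfg) {
  if (!inherits(stack, "attention_stack")) abort_invalid("stack must be an attention_stack")
  if (!inherits(cfg, "attention_config")) abort_invalid("cfg must be an attention_config")
  w <- stack$weights
  L <- dim(w)[1L]; H <- dim(w)[2L]; tt <- dim(w)[3L]
  layer_mats <- lapply(seq_len(L), function(l) {
    m <- matrix(0, tt, tt)
    for (h in seq_len(H)) m <- m + w[l, h, , ]
    m
  })
  agg <- switch(cfg$aggregation,
    sum_heads_mean_layers = Reduce(`+`, layer_mats) / L,
    rollout = {
      roll <- diag(tt)
      for (l in seq_len(L)) {
        a <- layer_mats[[l]] / H + diag(tt)  # mean over heads + residual
        a <- a / rowSums(a)
        roll <- a %*% roll
      }
      roll
    })
  row_vals <- switch(cfg$source_token,
    cls_row = agg[1L, ],
    mean_rows = colMeans(agg))
  patch <- row_vals[-1L]
  matrix(patch, nrow = stack$grid_rows, ncol = stack$grid_cols, byrow = TRUE)
}

#' Upsample a patch-grid saliency to image resolution
#'
#' @param patch_saliency Non-empty numeric matrix (patch grid).
#' @param image_height,image_width Target dimensions in pixels.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return An object of class `saliency_map` with fields `values` (a
#'   `image_height` x `image_width` non-negative matrix) and `source_grid`.
#' @export
upsample_to_image <- function(patch_saliency, image_height, image_width,
                              method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  patch_saliency <- as.matrix(patch_saliency)
  if (nrow(patch_saliency) < 1L || ncol(patch_saliency) < 1L) {
    abort_invalid("patch_saliency must be non-empty")
  }
  if (!is_count(image_height) || !is_count(image_width) ||
      image_height < 1 || image_width < 1) {
    abort_invalid("target image dimensions must be positive integers")
  }
  vals <- if (method == "bilinear") {
    resize_bilinear(patch_saliency, image_height, image_width)
  } else {
    gh <- nrow(patch_saliency); gw <- ncol(patch_saliency)
    ri <- pmin(floor((seq_len(image_height) - 0.5) * gh / image_height) + 1, gh)
    ci <- pmin(floor((seq_len(image_width) - 0.5) * gw / image_width) + 1, gw)
    patch_saliency[ri, ci, drop = FALSE]
  }
  saliency_map(vals, source_grid = dim(patch_saliency))
}

#' Construct a saliency map object
#'
#' @param values Non-negative numeric matrix at image resolution.
#' @param source_grid Optional `(grid_rows, grid_cols)` provenance.
#' @return Object of class `saliency_map`.
#' @export
saliency_map <- function(values, source_grid = dim(values)) {
  values <- as.matrix(values)
  if (any(values < 0)) abort_invalid("saliency values must be non-negative")
  structure(list(values = values, source_grid = as.integer(source_grid)),
            class = "saliency_map")
}

as_saliency <- function(x) {
  if (inherits(x, "saliency_map")) x else saliency_map(as.matrix(x))
}

#' Export a saliency map as an 8-bit grayscale PNG
#'
#' Values are min-max scaled to `[0, 1]`; a constant map exports as black.
#'
#' @param map A `saliency_map` or numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_saliency_png <- function(map, path) {
  v <- as_saliency(map)$values
  rng <- range(v)
  v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  png::writePNG(v, path)
  invisible(path)
}

#' Export a saliency map as a plain-text array
#'
#' Tab-separated values, one image row per line; portable and diffable.
#'
#' @param map A `saliency_map` or numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_saliency_array <- function(map, path) {
  utils::write.table(as_saliency(map)$values, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
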