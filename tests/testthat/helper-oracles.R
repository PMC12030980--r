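# Independent oracles used to cross-check the implementation. These are
# deliberately naive (recursion, explicit loops, direct counting) and share
# no code with the package internals.

# Recursive flood-fill connected-component labeling.
flood_fill_label <- function(m, connectivity) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  if (connectivity == 8) {
    nb <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  fill <- function(r, c, id) {
    if (r < 1 || r > h || c < 1 || c > w) return(invisible(NULL))
    if (m[r, c] == 0 || lab[r, c] != 0L) return(invisible(NULL))
    lab[r, c] <<- id
    for (k in seq_len(nrow(nb))) fill(r + nb[k, "dr"], c + nb[k, "dc"], id)
    invisible(NULL)
  }
  cur <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (m[r, c] != 0 && lab[r, c] == 0L) {
      cur <- cur + 1L
      fill(r, c, cur)
    }
  }
  lab
}

# Largest component with the lexicographic (row, col) tie-break, from the
# flood-fill labels: pick max size; among ties, the component whose smallest
# (row, col) pixel sorts first.
oracle_largest_component <- function(m, connectivity) {
  lab <- flood_fill_label(m, connectivity)
  n <- max(lab)
  if (n == 0L) return(matrix(0L, nrow(m), ncol(m)))
  sizes <- sapply(seq_len(n), function(id) sum(lab == id))
  best_ids <- which(sizes == max(sizes))
  keys <- sapply(best_ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    ord <- order(px[, 1], px[, 2])
    px[ord[1], 1] * (ncol(m) + 1) + px[ord[1], 2]
  })
  (lab == best_ids[which.min(keys)]) + 0L
}

# Direct-counting classification metrics (one explicit loop per count).
oracle_report <- function(true, pred, classes) {
  out <- list()
  n <- length(true)
  for (cl in classes) {
    tp <- fp <- fn <- 0L
    for (i in seq_len(n)) {
      if (pred[i] == cl && true[i] == cl) tp <- tp + 1L
      if (pred[i] == cl && true[i] != cl) fp <- fp + 1L
      if (pred[i] != cl && true[i] == cl) fn <- fn + 1L
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out[[cl]] <- c(precision = prec, recall = rec, f1 = f1,
                   support = tp + fn)
  }
  correct <- 0L
  for (i in seq_len(n)) if (true[i] == pred[i]) correct <- correct + 1L
  list(per_class = out, accuracy = correct / n)
}

# Counting mode with lowest-class-index tie-break.
oracle_mode <- function(votes, classes) {
  counts <- sapply(classes, function(cl) sum(votes == cl))
  classes[which(counts == max(counts))[1]]
}

random_binary_matrix <- function(h, w, p = 0.5) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

random_row_stochastic <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m / rowSums(m)
}

# Build a valid attention stack from independent random row-stochastic heads.
random_attention_stack <- function(L, H, grid_rows, grid_cols) {
  tt <- grid_rows * grid_cols + 1L
  w <- array(0, dim = c(L, H, tt, tt))
  for (l in seq_len(L)) for (h in seq_len(H)) w[l, h, , ] <- random_row_stochastic(tt)
  attention_stack(w, grid_rows, grid_cols)
}

# Shared tiny fixture: a 3-class synthetic dataset and a model trained on it,
# built once per test run.
tiny_fixture_env <- new.env(parent = emptyenv())

tiny_fixture <- function() {
  if (is.null(tiny_fixture_env$ds)) {
    ds <- generate_dataset(synth_params(), n_per_class = 12L, seed = 99L)
    split <- stratified_split(ds$manifest, 0.25, seed = 5L)
    spec <- backbone_spec()
    prov <- make_oracle_roi_provider(ds)
    model <- build_dual_branch(spec, 3L, init_seed = 2L)
    model <- train(model, split$train,
                   train_config(epochs = 15L, learning_rate = 0.01, seed = 2L),
                   images = ds$images, roi_provider = prov)
    tiny_fixture_env$ds <- ds
    tiny_fixture_env$split <- split
    tiny_fixture_env$spec <- spec
    tiny_fixture_env$prov <- prov
    tiny_fixture_env$model <- model
  }
  as.list(tiny_fixture_env)
}
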