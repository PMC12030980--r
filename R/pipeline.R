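# End-to-end orchestration: synth -> prepare -> extract-roi -> train ->
# predict -> ensemble -> report, driven by a single config (YAML file or
# nested list). Every stage writes its artifacts plus a JSON provenance
# record (config hash, seed, timestamp); a completed stage with an identical
# config is skipped unless forced.

default_config <- function() {
  list(
    seed = 1L,
    output_dir = "roiboost_run",
    synth = list(preset = "tiny", duplicate_groups = 1L),
    prepare = list(test_fraction = 0.15, target_per_class = "max"),
    roi = list(connectivity = 8L, min_box_fraction = 0.01, output_size = 48L,
               saliency = "oracle"),
    backbone = list(name = "spectral-tiny", input_size = 48L, n_bands = 12L),
    train = list(epochs = 20L, learning_rate = 0.01, batch_size = 8L,
                 early_stopping_patience = 10L, validation_fraction = 0.10),
    booster = "on",
    ensemble = list(members = 3L, tie_policy = "auto"),
    augment = list(rotation_max_deg = 180, shift_fraction = 0.10,
                   zoom_fraction = 0.10, horizontal_flip = 0.5,
                   vertical_flip = 0.5, saturation = 0.10, contrast = 0.10,
                   brightness = 0.10)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a pipeline run configuration
#'
#' @param path_or_list Path to a YAML file, or a nested list of overrides;
#'   `NULL` gives the defaults (tiny synthetic preset, 3-member ensemble,
#'   booster on).
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(path_or_list = NULL) {
  override <- if (is.null(path_or_list)) {
    list()
  } else if (is.character(path_or_list)) {
    yaml::read_yaml(path_or_list)
  } else {
    path_or_list
  }
  cfg <- merge_config(default_config(), override)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  tf <- cfg$prepare$test_fraction
  if (!is.numeric(tf) || tf < 0 || tf >= 1) add("prepare.test_fraction must be in [0, 1)")
  if (!cfg$synth$preset %in% c("tiny", "smoke")) add("synth.preset must be 'tiny' or 'smoke'")
  if (!cfg$roi$saliency %in% c("oracle", "contrast")) {
    add("roi.saliency must be 'oracle' or 'contrast'")
  }
  if (!cfg$roi$connectivity %in% c(4, 8)) add("roi.connectivity must be 4 or 8")
  if (!identical(cfg$booster, "on") && !identical(cfg$booster, "off")) {
    add("booster must be 'on' or 'off'")
  }
  if (!is.numeric(cfg$ensemble$members) || cfg$ensemble$members < 1) {
    add("ensemble.members must be >= 1")
  }
  if (!is.numeric(cfg$train$epochs) || cfg$train$epochs < 1) add("train.epochs must be >= 1")
  if (length(problems) > 0L) {
    abort_config(paste0("invalid config:\n  - ", paste(problems, collapse = "\n  - ")))
  }
  invisible(cfg)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

stage_dir <- function(cfg, stage) file.path(cfg$output_dir, stage)

stage_complete <- function(cfg, stage) {
  pf <- file.path(stage_dir(cfg, stage), "provenance.json")
  if (!file.exists(pf)) return(FALSE)
  prov <- tryCatch(jsonlite::read_json(pf), error = function(e) NULL)
  !is.null(prov) && identical(prov$config_hash, config_hash(cfg))
}

write_provenance <- function(cfg, stage) {
  jsonlite::write_json(
    list(stage = stage, config_hash = config_hash(cfg), seed = cfg$seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = unclass(cfg)),
    file.path(stage_dir(cfg, stage), "provenance.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
}

pipeline_stages <- c("synth", "prepare", "extract-roi", "train", "predict",
                     "ensemble", "report")

#' Run the pipeline end to end (or a subset of stages)
#'
#' Stages: `synth` (generate the synthetic dataset), `prepare` (dedup,
#' stratified split, rebalancing), `extract-roi` (saliency -> mask -> largest
#' component -> box -> crop for every image), `train` (the ensemble members,
#' dual-branch when `booster: on`), `predict` (per-member test predictions),
#' `ensemble` (majority vote + classification report), `report` (formatted
#' text table). Each stage writes artifacts and provenance under
#' `output_dir/<stage>/`; a completed stage with identical config is a no-op
#' unless `force = TRUE`.
#'
#' @param config A [run_config()] (or path/list accepted by it).
#' @param stages Character subset of the stage names, in pipeline order.
#' @param force Re-run stages whose provenance already matches.
#' @return Invisibly, a list with the output directory and per-stage status
#'   (`"ran"` or `"skipped"`).
#' @export
run_pipeline <- function(config = NULL, stages = pipeline_stages, force = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad) > 0L) abort_config(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  status <- character(0)
  for (st in stages) {
    if (!force && stage_complete(cfg, st)) {
      status[st] <- "skipped"
      next
    }
    t0 <- Sys.time()
    dir.create(stage_dir(cfg, st), recursive = TRUE, showWarnings = FALSE)
    switch(st,
           "synth" = stage_synth(cfg),
           "prepare" = stage_prepare(cfg),
           "extract-roi" = stage_extract_roi(cfg),
           "train" = stage_train(cfg),
           "predict" = stage_predict(cfg),
           "ensemble" = stage_ensemble(cfg),
           "report" = stage_report(cfg))
    write_provenance(cfg, st)
    message(sprintf("[roiboost] stage %-11s done in %.1fs", st,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    status[st] <- "ran"
  }
  invisible(list(output_dir = cfg$output_dir, status = status))
}

synth_params_from_config <- function(cfg) {
  args <- cfg$synth
  args$preset <- NULL; args$duplicate_groups <- NULL
  do.call(synth_params, args)
}

stage_synth <- function(cfg) {
  d <- stage_dir(cfg, "synth")
  params <- synth_params_from_config(cfg)
  ds <- synth_preset(cfg$synth$preset, seed = cfg$seed,
                     duplicate_groups = cfg$synth$duplicate_groups,
                     dir = file.path(d, "images"), params = params)
  write_manifest(ds$manifest, file.path(d, "manifest.csv"))
  utils::write.table(ds$truth, file.path(d, "truth_boxes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  mask_dir <- file.path(d, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  for (id in names(ds$masks)) {
    png::writePNG(ds$masks[[id]]$values + 0, file.path(mask_dir, paste0(id, ".png")))
  }
}

stage_prepare <- function(cfg) {
  d <- stage_dir(cfg, "prepare")
  manifest <- read_manifest(file.path(stage_dir(cfg, "synth"), "manifest.csv"))
  dedup <- deduplicate_by_group(manifest)
  split <- stratified_split(dedup, test_fraction = cfg$prepare$test_fraction,
                            seed = cfg$seed)
  acfg <- do.call(augment_config, c(cfg$augment, list(seed = cfg$seed)))
  target <- cfg$prepare$target_per_class
  if (is.numeric(target)) target <- as.integer(target)
  reb <- rebalance_oversample(split$train, acfg, target_per_class = target,
                              out_dir = file.path(d, "augmented"),
                              seed = cfg$seed)
  write_manifest(reb$manifest, file.path(d, "train.csv"))
  write_manifest(split$test, file.path(d, "test.csv"))
}

# Saliency for one manifest row under the configured source: the generator's
# oracle map when a truth mask exists (original synthetic rows), otherwise a
# tone/texture-contrast map computed from the image itself.
row_saliency <- function(cfg, image, image_id, params) {
  mask_file <- file.path(stage_dir(cfg, "synth"), "masks", paste0(image_id, ".png"))
  if (cfg$roi$saliency == "oracle" && file.exists(mask_file)) {
    mask <- binary_mask(round(png::readPNG(mask_file)))
    oracle_saliency(mask, params, seed = child_seed(cfg$seed, sum(utf8ToInt(image_id))))
  } else {
    contrast_saliency(image)
  }
}

stage_extract_roi <- function(cfg) {
  d <- stage_dir(cfg, "extract-roi")
  crop_dir <- file.path(d, "crops"); mask_dir <- file.path(d, "masks")
  dir.create(crop_dir, showWarnings = FALSE); dir.create(mask_dir, showWarnings = FALSE)
  params <- synth_params_from_config(cfg)
  prep <- stage_dir(cfg, "prepare")
  manifest <- rbind(read_manifest(file.path(prep, "train.csv")),
                    read_manifest(file.path(prep, "test.csv")))
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$image_id[i]
    img <- read_image(manifest$path[i])
    map <- row_saliency(cfg, img, id, params)
    roi <- extract_roi(img, map, connectivity = cfg$roi$connectivity,
                       min_box_fraction = cfg$roi$min_box_fraction,
                       output_size = cfg$roi$output_size)
    write_image(roi$crop, file.path(crop_dir, paste0(id, ".png")))
    png::writePNG(roi$component_mask$values + 0,
                  file.path(mask_dir, paste0(id, ".png")))
    rows[[i]] <- data.frame(image_id = id, row_start = roi$box$row_start,
                            col_start = roi$box$col_start, row_end = roi$box$row_end,
                            col_end = roi$box$col_end, fallback = roi$fallback,
                            stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), file.path(d, "boxes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
}

# ROI provider backed by the extract-roi stage's crops on disk.
crops_roi_provider <- function(cfg) {
  crop_dir <- file.path(stage_dir(cfg, "extract-roi"), "crops")
  function(image, image_id) {
    f <- file.path(crop_dir, paste0(image_id, ".png"))
    if (file.exists(f)) return(read_image(f))
    extract_roi(image, contrast_saliency(image),
                connectivity = cfg$roi$connectivity,
                min_box_fraction = cfg$roi$min_box_fraction,
                output_size = cfg$roi$output_size)$crop
  }
}

member_seeds <- function(cfg) {
  vapply(seq_len(cfg$ensemble$members), function(j) child_seed(cfg$seed, 100L + j),
         integer(1))
}

stage_train <- function(cfg) {
  d <- stage_dir(cfg, "train")
  train_manifest <- read_manifest(file.path(stage_dir(cfg, "prepare"), "train.csv"))
  spec <- do.call(backbone_spec, cfg$backbone)
  tcfg_args <- cfg$train
  provider <- crops_roi_provider(cfg)
  num_classes <- length(unique(train_manifest$label))
  for (j in seq_along(member_seeds(cfg))) {
    s <- member_seeds(cfg)[j]
    model <- if (identical(cfg$booster, "on")) {
      build_dual_branch(spec, num_classes, init_seed = s)
    } else {
      build_single_branch(spec, num_classes, init_seed = s)
    }
    tcfg <- do.call(train_config, c(tcfg_args, list(seed = s)))
    model <- train(model, train_manifest, tcfg, roi_provider = provider)
    save_checkpoint(model, file.path(d, sprintf("member%02d.json", j)))
    hist_file <- file.path(d, sprintf("member%02d_history.jsonl", j))
    writeLines(vapply(seq_len(nrow(model$history)), function(r) {
      jsonlite::toJSON(as.list(model$history[r, ]), auto_unbox = TRUE, digits = NA)
    }, character(1)), hist_file)
  }
}

load_members <- function(cfg) {
  d <- stage_dir(cfg, "train")
  files <- sort(list.files(d, pattern = "^member[0-9]+\\.json$", full.names = TRUE))
  if (length(files) == 0L) abort_config("no trained members found; run the train stage first")
  lapply(files, load_checkpoint)
}

stage_predict <- function(cfg) {
  d <- stage_dir(cfg, "predict")
  test_manifest <- read_manifest(file.path(stage_dir(cfg, "prepare"), "test.csv"))
  provider <- crops_roi_provider(cfg)
  members <- load_members(cfg)
  for (j in seq_along(members)) {
    pd <- predict_dataset(members[[j]], test_manifest, roi_provider = provider)
    utils::write.csv(pd, file.path(d, sprintf("member%02d_predictions.csv", j)),
                     row.names = FALSE)
  }
}

stage_ensemble <- function(cfg) {
  d <- stage_dir(cfg, "ensemble")
  test_manifest <- read_manifest(file.path(stage_dir(cfg, "prepare"), "test.csv"))
  provider <- crops_roi_provider(cfg)
  members <- load_members(cfg)
  res <- ensemble_predict(members, test_manifest, roi_provider = provider,
                          tie_policy = cfg$ensemble$tie_policy)
  utils::write.csv(res$predictions, file.path(d, "predictions.csv"),
                   row.names = FALSE)
  write_report_json(res$report, file.path(d, "report.json"))
}

stage_report <- function(cfg) {
  d <- stage_dir(cfg, "report")
  ens <- stage_dir(cfg, "ensemble")
  pred <- utils::read.csv(file.path(ens, "predictions.csv"),
                          stringsAsFactors = FALSE)
  report <- classification_report(pred$true_label, pred$ensemble_label)
  writeLines(format(report), file.path(d, "report.txt"))
  file.copy(file.path(ens, "report.json"), file.path(d, "report.json"),
            overwrite = TRUE)
}
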