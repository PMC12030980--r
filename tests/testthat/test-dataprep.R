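make_manifest <- function(n_per_class, classes = c("A", "B"), groups_of = 1L) {
  rows <- list(); i <- 0L
  for (cl in classes) for (j in seq_len(n_per_class)) {
    i <- i + 1L
    rows[[i]] <- data.frame(image_id = sprintf("img_%s_%03d", cl, j),
                            group_id = sprintf("g_%s_%03d", cl, (j - 1) %/% groups_of + 1),
                            label = cl, stringsAsFactors = FALSE)
  }
  as_manifest(do.call(rbind, rows))
}

test_that("group deduplication keeps the smallest image_id per lesion", {
  m <- make_manifest(6, groups_of = 1L)
  expect_identical(deduplicate_by_group(m), m)  # singleton groups: identity
  m3 <- data.frame(image_id = c("c", "a", "b"), group_id = "g1", label = "A")
  out <- deduplicate_by_group(m3)
  expect_equal(nrow(out), 1L)
  expect_equal(out$image_id, "a")
  bad <- data.frame(image_id = "x", group_id = NA_character_, label = "A")
  expect_error(deduplicate_by_group(bad), class = "roiboost_invalid_input")
})

test_that("post-dedup survivor count equals the distinct-group count", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    m <- data.frame(image_id = sprintf("i%03d", sample(1000, n)),
                    group_id = sprintf("g%02d", sample(1:12, n, replace = TRUE)),
                    label = sample(c("A", "B"), n, replace = TRUE))
    out <- deduplicate_by_group(as_manifest(m))
    expect_equal(nrow(out), length(unique(m$group_id)))
    expect_equal(anyDuplicated(out$group_id), 0L)
  }
})

test_that("stratified split has exact per-class counts and no group leakage", {
  m <- make_manifest(100, classes = c("A", "B", "C"))
  sp <- stratified_split(m, 0.15, seed = 4)
  expect_true(all(table(sp$test$label) == 15L))
  expect_true(all(table(sp$train$label) == 85L))
  expect_equal(length(intersect(sp$train$group_id, sp$test$group_id)), 0L)
  expect_equal(sort(c(sp$train$image_id, sp$test$image_id)), sort(m$image_id))
  # same seed reproduces; different seed differs
  sp2 <- stratified_split(m, 0.15, seed = 4)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(m, 0.15, seed = 5)
  expect_false(identical(sort(sp$test$image_id), sort(sp3$test$image_id)))
  # boundary: zero fraction
  sp0 <- stratified_split(m, 0, seed = 1)
  expect_equal(nrow(sp0$test), 0L)
  expect_equal(nrow(sp0$train), nrow(m))
  # round-half-up on odd counts: 0.15 * 10 = 1.5 -> 2
  m10 <- make_manifest(10)
  expect_true(all(table(stratified_split(m10, 0.15, seed = 1)$test$label) == 2L))
  # errors
  tiny <- data.frame(image_id = c("a", "b", "c"), group_id = c("g1", "g2", "g3"),
                     label = c("A", "A", "B"))
  expect_error(stratified_split(as_manifest(tiny), 0.15, 1),
               regexp = "B", class = "roiboost_invalid_input")
})

test_that("rebalancing reaches exact class targets without touching originals", {
  ds <- generate_dataset(synth_params(image_size = 48), n_per_class = 4, seed = 6)
  m <- ds$manifest
  m <- m[!(m$label == "C2" & m$image_id > sort(m$image_id[m$label == "C2"])[1]), ]
  # class sizes now {C1: 4, C2: 1, C3: 4}
  cfg <- augment_config(seed = 2)
  reb <- rebalance_oversample(m, cfg, target_per_class = "max", images = ds$images)
  counts <- table(reb$manifest$label)
  expect_true(all(counts == 4L))
  expect_true(all(m$image_id %in% reb$manifest$image_id))
  aug <- reb$manifest[reb$manifest$origin == "augmented", ]
  expect_equal(nrow(aug), 3L)
  # relational consistency: every parent exists and shares the class
  for (i in seq_len(nrow(aug))) {
    parent <- reb$manifest[reb$manifest$image_id == aug$parent_id[i], ]
    expect_equal(nrow(parent), 1L)
    expect_equal(parent$label, aug$label[i])
    expect_true(aug$image_id[i] %in% names(reb$images))
  }
  # no-op when already balanced
  ds2 <- generate_dataset(synth_params(image_size = 48), n_per_class = 3, seed = 7)
  reb2 <- rebalance_oversample(ds2$manifest, cfg, target_per_class = 3L,
                               images = ds2$images)
  expect_identical(reb2$manifest, as_manifest(ds2$manifest))
  # explicit target above max
  reb3 <- rebalance_oversample(ds2$manifest, cfg, target_per_class = 5L,
                               images = ds2$images)
  expect_true(all(table(reb3$manifest$label) == 5L))
  expect_error(rebalance_oversample(ds2$manifest, cfg, target_per_class = 2L,
                                    images = ds2$images),
               class = "roiboost_invalid_input")
})

test_that("rebalancing is reproducible under a fixed seed", {
  ds <- generate_dataset(synth_params(image_size = 48), n_per_class = 3, seed = 8)
  m <- ds$manifest[-2, ]
  cfg <- augment_config(seed = 9)
  r1 <- rebalance_oversample(m, cfg, images = ds$images, seed = 11)
  r2 <- rebalance_oversample(m, cfg, images = ds$images, seed = 11)
  expect_identical(r1$manifest, r2$manifest)
  expect_identical(r1$images, r2$images)
})

test_that("pixel augmentation honours identity, involution and jitter bounds", {
  img <- array(runif(20 * 20 * 3), dim = c(20, 20, 3))
  idcfg <- augment_config(horizontal_flip = 0, vertical_flip = 0,
                          saturation = 0, contrast = 0, brightness = 0)
  expect_equal(pixel_augment(img, idcfg, seed = 1), img)
  # horizontal flip with probability 1, applied twice, restores the original
  fcfg <- augment_config(horizontal_flip = 1, vertical_flip = 0,
                         saturation = 0, contrast = 0, brightness = 0)
  once <- pixel_augment(img, fcfg, seed = 3)
  expect_false(identical(once, img))
  expect_equal(pixel_augment(once, fcfg, seed = 4), img)
  # brightness jitter shifts the mean of a mid-gray image within range
  gray <- array(0.5, dim = c(16, 16, 3))
  bcfg <- augment_config(horizontal_flip = 0, vertical_flip = 0,
                         saturation = 0, contrast = 0, brightness = 0.1)
  for (s in 1:10) {
    shift <- mean(pixel_augment(gray, bcfg, seed = s)) - 0.5
    expect_lte(abs(shift), 0.1 + 1e-12)
  }
  expect_error(pixel_augment(matrix(0.5, 5, 5), idcfg, 1),
               class = "roiboost_invalid_input")
  # same seed, same output
  rcfg <- augment_config()
  expect_identical(pixel_augment(img, rcfg, seed = 5),
                   pixel_augment(img, rcfg, seed = 5))
})

test_that("full augmentation preserves dimensions, range and determinism", {
  img <- array(runif(30 * 30 * 3), dim = c(30, 30, 3))
  cfg <- augment_config()
  a1 <- augment_image(img, cfg, seed = 6)
  expect_equal(dim(a1), dim(img))
  expect_true(all(a1 >= 0 & a1 <= 1))
  expect_identical(a1, augment_image(img, cfg, seed = 6))
  expect_false(identical(a1, augment_image(img, cfg, seed = 7)))
})

test_that("manifests round-trip through CSV", {
  ds <- generate_dataset(synth_params(image_size = 48), n_per_class = 2, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_manifest(ds$manifest, f)
  back <- read_manifest(f)
  expect_equal(back$image_id, ds$manifest$image_id)
  expect_equal(back$label, ds$manifest$label)
  expect_true(all(is.na(back$path)))
})
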