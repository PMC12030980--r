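spec <- backbone_spec()

test_that("dual-branch construction wires the flatten/concatenation widths", {
  m <- build_dual_branch(spec, 7)
  f <- spec$feature_dim
  expect_equal(dim(m$params$W1), c(2L * f, 2L * f))  # head input = concat width
  expect_equal(dim(m$params$W2), c(2L * f, 7L))
  expect_error(build_dual_branch(spec, 1), class = "roiboost_invalid_input")
  expect_error(backbone_spec("resnet50"), class = "roiboost_config_error")
  s <- build_single_branch(spec, 3)
  expect_equal(dim(s$params$W1), c(f, f))
})

test_that("tied weight sharing keeps one adapter for both branches", {
  fx <- tiny_fixture()
  m <- build_dual_branch(spec, 3, weight_sharing = "tied", init_seed = 4)
  expect_null(m$params$Wr)  # single stored adapter serves both branches
  tcfg <- train_config(epochs = 1, learning_rate = 0.01, seed = 4)
  trained <- train(m, fx$split$train, tcfg, images = fx$ds$images,
                   roi_provider = fx$prov)
  expect_null(trained$params$Wr)  # still tied after a training step
  # independent branches with different weights are order-sensitive
  ind <- fx$model
  img <- resize_image(fx$ds$images[[1]], spec$input_size, spec$input_size)
  roi <- resize_image(fx$ds$images[[2]], spec$input_size, spec$input_size)
  expect_false(isTRUE(all.equal(forward(ind, img, roi), forward(ind, roi, img),
                                check.names = FALSE)))
})

test_that("forward outputs live on the probability simplex, deterministically", {
  fx <- tiny_fixture()
  m <- fx$model
  img <- resize_image(fx$ds$images[[3]], spec$input_size, spec$input_size)
  roi <- resize_image(fx$ds$images[[4]], spec$input_size, spec$input_size)
  p1 <- forward(m, img, roi)
  expect_equal(sum(p1), 1, tolerance = 1e-5)
  expect_true(all(p1 >= 0))
  expect_identical(p1, forward(m, img, roi))  # bit-identical in eval mode
  # zeroed classification head gives the uniform distribution
  m0 <- build_dual_branch(spec, 5)
  m0$params$W2[] <- 0; m0$params$b2[] <- 0
  m0$classes <- paste0("K", 1:5)
  p0 <- forward(m0, img, roi)
  expect_equal(unname(p0), rep(0.2, 5))
  expect_error(forward(m, resize_image(img, 10, 10), roi),
               class = "roiboost_invalid_input")
})

test_that("training is seeded-reproducible and respects early stopping", {
  fx <- tiny_fixture()
  tcfg <- train_config(epochs = 6, learning_rate = 0.01, seed = 3,
                       early_stopping_patience = 2)
  run <- function() {
    m <- build_dual_branch(spec, 3, init_seed = 5)
    train(m, fx$split$train, tcfg, images = fx$ds$images, roi_provider = fx$prov)
  }
  t1 <- run(); t2 <- run()
  expect_equal(t1$history$train_loss[1], t2$history$train_loss[1], tolerance = 1e-6)
  expect_identical(t1$params, t2$params)
  # checkpoint is the best validation accuracy observed
  expect_equal(t1$best_val_acc, max(t1$history$val_acc))
  # stopping: no more than patience epochs beyond the best epoch
  expect_lte(nrow(t1$history), t1$best_epoch + tcfg$early_stopping_patience)
  # invalid manifests
  expect_error(train(build_dual_branch(spec, 3), fx$split$train[0, ], tcfg),
               class = "roiboost_invalid_input")
  one_class <- fx$split$train[fx$split$train$label == "C1", ]
  expect_error(train(build_dual_branch(spec, 3), one_class, tcfg,
                     images = fx$ds$images, roi_provider = fx$prov),
               class = "roiboost_invalid_input")
})

test_that("a separable two-class problem is learned to perfect training accuracy", {
  p0 <- synth_params(num_classes = 2, noise_sd = 0)
  ds <- generate_dataset(p0, n_per_class = 10, seed = 21)
  prov <- make_oracle_roi_provider(ds)
  m <- build_dual_branch(spec, 2, init_seed = 1)
  m <- train(m, ds$manifest, train_config(epochs = 20, learning_rate = 0.01,
                                          seed = 1, early_stopping_patience = 20),
             images = ds$images, roi_provider = prov)
  expect_equal(m$history$train_acc[nrow(m$history)], 1.0)
})

test_that("predict_dataset accounts for every row and isolates failures", {
  fx <- tiny_fixture()
  pd <- predict_dataset(fx$model, fx$split$test, images = fx$ds$images,
                        roi_provider = fx$prov)
  expect_equal(nrow(pd), nrow(fx$split$test))
  expect_true(all(is.na(pd$error)))
  probs <- as.matrix(pd[, paste0("prob_", fx$model$classes)])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(pd)), tolerance = 1e-5)
  # argmax consistency
  expect_equal(pd$pred_label,
               fx$model$classes[max.col(probs, ties.method = "first")])
  # empty manifest -> empty table
  pd0 <- predict_dataset(fx$model, fx$split$test[0, ], images = fx$ds$images,
                         roi_provider = fx$prov)
  expect_equal(nrow(pd0), 0L)
  # unreadable image -> error row, run continues
  broken <- fx$split$test
  broken$path[1] <- "/nonexistent/file.png"
  imgs <- fx$ds$images
  imgs[[broken$image_id[1]]] <- NULL
  pdb <- predict_dataset(fx$model, broken, images = imgs, roi_provider = fx$prov)
  expect_false(is.na(pdb$error[1]))
  expect_true(is.na(pdb$pred_label[1]))
  expect_true(all(is.na(pdb$error[-1])))
})

test_that("checkpoints round-trip through JSON", {
  fx <- tiny_fixture()
  f <- tempfile(fileext = ".json")
  save_checkpoint(fx$model, f)
  back <- load_checkpoint(f)
  expect_equal(back$params, fx$model$params, tolerance = 1e-12)
  expect_equal(back$classes, fx$model$classes)
  pd1 <- predict_dataset(fx$model, fx$split$test[1:3, ], images = fx$ds$images,
                         roi_provider = fx$prov)
  pd2 <- predict_dataset(back, fx$split$test[1:3, ], images = fx$ds$images,
                         roi_provider = fx$prov)
  expect_equal(pd1$pred_label, pd2$pred_label)
})
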