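test_that("majority vote matches hand-worked and degenerate cases", {
  p <- vote_panel(matrix(c("A", "A", "B"), 1, 3), classes = c("A", "B"))
  expect_equal(majority_vote(p), "A")
  expect_equal(majority_vote(vote_panel(matrix("A", 1, 1))), "A")
  # 4-model tie, mean probabilities A: 0.55, B: 0.60
  labels <- matrix(c("A", "A", "B", "B"), 1, 4)
  probs <- array(0, dim = c(1, 4, 2))
  probs[1, , 1] <- c(0.7, 0.7, 0.2, 0.2)   # mean P(A) = 0.45
  probs[1, , 2] <- c(0.3, 0.3, 0.8, 0.8)   # mean P(B) = 0.55 -> B wins on prob
  pt <- vote_panel(labels, probabilities = probs, classes = c("A", "B"))
  expect_equal(majority_vote(pt, "highest_mean_prob"), "B")
  expect_equal(majority_vote(pt, "lowest_index"), "A")
  expect_error(majority_vote(vote_panel(labels, classes = c("A", "B")),
                             "highest_mean_prob"),
               class = "roiboost_config_error")
})

test_that("vote properties hold on random panels against the counting mode", {
  set.seed(33)
  classes <- c("A", "B", "C", "D")
  for (i in 1:300) {
    n <- sample(1:8, 1); k <- sample(1:7, 1)
    labels <- matrix(sample(classes, n * k, replace = TRUE), n, k)
    panel <- vote_panel(labels, classes = classes)
    got <- majority_vote(panel, "lowest_index")
    expect_equal(got, apply(labels, 1, oracle_mode, classes = classes))
    # permutation invariance over the model axis
    perm <- vote_panel(labels[, sample(k), drop = FALSE], classes = classes)
    expect_equal(majority_vote(perm, "lowest_index"), got)
    # unanimity
    unan <- which(apply(labels, 1, function(r) length(unique(r)) == 1))
    if (length(unan) > 0) expect_equal(got[unan], labels[unan, 1])
    # monotone reinforcement: duplicating the winning model's column
    winner_col <- vapply(seq_len(n), function(r) {
      cols <- which(labels[r, ] == got[r])
      cols[1]
    }, integer(1))
    aug <- cbind(labels, labels[cbind(seq_len(n), winner_col)])
    expect_equal(majority_vote(vote_panel(aug, classes = classes), "lowest_index"),
                 got)
  }
})

test_that("classification report reproduces the direct-count hand case", {
  # one-vs-rest counts for class P: TP = 8, FP = 2, FN = 2, TN = 8
  true <- c(rep("P", 8), rep("N", 2), rep("P", 2), rep("N", 8))
  pred <- c(rep("P", 8), rep("P", 2), rep("N", 2), rep("N", 8))
  rep_ <- classification_report(true, pred)
  row <- rep_$per_class[rep_$per_class$class == "P", ]
  expect_equal(row$precision, 0.8)
  expect_equal(row$recall, 0.8)
  expect_equal(row$f1, 0.8)
  expect_equal(rep_$accuracy, 16 / 20)
  expect_equal(sum(rep_$confusion), 20L)
  # perfect predictions
  perf <- classification_report(pred, pred)
  expect_equal(perf$accuracy, 1.0)
  expect_true(all(perf$per_class$f1 == 1.0))
  expect_error(classification_report(c("A", "B"), "A"),
               class = "roiboost_invalid_input")
})

test_that("report agrees with the counting oracle on random 7-class data", {
  set.seed(44)
  classes <- paste0("K", 1:7)
  for (i in 1:25) {
    true <- sample(classes, 200, replace = TRUE)
    pred <- sample(classes, 200, replace = TRUE)
    rep_ <- suppressWarnings(classification_report(true, pred, classes = classes))
    oracle <- oracle_report(true, pred, classes)
    expect_equal(rep_$accuracy, oracle$accuracy)
    for (j in seq_along(classes)) {
      oc <- oracle$per_class[[classes[j]]]
      expect_equal(rep_$per_class$precision[j], unname(oc["precision"]))
      expect_equal(rep_$per_class$recall[j], unname(oc["recall"]))
      expect_equal(rep_$per_class$f1[j], unname(oc["f1"]))
      expect_equal(rep_$per_class$support[j], unname(as.integer(oc["support"])))
    }
    # confusion-matrix cells by direct counting
    for (a in 1:7) for (b in 1:7) {
      expect_equal(rep_$confusion[a, b],
                   sum(true == classes[a] & pred == classes[b]))
    }
    # accuracy identity: mean of per-instance correctness
    expect_equal(rep_$accuracy, mean(true == pred))
  }
})

test_that("macro/weighted averages and zero-division conventions hold", {
  true <- c("A", "A", "A", "B")
  pred <- c("A", "A", "A", "A")  # class B never predicted
  expect_warning(rep_ <- classification_report(true, pred, classes = c("A", "B")),
                 class = "roiboost_metric_warning")
  b <- rep_$per_class[rep_$per_class$class == "B", ]
  expect_equal(b$precision, 0)
  expect_equal(b$recall, 0)
  supports <- rep_$per_class$support
  expect_equal(rep_$weighted$f1,
               sum(rep_$per_class$f1 * supports) / sum(supports))
  expect_equal(rep_$macro$f1, mean(rep_$per_class$f1))
})

test_that("one-vs-rest ROC-AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  classes <- c("X", "Y", "Z")
  true <- sample(classes, 120, replace = TRUE)
  scores <- matrix(runif(120 * 3), 120, 3)
  scores <- scores / rowSums(scores)
  rep_ <- classification_report(true, sample(classes, 120, replace = TRUE),
                                scores = scores, classes = classes)
  for (j in 1:3) {
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = as.integer(true == classes[j]), predictor = scores[, j],
      direction = "<", quiet = TRUE)))
    expect_equal(rep_$per_class$roc_auc[j], ref, tolerance = 1e-10)
  }
})

test_that("ensemble prediction reduces to its members in degenerate cases", {
  fx <- tiny_fixture()
  single <- predict_dataset(fx$model, fx$split$test, images = fx$ds$images,
                            roi_provider = fx$prov)
  # k = 1: ensemble equals the model exactly
  e1 <- suppressWarnings(
    ensemble_predict(list(fx$model), fx$split$test, images = fx$ds$images,
                     roi_provider = fx$prov))
  expect_equal(e1$predictions$ensemble_label, single$pred_label)
  # identical members: unanimity
  e3 <- suppressWarnings(
    ensemble_predict(list(fx$model, fx$model, fx$model), fx$split$test,
                     images = fx$ds$images, roi_provider = fx$prov))
  expect_equal(e3$predictions$ensemble_label, single$pred_label)
  expect_equal(e3$report$accuracy,
               mean(single$pred_label == fx$split$test$label))
})

test_that("a complementary-error panel lifts ensemble accuracy above members", {
  # models 1-2 correct where model 3 errs, and vice versa
  true <- rep(c("A", "B"), each = 6)
  m1 <- m2 <- true
  m3 <- true
  m1[1:2] <- "B"; m2[1:2] <- "B"        # members 1-2 err on 2 instances
  m3[3:8] <- ifelse(true[3:8] == "A", "B", "A")  # member 3 errs elsewhere
  panel <- vote_panel(cbind(m1, m2, m3), classes = c("A", "B"))
  voted <- majority_vote(panel, "lowest_index")
  accs <- c(mean(m1 == true), mean(m2 == true), mean(m3 == true))
  expect_gte(mean(voted == true), max(accs))
})

test_that("report formatting mirrors the per-class table layout", {
  true <- sample(c("AKIEC", "BCC", "MEL"), 30, replace = TRUE)
  rep_ <- classification_report(true, true)
  txt <- format(rep_)
  expect_match(txt, "AKIEC")
  expect_match(txt, "accuracy")
  expect_match(txt, "macro avg")
  expect_match(txt, "weighted avg")
  f <- tempfile(fileext = ".json")
  write_report_json(rep_, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$accuracy, 1.0)
})
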