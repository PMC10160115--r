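test_that("hold-out splits honor fractions and k-fold covers all rows", {
  p <- split_data(100, seed = 1)
  expect_equal(lengths(p), c(train = 70L, test = 20L, validation = 10L))
  expect_equal(sort(unname(unlist(p))), 1:100)

  kf <- split_data(100, seed = 1, mode = "kfold", k = 10)
  expect_equal(lengths(kf$folds), rep(10L, 10), ignore_attr = TRUE)
  expect_equal(sort(unname(unlist(kf$folds))), 1:100)

  expect_identical(split_data(57, seed = 5), split_data(57, seed = 5))
  expect_false(identical(split_data(57, seed = 5), split_data(57, seed = 6)))
  expect_error(split_data(100, fractions = c(0.7, 0.2, 0.2)), "sum to 1")

  # uneven n: partition sizes within one row of the requested fractions
  p2 <- split_data(103, seed = 2)
  expect_equal(sum(lengths(p2)), 103L)
  expect_lte(abs(length(p2$train) - 0.7 * 103), 1)
})

test_that("all four classifiers separate distant Gaussian blobs", {
  d <- gen_labeled_features(400, 10, d = 10, seed = 42)   # 10-sigma separation
  parts <- split_data(400, seed = 1)
  for (m in c("rf", "svm", "dt", "mlp")) {
    dec <- train_classifier(d$x[parts$train, ], d$y[parts$train], model = m,
                            seed = 2,
                            params = list(mlp = mlp_spec(epochs = 20, seed = 2)))
    rep <- evaluate(dec, d$x[parts$test, ], d$y[parts$test])
    expect_gte(rep$accuracy, 0.99)
  }
  expect_error(train_classifier(d$x[1:10, ], rep(1, 10), model = "rf"),
               "single class")
})

test_that("the MLP selects its output head by class count and its loss decays", {
  d3 <- gen_labeled_features(300, 8, d = 6, n_classes = 3, seed = 3)
  dec3 <- train_classifier(d3$x, d3$y, model = "mlp", seed = 1,
                           params = list(mlp = mlp_spec(epochs = 25, seed = 1)))
  expect_false(dec3$fit$binary)                      # softmax head
  expect_equal(ncol(dec3$fit$W[[length(dec3$fit$W)]]), 3L)
  expect_equal(dec3$fit$spec$hidden, c(100L, 90L, 70L, 50L, 30L, 20L, 10L))

  d2 <- gen_labeled_features(300, 8, d = 6, seed = 4)
  dec2 <- train_classifier(d2$x, d2$y, model = "mlp", seed = 1,
                           params = list(mlp = mlp_spec(epochs = 25, seed = 1)))
  expect_true(dec2$fit$binary)                       # single logistic unit
  expect_equal(ncol(dec2$fit$W[[length(dec2$fit$W)]]), 1L)

  # on separable data the training loss decreases towards zero
  lh <- dec2$fit$loss_history
  expect_lt(lh[length(lh)], 0.05)
  expect_lt(lh[length(lh)], lh[1])
  expect_lt(mean(diff(lh) > 0), 0.2)                 # mostly decreasing
})

test_that("evaluation metrics agree with the confusion matrix", {
  # perfect predictions
  r <- evaluate_predictions(c(1, 2, 1, 2), c(1, 2, 1, 2))
  expect_equal(r$accuracy, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 1)

  # constant predictor on balanced binary data: accuracy 0.5, macro recall 0.5
  r2 <- evaluate_predictions(rep(1, 10), rep(c(1, 2), 5), levels = c("1", "2"))
  expect_equal(r2$accuracy, 0.5)
  expect_equal(r2$recall, 0.5)

  # metrics recomputed from the emitted confusion matrix match the report
  set.seed(9)
  pred <- sample(0:2, 60, replace = TRUE)
  truth <- sample(0:2, 60, replace = TRUE)
  r3 <- evaluate_predictions(pred, truth)
  cm <- r3$confusion
  expect_equal(r3$accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(r3$precision, mean(diag(cm) / colSums(cm)))
  expect_equal(r3$recall, mean(diag(cm) / rowSums(cm)))
  expect_true(all(unlist(r3[c("accuracy", "precision", "recall", "f1")]) >= 0))
  expect_true(all(unlist(r3[c("accuracy", "precision", "recall", "f1")]) <= 1))
})

test_that("label shuffling preserves the class histogram and kills the signal", {
  d <- gen_labeled_features(300, 10, d = 8, seed = 10)
  ys <- shuffle_labels(d$y, seed = 3)
  expect_equal(c(table(ys)), c(table(d$y)))
  expect_false(all(ys == d$y))

  accs <- vapply(1:10, function(s) {
    ysh <- shuffle_labels(d$y, seed = s)
    parts <- split_data(300, seed = s)
    dec <- train_classifier(d$x[parts$train, ], ysh[parts$train], "rf",
                            seed = s, params = list(ntree = 50))
    evaluate(dec, d$x[parts$test, ], ysh[parts$test])$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.60)
})

test_that("decoders are reproducible under fixed seeds", {
  d <- gen_labeled_features(200, 6, d = 2, seed = 5)
  for (m in c("rf", "dt", "svm", "mlp")) {
    a <- train_classifier(d$x, d$y, model = m, seed = 11,
                          params = list(mlp = mlp_spec(epochs = 5, seed = 11)))
    b <- train_classifier(d$x, d$y, model = m, seed = 11,
                          params = list(mlp = mlp_spec(epochs = 5, seed = 11)))
    expect_identical(as.character(predict(a, d$x)), as.character(predict(b, d$x)))
  }
})

test_that("subtitle classification recovers lexicon labels from text", {
  cfg <- synth_config(n_sentences = 300, n_volumes = 100, n_subjects = 1,
                      seed = 14)
  ann <- gen_annotations(cfg)
  labs <- map_polarity_case(ann$true_polarity, "binary1")
  rep <- classify_subtitles(ann$sentences, labs, model = "rf", seed = 2)
  majority <- max(table(labs)) / length(labs)
  expect_gt(rep$accuracy, majority + 0.05)   # signal exists by construction

  # shuffled labels fall back to the majority-class neighborhood
  rep_sh <- classify_subtitles(ann$sentences, shuffle_labels(labs, seed = 1),
                               model = "rf", seed = 2)
  expect_lt(rep_sh$accuracy, majority + 0.1)

  # duplicated corpus with identical seed gives identical metrics
  sent2 <- rbind(ann$sentences, ann$sentences)
  class(sent2) <- class(ann$sentences)
  r1 <- classify_subtitles(sent2, rep(labs, 2), model = "rf", seed = 3)
  r2 <- classify_subtitles(sent2, rep(labs, 2), model = "rf", seed = 3)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(unclass(r1$confusion), unclass(r2$confusion))

  expect_error(classify_subtitles(ann$sentences, rep(1L, nrow(ann$sentences))),
               "2 classes")
})

test_that("TF-IDF vectorization weights terms by document frequency", {
  x <- tfidf_vectorize(c("love love story", "story of war"))
  expect_equal(nrow(x), 2L)
  expect_true("love" %in% colnames(x))
  # "story" appears everywhere: lowest idf weight among present terms
  expect_lt(x[1, "story"], x[1, "love"])
  expect_error(tfidf_vectorize(c("", "")), "empty vocabulary")
})
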