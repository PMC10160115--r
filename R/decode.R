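#' Split data into train/test/validation partitions or k folds
#'
#' Hold-out mode shuffles row indices under \code{seed} and cuts them into
#' disjoint partitions of the requested fractions (within one row). K-fold
#' mode returns k disjoint folds jointly covering all rows.
#'
#' @param n Number of rows (or a vector/matrix whose length/rows are used).
#' @param fractions Named or ordered fractions for train, test, validation;
#'   must sum to 1. Default 0.70 / 0.20 / 0.10.
#' @param seed Integer seed for the shuffle.
#' @param mode \code{"holdout"} (default) or \code{"kfold"}.
#' @param k Number of folds in k-fold mode (>= 2); default 10.
#' @return Hold-out: list with integer index vectors \code{train},
#'   \code{test}, \code{validation}. K-fold: list \code{folds} of k index
#'   vectors.
#' @export
split_data <- function(n, fractions = c(train = 0.7, test = 0.2, validation = 0.1),
                       seed = 1L, mode = c("holdout", "kfold"), k = 10L) {
  mode <- match.arg(mode)
  if (length(n) > 1L || is.matrix(n)) n <- NROW(n)
  n <- as.integer(n)
  idx <- with_seed(seed, sample.int(n))
  if (mode == "kfold") {
    if (k < 2L) stopf("k must be >= 2")
    fold_of <- rep(seq_len(k), length.out = n)
    return(list(folds = split(idx, fold_of)))
  }
  if (abs(sum(fractions) - 1) > 1e-8)
    stopf("fractions must sum to 1 (got %g)", sum(fractions))
  n_train <- round(fractions[[1L]] * n)
  n_test <- round(fractions[[2L]] * n)
  if (length(fractions) < 3L) n_test <- n - n_train
  list(
    train      = sort(idx[seq_len(n_train)]),
    test       = sort(idx[n_train + seq_len(n_test)]),
    validation = if (length(fractions) >= 3L && n_train + n_test < n)
      sort(idx[(n_train + n_test + 1L):n]) else integer(0)
  )
}

#' Train a sentiment decoder
#'
#' Fits one of four classifiers to a labeled feature matrix: random forest
#' (\code{"rf"}), RBF-kernel support vector machine (\code{"svm"}),
#' CART decision tree (\code{"dt"}), or the multilayer perceptron
#' (\code{"mlp"}, see \code{\link{mlp_spec}}). The pinned defaults
#' (100 trees; RBF kernel with C = 1; gini splits) are recorded in the
#' returned object so a "default" run is reproducible. Features are
#' standardized to zero mean / unit variance (training statistics) before
#' svm and mlp fitting.
#'
#' @param x Numeric feature matrix (n x p), or a \code{feature_matrix}.
#' @param y Class labels (any atomic type; coerced to factor).
#' @param model One of \code{"rf"}, \code{"svm"}, \code{"dt"}, \code{"mlp"}.
#' @param params Optional list of overrides: \code{ntree} (rf),
#'   \code{cost}, \code{gamma} (svm), \code{cp} (dt), or an
#'   \code{mlp_spec} under \code{mlp}.
#' @param seed Seed for the stochastic fitters (rf, mlp).
#' @param validation Optional list(x, y) monitored during mlp training.
#' @return An object of class \code{stim_decoder} with elements
#'   \code{model}, \code{fit}, \code{levels}, \code{params} (all resolved
#'   values), and the standardization statistics.
#' @export
train_classifier <- function(x, y = NULL, model = c("rf", "svm", "dt", "mlp"),
                             params = list(), seed = 1L, validation = NULL) {
  model <- match.arg(model)
  d <- as_xy(x, y)
  yf <- factor(d$y)
  if (nlevels(yf) < 2L) stopf("training labels contain a single class")
  x <- d$x
  center <- scale_ <- NULL
  if (model %in% c("svm", "mlp")) {
    center <- colMeans(x)
    scale_ <- apply(x, 2L, stats::sd)
    scale_[scale_ == 0] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  }
  resolved <- switch(model,
    rf  = list(ntree = params$ntree %||% 100L),
    svm = list(kernel = "radial", cost = params$cost %||% 1,
               gamma = params$gamma %||% (1 / ncol(x))),
    dt  = list(split = "gini", cp = params$cp %||% 0.01),
    mlp = list(mlp = params$mlp %||% mlp_spec(seed = seed)))
  fit <- switch(model,
    rf = with_seed(seed,
      randomForest::randomForest(x, yf, ntree = resolved$ntree)),
    svm = e1071::svm(x, yf, kernel = "radial", cost = resolved$cost,
                     gamma = resolved$gamma, scale = FALSE),
    dt = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- yf
      rpart::rpart(.y ~ ., df, method = "class",
                   control = rpart::rpart.control(cp = resolved$cp),
                   parms = list(split = "gini"))
    },
    mlp = mlp_fit(x, as.integer(yf), nlevels(yf), resolved$mlp))
  structure(list(model = model, fit = fit, levels = levels(yf),
                 center = center, scale = scale_, params = resolved,
                 seed = seed, n_features = ncol(x)),
            class = "stim_decoder")
}

#' @export
print.stim_decoder <- function(x, ...) {
  cat(sprintf("Sentiment decoder: %s (%d classes: %s; %d features)\n",
              toupper(x$model), length(x$levels),
              paste(x$levels, collapse = ", "), x$n_features))
  cat("resolved parameters:",
      paste(names(x$params), vapply(x$params, function(p)
        if (inherits(p, "mlp_spec")) paste0("[", paste(p$hidden, collapse = ","), "]")
        else paste(format(p), collapse = ","), character(1)),
        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.stim_decoder <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "feature_matrix")) newdata$features else as.matrix(newdata)
  if (!is.null(object$center))
    x <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  if (object$model == "svm") {
    if (type == "prob") stopf("probability output not enabled for svm")
    return(factor(as.character(stats::predict(object$fit, x)),
                  levels = object$levels))
  }
  prob <- switch(object$model,
    rf  = stats::predict(object$fit, x, type = "prob"),
    dt  = stats::predict(object$fit, data.frame(x, check.names = FALSE),
                         type = "prob"),
    mlp = {
      p <- mlp_predict_prob(object$fit, x)
      colnames(p) <- object$levels
      p
    })
  if (type == "prob") return(prob)
  factor(colnames(prob)[max.col(prob, ties.method = "first")],
         levels = object$levels)
}

#' Evaluate a fitted decoder on a test partition
#'
#' Predicts the test rows and reports the confusion matrix, overall
#' accuracy, per-class precision/recall/F1, and their macro averages
#' (unweighted mean over classes; classes absent from both truth and
#' prediction contribute 0 where the ratio is undefined).
#'
#' @param object A \code{stim_decoder}.
#' @param x,y Test features and labels.
#' @return An object of class \code{eval_report}.
#' @export
evaluate <- function(object, x, y = NULL) {
  d <- as_xy(x, y)
  if (length(d$y) == 0L) stopf("empty test set")
  pred <- predict(object, d$x)
  evaluate_predictions(pred, d$y, levels = union(object$levels, unique(as.character(d$y))))
}

#' @rdname evaluate
#' @param pred Predicted labels.
#' @param truth True labels.
#' @param levels Class levels spanning both vectors.
#' @export
evaluate_predictions <- function(pred, truth, levels = NULL) {
  levels <- levels %||% sort(union(unique(as.character(pred)),
                                   unique(as.character(truth))))
  pred <- factor(as.character(pred), levels = levels)
  truth <- factor(as.character(truth), levels = levels)
  cm <- table(truth = truth, predicted = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    confusion = cm,
    accuracy  = sum(tp) / sum(cm),
    per_class = data.frame(class = levels, precision = as.numeric(prec),
                           recall = as.numeric(rec), f1 = as.numeric(f1)),
    precision = mean(prec),
    recall    = mean(rec),
    f1        = mean(f1),
    n         = sum(cm)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d samples\n", x$n))
  cat(sprintf("  accuracy %.3f | macro precision %.3f | recall %.3f | F1 %.3f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  cat("confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' K-fold cross-validation of a decoder
#'
#' @param x,y Features and labels.
#' @param model Classifier (see \code{\link{train_classifier}}).
#' @param k Folds (default 10).
#' @param seed Seed for fold assignment and stochastic fitters.
#' @param params Classifier overrides.
#' @return List: \code{accuracy} (mean over folds), \code{per_fold}
#'   accuracies, \code{report} pooled over folds.
#' @export
cross_validate <- function(x, y = NULL, model = "rf", k = 10L, seed = 1L,
                           params = list()) {
  d <- as_xy(x, y)
  folds <- split_data(length(d$y), seed = seed, mode = "kfold", k = k)$folds
  preds <- character(length(d$y))
  accs <- numeric(length(folds))
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_along(d$y), te)
    dec <- train_classifier(d$x[tr, , drop = FALSE], d$y[tr], model = model,
                            params = params, seed = seed + f)
    p <- predict(dec, d$x[te, , drop = FALSE])
    preds[te] <- as.character(p)
    accs[f] <- mean(as.character(p) == as.character(d$y[te]))
  }
  list(accuracy = mean(accs), per_fold = accs,
       report = evaluate_predictions(preds, d$y))
}

#' Shuffle the label column (chance control)
#'
#' Permutes the labels uniformly at random while leaving the features
#' untouched, so any decoding signal is destroyed but the class histogram
#' is preserved. Decoding accuracy on shuffled labels estimates the
#' empirical chance level.
#'
#' @param x A \code{feature_matrix}, or a label vector.
#' @param seed Integer seed.
#' @return Same type as the input, with labels permuted.
#' @export
shuffle_labels <- function(x, seed = 1L) {
  if (inherits(x, "feature_matrix")) {
    x$labels <- with_seed(seed, sample(x$labels))
    x
  } else with_seed(seed, sample(x))
}

#' Classify subtitles from their own sentiment labels
#'
#' Vectorizes sentence texts with unigram TF-IDF and routes them through
#' split/train/evaluate. Used to validate that analyzer-generated labels
#' are learnable from the text itself before decoding them from fMRI.
#'
#' @param sentences A \code{sentences} data.frame.
#' @param labels Class labels, one per sentence.
#' @param model Classifier.
#' @param fractions Hold-out fractions.
#' @param seed Seed for split and fitters.
#' @param min_df Minimum document frequency of kept vocabulary terms.
#' @return An \code{eval_report} with attribute \code{"decoder"}.
#' @export
classify_subtitles <- function(sentences, labels, model = "rf",
                               fractions = c(train = 0.7, test = 0.2,
                                             validation = 0.1),
                               seed = 1L, min_df = 1L) {
  if (length(unique(labels)) < 2L) stopf("need >= 2 classes to classify")
  xm <- tfidf_vectorize(sentences$text, min_df = min_df)
  parts <- split_data(nrow(xm), fractions = fractions, seed = seed)
  dec <- train_classifier(xm[parts$train, , drop = FALSE],
                          labels[parts$train], model = model, seed = seed)
  rep <- evaluate(dec, xm[parts$test, , drop = FALSE], labels[parts$test])
  attr(rep, "decoder") <- dec
  rep
}

#' Unigram TF-IDF document-term matrix
#'
#' @param texts Character vector of documents.
#' @param min_df Minimum number of documents a term must appear in.
#' @return Dense numeric matrix (documents x vocabulary).
#' @export
tfidf_vectorize <- function(texts, min_df = 1L) {
  toks <- lapply(texts, tokenize)
  vocab <- sort(unique(unlist(toks)))
  if (length(vocab) == 0L) stopf("empty vocabulary: no tokens in any document")
  df_count <- table(factor(unlist(lapply(toks, unique)), levels = vocab))
  vocab <- vocab[df_count >= min_df]
  if (length(vocab) == 0L) stopf("empty vocabulary after min_df filtering")
  n <- length(texts)
  tf <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    tt <- table(factor(toks[[i]], levels = vocab))
    if (length(toks[[i]])) tf[i, ] <- as.numeric(tt) / length(toks[[i]])
  }
  idf <- log(n / pmax(as.numeric(df_count[vocab]), 1))
  sweep(tf, 2L, idf + 1, "*")  # +1 keeps terms present in every document
}
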