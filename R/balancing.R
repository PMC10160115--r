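#' Random oversampling (ROS)
#'
#' Equalizes class counts by replicating minority-class rows: rows of each
#' class below the majority count are drawn uniformly with replacement and
#' appended until all classes match the majority count. Added rows are
#' exact copies; original rows are preserved verbatim and first.
#'
#' @param x Feature matrix (n x p) or \code{feature_matrix}.
#' @param y Class labels (ignored when \code{x} is a \code{feature_matrix}).
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return A list with \code{x}, \code{y} and \code{origin} (index of the
#'   source row in the input for every output row).
#' @export
random_oversample <- function(x, y = NULL, seed = 1L) {
  d <- as_xy(x, y)
  counts <- table(d$y)
  if (length(counts) < 2L) stopf("need at least two classes to balance")
  if (any(counts == 0L)) stopf("a class has zero members")
  target <- max(counts)
  idx <- with_seed(seed, {
    extra <- lapply(names(counts), function(cl) {
      have <- which(d$y == cl)
      need <- target - length(have)
      if (need > 0L) sample(have, need, replace = TRUE) else integer(0)
    })
    c(seq_along(d$y), unlist(extra))
  })
  list(x = d$x[idx, , drop = FALSE], y = d$y[idx], origin = idx)
}

#' SMOTE oversampling
#'
#' Synthetic Minority Over-sampling TEchnique: instead of duplicating
#' minority rows, new samples are interpolated between a minority point and
#' one of its k nearest minority-class neighbors (Euclidean metric,
#' neighbors searched within the minority class only). Each synthetic row
#' is x + u * (z - x) with u uniform on [0, 1], so it lies on the segment
#' joining two minority points. Class counts are equalized to the majority
#' count; original rows are preserved verbatim and first.
#'
#' @param x Feature matrix (n x p) or \code{feature_matrix}.
#' @param y Class labels.
#' @param k_neighbors Number of nearest neighbors considered (default 5,
#'   capped at class size - 1).
#' @param seed Integer seed.
#' @return A list with \code{x}, \code{y}.
#' @export
smote_oversample <- function(x, y = NULL, k_neighbors = 5L, seed = 1L) {
  d <- as_xy(x, y)
  counts <- table(d$y)
  if (length(counts) < 2L) stopf("need at least two classes to balance")
  target <- max(counts)
  minority <- names(counts)[counts < target]
  for (cl in minority) {
    if (counts[[cl]] < 2L)
      stopf("class '%s' has a single member; SMOTE needs >= 2 (use random_oversample)", cl)
  }
  synth <- with_seed(seed, {
    out <- vector("list", length(minority))
    names(out) <- minority
    for (cl in minority) {
      rows <- which(d$y == cl)
      xc <- d$x[rows, , drop = FALSE]
      nc <- nrow(xc)
      k <- min(k_neighbors, nc - 1L)
      dm <- as.matrix(stats::dist(xc))
      nn <- matrix(0L, nc, k)  # self excluded from its own neighbor list
      for (i in seq_len(nc)) {
        ord <- order(dm[i, ])
        nn[i, ] <- ord[ord != i][seq_len(k)]
      }
      need <- target - nc
      base <- sample.int(nc, need, replace = TRUE)
      pick <- vapply(base, function(b) nn[b, sample.int(k, 1L)], integer(1))
      u <- stats::runif(need)
      out[[cl]] <- xc[base, , drop = FALSE] +
        u * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
    }
    out
  })
  x_out <- rbind(d$x, do.call(rbind, synth))
  y_out <- c(d$y, rep(minority, times = vapply(synth, nrow, integer(1))))
  rownames(x_out) <- NULL
  list(x = x_out, y = restore_label_type(y_out, d$y))
}

#' Balance a labeled dataset
#'
#' Dispatcher over the balancing methods: \code{"none"}, \code{"ros"}
#' (random oversampling), \code{"smote"}.
#'
#' @param x,y Features and labels (or a \code{feature_matrix}).
#' @param method One of \code{"none"}, \code{"ros"}, \code{"smote"}.
#' @param k_neighbors SMOTE neighbor count.
#' @param seed Integer seed.
#' @return A list with \code{x}, \code{y}.
#' @export
balance_classes <- function(x, y = NULL, method = c("none", "ros", "smote"),
                            k_neighbors = 5L, seed = 1L) {
  method <- match.arg(method)
  d <- as_xy(x, y)
  switch(method,
    none  = list(x = d$x, y = d$y),
    ros   = random_oversample(d$x, d$y, seed = seed),
    smote = smote_oversample(d$x, d$y, k_neighbors = k_neighbors, seed = seed))
}

as_xy <- function(x, y) {
  if (inherits(x, "feature_matrix")) list(x = x$features, y = x$labels)
  else {
    if (is.null(y)) stopf("labels y are required")
    x <- as.matrix(x)
    if (nrow(x) != length(y)) stopf("x has %d rows but y has %d labels",
                                    nrow(x), length(y))
    list(x = x, y = y)
  }
}

restore_label_type <- function(y_chr, y_orig) {
  if (is.integer(y_orig)) as.integer(y_chr)
  else if (is.numeric(y_orig)) as.numeric(y_chr)
  else if (is.factor(y_orig)) factor(y_chr, levels = levels(y_orig))
  else y_chr
}
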