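#' Multilayer perceptron specification
#'
#' Architecture and training hyperparameters of the decoding MLP: an input
#' layer, rectified-linear hidden layers of widths \code{hidden} (default
#' seven layers, 100-90-70-50-30-20-10), and an output layer that is a
#' single logistic unit with binary cross-entropy loss for two classes or
#' a softmax layer with (sparse) categorical cross-entropy for three or
#' more. Trained with the Adam optimizer on shuffled mini-batches.
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return A list of class \code{mlp_spec}.
#' @export
mlp_spec <- function(hidden = c(100L, 90L, 70L, 50L, 30L, 20L, 10L),
                     epochs = 50L, batch_size = 64L,
                     learning_rate = 1e-3, seed = 1L) {
  if (length(hidden) < 1L) stopf("need at least one hidden layer")
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "mlp_spec")
}

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Fit the MLP. x: numeric matrix (already standardized by the caller),
# y: integer class indices 1..K. Returns weights plus per-epoch mean loss.
mlp_fit <- function(x, y, n_classes, spec = mlp_spec()) {
  stopifnot(is.matrix(x), n_classes >= 2L)
  binary <- n_classes == 2L
  sizes <- c(ncol(x), spec$hidden, if (binary) 1L else n_classes)
  L <- length(sizes) - 1L
  with_seed(spec$seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1L]))
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(v) v * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    n <- nrow(x)
    t_step <- 0L
    loss_history <- numeric(spec$epochs)
    y_bin <- if (binary) as.numeric(y == 2L) else NULL
    for (epoch in seq_len(spec$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = spec$batch_size)
      ep_loss <- 0
      for (s in starts) {
        rows <- perm[s:min(s + spec$batch_size - 1L, n)]
        m <- length(rows)
        a <- vector("list", L + 1L)
        a[[1L]] <- x[rows, , drop = FALSE]
        for (l in seq_len(L - 1L))
          a[[l + 1L]] <- relu(sweep(a[[l]] %*% W[[l]], 2L, b[[l]], "+"))
        zout <- sweep(a[[L]] %*% W[[L]], 2L, b[[L]], "+")
        if (binary) {
          p <- 1 / (1 + exp(-zout))
          p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
          loss <- -mean(y_bin[rows] * log(p) + (1 - y_bin[rows]) * log(1 - p))
          delta <- (p - y_bin[rows]) / m
        } else {
          p <- softmax_rows(zout)
          picked <- p[cbind(seq_len(m), y[rows])]
          loss <- -mean(log(pmax(picked, 1e-12)))
          delta <- p
          delta[cbind(seq_len(m), y[rows])] <-
            delta[cbind(seq_len(m), y[rows])] - 1
          delta <- delta / m
        }
        ep_loss <- ep_loss + loss * m
        t_step <- t_step + 1L
        corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
        for (l in rev(seq_len(L))) {
          gW <- crossprod(a[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          W[[l]] <- W[[l]] - spec$learning_rate * (mW[[l]] / corr1) /
            (sqrt(vW[[l]] / corr2) + eps)
          b[[l]] <- b[[l]] - spec$learning_rate * (mb[[l]] / corr1) /
            (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      loss_history[epoch] <- ep_loss / n
    }
    list(W = W, b = b, binary = binary, n_classes = n_classes,
         spec = spec, loss_history = loss_history)
  })
}

mlp_predict_prob <- function(fit, x) {
  L <- length(fit$W)
  a <- x
  for (l in seq_len(L - 1L))
    a <- relu(sweep(a %*% fit$W[[l]], 2L, fit$b[[l]], "+"))
  z <- sweep(a %*% fit$W[[L]], 2L, fit$b[[L]], "+")
  if (fit$binary) {
    p <- 1 / (1 + exp(-z))
    cbind(1 - p, p)
  } else softmax_rows(z)
}
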