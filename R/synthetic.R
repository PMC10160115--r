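#' Synthetic study configuration
#'
#' Parameters of the synthetic annotation + fMRI generator. Defaults mirror
#' the design of the motivating naturalistic-movie study: 20 subjects,
#' 1744 usable volumes at TR = 1 s, six ROIs of 19/20/20/20/16/16 voxels
#' (111 in total), sentence lengths with mean 6.05 and sd 4.81 words,
#' sentence durations with mean 3.8 and sd 5.5 s (both drawn from truncated
#' log-normals matched to those moments), and the roughly 45/22/33
#' positive/negative/neutral sentence mix observed in that corpus.
#'
#' @param n_subjects Number of subjects.
#' @param n_volumes fMRI volumes per subject.
#' @param tr Repetition time (s).
#' @param roi_voxels Named integer vector: voxels per ROI.
#' @param n_sentences Sentences to generate; default fills the scan window.
#' @param length_mean,length_sd Sentence length moments (words).
#' @param duration_mean,duration_sd Sentence duration moments (s).
#' @param class_probs Named probabilities for positive/negative/neutral
#'   sentences.
#' @param gap_prob,gap_mean Probability of a silence gap after a sentence
#'   and its mean length (s, exponential).
#' @param d Class effect size: per-voxel class mean shift in units of the
#'   noise sd.
#' @param sigma Noise standard deviation.
#' @param noise \code{"iid"} Gaussian or \code{"ar1"} with coefficient
#'   \code{rho}.
#' @param rho AR(1) coefficient, 0 <= rho < 1.
#' @param seed Integer seed.
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(n_subjects = 20L, n_volumes = 1744L, tr = 1,
                         roi_voxels = c(L_ACC = 19L, R_STG = 20L,
                                        L_cere = 20L, L_medFG = 20L,
                                        R_IFG = 16L, L_ch = 16L),
                         n_sentences = NULL,
                         length_mean = 6.05, length_sd = 4.81,
                         duration_mean = 3.8, duration_sd = 5.5,
                         class_probs = c(positive = 0.45, negative = 0.22,
                                         neutral = 0.33),
                         gap_prob = 0.3, gap_mean = 2,
                         d = 1, sigma = 1,
                         noise = c("iid", "ar1"), rho = 0,
                         seed = 1L) {
  noise <- match.arg(noise)
  if (n_subjects < 1L || n_volumes < 1L || any(roi_voxels < 1L))
    stopf("counts must be positive")
  if (tr <= 0) stopf("tr must be > 0")
  if (length_mean <= 0 || length_sd < 0 || duration_mean <= 0 || duration_sd < 0)
    stopf("distribution parameters must be positive")
  if (d < 0) stopf("effect size d must be >= 0")
  if (rho < 0 || rho >= 1) stopf("rho must be in [0, 1)")
  if (abs(sum(class_probs) - 1) > 1e-8 || any(class_probs < 0))
    stopf("class_probs must be non-negative and sum to 1")
  n_sentences <- n_sentences %||%
    as.integer(ceiling(n_volumes * tr / (duration_mean + gap_prob * gap_mean)))
  structure(list(
    n_subjects = as.integer(n_subjects), n_volumes = as.integer(n_volumes),
    tr = tr, roi_voxels = roi_voxels, n_sentences = as.integer(n_sentences),
    length_mean = length_mean, length_sd = length_sd,
    duration_mean = duration_mean, duration_sd = duration_sd,
    class_probs = class_probs, gap_prob = gap_prob, gap_mean = gap_mean,
    d = d, sigma = sigma, noise = noise, rho = rho,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# log-normal parameters matched to a target mean/sd
lnorm_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# rejection-sample a truncated log-normal (x >= lower)
rlnorm_trunc <- function(n, m, s, lower) {
  p <- lnorm_params(m, s)
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, p["meanlog"], p["sdlog"])
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}

# word pools: sentiment words from the demo lexicon, filler words outside it
synth_vocab <- function(lexicon = read_lexicon()) {
  filler <- c("the", "a", "an", "and", "then", "he", "she", "it", "they",
              "was", "were", "said", "went", "to", "with", "on", "in",
              "story", "of", "boy", "meets", "girl", "town", "door", "road",
              "walked", "looked", "turned", "came", "house", "morning",
              "again", "slowly", "around", "while", "under", "over")
  filler <- setdiff(filler, c(names(lexicon$valence), lexicon$negations))
  list(positive = names(lexicon$valence)[lexicon$valence > 0],
       negative = names(lexicon$valence)[lexicon$valence < 0],
       filler = filler)
}

#' Generate a synthetic word-annotation stream with known polarities
#'
#' Draws sentences with configured length/duration distributions and a
#' known polarity each, realises them as words from the demo-lexicon
#' vocabulary (sentiment words of the matching sign plus out-of-lexicon
#' filler; no negations), spaces them with silence gaps, and emits the
#' word-level annotation rows the parser ingests. By construction, scoring
#' the generated sentences with the internal lexicon analyzer reproduces
#' the stored true polarities.
#'
#' @param config A \code{synth_config}.
#' @param path Optional CSV path to write (columns word, onset, offset,
#'   sentence_end); written deterministically for a given seed.
#' @param t_first Onset of the first sentence (s).
#' @return A list: \code{words} (a \code{word_annotations} data.frame),
#'   \code{sentences} (via \code{\link{build_sentences}}),
#'   \code{true_polarity} (integer -1/0/+1 per sentence), and \code{path}
#'   if written.
#' @export
gen_annotations <- function(config, path = NULL, t_first = 0) {
  vocab <- synth_vocab()
  with_seed(config$seed, {
    n <- config$n_sentences
    lens <- pmax(1L, as.integer(round(
      rlnorm_trunc(n, config$length_mean, config$length_sd, 0.5))))
    durs <- round(rlnorm_trunc(n, config$duration_mean, config$duration_sd, 1), 3)
    pol_class <- sample(names(config$class_probs), n, replace = TRUE,
                        prob = config$class_probs)
    polarity <- c(positive = 1L, negative = -1L, neutral = 0L)[pol_class]
    gaps <- ifelse(stats::runif(n) < config$gap_prob,
                   round(stats::rexp(n, 1 / config$gap_mean), 3), 0)
    rows <- vector("list", n)
    t <- t_first
    for (i in seq_len(n)) {
      L <- lens[i]
      n_sent_words <- min(L, 1L + stats::rbinom(1L, max(L - 1L, 0L), 0.25))
      toks <- sample(vocab$filler, L, replace = TRUE)
      if (polarity[i] != 0L) {
        pool <- if (polarity[i] > 0L) vocab$positive else vocab$negative
        where <- sample.int(L, n_sent_words)
        toks[where] <- sample(pool, n_sent_words, replace = TRUE)
      }
      bounds <- round(t + durs[i] * (0:L) / L, 3)
      bounds[L + 1L] <- round(t + durs[i], 3)
      rows[[i]] <- data.frame(
        token = toks,
        onset = bounds[seq_len(L)],
        offset = bounds[seq_len(L) + 1L],
        is_sentence_end = c(rep(FALSE, L - 1L), TRUE),
        stringsAsFactors = FALSE)
      t <- t + durs[i] + gaps[i]
    }
    words <- do.call(rbind, rows)
    class(words) <- c("word_annotations", "data.frame")
    out <- list(words = words, sentences = build_sentences(words),
                true_polarity = unname(polarity))
    if (!is.null(path)) {
      df <- data.frame(word = words$token,
                       onset = sprintf("%.3f", words$onset),
                       offset = sprintf("%.3f", words$offset),
                       sentence_end = ifelse(words$is_sentence_end, "END", ""),
                       stringsAsFactors = FALSE)
      utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
      out$path <- path
    }
    out
  })
}

# class mean patterns: one fixed random pattern per class, scaled so the
# per-voxel shift is d * sigma
class_patterns <- function(classes, n_voxels, d, sigma) {
  mu <- matrix(stats::rnorm(length(classes) * n_voxels), length(classes),
               n_voxels, dimnames = list(as.character(classes), NULL))
  d * sigma * mu
}

#' Generate synthetic per-ROI fMRI time series for labeled volumes
#'
#' For every subject and ROI, the signal of voxel v at volume t is
#' mu[class(t), v] + noise, where the class patterns mu are drawn once per
#' dataset from a standard normal and scaled by \code{d * sigma}
#' (\code{d} = class effect size in noise-sd units), and the noise is iid
#' Gaussian or a stationary AR(1) process with coefficient \code{rho}.
#' With d = 0 the signals carry no label information.
#'
#' @param config A \code{synth_config}.
#' @param tr_labels A \code{tr_labels} object or a plain label vector, one
#'   label per volume (length must be \code{config$n_volumes}).
#' @return A list of class \code{synth_fmri}: \code{subjects} (per subject:
#'   \code{rois} named list of n_volumes x n_voxels matrices and
#'   \code{labels}), \code{patterns} (class x voxel matrix), ready for
#'   \code{\link{assemble_feature_matrix}}.
#' @export
gen_fmri <- function(config, tr_labels) {
  labels <- if (inherits(tr_labels, "tr_labels")) tr_labels$labels else tr_labels
  if (length(labels) != config$n_volumes)
    stopf("need one label per volume (%d labels, %d volumes)",
          length(labels), config$n_volumes)
  classes <- sort(unique(labels))
  V <- sum(config$roi_voxels)
  with_seed(config$seed, {
    mu <- class_patterns(classes, V, config$d, config$sigma)
    row_of <- match(as.character(labels), rownames(mu))
    col_split <- rep(seq_along(config$roi_voxels), times = config$roi_voxels)
    subjects <- lapply(seq_len(config$n_subjects), function(s) {
      sig <- mu[row_of, , drop = FALSE] +
        ar1_noise(config$n_volumes, V, config$sigma,
                  if (config$noise == "ar1") config$rho else 0)
      rois <- lapply(seq_along(config$roi_voxels), function(r)
        sig[, col_split == r, drop = FALSE])
      names(rois) <- names(config$roi_voxels)
      list(rois = rois, labels = labels)
    })
    structure(list(subjects = subjects, patterns = mu, config = config),
              class = "synth_fmri")
  })
}

# stationary AR(1) noise matrix, marginal sd = sigma; rho = 0 gives iid
ar1_noise <- function(n_t, n_v, sigma, rho) {
  innov <- matrix(stats::rnorm(n_t * n_v), n_t, n_v)
  if (rho == 0) return(sigma * innov)
  x <- matrix(0, n_t, n_v)
  x[1L, ] <- innov[1L, ]
  scale <- sqrt(1 - rho^2)
  for (t in 2:n_t) x[t, ] <- rho * x[t - 1L, ] + scale * innov[t, ]
  sigma * x
}

#' Balanced labeled Gaussian feature data
#'
#' The core of the synthetic fMRI model without the annotation plumbing:
#' n rows of p features whose class-conditional means are fixed random
#' patterns scaled by \code{d * sigma}, plus iid Gaussian noise. Classes
#' are assigned in (near-)equal counts. Used for classifier benchmarking
#' and chance-level controls.
#'
#' @param n Rows. @param p Features. @param d Effect size (noise-sd units).
#' @param n_classes Number of classes (labels 0..n_classes-1).
#' @param sigma Noise sd. @param seed Integer seed.
#' @return List with \code{x} (n x p matrix) and \code{y} (integer labels).
#' @export
gen_labeled_features <- function(n, p, d, n_classes = 2L, sigma = 1,
                                 seed = 1L) {
  with_seed(seed, {
    y <- sample(rep(seq_len(n_classes) - 1L, length.out = n))
    mu <- class_patterns(seq_len(n_classes) - 1L, p, d, sigma)
    x <- mu[y + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n * p, sd = sigma), n, p)
    list(x = x, y = y)
  })
}

#' Accuracy as a function of synthetic effect size
#'
#' Runs the full synthetic pipeline (annotations -> lexicon labels -> TR
#' alignment -> fMRI generation -> feature matrix -> split/train/evaluate)
#' for each effect size in \code{d_grid} and each model, and reports test
#' accuracy next to the empirical chance level (majority-class share of
#' the test labels). On this ground-truth data accuracy should rise from
#' chance at d = 0 towards 1 as d grows.
#'
#' @param d_grid Numeric vector of effect sizes.
#' @param config A \code{synth_config} (its \code{d} is overridden).
#' @param models Character vector of classifiers.
#' @param case Polarity case for the labels.
#' @param seed Integer seed.
#' @return A data.frame: d, model, accuracy, chance, n_test.
#' @export
parameter_recovery_experiment <- function(d_grid, config = synth_config(),
                                          models = "rf", case = "binary1",
                                          seed = 1L) {
  rows <- list()
  for (d in d_grid) {
    cfg <- config
    cfg$d <- d
    cfg$seed <- as.integer(seed + round(1000 * d))
    ann <- gen_annotations(cfg)
    labs <- map_polarity_case(ann$true_polarity, case)
    # the generated stream intentionally overfills the window; clipping the
    # spill-over is expected, not a data problem
    trl <- suppressWarnings(
      assign_tr_labels(ann$sentences, labs, tr = cfg$tr, t_start = 0,
                       t_end = cfg$n_volumes * cfg$tr))
    fm <- assemble_feature_matrix(lapply(gen_fmri(cfg, trl)$subjects, identity))
    parts <- split_data(nrow(fm$features), seed = seed)
    for (m in models) {
      dec <- train_classifier(fm$features[parts$train, , drop = FALSE],
                              fm$labels[parts$train], model = m, seed = seed)
      rep <- evaluate(dec, fm$features[parts$test, , drop = FALSE],
                      fm$labels[parts$test])
      chance <- max(table(fm$labels[parts$test])) / length(parts$test)
      rows[[length(rows) + 1L]] <- data.frame(
        d = d, model = m, accuracy = rep$accuracy, chance = chance,
        n_test = length(parts$test))
    }
  }
  do.call(rbind, rows)
}

#' Embed synthetic ROI signals into a 4D NIfTI-like image
#'
#' Places each ROI's voxel time series at the sphere voxel locations of a
#' given grid so that \code{\link{extract_roi_timeseries}} recovers them;
#' the remaining voxels hold iid background noise.
#'
#' @param roi_data Named list of n_volumes x n_voxels matrices.
#' @param rois List of \code{roi_spec}, same names/order.
#' @param dim Grid dimensions. @param affine 4x4 voxel-to-mm affine.
#' @param sigma Background noise sd. @param seed Integer seed.
#' @return An \code{RNifti} image (4D) with the chosen affine.
#' @export
embed_rois_in_image <- function(roi_data, rois, dim, affine, sigma = 1,
                                seed = 1L) {
  n_t <- nrow(roi_data[[1L]])
  img <- with_seed(seed,
    array(stats::rnorm(prod(dim) * n_t, sd = sigma), c(dim, n_t)))
  for (r in seq_along(rois)) {
    vox <- sphere_voxel_indices(dim, affine, rois[[r]]$seed_mm,
                                rois[[r]]$radius_mm, rois[[r]]$name)
    if (nrow(vox) != ncol(roi_data[[r]]))
      stopf("ROI %s: %d sphere voxels but %d signal columns",
            rois[[r]]$name, nrow(vox), ncol(roi_data[[r]]))
    for (v in seq_len(nrow(vox)))
      img[vox[v, 1] + 1L, vox[v, 2] + 1L, vox[v, 3] + 1L, ] <- roi_data[[r]][, v]
  }
  im <- RNifti::asNifti(img)
  RNifti::sform(im) <- structure(affine, code = 4L)
  im
}
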