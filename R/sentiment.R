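#' Load a sentiment lexicon
#'
#' A lexicon maps lower-case tokens to signed valences. The scoring rule
#' additionally needs a set of negation words, a negation scaling factor,
#' and the normalization constant \code{alpha} of the compound score
#' (see \code{\link{score_sentence}}).
#'
#' @param path Two-column TSV (token, valence) with header. \code{NULL}
#'   (default) loads the small demo lexicon bundled with the package.
#' @param negations Character vector of negation words.
#' @param negation_factor Multiplier applied to a lexicon word's valence
#'   when a negation precedes it within the negation window. The default
#'   \code{-0.74} flips and damps the valence, the convention of the
#'   lexicon-analyzer family this scorer follows.
#' @param alpha Normalization constant of the compound score; must be > 0.
#' @return A list of class \code{sentiment_lexicon}.
#' @export
read_lexicon <- function(path = NULL,
                         negations = default_negations(),
                         negation_factor = -0.74,
                         alpha = 15) {
  if (is.null(path))
    path <- system.file("extdata", "demo_lexicon.tsv", package = "stimdecode",
                        mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("token", "valence") %in% names(df)))
    stopf("lexicon %s must have columns 'token' and 'valence'", path)
  if (anyNA(df$valence) || any(!is.finite(df$valence)))
    stopf("lexicon %s contains non-finite valences", path)
  if (!is.numeric(alpha) || alpha <= 0) stopf("alpha must be > 0")
  valence <- as.numeric(df$valence)
  names(valence) <- tolower(df$token)
  structure(list(valence = valence,
                 negations = tolower(negations),
                 negation_factor = negation_factor,
                 alpha = alpha),
            class = "sentiment_lexicon")
}

#' @rdname read_lexicon
#' @export
default_negations <- function() {
  c("not", "no", "never", "neither", "nor", "nothing", "nobody", "none",
    "cannot", "cant", "dont", "doesnt", "didnt", "wont", "isnt", "wasnt",
    "arent", "werent", "hardly", "without")
}

tokenize <- function(text) {
  toks <- tolower(unlist(strsplit(text, "[[:space:]]+")))
  toks <- gsub("[^a-z0-9']", "", toks)
  toks[nzchar(toks)]
}

#' Compound sentiment score of a sentence
#'
#' Tokenizes the sentence, looks each lower-cased token up in the lexicon,
#' flips/damps a matched word's valence by the negation factor when a
#' negation word occurs among the \code{window} preceding tokens, sums the
#' contributions into a raw valence sum S, and normalizes it to the
#' compound score S / sqrt(S^2 + alpha), which is bounded in (-1, +1) and
#' shares the sign of S. Out-of-lexicon tokens contribute zero; an empty or
#' fully unknown sentence scores exactly 0.
#'
#' @param sentence A character string, a character vector of tokens, or a
#'   single row of a \code{sentences} data.frame.
#' @param lexicon A \code{sentiment_lexicon} (see \code{\link{read_lexicon}}).
#' @param window Number of preceding tokens scanned for a negation word.
#' @return A list of class \code{sentiment_score}: \code{compound} in
#'   [-1, 1] and \code{raw_sum}.
#' @examples
#' lex <- read_lexicon()
#' score_sentence("did not love it", lex)
#' @export
score_sentence <- function(sentence, lexicon, window = 3L) {
  toks <- if (is.character(sentence) && length(sentence) > 1L) tolower(sentence)
          else if (is.character(sentence)) tokenize(sentence)
          else if (is.data.frame(sentence)) tokenize(sentence$text[1L])
          else stopf("sentence must be text or a sentences row")
  s <- 0
  for (i in seq_along(toks)) {
    v <- lexicon$valence[toks[i]]
    if (is.na(v)) next
    lo <- max(1L, i - window)
    if (i > 1L && any(toks[lo:(i - 1L)] %in% lexicon$negations))
      v <- v * lexicon$negation_factor
    s <- s + v
  }
  compound <- if (s == 0) 0 else s / sqrt(s^2 + lexicon$alpha)
  structure(list(compound = unname(compound), raw_sum = unname(s)),
            class = "sentiment_score")
}

#' Sentence polarity from a compound score
#'
#' The sign of the compound score: positive scores are positive sentiment
#' (+1), negative scores negative (-1), and exactly zero is neutral (0).
#'
#' @param score A \code{sentiment_score} or a numeric compound value.
#' @return One of -1, 0, +1 (integer).
#' @export
polarity_of <- function(score) {
  x <- if (inherits(score, "sentiment_score")) score$compound else score
  as.integer(sign(x))
}

#' Map a polarity onto a class scheme
#'
#' Three class schemes are supported for the neutral polarity: merged into
#' the positive class (\code{"binary1"}), merged into the negative class
#' (\code{"binary2"}), or kept as its own class (\code{"three"}). Class
#' labels are encoded as integers: neutral = 0, negative = 1, positive = 2.
#'
#' @param polarity Integer vector with values in \{-1, 0, +1\}.
#' @param case One of \code{"binary1"}, \code{"binary2"}, \code{"three"}.
#' @return Integer class labels (0 = neutral, 1 = negative, 2 = positive).
#' @export
map_polarity_case <- function(polarity, case = c("binary1", "binary2", "three")) {
  case <- match.arg(case)
  if (!all(polarity %in% c(-1L, 0L, 1L)))
    stopf("polarities must be in {-1, 0, +1}")
  out <- integer(length(polarity))
  out[polarity == 1L]  <- 2L
  out[polarity == -1L] <- 1L
  out[polarity == 0L]  <- switch(case, binary1 = 2L, binary2 = 1L, three = 0L)
  out
}

#' Similarity between two polarity vectors
#'
#' Counts positions where two per-sentence polarity (or class) vectors
#' agree, and the agreeing fraction. Used to compare label vectors produced
#' by different sentiment analyzers over the same sentence corpus.
#'
#' @param v1,v2 Vectors of equal length n >= 1.
#' @return A list with \code{matches} (count) and \code{fraction}.
#' @export
similarity_score <- function(v1, v2) {
  if (length(v1) != length(v2))
    stopf("polarity vectors differ in length (%d vs %d)", length(v1), length(v2))
  if (length(v1) == 0L) stopf("polarity vectors must be non-empty")
  m <- sum(v1 == v2)
  list(matches = as.integer(m), fraction = m / length(v1))
}

# --- analyzer registry -------------------------------------------------------

.analyzers <- new.env(parent = emptyenv())

#' Register and run sentiment analyzers
#'
#' Third-party sentence-level sentiment analyzers can be plugged in as
#' adapters returning polarities in the package's \{-1, 0, +1\} encoding.
#' The built-in \code{"lexicon"} analyzer (compound score + sign) is always
#' registered; no external analyzer is required by any other operation.
#'
#' @param id Analyzer identifier.
#' @param fun Function taking a \code{sentences} data.frame and returning an
#'   integer polarity vector in \{-1, 0, +1\}.
#' @export
register_analyzer <- function(id, fun) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fun))
  assign(id, fun, envir = .analyzers)
  invisible(id)
}

#' @rdname register_analyzer
#' @param sentences A \code{sentences} data.frame.
#' @param ... Passed to the analyzer function.
#' @return \code{run_analyzer}: integer polarity vector, one per sentence.
#' @export
run_analyzer <- function(sentences, id, ...) {
  if (!exists(id, envir = .analyzers, inherits = FALSE))
    stopf(paste0("sentiment analyzer '%s' is not available; it is an ",
                 "optional dependency (registered analyzers: %s)"),
          id, paste(ls(.analyzers), collapse = ", "))
  pol <- get(id, envir = .analyzers)(sentences, ...)
  pol <- as.integer(pol)
  if (!all(pol %in% c(-1L, 0L, 1L)))
    stopf("analyzer '%s' returned polarities outside {-1, 0, +1}", id)
  pol
}

#' Score a whole corpus with the built-in lexicon analyzer
#'
#' @param sentences A \code{sentences} data.frame.
#' @param lexicon A \code{sentiment_lexicon}; default: bundled demo lexicon.
#' @param window Negation window (tokens).
#' @return A data.frame: sentence_index, compound, polarity, and the class
#'   labels under all three polarity cases.
#' @export
label_sentences <- function(sentences, lexicon = read_lexicon(), window = 3L) {
  compound <- vapply(seq_len(nrow(sentences)), function(i)
    score_sentence(sentences$text[i], lexicon, window)$compound, numeric(1))
  polarity <- as.integer(sign(compound))
  data.frame(
    sentence_index = seq_len(nrow(sentences)),
    compound       = compound,
    polarity       = polarity,
    class_binary1  = map_polarity_case(polarity, "binary1"),
    class_binary2  = map_polarity_case(polarity, "binary2"),
    class_three    = map_polarity_case(polarity, "three")
  )
}

# built-in analyzer: compound score sign under the demo lexicon (or one
# supplied via `lexicon =`)
.analyzers$lexicon <- function(sentences, lexicon = read_lexicon(), window = 3L) {
  vapply(seq_len(nrow(sentences)), function(i)
    polarity_of(score_sentence(sentences$text[i], lexicon, window)), integer(1))
}
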