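#' Parse a word-annotation file
#'
#' Reads a CSV/TSV table of stimulus words with onset/offset timings, as
#' distributed with naturalistic-movie fMRI datasets: one row per spoken
#' word, timed in seconds relative to the start of the movie, optionally
#' carrying a sentence-boundary marker.
#'
#' @param path Path to a delimited text file with a header row.
#' @param columns Named list mapping the canonical fields to the file's
#'   column names: \code{word}, \code{onset}, \code{offset}, and optionally
#'   \code{sentence_end} (a column whose non-empty / TRUE / "END" values
#'   flag the last word of a sentence).
#' @param sep Field separator; \code{NULL} (default) infers "," for
#'   \code{.csv} and tab otherwise.
#'
#' @return A \code{data.frame} of class \code{word_annotations} with columns
#'   \code{token} (character), \code{onset}, \code{offset} (seconds), and
#'   \code{is_sentence_end} (logical), in file order.
#'
#' @details Offsets must be \code{>=} their onsets (a violation is an error
#'   naming the row). Onsets are expected to be non-decreasing in file
#'   order; real annotation files contain timing jitter, so a decrease
#'   raises a warning rather than an error.
#'
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("word,onset,offset,end", "story,61.0,61.4,", "of,61.5,61.7,END"), f)
#' parse_word_annotations(f, columns = list(word = "word", onset = "onset",
#'   offset = "offset", sentence_end = "end"))
#' @export
parse_word_annotations <- function(path,
                                   columns = list(word = "word",
                                                  onset = "onset",
                                                  offset = "offset",
                                                  sentence_end = "sentence_end"),
                                   sep = NULL) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", colClasses = NA,
                          blank.lines.skip = TRUE)
  for (field in c("word", "onset", "offset")) {
    col <- columns[[field]]
    if (is.null(col) || !col %in% names(df))
      stopf("annotation file %s lacks required column '%s' (field '%s')",
            path, col %||% "<unmapped>", field)
  }
  if (nrow(df) == 0L) return(empty_word_annotations())
  ann <- data.frame(
    token  = as.character(df[[columns$word]]),
    onset  = as.numeric(df[[columns$onset]]),
    offset = as.numeric(df[[columns$offset]]),
    stringsAsFactors = FALSE
  )
  ec <- columns$sentence_end
  if (!is.null(ec) && ec %in% names(df)) {
    v <- df[[ec]]
    ann$is_sentence_end <- if (is.logical(v)) !is.na(v) & v
      else !is.na(v) & trimws(as.character(v)) != "" &
           toupper(trimws(as.character(v))) != "FALSE" &
           trimws(as.character(v)) != "0"
  } else {
    ann$is_sentence_end <- FALSE
  }
  if (anyNA(ann$onset) || anyNA(ann$offset))
    stopf("annotation file %s: non-numeric onset/offset values", path)
  bad <- which(ann$offset < ann$onset)
  if (length(bad))
    stopf("annotation file %s: offset < onset at row %d (%.3f < %.3f)",
          path, bad[1L], ann$offset[bad[1L]], ann$onset[bad[1L]])
  if (any(diff(ann$onset) < 0))
    warnf("annotation file %s: onsets are not non-decreasing (timing jitter?)", path)
  class(ann) <- c("word_annotations", "data.frame")
  ann
}

empty_word_annotations <- function() {
  ann <- data.frame(token = character(), onset = numeric(),
                    offset = numeric(), is_sentence_end = logical(),
                    stringsAsFactors = FALSE)
  class(ann) <- c("word_annotations", "data.frame")
  ann
}

#' Reconstruct sentences from word annotations
#'
#' Partitions a word stream into sentences at sentence-end flags or,
#' alternatively, at tokens bearing terminal punctuation (. ? !). Trailing
#' words with no end marker form a final sentence. A sentence's onset is its
#' first word's onset, its offset the last word's offset, and its duration
#' the difference (inter-word gaps inside a sentence are counted).
#'
#' @param words A \code{word_annotations} data.frame (see
#'   \code{\link{parse_word_annotations}}).
#' @param boundary \code{"flag"} to split at \code{is_sentence_end} markers
#'   (default), \code{"punctuation"} to split after tokens ending in
#'   \code{.}, \code{?} or \code{!}.
#'
#' @return A \code{data.frame} of class \code{sentences} with columns
#'   \code{text}, \code{onset}, \code{offset}, \code{duration},
#'   \code{n_words}, plus a list column \code{words} holding each
#'   sentence's word rows.
#' @export
build_sentences <- function(words, boundary = c("flag", "punctuation")) {
  boundary <- match.arg(boundary)
  if (nrow(words) == 0L) stopf("no words to build sentences from")
  ends <- switch(boundary,
    flag        = words$is_sentence_end,
    punctuation = grepl("[.?!]$", words$token))
  ends[length(ends)] <- TRUE  # trailing words close the final sentence
  sentence_id <- rev(cumsum(rev(ends)))
  sentence_id <- max(sentence_id) - sentence_id + 1L
  idx <- split(seq_len(nrow(words)), sentence_id)
  rows <- lapply(idx, function(i) {
    w <- words[i, , drop = FALSE]
    data.frame(
      text     = paste(sub("[.?!]+$", "", w$token), collapse = " "),
      onset    = w$onset[1L],
      offset   = w$offset[nrow(w)],
      duration = w$offset[nrow(w)] - w$onset[1L],
      n_words  = nrow(w),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$words <- lapply(idx, function(i) words[i, , drop = FALSE])
  class(out) <- c("sentences", "data.frame")
  out
}

#' Summary statistics for a sentence corpus
#'
#' Computes the counts and the smallest/longest/mean/standard deviation of
#' sentence length (in words) and sentence duration (in seconds) used to
#' characterise a subtitle corpus.
#'
#' @param sentences A \code{sentences} data.frame from
#'   \code{\link{build_sentences}}.
#' @param sd_type \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"}.
#' @return A list of class \code{subtitle_stats} with elements
#'   \code{n_sentences}, \code{n_words}, \code{n_seconds}, and for both
#'   \code{length} (words) and \code{duration} (seconds): min, max, mean, sd.
#' @export
subtitle_stats <- function(sentences, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (nrow(sentences) == 0L) stopf("need at least one sentence")
  sdev <- function(x) {
    if (length(x) == 1L) return(0)
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  moments <- function(x) list(min = min(x), max = max(x),
                              mean = mean(x), sd = sdev(x))
  out <- list(
    n_sentences = nrow(sentences),
    n_words     = sum(sentences$n_words),
    n_seconds   = sum(sentences$duration),
    length      = moments(sentences$n_words),
    duration    = moments(sentences$duration)
  )
  class(out) <- "subtitle_stats"
  out
}

#' @export
print.subtitle_stats <- function(x, ...) {
  cat(sprintf("Subtitle corpus: %d sentences, %d words, %.1f s covered\n",
              x$n_sentences, x$n_words, x$n_seconds))
  cat(sprintf("  length   (words): min %g, max %g, mean %.2f, sd %.2f\n",
              x$length$min, x$length$max, x$length$mean, x$length$sd))
  cat(sprintf("  duration (s):     min %g, max %g, mean %.2f, sd %.2f\n",
              x$duration$min, x$duration$max, x$duration$mean, x$duration$sd))
  invisible(x)
}

#' Write sentences to a TSV file
#'
#' @param sentences A \code{sentences} data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sentences_tsv <- function(sentences, path) {
  utils::write.table(
    sentences[, c("text", "onset", "offset", "duration", "n_words")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Flatten sentences back to a word-annotation table (round-trip support).
sentences_to_words <- function(sentences) {
  out <- do.call(rbind, lapply(sentences$words, function(w) {
    w$is_sentence_end <- FALSE
    w$is_sentence_end[nrow(w)] <- TRUE
    w
  }))
  rownames(out) <- NULL
  class(out) <- c("word_annotations", "data.frame")
  out
}
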