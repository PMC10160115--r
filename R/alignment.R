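#' Assign sentence labels to fMRI volumes (TR grid)
#'
#' Converts per-sentence class labels into one label per fMRI volume. The
#' timeline [t_start, t_end) is divided into volumes of length \code{tr}
#' (0-based, half-open [t, t+tr) windows). Each sentence, in time order,
#' claims \code{ceiling(duration / tr)} volumes starting at the volume
#' containing its onset — so a 8.3 s sentence at TR = 1 s labels nine
#' volumes, not eight. When the ceiling extends a sentence into the next
#' one's onset, the later sentence overwrites (last-writer-wins). Volumes
#' falling in inter-sentence silence gaps carry the previous sentence's
#' label; volumes before the first sentence take the first sentence's label
#' (or neutral, per \code{initial_policy}).
#'
#' @param sentences A \code{sentences} data.frame (needs \code{onset},
#'   \code{duration}), sorted by onset.
#' @param labels Vector of class labels, one per sentence.
#' @param tr Repetition time in seconds (> 0); default 1.
#' @param t_start,t_end Window of the scan covered, in seconds;
#'   \code{t_end > t_start}.
#' @param gap_policy \code{"carry_previous"} (default) or \code{"neutral"}.
#' @param initial_policy \code{"backfill"} (first sentence's label, default)
#'   or \code{"neutral"}.
#' @param neutral_label Label used by the \code{"neutral"} policies.
#' @return A list of class \code{tr_labels}: \code{labels} (length
#'   \code{n_volumes}), \code{n_volumes}, \code{tr}, \code{t_start}.
#' @export
assign_tr_labels <- function(sentences, labels, tr = 1, t_start = 0,
                             t_end = NULL,
                             gap_policy = c("carry_previous", "neutral"),
                             initial_policy = c("backfill", "neutral"),
                             neutral_label = 0L) {
  gap_policy <- match.arg(gap_policy)
  initial_policy <- match.arg(initial_policy)
  if (tr <= 0) stopf("tr must be > 0")
  if (nrow(sentences) != length(labels))
    stopf("need one label per sentence (%d sentences, %d labels)",
          nrow(sentences), length(labels))
  if (is.null(t_end)) t_end <- max(sentences$onset + sentences$duration)
  if (t_end <= t_start) stopf("t_end must exceed t_start")
  n <- as.integer(floor((t_end - t_start) / tr + 1e-9))
  if (n < 1L) stopf("window shorter than one TR")
  ord <- order(sentences$onset)
  out <- rep(NA_integer_, n)
  mode(out) <- mode(labels)
  any_in <- FALSE
  n_clipped <- 0L
  for (s in ord) {
    onset <- sentences$onset[s]
    dur <- sentences$duration[s]
    v0 <- as.integer(floor((onset - t_start) / tr + 1e-9))
    nv <- max(1L, as.integer(ceiling(dur / tr - 1e-9)))
    v1 <- v0 + nv - 1L
    if (v1 < 0L || v0 >= n) {
      n_clipped <- n_clipped + 1L
      next
    }
    if (v0 < 0L || v1 >= n) n_clipped <- n_clipped + 1L
    out[max(v0, 0L):min(v1, n - 1L) + 1L] <- labels[s]
    any_in <- TRUE
  }
  if (n_clipped > 0L)
    warnf("%d sentence(s) extend outside [%g, %g) and were clipped",
          n_clipped, t_start, t_end)
  if (!any_in) stopf("no sentence falls inside [%g, %g)", t_start, t_end)
  first_lab <- which(!is.na(out))[1L]
  if (first_lab > 1L) {
    fill <- if (initial_policy == "backfill") out[first_lab] else neutral_label
    out[seq_len(first_lab - 1L)] <- fill
  }
  if (gap_policy == "carry_previous") {
    for (i in seq_len(n)[-1L]) if (is.na(out[i])) out[i] <- out[i - 1L]
  } else {
    out[is.na(out)] <- neutral_label
  }
  structure(list(labels = out, n_volumes = n, tr = tr, t_start = t_start),
            class = "tr_labels")
}

#' @export
print.tr_labels <- function(x, ...) {
  cat(sprintf("TR label series: %d volumes at TR = %g s (t0 = %g s)\n",
              x$n_volumes, x$tr, x$t_start))
  print(table(x$labels))
  invisible(x)
}

#' Discard lead-in volumes
#'
#' Drops the volumes covering an un-annotated lead-in at the start of a
#' scan (e.g. opening credits before the first subtitle) and returns the
#' remaining volume count: n_total - floor(lead_in / tr).
#'
#' @param n_total_volumes Total acquired volumes.
#' @param lead_in Lead-in duration in seconds (>= 0).
#' @param tr Repetition time in seconds.
#' @return Remaining volume count (integer).
#' @examples
#' discard_lead_in(1805, 61, 1)  # 1744
#' @export
discard_lead_in <- function(n_total_volumes, lead_in, tr = 1) {
  if (lead_in < 0) stopf("lead_in must be >= 0")
  if (tr <= 0) stopf("tr must be > 0")
  drop <- as.integer(floor(lead_in / tr + 1e-9))
  if (drop > n_total_volumes)
    stopf("lead-in (%g s = %d volumes) exceeds the %d acquired volumes",
          lead_in, drop, n_total_volumes)
  as.integer(n_total_volumes) - drop
}

#' Write a TR label series to TSV
#'
#' @param tr_labels A \code{tr_labels} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tr_labels_tsv <- function(tr_labels, path) {
  df <- data.frame(
    volume_index = seq_len(tr_labels$n_volumes) - 1L,
    t_start      = tr_labels$t_start + (seq_len(tr_labels$n_volumes) - 1L) * tr_labels$tr,
    label        = tr_labels$labels
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
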