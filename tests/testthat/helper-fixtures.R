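# fixtures built in code; no data files

write_annotation_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("word,onset,offset,sentence_end", rows), path)
  path
}

# a deterministic word table: sentence lengths and durations as given
make_words <- function(lengths, durations, gap = 0.5, t0 = 0) {
  rows <- list()
  t <- t0
  for (i in seq_along(lengths)) {
    L <- lengths[i]
    b <- t + durations[i] * (0:L) / L
    rows[[i]] <- data.frame(
      token = paste0("w", i, "_", seq_len(L)),
      onset = b[seq_len(L)], offset = b[seq_len(L) + 1],
      is_sentence_end = c(rep(FALSE, L - 1), TRUE))
    t <- t + durations[i] + gap
  }
  out <- do.call(rbind, rows)
  class(out) <- c("word_annotations", "data.frame")
  out
}

# brute-force sphere membership over the whole grid (independent oracle)
sphere_bruteforce <- function(dim, affine, seed_mm, radius_mm) {
  g <- expand.grid(i = 0:(dim[1] - 1), j = 0:(dim[2] - 1), k = 0:(dim[3] - 1))
  keep <- logical(nrow(g))
  for (r in seq_len(nrow(g))) {
    mm <- affine %*% c(g$i[r], g$j[r], g$k[r], 1)
    keep[r] <- sqrt(sum((mm[1:3] - seed_mm)^2)) <= radius_mm + 1e-9
  }
  m <- as.matrix(g[keep, , drop = FALSE])
  m[order(m[, 3], m[, 2], m[, 1]), , drop = FALSE]
}

# shortest distance from point p to segment [a, b]
dist_to_segment <- function(p, a, b) {
  ab <- b - a
  t <- if (sum(ab^2) == 0) 0 else
    max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
  sqrt(sum((p - (a + t * ab))^2))
}
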