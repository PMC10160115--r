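#' Write / read per-subject, per-ROI time-series TSV files
#'
#' The TSV bypass for the decoding half of the pipeline: instead of 4D
#' NIfTI images, a directory of plain files \code{<subject>.<roi>.tsv},
#' each an n_volumes x n_voxels matrix with a header row, is accepted.
#'
#' @param subjects List as in \code{\link{gen_fmri}}'s \code{subjects}
#'   element (each with a named \code{rois} list of matrices).
#' @param dir Directory (created if missing).
#' @param subject_ids Optional ids; default 1..n zero-padded.
#' @return \code{dir}, invisibly (write); nested list (read).
#' @export
write_roi_timeseries_dir <- function(subjects, dir, subject_ids = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subject_ids <- subject_ids %||% sprintf("sub%02d", seq_along(subjects))
  for (s in seq_along(subjects)) {
    for (r in names(subjects[[s]]$rois)) {
      path <- file.path(dir, paste0(subject_ids[s], ".", r, ".tsv"))
      utils::write.table(subjects[[s]]$rois[[r]], path, sep = "\t",
                         row.names = FALSE, col.names = TRUE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_roi_timeseries_dir
#' @export
read_roi_timeseries_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$")
  if (!length(files)) stopf("no .tsv time-series files in %s", dir)
  parts <- regmatches(files, regexec("^(.+?)\\.(.+)\\.tsv$", files))
  if (any(lengths(parts) != 3L)) stopf("time-series files must be named <subject>.<roi>.tsv")
  sub <- vapply(parts, `[`, character(1), 2L)
  roi <- vapply(parts, `[`, character(1), 3L)
  out <- lapply(unique(sub), function(s) {
    rois <- lapply(files[sub == s], function(f)
      as.matrix(utils::read.table(file.path(dir, f), header = TRUE, sep = "\t")))
    names(rois) <- roi[sub == s]
    list(rois = rois[sort(names(rois))])
  })
  names(out) <- unique(sub)
  out
}

#' Run the full decoding pipeline
#'
#' Orchestrates annotations -> sentiment labels -> TR alignment -> feature
#' matrix -> class balancing -> classification as one configured run,
#' writing every intermediate artifact plus a manifest (file MD5 hashes,
#' resolved seeds and parameters) to the output directory.
#'
#' The input is either synthetic (a \code{\link{synth_config}}, the
#' default) or real: a word-annotation file plus a directory of
#' pre-extracted per-ROI time-series TSVs
#' (see \code{\link{read_roi_timeseries_dir}}).
#'
#' @param config A list (or YAML path) with entries:
#'   \describe{
#'     \item{synth}{a \code{synth_config}, or a list of its arguments, for
#'       synthetic runs;}
#'     \item{annotations, columns, timeseries_dir, lexicon}{real-data
#'       inputs (annotation file + column map, time-series directory,
#'       optional lexicon TSV);}
#'     \item{case}{polarity case: "binary1" (default), "binary2", "three";}
#'     \item{tr, t_start, t_end, gap_policy, initial_policy}{alignment
#'       parameters;}
#'     \item{balance}{"none" (default), "ros", or "smote"; k_neighbors;}
#'     \item{model}{"rf" (default), "svm", "dt", "mlp";}
#'     \item{eval}{"holdout" (default) or "kfold"; k; fractions;}
#'     \item{shuffle}{TRUE to permute labels first (chance control);}
#'     \item{seeds}{named seeds: split_seed, balance_seed, model_seed,
#'       shuffle_seed.}
#'   }
#' @param out_dir Output directory for artifacts.
#' @return A list of class \code{pipeline_run}: \code{report}
#'   (\code{eval_report} or CV result), \code{manifest}, \code{paths}.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("stimrun")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- utils::modifyList(list(split_seed = 1L, balance_seed = 1L,
                                  model_seed = 1L, shuffle_seed = 1L),
                             config$seeds %||% list())
  case <- config$case %||% "binary1"
  model <- config$model %||% "rf"
  balance <- config$balance %||% "none"
  eval_mode <- config$eval %||% "holdout"
  paths <- list()
  log_line <- function(...) message(sprintf(...))

  synthetic <- !is.null(config$synth) || is.null(config$annotations)
  if (synthetic) {
    cfg <- config$synth %||% synth_config()
    if (!inherits(cfg, "synth_config")) cfg <- do.call(synth_config, cfg)
    log_line("stage annotations: generating %d synthetic sentences", cfg$n_sentences)
    ann <- gen_annotations(cfg, path = file.path(out_dir, "annotations.csv"))
    words <- ann$words
    sentences <- ann$sentences
    tr <- cfg$tr
    t_start <- config$t_start %||% 0
    t_end <- config$t_end %||% (cfg$n_volumes * cfg$tr)
  } else {
    log_line("stage annotations: parsing %s", config$annotations)
    words <- if (is.null(config$columns))
      parse_word_annotations(config$annotations)
    else parse_word_annotations(config$annotations, columns = config$columns)
    sentences <- build_sentences(words)
    tr <- config$tr %||% 1
    t_start <- config$t_start %||% 0
    t_end <- config$t_end
  }
  if (synthetic) paths$annotations <- file.path(out_dir, "annotations.csv")
  paths$sentences <- write_sentences_tsv(sentences, file.path(out_dir, "sentences.tsv"))

  log_line("stage sentiment: lexicon compound scoring, case %s", case)
  lexicon <- if (!is.null(config$lexicon)) read_lexicon(config$lexicon) else read_lexicon()
  labs <- label_sentences(sentences, lexicon)
  utils::write.table(labs, file.path(out_dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths$labels <- file.path(out_dir, "labels.tsv")
  class_col <- switch(case, binary1 = "class_binary1",
                      binary2 = "class_binary2", three = "class_three")

  log_line("stage alignment: TR = %g s over [%g, %s) s", tr, t_start,
           format(t_end %||% NA))
  align <- function() assign_tr_labels(
    sentences, labs[[class_col]], tr = tr, t_start = t_start, t_end = t_end,
    gap_policy = config$gap_policy %||% "carry_previous",
    initial_policy = config$initial_policy %||% "backfill")
  # synthetic streams overfill the scan window by design; clipping is expected
  trl <- if (synthetic) suppressWarnings(align()) else align()
  paths$tr_labels <- write_tr_labels_tsv(trl, file.path(out_dir, "tr_labels.tsv"))

  log_line("stage features: assembling the labeled matrix")
  if (synthetic) {
    fmri <- gen_fmri(cfg, trl)
    subjects <- fmri$subjects
  } else {
    subjects <- read_roi_timeseries_dir(config$timeseries_dir)
    subjects <- lapply(subjects, function(s) { s$labels <- trl$labels; s })
  }
  fm <- assemble_feature_matrix(subjects)
  paths$feature_matrix <- write_feature_matrix_tsv(
    fm, file.path(out_dir, "feature_matrix.tsv"))

  if (isTRUE(config$shuffle)) {
    log_line("stage shuffle: permuting the label column (chance control)")
    fm <- shuffle_labels(fm, seed = seeds$shuffle_seed)
  }

  log_line("stage balancing: %s", balance)
  bal <- balance_classes(fm$features, fm$labels, method = balance,
                         k_neighbors = config$k_neighbors %||% 5L,
                         seed = seeds$balance_seed)

  log_line("stage decode: %s (%s)", model, eval_mode)
  if (eval_mode == "kfold") {
    cv <- cross_validate(bal$x, bal$y, model = model,
                         k = config$k %||% 10L, seed = seeds$model_seed)
    report <- cv$report
    report$accuracy_kfold <- cv$accuracy
    report$per_fold <- cv$per_fold
  } else {
    parts <- split_data(nrow(bal$x),
                        fractions = unlist(config$fractions %||%
                          c(train = 0.7, test = 0.2, validation = 0.1)),
                        seed = seeds$split_seed)
    dec <- train_classifier(bal$x[parts$train, , drop = FALSE],
                            bal$y[parts$train], model = model,
                            seed = seeds$model_seed)
    report <- evaluate(dec, bal$x[parts$test, , drop = FALSE],
                       bal$y[parts$test])
  }
  report_json <- list(
    accuracy = report$accuracy, precision = report$precision,
    recall = report$recall, f1 = report$f1,
    per_class = report$per_class,
    confusion = as.data.frame.matrix(report$confusion),
    model = model, case = case, balance = balance, eval = eval_mode,
    seeds = seeds)
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  paths$report <- file.path(out_dir, "report.json")
  utils::write.table(as.data.frame.matrix(report$confusion),
                     file.path(out_dir, "confusion.tsv"), sep = "\t",
                     quote = FALSE)
  manifest <- list(
    seeds = seeds,
    parameters = list(case = case, model = model, balance = balance,
                      eval = eval_mode, tr = tr, t_start = t_start),
    feature_matrix_dim = c(nrow(fm$features), ncol(fm$features) + 1L),
    files = as.list(tools::md5sum(unlist(paths[file.exists(unlist(paths))])))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$manifest <- file.path(out_dir, "manifest.json")
  structure(list(report = report, manifest = manifest, paths = paths,
                 feature_matrix = fm),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run: %s / %s / balance=%s | feature matrix %d x %d\n",
              x$manifest$parameters$model, x$manifest$parameters$case,
              x$manifest$parameters$balance,
              x$manifest$feature_matrix_dim[1], x$manifest$feature_matrix_dim[2]))
  print(x$report)
  invisible(x)
}
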