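test_that("generated annotations parse back and match their stored polarities", {
  cfg <- synth_config(n_sentences = 120, n_volumes = 200, n_subjects = 1,
                      seed = 5)
  path <- tempfile(fileext = ".csv")
  ann <- gen_annotations(cfg, path = path)
  expect_equal(nrow(ann$sentences), 120L)

  # round trip through the parser reproduces the sentence partition
  parsed <- parse_word_annotations(path)
  sent <- build_sentences(parsed)
  expect_equal(nrow(sent), 120L)
  expect_equal(sent$text, ann$sentences$text)
  expect_equal(sent$duration, ann$sentences$duration, tolerance = 1e-6)

  # internal lexicon scorer recovers the stored ground-truth polarity
  scored <- run_analyzer(sent, "lexicon")
  expect_equal(scored, ann$true_polarity)

  # single-word positive sentences score positive by construction
  cfg_pos <- synth_config(n_sentences = 20, n_volumes = 50, n_subjects = 1,
                          length_mean = 1, length_sd = 0.01,
                          class_probs = c(positive = 1, negative = 0,
                                          neutral = 0), seed = 2)
  ann_pos <- gen_annotations(cfg_pos)
  expect_true(all(ann_pos$true_polarity == 1L))
  expect_equal(run_analyzer(ann_pos$sentences, "lexicon"),
               ann_pos$true_polarity)
})

test_that("annotation generation is deterministic and moment-matched", {
  cfg <- synth_config(n_sentences = 1000, n_volumes = 100, n_subjects = 1,
                      seed = 77)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  gen_annotations(cfg, path = f1)
  gen_annotations(cfg, path = f2)
  expect_identical(readLines(f1), readLines(f2))     # byte-identical

  st <- subtitle_stats(gen_annotations(cfg)$sentences)
  # sample moments of sentence length within 3 standard errors of the target
  se_mean <- cfg$length_sd / sqrt(1000)
  expect_lt(abs(st$length$mean - cfg$length_mean), 3 * se_mean + 0.25)
  expect_lt(abs(st$length$sd - cfg$length_sd), 0.75)
  expect_gte(st$length$min, 1)
  expect_gte(st$duration$min, 1)
})

test_that("synthetic fMRI carries exactly the configured class signal", {
  cfg <- synth_config(n_subjects = 3, n_volumes = 150, n_sentences = 40,
                      d = 5, seed = 9)
  labels <- rep_len(c(1L, 2L), cfg$n_volumes)
  fm <- gen_fmri(cfg, labels)
  expect_equal(length(fm$subjects), 3L)
  expect_equal(vapply(fm$subjects[[1]]$rois, ncol, integer(1)),
               cfg$roi_voxels)
  expect_equal(nrow(fm$subjects[[1]]$rois[[1]]), 150L)

  # d = 5: a random forest decodes the labels almost perfectly
  mat <- assemble_feature_matrix(fm$subjects)
  parts <- split_data(nrow(mat$features), seed = 1)
  dec <- train_classifier(mat$features[parts$train, ], mat$labels[parts$train],
                          "rf", seed = 1)
  acc5 <- evaluate(dec, mat$features[parts$test, ], mat$labels[parts$test])$accuracy
  expect_gte(acc5, 0.95)

  # d = 0: no label information, accuracy near chance
  cfg0 <- synth_config(n_subjects = 3, n_volumes = 150, n_sentences = 40,
                       d = 0, seed = 9)
  mat0 <- assemble_feature_matrix(gen_fmri(cfg0, labels)$subjects)
  dec0 <- train_classifier(mat0$features[parts$train, ], mat0$labels[parts$train],
                           "rf", seed = 1)
  acc0 <- evaluate(dec0, mat0$features[parts$test, ], mat0$labels[parts$test])$accuracy
  expect_lt(abs(acc0 - 0.5), 0.12)
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
  cfg <- synth_config(n_subjects = 1, n_volumes = 1744, n_sentences = 10,
                      d = 0, noise = "ar1", rho = 0.5, seed = 13)
  fm <- gen_fmri(cfg, rep(1L, 1744))
  x <- fm$subjects[[1]]$rois[[1]][, 1]   # signal-free voxel (d = 0)
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.5), 0.05)

  # iid noise: autocorrelation near zero
  cfg_iid <- synth_config(n_subjects = 1, n_volumes = 1744, n_sentences = 10,
                          d = 0, seed = 13)
  xi <- gen_fmri(cfg_iid, rep(1L, 1744))$subjects[[1]]$rois[[1]][, 1]
  expect_lt(abs(stats::cor(xi[-1], xi[-length(xi)])), 0.06)
})

test_that("end-to-end labels survive the annotation -> scoring -> alignment path", {
  # non-overlapping sentences with integer durations: alignment is lossless
  cfg <- synth_config(n_sentences = 25, n_volumes = 400, n_subjects = 1,
                      seed = 21)
  ann <- gen_annotations(cfg)
  sent <- ann$sentences
  sent$onset <- as.numeric(seq(0, by = 4, length.out = 25))
  sent$duration <- rep(3, 25)
  sent$offset <- sent$onset + sent$duration
  labs <- map_polarity_case(ann$true_polarity, "three")
  trl <- assign_tr_labels(sent, labs, tr = 1, t_start = 0, t_end = 100)
  claimed <- trl$labels[rep(seq(0, 96, by = 4), each = 3) +
                          rep(1:3, 25)]
  expect_equal(claimed, rep(labs, each = 3))
})

test_that("ROI time series round-trip through the TSV bypass", {
  cfg <- synth_config(n_subjects = 2, n_volumes = 30, n_sentences = 8,
                      d = 2, seed = 6)
  fm <- gen_fmri(cfg, rep_len(c(1L, 2L), 30))
  dir <- tempfile("tsdir")
  write_roi_timeseries_dir(fm$subjects, dir)
  back <- read_roi_timeseries_dir(dir)
  expect_equal(length(back), 2L)
  expect_equal(sort(names(back[[1]]$rois)), sort(names(cfg$roi_voxels)))
  expect_equal(unname(back[["sub01"]]$rois[["L_ACC"]]),
               unname(fm$subjects[[1]]$rois[["L_ACC"]]), tolerance = 1e-6)
})

test_that("synthetic ROI signals embedded in a 4D image are recoverable", {
  rois <- list(roi_spec("A", c(6, 6, 6), 3), roi_spec("B", c(-6, -6, -6), 3))
  aff <- diag(4); aff[1:3, 4] <- c(-12, -12, -12); aff[1:3, 1:3] <- diag(c(3, 3, 3))
  dim <- c(9L, 9L, 9L)
  nvox <- vapply(rois, function(r)
    nrow(sphere_voxel_indices(dim, aff, r$seed_mm, r$radius_mm)), integer(1))
  set.seed(2)
  dat <- lapply(nvox, function(v) matrix(rnorm(12 * v), 12, v))
  names(dat) <- c("A", "B")
  img <- embed_rois_in_image(dat, rois, dim, aff, seed = 3)
  for (r in 1:2) {
    ts <- extract_roi_timeseries(img, rois[[r]])
    expect_equal(unname(ts$data), unname(dat[[r]]), tolerance = 1e-6)
  }
})

test_that("decoding accuracy rises monotonically with the synthetic effect size", {
  cfg <- synth_config(n_subjects = 2, n_volumes = 250, n_sentences = 70,
                      roi_voxels = c(A = 10L, B = 10L), seed = 3)
  tab <- parameter_recovery_experiment(c(0, 1, 5), cfg, models = "rf",
                                       seed = 4)
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$accuracy) >= -0.02))     # non-decreasing up to noise
  expect_lt(abs(tab$accuracy[1] - tab$chance[1]), 0.12)
  expect_gte(tab$accuracy[3], 0.95)
  # reproducible under a fixed seed
  tab2 <- parameter_recovery_experiment(c(0, 1, 5), cfg, models = "rf",
                                        seed = 4)
  expect_identical(tab, tab2)
})
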