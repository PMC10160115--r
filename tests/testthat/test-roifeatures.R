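diag_affine <- function(spacing = c(3.2, 3.2, 3.2), origin = c(0, 0, 0)) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(spacing)
  a[1:3, 4] <- origin
  a
}

test_that("sphere membership matches an exhaustive distance-scan oracle", {
  dim <- c(8L, 8L, 8L)
  aff <- diag_affine()
  # radius 0 at a voxel center: exactly that voxel
  seed <- c(3.2 * 4, 3.2 * 4, 3.2 * 4)
  expect_equal(nrow(sphere_voxel_indices(dim, aff, seed, 0)), 1L)
  # radius below half-spacing: still one voxel
  expect_equal(nrow(sphere_voxel_indices(dim, aff, seed, 1)), 1L)
  # the study's 5 mm sphere on a 3.2 mm grid, against brute force
  got <- sphere_voxel_indices(dim, aff, seed, 5)
  expect_equal(unname(got), unname(sphere_bruteforce(dim, aff, seed, 5)))

  # random affines (rotation + anisotropic spacing + translation), seeds, radii
  set.seed(31)
  for (i in 1:100) {
    dim <- sample(4:7, 3, replace = TRUE)
    theta <- runif(1, 0, pi)
    rot <- diag(3)
    rot[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    aff <- diag(4)
    aff[1:3, 1:3] <- rot %*% diag(runif(3, 2, 4))
    aff[1:3, 4] <- runif(3, -10, 10)
    seed <- as.vector(aff %*% c(runif(3, 0, dim - 1), 1))[1:3] + runif(3, -2, 2)
    radius <- runif(1, 1, 8)
    brute <- sphere_bruteforce(dim, aff, seed, radius)
    if (nrow(brute) == 0) {
      expect_error(sphere_voxel_indices(dim, aff, seed, radius), "no voxel")
    } else {
      expect_equal(unname(sphere_voxel_indices(dim, aff, seed, radius)),
                   unname(brute))
    }
  }
})

test_that("sphere voxel count is non-decreasing in radius and errors off-grid", {
  dim <- c(10L, 10L, 10L)
  aff <- diag_affine(c(3, 3, 3))
  seed <- c(15, 15, 15)
  counts <- vapply(c(0, 2, 4, 6, 9, 12),
                   function(r) nrow(sphere_voxel_indices(dim, aff, seed, r)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(sphere_voxel_indices(dim, aff, c(500, 500, 500), 5, "L_ACC"),
               "L_ACC")
})

test_that("ROI extraction returns voxel columns in scan order", {
  dim <- c(5L, 5L, 5L)
  img <- array(0, c(dim, 7))
  img[2, 3, 4, ] <- 0:6                    # constructed ramp signal
  vox <- matrix(c(1L, 2L, 3L), 1)          # 0-based index of that voxel
  ts <- extract_roi_timeseries(img, vox)
  expect_equal(dim(ts$data), c(7L, 1L))
  expect_equal(ts$data[, 1], 0:6)

  # two-voxel ROI -> (n_volumes, 2); values equal direct array indexing
  set.seed(8)
  img2 <- array(rnorm(prod(dim) * 6), c(dim, 6))
  vox2 <- rbind(c(0L, 0L, 0L), c(4L, 4L, 4L))
  ts2 <- extract_roi_timeseries(img2, vox2)
  expect_equal(dim(ts2$data), c(6L, 2L))
  expect_equal(ts2$data[, 1], img2[1, 1, 1, ])
  expect_equal(ts2$data[, 2], img2[5, 5, 5, ])

  expect_error(extract_roi_timeseries(array(0, c(4, 4, 4)), vox), "4D")
})

test_that("roi_spec spheres resolve through the affine during extraction", {
  dim <- c(9L, 9L, 9L)
  aff <- diag_affine(c(2, 2, 2), origin = c(-8, -8, -8))
  roi <- roi_spec("mid", seed_mm = c(0, 0, 0), radius_mm = 3)
  img <- array(rnorm(prod(dim) * 5), c(dim, 5))
  ts <- extract_roi_timeseries(img, roi, affine = aff)
  oracle <- sphere_bruteforce(dim, aff, c(0, 0, 0), 3)
  expect_equal(ncol(ts$data), nrow(oracle))
  for (v in seq_len(nrow(oracle)))
    expect_equal(ts$data[, v],
                 img[oracle[v, 1] + 1, oracle[v, 2] + 1, oracle[v, 3] + 1, ])
})

test_that("feature matrix stacks subjects and keeps every value recoverable", {
  n_vol <- 10L
  mk_subject <- function(s) {
    rois <- list(A = matrix(s * 100 + seq_len(n_vol * 3), n_vol, 3),
                 B = matrix(s * 1000 + seq_len(n_vol * 2), n_vol, 2))
    list(rois = rois, labels = rep_len(c(1L, 2L), n_vol))
  }
  fm <- assemble_feature_matrix(lapply(1:2, mk_subject))
  expect_equal(dim(fm$features), c(20L, 5L))
  expect_equal(fm$roi_columns, c("A", "A", "A", "B", "B"))
  expect_equal(fm$labels, rep(rep_len(c(1L, 2L), n_vol), 2))
  # bijection: row = (subject-1)*n_vol + volume, col = roi voxel
  for (s in 1:2) for (t in c(1L, 7L)) for (v in 1:3)
    expect_equal(fm$features[(s - 1L) * n_vol + t, v],
                 mk_subject(s)$rois$A[t, v])

  # 1 subject, 10 volumes, 3 voxels -> 10 x 4 including label column
  fm1 <- assemble_feature_matrix(list(list(
    rois = list(A = matrix(0, 10, 3)), labels = rep(1L, 10))))
  expect_equal(dim(fm1$features) + c(0L, 1L), c(10L, 4L))

  bad <- lapply(1:2, mk_subject)
  bad[[2]]$rois$B <- bad[[2]]$rois$B[, 1, drop = FALSE]
  expect_error(assemble_feature_matrix(bad), "ROI B")
  bad2 <- lapply(1:2, mk_subject)
  bad2[[2]]$labels <- bad2[[2]]$labels[1:5]
  expect_error(assemble_feature_matrix(bad2), "labels")
})

test_that("feature matrices round-trip through TSV", {
  fm <- assemble_feature_matrix(list(list(
    rois = list(A = matrix(rnorm(12), 4, 3), B = matrix(rnorm(8), 4, 2)),
    labels = c(0L, 1L, 2L, 1L))))
  path <- tempfile(fileext = ".tsv")
  write_feature_matrix_tsv(fm, path)
  back <- read_feature_matrix_tsv(path)
  expect_equal(unname(back$features), unname(fm$features), tolerance = 1e-12)
  expect_equal(back$labels, fm$labels)
  expect_equal(back$roi_columns, fm$roi_columns)
})

test_that("the reference ROI table carries the six regions totalling 111 voxels", {
  tab <- reference_roi_table()
  expect_equal(sum(tab$n_voxels), 111L)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$radius_mm == 5))
})
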