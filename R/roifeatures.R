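#' Spherical ROI specification
#'
#' @param name ROI name (e.g. \code{"L_ACC"}).
#' @param seed_mm Numeric length-3 MNI seed coordinate in millimeters.
#' @param radius_mm Sphere radius in millimeters (>= 0); default 5.
#' @return A list of class \code{roi_spec}.
#' @export
roi_spec <- function(name, seed_mm, radius_mm = 5) {
  stopifnot(length(seed_mm) == 3L, is.numeric(seed_mm))
  if (radius_mm < 0) stopf("radius must be >= 0 (ROI %s)", name)
  structure(list(name = as.character(name), seed_mm = as.numeric(seed_mm),
                 radius_mm = as.numeric(radius_mm)), class = "roi_spec")
}

#' Read ROI specifications from YAML
#'
#' Expects a YAML list of entries with fields \code{name}, \code{seed}
#' (3 mm coordinates) and optional \code{radius} (default 5 mm).
#'
#' @param path YAML file path.
#' @return List of \code{roi_spec}.
#' @export
read_roi_specs <- function(path) {
  spec <- yaml::read_yaml(path)
  rois <- spec$rois %||% spec
  lapply(rois, function(r) {
    if (is.null(r$seed)) stopf("ROI '%s' lacks a seed coordinate", r$name %||% "?")
    roi_spec(r$name, unlist(r$seed), r$radius %||% 5)
  })
}

#' Voxels inside a sphere around an MNI seed
#'
#' Finds all voxels of an image grid whose center lies within
#' \code{radius_mm} of the seed (Euclidean distance in millimeters,
#' boundary inclusive). Voxel centers are mapped to millimeters through the
#' image affine; the seed is used exactly as given, with no rounding.
#'
#' @param dim Integer length-3 grid dimensions.
#' @param affine 4x4 matrix mapping 0-based voxel indices (i, j, k, 1) to
#'   millimeter coordinates.
#' @param seed_mm Length-3 seed coordinate (mm).
#' @param radius_mm Sphere radius (mm).
#' @param roi_name Name used in error messages.
#' @return Integer matrix (n_voxels x 3) of 0-based voxel indices, columns
#'   \code{i, j, k}, ordered by k, then j, then i.
#' @export
sphere_voxel_indices <- function(dim, affine, seed_mm, radius_mm,
                                 roi_name = "ROI") {
  stopifnot(length(dim) == 3L, all(dim >= 1L),
            is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  inv <- solve(affine)
  center_vox <- (inv %*% c(seed_mm, 1))[1:3]
  # exact voxel-space bounding box of the mm-sphere: |v_i - c_i| <= r * ||row_i(inv)||
  half <- radius_mm * sqrt(rowSums(inv[1:3, 1:3]^2))
  lo <- pmax(0L, as.integer(floor(center_vox - half - 1e-9)))
  hi <- pmin(dim - 1L, as.integer(ceiling(center_vox + half + 1e-9)))
  if (any(lo > hi))
    stopf("ROI %s: seed (%.1f, %.1f, %.1f) mm lies outside the image grid",
          roi_name, seed_mm[1], seed_mm[2], seed_mm[3])
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  mm <- cbind(cand, 1) %*% t(affine)
  d2 <- (mm[, 1] - seed_mm[1])^2 + (mm[, 2] - seed_mm[2])^2 + (mm[, 3] - seed_mm[3])^2
  keep <- d2 <= radius_mm^2 + 1e-9
  if (!any(keep))
    stopf("ROI %s: no voxel center within %g mm of seed (%.1f, %.1f, %.1f)",
          roi_name, radius_mm, seed_mm[1], seed_mm[2], seed_mm[3])
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out[, 3], out[, 2], out[, 1]), , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- list(NULL, c("i", "j", "k"))
  out
}

#' Extract an ROI's voxel time series from a 4D image
#'
#' @param image_4d A 4D array or an RNifti image (x, y, z, t); or a path to
#'   a NIfTI file.
#' @param roi A \code{roi_spec}, or an integer matrix of 0-based voxel
#'   indices as returned by \code{\link{sphere_voxel_indices}}.
#' @param affine 4x4 voxel-to-mm affine; taken from the NIfTI header when
#'   \code{image_4d} is an RNifti image or file and \code{affine} is NULL.
#' @return A list of class \code{voxel_timeseries}: \code{data}
#'   (n_volumes x n_voxels matrix, scan order), \code{voxels} (index
#'   matrix), \code{roi} (name).
#' @export
extract_roi_timeseries <- function(image_4d, roi, affine = NULL) {
  if (is.character(image_4d)) image_4d <- RNifti::readNifti(image_4d)
  if (is.null(affine) && inherits(image_4d, "niftiImage")) {
    affine <- structure(RNifti::xform(image_4d), class = "matrix")
    attributes(affine) <- list(dim = c(4L, 4L))
  }
  img <- unclass(image_4d)
  if (length(dim(img)) != 4L)
    stopf("expected a 4D image, got %d dimensions", length(dim(img)))
  d <- dim(img)
  if (inherits(roi, "roi_spec")) {
    if (is.null(affine)) stopf("an affine is required to resolve ROI '%s'", roi$name)
    vox <- sphere_voxel_indices(d[1:3], affine, roi$seed_mm, roi$radius_mm, roi$name)
    name <- roi$name
  } else {
    vox <- roi
    name <- attr(roi, "roi_name") %||% "ROI"
  }
  if (any(vox < 0L) || any(vox[, 1] >= d[1]) || any(vox[, 2] >= d[2]) ||
      any(vox[, 3] >= d[3]))
    stopf("ROI %s: voxel indices out of image bounds", name)
  n_t <- d[4L]
  mat <- matrix(NA_real_, n_t, nrow(vox))
  for (v in seq_len(nrow(vox)))
    mat[, v] <- img[vox[v, 1] + 1L, vox[v, 2] + 1L, vox[v, 3] + 1L, ]
  if (anyNA(mat)) stopf("ROI %s: missing values in extracted time series", name)
  structure(list(data = mat, voxels = vox, roi = name),
            class = "voxel_timeseries")
}

#' Assemble the labeled multi-subject feature matrix
#'
#' Stacks per-subject ROI time series into the decoding matrix: one row per
#' (subject, volume), columns are the concatenated ROI voxels in declared
#' ROI order, and the final column holds the per-volume class labels. With
#' 20 subjects, 1744 volumes and 111 ROI voxels this is the 34,880 x 112
#' matrix fed to the classifiers.
#'
#' @param per_subject A list, one element per subject, each a list with
#'   \code{rois} (named list of \code{voxel_timeseries} or plain
#'   n_volumes x n_voxels matrices, same ROIs/order for all subjects) and
#'   \code{labels} (vector or \code{tr_labels} of length n_volumes).
#' @param subject_ids Optional subject identifiers (default: list names or
#'   1..n).
#' @return A list of class \code{feature_matrix}: \code{features}
#'   (numeric matrix), \code{labels}, \code{subject} (row-wise subject id),
#'   \code{roi_columns} (ROI name per feature column).
#' @export
assemble_feature_matrix <- function(per_subject, subject_ids = NULL) {
  n_sub <- length(per_subject)
  if (n_sub == 0L) stopf("no subjects supplied")
  subject_ids <- subject_ids %||% names(per_subject) %||% as.character(seq_len(n_sub))
  as_mat <- function(x) if (inherits(x, "voxel_timeseries")) x$data else as.matrix(x)
  as_lab <- function(x) if (inherits(x, "tr_labels")) x$labels else x
  ref_rois <- lapply(per_subject[[1L]]$rois, as_mat)
  roi_names <- names(per_subject[[1L]]$rois) %||%
    paste0("roi", seq_along(ref_rois))
  ref_nvox <- vapply(ref_rois, ncol, integer(1))
  n_vol <- nrow(ref_rois[[1L]])
  blocks <- vector("list", n_sub)
  labels <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    rois <- lapply(per_subject[[s]]$rois, as_mat)
    for (r in seq_along(rois)) {
      if (ncol(rois[[r]]) != ref_nvox[r])
        stopf("subject %s, ROI %s: %d voxels, expected %d",
              subject_ids[s], roi_names[r], ncol(rois[[r]]), ref_nvox[r])
      if (nrow(rois[[r]]) != n_vol)
        stopf("subject %s, ROI %s: %d volumes, expected %d",
              subject_ids[s], roi_names[r], nrow(rois[[r]]), n_vol)
    }
    lab <- as_lab(per_subject[[s]]$labels)
    if (length(lab) != n_vol)
      stopf("subject %s: %d labels for %d volumes", subject_ids[s],
            length(lab), n_vol)
    blocks[[s]] <- do.call(cbind, rois)
    labels[[s]] <- lab
  }
  features <- do.call(rbind, blocks)
  structure(list(
    features    = features,
    labels      = unlist(labels, use.names = FALSE),
    subject     = rep(subject_ids, each = n_vol),
    roi_columns = rep(roi_names, times = ref_nvox),
    n_volumes   = n_vol
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d rows (%d subjects x %d volumes) x %d columns (%d voxels + 1 label)\n",
              nrow(x$features), length(unique(x$subject)), x$n_volumes,
              ncol(x$features) + 1L, ncol(x$features)))
  invisible(x)
}

#' Write / read a feature matrix as TSV
#'
#' The TSV has one header row, the voxel columns named
#' \code{<roi>.<index>}, plus \code{subject} and \code{label} columns.
#'
#' @param fm A \code{feature_matrix}.
#' @param path Output path.
#' @return \code{path} (write) or a \code{feature_matrix} (read).
#' @export
write_feature_matrix_tsv <- function(fm, path) {
  cn <- stats::ave(seq_along(fm$roi_columns), fm$roi_columns, FUN = seq_along)
  df <- as.data.frame(fm$features)
  names(df) <- paste0(fm$roi_columns, ".", cn)
  df$subject <- fm$subject
  df$label <- fm$labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix_tsv
#' @export
read_feature_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lab <- df$label
  sub <- as.character(df$subject)
  feat <- as.matrix(df[, setdiff(names(df), c("subject", "label")), drop = FALSE])
  roi <- sub("\\.[0-9]+$", "", colnames(feat))
  structure(list(features = feat, labels = lab, subject = sub,
                 roi_columns = roi,
                 n_volumes = sum(sub == sub[1L])),
            class = "feature_matrix")
}

#' Reference ROI configuration
#'
#' The six sentiment-network ROIs used in the motivating study — three
#' positive-emotion regions (L_ACC, R_STG, L_cere) and three
#' negative-emotion regions (L_medFG, R_IFG, L_ch) — with the per-ROI voxel
#' counts obtained there with 5 mm spheres (19, 20, 20, 20, 16, 16; 111 in
#' total). The MNI seed coordinates themselves come from prior literature
#' and must be supplied by the user; this reference carries names, counts
#' and the radius only.
#'
#' @return A data.frame with columns \code{name}, \code{n_voxels},
#'   \code{radius_mm}, \code{valence_class}.
#' @export
reference_roi_table <- function() {
  data.frame(
    name = c("L_ACC", "R_STG", "L_cere", "L_medFG", "R_IFG", "L_ch"),
    n_voxels = c(19L, 20L, 20L, 20L, 16L, 16L),
    radius_mm = 5,
    valence_class = c("positive", "positive", "positive",
                      "negative", "negative", "negative"),
    stringsAsFactors = FALSE
  )
}
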