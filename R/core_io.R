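# Round half away from zero (deterministic voxel snapping; R's round() goes
# to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Construct a 4D BOLD volume series
#'
#' Container for a preprocessed 4D BOLD image on a regular (typically 3 mm
#' MNI) grid, together with its voxel-to-world affine, repetition time and a
#' brain mask.
#'
#' @param data Numeric 4D array `[X, Y, Z, T]`.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world
#'   (MNI) millimetres.
#' @param tr_seconds Positive scalar repetition time in seconds.
#' @param brain_mask Logical 3D array of the spatial dimensions; defaults to
#'   voxels with nonzero temporal variance.
#' @return An object of class `bold_volume_series`.
#' @export
bold_volume_series <- function(data, affine, tr_seconds, brain_mask = NULL) {
  if (length(dim(data)) != 4L)
    stop("dimension error: 'data' must be a 4D array, got ",
         length(dim(data)), "D")
  if (dim(data)[4] < 2L)
    stop("dimension error: need at least 2 volumes, got ", dim(data)[4])
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("'affine' must be invertible")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("'tr_seconds' must be a positive scalar")
  sp <- dim(data)[1:3]
  if (is.null(brain_mask)) {
    v <- apply(data, 1:3, stats::var)
    brain_mask <- v > 0 & !is.na(v)
  }
  if (!all(dim(brain_mask) == sp))
    stop("mask shape ", paste(dim(brain_mask), collapse = "x"),
         " does not match spatial shape ", paste(sp, collapse = "x"))
  structure(list(data = data, affine = affine,
                 tr_seconds = as.numeric(tr_seconds),
                 brain_mask = array(as.logical(brain_mask), sp)),
            class = "bold_volume_series")
}

#' @export
print.bold_volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_volume_series> ", paste(d[1:3], collapse = "x"),
      " voxels x ", d[4], " volumes, TR = ", x$tr_seconds, " s, ",
      sum(x$brain_mask), " in-mask voxels\n", sep = "")
  invisible(x)
}

#' Read a 4D NIfTI BOLD image
#'
#' @param path Path to a NIfTI-1 `.nii`/`.nii.gz` file with 4 dimensions.
#' @param tr_seconds Optional TR override; by default taken from the header
#'   (`pixdim[4]`).
#' @return A [bold_volume_series].
#' @export
read_bold <- function(path, tr_seconds = NULL) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("format error reading '", path, "': ",
                         conditionMessage(e)))
  if (length(dim(img)) != 4L)
    stop("dimension error: '", path, "' has ", length(dim(img)),
         " dimensions; a 4D BOLD image is required")
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  if (is.null(tr_seconds)) {
    tr_seconds <- RNifti::niftiHeader(img)$pixdim[5]
    if (!is.finite(tr_seconds) || tr_seconds <= 0)
      stop("TR missing from header of '", path,
           "'; supply tr_seconds explicitly")
  }
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  bold_volume_series(data = arr, affine = aff, tr_seconds = tr_seconds)
}

#' Write a BOLD volume series (or a 3D statistic map) as NIfTI-1
#'
#' Data are stored as float32; the affine is written into the sform.
#'
#' @param x A [bold_volume_series], or a numeric 3D/4D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine,tr_seconds Required when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_bold <- function(x, path, affine = NULL, tr_seconds = NULL) {
  if (inherits(x, "bold_volume_series")) {
    arr <- x$data; affine <- x$affine; tr_seconds <- x$tr_seconds
  } else {
    arr <- x
    if (is.null(affine)) stop("'affine' required for a bare array")
    if (is.null(tr_seconds)) tr_seconds <- 1
  }
  img <- RNifti::asNifti(arr, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(affine, code = 4L))
  hdr <- RNifti::niftiHeader(img)
  sc <- sqrt(colSums(affine[1:3, 1:3]^2))
  hdr$pixdim[2:4] <- sc
  hdr$pixdim[5] <- tr_seconds
  hdr$qform_code <- 0L
  img <- RNifti::asNifti(arr, reference = hdr, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert an MNI millimetre coordinate to a voxel index
#'
#' Applies the inverse affine and rounds half away from zero. Indices are
#' 0-based (NIfTI convention); add 1 for R array subscripting.
#'
#' @param mni_mm Numeric length-3 world coordinate (mm).
#' @param affine 4x4 voxel-to-world matrix.
#' @param dim Optional spatial dimensions for a bounds check.
#' @return Integer length-3 0-based voxel index.
#' @export
mni_to_voxel <- function(mni_mm, affine, dim = NULL) {
  stopifnot(length(mni_mm) == 3L)
  v <- solve(affine, c(as.numeric(mni_mm), 1))[1:3]
  idx <- as.integer(round_half_away(v))
  if (!is.null(dim) && (any(idx < 0L) || any(idx >= dim[1:3])))
    stop("out-of-bounds error: MNI (", paste(mni_mm, collapse = ", "),
         ") maps to voxel (", paste(idx, collapse = ", "),
         ") outside image of dim ", paste(dim[1:3], collapse = "x"))
  idx
}

#' Convert a 0-based voxel index to MNI millimetres
#'
#' @inheritParams mni_to_voxel
#' @param voxel Integer length-3 0-based voxel index.
#' @return Numeric length-3 world coordinate.
#' @export
voxel_to_mni <- function(voxel, affine) {
  stopifnot(length(voxel) == 3L)
  (affine %*% c(as.numeric(voxel), 1))[1:3]
}

# Face-adjacent (6-connectivity) neighbor offsets on the voxel grid.
face_neighbors <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                        c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))

#' Extract a seed time course (seed voxel plus nearest six neighbors)
#'
#' The seed series is the unweighted mean over the seed voxel and its six
#' face-adjacent neighbors; neighbors outside the image or outside the brain
#' mask are dropped with a warning rather than zero-filled.
#'
#' @param vol A [bold_volume_series].
#' @param seed_mni Numeric length-3 MNI coordinate in mm.
#' @param label Optional seed label, used in messages.
#' @return Numeric vector of length `T`.
#' @export
extract_seed_series <- function(vol, seed_mni, label = NULL) {
  d <- dim(vol$data)
  idx0 <- mni_to_voxel(seed_mni, vol$affine, dim = d)
  ctr <- idx0 + 1L                      # 1-based
  if (!vol$brain_mask[ctr[1], ctr[2], ctr[3]])
    stop("seed error: seed ", if (!is.null(label)) paste0("'", label, "' "),
         "at MNI (", paste(seed_mni, collapse = ", "), ") is outside the mask")
  cand <- rbind(ctr, sweep(face_neighbors, 2, ctr, `+`))
  inb <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
         cand[, 2] >= 1 & cand[, 2] <= d[2] &
         cand[, 3] >= 1 & cand[, 3] <= d[3]
  cand <- cand[inb, , drop = FALSE]
  inm <- vol$brain_mask[cand]
  kept <- cand[inm, , drop = FALSE]
  n_drop <- 7L - nrow(kept)
  if (n_drop > 0L)
    warning("seed ", if (!is.null(label)) paste0("'", label, "' "),
            "at MNI (", paste(seed_mni, collapse = ", "), "): ", n_drop,
            " of 6 neighbor voxel(s) out of bounds/mask, averaging over ",
            nrow(kept), " voxel(s)")
  Tn <- d[4]
  acc <- numeric(Tn)
  for (i in seq_len(nrow(kept)))
    acc <- acc + vol$data[kept[i, 1], kept[i, 2], kept[i, 3], ]
  acc / nrow(kept)
}

#' Extract a multi-ROI time-series matrix from a volume
#'
#' Each ROI is a coordinate-defined seed handled by [extract_seed_series].
#'
#' @param vol A [bold_volume_series].
#' @param rois Data frame with columns `label`, `x_mm`, `y_mm`, `z_mm`.
#' @return A [roi_time_series] with one column per ROI, label order preserved.
#' @export
extract_roi_series <- function(vol, rois) {
  if (!is.data.frame(rois) || nrow(rois) == 0L)
    stop("validation error: 'rois' must be a non-empty data frame")
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(rois)))
    stop("validation error: 'rois' must have columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(rois$label))
    stop("validation error: duplicate ROI labels: ",
         paste(unique(rois$label[duplicated(rois$label)]), collapse = ", "))
  vals <- vapply(seq_len(nrow(rois)), function(i)
    extract_seed_series(vol, c(rois$x_mm[i], rois$y_mm[i], rois$z_mm[i]),
                        label = rois$label[i]),
    numeric(dim(vol$data)[4]))
  roi_time_series(vals, labels = as.character(rois$label),
                  tr_seconds = vol$tr_seconds)
}

#' Construct an ROI time-series matrix
#'
#' @param values Numeric matrix `[T x R]` of per-region BOLD time courses.
#' @param labels Character vector of R region labels.
#' @param tr_seconds Positive scalar repetition time in seconds.
#' @return An object of class `roi_time_series`.
#' @export
roi_time_series <- function(values, labels = colnames(values), tr_seconds) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- paste0("roi", seq_len(ncol(values)))
  if (length(labels) != ncol(values))
    stop("need one label per region (", ncol(values), "), got ",
         length(labels))
  if (anyDuplicated(labels))
    stop("validation error: duplicate region labels")
  if (anyNA(values)) stop("time series contain missing values")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("'tr_seconds' must be a positive scalar")
  colnames(values) <- labels
  structure(list(values = values, labels = as.character(labels),
                 tr_seconds = as.numeric(tr_seconds)),
            class = "roi_time_series")
}

#' @export
print.roi_time_series <- function(x, ...) {
  cat("<roi_time_series> ", nrow(x$values), " timepoints x ",
      ncol(x$values), " regions, TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' Discard initial volumes (magnetization equilibration)
#'
#' @param x A [bold_volume_series] or [roi_time_series].
#' @param n Number of leading volumes to drop (default 5).
#' @return The input with the first `n` volumes removed.
#' @export
discard_initial_volumes <- function(x, n = 5L) {
  n <- as.integer(n)
  if (inherits(x, "bold_volume_series")) {
    Tn <- dim(x$data)[4]
    if (n >= Tn - 1L) stop("cannot discard ", n, " of ", Tn, " volumes")
    bold_volume_series(x$data[, , , (n + 1L):Tn, drop = FALSE], x$affine,
                       x$tr_seconds, x$brain_mask)
  } else if (inherits(x, "roi_time_series")) {
    Tn <- nrow(x$values)
    if (n >= Tn - 1L) stop("cannot discard ", n, " of ", Tn, " timepoints")
    roi_time_series(x$values[(n + 1L):Tn, , drop = FALSE], x$labels,
                    x$tr_seconds)
  } else stop("unsupported input")
}

cohort_groups <- c("TSZ", "DSZ", "HC")
cohort_timepoints <- c("t1", "t2")
panss_cols <- c("panss_positive", "panss_negative", "panss_general",
                "panss_total")

#' Validate a longitudinal cohort table
#'
#' Checks the contract of the clinical/covariate table: one row per
#' (subject, timepoint), groups in TSZ/DSZ/HC, healthy controls present only
#' at baseline and without symptom scores.
#'
#' @param df Data frame with columns `subject_id`, `group`, `timepoint`,
#'   `age_years`, `sex`, `education_years`, `illness_duration_months`,
#'   `cpz_equiv_mg_per_day` and the four PANSS subscale columns.
#' @return `df`, invisibly, or an error.
#' @export
validate_cohort_table <- function(df) {
  need <- c("subject_id", "group", "timepoint", "age_years", "sex",
            "education_years", "illness_duration_months",
            "cpz_equiv_mg_per_day", panss_cols)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$group %in% cohort_groups))
    stop("group must be one of ", paste(cohort_groups, collapse = "/"))
  if (!all(df$timepoint %in% cohort_timepoints))
    stop("timepoint must be t1 or t2")
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be F or M")
  key <- paste(df$subject_id, df$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, timepoint) records")
  hc <- df$group == "HC"
  if (any(hc & df$timepoint != "t1"))
    stop("HC records must appear only at t1")
  if (any(!is.na(as.matrix(df[hc, panss_cols]))))
    stop("PANSS fields must be absent (NA) for HC")
  invisible(df)
}

#' Read a cohort table from TSV
#' @param path Path to a tab-separated file with a header row.
#' @return Validated data frame (see [validate_cohort_table]).
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_cohort_table(df)
  df
}

#' Read an ROI definition table from TSV
#' @param path TSV with columns `label`, `x_mm`, `y_mm`, `z_mm`.
#' @return Data frame of coordinate-defined seeds.
#' @export
read_roi_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("ROI table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$label)) stop("duplicate ROI labels")
  df
}

#' Read a 6-column rigid-body motion parameter table
#'
#' Columns: x/y/z translations in mm then three rotations in radians, one
#' row per volume. Accepts files with or without a header row.
#'
#' @param path Path to a whitespace/tab separated text file.
#' @return Numeric matrix `[T x 6]`.
#' @export
read_motion <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "[\t ]+")[[1]]))))
  m <- as.matrix(utils::read.table(path, header = has_header))
  if (ncol(m) != 6L)
    stop("validation error: motion table must have 6 columns, got ", ncol(m))
  storage.mode(m) <- "double"
  colnames(m) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                   "rot_x_rad", "rot_y_rad", "rot_z_rad")
  m
}

#' Write an ROI time-series matrix as labeled TSV
#' @param x A [roi_time_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(x, path) {
  utils::write.table(x$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an ROI time-series matrix from labeled TSV
#' @param path Input TSV (header row of region labels).
#' @param tr_seconds Repetition time of the series.
#' @return A [roi_time_series].
#' @export
read_series_tsv <- function(path, tr_seconds) {
  m <- as.matrix(utils::read.delim(path, sep = "\t", check.names = FALSE))
  storage.mode(m) <- "double"
  roi_time_series(m, labels = colnames(m), tr_seconds = tr_seconds)
}
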