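#' Zero-phase band-pass filter for BOLD time series
#'
#' Ideal (frequency-domain) band-pass: each column is demeaned, Fourier
#' transformed, bins outside `[low_hz, high_hz]` are zeroed, and the series
#' is transformed back. This is the filter style of the common
#' resting-state preprocessing toolboxes; it is exactly zero-phase and
#' idempotent (filtering twice equals filtering once), and its frequency
#' response is a sharp indicator of the band. Default band 0.01-0.08 Hz,
#' the conventional resting-state range. Output columns have zero mean.
#'
#' @param series Numeric matrix `[T x R]` (a vector is treated as one
#'   column) or a [roi_time_series].
#' @param tr_seconds Sampling interval in seconds.
#' @param low_hz,high_hz Pass-band edges in Hz.
#' @return Filtered matrix (or [roi_time_series]) of the same shape.
#' @export
bandpass <- function(series, tr_seconds, low_hz = 0.01, high_hz = 0.08) {
  if (inherits(series, "roi_time_series")) {
    out <- bandpass(series$values, series$tr_seconds, low_hz, high_hz)
    return(roi_time_series(out, series$labels, series$tr_seconds))
  }
  x <- as.matrix(series)
  nyq <- 1 / (2 * tr_seconds)
  if (low_hz <= 0 || high_hz <= low_hz)
    stop("parameter error: need 0 < low_hz < high_hz")
  if (high_hz >= nyq)
    stop("parameter error: high_hz (", high_hz, " Hz) must be below the ",
         "Nyquist frequency (", nyq, " Hz) for TR = ", tr_seconds, " s")
  n <- nrow(x)
  if (n < 16L)
    stop("parameter error: series too short (T = ", n, ") to filter")
  x <- sweep(x, 2, colMeans(x))
  freq <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L)) / (n * tr_seconds)
  keep <- freq >= low_hz & freq <= high_hz
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  out <- Re(stats::mvfft(X, inverse = TRUE)) / n
  dimnames(out) <- dimnames(x)
  out
}

#' Assemble the nuisance confound set
#'
#' Builds the standard nuisance design used for resting-state denoising:
#' white-matter and CSF mean signals, a linear trend and the 12 motion
#' parameters (the 6 rigid-body parameters and their backward-difference
#' derivatives, first row 0). The global mean signal is deliberately never
#' included.
#'
#' @param motion6 Numeric matrix `[T x 6]` (translations mm, rotations rad).
#' @param wm_mean,csf_mean Optional numeric vectors of length `T`.
#' @return An object of class `confound_set` (a design matrix plus parts).
#' @export
confound_set <- function(motion6, wm_mean = NULL, csf_mean = NULL) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L)
    stop("validation error: motion6 must have 6 columns")
  Tn <- nrow(motion6)
  d <- rbind(0, diff(motion6))
  motion12 <- cbind(motion6, d)
  colnames(motion12) <- c(paste0("mot", 1:6), paste0("mot", 1:6, "_d"))
  parts <- list(linear_trend = seq_len(Tn) - (Tn + 1) / 2,
                motion12 = motion12)
  if (!is.null(wm_mean)) {
    stopifnot(length(wm_mean) == Tn)
    parts$wm_mean <- as.numeric(wm_mean)
  }
  if (!is.null(csf_mean)) {
    stopifnot(length(csf_mean) == Tn)
    parts$csf_mean <- as.numeric(csf_mean)
  }
  X <- do.call(cbind, lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    if (is.matrix(p)) p else matrix(p, ncol = 1, dimnames = list(NULL, nm))
  }))
  structure(list(design = X, parts = parts, n = Tn), class = "confound_set")
}

#' Regress nuisance confounds out of a time-series matrix
#'
#' Returns least-squares residuals of each column on an intercept plus the
#' confound columns. A rank-deficient confound design is an error naming the
#' collinear columns rather than a silent drop.
#'
#' @param series Numeric matrix `[T x R]` or [roi_time_series].
#' @param confounds A [confound_set] or a plain numeric matrix `[T x k]`.
#' @return Residual matrix (or [roi_time_series]) of the same shape.
#' @export
regress_confounds <- function(series, confounds) {
  if (inherits(series, "roi_time_series")) {
    out <- regress_confounds(series$values, confounds)
    return(roi_time_series(out, series$labels, series$tr_seconds))
  }
  x <- as.matrix(series)
  C <- if (inherits(confounds, "confound_set")) confounds$design
       else as.matrix(confounds)
  if (nrow(C) != nrow(x))
    stop("confound rows (", nrow(C), ") != series rows (", nrow(x), ")")
  if (is.null(colnames(C))) colnames(C) <- paste0("c", seq_len(ncol(C)))
  X <- cbind(intercept = 1, C)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("degeneracy error: collinear confound columns: ",
         paste(bad, collapse = ", "))
  }
  x - X %*% qr.coef(qx, x)
}

#' Framewise displacement (Power convention)
#'
#' `FD_t = sum |delta translations| + 50 mm * sum |delta rotations|`, with
#' rotations in radians projected onto a 50 mm sphere; the first frame has
#' FD 0 by definition.
#'
#' @param motion6 Numeric matrix `[T x 6]` (translations mm, rotations rad).
#' @param radius_mm Sphere radius for the rotation term (default 50).
#' @return Numeric vector of length `T`.
#' @export
framewise_displacement <- function(motion6, radius_mm = 50) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L)
    stop("validation error: motion6 must have 6 columns, got ", ncol(motion6))
  d <- abs(diff(motion6))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Motion quality control: the 3 mm / 3 degree exclusion rule
#'
#' A subject is excluded when the maximum absolute translation along any
#' cardinal axis exceeds 3.0 mm or the maximum absolute rotation about any
#' axis exceeds 3.0 degrees, both measured relative to the reference volume.
#' Mean framewise displacement is reported alongside.
#'
#' @param motion6 Numeric matrix `[T x 6]` (translations mm, rotations rad).
#' @param max_trans_mm,max_rot_deg Exclusion thresholds.
#' @return A list of class `motion_qc_report`: `max_translation_mm`,
#'   `max_rotation_deg`, `mean_fd_mm`, `excluded`.
#' @export
qc_exclude <- function(motion6, max_trans_mm = 3.0, max_rot_deg = 3.0) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L)
    stop("validation error: motion6 must have 6 columns")
  mt <- max(abs(motion6[, 1:3]))
  mr <- max(abs(motion6[, 4:6])) * 180 / pi
  out <- list(max_translation_mm = mt,
              max_rotation_deg = mr,
              mean_fd_mm = mean(framewise_displacement(motion6)),
              excluded = mt > max_trans_mm || mr > max_rot_deg)
  class(out) <- "motion_qc_report"
  out
}

#' @export
print.motion_qc_report <- function(x, ...) {
  cat(sprintf(
    "<motion_qc_report> max trans %.2f mm, max rot %.2f deg, mean FD %.3f mm -> %s\n",
    x$max_translation_mm, x$max_rotation_deg, x$mean_fd_mm,
    if (x$excluded) "EXCLUDED" else "retained"))
  invisible(x)
}
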