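#' Sliding-window scheme
#'
#' @param length_tr Window length in TRs (default 50, the length implied by
#'   requiring the window to span at least one cycle of the slowest retained
#'   frequency, 0.01 Hz at TR 2 s).
#' @param step_tr Sliding step in TRs (default 1).
#' @return Object of class `window_scheme`.
#' @export
window_scheme <- function(length_tr = 50L, step_tr = 1L) {
  length_tr <- as.integer(length_tr); step_tr <- as.integer(step_tr)
  if (is.na(length_tr) || length_tr < 2L)
    stop("parameter error: length_tr must be >= 2")
  if (is.na(step_tr) || step_tr < 1L)
    stop("parameter error: step_tr must be >= 1")
  structure(list(length_tr = length_tr, step_tr = step_tr),
            class = "window_scheme")
}

#' Minimum admissible window length in TRs
#'
#' The window must span at least one full cycle of the slowest frequency in
#' the filtered signal: `ceil((1/fmin)/TR)`.
#'
#' @param fmin_hz Lowest retained frequency in Hz.
#' @param tr_seconds Repetition time in seconds.
#' @return Integer number of TRs.
#' @export
min_window_length <- function(fmin_hz, tr_seconds) {
  if (!is.numeric(fmin_hz) || fmin_hz <= 0)
    stop("parameter error: fmin_hz must be positive")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("parameter error: tr_seconds must be positive")
  as.integer(ceiling((1 / fmin_hz) / tr_seconds))
}

#' Enumerate sliding windows over a series of length T
#'
#' Windows start at 1, 1+step, 1+2*step, ... and are inclusive index ranges
#' of `length_tr` samples; the count is `floor((T - L)/step) + 1`.
#'
#' @param T Number of timepoints.
#' @param scheme A [window_scheme].
#' @return Integer matrix with columns `start`, `end` (1-based, inclusive).
#' @export
build_windows <- function(T, scheme = window_scheme()) {
  T <- as.integer(T)
  L <- scheme$length_tr; s <- scheme$step_tr
  if (T < L)
    stop("insufficient-data error: T = ", T, " < window length ", L)
  starts <- seq.int(1L, T - L + 1L, by = s)
  cbind(start = starts, end = starts + L - 1L)
}

#' Number of sliding windows
#' @inheritParams build_windows
#' @return Integer window count.
#' @export
n_windows <- function(T, scheme = window_scheme()) {
  nrow(build_windows(T, scheme))
}

# A window is degenerate when its sum of squared deviations is zero up to
# roundoff relative to the raw sum of squares.
degenerate_var <- function(v, ss) v <= pmax(ss, .Machine$double.xmin) * 1e-12

# Windowed sums via cumulative sums: for each window k, sum over the window
# of v. v may be a matrix (columns processed in parallel).
windowed_sums <- function(v, windows) {
  v <- as.matrix(v)
  cs <- rbind(0, apply(v, 2, cumsum))
  cs[windows[, "end"] + 1L, , drop = FALSE] -
    cs[windows[, "start"], , drop = FALSE]
}

# Pearson correlation of x and y within each window, vectorized.
# y may be a matrix [T x K]; returns [n_windows x K].
windowed_pearson <- function(x, y, windows, check_degenerate = TRUE,
                             context = "") {
  L <- windows[1, "end"] - windows[1, "start"] + 1L
  y <- as.matrix(y)
  sx <- windowed_sums(x, windows)[, 1]
  sxx <- windowed_sums(x * x, windows)[, 1]
  sy <- windowed_sums(y, windows)
  syy <- windowed_sums(y * y, windows)
  sxy <- windowed_sums(x * y, windows)
  vx <- sxx - sx^2 / L
  vy <- syy - sy^2 / L
  cxy <- sxy - sx * sy / L
  if (check_degenerate) {
    if (any(degenerate_var(vx, sxx))) {
      k <- which(degenerate_var(vx, sxx))[1]
      stop("degenerate-window error: zero variance in window ", k,
           if (nzchar(context)) paste0(" (", context, ")"))
    }
    badv <- degenerate_var(vy, syy)
    if (any(badv)) {
      k <- which(badv, arr.ind = TRUE)
      stop("degenerate-window error: zero variance in window ", k[1, 1],
           " of series ", k[1, 2],
           if (nzchar(context)) paste0(" (", context, ")"))
    }
  }
  r <- cxy / (sqrt(pmax(vx, 0)) * sqrt(pmax(vy, 0)))
  pmin(pmax(r, -1), 1)
}

#' Sliding-window Pearson correlation of two series
#'
#' @param x,y Numeric vectors of equal length `T`.
#' @param scheme A [window_scheme].
#' @return Object of class `windowed_correlation_series` with elements `r`
#'   (vector of per-window correlations, in window order) and `scheme`.
#' @export
windowed_correlation <- function(x, y, scheme = window_scheme()) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  w <- build_windows(length(x), scheme)
  r <- windowed_pearson(x, y, w)[, 1]
  structure(list(r = as.numeric(r), scheme = scheme),
            class = "windowed_correlation_series")
}

#' Temporal variability of a windowed-correlation series
#'
#' The statistic is the mean squared successive difference of the windowed
#' correlations: `I = (1/(m-1)) * sum_{k=2}^{m} (r_k - r_{k-1})^2`, computed
#' on raw correlations (no Fisher transform). High I means unstable
#' inter-regional coupling; I is 0 for perfectly stable coupling and cannot
#' exceed 4 (each successive jump is bounded by 2).
#'
#' @param rs A `windowed_correlation_series` or a plain numeric vector of
#'   windowed correlations (length m >= 2).
#' @return Non-negative scalar I.
#' @export
temporal_variability <- function(rs) {
  r <- if (inherits(rs, "windowed_correlation_series")) rs$r
       else as.numeric(rs)
  m <- length(r)
  if (m < 2L)
    stop("insufficient-windows error: need at least 2 windows, got ", m)
  if (any(!is.finite(r))) stop("non-finite windowed correlations")
  mean(diff(r)^2)
}

#' Region-by-region temporal-variability matrix
#'
#' Entry (i, j) is the temporal variability I of the windowed correlation
#' series between regions i and j; the matrix is symmetric with a zero
#' diagonal by convention.
#'
#' @param rois A [roi_time_series] (or plain `[T x R]` matrix).
#' @param scheme A [window_scheme].
#' @return Object of class `variability_matrix`: list with `values`
#'   (symmetric `[R x R]`), `labels`, `scheme`.
#' @export
roi_variability_matrix <- function(rois, scheme = window_scheme()) {
  v <- if (inherits(rois, "roi_time_series")) rois$values else as.matrix(rois)
  labels <- colnames(v)
  if (is.null(labels)) labels <- paste0("roi", seq_len(ncol(v)))
  R <- ncol(v)
  if (R < 2L) stop("need at least 2 regions")
  w <- build_windows(nrow(v), scheme)
  rw <- all_pairs_windowed_r(v, w)
  out <- matrix(0, R, R, dimnames = list(labels, labels))
  p <- 1L
  for (i in seq_len(R - 1L)) for (j in (i + 1L):R) {
    I <- mean(diff(rw[, p])^2)
    out[i, j] <- I; out[j, i] <- I
    p <- p + 1L
  }
  structure(list(values = out, labels = labels, scheme = scheme),
            class = "variability_matrix")
}

# Windowed correlations for every region pair: returns [n_windows x P]
# where P = R(R-1)/2, pairs in column-major upper-triangle order
# (1,2),(1,3),(2,3),... matching combn ordering of (i<j) nested loops used
# by roi_variability_matrix.
all_pairs_windowed_r <- function(v, windows) {
  R <- ncol(v); L <- windows[1, "end"] - windows[1, "start"] + 1L
  s1 <- windowed_sums(v, windows)            # [m x R]
  s2 <- windowed_sums(v * v, windows)
  varw <- s2 - s1^2 / L
  bad <- which(degenerate_var(varw, s2), arr.ind = TRUE)
  if (nrow(bad)) {
    lab <- colnames(v)
    if (is.null(lab)) lab <- paste0("roi", seq_len(R))
    stop("degenerate-window error: zero variance in window ", bad[1, 1],
         " of region '", lab[bad[1, 2]], "'")
  }
  P <- R * (R - 1L) / 2L
  out <- matrix(NA_real_, nrow(windows), P)
  p <- 1L
  for (i in seq_len(R - 1L)) for (j in (i + 1L):R) {
    sxy <- windowed_sums(v[, i] * v[, j], windows)[, 1]
    cxy <- sxy - s1[, i] * s1[, j] / L
    out[, p] <- pmin(pmax(cxy / sqrt(varw[, i] * varw[, j]), -1), 1)
    p <- p + 1L
  }
  out
}

# Pair labels in upper.tri() column-major order ((1,2),(1,3),(2,3),...),
# matching m[upper.tri(m)] extraction.
pair_labels <- function(labels) {
  R <- length(labels)
  unlist(lapply(2:R, function(j)
    paste(labels[seq_len(j - 1L)], labels[j], sep = "--")))
}

#' Mean sliding-window functional connectivity matrix
#'
#' Companion quantity to [roi_variability_matrix]: entry (i, j) is the mean
#' over windows of the windowed Pearson correlation, used for the
#' variability-connectivity coupling analysis. Diagonal is 1.
#'
#' @inheritParams roi_variability_matrix
#' @return Object of class `fc_matrix` (same layout as `variability_matrix`).
#' @export
mean_fc_matrix <- function(rois, scheme = window_scheme()) {
  v <- if (inherits(rois, "roi_time_series")) rois$values else as.matrix(rois)
  labels <- colnames(v)
  if (is.null(labels)) labels <- paste0("roi", seq_len(ncol(v)))
  R <- ncol(v)
  if (R < 2L) stop("need at least 2 regions")
  w <- build_windows(nrow(v), scheme)
  rw <- all_pairs_windowed_r(v, w)
  out <- diag(R); dimnames(out) <- list(labels, labels)
  p <- 1L
  for (i in seq_len(R - 1L)) for (j in (i + 1L):R) {
    out[i, j] <- out[j, i] <- mean(rw[, p]); p <- p + 1L
  }
  structure(list(values = out, labels = labels, scheme = scheme),
            class = "fc_matrix")
}

#' Seed-to-voxel temporal-variability map
#'
#' Computes, for every in-mask voxel, the temporal variability I between the
#' seed time course (seed voxel averaged with its six face neighbors) and
#' the voxel time course. Voxels belonging to the seed neighborhood itself
#' are set to 0 and flagged. Voxels producing a degenerate (zero-variance)
#' window are masked out with a count reported via a message. Computation
#' streams over fixed-size voxel blocks; block boundaries do not affect the
#' result.
#'
#' @param vol A preprocessed [bold_volume_series].
#' @param seed_mni Numeric length-3 MNI coordinate (mm).
#' @param scheme A [window_scheme].
#' @param block_size Number of voxels per streamed block.
#' @return Object of class `variability_map`: list with `values` (3D array,
#'   NA outside mask), `seed_mni`, `seed_voxels` (matrix of 1-based indices),
#'   `scheme`, `n_degenerate`.
#' @export
seed_variability_map <- function(vol, seed_mni, scheme = window_scheme(),
                                 block_size = 4096L) {
  d <- dim(vol$data)
  seed <- extract_seed_series(vol, seed_mni)
  w <- build_windows(d[4], scheme)
  # seed neighborhood (voxel + in-bounds face neighbors), for flagging
  ctr <- mni_to_voxel(seed_mni, vol$affine, dim = d) + 1L
  nb <- rbind(ctr, sweep(face_neighbors, 2, ctr, `+`))
  nb <- nb[nb[, 1] >= 1 & nb[, 1] <= d[1] &
           nb[, 2] >= 1 & nb[, 2] <= d[2] &
           nb[, 3] >= 1 & nb[, 3] <= d[3], , drop = FALSE]
  mask_lin <- which(vol$brain_mask)
  seed_lin <- (nb[, 3] - 1L) * d[1] * d[2] + (nb[, 2] - 1L) * d[1] + nb[, 1]
  vmat <- matrix(vol$data, prod(d[1:3]), d[4])   # voxels x time view
  out <- array(NA_real_, d[1:3])
  n_degen <- 0L
  for (b0 in seq(1L, length(mask_lin), by = block_size)) {
    blk <- mask_lin[b0:min(b0 + block_size - 1L, length(mask_lin))]
    y <- t(vmat[blk, , drop = FALSE])            # T x nblk
    r <- windowed_pearson(seed, y, w, check_degenerate = FALSE)
    Ivals <- colMeans(diff(r)^2)
    bad <- !is.finite(Ivals)
    n_degen <- n_degen + sum(bad)
    Ivals[bad] <- NA_real_
    out[blk] <- Ivals
  }
  out[seed_lin] <- 0
  if (n_degen > 0L)
    message("seed_variability_map: ", n_degen,
            " voxel(s) masked out due to degenerate windows")
  structure(list(values = out, seed_mni = seed_mni, seed_voxels = nb,
                 scheme = scheme, n_degenerate = n_degen),
            class = "variability_map")
}
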