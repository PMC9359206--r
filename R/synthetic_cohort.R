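# Synthetic longitudinal two-group cohorts with controllable dynamic
# connectivity. BOLD-like signals are drawn from a hidden-Markov covariance
# model: at each TR a multivariate Gaussian sample with the active state's
# covariance, plus white noise, band-pass filtered into the resting-state
# band. Temporal variability of windowed correlations is then governed by
# the state-switching rate, which gives a directly controllable planted
# ground truth for the treatment effect.

# Deterministic substream seed derivation (keeps values below 2^31).
substream_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729) %%
               2147483629)
}

#' Hidden covariance-state model
#'
#' @param covariances List of R x R symmetric positive-semidefinite
#'   matrices with unit diagonal, one per state.
#' @param transition Row-stochastic state transition matrix.
#' @return Object of class `state_model`.
#' @export
state_model <- function(covariances, transition) {
  if (!is.list(covariances) || !length(covariances))
    stop("covariances must be a non-empty list")
  R <- nrow(covariances[[1]])
  for (k in seq_along(covariances)) {
    S <- covariances[[k]]
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10)))
      stop("validation error: state ", k, " covariance not symmetric")
    if (any(abs(diag(S) - 1) > 1e-10))
      stop("validation error: state ", k, " covariance must have unit diagonal")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("validation error: state ", k, " covariance not positive ",
           "semidefinite (min eigenvalue ", signif(min(ev), 3), ")")
  }
  transition <- as.matrix(transition)
  n <- length(covariances)
  if (!all(dim(transition) == c(n, n)))
    stop("transition must be ", n, "x", n)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-10))
    stop("transition rows must be non-negative and sum to 1")
  structure(list(n_states = n, n_regions = R, covariances = covariances,
                 transition = transition),
            class = "state_model")
}

# Two-state transition matrix with symmetric switch probability p.
switch_transition <- function(p) {
  p <- min(max(p, 0), 0.5)
  matrix(c(1 - p, p, p, 1 - p), 2, 2, byrow = TRUE)
}

#' Default two-state connectivity model
#'
#' Regions are organized in disjoint pairs. "Responsive" pairs have an
#' off-diagonal correlation that switches between a low and a high value
#' with the hidden state (these are the pairs that carry temporal
#' variability and the planted treatment effect); "static" pairs keep a
#' fixed moderate correlation; remaining regions are independent. The
#' block-pair structure keeps every state covariance positive definite by
#' construction.
#'
#' The default state correlations are symmetric (-0.8 and +0.8). This
#' makes the sampling variance of the windowed correlation identical in
#' both states (for a bivariate normal, `Var(xy) = 1 + rho^2`), so the
#' temporal-variability statistic responds to the state-switching rate
#' itself rather than to a change in marginal noise level, and the mean
#' windowed connectivity of responsive pairs stays near zero while static
#' pairs keep high connectivity with low variability - reproducing the
#' negative variability-connectivity coupling seen in resting-state data.
#'
#' @param n_regions Number of regions (default 12).
#' @param responsive_pairs List of length-2 index vectors (default
#'   `(1,2), (3,4), (5,6)`).
#' @param static_pairs List of length-2 index vectors (default
#'   `(7,8), (9,10)`).
#' @param r_low,r_high Responsive-pair correlation in the two states
#'   (defaults -0.9 and 0.9).
#' @param r_static Static-pair correlation (default 0.5).
#' @param dwell_mean_tr Mean state dwell time in TRs (default 60), i.e.
#'   switch probability `1/dwell_mean_tr` per TR. The default sits just
#'   above the 50-TR analysis window, on the side where slower switching
#'   monotonically lowers the temporal variability; switching much faster
#'   than the window is averaged out and no longer identifiable.
#' @return A `state_model` with a `dwell_mean_tr` attribute.
#' @export
default_state_model <- function(n_regions = 12L,
                                responsive_pairs = list(c(1L, 2L), c(3L, 4L),
                                                        c(5L, 6L)),
                                static_pairs = list(c(7L, 8L), c(9L, 10L)),
                                r_low = -0.9, r_high = 0.9, r_static = 0.5,
                                dwell_mean_tr = 60) {
  idx <- unlist(c(responsive_pairs, static_pairs))
  if (any(idx > n_regions))
    stop("validation error: pair index exceeds n_regions")
  if (anyDuplicated(idx))
    stop("default model requires disjoint region pairs")
  mk <- function(r_resp) {
    S <- diag(n_regions)
    for (p in responsive_pairs) { S[p[1], p[2]] <- S[p[2], p[1]] <- r_resp }
    for (p in static_pairs) { S[p[1], p[2]] <- S[p[2], p[1]] <- r_static }
    S
  }
  m <- state_model(list(mk(r_low), mk(r_high)),
                   switch_transition(1 / dwell_mean_tr))
  m$dwell_mean_tr <- dwell_mean_tr
  m$responsive_pairs <- responsive_pairs
  m$static_pairs <- static_pairs
  m$r_low <- r_low; m$r_high <- r_high; m$r_static <- r_static
  m
}

# Subject-level series for the default block-pair model: every responsive
# pair follows its own independent state sequence (same switching rate,
# independent phases), so averaging features over pairs cancels
# phase/sampling noise; static pairs keep a fixed correlation; remaining
# regions are independent. Post-processing matches generate_roi_bold
# (white noise, band-pass, unit variance).
generate_block_series <- function(model, T, p_switch, state_process,
                                  noise_sd, tr_seconds, seed) {
  set.seed(seed)
  R <- model$n_regions
  X <- matrix(stats::rnorm(T * R), T, R)
  for (pr in model$responsive_pairs) {
    states <- if (state_process == "markov") {
      m2 <- model; m2$transition <- switch_transition(p_switch)
      sample_state_sequence(m2, T)
    } else regular_state_sequence(T, 1 / p_switch)
    rho <- c(model$r_low, model$r_high)[states]
    X[, pr[2]] <- rho * X[, pr[1]] + sqrt(1 - rho^2) * X[, pr[2]]
  }
  for (pr in model$static_pairs) {
    rho <- model$r_static
    X[, pr[2]] <- rho * X[, pr[1]] + sqrt(1 - rho^2) * X[, pr[2]]
  }
  X <- X + matrix(stats::rnorm(T * R, sd = noise_sd), T, R)
  X <- bandpass(X, tr_seconds)
  X <- sweep(X, 2, apply(X, 2, stats::sd), `/`)
  roi_time_series(X, labels = sprintf("roi%02d", seq_len(R)),
                  tr_seconds = tr_seconds)
}

#' Longitudinal cohort design
#'
#' Defaults describe the emulated study: two patient groups of 20 scanned
#' at baseline and after treatment plus a baseline-only healthy reference
#' group, 250 analyzed volumes at TR 2 s, and a treatment that multiplies
#' the state-switching rate of responsive pairs by `effect_delta` at t2 in
#' the treated (TSZ) group only. Per-subject baseline switch-rate
#' multipliers make the planted response heterogeneous and predictable from
#' baseline variability, and the negative-symptom remission ratio is
#' linearly linked to the planted variability drop.
#'
#' @param n_per_group Subjects per group (>= 3; default 20).
#' @param T Number of analyzed volumes (default 250).
#' @param tr_seconds Repetition time (default 2).
#' @param n_regions Number of regions (default 12).
#' @param effect_delta Multiplicative reduction of the switching rate at t2
#'   for treated subjects, in (0, 1]; 1 plants no effect (default 0.3).
#' @param responsive_pairs Region pairs carrying the effect.
#' @param noise_sd White-noise SD added to the state-model draw
#'   (default 0.3).
#' @param clinical_link_slope Slope linking the planted relative
#'   variability drop to the negative-symptom remission ratio
#'   (default 0.33).
#' @param clinical_link_noise_sd SD of the remission-ratio noise
#'   (default 0.08).
#' @param qc_fail_fraction Fraction of subjects given motion traces that
#'   violate the 3 mm / 3 degree rule (default 0).
#' @param groups Which groups to generate.
#' @param dwell_mean_tr Mean state dwell time in TRs (default 60).
#' @param state_process `"regular"` (default) alternates states with fixed
#'   dwell blocks and a random phase, so the realized switch count is
#'   tightly controlled by the rate; `"markov"` samples the Markov chain,
#'   whose Poisson-like flip-count variability adds substantial
#'   between-scan variance in the variability statistic.
#' @param seed Master seed.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 20L, T = 250L, tr_seconds = 2,
                          n_regions = 12L, effect_delta = 0.3,
                          responsive_pairs = list(c(1L, 2L), c(3L, 4L),
                                                  c(5L, 6L)),
                          noise_sd = 0.3, clinical_link_slope = 0.4,
                          clinical_link_noise_sd = 0.04,
                          qc_fail_fraction = 0,
                          groups = c("TSZ", "DSZ", "HC"),
                          dwell_mean_tr = 60,
                          state_process = c("regular", "markov"),
                          seed = 1L) {
  if (n_per_group < 3L) stop("n_per_group must be >= 3")
  if (effect_delta <= 0 || effect_delta > 1)
    stop("effect_delta must be in (0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (any(vapply(responsive_pairs, max, 1L) > n_regions))
    stop("validation error: responsive pair index exceeds n_regions")
  groups <- match.arg(groups, several.ok = TRUE)
  state_process <- match.arg(state_process)
  structure(list(n_per_group = as.integer(n_per_group), T = as.integer(T),
                 tr_seconds = tr_seconds, n_regions = as.integer(n_regions),
                 effect_delta = effect_delta,
                 responsive_pairs = responsive_pairs, noise_sd = noise_sd,
                 clinical_link_slope = clinical_link_slope,
                 clinical_link_noise_sd = clinical_link_noise_sd,
                 qc_fail_fraction = qc_fail_fraction, groups = groups,
                 dwell_mean_tr = dwell_mean_tr,
                 state_process = state_process, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Sample a hidden state sequence
#'
#' Markov-chain sample of length `T` with a uniform initial state.
#'
#' @param model A [state_model].
#' @param T Sequence length.
#' @param seed Integer seed (reproducible draws).
#' @return Integer vector of states in `1..n_states`.
#' @export
sample_state_sequence <- function(model, T, seed = NULL) {
  if (T < 1L) stop("T must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- model$n_states
  s <- integer(T)
  s[1] <- sample.int(n, 1)
  if (T > 1L) for (t in 2:T)
    s[t] <- sample.int(n, 1, prob = model$transition[s[t - 1], ])
  s
}

#' Regular alternating state sequence
#'
#' Alternates between two states in fixed blocks of `dwell_tr` TRs with a
#' random initial state and a random phase offset. Compared with a Markov
#' chain of the same rate, the realized number of state switches is nearly
#' deterministic, which makes the planted temporal-variability level
#' tightly controlled by the dwell time.
#'
#' @param T Sequence length.
#' @param dwell_tr Dwell time per state in TRs.
#' @param seed Integer seed.
#' @return Integer vector of states in `{1, 2}`.
#' @export
regular_state_sequence <- function(T, dwell_tr, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dwell_tr <- max(1L, as.integer(round(dwell_tr)))
  phase <- sample.int(2L * dwell_tr, 1) - 1L
  first <- sample.int(2L, 1)
  s <- (floor((seq_len(T) - 1L + phase) / dwell_tr)) %% 2L
  as.integer(ifelse(s == 0L, first, 3L - first))
}

#' Generate band-limited multi-region BOLD-like series
#'
#' At each TR a multivariate Gaussian draw with the active state's
#' covariance, plus white measurement noise, then zero-phase band-pass
#' filtered (0.01-0.08 Hz) so spectra resemble filtered BOLD; columns are
#' standardized to unit variance.
#'
#' @param model A [state_model].
#' @param states Integer state sequence of length `T`.
#' @param noise_sd White-noise SD.
#' @param tr_seconds Repetition time.
#' @param seed Integer seed.
#' @param labels Optional region labels.
#' @return A [roi_time_series].
#' @export
generate_roi_bold <- function(model, states, noise_sd = 0.3, tr_seconds = 2,
                              seed = NULL, labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Tn <- length(states)
  R <- model$n_regions
  chols <- lapply(model$covariances, function(S) {
    ev <- eigen(S, symmetric = TRUE)
    if (min(ev$values) < -1e-8) stop("validation error: non-PSD covariance")
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), R) %*% t(ev$vectors)
  })
  Z <- matrix(stats::rnorm(Tn * R), Tn, R)
  X <- matrix(0, Tn, R)
  for (k in seq_len(model$n_states)) {
    rows <- states == k
    if (any(rows)) X[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[k]]
  }
  X <- X + matrix(stats::rnorm(Tn * R, sd = noise_sd), Tn, R)
  X <- bandpass(X, tr_seconds)
  X <- sweep(X, 2, apply(X, 2, stats::sd), `/`)
  if (is.null(labels)) labels <- sprintf("roi%02d", seq_len(R))
  roi_time_series(X, labels = labels, tr_seconds = tr_seconds)
}

# Smooth pseudo-physiological motion trace: a lightly low-pass-filtered
# random walk rescaled to a target maximum excursion per column.
motion_trace <- function(T, max_trans_mm, max_rot_rad) {
  targets <- c(rep(max_trans_mm, 3), rep(max_rot_rad, 3))
  m <- vapply(targets, function(tg) {
    w <- cumsum(stats::rnorm(T))
    w <- stats::filter(w, rep(1 / 9, 9), sides = 2)
    w[is.na(w)] <- 0
    w <- w - w[1]
    mx <- max(abs(w))
    if (mx == 0) w else w * (tg / mx)
  }, numeric(T))
  colnames(m) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                   "rot_x_rad", "rot_y_rad", "rot_z_rad")
  m
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic longitudinal cohort
#'
#' Produces per-subject, per-timepoint ROI time series from the hidden
#' covariance-state model, a clinical/covariate table with PANSS-like
#' scores whose negative-subscale remission ratio is linked to the planted
#' variability drop, motion tables, and the planted ground truth.
#'
#' Treated (TSZ) subjects switch states at t2 at a rate reduced by the
#' planted per-subject drop; untreated (DSZ) and healthy (HC) subjects use
#' their baseline rate throughout. Subjects with a higher baseline
#' switching rate respond more, so baseline variability is predictive of
#' response by construction.
#'
#' @param design A [cohort_design].
#' @param model Optional [state_model]; defaults to
#'   [default_state_model] configured from the design.
#' @return Object of class `synthetic_cohort`: `roi_series` (named list
#'   keyed `"<subject>_<timepoint>"`), `cohort` (data frame), `motion`
#'   (named list), `ground_truth`, `design`, `model`.
#' @export
generate_cohort <- function(design, model = NULL) {
  if (is.null(model))
    model <- default_state_model(n_regions = design$n_regions,
                                 responsive_pairs = design$responsive_pairs,
                                 dwell_mean_tr = design$dwell_mean_tr)
  p0 <- 1 / design$dwell_mean_tr
  n <- design$n_per_group
  set.seed(substream_seed(design$seed, 0L))
  subs <- list()
  k <- 0L
  for (g in design$groups) {
    for (i in seq_len(n)) {
      k <- k + 1L
      subs[[k]] <- list(id = sprintf("S%03d", k), group = g)
    }
  }
  nsub <- length(subs)
  b <- clip(stats::rnorm(nsub, 0.85, 0.25), 0.4, 1.2)   # baseline rate mult
  qc_fail <- stats::runif(nsub) < design$qc_fail_fraction
  age <- round(clip(stats::rnorm(nsub, 46, 10), 18, 70), 1)
  sex <- ifelse(stats::runif(nsub) < 0.75, "M", "F")
  edu <- round(clip(stats::rnorm(nsub, 10.5, 3), 3, 20), 1)
  dur <- round(clip(stats::rnorm(nsub, 18, 8.6), 1, 60), 1)
  cpz <- round(clip(stats::rnorm(nsub, 300, 110), 50, 800), 1)
  pan_neg1 <- round(clip(stats::rnorm(nsub, 23.5, 5.5), 21, 45))
  pan_pos1 <- round(clip(stats::rnorm(nsub, 11.7, 4.2), 7, 24))
  pan_gen1 <- round(clip(stats::rnorm(nsub, 30, 6.1), 16, 60))
  # planted relative variability drop, larger for high-baseline subjects
  drop <- clip((1 - design$effect_delta) * b, 0, 0.95)
  rr_neg <- rr_pos <- rr_gen <- numeric(nsub)
  cohort <- list(); roi_series <- list(); motion <- list()
  for (s in seq_len(nsub)) {
    g <- subs[[s]]$group
    if (g == "TSZ") {
      rr_neg[s] <- design$clinical_link_slope * drop[s] +
        stats::rnorm(1, 0, design$clinical_link_noise_sd)
      rr_pos[s] <- stats::rnorm(1, 0.15, 0.10)
      rr_gen[s] <- stats::rnorm(1, 0.15, 0.10)
    } else {
      rr_neg[s] <- stats::rnorm(1, 0.07, 0.05)
      rr_pos[s] <- stats::rnorm(1, 0.12, 0.10)
      rr_gen[s] <- stats::rnorm(1, 0.07, 0.10)
    }
  }
  for (s in seq_len(nsub)) {
    g <- subs[[s]]$group
    id <- subs[[s]]$id
    tps <- if (g == "HC") "t1" else c("t1", "t2")
    neg1 <- pan_neg1[s]; pos1 <- pan_pos1[s]; gen1 <- pan_gen1[s]
    neg2 <- round(clip(neg1 * (1 - rr_neg[s]), 7, 49))
    pos2 <- round(clip(pos1 * (1 - rr_pos[s]), 7, 49))
    gen2 <- round(clip(gen1 * (1 - rr_gen[s]), 16, 112))
    for (tp in tps) {
      key <- paste0(id, "_", tp)
      p_switch <- if (g == "TSZ" && tp == "t2")
        p0 * b[s] * (1 - drop[s]) else p0 * b[s]
      ser_seed <- substream_seed(design$seed, s * 10L + (tp == "t2") * 5L + 2L)
      roi_series[[key]] <- if (!is.null(model$r_low)) {
        generate_block_series(model, design$T, p_switch,
                              design$state_process, design$noise_sd,
                              design$tr_seconds, ser_seed)
      } else {
        # custom covariance model: one global chain
        m_tp <- model
        m_tp$transition <- switch_transition(p_switch)
        st_seed <- substream_seed(design$seed,
                                  s * 10L + (tp == "t2") * 5L + 1L)
        states <- if (design$state_process == "markov")
          sample_state_sequence(m_tp, design$T, seed = st_seed)
        else
          regular_state_sequence(design$T, 1 / p_switch, seed = st_seed)
        generate_roi_bold(m_tp, states, noise_sd = design$noise_sd,
                          tr_seconds = design$tr_seconds, seed = ser_seed)
      }
      set.seed(substream_seed(design$seed, s * 10L + (tp == "t2") * 5L + 3L))
      motion[[key]] <- if (qc_fail[s] && tp == "t1")
        motion_trace(design$T, stats::runif(1, 3.2, 5), 0.01)
      else
        motion_trace(design$T, stats::runif(1, 0.2, 1.2),
                     stats::runif(1, 0.002, 0.015))
      hc <- g == "HC"
      cohort[[length(cohort) + 1L]] <- data.frame(
        subject_id = id, group = g, timepoint = tp,
        age_years = age[s], sex = sex[s], education_years = edu[s],
        illness_duration_months = if (hc) NA_real_ else dur[s],
        cpz_equiv_mg_per_day = if (hc) NA_real_ else cpz[s],
        panss_positive = if (hc) NA_real_ else if (tp == "t1") pos1 else pos2,
        panss_negative = if (hc) NA_real_ else if (tp == "t1") neg1 else neg2,
        panss_general = if (hc) NA_real_ else if (tp == "t1") gen1 else gen2,
        panss_total = if (hc) NA_real_ else
          (if (tp == "t1") pos1 + neg1 + gen1 else pos2 + neg2 + gen2))
    }
  }
  cohort <- do.call(rbind, cohort)
  validate_cohort_table(cohort)
  gt <- data.frame(subject_id = vapply(subs, `[[`, "", "id"),
                   group = vapply(subs, `[[`, "", "group"),
                   baseline_rate_multiplier = b,
                   planted_drop = ifelse(
                     vapply(subs, `[[`, "", "group") == "TSZ", drop, 0),
                   rr_negative_planted = rr_neg,
                   qc_fail_planted = qc_fail)
  structure(list(roi_series = roi_series, cohort = cohort, motion = motion,
                 ground_truth = list(subjects = gt,
                                     responsive_pairs = design$responsive_pairs,
                                     effect_delta = design$effect_delta),
                 design = design, model = model),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(unique(x$cohort$subject_id)),
      " subjects (", paste(x$design$groups, collapse = "/"), "), ",
      length(x$roi_series), " scans of ", x$design$T, " x ",
      x$design$n_regions, "\n", sep = "")
  invisible(x)
}

#' Embed an ROI time-series matrix in a small 4D volume
#'
#' Each region becomes a 3x3x3 voxel block on a 3 mm grid (plus iid voxel
#' noise); the remaining voxels carry background noise. Used to exercise
#' the voxel-wise path without full-size images.
#'
#' @param rts A [roi_time_series] with up to 27 regions.
#' @param voxel_noise_sd SD of iid voxel noise added inside blocks.
#' @param seed Integer seed.
#' @return List with `vol` (a [bold_volume_series]), `rois` (data frame of
#'   block-center seed coordinates, label/x_mm/y_mm/z_mm).
#' @export
series_to_volume <- function(rts, voxel_noise_sd = 0.2, seed = 1L) {
  set.seed(seed)
  R <- ncol(rts$values); Tn <- nrow(rts$values)
  if (R > 27L) stop("at most 27 regions supported")
  d <- c(12L, 12L, 12L)
  affine <- diag(c(3, 3, 3, 1)); affine[1:3, 4] <- -18
  arr <- array(stats::rnorm(prod(d) * Tn), c(d, Tn))
  lat <- as.matrix(expand.grid(1:3, 1:3, 1:3))[seq_len(R), , drop = FALSE]
  centers <- matrix(NA_real_, R, 3)
  for (r in seq_len(R)) {
    st <- 2L + 4L * (lat[r, ] - 1L)           # block start voxel (1-based)
    ix <- st[1]:(st[1] + 2L); iy <- st[2]:(st[2] + 2L); iz <- st[3]:(st[3] + 2L)
    blk <- array(rep(rts$values[, r], each = 27L), c(3, 3, 3, Tn)) +
      array(stats::rnorm(27 * Tn, sd = voxel_noise_sd), c(3, 3, 3, Tn))
    arr[ix, iy, iz, ] <- blk
    centers[r, ] <- voxel_to_mni(st, affine)  # st is the 0-based center
  }
  vol <- bold_volume_series(arr, affine, rts$tr_seconds)
  list(vol = vol,
       rois = data.frame(label = rts$labels, x_mm = centers[, 1],
                         y_mm = centers[, 2], z_mm = centers[, 3]))
}

#' Write a synthetic cohort to a directory
#'
#' Emits the cohort TSV, one time-series TSV and one motion TSV per scan,
#' and the ground truth as JSON.
#'
#' @param x A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (key in names(x$roi_series)) {
    write_series_tsv(x$roi_series[[key]],
                     file.path(dir, paste0(key, "_series.tsv")))
    utils::write.table(x$motion[[key]],
                       file.path(dir, paste0(key, "_motion.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(x$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
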