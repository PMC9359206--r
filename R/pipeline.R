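# End-to-end orchestration: simulate -> motion QC -> variability -> group
# statistics -> prediction, from a single validated configuration with a
# master seed, writing a manifest of outputs and checksums.

#' Default pipeline configuration
#'
#' All defaults mirror the analysis parameters of the emulated study
#' design: 50-TR windows sliding by 1 TR, 0.01-0.08 Hz band, 3 mm / 3
#' degree motion exclusion, height p 0.005 with cluster alpha 0.05, and
#' the default SVR grids.
#'
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_per_group = 10L, T = 250L, tr_seconds = 2,
                    n_regions = 12L, effect_delta = 0.3,
                    noise_sd = 0.3, qc_fail_fraction = 0),
    filter = list(low_hz = 0.01, high_hz = 0.08),
    window = list(length_tr = 50L, step_tr = 1L),
    qc = list(max_trans_mm = 3.0, max_rot_deg = 3.0),
    stats = list(height_p = 0.005, cluster_alpha = 0.05,
                 use_covariates = TRUE),
    predict = list(enabled = TRUE, kernel = "radial",
                   c_grid = 10^(-2:4), gamma_grid = 10^(-4:1),
                   epsilon = 0.01, max_features = 9L)
  )
}

known_config_keys <- list(
  top = c("seed", "simulate", "filter", "window", "qc", "stats", "predict"),
  simulate = c("n_per_group", "T", "tr_seconds", "n_regions", "effect_delta",
               "noise_sd", "qc_fail_fraction"),
  filter = c("low_hz", "high_hz"),
  window = c("length_tr", "step_tr"),
  qc = c("max_trans_mm", "max_rot_deg"),
  stats = c("height_p", "cluster_alpha", "use_covariates"),
  predict = c("enabled", "kernel", "c_grid", "gamma_grid", "epsilon",
              "max_features"))

#' Validate a pipeline configuration
#'
#' Checks every parameter against its module's preconditions, including
#' the window-length rule `length_tr >= min_window_length(low_hz, TR)`.
#' Violations are returned as data, not raised.
#'
#' @param config Configuration list (see [default_run_config]); may come
#'   from [read_run_config].
#' @return Character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  unknown <- setdiff(names(config), known_config_keys$top)
  if (length(unknown)) add(paste("unknown config keys:",
                                 paste(unknown, collapse = ", ")))
  for (sec in intersect(names(config), setdiff(known_config_keys$top, "seed"))) {
    u <- setdiff(names(config[[sec]]), known_config_keys[[sec]])
    if (length(u)) add(paste0("unknown keys in ", sec, ": ",
                              paste(u, collapse = ", ")))
  }
  s <- config$simulate; f <- config$filter; w <- config$window
  if (!is.null(s)) {
    if (isTRUE(s$tr_seconds <= 0)) add("simulate.tr_seconds must be positive")
    if (isTRUE(s$n_per_group < 3)) add("simulate.n_per_group must be >= 3")
    if (isTRUE(s$effect_delta <= 0) || isTRUE(s$effect_delta > 1))
      add("simulate.effect_delta must be in (0, 1]")
    if (isTRUE(s$noise_sd <= 0)) add("simulate.noise_sd must be positive")
  }
  if (!is.null(f) && !is.null(s) && isTRUE(s$tr_seconds > 0)) {
    nyq <- 1 / (2 * s$tr_seconds)
    if (isTRUE(f$low_hz <= 0) || isTRUE(f$high_hz <= f$low_hz))
      add("filter band must satisfy 0 < low_hz < high_hz")
    else if (isTRUE(f$high_hz >= nyq))
      add(paste0("filter.high_hz must be below Nyquist (", nyq, " Hz)"))
  }
  if (!is.null(w)) {
    if (isTRUE(w$length_tr < 2)) add("window.length_tr must be >= 2")
    if (isTRUE(w$step_tr < 1)) add("window.step_tr must be >= 1")
    if (!is.null(s) && !is.null(f) &&
        isTRUE(s$tr_seconds > 0) && isTRUE(f$low_hz > 0) &&
        isTRUE(w$length_tr < min_window_length(f$low_hz, s$tr_seconds)))
      add(paste0("window.length_tr (", w$length_tr,
                 ") < 1/fmin = ", min_window_length(f$low_hz, s$tr_seconds),
                 " TR"))
    if (!is.null(s) && isTRUE(w$length_tr > s$T))
      add("window.length_tr exceeds the series length")
  }
  st <- config$stats
  if (!is.null(st)) {
    if (isTRUE(st$height_p <= 0) || isTRUE(st$height_p >= 1))
      add("stats.height_p must be in (0, 1)")
    if (isTRUE(st$cluster_alpha <= 0) || isTRUE(st$cluster_alpha >= 1))
      add("stats.cluster_alpha must be in (0, 1)")
  }
  p <- config$predict
  if (!is.null(p) && isTRUE(p$enabled)) {
    if (!is.null(p$kernel) && !p$kernel %in% c("radial", "linear"))
      add("predict.kernel must be radial or linear")
    if (isTRUE(any(p$c_grid <= 0))) add("predict.c_grid must be positive")
    if (isTRUE(any(p$gamma_grid <= 0)))
      add("predict.gamma_grid must be positive")
  }
  v
}

#' Read a YAML pipeline configuration
#'
#' Values present in the file override the defaults section-wise.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = user$seed %||% 1L)
  for (sec in setdiff(known_config_keys$top, "seed"))
    if (!is.null(user[[sec]]))
      cfg[[sec]] <- utils::modifyList(cfg[[sec]], user[[sec]])
  extra <- setdiff(names(user), known_config_keys$top)
  for (k in extra) cfg[[k]] <- user[[k]]   # surfaced by validate_config
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes the stages in fixed order: simulate, motion QC (excluded
#' subjects dropped), region-wise temporal variability, group x time
#' interaction scan with post-hoc paired tests, variability-connectivity
#' coupling, and (optionally) SVR prediction of the negative-symptom
#' remission ratio from baseline variability on the pairs flagged by the
#' interaction scan. Writes per-stage outputs and a JSON manifest with
#' MD5 checksums; identical config and seed give identical checksums.
#'
#' @param config Configuration list (validated first; violations abort).
#' @param out_dir Output directory.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      qdir <- file.path(out_dir, "quarantine")
      dir.create(qdir, showWarnings = FALSE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs retained under ", out_dir, ")")
    })
  }
  files <- character(0)
  emit <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files <<- c(files, path)
    path
  }

  logf("stage simulate: seed ", config$seed)
  cohort <- stage("simulate", {
    s <- config$simulate
    des <- cohort_design(n_per_group = s$n_per_group, T = s$T,
                         tr_seconds = s$tr_seconds, n_regions = s$n_regions,
                         effect_delta = s$effect_delta, noise_sd = s$noise_sd,
                         qc_fail_fraction = s$qc_fail_fraction,
                         seed = config$seed)
    generate_cohort(des)
  })
  emit(cohort$cohort, "cohort.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))

  logf("stage qc")
  qc <- stage("qc", {
    lapply(cohort$motion, qc_exclude, max_trans_mm = config$qc$max_trans_mm,
           max_rot_deg = config$qc$max_rot_deg)
  })
  excluded_scans <- names(qc)[vapply(qc, `[[`, TRUE, "excluded")]
  excluded_subjects <- unique(sub("_t[12]$", "", excluded_scans))
  logf("qc excluded ", length(excluded_subjects), " subject(s)")
  keep_rows <- !(cohort$cohort$subject_id %in% excluded_subjects)
  cohort_kept <- cohort$cohort[keep_rows, ]

  logf("stage variability")
  scheme <- window_scheme(config$window$length_tr, config$window$step_tr)
  var_list <- stage("variability", {
    keys <- paste0(cohort_kept$subject_id, "_", cohort_kept$timepoint)
    out <- lapply(keys, function(k)
      roi_variability_matrix(cohort$roi_series[[k]], scheme))
    names(out) <- keys
    out
  })
  fc_list <- lapply(names(var_list), function(k)
    mean_fc_matrix(cohort$roi_series[[k]], scheme))
  names(fc_list) <- names(var_list)

  logf("stage stats")
  stats_out <- stage("stats", {
    po <- pair_outcomes(var_list, cohort_kept)
    covs <- if (isTRUE(config$stats$use_covariates)) default_covariates
            else NULL
    if (length(covs)) {
      # covariates that are constant in this (possibly QC-reduced) sample
      # carry no information and would only break the fit
      t1rows <- po$cohort[po$cohort$timepoint == "t1", ]
      t1rows$sex01 <- as.integer(t1rows$sex == "M")
      keepc <- vapply(covs, function(cn)
        stats::sd(t1rows[[cn]]) > 0, TRUE)
      if (any(!keepc))
        logf("dropping constant covariate(s): ",
             paste(covs[!keepc], collapse = ", "))
      covs <- covs[keepc]
      if (!length(covs)) covs <- NULL
    }
    scan <- interaction_scan(po, covariates = covs)
    sig <- scan$pair[scan$p_value < config$stats$height_p]
    tsz <- paired_t_scan(po, "TSZ")
    coup <- variability_fc_coupling(unname(var_list), unname(fc_list))
    list(scan = scan, significant_pairs = sig, paired_tsz = tsz,
         coupling = coup)
  })
  emit(stats_out$scan, "interaction_scan.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit(stats_out$paired_tsz, "paired_t_tsz.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))

  pred_summary <- NULL
  if (isTRUE(config$predict$enabled) &&
      length(stats_out$significant_pairs) >= 1L) {
    logf("stage predict: ", length(stats_out$significant_pairs),
         " selected pair(s)")
    pred <- stage("predict", {
      sel <- utils::head(stats_out$significant_pairs,
                         config$predict$max_features)
      cfg <- svr_config(kernel = config$predict$kernel,
                        c_grid = config$predict$c_grid,
                        gamma_grid = config$predict$gamma_grid,
                        epsilon = config$predict$epsilon)
      predict_response_pipeline(var_list, cohort_kept, sel, config = cfg)
    })
    pred_summary <- pred$summary
    emit(pred_summary, "prediction_summary.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dfcvar")),
    seed = config$seed,
    config = config,
    qc_excluded_subjects = excluded_subjects,
    coupling = stats_out$coupling,
    significant_pairs = stats_out$significant_pairs,
    prediction = pred_summary,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logf("done: ", length(files), " output file(s)")
  invisible(manifest)
}
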