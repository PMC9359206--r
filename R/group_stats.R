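# Group-level inference for two-group (TSZ vs DSZ), two-timepoint (t1, t2)
# longitudinal designs: the group x time interaction via the change-score
# GLM, post-hoc t-tests with the decrease-positive sign convention,
# remission ratios, partial Spearman brain-behaviour correlation and the
# variability-connectivity coupling check.

#' Symptom remission ratio
#'
#' `RR = (score_t1 - score_t2) / score_t1`; positive values mean
#' improvement. Defined only for positive baseline scores.
#'
#' @param score_t1,score_t2 Numeric scalars or vectors.
#' @return Numeric remission ratio(s).
#' @export
remission_ratio <- function(score_t1, score_t2) {
  if (any(score_t1 <= 0, na.rm = TRUE))
    stop("domain error: baseline score must be positive")
  (score_t1 - score_t2) / score_t1
}

#' Relative change in temporal variability
#'
#' `(I_t2 - I_t1) / I_t1`; negative values mean a variability reduction
#' after treatment.
#'
#' @param i_t1,i_t2 Numeric baseline and follow-up variability values.
#' @return Numeric relative change(s).
#' @export
delta_variability <- function(i_t1, i_t2) {
  if (any(i_t1 <= 0, na.rm = TRUE))
    stop("domain error: baseline variability must be positive")
  (i_t2 - i_t1) / i_t1
}

default_covariates <- c("age_years", "sex01", "illness_duration_months",
                        "education_years", "cpz_equiv_mg_per_day")

# Reshape a long outcome table (one row per subject x timepoint) into one
# row per subject with the within-subject change score.
change_scores <- function(data) {
  need <- c("subject_id", "group", "timepoint", "outcome")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("validation error: missing columns ", paste(miss, collapse = ", "))
  if (!all(data$timepoint %in% c("t1", "t2")))
    stop("validation error: timepoint must be t1/t2")
  wide <- merge(data[data$timepoint == "t1", setdiff(names(data), "timepoint")],
                data[data$timepoint == "t2", c("subject_id", "outcome")],
                by = "subject_id", suffixes = c("_t1", "_t2"))
  both <- table(data$subject_id)
  if (any(both != 2L))
    stop("validation error: subject(s) missing a timepoint: ",
         paste(names(both)[both != 2L], collapse = ", "))
  wide$delta <- wide$outcome_t2 - wide$outcome_t1
  if ("sex" %in% names(wide) && !"sex01" %in% names(wide))
    wide$sex01 <- as.integer(wide$sex == "M")
  wide
}

#' Group x time interaction test (repeated-measures ANCOVA)
#'
#' In a balanced two-timepoint design the repeated-measures ANCOVA
#' interaction between group and time is algebraically the group effect in
#' the change-score GLM: `delta = outcome_t2 - outcome_t1` regressed on
#' group plus the between-subject covariates. The reported F is the partial
#' F for group given the covariates.
#'
#' @param data Long-format data frame with columns `subject_id`, `group`
#'   (two levels), `timepoint` (`t1`/`t2`), `outcome`, and covariate
#'   columns (constant within subject). `sex` (`F`/`M`) is recoded to a 0/1
#'   `sex01` column automatically.
#' @param covariates Character vector of covariate column names; use
#'   `NULL`/`character(0)` for the unadjusted (repeated-measures ANOVA)
#'   variant.
#' @return List of class `interaction_result`: `f_value`, `p_value`, `df`
#'   (numerator, denominator).
#' @export
rm_ancova_interaction <- function(data, covariates = default_covariates) {
  wide <- change_scores(data)
  groups <- unique(wide$group)
  if (length(groups) != 2L)
    stop("validation error: need exactly 2 groups, got ",
         length(groups))
  if (min(table(wide$group)) < 2L)
    stop("validation error: need >= 2 subjects per group")
  if (is.null(covariates)) covariates <- character(0)
  miss <- setdiff(covariates, names(wide))
  if (length(miss))
    stop("validation error: missing covariates ", paste(miss, collapse = ", "))
  wide$group <- factor(wide$group)
  f_full <- stats::as.formula(paste(
    "delta ~ group", if (length(covariates))
      paste("+", paste(covariates, collapse = " + ")) else ""))
  f_red <- stats::as.formula(paste(
    "delta ~", if (length(covariates))
      paste(covariates, collapse = " + ") else "1"))
  fit_full <- stats::lm(f_full, data = wide)
  if (any(is.na(stats::coef(fit_full)))) {
    bad <- names(stats::coef(fit_full))[is.na(stats::coef(fit_full))]
    stop("degeneracy error: collinear model columns: ",
         paste(bad, collapse = ", "))
  }
  fit_red <- stats::lm(f_red, data = wide)
  an <- stats::anova(fit_red, fit_full)
  out <- list(f_value = an$F[2], p_value = an$`Pr(>F)`[2],
              df = c(an$Df[2], an$Res.Df[2]))
  class(out) <- "interaction_result"
  out
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("<interaction_result> F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f_value, x$p_value))
  invisible(x)
}

#' Post-hoc t-tests for the two-group, two-timepoint design
#'
#' Within each group a paired t-test of t1 vs t2 (so a decrease at t2
#' yields a positive t), a two-sample t-test between the groups at each
#' timepoint, and optionally two-sample t-tests of each group at each
#' timepoint against a healthy-control reference vector.
#'
#' @param data Long-format data frame as in [rm_ancova_interaction].
#' @param hc_outcome Optional numeric vector of healthy-control outcomes.
#' @return Data frame with columns `contrast`, `t`, `df`, `p`.
#' @export
posthoc_tests <- function(data, hc_outcome = NULL) {
  groups <- sort(unique(data$group))
  if (length(groups) != 2L) stop("need exactly 2 groups")
  rows <- list()
  for (g in groups) {
    d <- data[data$group == g, ]
    x1 <- d$outcome[d$timepoint == "t1"][order(d$subject_id[d$timepoint == "t1"])]
    x2 <- d$outcome[d$timepoint == "t2"][order(d$subject_id[d$timepoint == "t2"])]
    if (length(x1) < 2L) stop("group sizes must be >= 2")
    if (stats::sd(x1 - x2) == 0) {
      if (all(x1 == x2)) {
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = paste0(g, ": t1 vs t2 (paired)"),
          t = 0, df = length(x1) - 1L, p = 1)
        next
      }
      stop("degenerate-test error: zero within-pair variance in group ", g)
    }
    tt <- stats::t.test(x1, x2, paired = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = paste0(g, ": t1 vs t2 (paired)"),
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }
  for (tp in c("t1", "t2")) {
    a <- data$outcome[data$group == groups[1] & data$timepoint == tp]
    b <- data$outcome[data$group == groups[2] & data$timepoint == tp]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = paste0(groups[1], " vs ", groups[2], " at ", tp),
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
    if (!is.null(hc_outcome)) {
      for (g in groups) {
        x <- data$outcome[data$group == g & data$timepoint == tp]
        tt <- stats::t.test(x, hc_outcome, var.equal = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = paste0(g, " at ", tp, " vs HC"),
          t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x` and `y`, residualizes both on an intercept plus the
#' (unranked) covariates, and reports the Pearson correlation of the
#' residuals with a t-based p-value on `n - k - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @return List with `rho`, `p`, `df`.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2L)
    stop("need more observations than covariates + 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate error: constant input vector")
  rx <- rank(x); ry <- rank(y)
  if (!is.null(covariates)) {
    Z <- cbind(1, as.matrix(covariates))
    rx <- stats::lm.fit(Z, rx)$residuals
    ry <- stats::lm.fit(Z, ry)$residuals
  } else {
    rx <- rx - mean(rx); ry <- ry - mean(ry)
  }
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - k - 2L
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       df = df)
}

upper_tri_values <- function(m) {
  v <- if (is.list(m) && !is.null(m$values)) m$values else as.matrix(m)
  v[upper.tri(v)]
}

#' Coupling between temporal variability and mean connectivity
#'
#' Pearson correlation, across region pairs, of group-mean temporal
#' variability against group-mean windowed connectivity. A negative r means
#' that strongly connected pairs fluctuate less.
#'
#' @param var_mats A `variability_matrix` (or its `values`), or a list of
#'   them (averaged across subjects).
#' @param fc_mats A matching `fc_matrix` or list of them.
#' @return List with `r`, `p`, `n_pairs`.
#' @export
variability_fc_coupling <- function(var_mats, fc_mats) {
  avg <- function(ms) {
    if (is.list(ms) && is.null(ms$values)) {
      vs <- lapply(ms, upper_tri_values)
      Reduce(`+`, vs) / length(vs)
    } else upper_tri_values(ms)
  }
  labs <- function(ms) {
    m <- if (is.list(ms) && is.null(ms$values)) ms[[1]] else ms
    if (is.list(m) && !is.null(m$labels)) m$labels else NULL
  }
  l1 <- labs(var_mats); l2 <- labs(fc_mats)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("validation error: variability and FC matrices have mismatched labels")
  iv <- avg(var_mats); fv <- avg(fc_mats)
  if (length(iv) != length(fv))
    stop("validation error: matrices of different size")
  if (length(iv) < 3L) stop("need at least 3 region pairs")
  ct <- stats::cor.test(iv, fv)
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = length(iv))
}

#' Per-pair outcome matrix from subject-level variability matrices
#'
#' Assembles, for each cohort record, the upper-triangle entries of that
#' subject/timepoint's variability matrix, giving an `[n_records x n_pairs]`
#' outcome matrix aligned with the cohort rows.
#'
#' @param var_list Named list of `variability_matrix` objects keyed
#'   `"<subject_id>_<timepoint>"`.
#' @param cohort Cohort data frame ([validate_cohort_table] layout); HC rows
#'   are dropped.
#' @return List with `outcomes` (matrix), `cohort` (patient rows used),
#'   `pair_labels`.
#' @export
pair_outcomes <- function(var_list, cohort) {
  pat <- cohort[cohort$group %in% c("TSZ", "DSZ"), , drop = FALSE]
  keys <- paste0(pat$subject_id, "_", pat$timepoint)
  miss <- setdiff(keys, names(var_list))
  if (length(miss))
    stop("missing variability matrices for: ", paste(miss, collapse = ", "))
  labels <- var_list[[keys[1]]]$labels
  outcomes <- t(vapply(keys, function(k) upper_tri_values(var_list[[k]]),
                       numeric(length(labels) * (length(labels) - 1) / 2)))
  list(outcomes = outcomes, cohort = pat, pair_labels = pair_labels(labels))
}

#' Interaction scan over region pairs
#'
#' Runs [rm_ancova_interaction] for every region pair and returns a tidy
#' table of F and p per pair.
#'
#' @param po Result of [pair_outcomes].
#' @param covariates Covariate names passed to [rm_ancova_interaction].
#' @return Data frame with `pair`, `f_value`, `p_value`.
#' @export
interaction_scan <- function(po, covariates = default_covariates) {
  base <- po$cohort
  base$sex01 <- as.integer(base$sex == "M")
  res <- lapply(seq_along(po$pair_labels), function(p) {
    d <- base
    d$outcome <- po$outcomes[, p]
    r <- rm_ancova_interaction(d, covariates)
    data.frame(pair = po$pair_labels[p], f_value = r$f_value,
               p_value = r$p_value)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Paired t-statistics (t1 vs t2) per region pair for one group
#'
#' @param po Result of [pair_outcomes].
#' @param group Group to test ("TSZ" or "DSZ").
#' @return Data frame with `pair`, `t`, `p`; positive t means the
#'   variability decreased at t2.
#' @export
paired_t_scan <- function(po, group = "TSZ") {
  sel <- po$cohort$group == group
  d <- po$cohort[sel, ]
  o <- po$outcomes[sel, , drop = FALSE]
  i1 <- order(d$subject_id[d$timepoint == "t1"])
  i2 <- order(d$subject_id[d$timepoint == "t2"])
  x1 <- o[d$timepoint == "t1", , drop = FALSE][i1, , drop = FALSE]
  x2 <- o[d$timepoint == "t2", , drop = FALSE][i2, , drop = FALSE]
  res <- lapply(seq_along(po$pair_labels), function(p) {
    tt <- stats::t.test(x1[, p], x2[, p], paired = TRUE)
    data.frame(pair = po$pair_labels[p], t = unname(tt$statistic),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
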