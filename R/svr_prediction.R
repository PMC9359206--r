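# Leave-one-out, grid-searched support vector regression for predicting
# per-subject treatment response (symptom remission ratios) from baseline
# temporal-variability features. Feature standardization is estimated on
# each training fold only, so held-out predictions carry no information
# about the left-out subject.

#' Two-standard-deviation outlier exclusion
#'
#' Single-pass rule: mean and sample SD are computed once on the full
#' vector, and entries with `|value - mean| > 2 * SD` are excluded. With
#' zero SD nothing is excluded.
#'
#' @param values Numeric vector (n >= 3).
#' @return List with integer index vectors `kept` and `excluded`.
#' @export
exclude_outliers <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values")
  m <- mean(values); s <- stats::sd(values)
  if (s == 0) return(list(kept = seq_len(n), excluded = integer(0)))
  out <- abs(values - m) > 2 * s
  list(kept = which(!out), excluded = which(out))
}

#' SVR configuration
#'
#' @param kernel "radial" (RBF; the default, matching grid-searched C and
#'   gamma) or "linear".
#' @param c_grid Positive cost grid (default log-spaced 1e-2..1e4).
#' @param gamma_grid Positive RBF width grid (default log-spaced 1e-4..1e1;
#'   ignored for the linear kernel).
#' @param epsilon Epsilon-insensitive tube width (default 0.01). The tube
#'   must be small relative to the target spread: remission ratios vary on
#'   a scale of roughly 0.05-0.15, and a wider tube can swallow the whole
#'   target range, leaving a degenerate fit with no support vectors.
#' @return Object of class `svr_config`.
#' @export
svr_config <- function(kernel = c("radial", "linear"),
                       c_grid = 10^(-2:4), gamma_grid = 10^(-4:1),
                       epsilon = 0.01) {
  kernel <- match.arg(kernel)
  if (!length(c_grid) || any(c_grid <= 0)) stop("c_grid must be positive")
  if (kernel == "radial" && (!length(gamma_grid) || any(gamma_grid <= 0)))
    stop("gamma_grid must be positive")
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(list(kernel = kernel, c_grid = sort(c_grid),
                 gamma_grid = if (kernel == "radial") sort(gamma_grid) else NA,
                 epsilon = epsilon),
            class = "svr_config")
}

# LOOCV predictions for one (C, gamma) point; fold-wise z-scoring.
loocv_predict <- function(X, y, cost, gamma, kernel, epsilon) {
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Ztr <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
    Zte <- matrix((X[i, ] - mu) / sdv, nrow = 1)
    fit <- e1071::svm(Ztr, y[-i], type = "eps-regression", kernel = kernel,
                      cost = cost,
                      gamma = if (kernel == "radial") gamma else 1 / ncol(X),
                      epsilon = epsilon, scale = FALSE)
    # all training targets inside the epsilon tube -> no support vectors;
    # the fitted function is flat, i.e. the training mean
    pred[i] <- if (fit$tot.nSV == 0) mean(y[-i]) else stats::predict(fit, Zte)
  }
  pred
}

#' Grid-searched leave-one-out SVR
#'
#' For every grid point the full LOOCV is run (train on n-1 subjects,
#' predict the held-out subject, standardizing features with training-fold
#' statistics only); the grid point minimizing the LOOCV mean squared error
#' is selected, ties broken towards the smallest C then the smallest gamma
#' (preferring smoother models). The selected point's held-out predictions
#' are evaluated with the Pearson correlation between predicted and actual
#' values and its t-based p-value.
#'
#' @param features Numeric matrix `[n x q]` of baseline features (no
#'   missing entries).
#' @param target Numeric response vector of length n.
#' @param config An [svr_config].
#' @return Object of class `prediction_result`: `predicted`, `actual`,
#'   `best_c`, `best_gamma`, `cv_mse`, `r`, `p`.
#' @export
loocv_grid_svr <- function(features, target, config = svr_config()) {
  X <- as.matrix(features)
  y <- as.numeric(target)
  n <- nrow(X)
  if (n < 5L) stop("sample-size error: need n >= 5, got ", n)
  if (length(y) != n) stop("target length != feature rows")
  if (anyNA(X) || anyNA(y)) stop("missing values in features or target")
  if (stats::sd(y) == 0) stop("degenerate-target error: constant target")
  gammas <- if (config$kernel == "radial") config$gamma_grid else NA_real_
  grid <- expand.grid(gamma = gammas, cost = config$c_grid)
  best <- NULL
  for (gi in seq_len(nrow(grid))) {
    pred <- loocv_predict(X, y, grid$cost[gi], grid$gamma[gi],
                          config$kernel, config$epsilon)
    mse <- mean((pred - y)^2)
    # strict < keeps the first (smallest C, then smallest gamma) on ties,
    # because the grid is iterated cost-major over sorted values
    if (is.null(best) || mse < best$mse - 1e-12)
      best <- list(mse = mse, pred = pred, cost = grid$cost[gi],
                   gamma = grid$gamma[gi])
  }
  ct <- stats::cor.test(best$pred, y)
  out <- list(predicted = best$pred, actual = y,
              best_c = best$cost, best_gamma = best$gamma,
              cv_mse = best$mse, r = unname(ct$estimate), p = ct$p.value)
  class(out) <- "prediction_result"
  out
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "<prediction_result> n = %d, best C = %g, gamma = %g, LOOCV MSE = %.4g, r(predicted, actual) = %.3f (p = %.4g)\n",
    length(x$actual), x$best_c, x$best_gamma, x$cv_mse, x$r, x$p))
  invisible(x)
}

#' Predict treatment response from baseline variability patterns
#'
#' Builds the feature matrix from baseline (t1) temporal variability of the
#' treated group on the selected region pairs, computes the remission ratio
#' of each symptom subscale, applies the two-SD outlier rule to each target,
#' and runs the grid-searched LOOCV SVR per subscale.
#'
#' @param var_list Named list of `variability_matrix` objects keyed
#'   `"<subject_id>_<timepoint>"`.
#' @param cohort Cohort table; only the `group` subjects are used.
#' @param pair_selection Character vector of pair labels
#'   (`"roiA--roiB"`, as produced by the interaction/post-hoc scans), or a
#'   2-column matrix of region indices.
#' @param group Treated group (default "TSZ").
#' @param config An [svr_config].
#' @param outlier_mode "target" excludes outlying remission ratios before
#'   fitting (the default); "none" fits all subjects.
#' @return Named list (one `prediction_result` per subscale) plus a
#'   `summary` data frame of r/p per subscale.
#' @export
predict_response_pipeline <- function(var_list, cohort, pair_selection,
                                      group = "TSZ", config = svr_config(),
                                      outlier_mode = c("target", "none")) {
  outlier_mode <- match.arg(outlier_mode)
  cg <- cohort[cohort$group == group, ]
  t1 <- cg[cg$timepoint == "t1", ]
  t2 <- cg[cg$timepoint == "t2", ]
  t2 <- t2[match(t1$subject_id, t2$subject_id), ]
  if (nrow(t1) < 5L) stop("sample-size error: fewer than 5 treated subjects")
  labels <- var_list[[paste0(t1$subject_id[1], "_t1")]]$labels
  plabs <- pair_labels(labels)
  if (is.character(pair_selection)) {
    sel <- match(pair_selection, plabs)
    if (anyNA(sel))
      stop("unknown pair label(s): ",
           paste(pair_selection[is.na(sel)], collapse = ", "))
  } else {
    pm <- as.matrix(pair_selection)
    sel <- apply(pm, 1, function(ij) {
      i <- min(ij); j <- max(ij)
      which(plabs == paste(labels[i], labels[j], sep = "--"))
    })
  }
  X <- t(vapply(t1$subject_id, function(s)
    upper_tri_values(var_list[[paste0(s, "_t1")]])[sel],
    numeric(length(sel))))
  colnames(X) <- plabs[sel]
  subscales <- c(positive = "panss_positive", negative = "panss_negative",
                 general = "panss_general", total = "panss_total")
  results <- list()
  for (nm in names(subscales)) {
    col <- subscales[[nm]]
    rr <- remission_ratio(t1[[col]], t2[[col]])
    keep <- if (outlier_mode == "target") exclude_outliers(rr)$kept
            else seq_along(rr)
    if (length(keep) < 5L)
      stop("sample-size error: fewer than 5 subjects after outlier ",
           "exclusion for ", nm)
    res <- loocv_grid_svr(X[keep, , drop = FALSE], rr[keep], config)
    res$subject_ids <- t1$subject_id[keep]
    res$n_excluded <- length(rr) - length(keep)
    results[[nm]] <- res
  }
  results$summary <- data.frame(
    subscale = names(subscales),
    n = vapply(names(subscales), function(nm) length(results[[nm]]$actual),
               integer(1)),
    r = vapply(names(subscales), function(nm) results[[nm]]$r, numeric(1)),
    p = vapply(names(subscales), function(nm) results[[nm]]$p, numeric(1)),
    row.names = NULL)
  results
}
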