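test_that("remission ratio and variability change follow their formulas", {
  expect_equal(remission_ratio(20, 15), 0.25)
  expect_equal(remission_ratio(18, 18), 0)
  # group-mean consistency check on baseline/follow-up negative scores
  expect_equal(round(remission_ratio(23.56, 18.07), 4), 0.233)
  expect_error(remission_ratio(0, 5), "domain error")
  expect_equal(delta_variability(0.2, 0.1), -0.5)
  expect_equal(delta_variability(0.37, 0.37), 0)
  expect_error(delta_variability(0, 0.1), "domain error")
  # both are invariant to common positive rescaling
  expect_equal(remission_ratio(7 * 20, 7 * 15), remission_ratio(20, 15))
  expect_equal(delta_variability(3 * 0.2, 3 * 0.1),
               delta_variability(0.2, 0.1))
})

test_that("the interaction F equals a hand-computed change-score GLM F", {
  d <- data.frame(
    subject_id = rep(paste0("s", 1:8), each = 2),
    group = rep(c("TSZ", "DSZ"), each = 8),
    timepoint = rep(c("t1", "t2"), 8),
    outcome = c(1, 0.5, 2, 1.7, 1.5, 1.1, 1.8, 1.2,
                1.2, 1.3, 0.9, 1.0, 1.4, 1.2, 1.1, 1.15),
    age_years = rep(c(30, 40, 50, 35, 45, 55, 38, 42), each = 2))
  res <- rm_ancova_interaction(d, covariates = "age_years")
  # hand GLM: delta ~ group + age, partial F for group
  wide <- d[d$timepoint == "t1", ]
  wide$delta <- d$outcome[d$timepoint == "t2"] - d$outcome[d$timepoint == "t1"]
  rss <- function(X, y) {
    e <- y - X %*% solve(t(X) %*% X, t(X) %*% y)
    sum(e^2)
  }
  X1 <- cbind(1, wide$group == "TSZ", wide$age_years)
  X0 <- cbind(1, wide$age_years)
  f_hand <- (rss(X0, wide$delta) - rss(X1, wide$delta)) /
    (rss(X1, wide$delta) / (8 - 3))
  expect_equal(res$f_value, f_hand, tolerance = 1e-10)
  expect_equal(res$df, c(1, 5))
  expect_equal(res$p_value, pf(f_hand, 1, 5, lower.tail = FALSE))
})

test_that("interaction inference validates its inputs", {
  d <- make_long_outcome(6)
  expect_s3_class(rm_ancova_interaction(d, covariates = "age_years"),
                  "interaction_result")
  expect_error(rm_ancova_interaction(d[-1, ], covariates = NULL),
               "missing a timepoint")
  d2 <- d
  d2$age_years <- 1   # constant covariate collinear with intercept
  expect_error(rm_ancova_interaction(d2, covariates = "age_years"),
               "degeneracy|collinear")
})

test_that("interaction test keeps its nominal size under the null", {
  set.seed(41)
  p <- replicate(400, {
    d <- make_long_outcome(12, effect = 0, seed = sample.int(1e6, 1))
    rm_ancova_interaction(d, covariates = c("age_years", "sex01"))$p_value
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.08)
})

test_that("interaction test detects a planted group-specific change", {
  set.seed(42)
  # per-timepoint noise sd 1 makes sd(change) = sqrt(2); a 2-unit decrease
  # is a 1.41-SD change effect (noncentrality ~4.5, power ~0.9 at 0.005)
  p <- replicate(100, {
    d <- make_long_outcome(20, effect = 2, seed = sample.int(1e6, 1))
    rm_ancova_interaction(d, covariates = "age_years")$p_value
  })
  expect_gt(mean(p < 0.005), 0.8)
})

test_that("interaction result is invariant to subject row order", {
  d <- make_long_outcome(8, effect = 1, seed = 7)
  r1 <- rm_ancova_interaction(d, covariates = "age_years")
  set.seed(1)
  r2 <- rm_ancova_interaction(d[sample(nrow(d)), ],
                              covariates = "age_years")
  expect_equal(r1$f_value, r2$f_value)
})

test_that("post-hoc paired t uses the decrease-positive sign convention", {
  d <- make_long_outcome(6, seed = 3)
  # identical timepoints: t = 0, p = 1
  d0 <- d
  d0$outcome <- ave(d0$outcome, d0$subject_id)
  out0 <- posthoc_tests(d0)
  paired0 <- out0[grep("paired", out0$contrast), ]
  expect_equal(paired0$t, c(0, 0))
  expect_equal(paired0$p, c(1, 1))
  # a uniform decrease at t2 gives positive t
  d1 <- d
  dec <- d1$timepoint == "t2" & d1$group == "TSZ"
  d1$outcome[dec] <- d1$outcome[dec] - 2
  out1 <- posthoc_tests(d1)
  t_tsz <- out1$t[out1$contrast == "TSZ: t1 vs t2 (paired)"]
  expect_gt(t_tsz, 0)
  expect_lt(out1$p[out1$contrast == "TSZ: t1 vs t2 (paired)"], 0.005)
})

test_that("paired t matches the textbook formula on three pairs", {
  d <- data.frame(subject_id = rep(c("a", "b", "c"), each = 2),
                  group = "TSZ",
                  timepoint = rep(c("t1", "t2"), 3),
                  outcome = c(5, 4, 7, 5, 9, 7))
  d2 <- d; d2$subject_id <- paste0("x", d2$subject_id); d2$group <- "DSZ"
  out <- posthoc_tests(rbind(d, d2))
  diffs <- c(1, 2, 2)
  t_hand <- mean(diffs) / (sd(diffs) / sqrt(3))
  expect_equal(out$t[out$contrast == "TSZ: t1 vs t2 (paired)"], t_hand,
               tolerance = 1e-12)
})

test_that("healthy-control contrasts are included when a reference is given", {
  d <- make_long_outcome(5, seed = 9)
  out <- posthoc_tests(d, hc_outcome = rnorm(8, 10))
  expect_true(any(grepl("vs HC", out$contrast)))
  expect_equal(nrow(out[grepl("vs HC", out$contrast), ]), 4L)
})

test_that("partial Spearman is rank-invariant and recovers confounded links", {
  set.seed(43)
  x <- rnorm(30)
  expect_equal(spearman_partial(x, exp(x))$rho, 1)
  # planted confounding: naive association positive, direct link negative
  z <- rnorm(300)
  xc <- z + rnorm(300, 0, 0.5)
  y <- -1.0 * xc + 1.5 * z + rnorm(300, 0, 0.2)
  expect_gt(cor(xc, y, method = "spearman"), 0)
  expect_lt(spearman_partial(xc, y, covariates = cbind(z))$rho, -0.2)
  expect_error(spearman_partial(rep(1, 30), rnorm(30)), "degenerate")
})

test_that("partial Spearman keeps its nominal size", {
  set.seed(44)
  p <- replicate(300, {
    z <- matrix(rnorm(60), 30, 2)
    spearman_partial(rnorm(30), rnorm(30), covariates = z)$p
  })
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("variability-connectivity coupling detects exact affine relations", {
  set.seed(45)
  R <- 6
  v <- matrix(runif(R * R), R); v <- (v + t(v)) / 2; diag(v) <- 0
  fc <- -2 * v + 1; diag(fc) <- 1
  vm <- list(values = v, labels = letters[1:R])
  fm <- list(values = fc, labels = letters[1:R])
  out <- variability_fc_coupling(vm, fm)
  expect_equal(out$r, -1)
  expect_equal(out$n_pairs, R * (R - 1) / 2)
  fm_bad <- fm; fm_bad$labels <- rev(fm_bad$labels)
  expect_error(variability_fc_coupling(vm, fm_bad), "mismatched labels")
  # shuffling the pair structure destroys the relation on average
  rs <- replicate(30, {
    perm <- sample(R * (R - 1) / 2)
    iv <- v[upper.tri(v)]
    cor(iv, fc[upper.tri(fc)][perm])
  })
  expect_lt(mean(abs(rs)), 0.35)
})

test_that("pair scans recover the planted pairs on a small cohort", {
  des <- cohort_design(n_per_group = 10, seed = 46)
  ch <- generate_cohort(des)
  keys <- paste0(ch$cohort$subject_id, "_", ch$cohort$timepoint)
  var_list <- lapply(keys, function(k)
    roi_variability_matrix(ch$roi_series[[k]]))
  names(var_list) <- keys
  po <- pair_outcomes(var_list, ch$cohort)
  expect_equal(ncol(po$outcomes), 66L)
  expect_equal(nrow(po$outcomes), nrow(po$cohort))
  scan <- interaction_scan(po)
  resp <- c("roi01--roi02", "roi03--roi04", "roi05--roi06")
  # the planted pairs dominate the ranking
  expect_true(all(resp %in% scan$pair[order(scan$p_value)][1:5]))
  tsz <- paired_t_scan(po, "TSZ")
  expect_true(all(tsz$t[tsz$pair %in% resp] > 0))
})
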