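test_that("state model validation rejects malformed inputs", {
  S <- diag(2)
  expect_s3_class(state_model(list(S, S), matrix(0.5, 2, 2)), "state_model")
  bad_cov <- matrix(c(1, 2, 2, 1), 2)          # not PSD
  expect_error(state_model(list(bad_cov), matrix(1)), "positive")
  off_diag <- matrix(c(2, 0, 0, 2), 2)         # diagonal not 1
  expect_error(state_model(list(off_diag), matrix(1)), "unit diagonal")
  expect_error(state_model(list(S), matrix(c(0.5, 0.2), 1)), "transition")
  expect_error(state_model(list(S, S), matrix(c(0.9, 0.2, 0.2, 0.9), 2)),
               "sum to 1")
})

test_that("Markov state sequences behave at the degenerate corners", {
  m1 <- state_model(list(diag(2)), matrix(1))
  expect_equal(unique(sample_state_sequence(m1, 50, seed = 1)), 1L)
  mid <- state_model(list(diag(2), diag(2)), diag(2))
  s <- sample_state_sequence(mid, 100, seed = 2)
  expect_equal(length(unique(s)), 1L)   # identity transition never switches
})

test_that("Markov switch rate matches its binomial expectation", {
  m <- state_model(list(diag(2), diag(2)),
                   matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  s <- sample_state_sequence(m, 1e4, seed = 3)
  sw <- mean(diff(s) != 0)
  se <- sqrt(0.1 * 0.9 / (1e4 - 1))
  expect_lt(abs(sw - 0.1), 3 * se)
})

test_that("regular state sequences alternate with the requested dwell", {
  s <- regular_state_sequence(200, 25, seed = 4)
  runs <- rle(s)
  expect_true(all(runs$lengths[-c(1, length(runs$lengths))] == 25))
  expect_setequal(unique(s), c(1L, 2L))
  # switch count is controlled within one flip
  expect_lte(abs(length(runs$lengths) - 1 - 200 / 25), 1)
})

test_that("generated BOLD is reproducible and carries the planted covariance", {
  m <- default_state_model(n_regions = 4, responsive_pairs = list(c(1, 2)),
                           static_pairs = list(c(3, 4)))
  st <- rep(1L, 20000)
  a <- generate_roi_bold(m, st, noise_sd = 0.3, seed = 7)
  b <- generate_roi_bold(m, st, noise_sd = 0.3, seed = 7)
  expect_identical(a$values, b$values)
  expect_equal(apply(a$values, 2, sd), rep(1, 4), ignore_attr = TRUE)
  # state-1 correlation of the responsive pair, attenuated by white noise
  # of sd 0.3 (filter is common to both columns): rho / (1 + 0.3^2)
  expect_equal(cor(a$values[, 1], a$values[, 2]), -0.9 / 1.09,
               tolerance = 0.05)
  expect_equal(cor(a$values[, 3], a$values[, 4]), 0.5 / 1.09,
               tolerance = 0.05)
  # independent regions stay uncorrelated
  expect_lt(abs(cor(a$values[, 1], a$values[, 3])), 0.05)
})

test_that("cohort generation is deterministic and structurally consistent", {
  des <- cohort_design(n_per_group = 4, T = 100, seed = 5)
  c1 <- generate_cohort(des)
  c2 <- generate_cohort(des)
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(c1$roi_series[["S001_t1"]]$values,
                   c2$roi_series[["S001_t1"]]$values)
  expect_identical(c1$ground_truth, c2$ground_truth)
  # every cohort record has a matching series and motion table
  keys <- paste0(c1$cohort$subject_id, "_", c1$cohort$timepoint)
  expect_true(all(keys %in% names(c1$roi_series)))
  expect_true(all(keys %in% names(c1$motion)))
  # HC only at t1, patients at both timepoints
  expect_true(all(c1$cohort$timepoint[c1$cohort$group == "HC"] == "t1"))
  tab <- table(c1$cohort$subject_id[c1$cohort$group != "HC"])
  expect_true(all(tab == 2))
  # PANSS subscales within instrument bounds for patients
  pat <- c1$cohort[c1$cohort$group != "HC", ]
  expect_true(all(pat$panss_negative >= 7 & pat$panss_negative <= 49))
  expect_true(all(pat$panss_positive >= 7 & pat$panss_positive <= 49))
  expect_true(all(pat$panss_general >= 16 & pat$panss_general <= 112))
})

test_that("effect_delta = 1 plants no treatment effect", {
  des <- cohort_design(n_per_group = 4, T = 100, effect_delta = 1, seed = 6)
  ch <- generate_cohort(des)
  expect_true(all(ch$ground_truth$subjects$planted_drop == 0))
})

test_that("planted QC failures are flagged by qc_exclude", {
  des <- cohort_design(n_per_group = 10, T = 120, qc_fail_fraction = 0.3,
                       groups = "TSZ", seed = 8)
  ch <- generate_cohort(des)
  planted <- ch$ground_truth$subjects$subject_id[
    ch$ground_truth$subjects$qc_fail_planted]
  flagged <- unique(sub("_t[12]$", "", names(ch$motion)[
    vapply(ch$motion, function(m) qc_exclude(m)$excluded, TRUE)]))
  expect_setequal(flagged, planted)
  # clean traces stay within bounds
  clean <- setdiff(names(ch$motion),
                   as.vector(outer(planted, c("_t1", "_t2"), paste0)))
  expect_true(all(!vapply(ch$motion[clean],
                          function(m) qc_exclude(m)$excluded, TRUE)))
})

test_that("remission ratios in the cohort table track the planted link", {
  des <- cohort_design(n_per_group = 20, T = 60, seed = 9)
  ch <- generate_cohort(des)
  gt <- ch$ground_truth$subjects
  tsz <- gt$subject_id[gt$group == "TSZ"]
  t1 <- ch$cohort[ch$cohort$timepoint == "t1", ]
  t2 <- ch$cohort[ch$cohort$timepoint == "t2", ]
  rr <- remission_ratio(t1$panss_negative[match(tsz, t1$subject_id)],
                        t2$panss_negative[match(tsz, t2$subject_id)])
  planted <- gt$rr_negative_planted[match(tsz, gt$subject_id)]
  # integer PANSS rounding adds ~1/score jitter around the planted value
  expect_lt(max(abs(rr - planted)), 0.05)
  expect_gt(cor(rr, planted), 0.9)
  # the link ties response to the planted variability drop
  expect_gt(cor(planted, gt$planted_drop[match(tsz, gt$subject_id)]), 0.5)
})

test_that("variability computed by the analysis modules rises with switch rate", {
  # generator-level check across three dwell levels, Spearman over replicates
  sch <- window_scheme(50, 1)
  set.seed(10)
  lev <- c(200, 100, 50)
  med <- vapply(lev, function(dwell) {
    median(replicate(6, {
      m <- default_state_model(n_regions = 2,
                               responsive_pairs = list(c(1, 2)),
                               static_pairs = list())
      st <- regular_state_sequence(250, dwell)
      rb <- generate_roi_bold(m, st, noise_sd = 0.3)
      roi_variability_matrix(rb, sch)$values[1, 2]
    }))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("volume embedding round-trips region series through seed extraction", {
  des <- cohort_design(n_per_group = 3, T = 60, seed = 11)
  ch <- generate_cohort(des)
  sv <- series_to_volume(ch$roi_series[[1]], voxel_noise_sd = 0.05, seed = 2)
  rts <- extract_roi_series(sv$vol, sv$rois)
  expect_equal(rts$labels, ch$roi_series[[1]]$labels)
  # extracted series are noisy copies of the originals
  cors <- vapply(seq_len(ncol(rts$values)), function(j)
    cor(rts$values[, j], ch$roi_series[[1]]$values[, j]), numeric(1))
  expect_true(all(cors > 0.95))
})

test_that("cohort directories carry series, motion, table and ground truth", {
  des <- cohort_design(n_per_group = 3, T = 60, groups = "TSZ", seed = 12)
  ch <- generate_cohort(des)
  dir <- withr::local_tempdir()
  write_cohort_dir(ch, dir)
  expect_true(file.exists(file.path(dir, "cohort.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_true(file.exists(file.path(dir, "S001_t1_series.tsv")))
  back <- read_series_tsv(file.path(dir, "S001_t1_series.tsv"),
                          tr_seconds = 2)
  expect_equal(back$values, ch$roi_series[["S001_t1"]]$values,
               tolerance = 1e-6, ignore_attr = TRUE)
})
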