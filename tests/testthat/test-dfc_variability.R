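test_that("minimum window length is ceil((1/fmin)/TR)", {
  expect_equal(min_window_length(0.01, 2), 50L)
  expect_equal(min_window_length(0.05, 2), 10L)
  expect_equal(min_window_length(0.01, 3), 34L)   # ceiling of 33.3
  expect_error(min_window_length(0, 2), "parameter error")
  expect_error(min_window_length(0.01, -1), "parameter error")
})

test_that("window enumeration matches the count law", {
  w <- build_windows(250, window_scheme(50, 1))
  expect_equal(nrow(w), 201L)
  expect_equal(w[1, ], c(start = 1L, end = 50L))
  expect_equal(w[201, ], c(start = 201L, end = 250L))
  expect_equal(nrow(build_windows(50, window_scheme(50, 1))), 1L)
  w3 <- build_windows(60, window_scheme(50, 5))
  expect_equal(w3[, "start"], c(1L, 6L, 11L))
  expect_error(build_windows(40, window_scheme(50, 1)), "insufficient-data")
  expect_error(window_scheme(1, 1), "length_tr")
  expect_error(window_scheme(10, 0), "step_tr")
  # exhaustive check against direct enumeration
  for (T in c(10, 17, 23, 60)) for (L in c(2, 5, 9)) for (s in c(1, 3, 7)) {
    if (L > T) next
    starts <- seq(1, T - L + 1, by = s)
    expect_equal(nrow(build_windows(T, window_scheme(L, s))),
                 length(starts))
  }
})

test_that("windowed correlations agree with per-window cor()", {
  set.seed(11)
  x <- rnorm(80); y <- 0.5 * x + rnorm(80)
  for (p in list(c(8, 4), c(10, 1), c(20, 7))) {
    wc <- windowed_correlation(x, y, window_scheme(p[1], p[2]))
    expect_equal(wc$r, wc_oracle(x, y, p[1], p[2]), tolerance = 1e-12)
  }
  # toy 8-point pair with 4-TR windows, step 4
  x8 <- c(1, 2, 4, 3, 0, -1, 2, 5); y8 <- c(2, 1, 3, 5, 1, 0, 1, 4)
  wc8 <- windowed_correlation(x8, y8, window_scheme(4, 4))
  expect_equal(wc8$r, wc_oracle(x8, y8, 4, 4), tolerance = 1e-12)
})

test_that("self- and anti-correlation give r of 1 and -1 in every window", {
  x <- rnorm(60)
  expect_equal(windowed_correlation(x, x, window_scheme(10, 2))$r,
               rep(1, 26))
  expect_equal(windowed_correlation(x, -x, window_scheme(10, 2))$r,
               rep(-1, 26))
})

test_that("degenerate windows abort with the window index", {
  x <- rnorm(40); y <- rnorm(40)
  x[11:20] <- 7  # second window of a 10/10 scheme is constant
  expect_error(windowed_correlation(x, y, window_scheme(10, 10)),
               "degenerate-window error.*window 2")
})

test_that("temporal variability is the mean squared successive difference", {
  expect_equal(temporal_variability(rep(0.3, 17)), 0)
  expect_equal(temporal_variability(c(1, -1, 1)), 4)
  expect_equal(temporal_variability(c(0.2, 0.5, 0.1, 0.4)),
               (0.09 + 0.16 + 0.09) / 3)
  expect_error(temporal_variability(0.5), "insufficient-windows")
  # brute-force identity on random vectors
  set.seed(12)
  for (i in 1:50) {
    r <- runif(sample(2:40, 1), -1, 1)
    expect_equal(temporal_variability(r), tv_bruteforce(r))
  }
})

test_that("I is invariant to affine rescaling of the input series", {
  set.seed(13)
  x <- rnorm(100); y <- rnorm(100)
  sch <- window_scheme(20, 3)
  i0 <- temporal_variability(windowed_correlation(x, y, sch))
  i1 <- temporal_variability(windowed_correlation(3 * x - 7, y, sch))
  i2 <- temporal_variability(windowed_correlation(x, -2 * y + 1, sch))
  expect_equal(i1, i0, tolerance = 1e-10)
  # negating one series flips r_k but leaves squared differences intact
  expect_equal(i2, i0, tolerance = 1e-10)
  expect_lte(i0, 4)
})

test_that("the variability matrix equals looped pairwise computation", {
  set.seed(14)
  v <- matrix(rnorm(120 * 5), 120, 5)
  colnames(v) <- letters[1:5]
  sch <- window_scheme(30, 2)
  vm <- roi_variability_matrix(v, sch)
  expect_equal(vm$values, t(vm$values))
  expect_equal(diag(vm$values), setNames(rep(0, 5), letters[1:5]))
  expect_true(all(vm$values >= 0))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(vm$values[i, j],
                 temporal_variability(windowed_correlation(v[, i], v[, j],
                                                           sch)),
                 tolerance = 1e-12)
  }
  # identical columns give zero variability
  v2 <- cbind(a = v[, 1], b = v[, 1], c = v[, 2])
  expect_equal(roi_variability_matrix(v2, sch)$values["a", "b"], 0)
})

test_that("variability matrix is equivariant under column permutation", {
  set.seed(15)
  v <- matrix(rnorm(100 * 4), 100, 4)
  colnames(v) <- c("a", "b", "c", "d")
  sch <- window_scheme(25, 5)
  m1 <- roi_variability_matrix(v, sch)$values
  perm <- c(3, 1, 4, 2)
  m2 <- roi_variability_matrix(v[, perm], sch)$values
  expect_equal(m2, m1[perm, perm], tolerance = 1e-12)
})

test_that("mean windowed FC matches long-run correlation for static coupling", {
  set.seed(16)
  T <- 2000; rho <- 0.6
  z <- rnorm(T)
  v <- cbind(a = z, b = rho * z + sqrt(1 - rho^2) * rnorm(T))
  fc <- mean_fc_matrix(v, window_scheme(50, 10))
  expect_equal(fc$values["a", "b"], cor(v[, 1], v[, 2]), tolerance = 0.05)
  expect_equal(diag(fc$values), setNames(c(1, 1), c("a", "b")))
  # identical columns
  v2 <- cbind(a = z, b = z)
  expect_equal(mean_fc_matrix(v2, window_scheme(50, 10))$values["a", "b"], 1)
})

test_that("temporal variability rises with the state-switching rate", {
  # three switching rates in the identifiable (slower-than-window) regime
  sch <- window_scheme(50, 1)
  set.seed(17)
  med_i <- vapply(c(250, 100, 50), function(dwell) {
    median(replicate(8, {
      st <- regular_state_sequence(250, dwell)
      rho <- c(-0.9, 0.9)[st]
      z1 <- rnorm(250); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(250)
      f <- bandpass(cbind(z1, z2) + matrix(rnorm(500, 0, 0.3), 250), 2)
      temporal_variability(windowed_correlation(f[, 1], f[, 2], sch))
    }))
  }, numeric(1))
  expect_true(all(diff(med_i) > 0))
})

test_that("seed-to-voxel maps are block-size invariant and zero at the seed", {
  des <- cohort_design(n_per_group = 3, T = 80, seed = 21)
  ch <- generate_cohort(des)
  sv <- series_to_volume(ch$roi_series[[1]], seed = 5)
  sch <- window_scheme(30, 5)
  seed_mni <- as.numeric(sv$rois[1, c("x_mm", "y_mm", "z_mm")])
  m1 <- seed_variability_map(sv$vol, seed_mni, sch, block_size = 4096L)
  m2 <- seed_variability_map(sv$vol, seed_mni, sch, block_size = 7L)
  expect_identical(m1$values, m2$values)
  ctr <- mni_to_voxel(seed_mni, sv$vol$affine) + 1L
  expect_equal(m1$values[ctr[1], ctr[2], ctr[3]], 0)
  expect_true(all(m1$values[!is.na(m1$values)] >= 0))
  # voxels of a block driven by the same region as the seed have lower I
  # against the seed than unrelated background voxels
  blk <- m1$values[ctr[1] + 1, ctr[2], ctr[3]]
  bg <- m1$values[6, 6, 6]
  expect_true(is.finite(blk) && is.finite(bg))
})
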