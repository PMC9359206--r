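# Shared fixtures, built in code.

# 3 mm isotropic affine with a given origin (mm of voxel 0,0,0).
mni3_affine <- function(origin = c(-18, -18, -18)) {
  a <- diag(c(3, 3, 3, 1))
  a[1:3, 4] <- origin
  a
}

# Small random 4D volume with an all-TRUE mask.
make_test_volume <- function(dim = c(8, 8, 8), T = 60, tr = 2, seed = 1,
                             affine = mni3_affine()) {
  set.seed(seed)
  arr <- array(rnorm(prod(dim) * T), c(dim, T))
  bold_volume_series(arr, affine, tr, brain_mask = array(TRUE, dim))
}

# Long-format two-group outcome table with optional planted TSZ change.
make_long_outcome <- function(n_per_group = 10, effect = 0, seed = 1,
                              sd_outcome = 1) {
  set.seed(seed)
  rows <- list()
  for (g in c("TSZ", "DSZ")) for (i in seq_len(n_per_group)) {
    id <- paste0(g, i)
    base <- rnorm(1, 10, sd_outcome)
    age <- rnorm(1, 45, 10)
    sexv <- sample(c("F", "M"), 1)
    edu <- rnorm(1, 10, 3); dur <- rnorm(1, 18, 8); cpz <- rnorm(1, 300, 100)
    for (tp in c("t1", "t2")) {
      y <- base + rnorm(1, 0, sd_outcome)
      if (g == "TSZ" && tp == "t2") y <- y - effect
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = id, group = g, timepoint = tp, outcome = y,
        age_years = age, sex = sexv, education_years = edu,
        illness_duration_months = dur, cpz_equiv_mg_per_day = cpz)
    }
  }
  do.call(rbind, rows)
}

# Brute-force reference for the temporal-variability statistic.
tv_bruteforce <- function(r) {
  acc <- 0
  for (k in 2:length(r)) acc <- acc + (r[k] - r[k - 1])^2
  acc / (length(r) - 1)
}

# Per-window Pearson correlations via stats::cor, the independent oracle.
wc_oracle <- function(x, y, length_tr, step_tr) {
  starts <- seq(1, length(x) - length_tr + 1, by = step_tr)
  vapply(starts, function(s)
    cor(x[s:(s + length_tr - 1)], y[s:(s + length_tr - 1)]), numeric(1))
}
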