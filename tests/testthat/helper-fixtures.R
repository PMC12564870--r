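# small builders used across the suite; everything is generated in code

# one-cohort, one-bin spec with flat age trajectory and fixed sex offset
flat_spec <- function(n_male = 25, n_female = 25, baseline = 10000,
                      noise_sd = 500, sex_delta = 0, region = "R1",
                      bin_lo = 21, bin_hi = 30, cohort = "A") {
  synthetic_spec(
    demographics = data.frame(cohort = cohort, bin_lo = bin_lo,
                              bin_hi = bin_hi, n_male = n_male,
                              n_female = n_female),
    region_params = data.frame(region = region, baseline = baseline,
                               a1 = 0, a2 = 0, a3 = 0, noise_sd = noise_sd,
                               sex_delta = sex_delta,
                               stringsAsFactors = FALSE),
    cohort_offsets = stats::setNames(rep(0, length(cohort)), cohort))
}

# multi-cohort spec with known linear truth, balanced demographics
recovery_spec <- function(n_per_cell = 250, slope = -20, sex_delta = 200,
                          noise_sd = 600, offsets = c(A = 0, B = -0.5)) {
  lo <- seq(21, 81, by = 10)
  demo <- do.call(rbind, lapply(names(offsets), function(co) {
    data.frame(cohort = co, bin_lo = lo, bin_hi = lo + 9,
               n_male = n_per_cell, n_female = n_per_cell)
  }))
  synthetic_spec(
    demographics = demo,
    region_params = data.frame(region = "R1", baseline = 20000, a1 = slope,
                               a2 = 0, a3 = 0, noise_sd = noise_sd,
                               sex_delta = sex_delta,
                               stringsAsFactors = FALSE),
    cohort_offsets = offsets)
}

# tiny raw matrix with explicit lateralized volumes
tiny_lateralized <- function() {
  df <- data.frame(
    subject_id = c("s1", "s2"), cohort = "A", age = c(25, 67),
    sex = c("M", "F"),
    `Left-Hippocampus` = c(4384, 4100), `Right-Hippocampus` = c(4384, 4200),
    `Left-Thalamus` = c(8000, 7500), `Right-Thalamus` = c(8100, 7400),
    `Brain-Stem` = c(20063.7, 21000), check.names = FALSE)
  volume_matrix(df)
}

# paired segmentation "pipelines": B remeasures A with additive noise;
# per-hemisphere noise is scaled so the *bilateral* method differences
# entering the report have SD = noise_b
simulate_pipelines <- function(n = 20, noise_b = 400, seed = 99) {
  set.seed(seed)
  tax <- dkt_taxonomy()
  df <- data.frame(subject_id = sprintf("s%03d", seq_len(n)), cohort = "A",
                   age = sample(21:90, n, TRUE),
                   sex = sample(c("M", "F"), n, TRUE))
  for (r in tax$region_name) {
    df[[r]] <- stats::runif(1, 2000, 30000) * stats::rnorm(n, 1, 0.05)
  }
  a <- volume_matrix(df)
  db <- df
  for (r in tax$region_name) {
    db[[r]] <- pmax(db[[r]] + stats::rnorm(n, 0, noise_b / sqrt(2)), 1)
  }
  list(a = a, b = volume_matrix(db))
}

# brute-force Benjamini-Hochberg step-up by its sorting definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  ps <- p[o]
  for (i in seq_len(n)) {
    q[i] <- min(1, min(n * ps[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# ICC(2,1) via stats::aov mean squares (independent of the package's sums)
icc_aov_oracle <- function(a, b) {
  n <- length(a)
  d <- data.frame(y = c(a, b),
                  target = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ target + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# degree-3 polynomial least squares by explicit normal equations
cubic_normal_eq <- function(x, y) {
  X <- cbind(1, x, x^2, x^3)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}
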