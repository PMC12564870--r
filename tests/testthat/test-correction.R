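test_that("confound model recovers generative parameters within 3 SE", {
  sp <- recovery_spec(n_per_cell = 110, slope = -20, sex_delta = 200,
                      noise_sd = 600, offsets = c(A = 0, B = -0.5))
  vm <- generate_volumes(sp, seed = 17)   # ~3080 subjects
  fit <- fit_confound_model(vm, "R1")
  expect_equal(fit$reference, "A")
  expect_lt(abs(fit$beta_sex - 200), 3 * fit$se[["sex01"]])
  expect_lt(abs(fit$beta_age - (-20)), 3 * fit$se[["age"]])
  expect_lt(abs(fit$gamma[["B"]] - (-300)), 3 * fit$se[["B"]])

  # permuting subject order leaves the estimates unchanged
  perm <- vm
  set.seed(1)
  perm$data <- perm$data[sample(nrow(perm$data)), ]
  fit2 <- fit_confound_model(perm, "R1")
  expect_equal(coef(fit2), coef(fit))
})

test_that("noiseless single-cohort fit is exact", {
  df <- data.frame(subject_id = sprintf("s%d", 1:40), cohort = "K",
                   age = rep(21:40, 2), sex = rep(c("M", "F"), each = 20),
                   R1 = 5000 + 12.5 * rep(21:40, 2))
  vm <- volume_matrix(df)
  # zero residual noise makes summary.lm warn about a perfect fit
  fit <- suppressWarnings(fit_confound_model(vm, "R1"))
  expect_equal(unname(fit$beta_age), 12.5, tolerance = 1e-10)
  expect_equal(unname(fit$beta_sex), 0, tolerance = 1e-8)
  expect_length(fit$gamma, 0)
})

test_that("rank deficiency is reported, not silently dropped", {
  # cohort perfectly confounded with sex
  df <- data.frame(subject_id = sprintf("s%d", 1:20), cohort =
                     rep(c("A", "B"), each = 10),
                   age = rep(21:30, 2), sex = rep(c("M", "F"), each = 10),
                   R1 = stats::rnorm(20, 1000, 10))
  vm <- volume_matrix(df)
  expect_error(fit_confound_model(vm, "R1"), "collinear")
})

test_that("correction subtracts exactly the sex and cohort terms", {
  fit <- structure(list(region = "R1", reference = "ref", beta0 = 0,
                        beta_sex = 200, beta_age = -10,
                        gamma = c(k = -300), se = NULL, residual_sd = 1,
                        n_used = 10), class = "confound_fit")
  df <- data.frame(subject_id = c("m_ref", "m_k", "f_k"),
                   cohort = c("ref", "k", "k"), age = 50,
                   sex = c("M", "M", "F"), R1 = c(10000, 10000, 10000))
  vm <- volume_matrix(df)
  corr <- apply_correction(fit, vm)
  expect_equal(region_values(corr, "R1"), c(9800, 10100, 10300))
  expect_equal(corr$provenance, "corrected")

  # a cohort unseen at fit time is an error
  df$cohort[1] <- "mystery"
  expect_error(apply_correction(fit, volume_matrix(df)), "mystery")
})

test_that("reference-cohort females are untouched by correction", {
  df <- data.frame(subject_id = sprintf("s%d", 1:30), cohort = "only",
                   age = sample(21:90, 30, TRUE), sex = "F",
                   R1 = stats::rnorm(30, 9000, 300))
  vm <- volume_matrix(df)
  fit <- fit_confound_model(vm, "R1")
  corr <- apply_correction(fit, vm)
  expect_equal(region_values(corr, "R1"), region_values(vm, "R1"))
})

test_that("correction removes cohort gaps and is idempotent", {
  sp <- recovery_spec(n_per_cell = 60, offsets = c(A = 0, B = 0.8))
  vm <- generate_volumes(sp, seed = 23)
  vc <- correct_volumes(vm)
  corr <- vc$corrected
  byc <- split(region_values(corr, "R1"), corr$data$cohort)
  gap <- mean(byc$A) - mean(byc$B)
  se_gap <- sqrt(stats::var(byc$A) / length(byc$A) +
                   stats::var(byc$B) / length(byc$B))
  expect_lt(abs(gap), 3 * se_gap)

  # refitting the same design on corrected data gives zero coefficients
  # (projection identity), so a second correction changes nothing
  refit <- fit_confound_model(corr, "R1")
  expect_equal(unname(refit$beta_sex), 0, tolerance = 1e-8)
  expect_equal(unname(refit$gamma[["B"]]), 0, tolerance = 1e-8)
  corr2 <- apply_correction(refit, corr)
  expect_equal(region_values(corr2, "R1"), region_values(corr, "R1"),
               tolerance = 1e-10)
})

test_that("verification flags raw data and clears corrected data", {
  sp <- recovery_spec(n_per_cell = 60, offsets = c(A = 0, B = 0.8))
  vm <- generate_volumes(sp, seed = 31)
  pre <- verify_correction(vm)
  expect_true(all(pre$q[pre$term == "sex"] < 0.05))
  expect_true(all(pre$q[pre$term != "sex"] < 0.05))
  post <- verify_correction(correct_volumes(vm)$corrected)
  expect_true(all(post$q[post$term != "sex"] >= 0.05))
  expect_true(all(abs(post$estimate) < 1e-6))
  # q is never below p within each family
  expect_true(all(post$q >= post$p - 1e-15))
})

test_that("BH q-values match the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 1.0)),
               c(0.05, 0.05, 0.05, 0.05, 1.0))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(77)
  for (i in 1:50) {
    p <- stats::runif(sample(1:30, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("sex effect size is the pooled-SD standardized difference", {
  df <- data.frame(subject_id = sprintf("s%d", 1:40), cohort = "A",
                   age = 30, sex = rep(c("M", "F"), each = 20),
                   R1 = c(stats::rnorm(20, 500, 10), stats::rnorm(20, 500,
                                                                  10)))
  vm <- volume_matrix(df)
  d0 <- sex_effect_d(vm, "R1")
  # shifting the male group by one pooled SD adds exactly 1 to d
  vm2 <- vm
  sp <- braintraj:::pooled_sd(vm$data$R1[vm$data$sex == "M"],
                              vm$data$R1[vm$data$sex == "F"])
  vm2$data$R1[vm2$data$sex == "M"] <- vm2$data$R1[vm2$data$sex == "M"] + sp
  expect_equal(sex_effect_d(vm2, "R1"), d0 + 1, tolerance = 1e-3)

  onesex <- volume_matrix(data.frame(subject_id = c("a", "b"), cohort = "A",
                                     age = 30, sex = "F", R1 = c(1, 2)))
  expect_error(sex_effect_d(onesex, "R1"), "both sexes")
})

test_that("preservation metrics report kept age signal and identity", {
  # corrected == raw: ICC exactly 1
  vm <- generate_volumes(flat_spec(noise_sd = 300), seed = 2)
  pm <- preservation_metrics(vm, vm)
  expect_equal(pm$individual_icc, 1)

  # noiseless pure age trend: all variance is age variance
  df <- data.frame(subject_id = sprintf("s%d", 1:50), cohort = "A",
                   age = seq(21, 70, 1), sex = "F",
                   R1 = 9000 - 15 * seq(21, 70, 1))
  vmr <- volume_matrix(df)
  pm2 <- preservation_metrics(vmr, vmr)
  expect_equal(pm2$age_partial_r2, 1, tolerance = 1e-12)

  # known generative age share of variance is recovered
  lo <- seq(21, 81, by = 10)
  # slope * sd(age) == noise_sd implies age r^2 of 0.5
  sd_age <- stats::sd(rep(21:90, each = 1))
  spx <- synthetic_spec(
    demographics = data.frame(cohort = "A", bin_lo = lo, bin_hi = lo + 9,
                              n_male = 360, n_female = 360),
    region_params = data.frame(region = "R1", baseline = 50000,
                               a1 = 25, a2 = 0, a3 = 0,
                               noise_sd = 25 * sd_age, sex_delta = 0),
    cohort_offsets = c(A = 0))
  vmx <- generate_volumes(spx, seed = 5)
  pmx <- preservation_metrics(vmx, vmx)
  expect_equal(pmx$age_partial_r2, 0.5, tolerance = 0.05)
})
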