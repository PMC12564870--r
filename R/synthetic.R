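#' Default multi-cohort demographic plan
#'
#' Subject counts per (cohort, decade age bin, sex) cell emulating a
#' three-cohort adult study design: a Korean community sample (ages 21-80),
#' the IXI sample (21-90, skewed toward midlife), and an ADNI-like sample
#' contributing only ages 51-90. About 1830 subjects in total.
#'
#' @return Data frame with columns `cohort`, `bin_lo`, `bin_hi`, `n_male`,
#'   `n_female`.
#' @export
default_demographics <- function() {
  lo <- seq(21, 81, by = 10); hi <- lo + 9
  mk <- function(cohort, m, f) {
    data.frame(cohort = cohort, bin_lo = lo, bin_hi = hi,
               n_male = m, n_female = f)
  }
  rbind(
    mk("Korean", c(116, 24, 26, 23, 21, 8, 0), c(61, 13, 13, 8, 31, 17, 0)),
    mk("IXI",    c(45, 60, 41, 38, 47, 15, 5), c(55, 39, 48, 61, 71, 34, 3)),
    mk("ADNI",   c(0, 0, 0, 12, 134, 195, 67), c(0, 0, 0, 35, 200, 215, 51)))
}

#' Default per-region generative parameters
#'
#' Seeds the synthetic generator from the bundled normative table: for each
#' of the 50 bilateral/midline structures the baseline is the fitted volume
#' at the centring age 55.5, the residual noise SD is the 21-30 bin SD, and
#' the age trajectory is the least-squares linear slope of the seven bin
#' means against bin midpoint age (mm^3 per year). `sex_delta = NA` requests
#' calibration to the spec's target sex effect size at generation time.
#'
#' @return Data frame with columns `region`, `baseline`, `a1`, `a2`, `a3`
#'   (age-trajectory coefficients about centred age), `noise_sd`,
#'   `sex_delta`.
#' @export
default_region_params <- function() {
  nb <- normative_bin_means()
  mid <- bin_midpoints() - 55.5
  m <- bin_means_matrix(nb)
  slope <- apply(m, 1, function(v) stats::cov(mid, v) / stats::var(mid))
  data.frame(region = nb$region, baseline = unname(rowMeans(m)),
             a1 = unname(slope), a2 = 0, a3 = 0,
             noise_sd = unname(nb$sd1), sex_delta = NA_real_,
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic multi-cohort volume dataset
#'
#' Bundles everything [generate_volumes()] needs: the demographic plan
#' (counts per cohort x decade bin x sex), per-region generative parameters,
#' additive cohort offsets, and the target standardized sex difference.
#' Volumes are generated as
#' `baseline + f(age - 55.5) + sex_delta * 1(male) + cohort_offset + noise`,
#' with `f` the cubic `a1*x + a2*x^2 + a3*x^3` and homoscedastic Gaussian
#' noise, mirroring the additive linear model the correction stage assumes.
#'
#' @param regions region names to simulate; defaults to the 50-structure
#'   normative roster.
#' @param demographics demographic plan, as [default_demographics()].
#' @param region_params per-region parameters, as [default_region_params()];
#'   subset to `regions`.
#' @param cohort_offsets named numeric vector of additive cohort shifts in
#'   units of the per-region noise SD; the reference cohort must be 0.
#' @param sex_d target Cohen's d of the male-female difference; regions with
#'   `sex_delta = NA` get `sex_delta = sex_d * marginal SD` at generation
#'   time, so the realized marginal effect size matches the target.
#' @param seed default seed used by the generator.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(regions = NULL,
                           demographics = default_demographics(),
                           region_params = default_region_params(),
                           cohort_offsets = c(ADNI = 0, IXI = 0.5,
                                              Korean = -0.5),
                           sex_d = 0.427,
                           seed = 1L) {
  if (!is.null(regions)) {
    missing <- setdiff(regions, region_params$region)
    if (length(missing)) stop("no parameters for region(s): ",
                              paste(missing, collapse = ", "))
    region_params <- region_params[match(regions, region_params$region), ]
  }
  stopifnot(all(c("cohort", "bin_lo", "bin_hi", "n_male", "n_female") %in%
                  names(demographics)),
            all(region_params$noise_sd > 0))
  if (!nrow(demographics) ||
      sum(demographics$n_male + demographics$n_female) == 0) {
    stop("empty demographic plan")
  }
  cohorts <- unique(demographics$cohort)
  missing_off <- setdiff(cohorts, names(cohort_offsets))
  if (length(missing_off)) stop("cohort_offsets missing for: ",
                                paste(missing_off, collapse = ", "))
  structure(list(demographics = demographics,
                 region_params = region_params,
                 cohort_offsets = cohort_offsets,
                 sex_d = sex_d, seed = seed),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  n <- sum(x$demographics$n_male + x$demographics$n_female)
  cat("<synthetic_spec> ", n, " subjects, ",
      length(unique(x$demographics$cohort)), " cohorts, ",
      nrow(x$region_params), " regions, target sex d = ", x$sex_d,
      "\n", sep = "")
  invisible(x)
}

#' Sample subject demographics from a synthetic specification
#'
#' Draws one row per subject: cohort, an integer age uniform within the
#' subject's decade bin (inclusive bounds), and sex with the exact per-cell
#' counts of the plan. Deterministic under `seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; defaults to the spec's.
#' @return Data frame with columns `subject_id`, `cohort`, `age`, `sex`.
#' @export
sample_demographics <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  .sample_demographics(spec)
}

.sample_demographics <- function(spec) {
  d <- spec$demographics
  rows <- lapply(seq_len(nrow(d)), function(i) {
    n <- d$n_male[i] + d$n_female[i]
    if (n == 0) return(NULL)
    age <- sample(seq(d$bin_lo[i], d$bin_hi[i]), n, replace = TRUE)
    sex <- sample(rep(c("M", "F"), c(d$n_male[i], d$n_female[i])))
    data.frame(cohort = d$cohort[i], age = age, sex = sex,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$subject_id <- sprintf("sub-%04d", seq_len(nrow(out)))
  out[c("subject_id", "cohort", "age", "sex")]
}

#' Generate a synthetic multi-cohort volume matrix
#'
#' Samples demographics and per-region volumes under the spec's additive
#' model. Negative draws are clipped to zero (with a warning counting them).
#' The realized generative truth (per-region `sex_delta` after calibration
#' and cohort offsets in mm^3) is attached as attribute `"truth"` so that
#' recovery can be checked against it.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; defaults to the spec's.
#' @return A [volume_matrix()] with provenance `"synthetic"`.
#' @examples
#' sp <- synthetic_spec(regions = c("Hippocampus", "Thalamus"))
#' vm <- generate_volumes(sp, seed = 42)
#' vm
#' @export
generate_volumes <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  demo <- .sample_demographics(spec)
  n <- nrow(demo)
  male <- demo$sex == "M"
  x <- demo$age - 55.5
  rp <- spec$region_params
  out <- demo
  clipped <- 0L
  truth <- rp
  truth$cohort_offset_unit <- NA_real_
  off_mm3 <- matrix(0, nrow(rp), length(spec$cohort_offsets),
                    dimnames = list(rp$region, names(spec$cohort_offsets)))
  for (j in seq_len(nrow(rp))) {
    f_age <- rp$a1[j] * x + rp$a2[j] * x^2 + rp$a3[j] * x^3
    off <- spec$cohort_offsets[demo$cohort] * rp$noise_sd[j]
    off_mm3[j, ] <- spec$cohort_offsets * rp$noise_sd[j]
    det <- f_age + off
    sdelta <- rp$sex_delta[j]
    if (is.na(sdelta)) {
      # calibrate so the realized marginal Cohen's d matches the target:
      # sexes differ in age and cohort mix, so the deterministic part
      # contributes a cross-term to the marginal male-female contrast that
      # must be netted out of the additive sex offset
      nm <- sum(male); nf <- n - nm
      var_ws <- ((nm - 1) * stats::var(det[male]) +
                   (nf - 1) * stats::var(det[!male])) / (n - 2)
      cross <- mean(det[male]) - mean(det[!male])
      sdelta <- spec$sex_d * sqrt(var_ws + rp$noise_sd[j]^2) - cross
    }
    v <- rp$baseline[j] + det + sdelta * male +
      stats::rnorm(n, 0, rp$noise_sd[j])
    clipped <- clipped + sum(v < 0)
    v[v < 0] <- 0
    out[[rp$region[j]]] <- v
    truth$sex_delta[j] <- sdelta
  }
  if (clipped > 0) warning(clipped, " negative draw(s) clipped to zero")
  vm <- volume_matrix(out, rp$region, provenance = "synthetic")
  attr(vm, "truth") <- list(region_params = truth,
                            cohort_offsets_mm3 = off_mm3,
                            demographics = demo)
  vm
}
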