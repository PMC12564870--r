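#' Fit the per-region confound model
#'
#' Ordinary least squares of one region's volume on sex (coded male = 1,
#' female = 0), chronological age (continuous, in years), and cohort
#' membership indicators relative to a reference cohort:
#' `V = b0 + b_sex * Sex + b_age * Age + sum_k gamma_k * 1(Cohort = k) + e`.
#' Subjects with a missing volume for the region are dropped from the fit
#' only.
#'
#' @param x a [volume_matrix()].
#' @param region region name.
#' @param reference reference cohort level; defaults to the first in
#'   lexicographic order. Corrected volumes shift by a constant under a
#'   different choice, which cancels in all downstream change statistics.
#' @return An object of class `confound_fit` with elements `region`,
#'   `reference`, `beta0`, `beta_sex`, `beta_age`, `gamma` (named vector,
#'   one entry per non-reference cohort), `se` (standard errors, same
#'   naming), `residual_sd`, `n_used`.
#' @examples
#' vm <- generate_volumes(synthetic_spec(regions = "Hippocampus"), seed = 7)
#' fit <- fit_confound_model(vm, "Hippocampus")
#' coef(fit)
#' @export
fit_confound_model <- function(x, region, reference = NULL) {
  stopifnot(inherits(x, "volume_matrix"))
  df <- model_frame(x, region, reference)
  # single-sex or single-cohort inputs are allowed: the constant term is
  # dropped from the design and the correction reduces to the identity
  if (stats::var(df$age) == 0) stop("age does not vary")
  fit <- fit_delta_model(df, include_age = TRUE)
  structure(list(region = region, reference = levels(df$cohort)[1],
                 beta0 = fit$coef[["(Intercept)"]],
                 beta_sex = fit$coef[["sex01"]],
                 beta_age = fit$coef[["age"]],
                 gamma = fit$gamma, se = fit$se,
                 residual_sd = fit$sigma, n_used = fit$n),
            class = "confound_fit")
}

# shared design-matrix builder for the confound and verification models
model_frame <- function(x, region, reference = NULL) {
  v <- region_values(x, region)
  df <- data.frame(v = v, sex01 = as.numeric(x$data$sex == "M"),
                   age = x$data$age, cohort = x$data$cohort)
  df <- df[!is.na(df$v), ]
  levs <- sort(unique(df$cohort))
  if (!is.null(reference)) {
    if (!reference %in% levs) stop("reference cohort not present: ",
                                   reference)
    levs <- c(reference, setdiff(levs, reference))
  }
  df$cohort <- factor(df$cohort, levels = levs)
  df
}

fit_delta_model <- function(df, include_age = TRUE) {
  form <- if (include_age && stats::var(df$age) > 0) {
    v ~ sex01 + age + cohort
  } else {
    v ~ sex01 + cohort
  }
  # single-level factors would break model.matrix; drop the term instead
  if (nlevels(df$cohort) < 2) form <- stats::update(form, . ~ . - cohort)
  if (length(unique(df$sex01)) < 2) form <- stats::update(form, . ~ . - sex01)
  lmfit <- stats::lm(form, data = df)
  cf <- stats::coef(lmfit)
  if (anyNA(cf)) {
    stop("rank-deficient confound model; collinear term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(lmfit)
  co <- sm$coefficients
  full <- stats::setNames(rep(0, 2), c("sex01", "age"))
  full[intersect(names(cf), names(full))] <-
    cf[intersect(names(cf), names(full))]
  gname <- grep("^cohort", names(cf), value = TRUE)
  gamma <- stats::setNames(cf[gname], sub("^cohort", "", gname))
  pv <- stats::setNames(co[, 4], rownames(co))
  se <- stats::setNames(co[, 2], rownames(co))
  names(pv) <- sub("^cohort", "", names(pv))
  names(se) <- sub("^cohort", "", names(se))
  list(coef = c("(Intercept)" = unname(cf[["(Intercept)"]]),
                sex01 = unname(full[["sex01"]]),
                age = unname(full[["age"]])),
       gamma = gamma, p = pv, se = se, sigma = sm$sigma,
       n = nrow(df))
}

#' @export
print.confound_fit <- function(x, ...) {
  cat("<confound_fit> region:", x$region, " (n =", x$n_used, ")\n")
  print(coef(x))
  cat("reference cohort:", x$reference,
      " residual SD:", round(x$residual_sd, 2), "\n")
  invisible(x)
}

#' @export
coef.confound_fit <- function(object, ...) {
  c("(Intercept)" = object$beta0, sex = object$beta_sex,
    age = object$beta_age,
    stats::setNames(object$gamma, paste0("cohort:", names(object$gamma))))
}

#' Fit confound models for many regions
#'
#' @param x a [volume_matrix()].
#' @param regions regions to fit; defaults to all.
#' @param reference reference cohort, see [fit_confound_model()].
#' @return Named list of `confound_fit` objects, class `confound_fit_set`.
#' @export
fit_confound_models <- function(x, regions = x$regions, reference = NULL) {
  fits <- lapply(regions, function(r) fit_confound_model(x, r, reference))
  names(fits) <- regions
  class(fits) <- "confound_fit_set"
  fits
}

#' Remove fitted sex and cohort contributions from volumes
#'
#' Dual correction (residualization): subtracts only the fitted sex and
#' cohort terms, `V_corr = V - [b_sex * Sex + gamma_cohort]`, leaving the
#' age trend and the residual untouched. Reference-cohort females are
#' unchanged by construction.
#'
#' @param fits a `confound_fit_set` (or a single `confound_fit`).
#' @param x the [volume_matrix()] the fits came from (same sex coding and
#'   cohort labels).
#' @return A [volume_matrix()] with provenance `"corrected"` containing the
#'   fitted regions.
#' @export
apply_correction <- function(fits, x) {
  if (inherits(fits, "confound_fit")) {
    fits <- structure(stats::setNames(list(fits), fits$region),
                      class = "confound_fit_set")
  }
  stopifnot(inherits(fits, "confound_fit_set"), inherits(x, "volume_matrix"))
  out <- x$data[c("subject_id", "cohort", "age", "sex")]
  male <- as.numeric(x$data$sex == "M")
  for (f in fits) {
    known <- c(f$reference, names(f$gamma))
    bad <- setdiff(unique(x$data$cohort), known)
    if (length(bad)) {
      stop("cohort(s) absent from fit for region '", f$region, "': ",
           paste(bad, collapse = ", "))
    }
    off <- c(stats::setNames(0, f$reference), f$gamma)[x$data$cohort]
    out[[f$region]] <- region_values(x, f$region) -
      (f$beta_sex * male + unname(off))
  }
  volume_matrix(out, names(fits), provenance = "corrected")
}

#' Benjamini-Hochberg step-up q-values
#'
#' Adjusts a family of p-values to control the false discovery rate.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Re-test sex and cohort effects after correction
#'
#' Refits the verification model on each region and collects the sex and
#' cohort coefficients with their p-values; q-values are computed by
#' Benjamini-Hochberg separately within the sex family (one test per
#' region) and the cohort family (one test per region x non-reference
#' cohort). Age is retained as a covariate by default so that residual
#' sex/cohort effects are assessed at fixed age; this matters when cohorts
#' cover different age ranges, in which case an age-blind re-test would
#' attribute genuine age-trajectory differences to cohort. Set
#' `include_age = FALSE` for the plain sex + cohort re-test.
#'
#' @param x a [volume_matrix()] (typically provenance `"corrected"`).
#' @param reference reference cohort.
#' @param include_age keep age as a covariate in the verification model.
#' @return Data frame of class `verification_result` with columns `region`,
#'   `term` (`"sex"` or `"cohort:<level>"`), `estimate`, `se`, `p`, `q`.
#' @export
verify_correction <- function(x, reference = NULL, include_age = TRUE) {
  stopifnot(inherits(x, "volume_matrix"))
  rows <- lapply(x$regions, function(r) {
    df <- model_frame(x, r, reference)
    fit <- fit_delta_model(df, include_age = include_age)
    terms <- list()
    if ("sex01" %in% names(fit$p)) {
      terms <- c(terms, list(data.frame(
        region = r, term = "sex", estimate = fit$coef[["sex01"]],
        se = fit$se[["sex01"]], p = fit$p[["sex01"]])))
    }
    if (length(fit$gamma)) {
      terms <- c(terms, list(data.frame(
        region = r, term = paste0("cohort:", names(fit$gamma)),
        estimate = unname(fit$gamma), se = unname(fit$se[names(fit$gamma)]),
        p = unname(fit$p[names(fit$gamma)]))))
    }
    do.call(rbind, terms)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  sexf <- out$term == "sex"
  if (any(sexf)) out$q[sexf] <- bh_fdr(out$p[sexf])
  if (any(!sexf)) out$q[!sexf] <- bh_fdr(out$p[!sexf])
  rownames(out) <- NULL
  class(out) <- c("verification_result", "data.frame")
  out
}

#' @export
print.verification_result <- function(x, level = 0.05, ...) {
  y <- as.data.frame(x)
  sexf <- y$term == "sex"
  nr <- length(unique(y$region))
  cat("Residual confound re-test over", nr, "regions\n")
  cat("  sex significant (FDR <", level, "):",
      sum(y$q[sexf] < level), "/", sum(sexf), "\n")
  cat("  cohort significant (FDR <", level, "):",
      sum(y$q[!sexf] < level), "/", sum(!sexf), "\n")
  invisible(x)
}

#' Sex effect size (Cohen's d) for one region
#'
#' `(mean(male) - mean(female)) / pooled SD` with the pooled-variance
#' denominator.
#'
#' @param x a [volume_matrix()].
#' @param region region name.
#' @return A single number.
#' @export
sex_effect_d <- function(x, region) {
  v <- region_values(x, region)
  m <- v[x$data$sex == "M" & !is.na(v)]
  f <- v[x$data$sex == "F" & !is.na(v)]
  if (!length(m) || !length(f)) stop("both sexes required for region ",
                                     region)
  sp <- pooled_sd(m, f)
  if (sp <= 0) stop("zero pooled SD for region ", region)
  (mean(m) - mean(f)) / sp
}

#' What the correction kept: age signal and individual differences
#'
#' For each region reports the squared correlation of corrected volume with
#' age (the preserved age-related variance) and the ICC(2,1) between raw
#' and corrected volumes across subjects (the preserved individual
#' differences).
#'
#' @param raw,corrected [volume_matrix()] objects over the same subjects.
#' @return Data frame with columns `region`, `age_partial_r2`,
#'   `individual_icc`.
#' @export
preservation_metrics <- function(raw, corrected) {
  stopifnot(inherits(raw, "volume_matrix"),
            inherits(corrected, "volume_matrix"),
            identical(raw$data$subject_id, corrected$data$subject_id))
  regions <- intersect(raw$regions, corrected$regions)
  rows <- lapply(regions, function(r) {
    vr <- region_values(raw, r)
    vc <- region_values(corrected, r)
    if (stats::sd(vc, na.rm = TRUE) == 0) {
      stop("constant corrected volumes for region ", r)
    }
    data.frame(region = r,
               age_partial_r2 = stats::cor(vc, raw$data$age,
                                           use = "complete.obs")^2,
               individual_icc = icc_agreement(vr, vc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dual sex/cohort correction of a volume matrix
#'
#' The package's main fitting entry point: fits the per-region confound
#' model, removes the fitted sex and cohort contributions, and re-tests
#' for residual effects. Returns everything as one object.
#'
#' @param x a [volume_matrix()].
#' @param reference reference cohort (default: first lexicographically).
#' @param fdr_level FDR threshold used by `print`/`summary`.
#' @param verify_with_age see `include_age` in [verify_correction()].
#' @return Object of class `volume_correction` with elements `fits`
#'   (`confound_fit_set`), `corrected` ([volume_matrix()]), `verification`
#'   ([verify_correction()] output), `fdr_level`, `reference`.
#' @examples
#' vm <- generate_volumes(synthetic_spec(regions = c("Thalamus", "Insula")),
#'                        seed = 3)
#' vc <- correct_volumes(vm)
#' vc
#' @export
correct_volumes <- function(x, reference = NULL, fdr_level = 0.05,
                            verify_with_age = TRUE) {
  fits <- fit_confound_models(x, reference = reference)
  corrected <- apply_correction(fits, x)
  verification <- verify_correction(corrected, reference = reference,
                                    include_age = verify_with_age)
  structure(list(fits = fits, corrected = corrected,
                 verification = verification, fdr_level = fdr_level,
                 reference = fits[[1]]$reference),
            class = "volume_correction")
}

#' @export
print.volume_correction <- function(x, ...) {
  cat("<volume_correction> ", length(x$fits), " regions, reference cohort '",
      x$reference, "'\n", sep = "")
  print(x$verification, level = x$fdr_level)
  invisible(x)
}

#' @export
coef.volume_correction <- function(object, ...) {
  t(vapply(object$fits, coef, coef(object$fits[[1]])))
}

#' @export
summary.volume_correction <- function(object, ...) {
  v <- object$verification
  sexf <- v$term == "sex"
  out <- list(
    n_regions = length(object$fits),
    reference = object$reference,
    sex_significant = sum(v$q[sexf] < object$fdr_level),
    cohort_significant = sum(v$q[!sexf] < object$fdr_level),
    mean_abs_beta_sex = mean(abs(vapply(object$fits, `[[`, 0, "beta_sex"))))
  class(out) <- "summary.volume_correction"
  out
}

#' @export
print.summary.volume_correction <- function(x, ...) {
  cat("Dual sex/cohort correction over", x$n_regions, "regions",
      "(reference:", x$reference, ")\n")
  cat("  residual sex effects significant:", x$sex_significant, "\n")
  cat("  residual cohort effects significant:", x$cohort_significant, "\n")
  cat("  mean |fitted sex offset|:", round(x$mean_abs_beta_sex, 1),
      "mm^3\n")
  invisible(x)
}
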