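#' Decade age-bin labels and midpoints
#'
#' The analysis summarizes adulthood over seven decade bins, 21-30 through
#' 81-90, with inclusive integer bounds. Bin midpoints (25.5, 35.5, ...,
#' 85.5 years) are the default age abscissa for trajectory fits.
#'
#' @return `age_bins()`: character vector of the seven labels.
#' @export
age_bins <- function() {
  lo <- seq(21, 81, by = 10)
  paste0(lo, "-", lo + 9)
}

#' @rdname age_bins
#' @return `bin_midpoints()`: numeric vector of midpoint ages in years.
#' @export
bin_midpoints <- function() seq(25.5, 85.5, by = 10)

#' Assign ages to decade bins
#'
#' Integer age `a` maps to the bin `[10 * floor((a - 1) / 10) + 1, ... + 10]`,
#' so 21-30 share a bin and 30/31 fall on opposite sides of a boundary.
#' Ages below 21 (some cohorts recruit from age 20) are folded into the
#' first bin with a warning; ages above 90 are excluded (`NA`) with a
#' warning.
#'
#' @param ages numeric vector of ages in years.
#' @return Factor with levels [age_bins()].
#' @examples
#' bin_by_age(c(21, 30, 31, 90))
#' @export
bin_by_age <- function(ages) {
  if (any(!is.na(ages) & ages < 21)) {
    warning(sum(ages < 21, na.rm = TRUE),
            " age(s) below 21 folded into the 21-30 bin")
  }
  if (any(!is.na(ages) & ages > 90)) {
    warning(sum(ages > 90, na.rm = TRUE), " age(s) above 90 excluded")
  }
  idx <- floor((pmax(ages, 21) - 1) / 10) - 1L  # 21-30 -> 1
  idx[!is.na(ages) & ages > 90] <- NA
  factor(age_bins()[idx], levels = age_bins())
}

#' Per-bin summaries of regional volumes
#'
#' Mean, SD and normal-theory confidence interval of each region's volume
#' within each decade age bin. Zero volumes are treated as segmentation
#' failures and excluded (along with `NA`s) before summarizing; `n` counts
#' the values actually used. The CI is `mean +/- z * sd / sqrt(n)`.
#'
#' @param x a [volume_matrix()].
#' @param ci_z CI multiplier (1.96 for nominal 95%).
#' @return Data frame of class `age_bin_summary` with columns `region`,
#'   `bin`, `n`, `mean`, `sd`, `ci_lo`, `ci_hi`. Empty (region, bin) cells
#'   are omitted, with one warning if any bin is empty for all regions.
#' @export
summarize_bins <- function(x, ci_z = 1.96) {
  stopifnot(inherits(x, "volume_matrix"))
  bins <- bin_by_age(x$data$age)
  empty <- setdiff(age_bins(), unique(as.character(bins[!is.na(bins)])))
  if (length(empty)) {
    warning("empty age bin(s) omitted: ", paste(empty, collapse = ", "))
  }
  rows <- list()
  for (r in x$regions) {
    v <- region_values(x, r)
    use <- !is.na(v) & v != 0 & !is.na(bins)
    for (b in age_bins()) {
      sel <- use & bins == b
      n <- sum(sel)
      if (n == 0) next
      m <- mean(v[sel]); s <- stats::sd(v[sel])
      half <- if (n > 1) ci_z * s / sqrt(n) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, bin = b, n = n, mean = m, sd = s,
        ci_lo = m - half, ci_hi = m + half)
    }
  }
  out <- do.call(rbind, rows)
  out$bin <- factor(out$bin, levels = age_bins())
  rownames(out) <- NULL
  class(out) <- c("age_bin_summary", "data.frame")
  out
}

#' Turn a bin summary into a region-by-bin matrix of means
#'
#' @param s an `age_bin_summary`.
#' @return Numeric matrix (regions x bins), `NA` where a cell was empty.
#' @export
summary_to_matrix <- function(s) {
  regs <- unique(s$region)
  m <- matrix(NA_real_, length(regs), 7,
              dimnames = list(regs, age_bins()))
  m[cbind(match(s$region, regs), as.integer(s$bin))] <- s$mean
  m
}

#' Symmetric percent change
#'
#' `(to - from) / ((to + from) / 2) * 100`: bounded in (-200, 200),
#' antisymmetric under exchanging the arguments, and invariant under
#' rescaling both by the same positive constant.
#'
#' @param from,to positive values (mm^3).
#' @return Percent change.
#' @export
sym_pct_change <- function(from, to) {
  if (any(from <= 0 | to <= 0, na.rm = TRUE)) {
    stop("symmetric percent change requires positive volumes")
  }
  (to - from) / ((to + from) / 2) * 100
}

#' The three age-trajectory change statistics
#'
#' `endpoint_change` compares the youngest bin mean with the oldest;
#' `range_change` compares the smallest bin mean with the largest (always
#' >= the absolute endpoint change, and sensitive to mid-life extremes the
#' endpoints miss); `max_consecutive_change` is the largest absolute change
#' between adjacent bins (the steepest decade transition). All three are
#' symmetric percent changes.
#'
#' @param v_young,v_old mean volumes of the youngest and oldest bins.
#' @return Percent change (scalar).
#' @examples
#' endpoint_change(16102.0, 13322.4)  # about -18.9
#' @export
endpoint_change <- function(v_young, v_old) sym_pct_change(v_young, v_old)

#' @rdname endpoint_change
#' @param series numeric vector of per-bin means in bin order (typically 7
#'   values; `NA` for missing bins is tolerated with a warning).
#' @export
max_consecutive_change <- function(series) {
  series <- check_series(series)
  a <- series[-length(series)]
  b <- series[-1]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no adjacent pair of bins available")
  max(abs(sym_pct_change(a[ok], b[ok])))
}

#' @rdname endpoint_change
#' @export
range_change <- function(series) {
  series <- check_series(series)
  sym_pct_change(min(series, na.rm = TRUE), max(series, na.rm = TRUE))
}

check_series <- function(series) {
  if (sum(!is.na(series)) < 2) stop("need at least 2 bin means")
  if (anyNA(series)) {
    warning("missing bin mean(s); statistics computed over available bins")
  }
  series
}

#' Change statistics for every region of a bin-means matrix
#'
#' @param m region-by-bin matrix of means, as [summary_to_matrix()] or
#'   [bin_means_matrix()].
#' @return Data frame with columns `region`, `endpoint_change`,
#'   `range_change`, `max_consecutive_change` (percent).
#' @export
change_metrics <- function(m) {
  out <- data.frame(
    region = rownames(m),
    endpoint_change = apply(m, 1, function(v) {
      sym_pct_change(v[which(!is.na(v))[1]], v[rev(which(!is.na(v)))[1]])
    }),
    range_change = apply(m, 1, function(v)
      suppressWarnings(range_change(v))),
    max_consecutive_change = apply(m, 1, function(v)
      suppressWarnings(max_consecutive_change(v))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit linear and cubic trajectories to bin means
#'
#' Least-squares fits of the per-bin mean volumes against bin midpoint age:
#' a straight line and a cubic
#' `V = a0 + a1 * Age + a2 * Age^2 + a3 * Age^3`. The gain in R-squared of
#' the cubic over the line (non-negative, as the models are nested on the
#' same data) drives the non-monotonicity classification: see
#' [classify_pattern()].
#'
#' @param means per-bin mean volumes (>= 4 values for the cubic; with fewer
#'   only the linear fit is returned and the pattern is `"linear"`).
#' @param ages age abscissa, defaults to [bin_midpoints()].
#' @param improvement_threshold minimum R-squared gain for a non-linear
#'   label (default 0.2).
#' @param region optional region name carried through.
#' @return Object of class `trajectory_fit` with elements `region`, `ages`,
#'   `means`, `linear` (`intercept`, `slope`, `r2`), `cubic` (`a0..a3`,
#'   `r2`), `r2_improvement`, `pattern`, `extremum_age`.
#' @examples
#' m <- bin_means_matrix()
#' fit <- fit_trajectory(m["Caudate", ], region = "Caudate")
#' fit
#' @export
fit_trajectory <- function(means, ages = bin_midpoints(),
                           improvement_threshold = 0.2, region = NULL) {
  ok <- !is.na(means) & !is.na(ages)
  means <- as.numeric(means[ok]); ages <- as.numeric(ages[ok])
  if (length(means) < 2) stop("need at least 2 points")
  lin <- stats::lm(means ~ ages)
  # summary.lm warns on numerically perfect fits; only R^2 is used here
  r2l <- suppressWarnings(summary(lin)$r.squared)
  out <- list(region = region, ages = ages, means = means,
              linear = c(intercept = unname(stats::coef(lin)[1]),
                         slope = unname(stats::coef(lin)[2]), r2 = r2l),
              cubic = NULL, r2_improvement = 0,
              pattern = "linear", extremum_age = NA_real_,
              improvement_threshold = improvement_threshold)
  if (length(means) >= 4) {
    cub <- stats::lm(means ~ ages + I(ages^2) + I(ages^3))
    cf <- stats::coef(cub)
    r2c <- suppressWarnings(summary(cub)$r.squared)
    out$cubic <- c(a0 = unname(cf[1]), a1 = unname(cf[2]),
                   a2 = unname(cf[3]), a3 = unname(cf[4]), r2 = r2c)
    out$r2_improvement <- max(0, r2c - r2l)
  }
  out <- structure(out, class = "trajectory_fit")
  classify_pattern(out)
}

#' Classify a trajectory as U-shaped, inverted-U, or linear
#'
#' Peak detection on the smooth cubic: real roots of the cubic's
#' derivative strictly inside the fitted age range are candidate extrema;
#' a root where the second derivative is positive is a local minimum
#' (U-shaped candidate), negative a local maximum (inverted-U). The
#' non-linear label is only assigned when the cubic improves R-squared over
#' the line by more than the threshold; otherwise the region is `"linear"`.
#' If both a minimum and a maximum lie inside the range, the extremum whose
#' fitted value deviates farther from the chord joining the endpoint fits
#' wins.
#'
#' @param fit a `trajectory_fit`.
#' @param improvement_threshold overrides the fit's threshold if given.
#' @return The fit with `pattern` and `extremum_age` filled in.
#' @export
classify_pattern <- function(fit, improvement_threshold = NULL) {
  stopifnot(inherits(fit, "trajectory_fit"))
  thr <- if (is.null(improvement_threshold)) fit$improvement_threshold
         else improvement_threshold
  fit$pattern <- "linear"
  fit$extremum_age <- NA_real_
  if (is.null(fit$cubic) || fit$r2_improvement <= thr) return(fit)
  a1 <- fit$cubic[["a1"]]; a2 <- fit$cubic[["a2"]]; a3 <- fit$cubic[["a3"]]
  roots <- polynomial_roots(c(a1, 2 * a2, 3 * a3))  # derivative coefs
  lo <- min(fit$ages); hi <- max(fit$ages)
  roots <- roots[roots > lo & roots < hi]
  if (!length(roots)) return(fit)
  curv <- 2 * a2 + 6 * a3 * roots
  kind <- ifelse(curv > 0, "U-shaped", "inverted-U")
  if (length(roots) > 1 && length(unique(kind)) > 1) {
    pred <- function(x) fit$cubic[["a0"]] + a1 * x + a2 * x^2 + a3 * x^3
    chord <- function(x) {
      pred(lo) + (pred(hi) - pred(lo)) * (x - lo) / (hi - lo)
    }
    dev <- abs(pred(roots) - chord(roots))
    pick <- which.max(dev)
  } else {
    pick <- 1L
  }
  fit$pattern <- kind[pick]
  fit$extremum_age <- roots[pick]
  fit
}

# real roots of c[1] + c[2] x + c[3] x^2 (degenerate cases handled)
polynomial_roots <- function(co) {
  if (abs(co[3]) < 1e-12 * max(1, abs(co[1]), abs(co[2]))) {
    if (abs(co[2]) == 0) return(numeric(0))
    return(-co[1] / co[2])
  }
  disc <- co[2]^2 - 4 * co[3] * co[1]
  if (disc < 0) return(numeric(0))
  (-co[2] + c(-1, 1) * sqrt(disc)) / (2 * co[3])
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("<trajectory_fit>", if (!is.null(x$region)) x$region else "", "\n")
  cat("  linear R2:", round(x$linear[["r2"]], 3))
  if (!is.null(x$cubic)) {
    cat("  cubic R2:", round(x$cubic[["r2"]], 3),
        "  improvement:", round(x$r2_improvement, 3))
  }
  cat("\n  pattern:", x$pattern)
  if (!is.na(x$extremum_age)) {
    cat(" (extremum near age ", round(x$extremum_age, 1), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
coef.trajectory_fit <- function(object, model = c("cubic", "linear"), ...) {
  model <- match.arg(model)
  if (model == "cubic") {
    if (is.null(object$cubic)) stop("no cubic fit available")
    object$cubic[c("a0", "a1", "a2", "a3")]
  } else {
    object$linear[c("intercept", "slope")]
  }
}

#' @export
predict.trajectory_fit <- function(object, ages = object$ages,
                                   model = c("cubic", "linear"), ...) {
  model <- match.arg(model)
  if (model == "cubic" && !is.null(object$cubic)) {
    cf <- object$cubic
    cf[["a0"]] + cf[["a1"]] * ages + cf[["a2"]] * ages^2 +
      cf[["a3"]] * ages^3
  } else {
    object$linear[["intercept"]] + object$linear[["slope"]] * ages
  }
}

#' @export
residuals.trajectory_fit <- function(object, model = c("cubic", "linear"),
                                     ...) {
  object$means - predict(object, model = match.arg(model))
}

#' @export
plot.trajectory_fit <- function(x, ...) {
  graphics::plot(x$ages, x$means, pch = 19, xlab = "age (years)",
                 ylab = "mean bilateral volume (mm^3)",
                 main = if (!is.null(x$region)) x$region else "", ...)
  xs <- seq(min(x$ages), max(x$ages), length.out = 200)
  graphics::lines(xs, predict(x, xs, model = "linear"), lty = 2)
  if (!is.null(x$cubic)) graphics::lines(xs, predict(x, xs))
  if (!is.na(x$extremum_age)) {
    graphics::abline(v = x$extremum_age, col = "grey60", lty = 3)
  }
  invisible(x)
}

#' Trajectory classification table for every region
#'
#' Fits linear/cubic trajectories per region of a bin-means matrix and
#' combines the classification with the three change statistics.
#'
#' @inheritParams change_metrics
#' @param improvement_threshold see [fit_trajectory()].
#' @return Data frame with columns `region`, `pattern`, `r2_linear`,
#'   `r2_cubic`, `r2_improvement`, `extremum_age`, `endpoint_change`,
#'   `range_change`, `max_consecutive_change`.
#' @examples
#' tt <- trajectory_table(bin_means_matrix())
#' tt[tt$pattern != "linear", ]
#' @export
trajectory_table <- function(m, improvement_threshold = 0.2) {
  ch <- change_metrics(m)
  rows <- lapply(rownames(m), function(r) {
    f <- fit_trajectory(m[r, ], improvement_threshold = improvement_threshold,
                        region = r)
    data.frame(region = r, pattern = f$pattern,
               r2_linear = f$linear[["r2"]],
               r2_cubic = if (is.null(f$cubic)) NA_real_
                          else f$cubic[["r2"]],
               r2_improvement = f$r2_improvement,
               extremum_age = f$extremum_age, stringsAsFactors = FALSE)
  })
  out <- merge(do.call(rbind, rows), ch, by = "region", sort = FALSE)
  rownames(out) <- NULL
  out
}
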