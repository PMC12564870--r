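#' Intraclass correlation for paired method comparison, ICC(2,1)
#'
#' Two-way random-effects, single-rater, absolute-agreement intraclass
#' correlation between two paired measurement vectors (here, two
#' segmentation pipelines measuring the same subject-structure targets).
#' Computed from the explicit two-way ANOVA decomposition with targets in
#' rows and the two methods as raters:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `k = 2`.
#' Unlike a consistency ICC, a constant offset between the methods lowers
#' the coefficient.
#'
#' @param a,b numeric vectors of equal length (>= 3), paired by target.
#' @return A single number `<= 1`.
#' @examples
#' set.seed(1); v <- rnorm(20, 10000, 1000)
#' icc_agreement(v, v)          # 1
#' icc_agreement(v, v + 2000)   # offset penalized
#' @export
icc_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3) stop("need at least 3 complete pairs")
  k <- 2
  y <- cbind(a, b)
  grand <- mean(y)
  rowm <- rowMeans(y)
  colm <- colMeans(y)
  if (stats::var(rowm) < .Machine$double.eps * max(1, grand^2)) {
    stop("zero between-target variance: ICC undefined")
  }
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Between-subject coefficient of variation, in percent
#'
#' `100 * SD(values) / mean(values)` with the sample SD. Scale-invariant
#' under multiplicative rescaling.
#'
#' @param values numeric vector with positive mean.
#' @return Percent CoV (>= 0).
#' @examples
#' cov_percent(c(90, 100, 110))  # 10
#' @export
cov_percent <- function(values) {
  values <- values[!is.na(values)]
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("CoV requires a positive mean")
  100 * stats::sd(values) / m
}

#' Standardized mean difference between two methods (Cohen's D)
#'
#' `(mean(a) - mean(b))` divided by the pooled between-subject SD of the
#' two sets (not the SD of the differences), so the statistic reads as the
#' method offset in units of biological spread.
#'
#' @param a,b paired numeric vectors.
#' @return A single number.
#' @export
effect_size_d <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  sp <- pooled_sd(a, b)
  if (sp <= 0) stop("zero pooled SD: effect size undefined")
  (mean(a) - mean(b)) / sp
}

pooled_sd <- function(a, b) {
  na <- length(a); nb <- length(b)
  sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
         (na + nb - 2))
}

#' Bland-Altman reproducibility coefficient
#'
#' `1.96 * SD(differences)`: the half-width of the 95% limits of agreement
#' about the mean difference.
#'
#' @param differences numeric vector of paired differences (length >= 2).
#' @return A value in the units of the input.
#' @examples
#' reproducibility_coefficient(c(-100, 0, 100))  # 196
#' @export
reproducibility_coefficient <- function(differences) {
  differences <- differences[!is.na(differences)]
  if (length(differences) < 2) stop("need at least 2 differences")
  1.96 * stats::sd(differences)
}

#' Per-lobe agreement report between two segmentation pipelines
#'
#' Compares two volume matrices of the same subjects and regions (one per
#' pipeline). Lateralized structures are combined bilaterally, mapped to
#' the six-category validation grouping (frontal, parietal, temporal and
#' occipital lobes, limbic structures, cerebellum), and pooled across
#' subjects and structures within each group as (subject, structure)
#' targets. For each group the report carries the two method means, the SD
#' of the paired differences, ICC(2,1), the between-subject CoV of the
#' pooled values, Cohen's D of the method offset, the reproducibility
#' coefficient, and the squared Pearson correlation, plus a `Mean` summary
#' row.
#'
#' @param a,b two [volume_matrix()] objects with identical subjects and
#'   regions.
#' @param taxonomy taxonomy data frame, as [dkt_taxonomy()].
#' @return Data frame of class `agreement_report`, one row per group plus
#'   the mean row.
#' @export
agreement_report <- function(a, b, taxonomy = dkt_taxonomy()) {
  stopifnot(inherits(a, "volume_matrix"), inherits(b, "volume_matrix"))
  if (!identical(sort(a$data$subject_id), sort(b$data$subject_id))) {
    only_a <- setdiff(a$data$subject_id, b$data$subject_id)
    only_b <- setdiff(b$data$subject_id, a$data$subject_id)
    stop("subject mismatch between pipelines; only in A: ",
         paste(utils::head(only_a, 5), collapse = ", "), "; only in B: ",
         paste(utils::head(only_b, 5), collapse = ", "))
  }
  if (!setequal(a$regions, b$regions)) {
    stop("region mismatch between pipelines: ",
         paste(utils::head(c(setdiff(a$regions, b$regions),
                             setdiff(b$regions, a$regions)), 5),
               collapse = ", "))
  }
  ba <- suppressWarnings(combine_bilateral(a, taxonomy))
  bb <- suppressWarnings(combine_bilateral(b, taxonomy))
  bb$data <- bb$data[match(ba$data$subject_id, bb$data$subject_id), ]
  grp <- validation_lobes()
  groups <- c("Frontal lobe", "Parietal lobe", "Temporal lobe",
              "Occipital lobe", "Limbic lobe", "Cerebellum")
  rows <- lapply(groups, function(g) {
    regs <- intersect(names(grp)[grp == g], ba$regions)
    if (!length(regs)) return(NULL)
    va <- unlist(lapply(regs, function(r) region_values(ba, r)))
    vb <- unlist(lapply(regs, function(r) region_values(bb, r)))
    keep <- !is.na(va) & !is.na(vb)
    va <- va[keep]; vb <- vb[keep]
    d <- va - vb
    data.frame(lobe = g, n_pairs = length(va),
               mean_a = mean(va), mean_b = mean(vb),
               sd_diff = stats::sd(d),
               icc = icc_agreement(va, vb),
               cov_pct = cov_percent(c(va, vb)),
               effect_size_d = effect_size_d(va, vb),
               rc = reproducibility_coefficient(d),
               r_squared = stats::cor(va, vb)^2)
  })
  out <- do.call(rbind, rows)
  msum <- out[1, ]
  msum$lobe <- "Mean"
  msum$n_pairs <- sum(out$n_pairs)
  for (cn in names(out)[-(1:2)]) msum[[cn]] <- mean(out[[cn]])
  out <- rbind(out, msum)
  rownames(out) <- NULL
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' @export
print.agreement_report <- function(x, digits = 4, ...) {
  cat("Inter-pipeline agreement by lobe\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
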