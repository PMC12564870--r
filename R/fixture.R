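#' Bundled normative table of per-age-bin bilateral volume means
#'
#' The package ships a reference table of mean and standard deviation of
#' bilateral volumes (mm^3) for the 50 combined structures (45 bilateral
#' pairs plus 5 midline structures) over the seven decade age bins 21-30
#' through 81-90, pooled across three cognitively healthy adult cohorts
#' (a Korean sample, IXI, and ADNI; about 1800 subjects in total, after
#' sex/cohort residualization). It drives the packaged worked examples, the
#' default parameters of the synthetic generator, and the regeneration of
#' the percent-change and trajectory-classification tables.
#'
#' @param long if `TRUE`, return one row per (region, bin) with columns
#'   `region`, `lobe`, `bin`, `mean`, `sd`; otherwise one row per region
#'   with `mean1..mean7`/`sd1..sd7`.
#' @return A data frame (see `long`).
#' @examples
#' nb <- normative_bin_means()
#' nb[nb$region == "Hippocampus", c("mean1", "mean7")]
#' @export
normative_bin_means <- function(long = FALSE) {
  path <- system.file("extdata", "normative_bin_means.tsv",
                      package = "braintraj", mustWork = TRUE)
  wide <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!long) return(wide)
  bins <- age_bins()
  out <- do.call(rbind, lapply(seq_len(7), function(i) {
    data.frame(region = wide$region, lobe = wide$lobe, bin = bins[i],
               mean = wide[[paste0("mean", i)]],
               sd = wide[[paste0("sd", i)]],
               stringsAsFactors = FALSE)
  }))
  out$bin <- factor(out$bin, levels = bins)
  out[order(match(out$region, wide$region), out$bin), ]
}

#' Region-by-bin matrix of normative means
#'
#' @param wide output of [normative_bin_means()] (wide form).
#' @param what `"mean"` or `"sd"`.
#' @return Numeric matrix, regions in rows, the seven age bins in columns.
#' @export
bin_means_matrix <- function(wide = normative_bin_means(), what = "mean") {
  m <- as.matrix(wide[, paste0(what, 1:7)])
  dimnames(m) <- list(wide$region, age_bins())
  m
}
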