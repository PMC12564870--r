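#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end analysis: where the input volumes
#' come from (a delimited table, or the synthetic generator when `input` is
#' `NULL`), the reference cohort for the correction stage, the FDR level of
#' the verification re-test, the R-squared-improvement threshold of the
#' trajectory classifier, the CI multiplier of the bin summaries, and the
#' seed.
#'
#' @param input path to a volume table (CSV/TSV), or `NULL` to simulate
#'   from `spec`.
#' @param spec a [synthetic_spec()] used when `input` is `NULL`.
#' @param reference reference cohort (default: first lexicographically).
#' @param fdr_level FDR threshold in (0, 1).
#' @param improvement_threshold non-negative R-squared gain threshold.
#' @param ci_z CI multiplier.
#' @param seed integer seed for the simulate stage.
#' @param out_dir directory for emitted tables; `NULL` keeps everything in
#'   memory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, spec = synthetic_spec(),
                            reference = NULL, fdr_level = 0.05,
                            improvement_threshold = 0.2, ci_z = 1.96,
                            seed = 1L, out_dir = NULL) {
  stopifnot(fdr_level > 0, fdr_level < 1, improvement_threshold >= 0)
  structure(list(input = input, spec = spec, reference = reference,
                 fdr_level = fdr_level,
                 improvement_threshold = improvement_threshold,
                 ci_z = ci_z, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full normative-trajectory pipeline
#'
#' Load (or simulate) volumes, fit and apply the dual sex/cohort
#' correction, verify removal, summarize corrected volumes over decade
#' bins, compute the three change statistics, and classify age
#' trajectories. With `correction = FALSE` (e.g. for inputs that are
#' already analysis-ready bin means) the correction stage is skipped.
#' Deterministic under a fixed seed. When `out_dir` is set, each table is
#' written as TSV with `#`-prefixed provenance headers (input checksum and
#' configuration) and a run log listing every exclusion.
#'
#' @param config a [pipeline_config()].
#' @param correction run the correction stage.
#' @return Invisibly, a list with elements `volumes`, `correction`,
#'   `bin_summary`, `changes`, `patterns`, `log`, and `paths` (written
#'   files, if any).
#' @export
run_pipeline <- function(config = pipeline_config(), correction = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note("[", name, "] warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  vm <- stage("load", {
    if (is.null(config$input)) {
      note("simulating volumes, seed = ", config$seed)
      generate_volumes(config$spec, seed = config$seed)
    } else {
      note("loading ", config$input)
      load_volume_table(config$input)
    }
  })
  input_hash <- digest_volumes(vm)

  corr <- NULL
  analysis <- vm
  if (correction) {
    corr <- stage("correct", correct_volumes(vm, reference = config$reference,
                                             fdr_level = config$fdr_level))
    analysis <- corr$corrected
    v <- corr$verification
    note("correction: ", sum(v$q[v$term == "sex"] < config$fdr_level),
         " residual sex, ",
         sum(v$q[v$term != "sex"] < config$fdr_level),
         " residual cohort effects at FDR < ", config$fdr_level)
  } else {
    note("correction stage skipped")
  }

  bs <- stage("summarize", summarize_bins(analysis, ci_z = config$ci_z))
  m <- summary_to_matrix(bs)
  changes <- stage("changes", change_metrics(m))
  patterns <- stage("classify", trajectory_table(
    m, improvement_threshold = config$improvement_threshold))

  paths <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- c(paste0("input-md5: ", input_hash),
             paste0("seed: ", config$seed),
             paste0("fdr-level: ", config$fdr_level),
             paste0("improvement-threshold: ", config$improvement_threshold),
             paste0("ci-z: ", config$ci_z))
    wt <- function(df, name) {
      p <- file.path(config$out_dir, name)
      con <- file(p, "w")
      writeLines(paste0("# ", hdr), con)
      suppressWarnings(utils::write.table(df, con, sep = "\t",
                                          row.names = FALSE, quote = FALSE))
      close(con)
      p
    }
    paths <- c(paths, wt(as.data.frame(vm), "volumes.tsv"))
    if (!is.null(corr)) {
      paths <- c(paths, wt(as.data.frame(corr$corrected), "corrected.tsv"),
                 wt(as.data.frame(corr$verification), "verification.tsv"))
    }
    paths <- c(paths, wt(as.data.frame(bs), "bin_summaries.tsv"),
               wt(changes, "changes.tsv"), wt(patterns, "patterns.tsv"))
    logp <- file.path(config$out_dir, "run_log.txt")
    writeLines(log, logp)
    paths <- c(paths, logp)
  }
  invisible(list(volumes = vm, correction = corr, bin_summary = bs,
                 changes = changes, patterns = patterns, log = log,
                 paths = paths))
}

# checksum of the numeric content of a volume matrix, for provenance headers
digest_volumes <- function(vm) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  write_volume_table(vm, tf)
  unname(tools::md5sum(tf))
}

#' Group a change table by lobe
#'
#' Arranges per-region change statistics into the canonical lobe order
#' (subcortical, frontal, parietal, temporal, occipital, cingulate, other)
#' for reporting.
#'
#' @param changes data frame from [change_metrics()] (or
#'   [trajectory_table()]).
#' @param taxonomy taxonomy data frame, as [dkt_taxonomy()].
#' @return The input with a `lobe` column, ordered by lobe then region.
#'   Regions unknown to the taxonomy raise an error listing them.
#' @export
build_change_table <- function(changes, taxonomy = dkt_taxonomy()) {
  lut <- unique(taxonomy[c("bilateral_name", "lobe")])
  lobe <- lut$lobe[match(changes$region, lut$bilateral_name)]
  if (any(is.na(lobe)) && nrow(changes)) {
    stop("region(s) unknown to the taxonomy: ",
         paste(changes$region[is.na(lobe)], collapse = ", "))
  }
  out <- cbind(lobe = lobe, changes)
  out <- out[order(match(out$lobe, lobe_levels()), out$region), ]
  rownames(out) <- NULL
  out
}
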