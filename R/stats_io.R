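#' Parse a FreeSurfer/FastSurfer-style stats file
#'
#' Reads the whitespace-column tables written by segmentation pipelines:
#' the `aseg.stats` dialect (subcortical segmentations; volume in the
#' `Volume_mm3` column, label in `StructName`) and the `aparc.stats` dialect
#' (cortical parcellations; gray-matter volume in `GrayVol`, label in
#' `StructName`). Header lines are `#`-prefixed; when a `# ColHeaders` line
#' is present it determines the column layout, otherwise the conventional
#' positions are assumed (aseg: volume column 4, label column 5; aparc:
#' label column 1, volume column 4).
#'
#' @param path path to a stats file, or a character vector of lines.
#' @param dialect `"aseg"` or `"aparc"`.
#' @param hemisphere for the aparc dialect, `"lh"` or `"rh"`; labels are
#'   prefixed `ctx-<hemisphere>-`. Ignored for aseg.
#' @return Named numeric vector of volumes in cubic millimetres, one entry
#'   per data row. Unparseable rows raise a warning naming them; a file with
#'   no data rows returns an empty vector with a warning.
#' @examples
#' lines <- c("# Title example", "# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
#'            "1 4 100 100.0 Left-Lateral-Ventricle")
#' parse_stats_file(lines, "aseg")
#' @export
parse_stats_file <- function(path, dialect = c("aseg", "aparc"),
                             hemisphere = c("lh", "rh")) {
  dialect <- match.arg(dialect)
  hemisphere <- match.arg(hemisphere)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else as.character(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  dat <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]

  vol_name <- if (dialect == "aseg") "Volume_mm3" else "GrayVol"
  vol_idx <- if (dialect == "aseg") 4L else 4L
  lab_idx <- if (dialect == "aseg") 5L else 1L
  ch <- grep("^\\s*#\\s*ColHeaders", hdr, value = TRUE)
  if (length(ch)) {
    cols <- strsplit(trimws(sub("^\\s*#\\s*ColHeaders", "", ch[1])),
                     "\\s+")[[1]]
    if (!vol_name %in% cols) {
      stop("stats file lacks the '", vol_name, "' column required by the '",
           dialect, "' dialect")
    }
    vol_idx <- match(vol_name, cols)
    lab_idx <- match("StructName", cols)
    if (is.na(lab_idx)) stop("stats file lacks the 'StructName' column")
  }
  if (!length(dat)) {
    warning("no data rows in stats input")
    return(stats::setNames(numeric(0), character(0)))
  }
  fields <- strsplit(trimws(dat), "\\s+")
  bad <- vapply(fields, function(f) {
    length(f) < max(vol_idx, lab_idx) ||
      is.na(suppressWarnings(as.numeric(f[vol_idx])))
  }, logical(1))
  if (any(bad)) {
    warning(sum(bad), " unparseable row(s) skipped: ",
            paste(utils::head(trimws(dat)[bad], 3), collapse = " | "))
  }
  fields <- fields[!bad]
  labels <- vapply(fields, `[[`, character(1), lab_idx)
  if (dialect == "aparc") labels <- paste0("ctx-", hemisphere, "-", labels)
  vols <- vapply(fields, function(f) as.numeric(f[vol_idx]), numeric(1))
  if (anyDuplicated(labels)) {
    stop("duplicated region label(s) in stats file: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  stats::setNames(vols, labels)
}

#' Write volumes as an aseg-style stats file
#'
#' Emits the whitespace-column dialect read back by [parse_stats_file()];
#' the round trip is exact on values printed with full precision.
#'
#' @param volumes named numeric vector (names are structure labels).
#' @param path output path.
#' @param dialect `"aseg"` or `"aparc"` (aparc writes `StructName` first and
#'   the volume in the `GrayVol` column).
#' @return Invisibly, `path`.
#' @export
write_stats_file <- function(volumes, path, dialect = c("aseg", "aparc")) {
  dialect <- match.arg(dialect)
  stopifnot(is.numeric(volumes), !is.null(names(volumes)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Table of segmented structure volumes (mm3)", con)
  if (dialect == "aseg") {
    writeLines("# ColHeaders Index SegId NVoxels Volume_mm3 StructName", con)
    for (i in seq_along(volumes)) {
      writeLines(sprintf("%d %d %d %.17g %s", i, i, 0L, volumes[i],
                         names(volumes)[i]), con)
    }
  } else {
    writeLines("# ColHeaders StructName NumVert SurfArea GrayVol", con)
    for (i in seq_along(volumes)) {
      writeLines(sprintf("%s %d %d %.17g", names(volumes)[i], 0L, 0L,
                         volumes[i]), con)
    }
  }
  invisible(path)
}

#' Read a delimited subject-by-region volume table
#'
#' Expects a header `subject_id,cohort,age,sex,<region...>`; the delimiter
#' is inferred from the extension (`.tsv` = tab, otherwise comma). All
#' non-metadata columns are treated as region volumes in cubic millimetres.
#'
#' @param path path to a CSV/TSV file.
#' @param provenance provenance tag recorded on the result.
#' @return A [volume_matrix()].
#' @export
load_volume_table <- function(path, provenance = "raw") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  # metadata must stay character (an all-"F" sex column would otherwise be
  # read as logical)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character",
                                         cohort = "character",
                                         sex = "character"))
  volume_matrix(df, provenance = provenance)
}

#' Write a volume matrix as a delimited table
#'
#' Inverse of [load_volume_table()]: values survive the round trip exactly.
#'
#' @param x a [volume_matrix()].
#' @param path output path (`.tsv` writes tab-separated, else comma).
#' @param comment optional character vector written as `#`-prefixed header
#'   lines (provenance notes).
#' @return Invisibly, `path`.
#' @export
write_volume_table <- function(x, path, comment = NULL) {
  stopifnot(inherits(x, "volume_matrix"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- x$data
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  writeLines(paste(names(df), collapse = sep), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
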