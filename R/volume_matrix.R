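#' Construct a volume matrix
#'
#' The pipeline's universal data container: one row per subject with
#' metadata columns (`subject_id`, `cohort`, `age`, `sex`) followed by one
#' numeric column per region holding volumes in cubic millimetres. Sex codes
#' are normalized to `"M"`/`"F"`; missing volumes are allowed (`NA`) and are
#' excluded region-wise downstream, never by dropping the subject.
#'
#' @param data data frame with the four metadata columns and numeric region
#'   columns.
#' @param regions character vector naming the region columns; defaults to all
#'   non-metadata columns of `data`.
#' @param provenance free-text provenance tag (`"raw"`, `"corrected"`,
#'   `"synthetic"`, ...).
#' @return An object of class `volume_matrix`: a list with elements `data`,
#'   `regions` and `provenance`.
#' @examples
#' df <- data.frame(subject_id = c("s1", "s2"), cohort = "A",
#'                  age = c(25, 67), sex = c("M", "F"),
#'                  `Left-Hippocampus` = c(4400, 4100), check.names = FALSE)
#' vm <- volume_matrix(df)
#' vm
#' @export
volume_matrix <- function(data, regions = NULL,
                          provenance = "raw") {
  stopifnot(is.data.frame(data))
  meta <- c("subject_id", "cohort", "age", "sex")
  missing_meta <- setdiff(meta, names(data))
  if (length(missing_meta)) {
    stop("missing required metadata column(s): ",
         paste(missing_meta, collapse = ", "))
  }
  if (is.null(regions)) regions <- setdiff(names(data), meta)
  if (!length(regions)) stop("no region columns found")
  if (anyDuplicated(data$subject_id)) {
    stop("duplicated subject_id: ",
         paste(unique(data$subject_id[duplicated(data$subject_id)]),
               collapse = ", "))
  }
  if (!is.numeric(data$age) || any(!is.na(data$age) &
                                   (data$age < 0 | data$age > 120))) {
    stop("age must be numeric within [0, 120]")
  }
  data$sex <- normalize_sex(data$sex)
  data$subject_id <- as.character(data$subject_id)
  data$cohort <- as.character(data$cohort)
  for (r in regions) {
    v <- data[[r]]
    if (!is.numeric(v)) {
      bad <- data$subject_id[which(is.na(suppressWarnings(as.numeric(v))) &
                                     !is.na(v))]
      stop("non-numeric volume in region '", r, "' for subject(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    # residualized volumes may legitimately go negative; raw ones may not
    if (provenance != "corrected" && any(!is.na(v) & v < 0)) {
      stop("negative volume in region '", r, "'")
    }
  }
  structure(list(data = data[c(meta, regions)], regions = regions,
                 provenance = provenance),
            class = "volume_matrix")
}

normalize_sex <- function(sex) {
  s <- toupper(trimws(as.character(sex)))
  s[s %in% c("M", "MALE", "1")] <- "M"
  s[s %in% c("F", "FEMALE", "0")] <- "F"
  bad <- unique(s[!is.na(s) & !s %in% c("M", "F")])
  if (length(bad)) {
    stop("unknown sex code(s): ", paste(bad, collapse = ", "))
  }
  s
}

#' @export
print.volume_matrix <- function(x, ...) {
  cat("<volume_matrix> ", nrow(x$data), " subjects x ",
      length(x$regions), " regions (", x$provenance, ")\n", sep = "")
  cat("  cohorts: ", paste(names(table(x$data$cohort)), collapse = ", "),
      "\n", sep = "")
  ar <- range(x$data$age, na.rm = TRUE)
  cat("  age range: ", ar[1], "-", ar[2], "\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_matrix <- function(x) c(nrow(x$data), length(x$regions))

#' @export
as.data.frame.volume_matrix <- function(x, ...) x$data

#' Extract one region's volumes
#'
#' @param x a [volume_matrix()].
#' @param region region column name.
#' @return Numeric vector of volumes (may contain `NA`).
#' @export
region_values <- function(x, region) {
  stopifnot(inherits(x, "volume_matrix"))
  if (!region %in% x$regions) stop("unknown region: ", region)
  x$data[[region]]
}

#' Combine left/right pairs into bilateral volumes
#'
#' For every bilateral pair present in the taxonomy the left and right
#' volumes are summed per subject; midline structures pass through
#' unchanged. If one hemisphere is missing for a subject, the bilateral
#' value is `NA` for that subject (the subject is kept). Total volume mass
#' is conserved: the sum over all output columns equals the sum over all
#' input columns for every subject with complete data.
#'
#' @param x a [volume_matrix()] with lateralized region names.
#' @param taxonomy taxonomy data frame, as from [dkt_taxonomy()].
#' @return A [volume_matrix()] whose regions are bilateral display names
#'   plus midline structures (50 when all 95 inputs are present).
#' @examples
#' tax <- dkt_taxonomy()
#' df <- data.frame(subject_id = "s1", cohort = "A", age = 30, sex = "F",
#'                  `Left-Hippocampus` = 4384, `Right-Hippocampus` = 4384,
#'                  `Brain-Stem` = 20063.7, check.names = FALSE)
#' vb <- combine_bilateral(volume_matrix(df), tax)
#' region_values(vb, "Hippocampus")  # 8768
#' @export
combine_bilateral <- function(x, taxonomy = dkt_taxonomy()) {
  stopifnot(inherits(x, "volume_matrix"))
  regs <- normalize_region_name(x$regions)
  dat <- x$data
  names(dat)[match(x$regions, names(dat))] <- regs
  tax <- taxonomy[taxonomy$region_name %in% regs, ]
  unknown <- setdiff(regs, taxonomy$region_name)
  out <- dat[c("subject_id", "cohort", "age", "sex")]
  out_regions <- character(0)
  for (bn in unique(tax$bilateral_name)) {
    sub <- tax[tax$bilateral_name == bn, ]
    if (all(sub$laterality == "midline")) {
      out[[bn]] <- dat[[sub$region_name[1]]]
    } else {
      ln <- sub$region_name[sub$laterality == "left"]
      rn <- sub$region_name[sub$laterality == "right"]
      if (!length(ln) || !length(rn) ||
          !ln %in% names(dat) || !rn %in% names(dat)) {
        warning("region '", bn, "' missing one hemisphere; marked NA")
        out[[bn]] <- rep(NA_real_, nrow(dat))
      } else {
        out[[bn]] <- dat[[ln]] + dat[[rn]]
      }
    }
    out_regions <- c(out_regions, bn)
  }
  if (length(unknown)) {
    # pass unrecognized columns through untouched so no volume is lost
    for (u in unknown) out[[u]] <- dat[[u]]
    out_regions <- c(out_regions, unknown)
    warning("region(s) not in taxonomy passed through: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  }
  volume_matrix(out, out_regions, provenance = x$provenance)
}
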