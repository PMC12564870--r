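#' The 95-structure region taxonomy
#'
#' Catalogue of the 95 brain structures segmented under the
#' Desikan-Killiany-Tourville (DKT) convention: 45 bilateral pairs (90
#' lateralized structures) plus 5 midline structures (3rd and 4th ventricles,
#' brain stem, white-matter hypointensities, CSF). Each entry carries the
#' canonical FreeSurfer/FastSurfer label, its laterality, the display name of
#' the combined bilateral structure, and the anatomical lobe used for
#' grouped reporting (subcortical, frontal, parietal, temporal, occipital,
#' cingulate, other). The insula is grouped with the temporal lobe; the
#' lateral and inferior lateral ventricles fall under "other"; choroid plexus
#' and ventral diencephalon are subcortical.
#'
#' @return A data frame with one row per structure and columns
#'   `region_name` (canonical label, e.g. `"Left-Hippocampus"` or
#'   `"ctx-lh-parstriangularis"`), `laterality` (`"left"`, `"right"` or
#'   `"midline"`), `bilateral_name` (display name shared by a left/right
#'   pair, e.g. `"Hippocampus"`), and `lobe`.
#' @examples
#' tax <- dkt_taxonomy()
#' nrow(tax)                      # 95
#' table(tax$lobe[tax$laterality != "right"])
#' @export
dkt_taxonomy <- function() {
  # subcortical segmentations: display name -> aseg stem
  seg <- list(
    subcortical = c(
      "Thalamus"        = "Thalamus",
      "Caudate"         = "Caudate",
      "Putamen"         = "Putamen",
      "Pallidum"        = "Pallidum",
      "Hippocampus"     = "Hippocampus",
      "Amygdala"        = "Amygdala",
      "Accumbens Area"  = "Accumbens-area",
      "Ventral DC"      = "VentralDC",
      "Choroid Plexus"  = "choroid-plexus"),
    other = c(
      "Lateral Ventricle"       = "Lateral-Ventricle",
      "Inf Lat Vent"            = "Inf-Lat-Vent",
      "Cerebellum White Matter" = "Cerebellum-White-Matter",
      "Cerebellum Cortex"       = "Cerebellum-Cortex",
      "Cerebral White Matter"   = "Cerebral-White-Matter"))
  ctx <- list(
    frontal = c(
      "Caudal Middle Frontal"  = "caudalmiddlefrontal",
      "Rostral Middle Frontal" = "rostralmiddlefrontal",
      "Superior Frontal"       = "superiorfrontal",
      "Lateral Orbitofrontal"  = "lateralorbitofrontal",
      "Medial Orbitofrontal"   = "medialorbitofrontal",
      "Pars Opercularis"       = "parsopercularis",
      "Pars Orbitalis"         = "parsorbitalis",
      "Pars Triangularis"      = "parstriangularis",
      "Precentral"             = "precentral"),
    parietal = c(
      "Inferior Parietal" = "inferiorparietal",
      "Superior Parietal" = "superiorparietal",
      "Supramarginal"     = "supramarginal",
      "Paracentral"       = "paracentral",
      "Postcentral"       = "postcentral",
      "Precuneus"         = "precuneus"),
    temporal = c(
      "Entorhinal"          = "entorhinal",
      "Fusiform"            = "fusiform",
      "Inferior Temporal"   = "inferiortemporal",
      "Middle Temporal"     = "middletemporal",
      "Superior Temporal"   = "superiortemporal",
      "Transverse Temporal" = "transversetemporal",
      "Parahippocampal"     = "parahippocampal",
      "Insula"              = "insula"),
    occipital = c(
      "Cuneus"            = "cuneus",
      "Lateral Occipital" = "lateraloccipital",
      "Lingual"           = "lingual",
      "Pericalcarine"     = "pericalcarine"),
    cingulate = c(
      "Caudal Anterior Cingulate"  = "caudalanteriorcingulate",
      "Isthmus Cingulate"          = "isthmuscingulate",
      "Posterior Cingulate"        = "posteriorcingulate",
      "Rostral Anterior Cingulate" = "rostralanteriorcingulate"))
  midline <- c(
    "3rd Ventricle"      = "3rd-Ventricle",
    "4th Ventricle"      = "4th-Ventricle",
    "Brain Stem"         = "Brain-Stem",
    "CSF"                = "CSF",
    "WM Hypointensities" = "WM-hypointensities")

  rows <- list()
  for (lobe in names(seg)) {
    for (disp in names(seg[[lobe]])) {
      stem <- seg[[lobe]][[disp]]
      rows[[length(rows) + 1L]] <- data.frame(
        region_name = paste0(c("Left-", "Right-"), stem),
        laterality = c("left", "right"),
        bilateral_name = disp, lobe = lobe)
    }
  }
  for (lobe in names(ctx)) {
    for (disp in names(ctx[[lobe]])) {
      stem <- ctx[[lobe]][[disp]]
      rows[[length(rows) + 1L]] <- data.frame(
        region_name = paste0("ctx-", c("lh", "rh"), "-", stem),
        laterality = c("left", "right"),
        bilateral_name = disp, lobe = lobe)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    region_name = unname(midline), laterality = "midline",
    bilateral_name = names(midline), lobe = "other")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Canonical order of lobes for grouped reporting
#' @return Character vector of the seven lobe labels.
#' @export
lobe_levels <- function() {
  c("subcortical", "frontal", "parietal", "temporal",
    "occipital", "cingulate", "other")
}

# alias map: labels seen in the wild -> canonical labels of dkt_taxonomy()
.region_aliases <- c(
  "Left-Thalamus-Proper"  = "Left-Thalamus",
  "Right-Thalamus-Proper" = "Right-Thalamus",
  "Brainstem"             = "Brain-Stem",
  "3rd-ventricle"         = "3rd-Ventricle",
  "4th-ventricle"         = "4th-Ventricle")

#' Normalize region labels to the canonical taxonomy names
#'
#' Maps common label variants (e.g. `"Left-Thalamus-Proper"` from older
#' FreeSurfer releases) onto the canonical names used by [dkt_taxonomy()].
#' Unknown labels pass through unchanged.
#'
#' @param x character vector of region labels.
#' @return character vector of the same length.
#' @export
normalize_region_name <- function(x) {
  hit <- x %in% names(.region_aliases)
  x[hit] <- .region_aliases[x[hit]]
  x
}

#' Pipeline-validation lobe grouping
#'
#' The coarser six-category grouping used when benchmarking one segmentation
#' pipeline against another: frontal, parietal, temporal and occipital
#' cortical lobes, a limbic group (the cingulate structures together with
#' the parahippocampal and entorhinal cortices), and the cerebellum
#' (cortex plus white matter). Subcortical nuclei and ventricular/CSF
#' compartments are not part of this grouping.
#'
#' @return Named character vector mapping `bilateral_name` to one of
#'   `"Frontal lobe"`, `"Parietal lobe"`, `"Temporal lobe"`,
#'   `"Occipital lobe"`, `"Limbic lobe"`, `"Cerebellum"`.
#' @export
validation_lobes <- function() {
  tax <- dkt_taxonomy()
  tax <- tax[tax$laterality != "right", ]
  limbic <- c("Caudal Anterior Cingulate", "Isthmus Cingulate",
              "Posterior Cingulate", "Rostral Anterior Cingulate",
              "Parahippocampal", "Entorhinal")
  cereb <- c("Cerebellum Cortex", "Cerebellum White Matter")
  grp <- character(0)
  for (i in seq_len(nrow(tax))) {
    bn <- tax$bilateral_name[i]
    g <- if (bn %in% limbic) "Limbic lobe"
         else if (bn %in% cereb) "Cerebellum"
         else switch(tax$lobe[i],
                     frontal = "Frontal lobe", parietal = "Parietal lobe",
                     temporal = "Temporal lobe", occipital = "Occipital lobe",
                     NA_character_)
    grp[bn] <- g
  }
  grp[!is.na(grp)]
}
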