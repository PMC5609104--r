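#' Fixed receptor sequence of the 15-receptor panel
#'
#' The canonical ordering of the receptor axes used for all fingerprints
#' and polar plots. Comparability of fingerprints requires that every
#' collection share one receptor sequence, so this order is fixed
#' package-wide: glutamate (AMPA, NMDA, kainate), GABA (GABAA, GABAA/BZ,
#' GABAB), acetylcholine (M1, M2, M3, a4b2), noradrenaline (a1, a2),
#' serotonin (5-HT1A, 5-HT2) and dopamine (D1).
#'
#' @return character vector of length 15.
#' @export
receptor_order <- function() {
  c("AMPA", "NMDA", "kainate", "GABAA", "GABAA_BZ", "GABAB",
    "M1", "M2", "M3", "a4b2", "a1", "a2", "5-HT1A", "5-HT2", "D1")
}

#' Receptor panel with laminar distribution classes
#'
#' Describes the 15-receptor panel used by the synthetic ground-truth
#' generator: a base mean-areal density per receptor (fmol/mg protein)
#' and a laminar pattern class. Base magnitudes follow the empirical
#' rule that ionotropic GABA and glutamate receptors reach densities one
#' to two orders of magnitude above the modulatory (aminergic,
#' cholinergic, dopaminergic) receptors.
#'
#' Laminar pattern classes:
#' \describe{
#'   \item{canonical}{supragranular > granular > infragranular, the
#'     dominant laminar sequence across the cortex.}
#'   \item{infra_peak}{highest density in the infragranular stratum
#'     (kainate).}
#'   \item{granular_low}{highest in the supragranular and lowest in the
#'     granular stratum (a1, 5-HT1A).}
#'   \item{granular_peak_primary}{in primary sensory areas the granular
#'     stratum dominates (M2, nicotinic a4b2); canonical elsewhere.}
#' }
#'
#' @param receptors optional subset (character) of [receptor_order()].
#' @return data.frame with columns `receptor`, `base`, `pattern`.
#' @export
receptor_panel <- function(receptors = receptor_order()) {
  base <- c(AMPA = 430, NMDA = 1100, kainate = 520, GABAA = 1400,
            GABAA_BZ = 1700, GABAB = 1200, M1 = 650, M2 = 180, M3 = 500,
            a4b2 = 25, a1 = 300, a2 = 270, `5-HT1A` = 320, `5-HT2` = 350,
            D1 = 90)
  pattern <- c(AMPA = "canonical", NMDA = "canonical",
               kainate = "infra_peak", GABAA = "canonical",
               GABAA_BZ = "canonical", GABAB = "canonical",
               M1 = "canonical", M2 = "granular_peak_primary",
               M3 = "canonical", a4b2 = "granular_peak_primary",
               a1 = "granular_low", a2 = "canonical",
               `5-HT1A` = "granular_low", `5-HT2` = "canonical",
               D1 = "canonical")
  unknown <- setdiff(receptors, names(base))
  if (length(unknown)) {
    abort("unknown receptor(s): %s", paste(unknown, collapse = ", "))
  }
  data.frame(receptor = receptors, base = unname(base[receptors]),
             pattern = unname(pattern[receptors]),
             stringsAsFactors = FALSE)
}

#' Cortical area panel
#'
#' The 44 iso- and periallocortical areas of the visual, somatosensory,
#' auditory, motor and multimodal association systems, with their
#' functional group, agranular flag (motor areas 4 and 6 and cingulate
#' area 24 lack a visible layer IV) and primary-sensory flag (V1, 3b,
#' 41). Laminar border depth fractions `f1` (supragranular/granular) and
#' `f2` (granular/infragranular) are nominal values on the normalized
#' 0--1 cortical depth axis; agranular areas instead carry the depth
#' fraction of the lower border of layer III
#' (`layerIII_lower_fraction`), below which a granular stripe of 3% of
#' the cortical depth is assumed by convention.
#'
#' @param full logical; if `FALSE` return the reduced 8-area panel used
#'   for fast end-to-end checks (one area per functional group, all
#'   three primary sensory areas, one agranular area).
#' @return data.frame with columns `area`, `group`, `agranular`,
#'   `primary_sensory`, `f1`, `f2`, `layerIII_lower_fraction`.
#' @export
area_panel <- function(full = TRUE) {
  areas <- c("V1", "V2d", "V2v", "V3d", "V3A", "V3v", "V4v", "FG1", "FG2",
             "3a", "3b", "1", "2", "41", "42", "22",
             "4", "6",
             "44", "45", "46", "47", "8", "9", "10L", "10M", "11", "32",
             "5L", "5M", "PFt", "PFm", "PGa", "PGp",
             "20", "21", "36", "38", "37L", "37M", "37B",
             "24", "23", "31")
  group <- c(rep("visual", 9),
             rep("somatosensory", 4), rep("auditory", 3),
             rep("motor", 2),
             rep("prefrontal", 10),
             rep("parietal", 6),
             rep("temporal", 7),
             rep("cingulate", 3))
  agranular <- areas %in% c("4", "6", "24")
  primary <- areas %in% c("V1", "3b", "41")
  df <- data.frame(area = areas, group = group, agranular = agranular,
                   primary_sensory = primary,
                   f1 = ifelse(agranular, NA_real_, 0.5),
                   f2 = ifelse(agranular, NA_real_, 0.7),
                   layerIII_lower_fraction = ifelse(agranular, 0.55, NA_real_),
                   stringsAsFactors = FALSE)
  # V1's exceptionally broad layer IV
  df$f2[df$area == "V1"] <- 0.75
  if (!full) {
    keep <- c("V1", "3b", "41", "4", "PFm", "21", "11", "23")
    df <- df[match(keep, df$area), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Default study configuration for the synthetic-data generator
#'
#' Bundles the receptor and area panels with the replicate design
#' (3 brains) and noise levels into the configuration consumed by
#' [generate_ground_truth()]. The full design covers 44 areas x 15
#' receptors x 3 strata x 3 brains; the reduced design (8 areas x 6
#' receptors x 3 brains) preserves every laminar pattern class and the
#' agranular/primary-sensory special cases and is intended for fast
#' checks.
#'
#' @param full logical; full-size (44 x 15) or reduced (8 x 6) design.
#' @param n_brains number of replicate brains.
#' @param replicate_cv between-brain coefficient of variation of the
#'   densities (multiplicative log-normal noise).
#' @param area_sd standard deviation (log scale) of the per-area,
#'   per-receptor density modulation that creates regional heterogeneity.
#' @param group_sd standard deviation (log scale) of the shared
#'   functional-group modulation, which makes areas of one functional
#'   system resemble each other.
#' @return a list of class `study_config`.
#' @export
study_config <- function(full = FALSE, n_brains = 3L, replicate_cv = 0.05,
                         area_sd = 0.12, group_sd = 0.10) {
  receptors <- if (full) receptor_order() else
    c("NMDA", "kainate", "GABAA", "M2", "a4b2", "5-HT1A")
  cfg <- list(areas = area_panel(full = full),
              receptors = receptor_panel(receptors),
              n_brains = as.integer(n_brains),
              replicate_cv = replicate_cv,
              area_sd = area_sd,
              group_sd = group_sd)
  class(cfg) <- "study_config"
  cfg
}
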