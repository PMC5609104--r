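#' Laminar density multipliers of the pattern classes
#'
#' Multipliers applied to a receptor's base density to obtain the
#' expected supragranular/granular/infragranular densities. The
#' canonical class encodes the dominant cortical sequence sg > g > ig;
#' `infra_peak` places the maximum in the infragranular stratum;
#' `granular_low` combines a supragranular maximum with a granular
#' minimum; `granular_peak_primary` produces the granular-layer maximum
#' seen in primary sensory areas (canonical elsewhere).
#'
#' @return named list of numeric vectors `c(sg=, g=, ig=)`.
#' @keywords internal
laminar_multipliers <- function() {
  list(canonical = c(sg = 1.30, g = 1.00, ig = 0.70),
       infra_peak = c(sg = 0.95, g = 0.75, ig = 1.25),
       granular_low = c(sg = 1.40, g = 0.70, ig = 1.00),
       granular_peak_primary = c(sg = 1.05, g = 1.60, ig = 0.70))
}

#' Generate a ground-truth receptor density table
#'
#' Produces area x receptor x stratum x brain densities (fmol/mg
#' protein) with the qualitative laminar and regional structure of
#' cortical receptor architecture: a canonical supragranular > granular
#' > infragranular gradient for most receptors, an infragranular maximum
#' for kainate, a granular minimum for a1 and 5-HT1A, and
#' granular-layer peaks of M2 and nicotinic a4b2 restricted to primary
#' sensory areas. Regional heterogeneity is created by multiplicative
#' log-normal modulations shared within functional groups plus
#' area-specific modulation; these factors scale all three strata of an
#' area equally, so the planted laminar ordering holds in every area.
#' Between-brain replicates add independent log-normal noise with the
#' configured coefficient of variation.
#'
#' @param config a [study_config()] (or compatible list). Receptor rows
#'   may alternatively carry explicit per-stratum base densities in
#'   columns `sg`, `g`, `ig`, which bypass the pattern multipliers.
#' @param seed integer seed; identical seeds give identical tables.
#' @param multipliers optional replacement for [laminar_multipliers()];
#'   each element must be a numeric vector named with the stratum labels
#'   `sg`, `g`, `ig`.
#' @return object of class `ground_truth`: a list with `densities`
#'   (long data.frame `area, receptor, stratum, brain, density`),
#'   `expected` (noise-free area-level densities), `config`, and `seed`.
#' @export
generate_ground_truth <- function(config, seed = 1L,
                                  multipliers = laminar_multipliers()) {
  areas <- config$areas
  receptors <- config$receptors
  if (is.null(areas) || nrow(areas) < 2L) {
    abort("config must name at least 2 areas")
  }
  if (is.null(receptors) || nrow(receptors) < 2L) {
    abort("config must name at least 2 receptors")
  }
  cv <- config$replicate_cv
  if (!is_num1(cv) || cv < 0) abort("replicate_cv must be >= 0")
  n_brains <- config$n_brains
  if (!is_num1(n_brains) || n_brains < 1L) abort("n_brains must be >= 1")
  explicit <- all(c("sg", "g", "ig") %in% names(receptors))
  if (!explicit) {
    if (any(!is.finite(receptors$base) | receptors$base <= 0)) {
      abort("non-positive base density for receptor(s): %s",
            paste(receptors$receptor[!(receptors$base > 0)], collapse = ", "))
    }
    bad <- setdiff(unique(receptors$pattern), names(multipliers))
    if (length(bad)) abort("unknown laminar pattern(s): %s",
                           paste(bad, collapse = ", "))
    for (m in multipliers) {
      if (!setequal(names(m), c("sg", "g", "ig"))) {
        abort("unknown stratum label in multipliers: %s",
              paste(setdiff(names(m), c("sg", "g", "ig")), collapse = ", "))
      }
    }
  } else if (any(!(unlist(receptors[, c("sg", "g", "ig")]) > 0))) {
    abort("non-positive base density in explicit sg/g/ig columns")
  }
  area_sd <- if (is.null(config$area_sd)) 0 else config$area_sd
  group_sd <- if (is.null(config$group_sd)) 0 else config$group_sd

  strata <- c("sg", "g", "ig")
  with_seed(seed, {
    groups <- unique(areas$group)
    group_eff <- matrix(rnorm(length(groups) * nrow(receptors), 0, group_sd),
                        nrow = length(groups),
                        dimnames = list(groups, receptors$receptor))
    area_eff <- matrix(rnorm(nrow(areas) * nrow(receptors), 0, area_sd),
                       nrow = nrow(areas),
                       dimnames = list(areas$area, receptors$receptor))

    expected <- expand.grid(area = areas$area, receptor = receptors$receptor,
                            stratum = strata, KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
    ai <- match(expected$area, areas$area)
    ri <- match(expected$receptor, receptors$receptor)
    if (explicit) {
      base_mat <- as.matrix(receptors[, strata])
      lam <- base_mat[cbind(ri, match(expected$stratum, strata))]
    } else {
      pat <- receptors$pattern[ri]
      pat[pat == "granular_peak_primary" & !areas$primary_sensory[ai]] <-
        "canonical"
      mult <- mapply(function(p, s) multipliers[[p]][[s]], pat,
                     expected$stratum)
      lam <- receptors$base[ri] * mult
    }
    mod <- exp(group_eff[cbind(match(areas$group[ai], groups), ri)] +
                 area_eff[cbind(ai, ri)])
    expected$density <- lam * mod

    densities <- expected[rep(seq_len(nrow(expected)), each = n_brains), ]
    densities$brain <- rep(seq_len(n_brains), times = nrow(expected))
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      noise <- exp(rnorm(nrow(densities), -sdlog^2 / 2, sdlog))
      densities$density <- densities$density * noise
    }
    rownames(densities) <- NULL
    rownames(expected) <- NULL
    out <- list(densities = densities[, c("area", "receptor", "stratum",
                                          "brain", "density")],
                expected = expected, config = config,
                replicate_cv = cv, n_brains = as.integer(n_brains),
                seed = as.integer(seed))
    class(out) <- "ground_truth"
    out
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d areas x %d receptors x 3 strata x %d brains (seed %d, cv %.3g)\n",
              nrow(x$config$areas), nrow(x$config$receptors),
              x$n_brains, x$seed, x$replicate_cv))
  invisible(x)
}

#' Stratum thickness weights of an area
#'
#' Depth-fraction widths of the supragranular, granular and
#' infragranular sectors. Granular areas use the laminar border
#' fractions `(f1, f2)`; agranular areas use the 3%-of-depth granular
#' stripe below the lower border of layer III.
#'
#' @param area_row one row of an area panel data.frame.
#' @return named numeric `c(sg=, g=, ig=)` summing to 1.
#' @export
stratum_weights <- function(area_row) {
  if (isTRUE(area_row$agranular)) {
    l3 <- area_row$layerIII_lower_fraction
    if (!is_num1(l3) || l3 <= 0 || l3 + 0.03 >= 1) {
      abort("invalid layerIII_lower_fraction for area %s", area_row$area)
    }
    c(sg = l3, g = 0.03, ig = 1 - l3 - 0.03)
  } else {
    f1 <- area_row$f1; f2 <- area_row$f2
    if (!is_num1(f1) || !is_num1(f2) || !(0 < f1 && f1 < f2 && f2 < 1)) {
      abort("border fractions must satisfy 0 < f1 < f2 < 1 for area %s",
            area_row$area)
    }
    c(sg = f1, g = f2 - f1, ig = 1 - f2)
  }
}

#' Expand a ground-truth table with the all-layer mean
#'
#' Adds an `all` stratum per (area, receptor, brain): the
#' thickness-weighted mean of the three strata densities using each
#' area's laminar border fractions. This mirrors the mean areal density
#' computed as the integral beneath a full-depth profile.
#'
#' @param truth a `ground_truth` object or a long density data.frame
#'   with strata `sg`, `g`, `ig`.
#' @param areas area panel (required when `truth` is a plain
#'   data.frame).
#' @return long data.frame `area, receptor, stratum, brain, density`
#'   with strata `sg`, `g`, `ig`, `all`.
#' @export
add_all_stratum <- function(truth, areas = NULL) {
  if (inherits(truth, "ground_truth")) {
    df <- truth$densities
    areas <- truth$config$areas
  } else {
    df <- truth
    if (is.null(areas)) abort("'areas' panel required")
  }
  wide <- stats::reshape(df, idvar = c("area", "receptor", "brain"),
                         timevar = "stratum", direction = "wide")
  w <- t(vapply(seq_len(nrow(wide)), function(i) {
    stratum_weights(areas[match(wide$area[i], areas$area), , drop = FALSE])
  }, numeric(3)))
  wide$density.all <- w[, "sg"] * wide$density.sg + w[, "g"] * wide$density.g +
    w[, "ig"] * wide$density.ig
  long <- stats::reshape(wide, direction = "long",
                         varying = paste0("density.", c("sg", "g", "ig", "all")),
                         v.names = "density", timevar = "stratum",
                         times = c("sg", "g", "ig", "all"))
  rownames(long) <- NULL
  long[order(long$area, long$receptor, long$stratum, long$brain),
       c("area", "receptor", "stratum", "brain", "density")]
}
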