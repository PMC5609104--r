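#' Bonferroni correction
#'
#' Multiplies a raw p value by the number of tests. By default the
#' product is reported unclipped, so values above 1 are possible (and
#' simply mean "not significant at any level"); set `clip = TRUE` for
#' the conventional `min(p*m, 1)`.
#'
#' @param p raw p value(s) in `[0, 1]`.
#' @param m number of tests (>= 1).
#' @param clip clip the adjusted value at 1.
#' @return adjusted p value(s).
#' @export
bonferroni <- function(p, m, clip = FALSE) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p values must lie in [0, 1]")
  if (!is_num1(m) || m < 1) abort("m must be >= 1")
  out <- p * m
  if (clip) out <- pmin(out, 1)
  out
}

# pull one layer-set out of a long strata density table
layer_slice <- function(table, layer_set, areas = NULL) {
  stopifnot(layer_set %in% c("all", "sg", "g", "ig"))
  if (!layer_set %in% table$stratum) {
    if (layer_set == "all") {
      if (is.null(areas)) abort("table lacks an 'all' stratum and no area panel was supplied")
      table <- add_all_stratum(table, areas = areas)
    } else {
      abort("table lacks stratum '%s'", layer_set)
    }
  }
  table[table$stratum == layer_set, , drop = FALSE]
}

#' Per-receptor one-way ANOVA across areas
#'
#' For each receptor separately, tests whether its density (in the
#' chosen layer set) is homogeneously distributed over the areas:
#' one-way fixed-effects ANOVA with area as the factor and brains as
#' replicates. Raw p values are Bonferroni-multiplied by the number of
#' receptors tested (unclipped by default, so adjusted values above 1
#' occur for clearly non-significant receptors).
#'
#' @param table long density table `area, receptor, stratum, brain,
#'   density`.
#' @param layer_set one of `"all"`, `"sg"`, `"g"`, `"ig"`.
#' @param m number of tests for the Bonferroni multiplier (default: the
#'   number of receptors in the table).
#' @param areas area panel, needed only to derive a missing `all`
#'   stratum.
#' @param alpha significance threshold on the adjusted p.
#' @return data.frame of class `anova_table`: `receptor, layer_set, F,
#'   df1, df2, p_raw, p_adj, significant`.
#' @export
anova_by_area <- function(table, layer_set = "all", m = NULL, areas = NULL,
                          alpha = 0.05) {
  slice <- layer_slice(table, layer_set, areas)
  receptors <- unique(slice$receptor)
  if (is.null(m)) m <- length(receptors)
  rows <- lapply(receptors, function(rc) {
    d <- slice[slice$receptor == rc, ]
    tab <- table(d$area)
    if (length(tab) < 2L) abort("need >= 2 areas")
    if (any(tab < 2L)) {
      abort("area(s) with a single replicate for receptor %s: %s", rc,
            paste(names(tab)[tab < 2L], collapse = ", "))
    }
    fit <- stats::anova(stats::lm(density ~ factor(area), data = d))
    data.frame(receptor = rc, layer_set = layer_set,
               F = fit$`F value`[1L], df1 = fit$Df[1L], df2 = fit$Df[2L],
               p_raw = fit$`Pr(>F)`[1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p_raw, m)
  out$significant <- out$p_adj <= alpha
  class(out) <- c("anova_table", class(out))
  out
}

#' Gatekept one-sample t-tests for areal density extrema
#'
#' For every receptor whose ANOVA was significant, tests in each area
#' whether the replicate densities differ from the mean density of that
#' receptor over all examined areas (the expected value, treated as a
#' fixed constant). Receptors failing the ANOVA gate are recorded as
#' not tested, never as non-significant. p values are deliberately not
#' corrected for multiple testing: these are post-hoc tests protected by
#' the significant omnibus ANOVA. Areas with zero replicate variance
#' are flagged as degenerate (no valid t statistic).
#'
#' @param table long density table as in [anova_by_area()].
#' @param anova an [anova_by_area()] result computed on the same table.
#' @param areas area panel (only to derive a missing `all` stratum).
#' @param alpha significance threshold.
#' @return data.frame of class `extrema_table`: `receptor, layer_set,
#'   area, expected, mean, t, p, significant, tested, degenerate`.
#' @export
extrema_tests <- function(table, anova, areas = NULL, alpha = 0.05) {
  layer_set <- unique(anova$layer_set)
  if (length(layer_set) != 1L) abort("anova table must cover one layer set")
  slice <- layer_slice(table, layer_set, areas)
  rows <- lapply(seq_len(nrow(anova)), function(i) {
    rc <- anova$receptor[i]
    d <- slice[slice$receptor == rc, ]
    area_means <- tapply(d$density, d$area, mean)
    grand <- mean(area_means)   # mean over areas, i.e. the expected value
    if (!anova$significant[i]) {
      return(data.frame(receptor = rc, layer_set = layer_set,
                        area = names(area_means), expected = grand,
                        mean = as.numeric(area_means),
                        t = NA_real_, p = NA_real_, significant = NA,
                        tested = FALSE, degenerate = FALSE,
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(names(area_means), function(a) {
      x <- d$density[d$area == a]
      degen <- stats::sd(x) == 0
      if (degen) {
        tt <- list(statistic = NA_real_, p.value = NA_real_)
      } else {
        tt <- stats::t.test(x, mu = grand)
      }
      data.frame(receptor = rc, layer_set = layer_set, area = a,
                 expected = grand, mean = mean(x),
                 t = unname(tt$statistic), p = tt$p.value,
                 significant = if (degen) NA else tt$p.value <= alpha,
                 tested = TRUE, degenerate = degen,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("extrema_table", class(out))
  out
}
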