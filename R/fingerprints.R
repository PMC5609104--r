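#' Build multi-receptor fingerprints from a strata density table
#'
#' A receptor fingerprint is the ordered vector of the densities of all
#' receptors of the panel in one cortical area, for one stratum or for
#' the all-layer mean. Four fingerprints are produced per area (`all`,
#' `sg`, `g`, `ig`), replicate brains are averaged beforehand, and all
#' fingerprints share one receptor sequence so they are mutually
#' comparable.
#'
#' @param table long data.frame `area, receptor, stratum, brain,
#'   density` with strata `sg`, `g`, `ig` and optionally `all` (see
#'   [add_all_stratum()]); without an `all` stratum the `areas` panel is
#'   required to derive it from the laminar border fractions.
#' @param receptors receptor sequence to use (default: the receptors
#'   present, in panel order).
#' @param areas area panel, needed only to compute a missing `all`
#'   stratum.
#' @param strata strata to build (default `all`, `sg`, `g`, `ig`).
#' @return object of class `fingerprint_set`: numeric matrix with one
#'   row per area x stratum (rownames `"area|stratum"`) and one column
#'   per receptor, plus attributes `areas`, `strata`, `receptor_order`,
#'   `normalized`.
#' @export
build_fingerprints <- function(table, receptors = NULL, areas = NULL,
                               strata = c("all", "sg", "g", "ig")) {
  need <- setdiff(strata, unique(table$stratum))
  if ("all" %in% need) {
    if (is.null(areas)) {
      abort("table lacks an 'all' stratum and no area panel was supplied")
    }
    table <- add_all_stratum(table, areas = areas)
    need <- setdiff(strata, unique(table$stratum))
  }
  if (length(need)) abort("table lacks stratum/strata: %s",
                          paste(need, collapse = ", "))
  if (is.null(receptors)) {
    receptors <- intersect(receptor_order(), unique(table$receptor))
    receptors <- c(receptors, setdiff(unique(table$receptor), receptors))
  }
  area_ids <- unique(table$area)
  agg <- stats::aggregate(density ~ area + receptor + stratum, data = table,
                          FUN = mean)
  rows <- as.vector(t(outer(area_ids, strata, paste, sep = "|")))
  M <- matrix(NA_real_, nrow = length(rows), ncol = length(receptors),
              dimnames = list(rows, receptors))
  key <- paste(agg$area, agg$stratum, sep = "|")
  for (j in seq_along(receptors)) {
    sel <- agg$receptor == receptors[j]
    M[match(key[sel], rows), j] <- agg$density[sel]
  }
  if (anyNA(M)) {
    miss <- which(is.na(M), arr.ind = TRUE)
    cells <- paste0(rownames(M)[miss[, 1]], " x ", receptors[miss[, 2]])
    abort("missing density cell(s): %s",
          paste(utils::head(cells, 5L), collapse = "; "))
  }
  structure(M, class = c("fingerprint_set", "matrix", "array"),
            areas = area_ids, strata = strata, receptor_order = receptors,
            normalized = FALSE)
}

# split "area|stratum" rownames back into their parts
fp_meta <- function(fps) {
  parts <- strsplit(rownames(fps), "|", fixed = TRUE)
  data.frame(area = vapply(parts, `[[`, character(1), 1L),
             stratum = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Subset a fingerprint collection by stratum or area
#'
#' @param fps a `fingerprint_set`.
#' @param strata strata to keep (NULL keeps all).
#' @param areas areas to keep (NULL keeps all).
#' @param exclude_areas areas to drop, e.g. the agranular areas before a
#'   granular-stratum clustering.
#' @return a `fingerprint_set`.
#' @export
subset_fingerprints <- function(fps, strata = NULL, areas = NULL,
                                exclude_areas = NULL) {
  meta <- fp_meta(fps)
  keep <- rep(TRUE, nrow(fps))
  if (!is.null(strata)) keep <- keep & meta$stratum %in% strata
  if (!is.null(areas)) keep <- keep & meta$area %in% areas
  if (!is.null(exclude_areas)) keep <- keep & !(meta$area %in% exclude_areas)
  out <- fps[keep, , drop = FALSE]
  structure(out, class = class(fps),
            areas = unique(meta$area[keep]),
            strata = if (is.null(strata)) attr(fps, "strata") else strata,
            receptor_order = attr(fps, "receptor_order"),
            normalized = attr(fps, "normalized"))
}

#' Size of a receptor fingerprint
#'
#' Two size measures of an absolute fingerprint: the sum of the receptor
#' densities, and the area of the polygon drawn by the fingerprint in a
#' polar plot with the k receptors on equiangular axes,
#' `polar_area = 1/2 sin(2*pi/k) * sum_i r_i r_{i+1 mod k}`
#' (density^2 units). Sizes of z-normalized fingerprints are refused
#' because negative z-scores make them meaningless.
#'
#' @param fp a `fingerprint_set` (sizes are computed per row) or a
#'   single numeric fingerprint vector.
#' @return data.frame with columns `sum_size` and `polar_area` (one row
#'   per fingerprint).
#' @export
fingerprint_size <- function(fp) {
  if (inherits(fp, "fingerprint_set") && isTRUE(attr(fp, "normalized"))) {
    abort("fingerprint size is only defined for absolute densities")
  }
  M <- if (is.matrix(fp)) unclass(fp) else matrix(fp, nrow = 1L)
  k <- ncol(M)
  sum_size <- rowSums(M)
  polar <- if (k >= 2L) {
    0.5 * sin(2 * pi / k) * rowSums(M * M[, c(2:k, 1L), drop = FALSE])
  } else {
    rep(0, nrow(M))
  }
  # a polygon needs >= 2 nonzero spokes
  polar[rowSums(M > 0) < 2L] <- 0
  data.frame(row = rownames(M) %||% as.character(seq_len(nrow(M))),
             sum_size = sum_size, polar_area = polar,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' z-score normalize a fingerprint collection
#'
#' Per receptor, subtracts the mean and divides by the sample (n-1)
#' standard deviation over the scope's observation set, giving every
#' receptor equal weight while preserving relative differences among
#' areas (the map is affine per receptor). With scope `"per-stratum"`
#' each stratum is normalized over its own areas (within-stratum
#' comparisons); with `"pooled-strata"` all rows are normalized together
#' (required when strata are to be compared with each other, e.g. for
#' the strata-cluster MDS).
#'
#' @param fps a `fingerprint_set` of absolute densities.
#' @param scope `"per-stratum"` or `"pooled-strata"`.
#' @return a normalized `fingerprint_set` with attributes `center` and
#'   `scale` (per stratum-scope) for [denormalize_z()].
#' @export
normalize_z <- function(fps, scope = c("per-stratum", "pooled-strata")) {
  scope <- match.arg(scope)
  if (isTRUE(attr(fps, "normalized"))) abort("collection is already normalized")
  meta <- fp_meta(fps)
  out <- unclass(fps)
  groups <- if (scope == "per-stratum") meta$stratum else
    rep("pooled", nrow(fps))
  centers <- scales <- list()
  for (gr in unique(groups)) {
    i <- which(groups == gr)
    if (length(i) < 2L) abort("need >= 2 observations per receptor to normalize")
    mu <- colMeans(out[i, , drop = FALSE])
    sdv <- apply(out[i, , drop = FALSE], 2L, stats::sd)
    if (any(sdv <= 0)) {
      abort("zero variance for receptor(s): %s",
            paste(colnames(fps)[sdv <= 0], collapse = ", "))
    }
    out[i, ] <- sweep(sweep(out[i, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    centers[[gr]] <- mu; scales[[gr]] <- sdv
  }
  structure(out, class = class(fps), areas = attr(fps, "areas"),
            strata = attr(fps, "strata"),
            receptor_order = attr(fps, "receptor_order"),
            normalized = TRUE, scope = scope,
            center = centers, scale = scales)
}

#' Undo a z-score normalization
#'
#' Inverse affine map of [normalize_z()], restoring absolute densities.
#'
#' @param fps a normalized `fingerprint_set` carrying `center`/`scale`.
#' @return the absolute-density `fingerprint_set`.
#' @export
denormalize_z <- function(fps) {
  if (!isTRUE(attr(fps, "normalized"))) abort("collection is not normalized")
  meta <- fp_meta(fps)
  groups <- if (attr(fps, "scope") == "per-stratum") meta$stratum else
    rep("pooled", nrow(fps))
  out <- unclass(fps)
  for (gr in unique(groups)) {
    i <- which(groups == gr)
    out[i, ] <- sweep(sweep(out[i, , drop = FALSE], 2L,
                            attr(fps, "scale")[[gr]], "*"),
                      2L, attr(fps, "center")[[gr]], "+")
  }
  structure(out, class = class(fps), areas = attr(fps, "areas"),
            strata = attr(fps, "strata"),
            receptor_order = attr(fps, "receptor_order"),
            normalized = FALSE)
}

#' Polar plot of a receptor fingerprint
#'
#' Draws one fingerprint as a closed polygon on equiangular receptor
#' axes. For absolute fingerprints from a collection, pass the
#' collection-wide maximum as `rmax` so all plots share one radial
#' scale; normalized fingerprints are drawn around the zero-z reference
#' ring (dotted).
#'
#' @param fp a `fingerprint_set` row name or index, with the collection
#'   in `fps`; or a bare named numeric vector.
#' @param fps the collection (`fingerprint_set`) when `fp` indexes into
#'   it.
#' @param rmax radial axis limit; defaults to the collection maximum
#'   (absolute) or `max(|z|)` (normalized).
#' @param main plot title.
#' @param ... further arguments passed to [graphics::polygon()].
#' @return invisibly, the polygon coordinates.
#' @export
plot_fingerprint <- function(fp, fps = NULL, rmax = NULL, main = NULL, ...) {
  if (!is.null(fps)) {
    values <- fps[fp, ]
    normalized <- isTRUE(attr(fps, "normalized"))
    if (is.null(rmax)) {
      rmax <- if (normalized) max(abs(fps)) else max(fps)
    }
    if (is.null(main) && is.character(fp)) main <- fp
  } else {
    values <- fp
    normalized <- any(values < 0)
    if (is.null(rmax)) rmax <- max(abs(values))
  }
  k <- length(values)
  ang <- pi / 2 - (seq_len(k) - 1L) * 2 * pi / k   # clockwise from 12 o'clock
  # normalized plots shift z by an offset so the zero ring has a radius
  off <- if (normalized) rmax else 0
  r <- values + off
  lim <- rmax + off
  graphics::plot(NA, xlim = c(-lim, lim) * 1.25, ylim = c(-lim, lim) * 1.25,
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  if (normalized) {
    tt <- seq(0, 2 * pi, length.out = 181L)
    graphics::lines(off * cos(tt), off * sin(tt), lty = 3)
  }
  graphics::segments(0, 0, lim * cos(ang), lim * sin(ang), col = "gray80")
  labels <- names(values) %||% as.character(seq_len(k))
  graphics::text(1.18 * lim * cos(ang), 1.18 * lim * sin(ang), labels,
                 cex = 0.7)
  graphics::polygon(r * cos(ang), r * sin(ang), border = "black", ...)
  invisible(data.frame(x = r * cos(ang), y = r * sin(ang)))
}
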