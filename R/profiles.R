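#' Cortical ribbon geometry
#'
#' Pial and white-matter contours of a cortical ribbon in pixel
#' coordinates plus the laminar border depth fractions. Depths are
#' normalized so that 0 is the pial surface and 1 the layer VI /
#' white-matter border; the granular sector is the half-open interval
#' `[f1, f2)`. Agranular areas (no visible layer IV) instead carry the
#' depth fraction of the lower border of layer III; their granular
#' sector is the 3%-of-depth stripe directly below it.
#'
#' @param pial,wm data.frames with columns `x`, `y` (pixel coordinates,
#'   consistently oriented so corresponding arclength positions face
#'   each other).
#' @param f1,f2 depth fractions of the sg/g and g/ig borders
#'   (`0 < f1 < f2 < 1`); ignored when `agranular`.
#' @param agranular logical flag.
#' @param layerIII_lower_fraction depth fraction of the lower border of
#'   layer III (agranular areas only).
#' @return object of class `cortical_geometry`.
#' @export
cortical_geometry <- function(pial, wm, f1 = 0.5, f2 = 0.7,
                              agranular = FALSE,
                              layerIII_lower_fraction = NA_real_) {
  for (p in list(pial, wm)) {
    if (!is.data.frame(p) || !all(c("x", "y") %in% names(p)) || nrow(p) < 2L) {
      abort("contours must be data.frames with columns x, y and >= 2 points")
    }
  }
  # contours must not intersect
  for (i in seq_len(nrow(pial) - 1L)) {
    for (j in seq_len(nrow(wm) - 1L)) {
      if (segments_intersect(c(pial$x[i], pial$y[i]),
                             c(pial$x[i + 1L], pial$y[i + 1L]),
                             c(wm$x[j], wm$y[j]),
                             c(wm$x[j + 1L], wm$y[j + 1L]))) {
        abort("pial and white-matter contours intersect")
      }
    }
  }
  if (agranular) {
    l3 <- layerIII_lower_fraction
    if (!is_num1(l3) || l3 <= 0 || l3 + 0.03 >= 1) {
      abort("layerIII_lower_fraction must satisfy 0 < f and f + 0.03 < 1")
    }
  } else if (!is_num1(f1) || !is_num1(f2) || !(0 < f1 && f1 < f2 && f2 < 1)) {
    abort("border fractions must satisfy 0 < f1 < f2 < 1")
  }
  structure(list(pial = pial, wm = wm, f1 = f1, f2 = f2,
                 agranular = agranular,
                 layerIII_lower_fraction = layerIII_lower_fraction),
            class = "cortical_geometry")
}

# granular-sector depth interval of a geometry (half-open [lo, hi))
sector_bounds <- function(geom) {
  if (isTRUE(geom$agranular)) {
    c(geom$layerIII_lower_fraction, geom$layerIII_lower_fraction + 0.03)
  } else {
    c(geom$f1, geom$f2)
  }
}

#' Extract equidistant pial-to-white-matter traverses
#'
#' Places anchors at equidistant arclength positions along the pial
#' contour and connects each to its minimum-length point on the
#' white-matter contour. Crossing traverses are resolved by forcing the
#' white-matter endpoints' arclength positions to be non-decreasing
#' (running maximum), so no two traverses intersect. Traverses through
#' obliquely cut cortex are excluded when their length exceeds
#' `exclude_factor` times the median traverse length.
#'
#' @param geom a [cortical_geometry()].
#' @param spacing anchor spacing along the pial contour (px, > 0).
#' @param exclude_factor oblique-section exclusion threshold (default
#'   1.5 x median length); `Inf` disables exclusion.
#' @return data.frame of class `traverse_set` with columns `x0, y0`
#'   (pial anchor), `x1, y1` (white-matter endpoint), `length`,
#'   `excluded`.
#' @export
extract_traverses <- function(geom, spacing, exclude_factor = 1.5) {
  if (!inherits(geom, "cortical_geometry")) abort("'geom' must be a cortical_geometry")
  if (!is_num1(spacing) || spacing <= 0) abort("spacing must be > 0")
  total <- polyline_length(geom$pial)
  if (spacing > total) abort("spacing exceeds the pial contour length")
  s <- seq(spacing / 2, total - spacing / 2, by = spacing)
  anchors <- polyline_point(geom$pial, s)
  proj <- lapply(seq_len(nrow(anchors)), function(i) {
    polyline_project(geom$wm, c(anchors$x[i], anchors$y[i]))
  })
  ends_s <- cummax(vapply(proj, `[[`, numeric(1), "s"))
  ends <- polyline_point(geom$wm, ends_s)
  len <- sqrt((ends$x - anchors$x)^2 + (ends$y - anchors$y)^2)
  excluded <- len > exclude_factor * stats::median(len)
  out <- data.frame(x0 = anchors$x, y0 = anchors$y,
                    x1 = ends$x, y1 = ends$y,
                    length = len, excluded = excluded)
  class(out) <- c("traverse_set", class(out))
  out
}

#' Sample a laminar density profile along a traverse
#'
#' Bilinear sampling of a density image at `n_bins` equidistant points
#' along a straight traverse; the depth axis is normalized to 0--100%
#' (pial to white-matter border). Isolated masked samples are filled by
#' linear interpolation along the depth axis; a traverse whose samples
#' are all masked is an error.
#'
#' @param dimg a [density_image()] (or numeric matrix).
#' @param tr one traverse: a list/row with `x0, y0, x1, y1`.
#' @param n_bins number of equidistant sample points (default 101).
#' @return object of class `laminar_profile`: list with `depth`
#'   (percent) and `density`.
#' @export
sample_profile <- function(dimg, tr, n_bins = 101L) {
  if (!is_num1(n_bins) || n_bins < 1L) abort("n_bins must be >= 1")
  # the degenerate single-bin case returns the traverse mean, estimated
  # from a dense internal sampling
  t <- seq(0, 1, length.out = if (n_bins == 1L) 101L else n_bins)
  x <- tr$x0 + t * (tr$x1 - tr$x0)
  y <- tr$y0 + t * (tr$y1 - tr$y0)
  if (any(x < 1 | x > ncol(dimg) | y < 1 | y > nrow(dimg))) {
    abort("traverse leaves the image bounds")
  }
  v <- bilinear_sample(unclass(dimg), x, y)
  if (all(is.na(v))) abort("traverse is fully masked")
  if (anyNA(v)) {
    ok <- which(!is.na(v))
    v <- stats::approx(t[ok], v[ok], xout = t, rule = 2)$y
  }
  if (n_bins == 1L) {
    v <- mean(v)
    t <- 0.5
  }
  structure(list(depth = t * 100, density = v, n_bins = as.integer(n_bins),
                 length_px = sqrt((tr$x1 - tr$x0)^2 + (tr$y1 - tr$y0)^2)),
            class = "laminar_profile")
}

# integral of the piecewise-linear profile over depth fraction [a, b],
# inserting the exact sector boundaries as interpolation nodes.
# guard_lo/guard_hi (depth-fraction units) exclude a band inside each
# sector border and extrapolate the adjacent plateau across it: a
# laminar border appears in a sampled image as a ramp about one pixel
# wide, and integrating that ramp across the border systematically
# biases thin sectors; the guard band removes the ramp instead.
profile_integral <- function(depth_frac, density, a, b,
                             guard_lo = 0, guard_hi = 0) {
  if (b <= a) return(0)
  # guards must leave an interior; shrink them if the sector is thin
  shrink <- (b - a) / 3
  guard_lo <- min(guard_lo, shrink)
  guard_hi <- min(guard_hi, shrink)
  a2 <- a + guard_lo; b2 <- b - guard_hi
  inside <- depth_frac > a2 & depth_frac < b2
  xs <- c(a2, depth_frac[inside], b2)
  ys <- stats::approx(depth_frac, density, xout = xs, rule = 2)$y
  trapz(xs, ys) + guard_lo * ys[1L] + guard_hi * ys[length(ys)]
}

#' Partition a profile into strata densities
#'
#' Integrates a laminar profile over the supragranular, granular and
#' infragranular depth sectors (trapezoidal rule with the sector borders
#' inserted as exact nodes) and divides by sector width, yielding the
#' mean density of each stratum plus the all-layer mean (the integral
#' over the full depth). By construction the thickness-weighted identity
#' `mean_all = w_sg*mean_sg + w_g*mean_g + w_ig*mean_ig` holds exactly.
#'
#' A guard band of `guard_px` (default one pixel, using the traverse
#' length recorded in the profile) is excluded on both sides of each
#' interior sector border and bridged by extrapolating the adjacent
#' plateau: image sampling smears a laminar border into a ramp about
#' one pixel wide, and integrating the ramp across the border would
#' systematically bias thin sectors such as the agranular 3% stripe.
#'
#' @param p a [sample_profile()] result (or list with `depth` in percent
#'   and `density`).
#' @param geom a [cortical_geometry()] supplying the border fractions
#'   and the agranular rule.
#' @param guard_px guard band half-width in pixels around the interior
#'   sector borders; 0 disables it (it is also inactive for profiles
#'   lacking a recorded traverse length).
#' @return object of class `strata_densities`: `mean_sg`, `mean_g`,
#'   `mean_ig`, `mean_all`, `weights`, `n_profiles = 1`.
#' @export
partition_strata <- function(p, geom, guard_px = 1) {
  gb <- sector_bounds(geom)
  f1 <- gb[1]; f2 <- gb[2]
  if (!(0 < f1 && f1 < f2 && f2 < 1)) {
    abort("sector borders must lie strictly inside (0, 1)")
  }
  d <- p$depth / 100
  guard <- if (is.null(p$length_px) || p$length_px <= 0) 0 else
    guard_px / p$length_px
  i_sg <- profile_integral(d, p$density, 0, f1, guard_hi = guard)
  i_g <- profile_integral(d, p$density, f1, f2, guard_lo = guard,
                          guard_hi = guard)
  i_ig <- profile_integral(d, p$density, f2, 1, guard_lo = guard)
  w <- c(sg = f1, g = f2 - f1, ig = 1 - f2)
  structure(list(mean_sg = i_sg / w[["sg"]], mean_g = i_g / w[["g"]],
                 mean_ig = i_ig / w[["ig"]],
                 mean_all = i_sg + i_g + i_ig,
                 weights = w, n_profiles = 1L),
            class = "strata_densities")
}

#' Aggregate strata densities across traverses
#'
#' Unweighted mean of the per-traverse strata densities of one area
#' (and, upstream, one receptor and brain). All inputs must share the
#' same sector weights so the thickness-weighted identity survives
#' averaging.
#'
#' @param results non-empty list of [partition_strata()] results.
#' @return a single `strata_densities` with `n_profiles` summed.
#' @export
aggregate_area <- function(results) {
  if (length(results) == 0L) abort("no strata densities to aggregate")
  w0 <- results[[1L]]$weights
  for (r in results) {
    if (max(abs(r$weights - w0)) > 1e-9) {
      abort("cannot aggregate strata densities with differing sector weights")
    }
  }
  m <- function(f) mean(vapply(results, `[[`, numeric(1), f))
  structure(list(mean_sg = m("mean_sg"), mean_g = m("mean_g"),
                 mean_ig = m("mean_ig"), mean_all = m("mean_all"),
                 weights = w0,
                 n_profiles = sum(vapply(results, `[[`, integer(1),
                                         "n_profiles"))),
            class = "strata_densities")
}

#' @export
print.strata_densities <- function(x, ...) {
  cat(sprintf("strata_densities (n_profiles=%d): sg %.4g, g %.4g, ig %.4g, all %.4g fmol/mg\n",
              x$n_profiles, x$mean_sg, x$mean_g, x$mean_ig, x$mean_all))
  invisible(x)
}
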