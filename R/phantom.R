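#' Specification of a synthetic autoradiograph phantom
#'
#' Describes the layout and imaging physics of a rendered phantom: the
#' cortical ribbon (a band of constant thickness, straight or bent into
#' a circular arc, subdivided into equal-width area segments), the
#' co-exposed calibration-standards strip, the monotone saturating film
#' response, and additive Gaussian gray-value noise. Gray values live on
#' a continuous 0--255 scale; quantization only happens when an image is
#' written to disk (16-bit).
#'
#' @param areas area panel rows (see [area_panel()]) to place along the
#'   ribbon, in order.
#' @param thickness_px cortical thickness (px).
#' @param area_width_px width of each area segment along the ribbon
#'   (px along the pial surface for the arc geometry).
#' @param geometry `"flat"` or `"arc"`.
#' @param arc_radius_px pial radius for the arc geometry; defaults to
#'   `2.5 *` total ribbon length.
#' @param standards_levels strictly increasing radioactivity
#'   concentrations (cpm) of the co-exposed standards, >= 4 levels.
#'   `NULL` defers the choice to [render_phantom()], which spans the
#'   densities actually rendered.
#' @param film_params list `offset`, `gmax`, `a` of [film_response()];
#'   a `NULL` slope `a` is likewise chosen at render time so the
#'   rendered densities use the film's dynamic range.
#' @param noise_sd additive Gaussian gray-value noise sd.
#' @param seed integer seed for the noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(areas, thickness_px = 150L, area_width_px = 40L,
                         geometry = c("flat", "arc"), arc_radius_px = NULL,
                         standards_levels = NULL,
                         film_params = list(offset = 10, gmax = 230, a = NULL),
                         noise_sd = 0, seed = 1L) {
  geometry <- match.arg(geometry)
  if (!is.data.frame(areas) || nrow(areas) < 1L) abort("'areas' must be a data.frame")
  if (!is.null(standards_levels)) {
    if (length(standards_levels) < 4L || any(diff(standards_levels) <= 0)) {
      abort("standards_levels must be >= 4 strictly increasing levels")
    }
  }
  if (!is_num1(noise_sd) || noise_sd < 0) abort("noise_sd must be >= 0")
  structure(list(areas = areas, thickness_px = as.integer(thickness_px),
                 area_width_px = as.integer(area_width_px),
                 geometry = geometry, arc_radius_px = arc_radius_px,
                 standards_levels = standards_levels,
                 film_params = film_params, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# per-area granular-sector bounds from an area panel row
area_bounds <- function(row) {
  if (isTRUE(row$agranular)) {
    c(row$layerIII_lower_fraction, row$layerIII_lower_fraction + 0.03)
  } else {
    c(row$f1, row$f2)
  }
}

#' Render a ground-truth table into an autoradiograph phantom
#'
#' Forward model of the whole imaging chain for one receptor and brain:
#' each ribbon pixel takes the ground-truth density of its (area,
#' stratum) cell, densities are inverted exactly through the
#' densitometry formula to radioactivity, passed through the monotone
#' film response, and Gaussian gray noise is added. The standards strip
#' is rendered from the known radioactivity levels through the same
#' film response. Densities whose film response would come within 0.5%
#' of saturation are an error (reported, never clipped silently).
#'
#' @param spec a [phantom_spec()].
#' @param truth a [generate_ground_truth()] result covering the placed
#'   areas.
#' @param ligand a [ligand_params()] object.
#' @param receptor receptor name to render.
#' @param brain brain replicate to render.
#' @return object of class `phantom`: gray image, standards ROIs with
#'   their known radioactivities, pial/white-matter contours, per-area
#'   layout, resolved film parameters, and the ground truth restricted
#'   to the rendered areas.
#' @export
render_phantom <- function(spec, truth, ligand, receptor, brain = 1L) {
  if (!inherits(spec, "phantom_spec")) abort("'spec' must be a phantom_spec")
  dens <- truth$densities
  dens <- dens[dens$receptor == receptor & dens$brain == brain, ]
  if (nrow(dens) == 0L) abort("truth has no rows for receptor '%s', brain %d",
                              receptor, brain)
  areas <- spec$areas
  missing_areas <- setdiff(areas$area, dens$area)
  if (length(missing_areas)) {
    abort("truth does not cover area(s): %s",
          paste(missing_areas, collapse = ", "))
  }
  dens <- dens[dens$area %in% areas$area, ]

  # resolve film slope and standards from the density range
  Rmax_tissue <- max(density_to_radioactivity(dens$density, ligand))
  fp <- spec$film_params
  std <- spec$standards_levels
  if (is.null(std)) std <- seq(0, 1.25 * Rmax_tissue, length.out = 8L)
  if (is.null(fp$a)) fp$a <- 1.5 / max(std[length(std)], Rmax_tissue)
  sat_gray <- fp$offset + 0.995 * fp$gmax
  g_needed <- film_response(c(Rmax_tissue, std[length(std)]), fp)
  if (any(g_needed > sat_gray)) {
    abort("density maps outside the film's representable range (gray %.1f > %.1f); reduce densities or film slope",
          max(g_needed), sat_gray)
  }

  T <- spec$thickness_px
  W <- spec$area_width_px
  n_areas <- nrow(areas)
  left <- 61L   # columns 1..60 host the standards strip
  top <- 31L
  ribbon_len <- W * n_areas

  # per-pixel density lookup table: stratum x area
  dmat <- matrix(NA_real_, nrow = 3L, ncol = n_areas,
                 dimnames = list(c("sg", "g", "ig"), areas$area))
  for (i in seq_len(nrow(dens))) {
    dmat[dens$stratum[i], dens$area[i]] <- dens$density[i]
  }
  if (anyNA(dmat)) abort("truth is missing strata for the rendered areas")
  rmat <- density_to_radioactivity(dmat, ligand)
  gb <- vapply(seq_len(n_areas), function(i) {
    area_bounds(areas[i, , drop = FALSE])
  }, numeric(2))

  if (spec$geometry == "flat") {
    nr <- top + T + 30L
    nc <- left + ribbon_len + 20L
    img <- matrix(film_response(0, fp), nr, nc)
    # one padding row beyond each contour replicates the edge stratum so
    # bilinear samples taken exactly on a contour stay unbiased
    rows <- (top - 1L):(top + T)
    u <- pmin(pmax((rows - top + 0.5) / T, 0), 1 - 1e-9)
    for (ai in seq_len(n_areas)) {
      stratum <- ifelse(u < gb[1, ai], 1L, ifelse(u < gb[2, ai], 2L, 3L))
      cols <- (left + (ai - 1L) * W):(left + ai * W - 1L)
      img[rows, cols] <- film_response(rmat[stratum, ai], fp)
    }
    xs <- seq(left - 0.5, left + ribbon_len - 0.5, length.out = 2L * n_areas + 1L)
    pial <- data.frame(x = xs, y = rep(top - 0.5, length(xs)))
    wm <- data.frame(x = xs, y = rep(top + T - 0.5, length(xs)))
    layout <- data.frame(area = areas$area,
                         x_from = left + (seq_len(n_areas) - 1L) * W - 0.5,
                         x_to = left + seq_len(n_areas) * W - 0.5)
  } else {
    R0 <- spec$arc_radius_px             # inner (white-matter) radius
    if (is.null(R0)) R0 <- 2.5 * ribbon_len
    Rp <- R0 + T                         # outer (pial) radius
    span <- ribbon_len / Rp              # pial arc length = ribbon length
    th0 <- -pi / 2 - span / 2            # ribbon arcs over the top of a circle
    half_w <- Rp * sin(span / 2)
    cx <- left + 40 + half_w             # keep clear of the standards strip
    cy <- top + Rp
    nr <- ceiling(top + T + Rp * (1 - cos(span / 2))) + 30L
    nc <- ceiling(cx + half_w) + 20L
    img <- matrix(film_response(0, fp), nr, nc)
    cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    rr <- matrix(rep(seq_len(nr), times = nc), nr, nc)
    rad <- sqrt((cc - cx)^2 + (rr - cy)^2)
    th <- atan2(rr - cy, cc - cx)
    u <- (Rp - rad) / T                  # depth fraction, pial at outer radius
    frac_ang <- (th - th0) / span
    pad <- 1.5 / T
    in_ribbon <- u >= -pad & u < 1 + pad & frac_ang >= 0 & frac_ang < 1
    ai <- pmin(floor(frac_ang * n_areas) + 1L, n_areas)
    idx <- which(in_ribbon)
    uc <- pmin(pmax(u[idx], 0), 1 - 1e-9)
    stratum <- ifelse(uc < gb[1, ai[idx]], 1L,
                      ifelse(uc < gb[2, ai[idx]], 2L, 3L))
    img[idx] <- film_response(rmat[cbind(stratum, ai[idx])], fp)
    tt <- seq(th0, th0 + span, length.out = max(65L, 4L * n_areas + 1L))
    pial <- data.frame(x = cx + Rp * cos(tt), y = cy + Rp * sin(tt))
    wm <- data.frame(x = cx + R0 * cos(tt), y = cy + R0 * sin(tt))
    layout <- data.frame(area = areas$area,
                         th_from = th0 + (seq_len(n_areas) - 1L) / n_areas * span,
                         th_to = th0 + seq_len(n_areas) / n_areas * span,
                         cx = cx, cy = cy, R0 = R0)
  }

  # standards strip: stacked boxes in the left margin, outside the ribbon
  box_h <- 16L; box_w <- 36L; gap <- 4L
  rois <- vector("list", length(std))
  for (k in seq_along(std)) {
    r0 <- 8L + (k - 1L) * (box_h + gap)
    if (r0 + box_h - 1L > nrow(img)) abort("too many standards for the image height")
    rect <- c(r0, r0 + box_h - 1L, 8L, 8L + box_w - 1L)
    img[rect[1]:rect[2], rect[3]:rect[4]] <- film_response(std[k], fp)
    rois[[k]] <- list(rect = rect, known_R = std[k])
  }

  if (spec$noise_sd > 0) {
    noise_seed <- spec$seed + 131L * match(receptor, unique(truth$densities$receptor)) +
      7919L * as.integer(brain)
    img <- with_seed(noise_seed %% .Machine$integer.max,
                     img + matrix(rnorm(length(img), 0, spec$noise_sd),
                                  nrow(img)))
    img[img < 0] <- 0
  }

  structure(list(image = img, standards_rois = rois, pial = pial, wm = wm,
                 layout = layout, areas = areas, film_params = fp,
                 standards_levels = std, spec = spec,
                 ligand = ligand, receptor = receptor, brain = brain,
                 truth = dens),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %s/brain %d, %d x %d px, %d areas, %d standards (%s geometry)\n",
              x$receptor, x$brain, nrow(x$image), ncol(x$image),
              nrow(x$areas), length(x$standards_rois), x$spec$geometry))
  invisible(x)
}

#' Measure the co-exposed standards of a phantom
#'
#' @param phantom a [render_phantom()] result (or any object with
#'   `image` and `standards_rois`).
#' @return data.frame with columns `known_R`, `mean_gray`, and the ROI
#'   rectangle corners, suitable for [fit_calibration()].
#' @export
measure_standards <- function(phantom) {
  do.call(rbind, lapply(phantom$standards_rois, function(s) {
    r <- s$rect
    data.frame(known_R = s$known_R,
               mean_gray = mean(phantom$image[r[1]:r[2], r[3]:r[4]]),
               r0 = r[1], r1 = r[2], c0 = r[3], c1 = r[4])
  }))
}

#' Cortical geometry of one phantom area
#'
#' Cuts the phantom's pial/white-matter contours down to one area's
#' span (with a safety margin so traverses do not straddle the sharp
#' area boundary) and attaches that area's laminar border fractions.
#'
#' @param phantom a [render_phantom()] result.
#' @param area area name.
#' @param margin_px margin kept from each area boundary (default 2).
#' @return a [cortical_geometry()].
#' @export
phantom_area_geometry <- function(phantom, area, margin_px = 2) {
  i <- match(area, phantom$areas$area)
  if (is.na(i)) abort("area '%s' is not rendered in this phantom", area)
  row <- phantom$areas[i, , drop = FALSE]
  if (phantom$spec$geometry == "flat") {
    lay <- phantom$layout[i, ]
    xs <- seq(lay$x_from + margin_px, lay$x_to - margin_px, length.out = 9L)
    pial <- data.frame(x = xs, y = phantom$pial$y[1])
    wm <- data.frame(x = xs, y = phantom$wm$y[1])
  } else {
    lay <- phantom$layout[i, ]
    T <- phantom$spec$thickness_px
    dth <- margin_px / (lay$R0 + T)
    tt <- seq(lay$th_from + dth, lay$th_to - dth, length.out = 17L)
    pial <- data.frame(x = lay$cx + (lay$R0 + T) * cos(tt),
                       y = lay$cy + (lay$R0 + T) * sin(tt))
    wm <- data.frame(x = lay$cx + lay$R0 * cos(tt),
                     y = lay$cy + lay$R0 * sin(tt))
  }
  cortical_geometry(pial, wm, f1 = row$f1, f2 = row$f2,
                    agranular = row$agranular,
                    layerIII_lower_fraction = row$layerIII_lower_fraction)
}

#' Write a phantom to disk
#'
#' Writes the gray image as 16-bit TIFF (and optionally PNG) plus a JSON
#' sidecar with the standards ROIs, contours, layout, film parameters
#' and the restricted ground truth. Gray values on the 0--255 scale are
#' stored as `gray / 255` in 16 bits.
#'
#' @param phantom a [render_phantom()] result.
#' @param prefix output path prefix (files `<prefix>.tif`,
#'   `<prefix>.json` and optionally `<prefix>.png`).
#' @param png also write a PNG copy.
#' @return invisibly, the paths written.
#' @export
write_phantom <- function(phantom, prefix, png = FALSE) {
  img01 <- pmin(pmax(phantom$image / 255, 0), 1)
  tif <- paste0(prefix, ".tif")
  tiff::writeTIFF(img01, tif, bits.per.sample = 16L)
  paths <- tif
  if (png) {
    pngf <- paste0(prefix, ".png")
    png::writePNG(img01, pngf)
    paths <- c(paths, pngf)
  }
  side <- list(receptor = phantom$receptor, brain = phantom$brain,
               geometry = phantom$spec$geometry,
               film_params = phantom$film_params,
               standards = lapply(phantom$standards_rois, function(s)
                 list(rect = s$rect, known_R = s$known_R)),
               pial = phantom$pial, wm = phantom$wm,
               layout = phantom$layout, areas = phantom$areas,
               truth = phantom$truth)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, js))
}

#' Read a phantom image back from disk
#'
#' @param path a `.tif` or `.png` written by [write_phantom()].
#' @return gray-value matrix on the 0--255 scale.
#' @export
read_phantom_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img01 <- switch(ext,
                  tif = , tiff = tiff::readTIFF(path),
                  png = png::readPNG(path),
                  abort("unsupported image format: .%s", ext))
  if (length(dim(img01)) == 3L) img01 <- img01[, , 1L]
  img01 * 255
}
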