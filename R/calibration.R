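#' Ligand incubation and counting parameters
#'
#' The experimental constants that turn a radioactivity concentration R
#' (cpm) measured on film into a binding-site density Cb (fmol/mg
#' protein):
#' \deqn{C_b = \frac{R}{E \cdot B \cdot W_b \cdot S_a} \cdot
#'   \frac{K_D + L}{L}}
#' where E is the scintillation-counter efficiency, B the number of
#' decays per unit time and radioactivity (Ci/min), Wb the protein
#' weight of a standard (mg), Sa the specific activity of the ligand
#' (Ci/mmol), KD the dissociation constant (nM) and L the free ligand
#' concentration during incubation (nM). The factor (KD+L)/L corrects
#' sub-saturation binding up to the density at receptor saturation.
#'
#' @param E,B,Wb,Sa,KD,L strictly positive scalars (units above).
#' @return object of class `ligand_params`.
#' @export
ligand_params <- function(E, B, Wb, Sa, KD, L) {
  p <- list(E = E, B = B, Wb = Wb, Sa = Sa, KD = KD, L = L)
  for (nm in names(p)) {
    if (!is_num1(p[[nm]]) || p[[nm]] <= 0) {
      abort("ligand parameter '%s' must be a single positive number", nm)
    }
  }
  structure(p, class = "ligand_params")
}

#' Convert radioactivity to binding-site density
#'
#' Applies the saturation-corrected densitometry formula (see
#' [ligand_params()]) elementwise. Cb is linear in R and in the
#' saturation factor (KD+L)/L.
#'
#' @param R radioactivity concentration(s) in cpm, all `>= 0` (NA
#'   allowed and propagated).
#' @param ligand a [ligand_params()] object.
#' @return densities in fmol/mg protein, same shape as `R`.
#' @export
radioactivity_to_density <- function(R, ligand) {
  if (!inherits(ligand, "ligand_params")) {
    ligand <- do.call(ligand_params, as.list(ligand)[c("E", "B", "Wb", "Sa",
                                                       "KD", "L")])
  }
  if (any(R < 0, na.rm = TRUE)) abort("R must be >= 0")
  R / (ligand$E * ligand$B * ligand$Wb * ligand$Sa) *
    (ligand$KD + ligand$L) / ligand$L
}

# inverse of the above: density -> radioactivity (used by the phantom
# renderer as the exact forward model)
density_to_radioactivity <- function(Cb, ligand) {
  Cb * (ligand$E * ligand$B * ligand$Wb * ligand$Sa) *
    ligand$L / (ligand$KD + ligand$L)
}

#' Saturating film response
#'
#' Monotone two-parameter film characteristic
#' `G = offset + gmax * (1 - exp(-a * R))` mapping radioactivity R (cpm)
#' to film gray value G. It saturates at `offset + gmax` and is
#' invertible in closed form on `[offset, offset + gmax)`.
#'
#' @param R radioactivity (cpm).
#' @param params list with `offset`, `gmax`, `a` (gmax, a > 0).
#' @return gray values.
#' @export
film_response <- function(R, params) {
  params$offset + params$gmax * (1 - exp(-params$a * R))
}

#' Closed-form inverse of the saturating film response
#'
#' @param gray gray values within `[offset, offset + gmax)`.
#' @param params as in [film_response()].
#' @return radioactivity (cpm); NA where `gray` is outside the
#'   invertible range.
#' @export
film_inverse <- function(gray, params) {
  u <- (gray - params$offset) / params$gmax
  # tolerate float-level undershoot below the fitted offset
  u[u < 0 & u > -1e-9] <- 0
  out <- ifelse(u >= 0 & u < 1, -log1p(-pmin(u, 1 - 1e-15)) / params$a,
                NA_real_)
  out[u >= 0 & u < 1e-12] <- 0
  out
}

#' Fit a film calibration curve from co-exposed standards
#'
#' Non-linear least-squares fit of a monotone gray-value vs
#' radioactivity curve through the co-exposed standards (known
#' radioactivity, observed mean gray). Two model families are
#' available: the default saturating form of [film_response()]
#' (Levenberg-Marquardt damped least squares), and a cubic polynomial
#' in gray predicting log radioactivity, useful for probing model
#' mismatch. Fits that are not strictly monotone over the observed gray
#' range are refused.
#'
#' @param standards data.frame with columns `known_R` (cpm, >= 0) and
#'   `mean_gray`; at least 4 standards with distinct `known_R`.
#' @param family `"saturating"` or `"logpoly"`.
#' @return object of class `film_calibration`: `family`, `params` (or
#'   `coef`), `residuals` (gray units for the saturating family),
#'   `rss`, `valid_gray_range`, and the standards used.
#' @export
fit_calibration <- function(standards, family = c("saturating", "logpoly")) {
  family <- match.arg(family)
  if (!all(c("known_R", "mean_gray") %in% names(standards))) {
    abort("standards must have columns 'known_R' and 'mean_gray'")
  }
  standards <- standards[order(standards$known_R), , drop = FALSE]
  R <- standards$known_R; g <- standards$mean_gray
  if (length(unique(R)) < 4L) {
    abort("insufficient standards: need >= 4 distinct radioactivity levels")
  }
  if (any(R < 0)) abort("known_R must be >= 0")
  if (diff(range(g)) < .Machine$double.eps^0.5) {
    abort("degenerate standards: all gray values equal")
  }

  if (family == "saturating") {
    # heuristic starting values: offset near the dimmest standard,
    # gmax from the observed gray span, a from the half-rise point
    offset0 <- min(g) - 0.05 * diff(range(g))
    gmax0 <- 1.5 * diff(range(g))
    a0 <- 1 / stats::median(R[R > 0])
    fit <- minpack.lm::nlsLM(
      g ~ offset + gmax * (1 - exp(-a * R)),
      start = list(offset = offset0, gmax = gmax0, a = a0),
      lower = c(offset = -Inf, gmax = 1e-9, a = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    params <- as.list(stats::coef(fit))
    if (params$a <= 0 || params$gmax <= 0) {
      abort("calibration fit is not monotone increasing")
    }
    res <- g - film_response(R, params)
    out <- list(family = family, params = params,
                residuals = res, rss = sum(res^2),
                valid_gray_range = c(film_response(0, params) -
                                       1e-9 * diff(range(g)),
                                     max(g) + 0.001 * diff(range(g))),
                standards = standards)
  } else {
    # log-polynomial family: log(R + r0) modeled as a cubic in gray
    r0 <- max(min(R[R > 0]) * 1e-3, 1e-8)
    cf <- stats::lm(log(R + r0) ~ poly(g, 3, raw = TRUE))
    grid <- seq(min(g), max(g), length.out = 257L)
    pred <- stats::predict(cf, data.frame(g = grid))
    if (any(diff(pred) <= 0)) {
      abort("calibration fit is not monotone increasing")
    }
    res <- stats::residuals(cf)
    out <- list(family = family, coef = stats::coef(cf), r0 = r0,
                residuals = res, rss = sum(res^2),
                valid_gray_range = range(g), standards = standards)
  }
  class(out) <- "film_calibration"
  out
}

#' @export
print.film_calibration <- function(x, ...) {
  cat(sprintf("film_calibration (%s family): %d standards, RSS %.4g, gray range [%.3g, %.3g]\n",
              x$family, nrow(x$standards), x$rss,
              x$valid_gray_range[1], x$valid_gray_range[2]))
  invisible(x)
}

#' Convert gray values to radioactivity through a fitted calibration
#'
#' Elementwise application of the inverse calibration curve. Gray values
#' outside the calibration's valid range are masked (NA) with a warning
#' rather than extrapolated; input NAs propagate.
#'
#' @param cal a [fit_calibration()] result.
#' @param gray numeric vector or matrix of gray values.
#' @return radioactivity (cpm), same shape as `gray`.
#' @export
gray_to_radioactivity <- function(cal, gray) {
  if (!inherits(cal, "film_calibration")) abort("'cal' must be a film_calibration")
  rng <- cal$valid_gray_range
  inside <- gray >= rng[1] & gray <= rng[2]
  out <- gray
  out[] <- NA_real_
  if (cal$family == "saturating") {
    out[which(inside)] <- film_inverse(gray[which(inside)], cal$params)
  } else {
    gg <- gray[which(inside)]
    out[which(inside)] <- pmax(
      exp(cbind(1, gg, gg^2, gg^3) %*% cal$coef) - cal$r0, 0)
  }
  n_out <- sum(!inside, na.rm = TRUE)
  if (n_out > 0) {
    warning(sprintf("%d gray value(s) outside the calibrated range were masked",
                    n_out), call. = FALSE)
  }
  out
}

#' Quantify an autoradiograph image into a density image
#'
#' Per-pixel composition gray -> radioactivity -> density: the inverse
#' calibration curve followed by the saturation-corrected densitometry
#' formula. Saturated or out-of-range pixels come out masked (NA).
#'
#' @param image numeric gray-value matrix.
#' @param cal a [fit_calibration()] result.
#' @param ligand a [ligand_params()] object.
#' @return a `density_image`: matrix of densities (fmol/mg protein) with
#'   calibration/ligand provenance attributes.
#' @export
quantify_image <- function(image, cal, ligand) {
  R <- gray_to_radioactivity(cal, image)
  d <- radioactivity_to_density(R, ligand)
  density_image(d, provenance = list(family = cal$family,
                                     ligand = unclass(ligand)))
}

#' Construct a density image
#'
#' @param values numeric matrix of densities (fmol/mg protein); finite
#'   values must be `>= 0`, NA marks masked pixels.
#' @param provenance optional list recording calibration and ligand
#'   identifiers.
#' @return matrix of class `density_image`.
#' @export
density_image <- function(values, provenance = list()) {
  if (!is.matrix(values)) abort("'values' must be a matrix")
  if (any(values < 0, na.rm = TRUE)) abort("densities must be >= 0")
  structure(values, class = c("density_image", class(values)),
            provenance = provenance)
}

#' Specific binding as total minus non-specific
#'
#' Elementwise difference of the total-binding and non-specific-binding
#' density images, floored at zero; the number of floored pixels is
#' recorded in the `n_floored` attribute.
#'
#' @param total,nonspecific congruent `density_image` (or plain matrix)
#'   rasters.
#' @return a `density_image` of specific binding.
#' @export
specific_binding <- function(total, nonspecific) {
  if (!all(dim(total) == dim(nonspecific))) {
    abort("total and nonspecific images differ in shape")
  }
  d <- unclass(total) - unclass(nonspecific)
  n_floored <- sum(d < 0, na.rm = TRUE)
  d[d < 0] <- 0
  out <- density_image(d, provenance = attr(total, "provenance"))
  attr(out, "n_floored") <- n_floored
  out
}
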