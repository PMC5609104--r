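test_that("parallel straight contours yield perpendicular traverses of the gap length", {
  geom <- flat_geometry(thickness = 80, width = 100)
  trs <- extract_traverses(geom, spacing = 10)
  expect_true(all(abs(trs$length - 80) < 1e-9))
  expect_true(all(abs(trs$x1 - trs$x0) < 1e-9))
  # anchors equidistant along the pial contour
  expect_equal(diff(trs$x0), rep(10, nrow(trs) - 1), tolerance = 1e-9)
})

test_that("concentric arcs yield radial traverses with the annulus thickness", {
  th <- seq(-pi / 2 - 0.5, -pi / 2 + 0.5, length.out = 41)
  R0 <- 200; T <- 70; cx <- 300; cy <- 300
  pial <- data.frame(x = cx + (R0 + T) * cos(th), y = cy + (R0 + T) * sin(th))
  wm <- data.frame(x = cx + R0 * cos(th), y = cy + R0 * sin(th))
  geom <- cortical_geometry(pial, wm)
  trs <- extract_traverses(geom, spacing = 15)
  expect_true(all(abs(trs$length - T) <= 1))
  # radial: traverse direction passes through the center
  for (i in seq_len(nrow(trs))) {
    v1 <- c(trs$x0[i] - cx, trs$y0[i] - cy)
    v2 <- c(trs$x1[i] - cx, trs$y1[i] - cy)
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    expect_gt(cosang, 0.999)
  }
})

test_that("traverses never cross and oblique ones are excluded", {
  # skewed white-matter contour invites crossing projections
  pial <- data.frame(x = seq(1, 100, length.out = 11), y = rep(1, 11))
  wm <- data.frame(x = c(seq(30, 40, length.out = 6),
                         seq(41, 100, length.out = 5)), y = rep(61, 11))
  geom <- cortical_geometry(pial, wm)
  trs <- extract_traverses(geom, spacing = 8, exclude_factor = Inf)
  expect_true(nrow(trs) > 3)
  for (i in seq_len(nrow(trs) - 1)) {
    expect_false(segments_intersect_oracle(
      c(trs$x0[i], trs$y0[i]), c(trs$x1[i], trs$y1[i]),
      c(trs$x0[i + 1], trs$y0[i + 1]), c(trs$x1[i + 1], trs$y1[i + 1])))
  }
  # exclusion: traverses through an obliquely cut (locally much thicker)
  # stretch of cortex are flagged
  pial2 <- data.frame(x = seq(1, 120, length.out = 13), y = rep(1, 13))
  wm2 <- data.frame(x = c(1, 55, 65, 120), y = c(41, 41, 161, 161))
  geom2 <- cortical_geometry(pial2, wm2)
  trs2 <- extract_traverses(geom2, spacing = 10, exclude_factor = 1.5)
  expect_true(any(trs2$excluded))
  expect_true(all(trs2$length[trs2$excluded] >
                    1.5 * median(trs2$length)))
  expect_error(extract_traverses(geom, spacing = 1e5), "spacing exceeds")
})

test_that("crossing contours are rejected", {
  pial <- data.frame(x = c(1, 100), y = c(10, 60))
  wm <- data.frame(x = c(1, 100), y = c(60, 10))
  expect_error(cortical_geometry(pial, wm), "intersect")
})

test_that("profiles sample constant and stepped fields faithfully", {
  img <- matrix(50, 120, 60)
  tr <- list(x0 = 30, y0 = 5, x1 = 30, y1 = 105)
  p <- sample_profile(img, tr, n_bins = 101)
  expect_true(all(p$density == 50))
  expect_equal(range(p$depth), c(0, 100))
  # step at 50% depth: 100 above, 20 below
  img2 <- img
  img2[1:55, ] <- 100; img2[56:120, ] <- 20
  p2 <- sample_profile(img2, tr, n_bins = 201)
  step_bin <- which(p2$density < 60)[1]
  expect_lt(abs(p2$depth[step_bin] - 50), 1.5)  # within ~one bin of 50%
  expect_true(all(p2$density[p2$depth < 45] == 100))
  expect_true(all(p2$density[p2$depth > 55] == 20))
  # n_bins = 1 returns the traverse mean
  p3 <- sample_profile(img2, tr, n_bins = 1)
  expect_equal(length(p3$density), 1L)
  expect_equal(p3$density, mean(c(100, 20)), tolerance = 0.05)
})

test_that("masked pixels propagate into profiles and full masking errors", {
  img <- matrix(50, 120, 60)
  img[, 30] <- NA
  tr <- list(x0 = 30, y0 = 5, x1 = 30, y1 = 105)
  expect_error(sample_profile(img, tr), "fully masked")
  img[60, ] <- NA   # one masked row: interpolated through
  tr2 <- list(x0 = 20, y0 = 5, x1 = 20, y1 = 105)
  p <- sample_profile(img, tr2)
  expect_true(all(is.finite(p$density)))
})

test_that("strata partition reproduces piecewise-constant sector means", {
  geom <- flat_geometry(f1 = 0.5, f2 = 0.7)
  # constant profile: all strata equal the constant
  pc <- step_profile(80, 80, 80)
  sc <- partition_strata(pc, geom)
  expect_equal(c(sc$mean_sg, sc$mean_g, sc$mean_ig, sc$mean_all),
               rep(80, 4), tolerance = 1e-9)
  # stepped profile: 0.5*100 + 0.2*50 + 0.3*25 = 67.5
  ps <- step_profile(100, 50, 25, n = 2001L)
  ss <- partition_strata(ps, geom)
  expect_equal(ss$mean_sg, 100, tolerance = 1e-3)
  expect_equal(ss$mean_g, 50, tolerance = 1e-3)
  expect_equal(ss$mean_ig, 25, tolerance = 1e-3)
  expect_equal(ss$mean_all, 67.5, tolerance = 1e-3)
})

test_that("agranular areas get a granular stripe of exactly 3% below layer III", {
  geom <- flat_geometry(agranular = TRUE, l3 = 0.55)
  bounds <- receptarch:::sector_bounds(geom)
  expect_equal(bounds, c(0.55, 0.58), tolerance = 1e-12)
  # a profile nonzero only inside [55, 58)% lands entirely in the
  # granular sector
  d <- seq(0, 1, length.out = 4001)
  v <- ifelse(d >= 0.55 & d < 0.58, 90, 0)
  p <- structure(list(depth = d * 100, density = v, n_bins = 4001L,
                      length_px = NULL), class = "laminar_profile")
  s <- partition_strata(p, geom)
  expect_equal(s$mean_g, 90, tolerance = 0.06)
  # the bins straddling the sector borders leak a sliver of the stripe
  expect_lt(s$mean_sg, 0.05)
  expect_lt(s$mean_ig, 0.05)
})

test_that("thickness-weighted identity holds for every partition", {
  set.seed(11)
  geoms <- list(flat_geometry(f1 = 0.35, f2 = 0.6),
                flat_geometry(f1 = 0.5, f2 = 0.7),
                flat_geometry(agranular = TRUE, l3 = 0.5))
  for (geom in geoms) {
    for (rep in 1:5) {
      d <- seq(0, 1, length.out = 101)
      v <- abs(100 + cumsum(rnorm(101, 0, 5)))
      p <- structure(list(depth = d * 100, density = v, n_bins = 101L,
                          length_px = 120), class = "laminar_profile")
      s <- partition_strata(p, geom)
      w <- s$weights
      lhs <- w[["sg"]] * s$mean_sg + w[["g"]] * s$mean_g +
        w[["ig"]] * s$mean_ig
      expect_equal(lhs, s$mean_all, tolerance = 1e-6)
    }
  }
})

test_that("area aggregation averages per stratum and preserves the identity", {
  geom <- flat_geometry()
  s1 <- partition_strata(step_profile(10, 20, 30, n = 2001L), geom)
  s2 <- partition_strata(step_profile(30, 40, 50, n = 2001L), geom)
  agg <- aggregate_area(list(s1, s2))
  expect_equal(c(agg$mean_sg, agg$mean_g, agg$mean_ig),
               c(20, 30, 40), tolerance = 1e-3)
  expect_equal(agg$n_profiles, 2L)
  w <- agg$weights
  expect_equal(w[["sg"]] * agg$mean_sg + w[["g"]] * agg$mean_g +
                 w[["ig"]] * agg$mean_ig, agg$mean_all, tolerance = 1e-9)
  expect_identical(aggregate_area(list(s1))$mean_all, s1$mean_all)
  expect_error(aggregate_area(list()), "no strata")
})

test_that("recovered strata match an analytic depth-coordinate oracle on phantoms", {
  cfg <- tiny_config()
  gt <- generate_ground_truth(cfg, seed = 5)
  lig <- default_ligand_params("NMDA")[["NMDA"]]
  for (geometry in c("flat", "arc")) {
    spec <- phantom_spec(cfg$areas, noise_sd = 0, geometry = geometry)
    rec <- quantify_phantoms(gt, spec, default_ligand_params(cfg$receptors$receptor),
                             spacing = 10, n_bins = 301, receptors = "NMDA",
                             brains = 1)
    m <- merge(rec, gt$densities,
               by = c("area", "receptor", "stratum", "brain"))
    expect_lt(max(abs(m$density.x - m$density.y) / m$density.y), 0.02)
  }
})

test_that("rotating the phantom by 90 degrees leaves strata densities unchanged", {
  cfg <- tiny_config()
  gt <- generate_ground_truth(cfg, seed = 6)
  ligs <- default_ligand_params(cfg$receptors$receptor)
  spec <- phantom_spec(cfg$areas, noise_sd = 0)
  ph <- render_phantom(spec, gt, ligs[["NMDA"]], "NMDA", brain = 1)
  cal <- fit_calibration(measure_standards(ph))
  dimg <- quantify_image(ph$image, cal, ligs[["NMDA"]])
  geom <- phantom_area_geometry(ph, "A1")
  trs <- extract_traverses(geom, spacing = 10)
  base <- aggregate_area(lapply(seq_len(nrow(trs)), function(i)
    partition_strata(sample_profile(dimg, trs[i, ], 301), geom)))
  # rotate image and geometry 90 degrees counterclockwise
  rot <- t(dimg)[ncol(dimg):1, ]
  rot_pt <- function(x, y) list(x = y, y = ncol(dimg) - x + 1)
  pr <- rot_pt(geom$pial$x, geom$pial$y)
  wr <- rot_pt(geom$wm$x, geom$wm$y)
  geom_r <- cortical_geometry(data.frame(x = pr$x, y = pr$y),
                              data.frame(x = wr$x, y = wr$y),
                              f1 = geom$f1, f2 = geom$f2)
  trs_r <- extract_traverses(geom_r, spacing = 10)
  rot_d <- density_image(rot)
  base_r <- aggregate_area(lapply(seq_len(nrow(trs_r)), function(i)
    partition_strata(sample_profile(rot_d, trs_r[i, ], 301), geom_r)))
  for (f in c("mean_sg", "mean_g", "mean_ig", "mean_all")) {
    expect_lt(abs(base_r[[f]] - base[[f]]) / base[[f]], 0.01)
  }
})
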