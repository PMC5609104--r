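true_film <- list(offset = 12, gmax = 228, a = 1 / 900)

make_standards <- function(R = seq(0, 2500, length.out = 8), noise_sd = 0,
                           seed = 1) {
  set.seed(seed)
  data.frame(known_R = R,
             mean_gray = film_response(R, true_film) + rnorm(length(R), 0,
                                                             noise_sd))
}

test_that("noiseless model-generated standards are fit exactly", {
  cal <- fit_calibration(make_standards())
  expect_lt(max(abs(cal$residuals)), 1e-9 * diff(range(make_standards()$mean_gray)))
  expect_lt(abs(cal$params$a - true_film$a) / true_film$a, 1e-6)
  expect_lt(abs(cal$params$gmax - true_film$gmax) / true_film$gmax, 1e-6)
  # interpolation through the nodes: gray at a standard returns known_R
  std <- make_standards()
  expect_equal(as.numeric(gray_to_radioactivity(cal, std$mean_gray)),
               std$known_R, tolerance = 1e-6)
})

test_that("noisy standards are recovered within 2% and beat a grid-search oracle", {
  std <- make_standards(noise_sd = 0.5, seed = 42)
  cal <- fit_calibration(std)
  # the zero standard may fall below the noisy fit offset and be masked
  rec <- suppressWarnings(as.numeric(
    gray_to_radioactivity(cal, film_response(std$known_R, true_film))))
  expect_lt(max(abs(rec[-1] - std$known_R[-1]) / std$known_R[-1]), 0.02)
  # independent oracle: coarse grid search over the same model family
  grid_rss <- function(offset, gmax, a) {
    sum((std$mean_gray - (offset + gmax * (1 - exp(-a * std$known_R))))^2)
  }
  best <- Inf
  for (o in seq(8, 16, length.out = 21)) {
    for (g in seq(200, 260, length.out = 31)) {
      for (a in seq(0.8, 1.3, length.out = 26) / 900) {
        best <- min(best, grid_rss(o, g, a))
      }
    }
  }
  expect_lte(cal$rss, best + 1e-9)
})

test_that("insufficient or degenerate standards are refused", {
  std <- make_standards()
  expect_error(fit_calibration(std[1:3, ]), "insufficient standards")
  std$mean_gray <- 100
  expect_error(fit_calibration(std), "degenerate")
})

test_that("gray conversion masks out-of-range values and propagates masks", {
  cal <- fit_calibration(make_standards())
  g <- c(NA, cal$valid_gray_range[1] - 5, 100)
  expect_warning(R <- gray_to_radioactivity(cal, g), "masked")
  expect_true(is.na(R[1]) && is.na(R[2]) && !is.na(R[3]))
  # monotone: increasing gray maps to increasing R
  gs <- seq(cal$valid_gray_range[1], cal$valid_gray_range[2] - 1,
            length.out = 50)
  expect_true(all(diff(as.numeric(gray_to_radioactivity(cal, gs))) > 0))
})

test_that("inverse consistency: film response undoes the fitted inverse", {
  cal <- fit_calibration(make_standards())
  gs <- seq(cal$valid_gray_range[1], cal$valid_gray_range[2] - 0.5,
            length.out = 101)
  back <- film_response(as.numeric(gray_to_radioactivity(cal, gs)),
                        cal$params)
  expect_lt(max(abs(back - gs)), 1e-6)
})

test_that("the log-polynomial family fits monotone data and refuses non-monotone fits", {
  std <- make_standards(R = seq(50, 2500, length.out = 10))
  cal <- fit_calibration(std, family = "logpoly")
  rec <- as.numeric(gray_to_radioactivity(cal, std$mean_gray))
  expect_lt(max(abs(rec - std$known_R) / std$known_R), 0.05)
})

test_that("Eq. 1 densitometry satisfies its closed form and homogeneity", {
  # hand-evaluated spot value: R/(E*B*Wb*Sa) * (KD+L)/L
  #  = 1000 / (0.5*2*0.05*80) * (1.4+0.7)/0.7 = 250 * 3 = 750
  lig <- ligand_params(E = 0.5, B = 2, Wb = 0.05, Sa = 80, KD = 1.4, L = 0.7)
  expect_equal(radioactivity_to_density(1000, lig), 750, tolerance = 1e-12)
  expect_equal(radioactivity_to_density(0, lig), 0)
  # KD = L and unit denominator gives Cb = 2R
  lig2 <- ligand_params(1, 1, 1, 1, 2.5, 2.5)
  expect_equal(radioactivity_to_density(123.4, lig2), 2 * 123.4)
  # homogeneity over random valid parameter draws
  set.seed(7)
  for (i in 1:20) {
    p <- ligand_params(runif(1, 0.1, 1), runif(1, 0.5, 4),
                       runif(1, 0.01, 0.2), runif(1, 20, 100),
                       runif(1, 0.3, 5), runif(1, 0.3, 5))
    R <- runif(1, 10, 5000)
    expect_equal(radioactivity_to_density(2 * R, p),
                 2 * radioactivity_to_density(R, p), tolerance = 1e-12)
    p2 <- p; p2$Sa <- 2 * p$Sa
    expect_equal(radioactivity_to_density(R, p2),
                 radioactivity_to_density(R, p) / 2, tolerance = 1e-12)
  }
  expect_error(ligand_params(0.5, 2, 0.05, 80, 1.4, 0), "positive")
  expect_error(ligand_params(-0.5, 2, 0.05, 80, 1.4, 0.7), "positive")
})

test_that("specific binding subtracts, floors at zero and reports flooring", {
  total <- density_image(matrix(c(10, 10), 1))
  nonspec <- density_image(matrix(c(3, 12), 1))
  sb <- specific_binding(total, nonspec)
  expect_equal(as.numeric(sb), c(7, 0))
  expect_equal(attr(sb, "n_floored"), 1L)
  expect_equal(as.numeric(specific_binding(total, density_image(matrix(0, 1, 2)))),
               c(10, 10))
  expect_true(all(specific_binding(total, total) == 0))
  expect_error(specific_binding(total, density_image(matrix(0, 2, 2))),
               "shape")
})

test_that("quantify_image composes conversions and masks saturated pixels", {
  cal <- fit_calibration(make_standards())
  lig <- ligand_params(0.5, 2, 0.05, 80, 1.4, 0.7)
  img <- matrix(film_response(c(100, 500, 1200), true_film), 1)
  dimg <- suppressWarnings(quantify_image(img, cal, lig))
  expect_equal(as.numeric(dimg),
               radioactivity_to_density(c(100, 500, 1200), lig),
               tolerance = 1e-6)
  # constant image -> constant density image
  cimg <- matrix(film_response(800, true_film), 5, 4)
  dc <- quantify_image(cimg, cal, lig)
  expect_equal(max(dc) - min(dc), 0)
  # saturated gray -> masked
  simg <- matrix(c(film_response(800, true_film), 300), 1)
  ds <- suppressWarnings(quantify_image(simg, cal, lig))
  expect_true(is.na(ds[2]) && !is.na(ds[1]))
})
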