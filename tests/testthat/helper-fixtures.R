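# small fixtures shared across the suite; everything is generated in code

# two-area / two-receptor configuration with switchable noise
tiny_config <- function(replicate_cv = 0, area_sd = 0, group_sd = 0,
                        n_brains = 3L) {
  areas <- data.frame(area = c("A1", "A2"),
                      group = c("g1", "g2"),
                      agranular = FALSE, primary_sensory = c(TRUE, FALSE),
                      f1 = 0.5, f2 = 0.7,
                      layerIII_lower_fraction = NA_real_,
                      stringsAsFactors = FALSE)
  cfg <- list(areas = areas,
              receptors = receptor_panel(c("NMDA", "kainate", "a4b2")),
              n_brains = n_brains, replicate_cv = replicate_cv,
              area_sd = area_sd, group_sd = group_sd)
  class(cfg) <- "study_config"
  cfg
}

# reduced study config without any randomness in the structure
quiet_config <- function(replicate_cv = 0) {
  cfg <- study_config(full = FALSE, replicate_cv = replicate_cv)
  cfg
}

# flat parallel-contour geometry of given thickness
flat_geometry <- function(thickness = 100, width = 60, f1 = 0.5, f2 = 0.7,
                          agranular = FALSE, l3 = NA_real_) {
  xs <- seq(1, width, length.out = 7)
  cortical_geometry(pial = data.frame(x = xs, y = rep(1, 7)),
                    wm = data.frame(x = xs, y = rep(1 + thickness, 7)),
                    f1 = f1, f2 = f2, agranular = agranular,
                    layerIII_lower_fraction = l3)
}

# synthetic piecewise-constant profile with values per stratum
step_profile <- function(sg, g, ig, f1 = 0.5, f2 = 0.7, n = 401L,
                         length_px = NULL) {
  d <- seq(0, 1, length.out = n)
  v <- ifelse(d < f1, sg, ifelse(d < f2, g, ig))
  structure(list(depth = d * 100, density = v, n_bins = n,
                 length_px = length_px),
            class = "laminar_profile")
}

# long density table from named area means, n replicates with given sd
toy_density_table <- function(area_means, n = 3L, sd = 0, stratum = "all",
                              receptor = "X", seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(names(area_means), function(a) {
    data.frame(area = a, receptor = receptor, stratum = stratum,
               brain = seq_len(n),
               density = abs(area_means[[a]] + rnorm(n, 0, sd)),
               stringsAsFactors = FALSE)
  }))
}

# exhaustive minimum within-cluster sum-of-squares 2-partition (oracle
# for the first Ward split); n <= 12
best_two_partition <- function(X) {
  n <- nrow(X)
  stopifnot(n <= 12L)
  best <- NULL; best_ss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    side <- c(0L, as.integer(intToBits(code))[1:(n - 1)])
    if (all(side == side[1])) next
    ss <- 0
    for (s in 0:1) {
      Y <- X[side == s, , drop = FALSE]
      ss <- ss + sum(sweep(Y, 2, colMeans(Y))^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- side }
  }
  list(partition = best, ss = best_ss)
}

# independent hand-written Eq. 1 inversion (density -> cpm), kept apart
# from the package internals to serve as a forward-model oracle
density_to_radioactivity_oracle <- function(Cb, lig) {
  Cb * lig$E * lig$B * lig$Wb * lig$Sa * lig$L / (lig$KD + lig$L)
}

# proper segment intersection, re-derived for the non-crossing oracle
segments_intersect_oracle <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}
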