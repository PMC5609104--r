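planted_blobs <- function(n_per = 4, k = 3, sep = 10, p = 5, seed = 5) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * p, mean = (i - 1) * sep), n_per, p)))
  rownames(X) <- paste0("obs", seq_len(nrow(X)))
  X
}

test_that("Ward first split matches the exhaustive 2-partition oracle on planted groups", {
  X <- planted_blobs(n_per = 4, k = 3, sep = 10)
  hres <- hcluster(X)
  split2 <- cutree(hres$hclust, 2)
  oracle <- best_two_partition(X)
  # identical up to label swap
  agree <- mean((split2 - 1) == oracle$partition)
  expect_true(agree %in% c(0, 1))
  # and each side is a union of planted groups
  planted <- rep(1:3, each = 4)
  expect_true(all(tapply(split2, planted, function(x) length(unique(x))) == 1))
})

test_that("cophenetic correlation: exact tree representation and Ward near-exactness on ultrametric input", {
  d <- as.dist(matrix(c(0, 1, 4, 4,
                        1, 0, 4, 4,
                        4, 4, 0, 2,
                        4, 4, 2, 0), 4))
  hres <- hcluster(d)
  # average linkage reproduces an ultrametric exactly
  expect_equal(unname(hres$linkage_comparison["average"]), 1,
               tolerance = 1e-9)
  expect_gt(hres$cophenetic_correlation, 0.98)
  # duplicated observations merge first at height 0
  X <- rbind(c(0, 0), c(0, 0), c(5, 5), c(9, 1))
  h2 <- hcluster(X)$hclust
  expect_equal(h2$height[1], 0)
  expect_setequal(h2$merge[1, ], c(-1, -2))
  # merge heights non-decreasing
  expect_true(all(diff(h2$height) >= -1e-12))
})

test_that("hcluster is permutation-invariant and scales heights by c^2 ... c", {
  X <- planted_blobs()
  h1 <- hcluster(X)$hclust
  perm <- sample(nrow(X))
  h2 <- hcluster(X[perm, ])$hclust
  expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-9)
  # ward.D2 heights scale linearly with the feature scale c
  h3 <- hcluster(3 * X)$hclust
  expect_equal(h3$height, 3 * h1$height, tolerance = 1e-9)
  Xna <- X; Xna[1, 1] <- NA
  expect_error(hcluster(Xna), "missing")
})

test_that("choose_k finds three planted blobs and is seed-deterministic", {
  X <- planted_blobs(n_per = 6, k = 3, sep = 8)
  kc <- choose_k(X, k_max = 8, seed = 2)
  expect_equal(kc$k, 3L)
  # silhouette oracle over the k grid: reported best really is the max
  expect_equal(unname(which.max(kc$scores)) + 1L, kc$k)
  kc2 <- choose_k(X, k_max = 8, seed = 2)
  expect_identical(kc$cluster, kc2$cluster)
  expect_error(choose_k(X, k_max = nrow(X)), "smaller")
  expect_error(choose_k(matrix(1, 10, 3), k_max = 4), "zero variance")
})

test_that("MDS embeds low-dimensional and tiny configurations with ~zero stress", {
  set.seed(4)
  X2 <- matrix(rnorm(24), 12, 2)
  m <- mds_kruskal(X2, seed = 1)
  expect_lt(m$stress, 1e-6)
  X3 <- matrix(c(0, 0, 3, 0, 0, 4), 3, 2, byrow = TRUE)
  expect_lt(mds_kruskal(X3, seed = 1)$stress, 1e-6)
  # best-of-restarts is monotone in the restart count
  X5 <- matrix(rnorm(60), 12, 5)
  s1 <- mds_kruskal(X5, n_restarts = 2, seed = 9)
  s2 <- mds_kruskal(X5, n_restarts = 10, seed = 9)
  expect_lte(min(s2$restart_stress), min(s1$restart_stress) + 1e-12)
})

test_that("strata-specific fingerprints separate into three clusters with pure supragranular cluster", {
  # the full study design is the stated condition for this property
  cfg <- study_config(full = TRUE, replicate_cv = 0.05)
  tab <- add_all_stratum(generate_ground_truth(cfg, seed = 21))
  fps <- build_fingerprints(tab)
  sf <- subset_fingerprints(fps, strata = c("sg", "g", "ig"),
                            exclude_areas = cfg$areas$area[cfg$areas$agranular])
  z <- normalize_z(sf, scope = "pooled-strata")
  m <- mds_kruskal(z, seed = 2)
  kc <- choose_k(m$points, k_max = 6, seed = 3)
  expect_equal(kc$k, 3L)
  stratum <- receptarch:::fp_meta(sf)$stratum
  tabk <- table(stratum, kc$cluster)
  sg_cl <- which.max(tabk["sg", ])
  expect_gte(tabk["sg", sg_cl] / sum(tabk[, sg_cl]), 0.95)
})

test_that("discriminant omnibus is calibrated under the null and powerful under shift", {
  # null: all groups from one distribution; permutation p approximately
  # uniform -> rejection rate at 0.1 close to 0.1
  set.seed(31)
  ps <- replicate(60, {
    X <- matrix(rnorm(8 * 6), 8, 6)
    discriminant_tests(X, rep(1:4, each = 2), n_perm = 99,
                       seed = sample.int(1e6, 1), pairwise = FALSE)$p_value
  })
  expect_gt(mean(ps <= 0.1), 0.02)
  expect_lt(mean(ps <= 0.1), 0.25)
  # power: two groups shifted by 10 sd
  set.seed(32)
  X <- rbind(matrix(rnorm(20 * 5), 20, 5), matrix(rnorm(20 * 5, 10), 20, 5))
  d <- discriminant_tests(X, rep(1:2, each = 20), n_perm = 1999,
                          pairwise = FALSE)
  expect_lt(d$p_value, 0.001)
  # label symmetry: permuting group codes leaves the statistic unchanged
  g <- rep(c("a", "b", "c"), each = 4)
  Xs <- planted_blobs(n_per = 4, k = 3, sep = 3, seed = 8)
  s1 <- discriminant_tests(Xs, g, n_perm = 19, seed = 1, pairwise = FALSE)
  g2 <- c(a = "c", b = "a", c = "b")[g]
  s2 <- discriminant_tests(Xs, g2, n_perm = 19, seed = 1, pairwise = FALSE)
  expect_equal(s1$statistic, s2$statistic, tolerance = 1e-12)
  expect_error(discriminant_tests(Xs[1:5, ], c(1, 1, 2, 2, 3), n_perm = 9),
               "single replicate")
})

test_that("pairwise discriminant matrix is symmetric with valid p values", {
  X <- planted_blobs(n_per = 3, k = 3, sep = 6, seed = 12)
  d <- discriminant_tests(X, rep(1:3, each = 3), n_perm = 99, seed = 5)
  P <- d$pairwise_p
  expect_true(isSymmetric(unname(P)))
  offd <- P[upper.tri(P)]
  expect_true(all(offd >= 0 & offd <= 1))
  expect_true(all(is.na(diag(P))))
})

test_that("dendrograms serialize to Newick with branch lengths", {
  X <- planted_blobs()
  hres <- hcluster(X)
  f <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(hres, f)
  tr <- ape::read.tree(f)
  expect_equal(sort(tr$tip.label), sort(rownames(X)))
  expect_true(all(is.finite(tr$edge.length)))
  unlink(f)
})
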