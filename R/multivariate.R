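# fingerprint_set / matrix / dist -> dist (Euclidean)
as_feature_dist <- function(x) {
  if (inherits(x, "dist")) return(x)
  M <- if (inherits(x, "fingerprint_set")) unclass(x) else as.matrix(x)
  if (anyNA(M)) abort("missing values in the feature matrix")
  stats::dist(M, method = "euclidean")
}

as_feature_matrix <- function(x) {
  M <- if (inherits(x, "fingerprint_set")) unclass(x) else as.matrix(x)
  if (anyNA(M)) abort("missing values in the feature matrix")
  M
}

#' Ward hierarchical clustering of fingerprints
#'
#' Agglomerative clustering with Euclidean distances and the Ward
#' linkage (`ward.D2`, which operates on the squared Euclidean
#' distances and produces non-decreasing merge heights). The cophenetic
#' correlation coefficient against the input distances is reported, and
#' optionally also for a set of alternative linkages, documenting that
#' Ward attains the maximum for the data at hand. Euclidean distance is
#' used because it is sensitive to both the size and the shape of a
#' fingerprint.
#'
#' @param x a normalized `fingerprint_set`, a numeric matrix
#'   (observations in rows), or a `dist`.
#' @param compare_linkages character vector of additional `hclust`
#'   methods to score by cophenetic correlation (NULL skips).
#' @return object of class `dendrogram_result`: the `hclust` tree,
#'   `cophenetic_correlation`, and `linkage_comparison`.
#' @export
hcluster <- function(x, compare_linkages = c("complete", "average", "single")) {
  d <- as_feature_dist(x)
  if (attr(d, "Size") < 3L) abort("need >= 3 observations to cluster")
  hc <- stats::hclust(d, method = "ward.D2")
  coph <- stats::cor(d, stats::cophenetic(hc))
  cmp <- c(ward.D2 = coph)
  for (m in compare_linkages %||% character()) {
    cmp[m] <- stats::cor(d, stats::cophenetic(stats::hclust(d, method = m)))
  }
  structure(list(hclust = hc, cophenetic_correlation = coph,
                 linkage_comparison = cmp, labels = hc$labels),
            class = "dendrogram_result")
}

#' @export
print.dendrogram_result <- function(x, ...) {
  cat(sprintf("dendrogram_result: n=%d, Ward/Euclidean, cophenetic r = %.4f\n",
              length(x$hclust$order), x$cophenetic_correlation))
  invisible(x)
}

#' Export a dendrogram as a Newick tree
#'
#' Serializes the merge tree with heights as branch lengths.
#'
#' @param dres a [hcluster()] result (or `hclust` object).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_dendrogram_newick <- function(dres, path) {
  hc <- if (inherits(dres, "dendrogram_result")) dres$hclust else dres
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Choose the number of clusters by k-means and silhouette
#'
#' Runs seeded k-means with multiple restarts for each candidate `k` and
#' selects the `k` maximizing the mean silhouette width. This
#' operationalizes "the number of clusters was defined using k-means":
#' the dendrogram shows the hierarchy, k-means plus silhouette says
#' where to cut it.
#'
#' @param x fingerprint set, matrix or 2-D embedding coordinates.
#' @param k_max largest candidate `k` (must be < number of
#'   observations).
#' @param nstart k-means restarts per candidate.
#' @param seed integer seed.
#' @return object of class `cluster_assignment`: chosen `k`, integer
#'   `cluster` labels (named by observation), and `scores` (mean
#'   silhouette per candidate k).
#' @export
choose_k <- function(x, k_max = 12L, nstart = 10L, seed = 1L) {
  M <- as_feature_matrix(x)
  n <- nrow(M)
  if (k_max >= n) abort("k_max must be smaller than the number of observations")
  if (k_max < 2L) abort("k_max must be >= 2")
  if (all(apply(M, 2L, stats::sd) == 0)) abort("zero variance: all observations identical")
  d <- stats::dist(M)
  with_seed(seed, {
    ks <- 2L:k_max
    fits <- lapply(ks, function(k) stats::kmeans(M, centers = k,
                                                 nstart = nstart,
                                                 iter.max = 50L))
    scores <- vapply(seq_along(ks), function(i) {
      mean(cluster::silhouette(fits[[i]]$cluster, d)[, "sil_width"])
    }, numeric(1))
    best <- which.max(scores)
    cl <- fits[[best]]$cluster
    names(cl) <- rownames(M)
    structure(list(k = ks[best], cluster = cl,
                   scores = stats::setNames(scores, ks)),
              class = "cluster_assignment")
  })
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: k = %d (mean silhouette %.3f)\n",
              x$k, max(x$scores)))
  invisible(x)
}

#' Non-metric multidimensional scaling (Kruskal stress)
#'
#' Embeds the Euclidean distances between fingerprints in two dimensions
#' by non-metric MDS minimizing Kruskal's stress-1, with a classical
#' (metric) solution plus seeded random restarts; the configuration with
#' the lowest stress wins.
#'
#' @param x fingerprint set, matrix or `dist`.
#' @param k embedding dimension (default 2).
#' @param n_restarts random restarts in addition to the classical-MDS
#'   initialization.
#' @param seed integer seed.
#' @return object of class `mds_result`: `points` (n x k), `stress`
#'   (Kruskal stress-1, as a fraction), `restart_stress`.
#' @export
mds_kruskal <- function(x, k = 2L, n_restarts = 20L, seed = 1L) {
  d <- as_feature_dist(x)
  n <- attr(d, "Size")
  if (n < 3L) abort("need >= 3 observations for MDS")
  if (any(d <= 0)) {
    if (!any(d > 0)) abort("degenerate input: all observations identical")
    # isoMDS requires positive dissimilarities; nudge exact duplicates
    d[d <= 0] <- min(d[d > 0]) * 1e-6
  }
  with_seed(seed, {
    inits <- c(list(stats::cmdscale(d, k = k)),
               lapply(seq_len(n_restarts), function(i)
                 matrix(stats::rnorm(n * k), n, k)))
    fits <- lapply(inits, function(y0) {
      fit <- try(MASS::isoMDS(d, y = y0, k = k, trace = FALSE,
                              tol = 1e-6, maxit = 200L), silent = TRUE)
      if (inherits(fit, "try-error")) NULL else fit
    })
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) abort("all MDS starts failed")
    stresses <- vapply(fits, `[[`, numeric(1), "stress") / 100
    best <- which.min(stresses)
    pts <- fits[[best]]$points
    rownames(pts) <- attr(d, "Labels")
    structure(list(points = pts, stress = stresses[best],
                   restart_stress = stresses),
              class = "mds_result")
  })
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("mds_result: %d points in %d-D, Kruskal stress-1 = %.4g\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

# pooled within-group covariance with analytic shrinkage toward its
# diagonal (Schafer-Strimmer style), for n << p group designs
shrunk_within_cov <- function(X, groups) {
  centered <- X
  for (g in unique(groups)) {
    i <- groups == g
    centered[i, ] <- sweep(X[i, , drop = FALSE], 2L,
                           colMeans(X[i, , drop = FALSE]))
  }
  n <- nrow(X)
  S <- crossprod(centered) / (n - 1)
  # variance of the off-diagonal entries of S
  W <- array(0, dim = c(ncol(X), ncol(X)))
  for (i in seq_len(n)) {
    wi <- tcrossprod(centered[i, ])
    W <- W + (wi - S)^2
  }
  varS <- W * n / ((n - 1)^3)
  off <- upper.tri(S)
  num <- sum(varS[off])
  den <- sum(S[off]^2)
  lambda <- if (den > 0) min(1, max(0, num / den)) else 1
  Sstar <- (1 - lambda) * S + lambda * diag(diag(S), ncol(X))
  list(cov = Sstar, lambda = lambda)
}

# regularized between/within trace statistic (Lawley-Hotelling flavor)
discriminant_statistic <- function(X, groups) {
  groups <- as.factor(groups)
  grand <- colMeans(X)
  B <- array(0, dim = c(ncol(X), ncol(X)))
  for (g in levels(groups)) {
    i <- groups == g
    dmu <- colMeans(X[i, , drop = FALSE]) - grand
    B <- B + sum(i) * tcrossprod(dmu)
  }
  sw <- shrunk_within_cov(X, groups)
  list(stat = sum(diag(solve(sw$cov, B))) / nrow(X), lambda = sw$lambda)
}

#' Discriminant tests of group separation of fingerprints
#'
#' Tests whether fingerprints differ between groups (e.g. with area as
#' the grouping factor): an omnibus multivariate test of the
#' between-group to within-group spread (Lawley-Hotelling-type trace
#' statistic), followed by pairwise two-group tests. With few replicates
#' per group and many receptors the pooled within-group covariance is
#' singular, so it is shrunk toward its diagonal with an analytically
#' chosen intensity; p values come from label permutations, which remain
#' exact under regularization. Pairwise p values are reported
#' uncorrected: they are post-hoc tests run only after a significant
#' omnibus test.
#'
#' @param x fingerprint matrix / `fingerprint_set` with replicate rows.
#' @param groups group label per row (>= 2 groups, >= 2 replicates
#'   each).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param pairwise also run all two-group comparisons.
#' @return object of class `discriminant_result`: `statistic`,
#'   `p_value`, `shrinkage` (omnibus), and a symmetric `pairwise_p`
#'   matrix (NA diagonal) when requested.
#' @export
discriminant_tests <- function(x, groups, n_perm = 999L, seed = 1L,
                               pairwise = TRUE) {
  X <- as_feature_matrix(x)
  groups <- as.factor(groups)
  if (length(groups) != nrow(X)) abort("'groups' must label every row")
  tab <- table(groups)
  if (length(tab) < 2L) abort("need >= 2 groups")
  if (any(tab < 2L)) {
    abort("group(s) with a single replicate: %s",
          paste(names(tab)[tab < 2L], collapse = ", "))
  }
  perm_p <- function(Xs, gs) {
    obs <- discriminant_statistic(Xs, gs)
    perm <- vapply(seq_len(n_perm), function(i) {
      discriminant_statistic(Xs, sample(gs))$stat
    }, numeric(1))
    list(stat = obs$stat, lambda = obs$lambda,
         p = (1 + sum(perm >= obs$stat - 1e-12)) / (1 + n_perm))
  }
  with_seed(seed, {
    omni <- perm_p(X, groups)
    out <- list(statistic = omni$stat, p_value = omni$p,
                shrinkage = omni$lambda, n_perm = as.integer(n_perm))
    if (pairwise) {
      lev <- levels(groups)
      P <- matrix(NA_real_, length(lev), length(lev),
                  dimnames = list(lev, lev))
      for (i in seq_along(lev)[-length(lev)]) {
        for (j in (i + 1L):length(lev)) {
          sel <- groups %in% lev[c(i, j)]
          pr <- perm_p(X[sel, , drop = FALSE], droplevels(groups[sel]))
          P[i, j] <- P[j, i] <- pr$p
        }
      }
      out$pairwise_p <- P
    }
    structure(out, class = "discriminant_result")
  })
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat(sprintf("discriminant_result: omnibus stat %.4g, p = %.4g (shrinkage %.3f, %d permutations)\n",
              x$statistic, x$p_value, x$shrinkage, x$n_perm))
  invisible(x)
}
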