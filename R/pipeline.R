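#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run
#' `simulate -> calibrate -> quantify -> profiles -> fingerprints ->
#' analyze -> report` into one validated object. All stochastic stages
#' derive their seeds from the single `seed`, so two runs with the same
#' configuration are bit-identical in every non-plot output.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master integer seed.
#' @param full full-size study design (44 areas x 15 receptors) or the
#'   reduced 8 x 6 design.
#' @param n_brains replicate brains.
#' @param replicate_cv between-brain coefficient of variation.
#' @param noise_sd additive film gray noise sd (0--255 gray scale).
#' @param spacing traverse spacing along the pial contour (px).
#' @param n_bins profile sample points.
#' @param geometry phantom ribbon geometry, `"flat"` or `"arc"`.
#' @param z_scope z-scoring scope for the strata-cluster analysis.
#' @param k_max largest candidate cluster count.
#' @param exclude_agranular drop the agranular areas (4, 6, 24) from the
#'   stratum-specific cluster analyses, whose granular stripe is a
#'   convention rather than a cytoarchitectonic layer IV.
#' @param discriminant_pairwise run all pairwise discriminant tests.
#' @param n_perm permutations for the discriminant tests.
#' @param write_images also write the phantom TIFFs (off by default;
#'   they are bulky and reproducible from the seed).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, full = FALSE, n_brains = 3L,
                            replicate_cv = 0.05, noise_sd = 0.5,
                            spacing = 8, n_bins = 201L,
                            geometry = c("flat", "arc"),
                            z_scope = "pooled-strata", k_max = 12L,
                            exclude_agranular = TRUE,
                            discriminant_pairwise = !full, n_perm = 199L,
                            write_images = FALSE) {
  geometry <- match.arg(geometry)
  if (!is_num1(seed)) abort("seed must be a single integer")
  structure(list(out_dir = out_dir, seed = as.integer(seed), full = full,
                 n_brains = as.integer(n_brains),
                 replicate_cv = replicate_cv, noise_sd = noise_sd,
                 spacing = spacing, n_bins = as.integer(n_bins),
                 geometry = geometry, z_scope = z_scope,
                 k_max = as.integer(k_max),
                 exclude_agranular = exclude_agranular,
                 discriminant_pairwise = discriminant_pairwise,
                 n_perm = as.integer(n_perm),
                 write_images = write_images),
            class = "pipeline_config")
}

# short md5 of the serialized configuration (paths excluded: the science
# of a run, not where it lands), for output provenance
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  substr(unname(tools::md5sum(f)), 1L, 12L)
}

write_csv_prov <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Recover the strata density table from rendered phantoms
#'
#' The quantification core shared by [run_pipeline()] and the
#' package's validation scripts: for every receptor and brain it
#' renders (or accepts) a phantom, fits the film calibration from the
#' co-exposed standards, quantifies the image, extracts equidistant
#' traverses per area, samples and partitions the laminar profiles and
#' aggregates them into per-area strata densities.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param spec a [phantom_spec()] (its `areas` define what is
#'   quantified).
#' @param ligands named list of [ligand_params()] per receptor.
#' @param spacing traverse spacing (px).
#' @param n_bins profile sample points.
#' @param receptors,brains subsets to process (defaults: everything in
#'   `truth`).
#' @param keep_calibrations return the fitted calibrations as an
#'   attribute.
#' @return long data.frame `area, receptor, stratum, brain, density,
#'   n_profiles` with strata `sg, g, ig`.
#' @export
quantify_phantoms <- function(truth, spec, ligands, spacing = 8,
                              n_bins = 201L, receptors = NULL, brains = NULL,
                              keep_calibrations = FALSE) {
  receptors <- receptors %||% unique(truth$densities$receptor)
  brains <- brains %||% unique(truth$densities$brain)
  cals <- list()
  rows <- list()
  for (rc in receptors) {
    for (b in brains) {
      ph <- render_phantom(spec, truth, ligands[[rc]], rc, brain = b)
      cal <- fit_calibration(measure_standards(ph))
      if (keep_calibrations) cals[[paste(rc, b, sep = "_")]] <- cal
      dimg <- suppressWarnings(quantify_image(ph$image, cal, ligands[[rc]]))
      for (a in spec$areas$area) {
        geom <- phantom_area_geometry(ph, a)
        trs <- extract_traverses(geom, spacing = spacing)
        trs <- trs[!trs$excluded, , drop = FALSE]
        sds <- lapply(seq_len(nrow(trs)), function(i)
          partition_strata(sample_profile(dimg, trs[i, ], n_bins = n_bins),
                           geom))
        agg <- aggregate_area(sds)
        rows[[length(rows) + 1L]] <- data.frame(
          area = a, receptor = rc, brain = b,
          stratum = c("sg", "g", "ig"),
          density = c(agg$mean_sg, agg$mean_g, agg$mean_ig),
          n_profiles = agg$n_profiles, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)[, c("area", "receptor", "stratum", "brain",
                                  "density", "n_profiles")]
  if (keep_calibrations) attr(out, "calibrations") <- cals
  out
}

#' Run the full analysis pipeline
#'
#' Simulates ground truth, renders and quantifies the phantoms, builds
#' fingerprints, and runs the multivariate and univariate statistics,
#' writing every intermediate artifact (strata CSV, calibration JSONs,
#' fingerprint CSVs, dendrogram Newick files, MDS coordinates, ANOVA /
#' t-test / discriminant tables) plus a run manifest into
#' `config$out_dir`. Each stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of class `analysis_report` with all
#'   in-memory results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) abort("'config' must be a pipeline_config")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  scfg <- study_config(full = config$full, n_brains = config$n_brains,
                       replicate_cv = config$replicate_cv)
  truth <- stage("simulate", generate_ground_truth(scfg, seed = config$seed))
  ligands <- default_ligand_params(scfg$receptors$receptor)
  spec <- phantom_spec(scfg$areas, geometry = config$geometry,
                       noise_sd = config$noise_sd, seed = config$seed + 1L)

  recovered <- stage("quantify", quantify_phantoms(
    truth, spec, ligands, spacing = config$spacing, n_bins = config$n_bins,
    keep_calibrations = TRUE))
  cals <- attr(recovered, "calibrations")
  dir.create(file.path(out, "calibrations"), showWarnings = FALSE)
  for (nm in names(cals)) {
    write_calibration(cals[[nm]], file.path(out, "calibrations",
                                            paste0(nm, ".json")))
  }
  table <- add_all_stratum(recovered[, c("area", "receptor", "stratum",
                                         "brain", "density")],
                           areas = scfg$areas)
  write_csv_prov(table, file.path(out, "strata_densities.csv"),
                 hash, config$seed)
  write_csv_prov(truth$densities, file.path(out, "ground_truth.csv"),
                 hash, config$seed)
  if (config$write_images) {
    dir.create(file.path(out, "images"), showWarnings = FALSE)
    for (rc in scfg$receptors$receptor) {
      ph <- render_phantom(spec, truth, ligands[[rc]], rc, brain = 1L)
      write_phantom(ph, file.path(out, "images", gsub("[^A-Za-z0-9]", "_", rc)))
    }
  }

  fps <- stage("fingerprint", build_fingerprints(table))
  sizes <- fingerprint_size(fps)
  write_csv_prov(cbind(fp_meta(fps), as.data.frame(unclass(fps))),
                 file.path(out, "fingerprints.csv"), hash, config$seed)
  write_csv_prov(sizes, file.path(out, "fingerprint_sizes.csv"),
                 hash, config$seed)

  excl <- if (config$exclude_agranular)
    scfg$areas$area[scfg$areas$agranular] else NULL

  # strata clusters: pooled z over sg/g/ig fingerprints, MDS + k-means
  strata_fps <- subset_fingerprints(fps, strata = c("sg", "g", "ig"),
                                    exclude_areas = excl)
  zpool <- normalize_z(strata_fps, scope = "pooled-strata")
  mds <- stage("analyze", mds_kruskal(zpool, seed = config$seed + 2L))
  kc <- choose_k(mds$points, k_max = config$k_max, seed = config$seed + 3L)
  write_csv_prov(data.frame(fp_meta(zpool), dim1 = mds$points[, 1],
                            dim2 = mds$points[, 2], cluster = kc$cluster),
                 file.path(out, "mds_strata.csv"), hash, config$seed)

  # per-stratum and all-layer dendrograms on per-stratum z-scores
  dendros <- list()
  for (st in c("all", "sg", "g", "ig")) {
    fsub <- subset_fingerprints(fps, strata = st,
                                exclude_areas = if (st == "all") NULL else excl)
    z <- normalize_z(fsub, scope = "per-stratum")
    rownames(z) <- fp_meta(z)$area
    dres <- hcluster(z)
    dendros[[st]] <- dres
    write_dendrogram_newick(dres, file.path(out, paste0("dendrogram_", st,
                                                        ".nwk")))
  }

  # univariate battery per layer set
  anovas <- list(); extrema <- list()
  for (st in c("all", "sg", "g", "ig")) {
    at <- stage("report", anova_by_area(table, layer_set = st))
    anovas[[st]] <- at
    extrema[[st]] <- extrema_tests(table, at)
  }
  write_csv_prov(do.call(rbind, anovas), file.path(out, "anova.csv"),
                 hash, config$seed)
  write_csv_prov(do.call(rbind, extrema), file.path(out, "extrema_tests.csv"),
                 hash, config$seed)

  # discriminant analysis with area as the grouping factor, on
  # brain-replicate all-layer fingerprints
  repl <- table[table$stratum == "all", ]
  wide <- stats::reshape(repl[, c("area", "receptor", "brain", "density")],
                         idvar = c("area", "brain"), timevar = "receptor",
                         direction = "wide")
  X <- as.matrix(wide[, -(1:2)])
  disc <- stage("analyze", discriminant_tests(
    X, wide$area, n_perm = config$n_perm, seed = config$seed + 4L,
    pairwise = config$discriminant_pairwise))
  jsonlite::write_json(list(statistic = disc$statistic, p = disc$p_value,
                            shrinkage = disc$shrinkage,
                            pairwise_p = disc$pairwise_p),
                       file.path(out, "discriminant.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  manifest <- list(package_version = as.character(utils::packageVersion("receptarch")),
                   r_version = as.character(getRversion()),
                   seed = config$seed, config_hash = hash,
                   config = unclass(config),
                   timestamp = NULL)   # deliberately omitted: outputs must be bit-stable
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  report <- list(truth = truth, recovered = table, fingerprints = fps,
                 sizes = sizes, mds = mds, clusters = kc,
                 dendrograms = dendros, anova = anovas, extrema = extrema,
                 discriminant = disc, config = config, config_hash = hash)
  class(report) <- "analysis_report"
  invisible(report)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report: %d areas, %d receptors, %d strata fingerprints; MDS stress %.3f; k = %d\n",
              length(attr(x$fingerprints, "areas")),
              ncol(x$fingerprints), nrow(x$fingerprints),
              x$mds$stress, x$clusters$k))
  invisible(x)
}
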