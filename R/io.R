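.strata_vocab <- c(sg = "sg", g = "g", ig = "ig", all = "all",
                   supragranular = "sg", granular = "g",
                   infragranular = "ig", layerIV = "g",
                   "layers I-III" = "sg", "layers V-VI" = "ig")

#' Read a long-form strata density table
#'
#' Canonical exchange format: CSV with header
#' `area,receptor,stratum,brain,density` (densities in fmol/mg
#' protein). Strata must be `sg`, `g`, `ig` (optionally `all`); common
#' synonyms are rejected with the canonical label suggested. Malformed
#' or negative-density rows are reported with their line numbers.
#' Receptor and area names can be validated against a configuration.
#'
#' @param path CSV file.
#' @param receptors,areas optional vocabularies to validate against.
#' @return long data.frame `area, receptor, stratum, brain, density`.
#' @export
read_density_table <- function(path, receptors = NULL, areas = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("area", "receptor", "stratum", "brain", "density")
  if (!identical(names(df)[seq_along(need)], need)) {
    abort("expected header '%s', found '%s'", paste(need, collapse = ","),
          paste(names(df), collapse = ","))
  }
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  bad_stratum <- !(df$stratum %in% c("sg", "g", "ig", "all"))
  if (any(bad_stratum)) {
    i <- which(bad_stratum)[1L]
    hint <- .strata_vocab[df$stratum[i]]
    abort("line %d: unknown stratum label '%s'%s", line[i], df$stratum[i],
          if (!is.na(hint)) sprintf(" (did you mean '%s'?)", hint) else "")
  }
  dens <- suppressWarnings(as.numeric(df$density))
  if (anyNA(dens)) {
    abort("line %d: non-numeric density '%s'", line[which(is.na(dens))[1L]],
          df$density[which(is.na(dens))[1L]])
  }
  df$density <- dens
  if (any(df$density < 0)) {
    abort("line %d: negative density %s", line[which(df$density < 0)[1L]],
          df$density[which(df$density < 0)[1L]])
  }
  if (!is.null(receptors)) {
    bad <- setdiff(unique(df$receptor), receptors)
    if (length(bad)) abort("unknown receptor(s): %s", paste(bad, collapse = ", "))
  }
  if (!is.null(areas)) {
    bad <- setdiff(unique(df$area), areas)
    if (length(bad)) abort("unknown area(s): %s", paste(bad, collapse = ", "))
  }
  df[, need]
}

#' Write a long-form strata density table
#'
#' @param table long data.frame `area, receptor, stratum, brain,
#'   density`.
#' @param path output CSV.
#' @return invisibly, the path.
#' @export
write_density_table <- function(table, path) {
  need <- c("area", "receptor", "stratum", "brain", "density")
  if (!all(need %in% names(table))) {
    abort("table must have columns %s", paste(need, collapse = ", "))
  }
  utils::write.csv(table[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a film calibration as JSON
#'
#' @param cal a [fit_calibration()] result.
#' @param path JSON file.
#' @return `write_calibration`: invisibly the path; `read_calibration`:
#'   a `film_calibration`.
#' @export
write_calibration <- function(cal, path) {
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$standards <- as.data.frame(x$standards)
  if (!is.null(x$coef)) x$coef <- unlist(x$coef)
  class(x) <- "film_calibration"
  x
}

#' Read / write ligand parameter files
#'
#' Ligand parameters are stored keyed by receptor in YAML (or JSON),
#' each entry holding the six constants of [ligand_params()].
#'
#' @param path YAML or JSON file.
#' @return named list of [ligand_params()] objects.
#' @export
read_ligand_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(p) do.call(ligand_params,
                                  as.list(p)[c("E", "B", "Wb", "Sa", "KD", "L")]))
}

#' @rdname read_ligand_params
#' @param ligands named list of [ligand_params()] objects.
#' @export
write_ligand_params <- function(ligands, path) {
  yaml::write_yaml(lapply(ligands, unclass), path)
  invisible(path)
}

#' Default ligand parameter set
#'
#' Plausible incubation/counting constants per receptor of the panel
#' (counter efficiency 0.4--0.5, tracer-specific activities 40--90
#' Ci/mmol, dissociation constants 0.5--5 nM with free ligand
#' concentrations near KD). These are synthetic stand-ins with realistic
#' magnitudes, sufficient for exercising the unit bookkeeping; any real
#' experiment supplies its own file via [read_ligand_params()].
#'
#' @param receptors receptor names.
#' @return named list of [ligand_params()].
#' @export
default_ligand_params <- function(receptors = receptor_order()) {
  kd <- c(AMPA = 1.1, NMDA = 4.4, kainate = 5.0, GABAA = 2.0,
          GABAA_BZ = 1.0, GABAB = 1.5, M1 = 1.0, M2 = 1.7, M3 = 0.8,
          a4b2 = 0.5, a1 = 0.7, a2 = 1.2, `5-HT1A` = 1.0, `5-HT2` = 1.9,
          D1 = 1.4)
  sa <- c(AMPA = 45, NMDA = 50, kainate = 58, GABAA = 36, GABAA_BZ = 85,
          GABAB = 40, M1 = 80, M2 = 82, M3 = 85, a4b2 = 70, a1 = 75,
          a2 = 60, `5-HT1A` = 65, `5-HT2` = 76, D1 = 81)
  out <- lapply(receptors, function(rc) {
    k <- if (rc %in% names(kd)) kd[[rc]] else 1.5
    s <- if (rc %in% names(sa)) sa[[rc]] else 60
    ligand_params(E = 0.45, B = 2.0, Wb = 0.05, Sa = s, KD = k, L = k * 0.6)
  })
  stats::setNames(out, receptors)
}
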