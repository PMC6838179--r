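#' Pipeline run configuration
#'
#' Bundles every tunable of a full profiling run. Axis selection decides
#' which measurement column plays the spatial y coordinate and which the
#' interpolated response z; swapping them re-analyses the same table in
#' the orthogonal orientation (e.g. trafficking-over-cholesterol versus
#' cholesterol-over-trafficking) without editing the data.
#'
#' @param y_col,z_col measurement columns mapped to the y and z axes.
#' @param family variogram family (default spherical).
#' @param n_bins,active_lag empirical variogram binning (NULL active lag =
#'   half the maximum pair distance).
#' @param min_n,max_n,search_radius neighborhood policy (NULL radius =
#'   variogram range).
#' @param grid_res landscape grid resolution per axis.
#' @param confidence_q confidence-mask quantile.
#' @param cv_k folds for cross-validation (NULL = leave-one-out).
#' @param cv_repeats k-fold partition repetitions.
#' @param seed integer seed for all stochastic stages.
#' @param normalize,reference measurement normalization passed to
#'   [load_variant_table()].
#' @param protein_length protein length override (NULL reads a `length`
#'   column).
#' @param out_dir output directory for [run_pipeline()].
#' @return a `vsp_config` list.
#' @export
vsp_config <- function(y_col = "Chol", z_col = "TrIdx",
                       family = "spherical", n_bins = 12,
                       active_lag = NULL, min_n = 5L, max_n = 20L,
                       search_radius = NULL, grid_res = 100L,
                       confidence_q = 0.25, cv_k = NULL, cv_repeats = 5L,
                       seed = 1L, normalize = "none", reference = NULL,
                       protein_length = NULL, out_dir = ".") {
  structure(as.list(environment()), class = "vsp_config")
}

# one-line fingerprint embedded in every output; the output directory is
# not part of it (identical analyses in different directories are the
# same analysis)
.config_fingerprint <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]
  flat <- purrr::imap_chr(config, function(v, nm) {
    paste0(nm, "=", if (is.null(v)) "auto" else paste(format(v), collapse = ","))
  })
  paste0("vsprofiler ", utils::packageVersion("vsprofiler"), " | ",
         paste(flat, collapse = "; "))
}

#' Run the full variation-spatial-profiling pipeline
#'
#' Loads (or accepts) a variant table, computes and fits the molecular
#' variogram, cross-validates the Kriging predictor, builds the
#' confidence-masked phenotype landscape, annotates residues, and writes
#' every artifact to `config$out_dir`: `variogram.tsv`,
#' `variogram_model.json`, `landscape.tsv`, `cv_summary.json`,
#' `residues.tsv`, and optionally `annotated.pdb`. All outputs embed the
#' configuration fingerprint and package version.
#'
#' @param table a `variant_tbl` or path to a delimited variant table.
#' @param config a [vsp_config()].
#' @param pdb optional path to a PDB file to annotate.
#' @return invisible list with elements `dataset`, `empirical`, `model`,
#'   `cv`, `landscape`, `residues`, and `paths` (the files written).
#' @export
run_pipeline <- function(table, config = vsp_config(), pdb = NULL) {
  dataset <- if (is.character(table)) {
    load_variant_table(table, y_col = config$y_col, z_col = config$z_col,
                       protein_length = config$protein_length,
                       normalize = config$normalize,
                       reference = config$reference)
  } else table
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- .config_fingerprint(config)
  policy <- neighborhood_policy(config$min_n, config$max_n,
                                config$search_radius)

  pairs <- pairwise_semivariances(dataset)
  emp <- empirical_variogram(pairs, n_bins = config$n_bins,
                             active_lag = config$active_lag)
  model <- fit_variogram(emp, config$family)

  cv <- if (is.null(config$cv_k)) {
    loo_cv(dataset, policy = policy, model = model)
  } else {
    kfold_cv(dataset, k = config$cv_k, repeats = config$cv_repeats,
             seed = config$seed, policy = policy, model = model)
  }

  landscape <- build_landscape(dataset, model, policy,
                               grid_res = config$grid_res)
  landscape <- confidence_mask(landscape, config$confidence_q)
  residues <- annotate_residues(landscape, protein_length(dataset))

  paths <- list(
    variogram = file.path(config$out_dir, "variogram.tsv"),
    model = file.path(config$out_dir, "variogram_model.json"),
    landscape = file.path(config$out_dir, "landscape.tsv"),
    cv = file.path(config$out_dir, "cv_summary.json"),
    residues = file.path(config$out_dir, "residues.tsv"))

  writeLines(paste0("# ", fp), paths$variogram)
  readr::write_tsv(tibble::as_tibble(emp), paths$variogram, append = TRUE,
                   col_names = TRUE)

  jsonlite::write_json(
    c(as.list(glance(model)), list(provenance = fp)),
    paths$model, auto_unbox = TRUE, digits = NA)

  write_landscape(landscape, paths$landscape)

  jsonlite::write_json(
    c(as.list(glance(cv)), list(provenance = fp)),
    paths$cv, auto_unbox = TRUE, digits = NA, na = "null")

  writeLines(paste0("# ", fp), paths$residues)
  readr::write_tsv(residues, paths$residues, append = TRUE,
                   col_names = TRUE)

  if (!is.null(pdb)) {
    paths$pdb <- file.path(config$out_dir, "annotated.pdb")
    write_annotated_pdb(pdb, residues, paths$pdb)
  }

  invisible(list(dataset = dataset, empirical = emp, model = model,
                 cv = cv, landscape = landscape, residues = residues,
                 paths = paths))
}
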