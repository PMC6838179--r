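#' Build a variant dataset from a data frame
#'
#' A variant dataset is a tibble with one row per variant observation and
#' columns `label`, `position`, `x`, `y`, `z`, `condition`, `is_null`.
#' `x = position / protein_length` is the normalized sequence coordinate in
#' (0, 1]; `y` is the functional coordinate chosen for the run's y-axis and
#' `z` the response value interpolated by Kriging. The protein length and
#' axis provenance are carried as attributes so downstream verbs can stamp
#' their outputs.
#'
#' Duplicate `(x, y)` coordinate pairs are legal in the table but make the
#' Kriging covariance matrix singular; they are detected here and reported
#' as a warning naming both labels. Kriging matrix assembly jitters the
#' second member of each duplicate pair by +1e-9 in x internally (reports
#' and tables always show the original coordinates).
#'
#' @param df data frame with at least `position`, `y`, `z`; optional
#'   `label`, `condition`, `is_null`.
#' @param protein_length full-length protein size in residues; all rows
#'   share it.
#' @param axes optional named list describing the y/z axis provenance
#'   (free-form metadata, stored as the `axes` attribute).
#' @return a `variant_tbl` tibble.
#' @export
variant_dataset <- function(df, protein_length, axes = NULL) {
  stopifnot(is.data.frame(df))
  if (!is.numeric(protein_length) || length(protein_length) != 1L ||
      protein_length < 1 || protein_length != round(protein_length)) {
    abort("`protein_length` must be a single positive integer (residues).")
  }
  required <- c("position", "y", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("variant table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "vsp_schema_error")
  }
  out <- tibble::as_tibble(df)
  if (!"label" %in% names(out)) out$label <- paste0("v", seq_len(nrow(out)))
  if (!"condition" %in% names(out)) out$condition <- "CTL"
  if (!"is_null" %in% names(out)) out$is_null <- FALSE
  for (col in c("position", "y", "z")) {
    if (!is.numeric(out[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(out[[col]]))))
      abort(paste0("non-numeric value in column `", col, "` at row(s) ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "vsp_parse_error")
    }
  }
  if (any(!is.finite(out$y)) || any(!is.finite(out$z))) {
    bad <- which(!is.finite(out$y) | !is.finite(out$z))
    abort(paste0("missing/non-finite measurement at row(s) ",
                 paste(head(bad, 5), collapse = ", "),
                 "; measurements must be complete at load time"),
          class = "vsp_parse_error")
  }
  if (any(out$position < 1 | out$position > protein_length)) {
    abort("`position` must lie in [1, protein_length]",
          class = "vsp_domain_error")
  }
  out$x <- out$position / protein_length
  out <- dplyr::select(out, "label", "position", "x", "y", "z",
                       "condition", "is_null", dplyr::everything())
  dup <- duplicated(out[, c("x", "y")]) |
    duplicated(out[, c("x", "y")], fromLast = TRUE)
  if (any(dup)) {
    pairs <- split(out$label[dup], interaction(out$x[dup], out$y[dup], drop = TRUE))
    msg <- paste(vapply(pairs, paste, "", collapse = " / "), collapse = "; ")
    warn(paste0("duplicate (x, y) coordinates detected: ", msg,
                " (second member jittered inside Kriging matrices only)"),
         class = "vsp_duplicate_warning")
  }
  structure(out,
            protein_length = as.integer(protein_length),
            axes = axes,
            class = c("variant_tbl", class(out)))
}

#' @export
print.variant_tbl <- function(x, ...) {
  cat("# Variant dataset:", nrow(x), "observations, protein length",
      attr(x, "protein_length"), "residues\n")
  NextMethod()
}

#' Protein length of a variant dataset
#' @param dataset a `variant_tbl`.
#' @return integer number of residues.
#' @export
protein_length <- function(dataset) {
  pl <- attr(dataset, "protein_length")
  if (is.null(pl)) abort("not a variant dataset: missing protein_length")
  pl
}

#' Read a delimited variant table
#'
#' Reads a TSV/CSV variant table (header required) and maps measurement
#' columns onto the run's y and z axes. Ratio normalization against a
#' reference variant ("normalized to I1061T" style) divides the selected
#' column by the reference variant's raw value so the reference maps to 1;
#' a min-max alternative rescales the column to [0, 1]. The normalization
#' actually applied is recorded in the `axes` attribute.
#'
#' @param path file path to a delimited table (delimiter sniffed from the
#'   extension: `.csv` comma, otherwise tab).
#' @param y_col,z_col names of the measurement columns to place on the y and
#'   z axes.
#' @param length_col column holding the full protein length, or a number
#'   giving it directly via `protein_length`.
#' @param protein_length protein length in residues; overrides `length_col`.
#' @param normalize one of "none", "reference", "minmax": normalization for
#'   the y column (and z when `normalize_z` is TRUE).
#' @param reference label of the reference variant for
#'   `normalize = "reference"`.
#' @param normalize_z also normalize the z column the same way.
#' @param condition value for the condition tag if the table has no
#'   `condition` column.
#' @return a `variant_tbl` (see [variant_dataset()]).
#' @export
load_variant_table <- function(path, y_col, z_col,
                               length_col = "length",
                               protein_length = NULL,
                               normalize = c("none", "reference", "minmax"),
                               reference = NULL,
                               normalize_z = FALSE,
                               condition = "CTL") {
  normalize <- match.arg(normalize)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (col in c("position", y_col, z_col)) {
    if (!col %in% names(raw)) {
      abort(paste0("variant table is missing column(s): ", col),
            class = "vsp_schema_error")
    }
  }
  if (is.null(protein_length)) {
    if (!length_col %in% names(raw)) {
      abort(paste0("variant table is missing column(s): ", length_col),
            class = "vsp_schema_error")
    }
    protein_length <- unique(raw[[length_col]])
    if (length(protein_length) != 1L) {
      abort("all rows must share one protein length",
            class = "vsp_schema_error")
    }
  }
  norm_col <- function(v, what) {
    switch(normalize,
      none = v,
      minmax = {
        r <- range(v)
        if (diff(r) == 0) abort(paste0("cannot min-max normalize constant ",
                                       what, " column"))
        (v - r[1]) / diff(r)
      },
      reference = {
        if (is.null(reference)) {
          abort("`reference` must name a variant for reference normalization",
                class = "vsp_config_error")
        }
        idx <- which(raw$label == reference)
        if (!length(idx)) {
          abort(paste0("reference variant `", reference,
                       "` absent from the table"),
                class = "vsp_config_error")
        }
        v / v[idx[1]]
      })
  }
  df <- tibble::tibble(
    label = if ("label" %in% names(raw)) raw$label else paste0("v", seq_len(nrow(raw))),
    position = raw$position,
    y = norm_col(raw[[y_col]], y_col),
    z = if (normalize_z) norm_col(raw[[z_col]], z_col) else raw[[z_col]],
    condition = if ("condition" %in% names(raw)) raw$condition else condition,
    is_null = if ("is_null" %in% names(raw)) as.logical(raw$is_null) else FALSE
  )
  variant_dataset(df, protein_length,
                  axes = list(y = y_col, z = z_col,
                              normalize = normalize, reference = reference,
                              normalize_z = normalize_z))
}

#' Write a variant dataset back to a delimited table
#'
#' Inverse of [load_variant_table()]: numeric fields are written at full
#' precision so a load/write round trip reproduces them exactly.
#'
#' @param dataset a `variant_tbl`.
#' @param path output path; `.csv` writes comma-delimited, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(dataset, path) {
  out <- tibble::as_tibble(dataset)
  out$length <- protein_length(dataset)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Bin a trafficking index into functional classes I-IV
#'
#' Class I marks variants with no polypeptide expression (nonsense/splice
#' truncations) and is only assignable from the explicit `is_null` flag,
#' never inferred from a trafficking index. For expressed missense variants
#' the trafficking index TrIdx (the Endo H-resistant fraction of
#' glycoforms, in [0, 1]) is binned as: class II below 0.2 (largely ER
#' retained), class III in [0.2, 0.5] (intermediate trafficking), class IV
#' above 0.5 (significant ER export). The source description of the
#' boundaries is approximate ("~0.2", "~0.5"); the half-open convention
#' `[0, 0.2) / [0.2, 0.5] / (0.5, 1]` is fixed here so classification is
#' deterministic.
#'
#' @param trIdx numeric vector of trafficking indices in [0, 1].
#' @param is_null logical vector (recycled): TRUE marks null/truncation
#'   variants.
#' @return factor with levels `I`, `II`, `III`, `IV`.
#' @export
classify_trafficking <- function(trIdx, is_null = FALSE) {
  if (any(trIdx < 0 | trIdx > 1, na.rm = TRUE)) {
    abort("trafficking index must lie in [0, 1]", class = "vsp_domain_error")
  }
  is_null <- rep_len(as.logical(is_null), length(trIdx))
  cls <- dplyr::case_when(
    is_null ~ "I",
    trIdx < 0.2 ~ "II",
    trIdx <= 0.5 ~ "III",
    TRUE ~ "IV"
  )
  factor(cls, levels = c("I", "II", "III", "IV"))
}
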