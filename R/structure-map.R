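#' Per-residue annotations from a phenotype landscape
#'
#' Collapses a landscape to one record per residue: residue r maps to
#' normalized coordinate `x_r = r / protein_length`, the nearest grid
#' column is taken, and within that column the row with the smallest
#' Kriging variance — the highest-confidence prediction — supplies the
#' value. The y coordinate where that best prediction occurs is reported
#' as the companion value (e.g. the cholesterol score accompanying a
#' best-confidence trafficking prediction). Ties in variance resolve to
#' the lower y.
#'
#' A grid much coarser than the protein makes neighboring residues share
#' columns; a warning fires when `grid_res < protein_length / 10`.
#'
#' @param landscape a `phenotype_landscape` (optionally a delta landscape;
#'   a `delta` column is carried through if present).
#' @param protein_length number of residues to annotate.
#' @return tibble with `residue`, `value`, `companion`, `sigma2` (+
#'   `delta` when the landscape has a `delta` column).
#' @export
annotate_residues <- function(landscape, protein_length) {
  gx <- attr(landscape, "grid_x")
  gy <- attr(landscape, "grid_y")
  if (is.null(gx) || !nrow(landscape)) {
    abort("empty or non-landscape input", class = "vsp_shape_error")
  }
  if (length(gx) < protein_length / 10) {
    warn(sprintf(
      "landscape grid (%d columns) is coarse for %d residues; grid_res >= protein_length/10 recommended",
      length(gx), protein_length), class = "vsp_resolution_warning")
  }
  # column-major layout from tidyr::expand_grid(x, y): y varies fastest
  ny <- length(gy)
  purrr::map(seq_len(protein_length), function(r) {
    xr <- r / protein_length
    col <- which.min(abs(gx - xr))
    rows <- ((col - 1L) * ny + 1L):(col * ny)
    block <- landscape[rows, ]
    best <- order(block$sigma2, block$y)[1]
    tibble::tibble(residue = r,
                   value = block$z_hat[best],
                   companion = block$y[best],
                   sigma2 = block$sigma2[best])
  }) |> dplyr::bind_rows()
}

#' Write residue annotations into a PDB file's B-factor column
#'
#' Splices per-residue values into the B-factor field (columns 61-66) of
#' `ATOM`/`HETATM` records, leaving every other byte of the file untouched.
#' Values are linearly scaled by `scale` (default x100, matching values in
#' [0, 1] to B-factors in [0, 100]) and clipped to the field's printable
#' range [0, 999.99]. Optionally the occupancy field (columns 55-60) is
#' overwritten with the confidence rank of the residue (1 = most
#' confident). Residues present in the structure but absent from the
#' annotation table keep their original B-factors and are returned in the
#' `unmatched` attribute.
#'
#' @param pdb_in path to the input PDB file.
#' @param annotations tibble from [annotate_residues()] (needs `residue`
#'   and the column named by `value_col`).
#' @param pdb_out output path.
#' @param value_col annotation column written to the B-factor field.
#' @param scale linear scale factor applied before writing.
#' @param residue_offset added to annotation residue numbers to match
#'   structure numbering.
#' @param occupancy_confidence write confidence rank (in (0, 1]) into the
#'   occupancy field.
#' @return `pdb_out` invisibly, with attribute `unmatched` listing residue
#'   numbers present in the structure but not annotated.
#' @export
write_annotated_pdb <- function(pdb_in, annotations, pdb_out,
                                value_col = "value", scale = 100,
                                residue_offset = 0L,
                                occupancy_confidence = FALSE) {
  lines <- readLines(pdb_in)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  ann <- annotations
  ann$residue <- ann$residue + residue_offset
  vals <- setNames(ann[[value_col]], ann$residue)
  conf_rank <- NULL
  if (occupancy_confidence) {
    rk <- rank(ann$sigma2, ties.method = "min")
    conf_rank <- setNames(1 - (rk - 1) / nrow(ann), ann$residue)
  }
  unmatched <- integer(0)
  matched_any <- FALSE
  out <- lines
  for (k in which(is_atom)) {
    ln <- lines[k]
    if (nchar(ln) < 66) {
      abort(sprintf("malformed ATOM record at line %d: too short", k),
            class = "vsp_parse_error")
    }
    res_str <- substr(ln, 23, 26)
    res <- suppressWarnings(as.integer(trimws(res_str)))
    if (is.na(res)) {
      abort(sprintf("malformed ATOM record at line %d: bad residue number", k),
            class = "vsp_parse_error")
    }
    key <- as.character(res)
    if (!key %in% names(vals)) {
      unmatched <- c(unmatched, res)
      next
    }
    matched_any <- TRUE
    b <- min(max(vals[[key]] * scale, 0), 999.99)
    ln <- paste0(substr(ln, 1, 60), formatC(b, format = "f", digits = 2,
                                            width = 6),
                 substr(ln, 67, nchar(ln)))
    if (occupancy_confidence) {
      occ <- formatC(conf_rank[[key]], format = "f", digits = 2, width = 6)
      ln <- paste0(substr(ln, 1, 54), occ, substr(ln, 61, nchar(ln)))
    }
    out[k] <- ln
  }
  if (nrow(ann) && !matched_any && any(is_atom)) {
    abort("no structure residues matched the annotations; check residue_offset",
          class = "vsp_mapping_error")
  }
  unmatched <- sort(unique(unmatched))
  if (nrow(ann)) {
    hdr <- sprintf(
      "REMARK 999 B-FACTOR CARRIES %s SCALED BY %g (VSPROFILER)",
      toupper(value_col), scale)
    out <- c(hdr, out)
  }
  writeLines(out, pdb_out)
  invisible(structure(pdb_out, unmatched = unmatched))
}

#' Write a residue annotation table to TSV
#'
#' @param annotations tibble from [annotate_residues()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_residue_table <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}
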