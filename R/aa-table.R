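#' Amino-acid interaction-energy table
#'
#' Loads the packaged table of amino-acid / silicon nitride pore-wall
#' interaction energies (18 residues, all attractive), or a user table in
#' the same TSV layout (`code`, `minus_delta_e_ev`, `r_group_class`).  The
#' file stores the conventional positive magnitudes; on load they are
#' negated so that `delta_e` is the signed interaction energy in eV
#' (attraction negative), which is what the dwell-time exponent needs.
#'
#' @param path Optional path to a table TSV; default uses the packaged
#'   table.  A data frame with `code` and either `delta_e` (signed) or
#'   `minus_delta_e_ev` columns is also accepted.
#' @param substitutes Optional named character vector mapping absent residue
#'   codes to present ones (e.g. `c(MET = "CYS")`); the table has no entries
#'   for MET or ILE and lookups of unmapped absent codes are an error.
#' @return A tibble of class `aa_energy_table` with columns `code`,
#'   `delta_e` (eV, signed) and `r_group_class`.
#' @seealso [aa_energy()] for lookups, [fit_energy_table()] to build a table
#'   from scan files.
#' @export
#' @examples
#' tab <- aa_energy_table()
#' aa_energy(tab, c("CYS", "GLY"))
aa_energy_table <- function(path = NULL, substitutes = NULL) {
  if (is.data.frame(path)) {
    tab <- as_tibble(path)
  } else {
    file <- path %||% porepass_extdata("aa_interaction_energies.tsv")
    tab <- readr::read_tsv(file, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  }
  if (!"code" %in% names(tab)) {
    stop_porepass("energy table needs a `code` column.", "porepass_input_error")
  }
  if ("delta_e" %in% names(tab)) {
    delta <- as.numeric(tab$delta_e)
  } else if ("minus_delta_e_ev" %in% names(tab)) {
    delta <- -as.numeric(tab$minus_delta_e_ev)
  } else {
    stop_porepass("energy table needs `delta_e` or `minus_delta_e_ev`.",
                  "porepass_input_error")
  }
  out <- tibble(code = toupper(as.character(tab$code)),
                delta_e = delta,
                r_group_class = if ("r_group_class" %in% names(tab))
                  as.character(tab$r_group_class) else NA_character_)
  if (anyDuplicated(out$code)) {
    stop_porepass("duplicate residue codes in energy table.",
                  "porepass_input_error")
  }
  if (is.null(path) && any(out$delta_e >= 0)) {
    stop_porepass("packaged energy table must be all-attractive (delta_e < 0).",
                  "porepass_data_error")
  }
  if (!is.null(substitutes)) {
    if (is.null(names(substitutes)) || any(!nzchar(names(substitutes)))) {
      stop_porepass("`substitutes` must be a named character vector.",
                    "porepass_input_error")
    }
    for (miss in names(substitutes)) {
      src <- toupper(substitutes[[miss]])
      if (!src %in% out$code) {
        stop_porepass(sprintf("substitute source '%s' not in table.", src),
                      "porepass_lookup_error")
      }
      row <- out[out$code == src, ]
      row$code <- toupper(miss)
      out <- dplyr::bind_rows(out[out$code != toupper(miss), ], row)
    }
  }
  structure(out, class = c("aa_energy_table", class(out)))
}

#' Look up signed interaction energies by residue code
#'
#' @param table An [aa_energy_table()].
#' @param codes Character vector of 3-letter residue codes.
#' @return Numeric vector of signed interaction energies (eV).  Absent
#'   codes raise an error naming the residue — never a silent default.
#' @export
aa_energy <- function(table, codes) {
  codes <- toupper(codes)
  idx <- match(codes, table$code)
  if (anyNA(idx)) {
    missing <- unique(codes[is.na(idx)])
    stop_porepass(
      sprintf("no interaction energy for residue(s): %s. Supply a substitutes mapping to aa_energy_table().",
              paste(missing, collapse = ", ")),
      "porepass_lookup_error")
  }
  table$delta_e[idx]
}

#' Build an interaction-energy table from a set of energy curves
#'
#' Runs the full per-residue derivation — quadratic-spline equilibrium point
#' and Morse-fit asymptote — over a list of energy curves (or a directory of
#' scan TSVs) and assembles the resulting signed interaction energies into
#' an [aa_energy_table()].
#'
#' @param curves A list of [energy_curve()] objects, or a directory path
#'   containing `*.tsv` scan files readable by [read_energy_curve()].
#' @return An `aa_energy_table` tibble, plus a `details` attribute holding
#'   the per-curve [interaction_energy()] rows.
#' @export
fit_energy_table <- function(curves) {
  if (is.character(curves) && length(curves) == 1L && dir.exists(curves)) {
    files <- list.files(curves, pattern = "\\.tsv$", full.names = TRUE)
    if (!length(files)) {
      stop_porepass("no .tsv scan files found in directory.",
                    "porepass_input_error")
    }
    curves <- lapply(files, read_energy_curve)
  }
  details <- purrr::map_dfr(curves, interaction_energy)
  if (anyNA(details$residue_code)) {
    stop_porepass("every curve must carry a residue code.",
                  "porepass_input_error")
  }
  tab <- tibble(code = toupper(details$residue_code),
                delta_e = details$delta_e,
                r_group_class = NA_character_)
  out <- structure(tab, class = c("aa_energy_table", class(tab)))
  attr(out, "details") <- details
  out
}

#' Write an interaction-energy table as TSV
#'
#' Writes the on-disk layout (`code`, `minus_delta_e_ev`, `r_group_class`),
#' i.e. positive magnitudes, matching the packaged default.
#'
#' @param table An [aa_energy_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(table, path) {
  readr::write_tsv(
    tibble(code = table$code,
           minus_delta_e_ev = -table$delta_e,
           r_group_class = table$r_group_class),
    path)
  invisible(path)
}
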