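#' Construct an amino-acid pore-wall energy curve
#'
#' An energy curve is the total energy of one amino acid against the pore
#' wall, sampled over increasing separation distances.  It is the raw input
#' from which an interaction energy is derived: the equilibrium (minimum)
#' energy via quadratic-spline interpolation and the asymptotic energy via a
#' Morse-potential fit.
#'
#' @param data A data frame with numeric columns `separation` (Angstrom,
#'   strictly increasing) and `energy` (eV).  The columns
#'   `separation_angstrom` / `energy_ev` are accepted as synonyms.
#' @param residue_code Three-letter amino-acid code (e.g. `"ASN"`).
#' @param orientation_note Free-text note on how the residue faces the
#'   surface (e.g. `"R-group facing surface"`).
#'
#' @details Curves must have at least 6 points, strictly increasing
#'   separations, and at least one point beyond 10 Angstrom so that the
#'   asymptotic plateau is sampled.
#'
#' @return A tibble of class `energy_curve` with columns `separation` and
#'   `energy` and attributes `residue_code` and `orientation_note`.
#' @seealso [fit_morse()], [equilibrium_energy()], [interaction_energy()],
#'   [gen_energy_curve()]
#' @export
#' @examples
#' s <- c(seq(1.5, 4, by = 0.25), 6, 8, 12)
#' e <- 1.0 * (1 - exp(-1.2 * (s - 2.5)))^2 - 3.0
#' curve <- energy_curve(data.frame(separation = s, energy = e), "ALA")
#' interaction_energy(curve)
energy_curve <- function(data, residue_code = NA_character_,
                         orientation_note = NULL) {
  if (!is.data.frame(data)) {
    stop_porepass("`data` must be a data frame.", "porepass_input_error")
  }
  nm <- names(data)
  sep_col <- intersect(c("separation", "separation_angstrom"), nm)[1]
  en_col <- intersect(c("energy", "energy_ev"), nm)[1]
  if (is.na(sep_col) || is.na(en_col)) {
    stop_porepass(
      "`data` needs columns `separation` and `energy` (or `separation_angstrom` / `energy_ev`).",
      "porepass_input_error")
  }
  out <- tibble(separation = as.numeric(data[[sep_col]]),
                energy = as.numeric(data[[en_col]]))
  validate_energy_curve(out, residue_code)
  structure(out,
            class = c("energy_curve", class(out)),
            residue_code = as.character(residue_code),
            orientation_note = orientation_note)
}

validate_energy_curve <- function(points, residue_code = NA_character_) {
  who <- if (is.na(residue_code)) "energy curve" else
    sprintf("energy curve for %s", residue_code)
  if (nrow(points) < 6L) {
    stop_porepass(sprintf("%s has %d points; at least 6 are required.",
                          who, nrow(points)), "porepass_input_error")
  }
  if (anyNA(points$separation) || anyNA(points$energy) ||
      any(!is.finite(points$separation)) || any(!is.finite(points$energy))) {
    stop_porepass(sprintf("%s contains non-finite values.", who),
                  "porepass_input_error")
  }
  if (any(diff(points$separation) <= 0)) {
    stop_porepass(sprintf("separations in %s must be strictly increasing.", who),
                  "porepass_input_error")
  }
  if (max(points$separation) <= 10) {
    stop_porepass(
      sprintf("%s has no point beyond 10 Angstrom; the asymptotic region must be sampled.",
              who),
      "porepass_input_error")
  }
  invisible(points)
}

#' @export
print.energy_curve <- function(x, ...) {
  code <- attr(x, "residue_code")
  cat(sprintf("<energy_curve> %s: %d points, %.1f-%.1f Angstrom\n",
              ifelse(is.na(code), "(unnamed)", code), nrow(x),
              min(x$separation), max(x$separation)))
  NextMethod()
}

#' Read an energy curve from a TSV scan file
#'
#' Expects a header `separation_angstrom<TAB>energy_ev`.  The residue code is
#' taken from a `# residue: XYZ` comment line if present, otherwise from the
#' first three-letter amino-acid code found in the file name.
#'
#' @param path Path to the TSV file.
#' @return An [energy_curve()].
#' @export
read_energy_curve <- function(path) {
  header <- readLines(path, n = 20L)
  code <- NA_character_
  note <- NULL
  res_line <- grep("^#\\s*residue:", header, value = TRUE)
  if (length(res_line)) {
    code <- toupper(trimws(sub("^#\\s*residue:\\s*", "", res_line[1])))
  }
  note_line <- grep("^#\\s*orientation:", header, value = TRUE)
  if (length(note_line)) {
    note <- trimws(sub("^#\\s*orientation:\\s*", "", note_line[1]))
  }
  if (is.na(code)) {
    m <- regmatches(basename(path),
                    regexpr("[A-Za-z]{3}", basename(path)))
    if (length(m)) code <- toupper(m)
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  energy_curve(tab, residue_code = code, orientation_note = note)
}

#' @exportS3Method ggplot2::autoplot
autoplot.energy_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$separation, y = .data$energy)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "separation (Å)", y = "total energy (eV)",
      title = sprintf("Pore-wall energy scan%s",
                      ifelse(is.na(attr(object, "residue_code")), "",
                             paste0(": ", attr(object, "residue_code"))))
    )
  if (!is.null(fit)) {
    grid <- tibble(separation = seq(min(object$separation),
                                    max(object$separation), length.out = 300))
    grid$energy <- predict(fit, grid$separation)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}
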