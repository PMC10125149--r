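#' Dipole orientation track of the analyte
#'
#' Per-frame dipole vector of the protein, \eqn{\vec p = \sum_i q_i \vec
#' r_i} (e Angstrom), and a flag marking frames where the dipole is aligned
#' with the external field axis.  "Aligned" means the angle between dipole
#' and field axis is below the threshold; at the default 90 degrees this is
#' simply the sign of the dipole component along the field.
#'
#' @param atoms Data frame with columns `time` (ps), `charge` (e) and `x`,
#'   `y`, `z` (Angstrom), one row per protein atom per frame.
#' @param field_axis Unit-direction of the external field (default `+z`).
#' @param threshold_deg Alignment threshold angle in degrees (default 90).
#' @return A tibble of class `dipole_trace` with columns `time`, `px`,
#'   `py`, `pz` and logical `aligned`.
#' @export
dipole_trace <- function(atoms, field_axis = c(0, 0, 1), threshold_deg = 90) {
  if (!all(c("time", "charge", "x", "y", "z") %in% names(atoms))) {
    stop_porepass("`atoms` needs columns time, charge, x, y, z.",
                  "porepass_input_error")
  }
  axis <- field_axis / sqrt(sum(field_axis^2))
  out <- dplyr::summarise(
    dplyr::group_by(as_tibble(atoms), .data$time),
    px = sum(.data$charge * .data$x),
    py = sum(.data$charge * .data$y),
    pz = sum(.data$charge * .data$z), .groups = "drop")
  out <- dplyr::arrange(out, .data$time)
  dot <- out$px * axis[1] + out$py * axis[2] + out$pz * axis[3]
  norm <- sqrt(out$px^2 + out$py^2 + out$pz^2)
  cosang <- ifelse(norm > 0, dot / norm, 0)
  out$aligned <- cosang > cos(threshold_deg * pi / 180)
  structure(out, class = c("dipole_trace", class(out)),
            field_axis = axis, threshold_deg = threshold_deg)
}

#' Current histograms conditioned on dipole alignment
#'
#' Splits a current trace into frames where the analyte's dipole was
#' aligned with the field axis and frames where it was not, and histograms
#' the two subsets with a shared binning so their shapes are directly
#' comparable.
#'
#' @param trace A `current_trace`.
#' @param dipole A [dipole_trace()] covering every trace frame time.
#' @param bins Shared bin count or break vector (see
#'   [current_histogram()]).
#' @return A tibble with columns `alignment` (`"aligned"` /
#'   `"anti_aligned"`), `bin_left`, `bin_right`, `mid`, `count`.  An
#'   all-aligned trace yields all-zero counts on the anti-aligned side.
#' @export
dipole_conditioned_histograms <- function(trace, dipole, bins = 60) {
  if (!inherits(trace, "current_trace")) {
    stop_porepass("`trace` must be a current_trace.", "porepass_input_error")
  }
  idx <- match(trace$time, dipole$time)
  if (anyNA(idx)) {
    stop_porepass("dipole trace does not cover every current frame time.",
                  "porepass_input_error")
  }
  flag <- dipole$aligned[idx]
  rng <- range(trace$current)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- if (length(bins) > 1L) sort(as.numeric(bins)) else
    seq(rng[1], rng[2], length.out = as.integer(bins) + 1L)
  one <- function(values, label) {
    counts <- if (length(values)) {
      tabulate(findInterval(values, breaks, rightmost.closed = TRUE,
                            all.inside = TRUE),
               nbins = length(breaks) - 1L)
    } else rep(0L, length(breaks) - 1L)
    tibble(alignment = label, bin_left = breaks[-length(breaks)],
           bin_right = breaks[-1],
           mid = (breaks[-length(breaks)] + breaks[-1]) / 2, count = counts)
  }
  dplyr::bind_rows(one(trace$current[flag], "aligned"),
                   one(trace$current[!flag], "anti_aligned"))
}
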