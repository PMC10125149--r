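#' Construct an ion trajectory
#'
#' Long-format per-frame ion records used by the occupied-pore current
#' analysis: one row per ion per frame.  Frames must be uniformly spaced in
#' time and charges must be +1 or -1 e (monovalent electrolyte).
#'
#' @param data Data frame with columns `time` (ps), `ion` (id), `charge`
#'   (e), `x`, `y`, `z` (Angstrom).  `time_ps` / `ion_id` are accepted as
#'   synonyms.
#' @param lz Pore-region length along z in Angstrom (default 36).
#' @param center_z Membrane center along z (default 0).
#' @param box_z Optional periodic box height along z; when supplied,
#'   frame-to-frame displacements are minimum-image corrected so wrapped
#'   coordinates yield physical displacements.
#' @return A tibble of class `ion_trajectory` with attributes `lz`,
#'   `center_z`, `box_z` and `delta_t` (ps).
#' @seealso [instantaneous_current()], [gen_ion_trajectory()]
#' @export
ion_trajectory <- function(data, lz = 36, center_z = 0, box_z = NULL) {
  if (!is.data.frame(data)) {
    stop_porepass("`data` must be a data frame.", "porepass_input_error")
  }
  nm <- names(data)
  pick <- function(...) intersect(c(...), nm)[1]
  cols <- c(time = pick("time", "time_ps"), ion = pick("ion", "ion_id"),
            charge = pick("charge"), x = pick("x"), y = pick("y"),
            z = pick("z"))
  if (anyNA(cols)) {
    stop_porepass("trajectory needs columns time, ion, charge, x, y, z.",
                  "porepass_input_error")
  }
  out <- tibble(time = as.numeric(data[[cols["time"]]]),
                ion = data[[cols["ion"]]],
                charge = as.numeric(data[[cols["charge"]]]),
                x = as.numeric(data[[cols["x"]]]),
                y = as.numeric(data[[cols["y"]]]),
                z = as.numeric(data[[cols["z"]]]))
  if (!all(out$charge %in% c(-1, 1))) {
    stop_porepass("ion charges must be +1 or -1 e.", "porepass_input_error")
  }
  times <- sort(unique(out$time))
  if (length(times) < 2L) {
    stop_porepass("trajectory needs at least 2 frames.", "porepass_input_error")
  }
  dts <- diff(times)
  if (max(dts) - min(dts) > 1e-6 * mean(dts)) {
    stop_porepass("frame times must be uniformly spaced.",
                  "porepass_input_error")
  }
  check_number(lz, "lz", positive = TRUE)
  structure(out, class = c("ion_trajectory", class(out)),
            lz = lz, center_z = center_z, box_z = box_z,
            delta_t = mean(dts))
}

#' Read an ion trajectory from column text
#'
#' Whitespace-separated columns `time_ps ion_id charge x y z`, one row per
#' ion per frame; `#` comments allowed.
#'
#' @param path File path.
#' @inheritParams ion_trajectory
#' @return An [ion_trajectory()].
#' @export
read_ion_trajectory <- function(path, lz = 36, center_z = 0, box_z = NULL) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  ion_trajectory(tab, lz = lz, center_z = center_z, box_z = box_z)
}

#' Write an ion trajectory as column text
#'
#' @param traj An [ion_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ion_trajectory <- function(traj, path) {
  df <- data.frame(time_ps = traj$time, ion_id = traj$ion,
                   charge = traj$charge, x = traj$x, y = traj$y, z = traj$z)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

in_slab <- function(z, lz, center_z) abs(z - center_z) < lz / 2

#' Instantaneous occupied-pore ionic current from ion displacements
#'
#' For each pair of consecutive frames the current is the charge-weighted
#' sum of z-displacements of the ions inside the pore slab,
#' \deqn{I(t) = \frac{1}{\delta t\, l_z} \sum_i q_i \,[z_i(t+\delta t) - z_i(t)],}
#' with slab membership \eqn{|z - z_c| < l_z/2} judged at the earlier
#' frame.  Currents are returned in nA (1 e/ps = 160.2177 nA).  Ions
#' present at `t` but absent at `t + delta_t` are skipped and counted in a
#' single warning.  When the trajectory carries a periodic `box_z`,
#' displacements are minimum-image corrected.
#'
#' @param traj An [ion_trajectory()].
#' @return A tibble of class `current_trace` with columns `time` (ps, frame
#'   start) and `current` (nA); one row per frame pair.  Attributes:
#'   `delta_t` (ps) and `filter_applied` (`NULL` until [lowpass()] is
#'   used).
#' @export
instantaneous_current <- function(traj) {
  if (!inherits(traj, "ion_trajectory")) {
    stop_porepass("`traj` must be an ion_trajectory.", "porepass_input_error")
  }
  lz <- attr(traj, "lz"); cz <- attr(traj, "center_z")
  bz <- attr(traj, "box_z"); dt <- attr(traj, "delta_t")
  times <- sort(unique(traj$time))

  df <- dplyr::arrange(as_tibble(traj), .data$ion, .data$time)
  df <- dplyr::mutate(dplyr::group_by(df, .data$ion),
                      z_next = dplyr::lead(.data$z),
                      t_next = dplyr::lead(.data$time))
  df <- dplyr::ungroup(df)
  df <- df[df$time < times[length(times)], , drop = FALSE]

  consecutive <- !is.na(df$t_next) & abs(df$t_next - df$time - dt) < 1e-6 * dt
  n_skip <- sum(!consecutive)
  if (n_skip > 0L) {
    rlang::warn(sprintf(
      "%d ion-frame record(s) had no matching ion in the following frame; skipped",
      n_skip), class = "porepass_missing_ion_warning")
  }
  df <- df[consecutive & in_slab(df$z, lz, cz), , drop = FALSE]
  dz <- df$z_next - df$z
  if (!is.null(bz)) dz <- dz - bz * round(dz / bz)

  frame <- findInterval(df$time, times)
  contrib <- df$charge * dz / (lz * dt)   # e/ps
  current <- numeric(length(times) - 1L)
  if (nrow(df)) {
    agg <- tapply(contrib, factor(frame, levels = seq_len(length(times) - 1L)),
                  sum, default = 0)
    current <- as.numeric(agg)
  }
  new_current_trace(tibble(time = times[-length(times)],
                           current = current * E_PER_PS_TO_NA),
                    delta_t = dt)
}

new_current_trace <- function(df, delta_t, filter_applied = NULL) {
  structure(df, class = unique(c("current_trace", class(df))),
            delta_t = delta_t, filter_applied = filter_applied)
}

#' Construct a current trace directly
#'
#' @param time Frame times in ps (uniform spacing).
#' @param current Currents in nA.
#' @return A `current_trace` tibble.
#' @export
current_trace <- function(time, current) {
  if (length(time) != length(current) || length(time) < 2L) {
    stop_porepass("`time` and `current` must be equal length >= 2.",
                  "porepass_input_error")
  }
  dts <- diff(time)
  if (max(dts) - min(dts) > 1e-6 * mean(dts)) {
    stop_porepass("trace times must be uniformly spaced.",
                  "porepass_input_error")
  }
  new_current_trace(tibble(time = as.numeric(time),
                           current = as.numeric(current)),
                    delta_t = mean(dts))
}

#' @export
print.current_trace <- function(x, ...) {
  f <- attr(x, "filter_applied")
  cat(sprintf("<current_trace> %d frames, dt = %g ps%s\n", nrow(x),
              attr(x, "delta_t"),
              if (is.null(f)) "" else
                sprintf(", low-passed at %g GHz (order %d %s)",
                        f$cutoff_ghz, f$order, f$kind)))
  NextMethod()
}

#' Per-frame count of ions inside the pore region
#'
#' Counts ions whose z lies strictly inside the slab
#' `|z - center_z| < lz / 2`; an ion exactly on the slab face is not
#' counted.
#'
#' @param traj An [ion_trajectory()].
#' @return A tibble with columns `time` and `count`.
#' @export
count_pore_ions <- function(traj) {
  if (!inherits(traj, "ion_trajectory")) {
    stop_porepass("`traj` must be an ion_trajectory.", "porepass_input_error")
  }
  lz <- attr(traj, "lz"); cz <- attr(traj, "center_z")
  df <- as_tibble(traj)
  df$inside <- in_slab(df$z, lz, cz)
  out <- dplyr::summarise(dplyr::group_by(df, .data$time),
                          count = sum(.data$inside), .groups = "drop")
  dplyr::arrange(out, .data$time)
}

#' Histogram of a current trace
#'
#' @param trace A `current_trace` (or numeric vector).
#' @param bins Number of equal-width bins (default 60), or a numeric vector
#'   of break points.
#' @param exclude Optional list of `c(t_start, t_end)` time windows (ps)
#'   whose frames are excluded before binning — e.g. windows where the
#'   analyte left the pore or unfolded.
#' @return A tibble of class `current_histogram` with columns `bin_left`,
#'   `bin_right`, `mid` and `count`.
#' @export
current_histogram <- function(trace, bins = 60, exclude = NULL) {
  if (inherits(trace, "current_trace")) {
    values <- trace$current
    times <- trace$time
  } else {
    values <- as.numeric(trace)
    times <- seq_along(values)
  }
  if (!length(values)) {
    stop_porepass("empty trace.", "porepass_input_error")
  }
  if (!is.null(exclude)) {
    if (is.numeric(exclude)) exclude <- list(exclude)
    keep <- rep(TRUE, length(values))
    for (w in exclude) {
      keep <- keep & !(times >= w[1] & times <= w[2])
    }
    values <- values[keep]
    if (!length(values)) {
      stop_porepass("all frames excluded by the time-window mask.",
                    "porepass_input_error")
    }
  }
  breaks <- if (length(bins) > 1L) sort(as.numeric(bins)) else {
    rng <- range(values)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    seq(rng[1], rng[2], length.out = as.integer(bins) + 1L)
  }
  nb <- length(breaks) - 1L
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- tibble(bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
                mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                count = tabulate(idx, nbins = nb))
  structure(out, class = c("current_histogram", class(out)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.current_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$current)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ps)", y = "current (nA)",
                  title = "Occupied-pore ionic current")
}

#' @exportS3Method ggplot2::autoplot
autoplot.current_histogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_left[1:2]) %||% 1,
                      fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "current (nA)", y = "count",
                  title = "Current histogram")
}

#' Center-of-mass z track of the analyte
#'
#' Mass-weighted mean z per frame of a per-frame atom table; optionally
#' smoothed with the standard 1 GHz low-pass.
#'
#' @param atoms Data frame with columns `time` (ps), `z` (Angstrom) and
#'   `mass` (any consistent unit), one row per atom per frame.
#' @param cutoff_ghz Optional low-pass cutoff in GHz applied to the track.
#' @return A tibble with columns `time` and `z_com`.
#' @export
com_track <- function(atoms, cutoff_ghz = NULL) {
  if (!all(c("time", "z", "mass") %in% names(atoms))) {
    stop_porepass("`atoms` needs columns time, z, mass.",
                  "porepass_input_error")
  }
  if (any(tapply(atoms$mass, atoms$time, sum) <= 0)) {
    stop_porepass("total mass must be positive in every frame.",
                  "porepass_input_error")
  }
  out <- dplyr::summarise(
    dplyr::group_by(as_tibble(atoms), .data$time),
    z_com = sum(.data$z * .data$mass) / sum(.data$mass), .groups = "drop")
  out <- dplyr::arrange(out, .data$time)
  if (!is.null(cutoff_ghz)) {
    dt <- mean(diff(out$time))
    out$z_com <- lowpass(out$z_com, filter_spec(cutoff_ghz), delta_t = dt)
  }
  out
}
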