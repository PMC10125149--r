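#' Equilibrium point of an energy curve by quadratic-spline interpolation
#'
#' Interpolates the sampled scan with a C1 piecewise-quadratic spline and
#' returns the interpolated minimum (vertex).  If the best spline vertex
#' evaluates above the lowest sampled energy, or the sampled minimum sits at
#' the boundary of the scan so no interior vertex brackets it, the lowest
#' computed value is returned instead and `method` is `"lowest_point"` (with
#' a warning in the boundary case) — the rule used for curves whose sampled
#' well is sharper than the interpolant.
#'
#' @inheritParams fit_morse
#' @return A one-row tibble with columns `s_eq` (Angstrom), `e_eq` (eV) and
#'   `method` (`"spline"` or `"lowest_point"`).
#' @seealso [interaction_energy()]
#' @export
equilibrium_energy <- function(curve) {
  pts <- curve_points(curve)
  if (nrow(pts) < 3L) {
    stop_porepass("equilibrium point needs at least 3 points.",
                  "porepass_input_error")
  }
  s <- pts$separation
  e <- pts$energy
  i_min <- which.min(e)
  lowest <- tibble(s_eq = s[i_min], e_eq = e[i_min], method = "lowest_point")

  if (i_min == 1L || i_min == length(e)) {
    rlang::warn(paste0(
      "sampled minimum lies at the scan boundary; ",
      "falling back to the lowest computed value"),
      class = "porepass_boundary_warning")
    return(lowest)
  }

  spl <- quad_spline_coefs(s, e)
  vertices <- spline_vertices(spl)
  if (nrow(vertices) == 0L || min(vertices$energy) > e[i_min]) {
    return(lowest)
  }
  j <- which.min(vertices$energy)
  tibble(s_eq = vertices$s[j], e_eq = vertices$energy[j], method = "spline")
}

# Piecewise-quadratic interpolant through (s_i, e_i):
#   q_i(x) = e_i + d_i (x - s_i) + c_i (x - s_i)^2 on [s_i, s_{i+1}].
# The knot slope d_i is the derivative at s_i of the Lagrange parabola
# through the three points centred on i (one-sided at the first knot), and
# c_i then pins q_i(s_{i+1}) = e_{i+1}.  Local slopes keep the interpolant
# stable (the chained C1 recurrence d_{i+1} = 2*slope - d_i oscillates and
# inflates the vertex error) and a globally quadratic curve is reproduced
# exactly.
quad_spline_coefs <- function(s, e) {
  n <- length(s)
  h <- diff(s)
  # derivative at s[i] of the parabola through points (j1, j2, j3)
  parab_slope <- function(i, j1, j2, j3) {
    a <- s[j1]; b <- s[j2]; cc <- s[j3]; x <- s[i]
    e[j1] * (2 * x - b - cc) / ((a - b) * (a - cc)) +
      e[j2] * (2 * x - a - cc) / ((b - a) * (b - cc)) +
      e[j3] * (2 * x - a - b) / ((cc - a) * (cc - b))
  }
  d <- numeric(n - 1L)
  d[1] <- parab_slope(1L, 1L, 2L, 3L)
  for (i in seq_len(n - 2L)[-1L]) {
    d[i] <- parab_slope(i, i - 1L, i, i + 1L)
  }
  if (n >= 3L) d[n - 1L] <- parab_slope(n - 1L, n - 2L, n - 1L, n)
  cc <- ((e[-1L] - e[-n]) / h - d) / h
  list(s = s, e = e, d = d, c = cc, h = h)
}

# Interior vertices (local minima candidates) of each convex piece.
spline_vertices <- function(spl) {
  keep_s <- numeric(0)
  keep_e <- numeric(0)
  for (i in seq_along(spl$h)) {
    ci <- spl$c[i]
    if (!is.finite(ci) || ci <= 0) next
    x <- -spl$d[i] / (2 * ci)          # offset from s_i
    if (x < 0 || x > spl$h[i]) next
    keep_s <- c(keep_s, spl$s[i] + x)
    keep_e <- c(keep_e, spl$e[i] + spl$d[i] * x + ci * x^2)
  }
  tibble(s = keep_s, energy = keep_e)
}

# Evaluate the spline at arbitrary separations (used by the dense-grid
# oracle in the tests).
eval_quad_spline <- function(curve, at) {
  pts <- curve_points(curve)
  spl <- quad_spline_coefs(pts$separation, pts$energy)
  idx <- findInterval(at, spl$s, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(spl$h))
  x <- at - spl$s[idx]
  spl$e[idx] + spl$d[idx] * x + spl$c[idx] * x^2
}

#' Interaction energy of one amino acid with the pore wall
#'
#' The interaction energy is the equilibrium energy minus the asymptotic
#' (large-separation) energy, \eqn{\Delta E = E_{eq} - E_{asymp}}: negative
#' for attraction.  The equilibrium point comes from [equilibrium_energy()]
#' and the asymptote from the Morse fit of [fit_morse()], so an arbitrary
#' additive offset on the scan energies cancels out.
#'
#' @inheritParams fit_morse
#' @return A one-row tibble with columns `residue_code`, `delta_e` (eV,
#'   signed), `s_eq`, `e_eq`, `e_asymp`, `method` and `rmse` (Morse fit rmse,
#'   eV).  A warning is raised for repulsive (positive) results, which the
#'   packaged energy table never contains.
#' @export
#' @examples
#' curve <- gen_energy_curve(D = 1, a = 1.2, s0 = 2.5, C = -3)
#' interaction_energy(curve)$delta_e  # -1 eV: well depth of the Morse truth
interaction_energy <- function(curve, restarts = 10L) {
  fit <- fit_morse(curve, restarts = restarts)
  eq <- equilibrium_energy(curve)
  delta_e <- eq$e_eq - fit$asymptote
  if (delta_e > 0) {
    rlang::warn(sprintf(
      "repulsive interaction energy (+%.4f eV); pore-wall scans are expected to be attractive",
      delta_e), class = "porepass_repulsive_warning")
  }
  tibble(residue_code = attr(curve, "residue_code") %||% NA_character_,
         delta_e = delta_e,
         s_eq = eq$s_eq, e_eq = eq$e_eq, e_asymp = fit$asymptote,
         method = eq$method, rmse = fit$rmse)
}
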