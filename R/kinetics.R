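#' Configuration for the dwell-time kinetics model
#'
#' The dwell time is modelled as a Boltzmann transition between the
#' pore-wall-bound state and the far-away state,
#' \eqn{\tau = \tau_0 e^{-\beta \Delta E_{protein}}}.  The prefactor
#' \eqn{\tau_0} is the noninteracting transit time obtained by integrating
#' the analyte's equation of motion under a uniform electrostatic force and
#' a linear drag force inside the pore.
#'
#' @param bias_voltage Applied bias in volts (> 0; default 1).
#' @param beta_inv Optional characteristic transition energy in eV; when
#'   `NULL` it is derived as `|net charge| * bias_voltage` by
#'   [beta_inverse()].
#' @param membrane_thickness Membrane thickness in Angstrom (default 38).
#' @param traversal_length Distance integrated for the transit, Angstrom;
#'   defaults to the membrane thickness.
#' @param terminal_velocity Steady drift speed in m/s used to calibrate the
#'   drag coefficient as `|q| E / v`; default 0.1 m/s (the observed
#'   center-of-mass speed scale).  Mutually exclusive with
#'   `drag_coefficient`.
#' @param drag_coefficient Drag coefficient in kg/s (>= 0); mutually
#'   exclusive with `terminal_velocity`.  Zero gives the ballistic limit.
#' @param initial_velocity Entry velocity in m/s (default 0).
#' @return A list of class `kinetics_config`.
#' @export
kinetics_config <- function(bias_voltage = 1.0, beta_inv = NULL,
                            membrane_thickness = 38,
                            traversal_length = NULL,
                            terminal_velocity = NULL,
                            drag_coefficient = NULL,
                            initial_velocity = 0) {
  check_number(bias_voltage, "bias_voltage", positive = TRUE)
  check_number(membrane_thickness, "membrane_thickness", positive = TRUE)
  traversal_length <- traversal_length %||% membrane_thickness
  check_number(traversal_length, "traversal_length", positive = TRUE)
  if (!is.null(terminal_velocity) && !is.null(drag_coefficient)) {
    stop_porepass(
      "supply exactly one of `terminal_velocity` or `drag_coefficient`.",
      "porepass_input_error")
  }
  if (is.null(terminal_velocity) && is.null(drag_coefficient)) {
    terminal_velocity <- 0.1
  }
  if (!is.null(terminal_velocity)) {
    check_number(terminal_velocity, "terminal_velocity", positive = TRUE)
  }
  if (!is.null(drag_coefficient)) {
    check_number(drag_coefficient, "drag_coefficient")
    if (drag_coefficient < 0) {
      stop_porepass("`drag_coefficient` must be >= 0.", "porepass_input_error")
    }
  }
  if (!is.null(beta_inv)) check_number(beta_inv, "beta_inv", positive = TRUE)
  check_number(initial_velocity, "initial_velocity")
  structure(list(bias_voltage = bias_voltage, beta_inv = beta_inv,
                 membrane_thickness = membrane_thickness,
                 traversal_length = traversal_length,
                 terminal_velocity = terminal_velocity,
                 drag_coefficient = drag_coefficient,
                 initial_velocity = initial_velocity),
            class = "kinetics_config")
}

#' Characteristic transition energy from net charge and bias
#'
#' The energy scale of the pore-escape transition for a charged analyte is
#' the electrostatic work available over the membrane:
#' \eqn{\beta^{-1} = |q| \cdot V} in eV (a +1e analyte at 1 V gives 1 eV; a
#' -2e analyte gives 2 eV).  For an uncharged analyte the electrophoretic
#' picture breaks down and `beta_inv` must be supplied explicitly.
#'
#' @param net_charge Net charge in units of e (non-zero integer).
#' @param bias_voltage Bias in volts.
#' @return The characteristic energy in eV.
#' @export
beta_inverse <- function(net_charge, bias_voltage) {
  check_number(net_charge, "net_charge")
  check_number(bias_voltage, "bias_voltage", positive = TRUE)
  if (net_charge == 0) {
    stop_porepass(paste0(
      "net charge is zero: the electrophoretic energy scale is undefined; ",
      "supply `beta_inv` explicitly in kinetics_config()."),
      "porepass_input_error")
  }
  abs(net_charge) * bias_voltage
}

#' Noninteracting transit time through the pore
#'
#' Integrates \eqn{m \dot v = q E - \gamma v} with a uniform field
#' \eqn{E = V / h} inside the membrane and returns the first time the
#' analyte has covered the traversal length.  The drag coefficient is
#' either supplied or calibrated as \eqn{\gamma = |q| E / v_\infty} from
#' the configured terminal speed.  The numerical trajectory (stiff ODE with
#' root detection) is cross-validated against the closed-form solution
#' \eqn{x(t) = v_\infty t - (v_\infty - v_0)(m/\gamma)(1 - e^{-\gamma t/m})};
#' the two agree to better than 1e-8 relative or a warning is raised.
#' Bias polarity is assumed to be set so the analyte is driven through the
#' pore; a zero net charge has no electrophoretic drive and errors.
#'
#' @param protein A [pore_protein()] supplying net charge and mass.
#' @param cfg A [kinetics_config()].
#' @return Transit time \eqn{\tau_0} in seconds, with attribute
#'   `closed_form` holding the analytic value.
#' @export
solve_tau0 <- function(protein, cfg = kinetics_config()) {
  if (!inherits(cfg, "kinetics_config")) {
    stop_porepass("`cfg` must be a kinetics_config.", "porepass_input_error")
  }
  q_e <- attr(protein, "net_charge")
  if (is.null(q_e)) {
    stop_porepass("`protein` must be a pore_protein.", "porepass_input_error")
  }
  if (q_e == 0) {
    stop_porepass("zero net charge: no electrophoretic drive through the pore.",
                  "porepass_no_crossing_error")
  }
  m <- attr(protein, "mass_kda") * KDA_TO_KG
  E_field <- cfg$bias_voltage / (cfg$membrane_thickness * ANGSTROM_TO_M)
  force <- abs(q_e) * ELEMENTARY_CHARGE_C * E_field
  if (force <= 0) {
    stop_porepass("non-positive drive along the traversal axis.",
                  "porepass_no_crossing_error")
  }
  gamma <- cfg$drag_coefficient %||% (force / cfg$terminal_velocity)
  L <- cfg$traversal_length * ANGSTROM_TO_M
  v0 <- cfg$initial_velocity

  tau_cf <- tau0_closed_form(m, force, gamma, L, v0)
  tau_num <- tau0_numeric(m, force, gamma, L, v0, tau_cf)
  rel <- abs(tau_num - tau_cf) / tau_cf
  if (rel > 1e-6) {
    rlang::warn(sprintf(
      "numeric and closed-form transit times disagree (rel. %.2e)", rel))
  }
  structure(tau_num, closed_form = tau_cf)
}

# First-passage time of x(t) = vinf t - (vinf - v0)(m/gamma)(1 - exp(-gamma t/m))
# at x = L; limits: gamma -> 0 ballistic, m -> 0 overdamped.
tau0_closed_form <- function(m, force, gamma, L, v0) {
  if (gamma == 0) {
    # constant acceleration: L = v0 t + (F/2m) t^2
    a <- force / m
    return((-v0 + sqrt(v0^2 + 2 * a * L)) / a)
  }
  vinf <- force / gamma
  tau_relax <- m / gamma
  if (tau_relax == 0 || tau_relax < 1e-12 * (L / vinf) * 1e-6) {
    # fully overdamped
    if (v0 == vinf) return(L / vinf)
  }
  xfun <- function(t) {
    vinf * t - (vinf - v0) * tau_relax * (1 - exp(-t / tau_relax)) - L
  }
  upper <- (L + max(vinf - v0, 0) * tau_relax) / vinf * 1.01 + tau_relax
  stats::uniroot(xfun, c(0, upper), tol = 1e-16 * upper,
                 extendInt = "upX")$root
}

# Stiff numeric integration on nondimensional variables u = x/L, w = v/vref,
# T = t/tau_cf, with root detection at u = 1.
tau0_numeric <- function(m, force, gamma, L, v0, tau_cf) {
  vref <- if (gamma > 0) force / gamma else force / m * tau_cf
  deriv <- function(t, y, parms) {
    v <- y[2] * vref
    a <- (force - gamma * v) / m
    list(c(y[2] * vref * tau_cf / L, a * tau_cf / vref))
  }
  root <- function(t, y, parms) y[1] - 1
  sol <- deSolve::lsodar(
    y = c(u = 0, w = v0 / vref), times = c(0, 4), func = deriv,
    rootfunc = root, rtol = 1e-12, atol = 1e-12, maxsteps = 1e6)
  t_root <- attr(sol, "troot")
  if (is.null(t_root) || !length(t_root)) {
    stop_porepass("trajectory never covered the traversal length.",
                  "porepass_no_crossing_error")
  }
  t_root[1] * tau_cf
}

#' Dwell-time estimate from an interaction-energy distribution
#'
#' Evaluates \eqn{\tau = \tau_0 e^{-\beta \Delta E}} at the distribution's
#' mean (central estimate) and at mean +/- one standard deviation (the
#' reported range, ordered so `tau_low <= tau_high`).  Attractive energies
#' (negative \eqn{\Delta E}) lengthen the dwell, repulsive ones shorten it,
#' and \eqn{\Delta E = 0} returns \eqn{\tau_0} exactly.  Exponents beyond
#' 700 in magnitude overflow to `Inf` and are flagged.
#'
#' @param dist An [sample_energy_distribution()] result (or any object with
#'   `mean` and `std` in eV).
#' @param protein A [pore_protein()].
#' @param cfg A [kinetics_config()].
#' @return An object of class `dwell_estimate` with `tau0`, `tau_mean`,
#'   `tau_low`, `tau_high` (seconds), `beta_inv_used` (eV) and an
#'   `overflow` flag.  Supports [tidy()] and [glance()].
#' @export
dwell_time <- function(dist, protein, cfg = kinetics_config()) {
  beta_inv <- cfg$beta_inv %||%
    beta_inverse(attr(protein, "net_charge"), cfg$bias_voltage)
  tau0 <- as.numeric(solve_tau0(protein, cfg))
  de <- c(mean = dist$mean, low = dist$mean + dist$std,
          high = dist$mean - dist$std)
  expo <- -de / beta_inv
  overflow <- any(abs(expo) > 700)
  tau <- ifelse(expo > 700, Inf, tau0 * exp(expo))
  structure(
    list(tau0 = tau0, tau_mean = unname(tau["mean"]),
         tau_low = unname(min(tau["low"], tau["high"])),
         tau_high = unname(max(tau["low"], tau["high"])),
         beta_inv_used = beta_inv,
         delta_e_mean = dist$mean, delta_e_std = dist$std,
         overflow = overflow,
         protein = attr(protein, "name")),
    class = "dwell_estimate")
}

#' @export
print.dwell_estimate <- function(x, ...) {
  cat(sprintf(
    "<dwell_estimate> %s: tau0 = %.3e s, tau = %.3e s [%.3e, %.3e]\n",
    x$protein %||% "protein", x$tau0, x$tau_mean, x$tau_low, x$tau_high))
  cat(sprintf("  beta^-1 = %.3f eV, dE = %.4f +/- %.4f eV%s\n",
              x$beta_inv_used, x$delta_e_mean, x$delta_e_std,
              if (x$overflow) " [overflow]" else ""))
  invisible(x)
}

#' @rdname dwell_time
#' @param x A `dwell_estimate`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dwell_estimate <- function(x, ...) {
  tibble(term = c("tau0", "tau_mean", "tau_low", "tau_high", "beta_inv"),
         estimate = c(x$tau0, x$tau_mean, x$tau_low, x$tau_high,
                      x$beta_inv_used),
         unit = c("s", "s", "s", "s", "eV"))
}

#' @rdname dwell_time
#' @exportS3Method generics::glance
glance.dwell_estimate <- function(x, ...) {
  tibble(protein = x$protein %||% NA_character_, tau0 = x$tau0,
         tau_mean = x$tau_mean, tau_low = x$tau_low, tau_high = x$tau_high,
         beta_inv = x$beta_inv_used, overflow = x$overflow)
}

#' Compare two dwell-time estimates
#'
#' Signed order-of-magnitude separation of the central dwell times and a
#' separability verdict: the two analytes are called separable when their
#' closed `[tau_low, tau_high]` ranges are disjoint (ranges touching at one
#' endpoint are not separable).
#'
#' @param a,b [dwell_time()] estimates.
#' @return A one-row tibble with `log10_ratio` (`log10(tau_a / tau_b)`) and
#'   logical `separable`.
#' @export
compare_dwell <- function(a, b) {
  if (!all(is.finite(c(a$tau_mean, b$tau_mean)))) {
    stop_porepass("both estimates must be finite to compare.",
                  "porepass_input_error")
  }
  tibble(log10_ratio = log10(a$tau_mean / b$tau_mean),
         separable = a$tau_high < b$tau_low || b$tau_high < a$tau_low)
}
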