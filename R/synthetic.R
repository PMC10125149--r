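# Synthetic fixture generators: every input the pipeline needs without
# running molecular dynamics or electronic-structure calculations.  Each
# generator is seeded and records its ground truth in a `truth` attribute so
# downstream tests never re-derive it by hand.

#' Generate a Morse-shaped energy scan
#'
#' Samples \eqn{V(s) = C + D (1 - e^{-a(s - s_0)})^2} on a scan grid that
#' mimics a real separation scan: fine steps (0.1 Angstrom) around the
#' well, coarser steps (0.2 Angstrom) beyond it and 1 Angstrom steps in the
#' far field out to 15 Angstrom.  Optional Gaussian noise emulates
#' convergence scatter in the computed total energies.
#'
#' @param D Well depth, eV (> 0 for an attractive curve).
#' @param a Inverse width, 1/Angstrom.
#' @param s0 Equilibrium separation, Angstrom.
#' @param C Energy offset, eV (the asymptote is `C + D`).
#' @param noise_sd Gaussian noise standard deviation, eV (default 0).
#' @param grid Optional separation grid; must cover `s0` and reach beyond
#'   10 Angstrom.
#' @param seed RNG seed (mandatory; only consumed when `noise_sd > 0`).
#' @param residue_code Optional 3-letter code attached to the curve.
#' @return An [energy_curve()] whose `truth` attribute records the
#'   generating parameters, including `delta_e_true = -D`.
#' @export
gen_energy_curve <- function(D = 1.0, a = 1.2, s0 = 2.5, C = -3.0,
                             noise_sd = 0, grid = NULL, seed = 1L,
                             residue_code = NA_character_) {
  check_number(D, "D", positive = TRUE)
  check_number(a, "a", positive = TRUE)
  check_number(seed, "seed")
  if (is.null(grid)) {
    grid <- c(seq(s0 - 0.8, s0 + 2, by = 0.1),
              seq(s0 + 2.2, s0 + 6, by = 0.2),
              seq(ceiling(s0 + 7), 15, by = 1.0))
    grid <- sort(unique(round(grid, 6)))
  }
  if (min(grid) > s0 || max(grid) <= 10) {
    stop_porepass("grid must cover the well (s0) and reach beyond 10 Angstrom.",
                  "porepass_input_error")
  }
  energy <- C + D * (1 - exp(-a * (grid - s0)))^2
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    energy <- energy + rnorm(length(grid), sd = noise_sd)
  }
  out <- energy_curve(tibble(separation = grid, energy = energy),
                      residue_code = residue_code)
  attr(out, "truth") <- list(D = D, a = a, s0 = s0, C = C,
                             asymptote = C + D, delta_e_true = -D,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a toy protein model
#'
#' Deterministic line or ring geometries (analytically known neighbor
#' structure) or a seeded Gaussian cloud, with user-supplied residue codes
#' and RSA weights passed straight through.
#'
#' @param n Number of residues.
#' @param codes Character vector of length `n` of 3-letter codes.
#' @param rsa Numeric vector of length `n` of RSA weights in \[0, 1\].
#' @param geometry `"line"`, `"ring"` or `"random"`.
#' @param spacing Characteristic inter-residue distance, Angstrom
#'   (default 3.8, a CA-CA bond length).
#' @param seed RNG seed (mandatory; consumed only by `"random"`).
#' @param name,net_charge,mass_kda Passed to [pore_protein()].
#' @return A [pore_protein()] with a `truth` attribute echoing the
#'   generator parameters.
#' @export
gen_toy_protein <- function(n, codes, rsa, geometry = c("line", "ring",
                                                        "random"),
                            spacing = 3.8, seed = 1L, name = "toy",
                            net_charge = 1L, mass_kda = 3.9) {
  geometry <- match.arg(geometry)
  n <- as.integer(n)
  check_number(seed, "seed")
  if (length(codes) != n || length(rsa) != n) {
    stop_porepass("`codes` and `rsa` must have length `n`.",
                  "porepass_input_error")
  }
  coords <- switch(geometry,
    line = cbind(x = (seq_len(n) - 1) * spacing, y = 0, z = 0),
    ring = {
      r <- spacing / (2 * sin(pi / n))
      th <- 2 * pi * (seq_len(n) - 1) / n
      cbind(x = r * cos(th), y = r * sin(th), z = 0)
    },
    random = {
      set.seed(as.integer(seed))
      matrix(rnorm(3 * n, sd = spacing), ncol = 3,
             dimnames = list(NULL, c("x", "y", "z")))
    })
  p <- pore_protein(
    tibble(index = seq_len(n), code = codes,
           x = coords[, "x"], y = coords[, "y"], z = coords[, "z"],
           rsa = rsa),
    name = name, net_charge = net_charge, mass_kda = mass_kda)
  attr(p, "truth") <- list(geometry = geometry, spacing = spacing,
                           seed = seed)
  p
}

#' Generate a drift-diffusion ion trajectory
#'
#' A field-driven monovalent electrolyte stand-in: half the ions carry +1 e
#' and drift along +z, half carry -1 e and drift along -z (both therefore
#' contribute positive current).  Per step,
#' `z <- z + q * drift * dt + sqrt(2 * diffusion * dt) * N(0, 1)`, wrapped
#' periodically in the box; because the analyzer receives the box height it
#' can minimum-image the wrapped coordinates back to physical
#' displacements.  The expected slab-mean current,
#' `n * (lz / box_z) * drift / lz` in e/ps, is recorded in the `truth`
#' attribute.  Defaults give roughly ten pore ions and currents of order
#' 100 nA, resembling the scale of occupied-pore traces (a metadata-level
#' resemblance only, with no claim of physical fidelity).
#'
#' @param n_ions Total ion count (split evenly between charges).
#' @param drift Drift speed magnitude, Angstrom/ps.
#' @param diffusion Diffusion coefficient, Angstrom^2/ps.
#' @param frames Number of frames.
#' @param box `c(x, y, z)` box dimensions, Angstrom; ions wrap in z.
#' @param lz Pore-region length, Angstrom.
#' @param delta_t Frame spacing, ps (default 1).
#' @param seed RNG seed (mandatory).
#' @return An [ion_trajectory()] with `box_z` set and a `truth` attribute
#'   holding the generator parameters and `expected_current_na`.
#' @export
gen_ion_trajectory <- function(n_ions = 20L, drift = 2.5, diffusion = 2.0,
                               frames = 200L, box = c(40, 40, 80), lz = 36,
                               delta_t = 1, seed = 1L) {
  n_ions <- as.integer(n_ions); frames <- as.integer(frames)
  check_number(seed, "seed")
  check_number(drift, "drift")
  if (length(box) != 3L || any(box <= 0)) {
    stop_porepass("`box` must be three positive lengths.",
                  "porepass_input_error")
  }
  bz <- box[3]
  if (abs(drift) * delta_t >= bz / 4) {
    stop_porepass("drift per step must be small compared to the box height.",
                  "porepass_input_error")
  }
  set.seed(as.integer(seed))
  charge <- rep(c(1, -1), length.out = n_ions)
  x <- runif(n_ions, 0, box[1])
  y <- runif(n_ions, 0, box[2])
  z <- runif(n_ions, -bz / 2, bz / 2)
  sigma <- sqrt(2 * diffusion * delta_t)
  rows <- vector("list", frames)
  for (f in seq_len(frames)) {
    rows[[f]] <- tibble(time = (f - 1) * delta_t, ion = seq_len(n_ions),
                        charge = charge, x = x, y = y, z = z)
    step <- charge * drift * delta_t +
      if (diffusion > 0) rnorm(n_ions, sd = sigma) else 0
    z <- z + step
    z <- ((z + bz / 2) %% bz) - bz / 2   # periodic wrap
  }
  traj <- ion_trajectory(dplyr::bind_rows(rows), lz = lz, center_z = 0,
                         box_z = bz)
  expected_epps <- n_ions * (lz / bz) * drift / lz
  attr(traj, "truth") <- list(
    n_ions = n_ions, drift = drift, diffusion = diffusion, frames = frames,
    box = box, lz = lz, delta_t = delta_t, seed = seed,
    expected_current_epps = expected_epps,
    expected_current_na = expected_epps * E_PER_PS_TO_NA)
  traj
}
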