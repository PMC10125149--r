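# Rolling-probe accessible surface area (Shrake-Rupley point sampling) and
# its normalisation to relative surface accessibility.

# Deterministic Fibonacci-lattice points on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# van der Waals radii (A) by element; Bondi-style values commonly used for
# solvent accessibility.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               SE = 1.90)

atom_element <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    ok <- nzchar(e) & !is.na(e)
    if (all(ok)) return(e)
  } else {
    e <- rep(NA_character_, length(elety))
    ok <- logical(length(elety))
  }
  guess <- toupper(substr(gsub("^[0-9]+", "", trimws(elety)), 1, 1))
  ifelse(ok, e, guess)
}

#' Per-residue relative surface accessibility from a structure
#'
#' Rolling-probe accessible surface area by Shrake-Rupley point sampling
#' with a deterministic Fibonacci-lattice point set, normalised by a
#' published theoretical maximum ASA per residue type to give RSA in
#' \[0, 1\] (clipped at 1).  This is an offline convenience: the selection
#' model's source of record for RSA is a user-supplied table (typically a
#' structure-based predictor), never this routine silently.
#'
#' @param pdb Path to a PDB file, or a `bio3d` pdb object, or a data frame
#'   of atoms with columns `resno`, `resid`, `elety`, `x`, `y`, `z` (and
#'   optionally `elesy`).
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4, a
#'   water-sized probe).
#' @param n_points Sphere sample points per atom (default 960).
#' @param chain Optional chain selector for multi-chain files.
#' @return A tibble with columns `index`, `code`, `asa` (Angstrom^2) and
#'   `rsa`.
#' @export
compute_rsa <- function(pdb, probe_radius = 1.4, n_points = 960L,
                        chain = NULL) {
  check_number(probe_radius, "probe_radius", positive = TRUE)
  atoms <- sasa_atoms(pdb, chain)
  if (nrow(atoms) == 0L) {
    stop_porepass("no atoms to compute RSA from.", "porepass_input_error")
  }
  asa <- atom_sasa(as.matrix(atoms[c("x", "y", "z")]), atoms$radius,
                   probe_radius, n_points)
  resno <- unique(atoms$resno)
  max_asa <- read_max_asa()
  purrr::map_dfr(seq_along(resno), function(i) {
    sel <- atoms$resno == resno[i]
    code <- toupper(atoms$resid[sel][1])
    area <- sum(asa[sel])
    mx <- max_asa$max_asa_a2[match(code, max_asa$code)]
    tibble(index = i, code = code, asa = area,
           rsa = if (is.na(mx)) NA_real_ else min(area / mx, 1))
  })
}

sasa_atoms <- function(pdb, chain = NULL) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  atoms <- if (is.data.frame(pdb)) pdb else
    pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chain) && "chain" %in% names(atoms)) {
    atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  }
  el <- atom_element(atoms$elety, atoms$elesy)
  radius <- VDW_RADII[el]
  radius[is.na(radius)] <- VDW_RADII[["C"]]
  atoms$radius <- unname(radius)
  # hydrogens are excluded: the max-ASA normalisation set is heavy-atom based
  atoms[!atom_element(atoms$elety, atoms$elesy) %in% c("H", "D"), ,
        drop = FALSE]
}

# Shrake-Rupley: fraction of sphere points (at radius r_i + probe) not
# buried inside any neighbouring atom's probe-expanded sphere.
atom_sasa <- function(coords, radii, probe, n_points) {
  n <- nrow(coords)
  sphere <- fibonacci_sphere(as.integer(n_points))
  expanded <- radii + probe
  # pairwise prefilter: only atoms whose expanded spheres can overlap
  out <- numeric(n)
  for (i in seq_len(n)) {
    ri <- expanded[i]
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    cand <- which(d2 < (ri + expanded)^2 & seq_len(n) != i)
    pts <- sweep(sphere * ri, 2, coords[i, ], `+`)
    accessible <- rep(TRUE, nrow(pts))
    for (j in cand) {
      if (!any(accessible)) break
      dj <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      accessible <- accessible & (dj >= expanded[j]^2)
    }
    out[i] <- 4 * pi * ri^2 * mean(accessible)
  }
  out
}

read_max_asa <- function() {
  readr::read_tsv(porepass_extdata("max_asa.tsv"), comment = "#",
                  show_col_types = FALSE, progress = FALSE)
}
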