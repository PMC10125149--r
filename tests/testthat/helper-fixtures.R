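# Shared fixtures, built in code.

# Small all-attractive energy table with distinct values (eV, signed).
toy_table <- function() {
  aa_energy_table(data.frame(
    code = c("CYS", "GLY", "ALA", "SER", "THR", "VAL", "LEU", "PHE"),
    delta_e = c(-1.4944, -1.4880, -0.9876, -1.4538, -0.9887, -0.9424,
                -1.1341, -0.8881)))
}

# Heteropolymer toy with distinct residue energies and uneven RSA.
hetero_protein <- function(n = 6, seed = 42, geometry = "random") {
  codes <- c("CYS", "GLY", "ALA", "SER", "THR", "VAL", "LEU", "PHE")[seq_len(n)]
  set.seed(seed)
  rsa <- runif(n, 0.05, 0.95)
  gen_toy_protein(n, codes = codes, rsa = rsa, geometry = geometry,
                  seed = seed)
}

homopolymer_cys <- function(n = 6) {
  gen_toy_protein(n, codes = rep("CYS", n), rsa = rep(0.5, n),
                  geometry = "line", seed = 1)
}

# Independent brute-force law of the patch energy: explicit loops over seed
# residues and partner subsets, no package internals beyond neighbor lists
# and the energy lookup.
brute_force_patch_law <- function(protein, nb, table, N, L) {
  w <- protein$rsa
  if (all(w == 0)) w <- rep(1, length(w))
  w <- w / sum(w)
  e <- aa_energy(table, protein$code)
  pools <- lapply(split(nb$neighbor, nb$residue)[as.character(seq_len(nrow(protein)))],
                  function(p) p[seq_len(min(L, length(p)))])
  energies <- numeric(0); probs <- numeric(0)
  for (i in seq_len(nrow(protein))) {
    if (w[i] == 0) next
    if (N == 1) {
      energies <- c(energies, e[i]); probs <- c(probs, w[i]); next
    }
    subs <- utils::combn(pools[[i]], N - 1)
    for (k in seq_len(ncol(subs))) {
      energies <- c(energies, e[i] + sum(e[subs[, k]]))
      probs <- c(probs, w[i] / ncol(subs))
    }
  }
  mu <- sum(energies * probs)
  list(mean = mu,
       std = sqrt(sum(energies^2 * probs) - mu^2),
       energies = energies, probs = probs)
}

# Minimal PDB text for a 3-residue peptide; deliberately hand-written
# coordinates so reads can be checked against literals.
write_toy_pdb <- function(path, drop_ca_for = integer(0)) {
  fmt <- function(serial, name, res, resno, x, y, z) {
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            serial, name, res, resno, x, y, z, substr(trimws(name), 1, 1))
  }
  lines <- character(0)
  serial <- 0L
  res_names <- c("GLY", "ALA", "SER")
  for (r in 1:3) {
    base <- (r - 1) * 3.8
    add <- function(name, dx, dy, dz) {
      serial <<- serial + 1L
      lines <<- c(lines, fmt(serial, name, res_names[r], r,
                             base + dx, dy, dz))
    }
    add(" N  ", -0.5, 0.8, 0.1)
    if (!(r %in% drop_ca_for)) add(" CA ", 0.0, 0.0, 0.0)
    add(" C  ", 0.7, -0.9, 0.2)
    add(" O  ", 0.9, -1.1, 1.3)
  }
  writeLines(c(lines, "END"), path)
  path
}
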