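#' Construct a per-residue protein model
#'
#' The protein model is what the contact-patch selection model consumes: one
#' row per residue with its 3-letter code, a representative coordinate
#' (Angstrom) and its relative surface accessibility (RSA, in \[0, 1\]),
#' plus whole-protein net charge and mass held as attributes.  Charge and
#' mass are required explicitly — they set the dwell-time kinetics and are
#' never inferred from the sequence.
#'
#' @param residues Data frame with columns `index` (1..n, contiguous),
#'   `code`, `x`, `y`, `z` and `rsa`.
#' @param name Protein name.
#' @param net_charge Net charge in units of e (integer, may be negative).
#' @param mass_kda Mass in kDa (> 0).
#' @return A tibble of class `pore_protein` with attributes `name`,
#'   `net_charge` and `mass_kda`.
#' @seealso [load_protein()], [neighbors()], [gen_toy_protein()]
#' @export
pore_protein <- function(residues, name, net_charge, mass_kda) {
  if (!is.data.frame(residues)) {
    stop_porepass("`residues` must be a data frame.", "porepass_input_error")
  }
  need <- c("index", "code", "x", "y", "z", "rsa")
  if (!all(need %in% names(residues))) {
    stop_porepass(sprintf("`residues` needs columns: %s.",
                          paste(need, collapse = ", ")),
                  "porepass_input_error")
  }
  res <- as_tibble(residues)[need]
  res$index <- as.integer(res$index)
  res$code <- toupper(as.character(res$code))
  n <- nrow(res)
  if (n < 1L) stop_porepass("empty residue table.", "porepass_input_error")
  if (!identical(res$index, seq_len(n))) {
    stop_porepass("residue indices must be unique and contiguous from 1.",
                  "porepass_input_error")
  }
  coords <- as.matrix(res[c("x", "y", "z")])
  if (any(!is.finite(coords))) {
    stop_porepass("residue coordinates must be finite.", "porepass_input_error")
  }
  if (anyNA(res$rsa) || any(res$rsa < 0 | res$rsa > 1)) {
    stop_porepass("RSA values must lie in [0, 1].", "porepass_input_error")
  }
  check_number(net_charge, "net_charge")
  if (abs(net_charge - round(net_charge)) > 1e-9) {
    stop_porepass("`net_charge` must be an integer multiple of e.",
                  "porepass_input_error")
  }
  check_number(mass_kda, "mass_kda", positive = TRUE)
  structure(res,
            class = c("pore_protein", class(res)),
            name = as.character(name),
            net_charge = as.integer(round(net_charge)),
            mass_kda = mass_kda)
}

#' @export
print.pore_protein <- function(x, ...) {
  cat(sprintf("<pore_protein> %s: %d residues, net charge %+de, mass %.2f kDa\n",
              attr(x, "name"), nrow(x), attr(x, "net_charge"),
              attr(x, "mass_kda")))
  NextMethod()
}

#' Load a protein model from a PDB file and an RSA table
#'
#' Reads standard ATOM records, takes the alpha-carbon as each residue's
#' representative coordinate (falling back to the centroid of the residue's
#' heavy atoms when no CA is present), and joins the user-supplied
#' per-residue RSA values by sequence position.  The RSA table is the source
#' of record for surface accessibility (typically from a structure-based
#' predictor); [compute_rsa()] is available as an offline convenience.
#'
#' @param pdb Path to a PDB file, or a `bio3d` pdb object.
#' @param rsa_table Path to a TSV with columns `index`, `code`, `rsa`, or a
#'   data frame of the same layout.  Must cover every residue of the chain.
#' @param net_charge,mass_kda Passed to [pore_protein()].
#' @param name Protein name; defaults to the PDB file stem.
#' @param chain Chain identifier; required when the file has several chains.
#' @param representative `"ca"` (default) or `"sidechain_centroid"`.
#' @return A [pore_protein()].
#' @export
load_protein <- function(pdb, rsa_table, net_charge, mass_kda,
                         name = NULL, chain = NULL,
                         representative = c("ca", "sidechain_centroid")) {
  representative <- match.arg(representative)
  if (is.character(pdb)) {
    name <- name %||% sub("\\.pdb$", "", basename(pdb), ignore.case = TRUE)
    pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  }
  name <- name %||% "protein"
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop_porepass("PDB contains no ATOM records.", "porepass_input_error")
  }
  chains <- unique(atoms$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L) {
      stop_porepass(sprintf("PDB has chains %s; select one with `chain`.",
                            paste(chains, collapse = ", ")),
                    "porepass_input_error")
    }
    chain <- chains
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop_porepass(sprintf("chain '%s' is empty.", chain),
                  "porepass_input_error")
  }

  resno <- unique(atoms$resno)
  reps <- purrr::map_dfr(seq_along(resno), function(i) {
    a <- atoms[atoms$resno == resno[i], , drop = FALSE]
    xyz <- representative_coord(a, representative)
    tibble(index = i, code = toupper(a$resid[1]),
           x = xyz[1], y = xyz[2], z = xyz[3])
  })

  rsa <- if (is.data.frame(rsa_table)) as_tibble(rsa_table) else
    read_rsa_table(rsa_table)
  if (nrow(rsa) != nrow(reps)) {
    stop_porepass(sprintf(
      "RSA table has %d rows but the chain has %d residues.",
      nrow(rsa), nrow(reps)), "porepass_input_error")
  }
  rsa <- rsa[order(rsa$index), ]
  if ("code" %in% names(rsa) &&
      !all(toupper(rsa$code) == reps$code)) {
    stop_porepass("RSA table residue codes do not match the PDB sequence.",
                  "porepass_input_error")
  }
  reps$rsa <- as.numeric(rsa$rsa)
  pore_protein(reps, name = name, net_charge = net_charge,
               mass_kda = mass_kda)
}

representative_coord <- function(a, representative) {
  heavy <- a[!substr(trimws(a$elety), 1, 1) %in% c("H", "D"), , drop = FALSE]
  if (nrow(heavy) == 0L) heavy <- a
  if (representative == "ca") {
    ca <- a[trimws(a$elety) == "CA", , drop = FALSE]
    if (nrow(ca) >= 1L) {
      return(c(ca$x[1], ca$y[1], ca$z[1]))
    }
    return(unname(colMeans(heavy[c("x", "y", "z")])))
  }
  # side-chain centroid: heavy atoms outside the backbone; glycine falls
  # back to CA/backbone centroid
  side <- heavy[!trimws(heavy$elety) %in% c("N", "CA", "C", "O", "OXT"), ,
                drop = FALSE]
  if (nrow(side) == 0L) side <- heavy
  unname(colMeans(side[c("x", "y", "z")]))
}

#' Read a per-residue RSA table
#'
#' @param path TSV with header `index<TAB>code<TAB>rsa`.
#' @return A tibble with those columns.
#' @export
read_rsa_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("index", "rsa") %in% names(tab))) {
    stop_porepass("RSA table needs `index` and `rsa` columns.",
                  "porepass_input_error")
  }
  as_tibble(tab)
}

#' L-nearest-neighbor lists over residue coordinates
#'
#' For every residue, the `L` geometrically closest other residues by
#' Euclidean distance between representative coordinates, nearest first.
#' Exact ties are broken by ascending residue index, so the result is
#' deterministic regardless of input ordering.
#'
#' @param protein A [pore_protein()].
#' @param L Number of neighbors per residue (default 5, the pool from which
#'   contact-patch partners are drawn).
#' @return A tibble of class `neighbor_list` with columns `residue`, `rank`,
#'   `neighbor` and `distance` (Angstrom); `min(L, n - 1)` rows per residue.
#' @export
neighbors <- function(protein, L = 5L) {
  if (!inherits(protein, "pore_protein")) {
    stop_porepass("`protein` must be a pore_protein.", "porepass_input_error")
  }
  n <- nrow(protein)
  if (n < 2L) stop_porepass("need at least 2 residues.", "porepass_input_error")
  if (!is.numeric(L) || length(L) != 1L || L < 1) {
    stop_porepass("`L` must be a positive count.", "porepass_input_error")
  }
  L <- as.integer(L)
  k <- min(L, n - 1L)
  dmat <- as.matrix(stats::dist(as.matrix(protein[c("x", "y", "z")])))
  out <- purrr::map_dfr(seq_len(n), function(i) {
    d <- unname(dmat[i, ])
    # distances compared at 12 significant digits so exact geometric ties
    # (up to floating construction noise) break by ascending index
    idx <- setdiff(order(signif(d, 12), seq_len(n)), i)[seq_len(k)]
    tibble(residue = i, rank = seq_len(k), neighbor = idx,
           distance = d[idx])
  })
  structure(out, class = c("neighbor_list", class(out)), L = L)
}

# Per-residue integer neighbor vectors, as a plain list (internal).
neighbor_index_list <- function(nb) {
  split(nb$neighbor, nb$residue)[as.character(sort(unique(nb$residue)))]
}
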