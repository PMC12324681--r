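# In-code fixtures shared across the suite.

# Deterministic tiny protein: straight-line backbone, constant or given
# confidence values.
make_protein <- function(id = "P1", n = 10, plddt = rep(90, n),
                         pae = NULL, species = "SPTEST",
                         is_fragment = FALSE, tm = NA_integer_,
                         with_atoms = FALSE, seq1 = NULL) {
  if (is.null(pae)) pae <- matrix(1, n, n) - diag(n)
  if (is.null(seq1)) {
    seq1 <- paste(rep(c("A", "G", "L", "K", "D"), length.out = n), collapse = "")
  }
  ca <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
  atoms <- NULL
  if (with_atoms) {
    atoms <- data.frame(
      residue = seq_len(n), atom = "CA", element = "C",
      x = ca[, 1], y = ca[, 2], z = ca[, 3], stringsAsFactors = FALSE
    )
  }
  protein_record(id, species, seq1, ca, plddt, pae, atom_coords = atoms,
                 is_fragment = is_fragment, tm_checks_passed = tm)
}

make_pocket <- function(id = "P1.pocket1", protein_id = "P1", idx = 1:5,
                        probability = 0.8, rank = 1L, chain = "A") {
  pocket_table(id, protein_id, rank, probability,
               list(residue_set(chain, idx)))
}

make_site <- function(id = "P1.site1", protein_id = "P1", idx = 1:4,
                      ligand = "CHEBI:90001", chain = "A") {
  known_site_table(id, protein_id, list(residue_set(chain, idx)), ligand)
}

# Brute-force union-find oracle for connected components.
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  # path-compress into canonical labels
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

# Two-sided Fisher exact p by direct hypergeometric enumeration.
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b  # row 1
  n2 <- c + d # row 2
  k <- a + c  # column 1
  support <- max(0, k - n2):min(m, k)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A minimal mmCIF atom_site block with per-residue confidence in the
# B-factor column (synthetic fixture).
write_mini_cif <- function(path, resid = c("ALA", "GLY", "TRP"),
                           plddt = c(91.2, 77.5, 60.25)) {
  header <- c(
    "data_synthetic", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"))
  )
  rows <- vapply(seq_along(resid), function(i) {
    sprintf("ATOM %d C CA . %s A 1 %d ? %.3f 0.000 0.000 1.00 %.2f ? %d %s A CA 1",
            i, resid[i], i, 3.8 * (i - 1), plddt[i], i, resid[i])
  }, "")
  writeLines(c(header, rows), path)
  path
}
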