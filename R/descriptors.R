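# Physicochemical pocket descriptors: hydropathy (GRAVY), aromatic residue
# fraction, net side-chain charge at pH 7, and relative solvent-accessible
# surface area from sphere-point (Shrake-Rupley) sampling, plus the model
# confidence means and residue count.

#' Grand-average hydropathy of a residue multiset
#'
#' Mean Kyte-Doolittle hydropathy over the residues lining a pocket.
#'
#' @param residue_types character vector of one-letter residue codes
#'   (a multiset; repeats count).
#' @return GRAVY value (positive = hydrophobic).
#' @export
hydrophobicity <- function(residue_types) {
  residue_types <- check_residue_codes(residue_types)
  if (length(residue_types) == 0L) stop("empty residue multiset", call. = FALSE)
  mean(kyte_doolittle[residue_types])
}

#' Aromatic residue fraction
#'
#' Relative frequency of Phe, Trp and Tyr among the residues.
#'
#' @inheritParams hydrophobicity
#' @return fraction in \[0, 1\].
#' @export
aromaticity <- function(residue_types) {
  residue_types <- check_residue_codes(residue_types)
  if (length(residue_types) == 0L) stop("empty residue multiset", call. = FALSE)
  mean(residue_types %in% aa_aromatic)
}

#' Net side-chain charge at pH 7
#'
#' Sum of per-residue charges: Asp/Glu -1, Lys/Arg +1, His +0.5, all other
#' residue types 0. Additive over disjoint multisets.
#'
#' @inheritParams hydrophobicity
#' @return net charge in elementary charge units.
#' @export
net_charge <- function(residue_types) {
  residue_types <- check_residue_codes(residue_types)
  sum(aa_charge[residue_types])
}

# Deterministic, approximately uniform unit-sphere points (golden spiral).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Molecule-intrinsic orthonormal frame (principal axes with third-moment
# sign fixing, right-handed). Orienting the quadrature grid in this frame
# makes the sphere-point SASA invariant under rigid rotation and
# translation of the coordinates up to floating-point error.
principal_frame <- function(xyz) {
  if (nrow(xyz) < 3L) return(diag(3))
  centered <- sweep(xyz, 2, colMeans(xyz))
  v <- eigen(stats::cov(centered), symmetric = TRUE)$vectors
  for (k in 1:2) {
    m3 <- sum((centered %*% v[, k])^3)
    if (abs(m3) > 1e-8 && m3 < 0) v[, k] <- -v[, k]
  }
  v[, 3] <- c(
    v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
    v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
    v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2]
  )
  v
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-point sampling of the solvent-accessible surface: each atom is
#' expanded by the probe radius, test points are placed on the expanded
#' sphere, and the accessible fraction is the share of points lying outside
#' every other expanded atom sphere.
#'
#' @param atoms data.frame with columns `residue`, `element`, `x`, `y`, `z`.
#' @param probe_radius solvent probe radius in Angstrom.
#' @param n_points sphere points per atom.
#' @return named numeric vector of SASA (square Angstrom) per residue index.
#' @export
shrake_rupley_sasa <- function(atoms, probe_radius = 1.4, n_points = 960L) {
  stopifnot(all(c("residue", "element", "x", "y", "z") %in% names(atoms)))
  elem <- toupper(substr(atoms$element, 1, 1))
  unknown <- setdiff(unique(elem), names(vdw_radii))
  if (length(unknown) > 0L) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  radii <- vdw_radii[elem] + probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n_atoms <- nrow(xyz)
  pts <- sphere_points(n_points) %*% t(principal_frame(xyz))
  atom_sasa <- numeric(n_atoms)
  for (a in seq_len(n_atoms)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[a, ])^2)
    nb <- which(d2 < (radii + radii[a])^2 & seq_len(n_atoms) != a)
    test <- sweep(pts * radii[a], 2, xyz[a, ], `+`)
    if (length(nb) > 0L) {
      free <- rep(TRUE, n_points)
      for (b in nb) {
        inside <- rowSums(sweep(test, 2, xyz[b, ])^2) < radii[b]^2
        free <- free & !inside
        if (!any(free)) break
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    atom_sasa[a] <- frac * 4 * pi * radii[a]^2
  }
  sasa <- tapply(atom_sasa, atoms$residue, sum)
  stats::setNames(as.numeric(sasa), names(sasa))
}

#' Relative solvent-accessible surface area of a pocket
#'
#' Sum of per-residue SASA over the pocket residues (computed in the
#' context of the whole protein), divided by the sum of the theoretical
#' maximum ASA values of those residues' types.
#'
#' @param pocket_residues residue set of the pocket.
#' @param protein a [protein_record()] with `atom_coords`.
#' @param probe_radius,n_points passed to [shrake_rupley_sasa()].
#' @param sasa optional precomputed per-residue SASA vector for the protein
#'   (avoids recomputation across pockets of the same protein).
#' @return dimensionless accessibility ratio (>= 0).
#' @export
relative_sasa <- function(pocket_residues, protein, probe_radius = 1.4,
                          n_points = 960L, sasa = NULL) {
  if (is.null(protein$atom_coords)) {
    stop("protein ", protein$protein_id, " has no all-atom coordinates",
         call. = FALSE)
  }
  if (is.null(sasa)) {
    sasa <- shrake_rupley_sasa(protein$atom_coords, probe_radius, n_points)
  }
  idx <- pocket_residue_indices(pocket_residues, protein)
  missing <- setdiff(as.character(idx), names(sasa))
  if (length(missing) > 0L) {
    stop("no atoms for pocket residue(s) ", paste(missing, collapse = ", "),
         " of protein ", protein$protein_id, call. = FALSE)
  }
  aa1 <- strsplit(protein$sequence, "")[[1]][idx]
  sum(sasa[as.character(idx)]) / sum(max_asa_theoretical[aa1])
}

#' Compute all descriptors for a pocket cohort
#'
#' Joins the physicochemical descriptors with the confidence means and the
#' residue count; one row per pocket. SASA is computed once per protein and
#' reused across its pockets; proteins without all-atom coordinates get
#' `NA` for `rel_sasa`.
#'
#' @param pockets a [pocket_table()].
#' @param proteins named list of [protein_record()]s.
#' @param probe_radius,n_points SASA parameters.
#' @return data.frame keyed by `pocket_id` with columns `hydrophobicity`,
#'   `aromaticity`, `net_charge`, `rel_sasa`, `mean_plddt`, `mean_pae`,
#'   `n_residues`, `probability`.
#' @export
compute_descriptors <- function(pockets, proteins, probe_radius = 1.4,
                                n_points = 960L) {
  sasa_cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(pockets)), function(r) {
    prot <- proteins[[pockets$protein_id[r]]]
    res <- pockets$residues[[r]]
    idx <- pocket_residue_indices(res, prot)
    aa1 <- strsplit(prot$sequence, "")[[1]][idx]
    rs <- NA_real_
    if (!is.null(prot$atom_coords)) {
      if (!exists(prot$protein_id, envir = sasa_cache)) {
        assign(prot$protein_id,
               shrake_rupley_sasa(prot$atom_coords, probe_radius, n_points),
               envir = sasa_cache)
      }
      rs <- relative_sasa(res, prot, sasa = get(prot$protein_id, envir = sasa_cache))
    }
    data.frame(
      pocket_id = pockets$pocket_id[r],
      hydrophobicity = hydrophobicity(aa1),
      aromaticity = aromaticity(aa1),
      net_charge = net_charge(aa1),
      rel_sasa = rs,
      mean_plddt = pocket_mean_plddt(res, prot),
      mean_pae = pocket_mean_pae(res, prot),
      n_residues = length(idx),
      probability = pockets$probability[r],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
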