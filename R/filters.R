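# Protein- and pocket-level inclusion rules.
#
# Proteins enter the analysis only if they are not fragments, have at least
# `min_protein_length` residues and -- for membrane proteins -- pass all six
# transmembrane-model quality checks. Pockets survive if their ligandability
# probability reaches `probability_threshold` and the model confidence over
# their residues is adequate: exclusion is strict (mean pLDDT < 70 or mean
# PAE > 10 A), so pockets sitting exactly on a boundary are kept.

#' Filtering thresholds
#'
#' @param min_protein_length minimum protein length in residues.
#' @param min_tm_checks minimum number of passed transmembrane-model quality
#'   checks (out of 6) for membrane proteins.
#' @param probability_threshold minimum pocket ligandability probability
#'   (inclusive).
#' @param min_pocket_plddt pockets with mean pLDDT strictly below this are
#'   excluded.
#' @param max_pocket_pae pockets with mean PAE (Angstrom) strictly above
#'   this are excluded.
#' @param min_known_site_residues minimum residue count for a known site to
#'   be considered.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_protein_length = 100L, min_tm_checks = 6L,
                          probability_threshold = 0.5, min_pocket_plddt = 70,
                          max_pocket_pae = 10, min_known_site_residues = 4L) {
  cfg <- list(
    min_protein_length = as.integer(min_protein_length),
    min_tm_checks = as.integer(min_tm_checks),
    probability_threshold = probability_threshold,
    min_pocket_plddt = min_pocket_plddt,
    max_pocket_pae = max_pocket_pae,
    min_known_site_residues = as.integer(min_known_site_residues)
  )
  stopifnot(all(vapply(cfg, is.finite, TRUE)))
  structure(cfg, class = "filter_config")
}

#' Protein-level inclusion test
#'
#' @param protein a [protein_record()].
#' @param cfg a [filter_config()].
#' @return list with `pass` (logical) and `reason` (`"ok"`, `"fragment"`,
#'   `"length"`, or `"tm_checks"`; the first failing rule).
#' @export
protein_passes <- function(protein, cfg = filter_config()) {
  if (protein$is_fragment) {
    return(list(pass = FALSE, reason = "fragment"))
  }
  if (protein_length(protein) < cfg$min_protein_length) {
    return(list(pass = FALSE, reason = "length"))
  }
  tm <- protein$tm_checks_passed
  if (!is.na(tm) && tm < cfg$min_tm_checks) {
    return(list(pass = FALSE, reason = "tm_checks"))
  }
  list(pass = TRUE, reason = "ok")
}

pocket_residue_indices <- function(pocket_residues, protein) {
  idx <- pocket_residues$index
  n <- protein_length(protein)
  bad <- idx < 1L | idx > n
  if (any(bad)) {
    stop("pocket residue(s) outside protein ", protein$protein_id, ": ",
         paste(residue_keys(pocket_residues)[bad], collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Mean model confidence over a pocket
#'
#' Arithmetic mean of the per-residue pLDDT values of the pocket residues.
#'
#' @param pocket_residues residue set of the pocket ([residue_set()]).
#' @param protein the owning [protein_record()].
#' @return mean pLDDT in \[0, 100\].
#' @export
pocket_mean_plddt <- function(pocket_residues, protein) {
  idx <- pocket_residue_indices(pocket_residues, protein)
  mean(protein$plddt[idx])
}

#' Mean predicted aligned error over a pocket
#'
#' Mean of the full all-against-all PAE submatrix over the pocket residues,
#' i.e. over every ordered pair including the diagonal, using the stored
#' (possibly asymmetric) matrix.
#'
#' @inheritParams pocket_mean_plddt
#' @return mean PAE in Angstrom.
#' @export
pocket_mean_pae <- function(pocket_residues, protein) {
  idx <- pocket_residue_indices(pocket_residues, protein)
  mean(protein$pae[idx, idx, drop = FALSE])
}

#' Pocket-level inclusion test
#'
#' @param pocket one-row slice of a [pocket_table()] (or a list with
#'   `probability` and `residues` fields).
#' @param protein the owning [protein_record()].
#' @param cfg a [filter_config()].
#' @return list with `pass` and `reason` (`"ok"`, `"probability"`,
#'   `"plddt"`, or `"pae"`).
#' @export
pocket_passes <- function(pocket, protein, cfg = filter_config()) {
  prob <- pocket$probability[1]
  res <- if (is.list(pocket$residues) && !is.data.frame(pocket$residues)) {
    pocket$residues[[1]]
  } else {
    pocket$residues
  }
  if (prob < cfg$probability_threshold) {
    return(list(pass = FALSE, reason = "probability"))
  }
  if (pocket_mean_plddt(res, protein) < cfg$min_pocket_plddt) {
    return(list(pass = FALSE, reason = "plddt"))
  }
  if (pocket_mean_pae(res, protein) > cfg$max_pocket_pae) {
    return(list(pass = FALSE, reason = "pae"))
  }
  list(pass = TRUE, reason = "ok")
}

#' Apply protein and pocket filters to a cohort
#'
#' Pockets on proteins failing the protein-level rules are removed
#' regardless of their own scores. The operation is idempotent.
#'
#' @param pockets a [pocket_table()].
#' @param proteins named list of [protein_record()]s keyed by protein id.
#' @param cfg a [filter_config()].
#' @return list with `pockets` (surviving rows), `protein_reasons` and
#'   `pocket_reasons` (named character vectors), and `counts` (per-reason
#'   exclusion tallies).
#' @export
filter_cohort <- function(pockets, proteins, cfg = filter_config()) {
  protein_reasons <- vapply(proteins, function(p) protein_passes(p, cfg)$reason, "")
  pocket_reasons <- character(nrow(pockets))
  for (r in seq_len(nrow(pockets))) {
    prot <- proteins[[pockets$protein_id[r]]]
    if (is.null(prot)) {
      stop("pocket ", pockets$pocket_id[r], " refers to unknown protein ",
           pockets$protein_id[r], call. = FALSE)
    }
    pr <- protein_reasons[[pockets$protein_id[r]]]
    pocket_reasons[r] <- if (pr != "ok") {
      paste0("protein_", pr)
    } else {
      pocket_passes(pockets[r, ], prot, cfg)$reason
    }
  }
  names(pocket_reasons) <- pockets$pocket_id
  keep <- pocket_reasons == "ok"
  list(
    pockets = pockets[keep, , drop = FALSE],
    protein_reasons = protein_reasons,
    pocket_reasons = pocket_reasons,
    counts = table(pocket_reasons)
  )
}

#' Recall of known sites across probability thresholds
#'
#' For each threshold `t`, the fraction of known sites (with at least
#' `min_known_site_residues` residues) that share at least one
#' (chain, index) residue with a same-protein pocket of probability >= `t`.
#' Recall is non-increasing in `t`.
#'
#' @param pockets a [pocket_table()].
#' @param known_sites a [known_site_table()].
#' @param thresholds numeric vector of probability thresholds.
#' @param cfg a [filter_config()] (supplies `min_known_site_residues`).
#' @return data.frame with columns `threshold` and `recall`.
#' @export
recall_vs_threshold <- function(pockets, known_sites, thresholds,
                                cfg = filter_config()) {
  sizes <- vapply(known_sites$residues, nrow, 1L)
  known_sites <- known_sites[sizes >= cfg$min_known_site_residues, , drop = FALSE]
  if (nrow(known_sites) == 0L) {
    stop("no known sites to evaluate recall on", call. = FALSE)
  }
  pocket_keys <- lapply(pockets$residues, residue_keys)
  site_keys <- lapply(known_sites$residues, residue_keys)
  # per site, the highest probability of any overlapping same-protein pocket
  best <- vapply(seq_len(nrow(known_sites)), function(s) {
    cand <- which(pockets$protein_id == known_sites$protein_id[s])
    hits <- cand[vapply(cand, function(p) {
      any(site_keys[[s]] %in% pocket_keys[[p]])
    }, TRUE)]
    if (length(hits) == 0L) -Inf else max(pockets$probability[hits])
  }, 0)
  data.frame(
    threshold = thresholds,
    recall = vapply(thresholds, function(t) mean(best >= t), 0)
  )
}
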