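# Synthetic-data generators emulating every upstream input of the
# pipeline: proteomes with per-residue confidence and pairwise error
# matrices, pocket predictions and annotated sites with plantable
# ligand-class enrichment, per-species sparse similarity matrices with
# planted community structure and a planted proteome-to-pocketome scaling
# exponent, and pocket embedding vectors with controllable kingdom
# mixing. All generators are pure functions of (config, seed): per-stage
# RNG streams are derived from the master seed by fixed offsets.

#' Synthetic-data configuration
#'
#' Defaults encode the statistical regime the downstream analyses assume:
#' predicted pockets with a median of about 24 lining residues versus
#' about 6 for annotated sites, roughly half of annotated sites recovered
#' by prediction, ligand-class enrichment odds spanning strong enrichment
#' (nucleotides) to strong depletion (inorganic ions), heavy-tailed
#' community sizes, and a sub-linear planted scaling exponent.
#'
#' @param seed master integer seed.
#' @param n_species number of species.
#' @param proteins_per_species proteins generated per species.
#' @param mean_protein_length mean residue count (lognormal lengths).
#' @param pocket_rate mean pockets per protein (Poisson).
#' @param site_rate mean annotated sites per pocket-bearing protein.
#' @param a_true planted scaling exponent for unique pockets vs fold
#'   clusters.
#' @param unique_coefficient prefactor `c` in
#'   `N_unique = round(c * N_FS^a_true)`.
#' @param pockets_per_fs pockets per fold cluster (sets total pocket
#'   counts linear in `N_FS`).
#' @param n_fs_range range of fold-cluster counts across species
#'   (log-spaced).
#' @param singleton_fraction fraction of the unique-pocket budget realised
#'   as singletons (isolated pockets).
#' @param community_size_power power-law exponent of community sizes.
#' @param max_community_size truncation of the community-size law.
#' @param enrichment_odds named vector of planted per-class odds ratios
#'   for recovery ("found") of annotated sites.
#' @param class_probs named vector of ligand-class frequencies.
#' @param baseline_found_rate found probability for an odds-1 class.
#' @param pocket_size_median,site_size_median median residue counts.
#' @param plddt_beta_params shape parameters of the Beta law scaled to
#'   \[0, 100\] for per-residue confidence.
#' @param pae_scale asymptotic pairwise-error level in Angstrom.
#' @param fragment_fraction,tm_fraction fractions of fragment entries and
#'   membrane proteins (the latter get 4-6 passed quality checks).
#' @param kingdoms kingdom labels cycled over species.
#' @param n_components,component_separation embedding mixture shape.
#' @param kingdom_association `"none"` (components shared across
#'   kingdoms) or `"strong"` (one component per kingdom).
#' @param kingdom_mixture optional named list kingdom -> list(mean, sd)
#'   overriding the mixture layout.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L, n_species = 11L, proteins_per_species = 30L,
    mean_protein_length = 150, pocket_rate = 1.5, site_rate = 1,
    a_true = 0.5, unique_coefficient = 4, pockets_per_fs = 0.5,
    n_fs_range = c(500, 5000), singleton_fraction = 0.6,
    community_size_power = 2, max_community_size = 300L,
    enrichment_odds = c(
      "Nucleobases, nucleosides & nucleotides" = 8.55,
      "Inorganic ions" = 0.05,
      "Carbohydrates & derivatives" = 5.08,
      "Hemes" = 5.97,
      "Hetero nuclear clusters" = 0.17
    ),
    class_probs = c(
      "Nucleobases, nucleosides & nucleotides" = 0.462,
      "Inorganic ions" = 0.378,
      "Other compounds" = 0.063,
      "Carbohydrates & derivatives" = 0.029,
      "Amino acids & derivatives" = 0.018,
      "Hetero nuclear clusters" = 0.023,
      "Lipids" = 0.012,
      "Oligo- & polypeptides" = 0.008,
      "Monosaccharides & derivatives" = 0.005,
      "Glycans" = 0.0034,
      "Hemes" = 0.0007,
      "Nucleic acids" = 0.0003
    ),
    baseline_found_rate = 0.5, pocket_size_median = 24, site_size_median = 6,
    plddt_beta_params = c(7, 1), pae_scale = 5,
    fragment_fraction = 0.05, tm_fraction = 0.2,
    kingdoms = c("Bacteria", "Fungi", "Plantae", "Animalia"),
    n_components = 5L, component_separation = 10,
    kingdom_association = c("none", "strong"), kingdom_mixture = NULL) {
  kingdom_association <- match.arg(kingdom_association)
  stopifnot(
    n_species >= 1L, proteins_per_species >= 1L, mean_protein_length >= 1,
    a_true > 0, singleton_fraction >= 0, singleton_fraction <= 1,
    fragment_fraction >= 0, fragment_fraction <= 1,
    baseline_found_rate >= 0, baseline_found_rate <= 1,
    all(enrichment_odds >= 0)
  )
  cfg <- as.list(environment())
  cfg$class_probs <- class_probs / sum(class_probs)
  structure(cfg, class = "synthetic_config")
}

species_names <- function(cfg) sprintf("SP%02d", seq_len(cfg$n_species))

species_kingdoms <- function(cfg) {
  stats::setNames(rep_len(cfg$kingdoms, cfg$n_species), species_names(cfg))
}

# Fixed per-stage seed offsets keep the generator streams independent.
stage_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

# sample() that never treats a length-1 vector as 1:n
resample <- function(x, size = length(x), ...) x[sample.int(length(x), size, ...)]

# Backbone-like 3D walk: 3.8 A steps, direction resampled when the new
# position would clash (< 3 A) with one of the preceding 20 residues.
random_backbone <- function(n, step = 3.8) {
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    for (attempt in 1:20) {
      dir <- stats::rnorm(3)
      cand <- xyz[i - 1, ] + step * dir / sqrt(sum(dir^2))
      window <- max(1, i - 20):(i - 1)
      d2 <- rowSums(sweep(xyz[window, , drop = FALSE], 2, cand)^2)
      if (all(d2 > 3^2) || attempt == 20L) break
    }
    xyz[i, ] <- cand
  }
  xyz
}

# Pseudo-atoms (N, CA, C, O, CB) jittered around each C-alpha.
pseudo_atoms <- function(ca_coords) {
  offsets <- rbind(
    N  = c(-1.2,  0.6, 0), CA = c(0, 0, 0), C = c(1.3, 0.5, 0),
    O  = c( 1.9,  1.5, 0.4), CB = c(-0.5, -1.4, 0.8)
  )
  elements <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  n <- nrow(ca_coords)
  res <- rep(seq_len(n), each = nrow(offsets))
  at <- rep(rownames(offsets), n)
  base <- ca_coords[res, , drop = FALSE] + offsets[at, , drop = FALSE]
  base <- base + matrix(stats::rnorm(length(base), sd = 0.05), nrow(base))
  data.frame(residue = res, atom = at, element = unname(elements[at]),
             x = base[, 1], y = base[, 2], z = base[, 3],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic proteome
#'
#' Sequences are i.i.d. over the 20 amino acids; C-alpha traces are
#' clash-avoiding 3.8 A random walks; per-residue confidence follows a
#' scaled Beta law; the pairwise error matrix grows with sequence
#' separation towards `pae_scale` plus non-negative noise. A configurable
#' fraction of entries are fragments or membrane proteins (with 4-6
#' passed quality checks), and a small share of proteins is generated
#' below the 100-residue analysis cutoff so the protein filter has work
#' to do.
#'
#' @param cfg a [synthetic_config()].
#' @param species species mnemonic (also seeds the species stream).
#' @param with_atoms generate pseudo-atom coordinates for SASA.
#' @return named list of [protein_record()]s.
#' @export
generate_proteome <- function(cfg, species = "SP01", with_atoms = TRUE) {
  set.seed(stage_seed(cfg, 101L + abs(sum(utf8ToInt(species)))))
  aa <- names(kyte_doolittle)
  out <- list()
  for (k in seq_len(cfg$proteins_per_species)) {
    len <- max(30L, round(stats::rlnorm(1, log(cfg$mean_protein_length), 0.35)))
    seq1 <- paste(sample(aa, len, replace = TRUE), collapse = "")
    ca <- random_backbone(len)
    plddt <- 100 * stats::rbeta(len, cfg$plddt_beta_params[1],
                                cfg$plddt_beta_params[2])
    sep <- abs(outer(seq_len(len), seq_len(len), `-`))
    pae <- cfg$pae_scale * (1 - exp(-sep / 30)) +
      abs(matrix(stats::rnorm(len^2, sd = 0.5), len))
    diag(pae) <- 0
    is_frag <- stats::runif(1) < cfg$fragment_fraction
    tm <- if (stats::runif(1) < cfg$tm_fraction) {
      sample(4:6, 1, prob = c(0.15, 0.15, 0.7))
    } else {
      NA_integer_
    }
    id <- sprintf("%s_P%04d", species, k)
    out[[id]] <- protein_record(
      protein_id = id, species = species, sequence = seq1, ca_coords = ca,
      plddt = plddt, pae = pae,
      atom_coords = if (with_atoms) pseudo_atoms(ca) else NULL,
      is_fragment = is_frag, tm_checks_passed = tm
    )
  }
  out
}

# Spatially contiguous residue set: the size nearest residues (by C-alpha
# distance) around a random seed residue.
spatial_patch <- function(protein, size, exclude = integer()) {
  n <- protein_length(protein)
  candidates <- setdiff(seq_len(n), exclude)
  if (length(candidates) == 0L) return(integer())
  seed_res <- resample(candidates, 1)
  d2 <- rowSums(sweep(protein$ca_coords, 2, protein$ca_coords[seed_res, ])^2)
  ord <- order(d2)
  ord <- ord[!(ord %in% exclude)]
  sort(ord[seq_len(min(size, length(ord)))])
}

# Solve per-class found probabilities such that every class named in the
# odds targets realises, in expectation, exactly that odds ratio of
# recovery versus the complement of all other classes. Unnamed classes
# keep the baseline rate, so the system has as many unknowns as
# constraints and is solved to numerical precision (least squares on the
# logit scale). An odds target of 0 forces the rate to 0.
solve_found_rates <- function(class_probs, odds_targets, baseline, n_iter = 500L) {
  cls <- names(class_probs)
  p <- rep(baseline, length(cls))
  names(p) <- cls
  if (baseline <= 0 || baseline >= 1) return(p)  # degenerate planting
  targets <- intersect(names(odds_targets), cls)
  if (length(targets) == 0L) return(p)
  or <- vapply(targets, function(cl) odds_targets[[cl]], 0)
  p[targets[or <= 0]] <- 0
  free <- match(targets[or > 0], cls)
  if (length(free) == 0L) return(p)
  log_or <- log(or[or > 0])
  obj <- function(x) {
    p[free] <- stats::plogis(x)
    resid <- vapply(seq_along(free), function(m) {
      k <- free[m]
      fr <- sum(class_probs[-k] * p[-k])
      nr <- sum(class_probs[-k] * (1 - p[-k]))
      stats::qlogis(p[k]) - log(fr / nr) - log_or[m]
    }, 0)
    sum(resid^2)
  }
  x0 <- stats::qlogis(baseline) + log_or
  fit <- stats::optim(x0, obj, method = "BFGS",
                      control = list(maxit = n_iter, reltol = 1e-14))
  p[free] <- stats::plogis(fit$par)
  p
}

#' Generate pockets and annotated sites for a proteome
#'
#' Pockets are spatial residue patches with lognormal sizes (median
#' `pocket_size_median`); annotated sites have median
#' `site_size_median` residues. Each site draws a ligand class from
#' `class_probs`, then its recovery ("found") status from a Bernoulli
#' law whose odds are the baseline odds times the planted class odds
#' ratio; found sites are placed overlapping a pocket, not-found sites
#' disjoint from all pockets of the protein. Sites are only placed on
#' pocket-bearing proteins so that planted odds are realised without
#' structural bias.
#'
#' @param cfg a [synthetic_config()].
#' @param proteome output of [generate_proteome()].
#' @return list with `pockets` ([pocket_table()]), `sites`
#'   ([known_site_table()]) and `site_classes` (planted class per site).
#' @export
generate_pockets_and_sites <- function(cfg, proteome) {
  species <- proteome[[1]]$species
  set.seed(stage_seed(cfg, 202L + abs(sum(utf8ToInt(species)))))
  found_rates <- solve_found_rates(cfg$class_probs, cfg$enrichment_odds,
                                   cfg$baseline_found_rate)
  p_id <- c(); p_prot <- c(); p_rank <- c(); p_prob <- c(); p_res <- list()
  s_id <- c(); s_prot <- c(); s_chebi <- c(); s_res <- list(); s_class <- c()
  leaf_ids <- synthetic_class_leaves()
  for (prot in proteome) {
    n_pockets <- stats::rpois(1, cfg$pocket_rate)
    min_len_for_pockets <- cfg$pocket_size_median * 2
    if (protein_length(prot) < min_len_for_pockets) n_pockets <- 0L
    if (n_pockets == 0L) next
    pocket_idx <- vector("list", n_pockets)
    probs <- stats::rbeta(n_pockets, 4, 1.5)
    for (q in seq_len(n_pockets)) {
      size <- max(4L, round(stats::rlnorm(1, log(cfg$pocket_size_median), 0.4)))
      size <- min(size, protein_length(prot))
      pocket_idx[[q]] <- spatial_patch(prot, size)
    }
    rank <- rank(-probs, ties.method = "first")
    for (q in seq_len(n_pockets)) {
      p_id <- c(p_id, sprintf("%s.pocket%d", prot$protein_id, rank[q]))
      p_prot <- c(p_prot, prot$protein_id)
      p_rank <- c(p_rank, rank[q])
      p_prob <- c(p_prob, round(probs[q], 4))
      p_res[[length(p_res) + 1L]] <-
        residue_set(prot$chain, pocket_idx[[q]])
    }
    all_pocket_res <- sort(unique(unlist(pocket_idx)))
    n_sites <- stats::rpois(1, cfg$site_rate)
    for (sdx in seq_len(n_sites)) {
      cl <- sample(names(cfg$class_probs), 1, prob = cfg$class_probs)
      found <- stats::runif(1) < found_rates[[cl]]
      size <- max(4L, round(stats::rlnorm(1, log(cfg$site_size_median), 0.35)))
      idx <- if (found) {
        src <- pocket_idx[[sample.int(n_pockets, 1)]]
        resample(src, min(size, length(src)))
      } else {
        free <- setdiff(seq_len(protein_length(prot)), all_pocket_res)
        if (length(free) < 4L) next
        patch <- spatial_patch(prot, size, exclude = all_pocket_res)
        if (length(patch) < 4L) next
        patch
      }
      sid <- sprintf("%s.site%d", prot$protein_id, sdx)
      s_id <- c(s_id, sid); s_prot <- c(s_prot, prot$protein_id)
      s_chebi <- c(s_chebi, leaf_ids[[cl]])
      s_class <- c(s_class, cl)
      s_res[[length(s_res) + 1L]] <- residue_set(prot$chain, sort(idx))
    }
  }
  list(
    pockets = pocket_table(p_id, p_prot, p_rank, p_prob, p_res),
    sites = known_site_table(s_id, s_prot, s_res, s_chebi),
    site_classes = stats::setNames(s_class, s_id)
  )
}

#' Synthetic compound ontology
#'
#' A small, synthetic child-to-parent edge list in which each compound
#' class has one leaf id reaching its first root through one
#' intermediate node. The ATP id (CHEBI:30616) is wired to the
#' nucleotide root so realistic queries resolve. This is a test fixture,
#' not a snapshot of the real ontology.
#'
#' @return a [compound_ontology()].
#' @export
synthetic_ontology <- function() {
  leaves <- synthetic_class_leaves()
  roots <- compound_classes()
  children <- character(); parents <- character()
  k <- 0L
  for (cl in names(roots)) {
    k <- k + 1L
    mid <- sprintf("CHEBI:91%03d", k)
    children <- c(children, leaves[[cl]], mid)
    parents <- c(parents, mid, roots[[cl]][1])
  }
  children <- c(children, "CHEBI:30616")
  parents <- c(parents, "CHEBI:92001")
  children <- c(children, "CHEBI:92001")
  parents <- c(parents, "CHEBI:36976")
  compound_ontology(children, parents)
}

# One synthetic leaf compound id per class; the "Other compounds" leaf has
# no path to any class root.
synthetic_class_leaves <- function() {
  roots <- compound_classes()
  leaves <- stats::setNames(sprintf("CHEBI:90%03d", seq_along(roots)),
                            names(roots))
  c(leaves, "Other compounds" = "CHEBI:90999")
}

#' Plant a similarity matrix with known structure
#'
#' Builds a sparse symmetric score matrix over `n_singletons` isolated
#' pockets plus communities of the given sizes. Each community is a
#' connected sparse random graph (spanning tree plus extra edges up to
#' about 2.5 per node) with scores uniform on \[3, 10\]; scores are
#' therefore always above 0.1 of the species maximum, so edge
#' thresholding never splits a planted community.
#'
#' @param species species mnemonic.
#' @param community_sizes integer vector of community sizes (each >= 2).
#' @param n_singletons number of isolated pockets.
#' @param seed RNG seed.
#' @return list with `sim` ([similarity_matrix()]) and `membership`
#'   (named vector: community index or `"singleton"`).
#' @export
plant_similarity <- function(species, community_sizes, n_singletons, seed = 1L) {
  stopifnot(all(community_sizes >= 2L))
  set.seed(seed)
  n <- n_singletons + sum(community_sizes)
  ids <- sprintf("%s_pk%05d", species, seq_len(n))
  membership <- rep("singleton", n)
  ii <- integer(); jj <- integer(); ss <- numeric()
  offset <- n_singletons
  for (cidx in seq_along(community_sizes)) {
    size <- community_sizes[cidx]
    nodes <- offset + seq_len(size)
    membership[nodes] <- as.character(cidx)
    # ring (connectivity) plus two random chords per node: minimum
    # within-community degree ~4, above the detachment threshold of the
    # constant Potts model at resolution 0.01 for sizes up to the cap,
    # so planted communities are recovered whole
    perm <- sample(nodes)
    ring <- cbind(perm, c(perm[-1], perm[1]))
    pairs <- if (size == 2L) ring[1, , drop = FALSE] else ring
    if (size > 4L) {
      have <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
      for (v in nodes) {
        others <- resample(setdiff(nodes, v), 2)
        for (u in others) {
          key <- paste(min(u, v), max(u, v))
          if (!(key %in% have)) {
            have <- c(have, key)
            pairs <- rbind(pairs, c(u, v))
          }
        }
      }
    }
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    ii <- c(ii, pairs[, 1]); jj <- c(jj, pairs[, 2])
    ss <- c(ss, stats::runif(nrow(pairs), 3, 10))
    offset <- offset + size
  }
  list(
    sim = similarity_matrix(ids, ii, jj, ss, species = species),
    membership = stats::setNames(membership, ids)
  )
}

# Draw community sizes from a truncated discrete power law and adjust
# them (largest first) so they sum exactly to `target`.
draw_community_sizes <- function(n_comm, target, power, max_size) {
  if (n_comm == 0L) {
    if (target != 0) stop("no communities but nonzero pocket budget", call. = FALSE)
    return(integer())
  }
  if (target < 2L * n_comm) {
    stop("infeasible planting: singleton fraction leaves fewer than 2 ",
         "pockets per community", call. = FALSE)
  }
  s <- 2:max_size
  w <- s^(-power)
  sizes <- sample(s, n_comm, replace = TRUE, prob = w)
  delta <- target - sum(sizes)
  # grow: spread the surplus over communities with headroom below the
  # size cap, largest-headroom-weighted, so the tail thickens without a
  # single community absorbing everything
  while (delta > 0L) {
    headroom <- pmax(max_size - sizes, 0L)
    if (sum(headroom) == 0L) {
      # every community at the cap: unavoidable overflow, spread evenly
      bump <- delta %/% n_comm
      sizes <- sizes + bump
      extra <- delta - bump * n_comm
      if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      delta <- 0L
    } else {
      k <- resample(which(headroom > 0L), 1)
      add <- min(delta, headroom[k])
      sizes[k] <- sizes[k] + add
      delta <- delta - add
    }
  }
  # shrink: trim the largest communities down towards the minimum of 2
  while (delta < 0L) {
    k <- which.max(sizes)
    sub <- min(-delta, sizes[k] - 2L)
    if (sub == 0L) stop("infeasible planting", call. = FALSE)
    sizes[k] <- sizes[k] - sub
    delta <- delta + sub
  }
  sizes
}

#' Generate a per-species similarity ensemble with a planted scaling law
#'
#' Fold-cluster counts are log-spaced over `n_fs_range`; total pocket
#' counts grow linearly with fold clusters (`pockets_per_fs`), while the
#' planted number of unique pockets follows
#' `N_unique = round(c * N_FS^a_true)`, split into singletons
#' (`singleton_fraction` of the unique budget) and power-law-sized
#' communities. Because pockets grow linearly but unique pockets
#' sub-linearly, community sizes grow with species size, mirroring the
#' crowding of pocket space in larger proteomes.
#'
#' @param cfg a [synthetic_config()].
#' @param scaling_noise_cv multiplicative lognormal noise on the planted
#'   unique counts (0 = exact planting).
#' @param counts_only skip matrix construction and return the planted
#'   counts only (fast path for fit-recovery studies).
#' @return list with `sims` (list of [similarity_matrix()]),
#'   `membership` (per species), `n_fs` (named vector), and `truth`
#'   (a [species_cluster_stats()] with the planted counts).
#' @export
generate_similarity_ensemble <- function(cfg, scaling_noise_cv = 0,
                                         counts_only = FALSE) {
  set.seed(stage_seed(cfg, 303L))
  sp <- species_names(cfg)
  n_fs <- round(exp(seq(log(cfg$n_fs_range[1]), log(cfg$n_fs_range[2]),
                        length.out = cfg$n_species)))
  names(n_fs) <- sp
  sims <- list(); membership <- list()
  truth <- NULL
  for (s in seq_along(sp)) {
    p_total <- max(4L, round(cfg$pockets_per_fs * n_fs[s]))
    u <- round(cfg$unique_coefficient * n_fs[s]^cfg$a_true *
                 if (scaling_noise_cv > 0) {
                   stats::rlnorm(1, 0, scaling_noise_cv)
                 } else 1)
    u <- max(1L, min(u, p_total))
    n_single <- round(cfg$singleton_fraction * u)
    n_comm <- u - n_single
    if (n_comm == 0L) {
      n_single <- p_total  # all pockets isolated
      sizes <- integer()
    } else {
      sizes <- draw_community_sizes(n_comm, p_total - n_single,
                                    cfg$community_size_power,
                                    cfg$max_community_size)
    }
    if (!counts_only) {
      planted <- plant_similarity(sp[s], sizes, n_single,
                                  seed = stage_seed(cfg, 400L + s))
      sims[[sp[s]]] <- planted$sim
      membership[[sp[s]]] <- planted$membership
    }
    truth <- rbind(truth, data.frame(
      species = sp[s], n_fs = n_fs[[s]],
      n_pocket_clusters = length(sizes) + n_single,
      n_communities = length(sizes), stringsAsFactors = FALSE
    ))
  }
  class(truth) <- c("species_cluster_stats", "data.frame")
  list(sims = sims, membership = membership, n_fs = n_fs, truth = truth)
}

#' Generate pocket embedding vectors with controllable kingdom mixing
#'
#' Vectors are drawn from a 128-dimensional Gaussian mixture. With
#' `kingdom_association = "none"` every kingdom shares the same
#' components, so any local region of the embedding holds a
#' kingdom-diverse population; with `"strong"` each kingdom has its own
#' component and local label entropy collapses to 0.
#'
#' @param cfg a [synthetic_config()].
#' @param labels data.frame with columns `pocket_id`, `species`,
#'   `kingdom` (one row per pocket); defaults to a balanced cohort of
#'   `n_per_species` pockets per species.
#' @param n_per_species cohort size when `labels` is NULL.
#' @return an [embedding_set()].
#' @export
generate_embeddings <- function(cfg, labels = NULL, n_per_species = 100L) {
  set.seed(stage_seed(cfg, 505L))
  if (is.null(labels)) {
    sp <- species_names(cfg)
    kg <- species_kingdoms(cfg)
    labels <- data.frame(
      pocket_id = sprintf("%s_pk%05d", rep(sp, each = n_per_species),
                          seq_len(n_per_species)),
      species = rep(sp, each = n_per_species),
      kingdom = rep(unname(kg), each = n_per_species),
      stringsAsFactors = FALSE
    )
  }
  n <- nrow(labels)
  kingdoms <- sort(unique(labels$kingdom))
  if (!is.null(cfg$kingdom_mixture)) {
    vec <- t(vapply(seq_len(n), function(i) {
      comp <- cfg$kingdom_mixture[[labels$kingdom[i]]]
      mu <- rep_len(comp$mean, 128)
      mu + stats::rnorm(128, sd = comp$sd)
    }, numeric(128)))
  } else if (cfg$kingdom_association == "strong") {
    centers <- matrix(stats::rnorm(length(kingdoms) * 128), length(kingdoms))
    centers <- centers / sqrt(rowSums(centers^2)) * cfg$component_separation
    comp <- match(labels$kingdom, kingdoms)
    vec <- centers[comp, , drop = FALSE] +
      matrix(stats::rnorm(n * 128), n)
  } else {
    centers <- matrix(stats::rnorm(cfg$n_components * 128), cfg$n_components)
    centers <- centers / sqrt(rowSums(centers^2)) * cfg$component_separation
    comp <- sample(cfg$n_components, n, replace = TRUE)
    vec <- centers[comp, , drop = FALSE] +
      matrix(stats::rnorm(n * 128), n)
  }
  embedding_set(labels$pocket_id, vec, labels)
}

#' Write a complete synthetic input tree
#'
#' Generates proteomes, pocket predictions, annotated sites, fold
#' clusters, domain annotations, the compound ontology, per-species
#' similarity matrices and pocket embeddings, and writes them in the
#' plain-text formats the readers consume.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if absent).
#' @param with_structures also write per-protein PDB and pairwise-error
#'   JSON files (slowest part; skip for graph-only work).
#' @return invisibly, a list of the generated in-memory objects.
#' @export
write_synthetic_inputs <- function(cfg, dir, with_structures = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("pockets", "similarity")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }
  if (with_structures) {
    for (d in c("structures", "pae")) {
      dir.create(file.path(dir, d), showWarnings = FALSE)
    }
  }
  sp <- species_names(cfg)
  kingdom <- species_kingdoms(cfg)
  proteomes <- list(); pockets <- list(); sites <- list(); classes <- c()
  set.seed(stage_seed(cfg, 606L))
  for (s in sp) {
    proteomes[[s]] <- generate_proteome(cfg, s)
    ps <- generate_pockets_and_sites(cfg, proteomes[[s]])
    pockets[[s]] <- ps$pockets
    sites[[s]] <- ps$sites
    classes <- c(classes, ps$site_classes)
    for (prot in proteomes[[s]]) {
      if (with_structures) {
        write_protein_pdb(prot, file.path(dir, "structures",
                                          paste0(prot$protein_id, ".pdb")))
        write_pae_json(prot$pae, file.path(dir, "pae",
                                           paste0(prot$protein_id, ".json")))
      }
      rows <- ps$pockets[ps$pockets$protein_id == prot$protein_id, , drop = FALSE]
      write_p2rank_table(rows, file.path(dir, "pockets",
                                         paste0(prot$protein_id, ".csv")))
    }
  }
  meta <- do.call(rbind, lapply(unlist(proteomes, recursive = FALSE),
                                function(p) data.frame(
    protein_id = p$protein_id, species = p$species,
    is_fragment = p$is_fragment, tm_checks_passed = p$tm_checks_passed,
    stringsAsFactors = FALSE
  )))
  utils::write.table(meta, file.path(dir, "proteins.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  all_sites <- do.call(rbind, unname(sites))
  write_annotation_table(all_sites, file.path(dir, "annotations.tsv"))
  write_ontology(synthetic_ontology(), file.path(dir, "ontology.tsv"))
  # fold clusters: proteins share a fold cluster in small random groups
  fold <- unlist(lapply(sp, function(s) {
    ids <- names(proteomes[[s]])
    n_clusters <- max(1L, round(length(ids) * 0.7))
    stats::setNames(sprintf("%s_FS%03d", s,
                            sample(n_clusters, length(ids), replace = TRUE)),
                    ids)
  }))
  write_fold_clusters(fold, file.path(dir, "fold_clusters.tsv"))
  # domain annotations: 0-2 random intervals per protein
  dom <- list()
  for (s in sp) for (prot in proteomes[[s]]) {
    nd <- sample(0:2, 1)
    if (nd == 0) next
    len <- protein_length(prot)
    starts <- sort(sample(seq_len(max(1, len - 30)), nd))
    dom[[length(dom) + 1L]] <- domain_table(
      prot$protein_id, sprintf("IPR%05d", sample(1e4, nd)),
      starts, pmin(starts + sample(20:60, nd, replace = TRUE), len),
      is_duf = stats::runif(nd) < 0.05
    )
  }
  write_domain_table(do.call(rbind, dom), file.path(dir, "domains.tsv"))
  ens <- generate_similarity_ensemble(cfg)
  for (s in sp) {
    write_similarity_matrix(ens$sims[[s]],
                            file.path(dir, "similarity", paste0(s, ".tsv")))
    writeLines(ens$sims[[s]]$pocket_ids,
               file.path(dir, "similarity", paste0(s, ".nodes")))
  }
  utils::write.table(ens$truth, file.path(dir, "fold_cluster_counts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  emb <- generate_embeddings(cfg)
  write_embeddings(emb, file.path(dir, "embeddings.tsv"),
                   file.path(dir, "embedding_labels.tsv"))
  invisible(list(proteomes = proteomes, pockets = pockets, sites = sites,
                 site_classes = classes, ensemble = ens, embeddings = emb,
                 fold_clusters = fold))
}
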