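# Generators: shape contracts, determinism, and recovery of planted
# statistical structure by the downstream estimators.

test_that("proteome generation honours shape contracts and the seed", {
  cfg <- synthetic_config(seed = 42, proteins_per_species = 3,
                          mean_protein_length = 100)
  prots <- generate_proteome(cfg, "SP01", with_atoms = FALSE)
  expect_length(prots, 3)
  for (p in prots) {
    n <- nchar(p$sequence)
    expect_length(p$plddt, n)
    expect_equal(dim(p$pae), c(n, n))
    expect_true(all(p$pae >= 0))
    expect_equal(dim(p$ca_coords), c(n, 3))
    # consecutive C-alpha atoms are one backbone step apart
    steps <- sqrt(rowSums(diff(p$ca_coords)^2))
    expect_equal(steps, rep(3.8, n - 1), tolerance = 1e-6)
  }
  again <- generate_proteome(cfg, "SP01", with_atoms = FALSE)
  expect_identical(prots, again)
})

test_that("per-residue confidence follows the configured Beta law", {
  cfg <- synthetic_config(seed = 3, proteins_per_species = 70,
                          mean_protein_length = 150,
                          plddt_beta_params = c(7, 1))
  prots <- generate_proteome(cfg, "SP01", with_atoms = FALSE)
  all_plddt <- unlist(lapply(prots, `[[`, "plddt"))
  expect_gt(length(all_plddt), 10000)
  beta_mean <- 100 * 7 / (7 + 1)
  expect_lt(abs(mean(all_plddt) - beta_mean), 2)
})

test_that("pocket and site size medians match the planted regime", {
  cfg <- synthetic_config(seed = 8, proteins_per_species = 120,
                          pocket_rate = 2, site_rate = 2)
  pro <- generate_proteome(cfg, "SP01", with_atoms = FALSE)
  ps <- generate_pockets_and_sites(cfg, pro)
  pocket_sizes <- vapply(ps$pockets$residues, nrow, 1L)
  site_sizes <- vapply(ps$sites$residues, nrow, 1L)
  expect_lt(abs(median(pocket_sizes) - 24), 3)
  expect_lt(abs(median(site_sizes) - 6), 2)
  # pockets are spatially compact: all residues within a ball around the
  # centroid far smaller than the protein extent
  p1 <- ps$pockets[1, ]
  prot <- pro[[p1$protein_id]]
  xyz <- prot$ca_coords[p1$residues[[1]]$index, ]
  r_pocket <- max(sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
  r_prot <- max(dist(prot$ca_coords)) / 2
  expect_lt(r_pocket, r_prot)
})

test_that("null and degenerate recovery plantings behave as configured", {
  # all odds 1: realized per-class odds ratios ~ 1 within Monte-Carlo error
  cfg <- synthetic_config(seed = 13, proteins_per_species = 200,
                          site_rate = 12, pocket_rate = 2,
                          enrichment_odds = c())
  pro <- generate_proteome(cfg, "SP01", with_atoms = FALSE)
  ps <- generate_pockets_and_sites(cfg, pro)
  m <- match_known_to_predicted(ps$sites, ps$pockets)
  classes <- lapply(ps$sites$ligand_chebi, assign_compound_class,
                    synthetic_ontology())
  enr <- enrichment_table(m$found, classes)
  big <- enr[enr$n_found + enr$n_not_found > 200, ]
  expect_true(all(abs(log(big$odds_ratio)) < log(1.5)))

  # recovery probability 0: every site is missed
  cfg0 <- synthetic_config(seed = 13, proteins_per_species = 30,
                           site_rate = 3, baseline_found_rate = 0,
                           enrichment_odds = c())
  pro0 <- generate_proteome(cfg0, "SP01", with_atoms = FALSE)
  ps0 <- generate_pockets_and_sites(cfg0, pro0)
  m0 <- match_known_to_predicted(ps0$sites, ps0$pockets)
  expect_true(nrow(ps0$sites) > 0)
  expect_false(any(m0$found))
})

test_that("planted class odds are recovered by the enrichment estimator", {
  cfg <- synthetic_config(
    seed = 21, proteins_per_species = 250, site_rate = 20, pocket_rate = 2,
    enrichment_odds = c("Nucleobases, nucleosides & nucleotides" = 8)
  )
  pro <- generate_proteome(cfg, "SP01", with_atoms = FALSE)
  ps <- generate_pockets_and_sites(cfg, pro)
  m <- match_known_to_predicted(ps$sites, ps$pockets)
  expect_gt(nrow(ps$sites), 3000)
  classes <- lapply(ps$sites$ligand_chebi, assign_compound_class,
                    synthetic_ontology())
  enr <- enrichment_table(m$found, classes)
  or_hat <- enr$odds_ratio[
    enr$class_name == "Nucleobases, nucleosides & nucleotides"]
  expect_lt(abs(or_hat - 8), 1)
})

test_that("similarity ensembles plant singletons, partitions and scaling", {
  # all-singleton limit: no off-diagonal entries at all
  cfg1 <- synthetic_config(seed = 4, n_species = 2, singleton_fraction = 1,
                           n_fs_range = c(100, 200), pockets_per_fs = 0.3)
  ens1 <- generate_similarity_ensemble(cfg1)
  for (sim in ens1$sims) {
    expect_equal(Matrix::nnzero(sim$scores), 0)
    expect_setequal(find_singletons(sim), sim$pocket_ids)
  }

  # separable planted partition: Leiden recovers it exactly
  planted <- plant_similarity("SPX", community_sizes = c(12, 20, 35, 9, 50),
                              n_singletons = 30, seed = 5)
  g <- build_graph(planted$sim)
  cl <- leiden_communities(g, singletons = find_singletons(planted$sim))
  expect_equal(cl$n_communities, 5)
  expect_equal(cl$n_singletons, 30)
  got <- lapply(cl$communities, sort)
  want <- split(names(planted$membership),
                planted$membership)[as.character(1:5)]
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(lapply(want, sort), paste, "", collapse = ","))

  # planted singleton fraction recovered exactly from the ground truth
  cfg2 <- synthetic_config(seed = 6, n_species = 3, singleton_fraction = 0.4)
  ens2 <- generate_similarity_ensemble(cfg2)
  for (s in names(ens2$sims)) {
    truth_singles <- names(ens2$membership[[s]])[
      ens2$membership[[s]] == "singleton"]
    expect_setequal(find_singletons(ens2$sims[[s]]), truth_singles)
  }

  # infeasible planting is refused
  cfg3 <- synthetic_config(seed = 6, n_species = 2, n_fs_range = c(50, 80),
                           singleton_fraction = 0.1)
  expect_error(generate_similarity_ensemble(cfg3), "infeasible")
})

test_that("embedding generation is seed-stable with the declared geometry", {
  cfg <- synthetic_config(seed = 17, n_species = 4)
  emb <- generate_embeddings(cfg, n_per_species = 25)
  expect_equal(dim(emb$vectors), c(100, 128))
  expect_identical(generate_embeddings(cfg, n_per_species = 25)$vectors,
                   emb$vectors)
  expect_equal(emb$labels$pocket_id, emb$pocket_ids)
})
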