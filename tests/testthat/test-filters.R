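# Inclusion rules: protein-level reasons, confidence means over pockets,
# strict exclusion boundaries, recall curves and idempotence.

test_that("protein-level rules fire in order with the right reasons", {
  cfg <- filter_config()
  short <- make_protein(n = 99)
  expect_false(protein_passes(short, cfg)$pass)
  expect_equal(protein_passes(short, cfg)$reason, "length")

  frag <- make_protein(n = 150, is_fragment = TRUE)
  expect_equal(protein_passes(frag, cfg)$reason, "fragment")

  tm5 <- make_protein(n = 150, tm = 5L)
  expect_false(protein_passes(tm5, cfg)$pass)
  expect_equal(protein_passes(tm5, cfg)$reason, "tm_checks")
  expect_true(protein_passes(make_protein(n = 150, tm = 6L), cfg)$pass)

  # boundary inclusive: exactly 100 residues pass
  expect_true(protein_passes(make_protein(n = 100), cfg)$pass)
})

test_that("pocket confidence means follow the stated definitions", {
  p <- make_protein(n = 6, plddt = rep(80, 6))
  res <- residue_set("A", 1:4)
  expect_equal(pocket_mean_plddt(res, p), 80)

  # constant matrix value c -> mean c
  p2 <- make_protein(n = 6, pae = matrix(3.5, 6, 6))
  expect_equal(pocket_mean_pae(res, p2), 3.5)

  # 2-residue pocket over submatrix [[0,4],[6,0]]: mean over all 4
  # ordered pairs including the diagonal
  pae <- matrix(0, 6, 6)
  pae[2, 5] <- 4; pae[5, 2] <- 6
  p3 <- make_protein(n = 6, pae = pae)
  expect_equal(pocket_mean_pae(residue_set("A", c(2, 5)), p3), 2.5)

  expect_error(pocket_mean_plddt(residue_set("A", 7), p), "outside")
})

test_that("pocket exclusion is strict while inclusion holds the boundary", {
  prot <- make_protein(n = 20, plddt = rep(70, 20),
                       pae = matrix(10, 20, 20))
  cfg <- filter_config()
  boundary <- make_pocket(idx = 1:6, probability = 0.5)
  expect_true(pocket_passes(boundary[1, ], prot, cfg)$pass)

  low_prob <- make_pocket(idx = 1:6, probability = 0.49)
  expect_equal(pocket_passes(low_prob[1, ], prot, cfg)$reason, "probability")

  low_conf <- make_protein(n = 20, plddt = rep(69.9, 20))
  expect_equal(pocket_passes(boundary[1, ], low_conf, cfg)$reason, "plddt")

  high_err <- make_protein(n = 20, pae = matrix(10.1, 20, 20) - diag(20) * 10.1)
  # mean over pairs < 10 here because the diagonal is zero; force all-10.1
  high_err$pae <- matrix(10.1, 20, 20)
  expect_equal(pocket_passes(boundary[1, ], high_err, cfg)$reason, "pae")
})

test_that("cohort filtering equals the brute-force rule and is idempotent", {
  cfg_s <- synthetic_config(seed = 31, proteins_per_species = 40,
                            pocket_rate = 2)
  proteins <- generate_proteome(cfg_s, "SP01", with_atoms = FALSE)
  ps <- generate_pockets_and_sites(cfg_s, proteins)
  fcfg <- filter_config()
  got <- filter_cohort(ps$pockets, proteins, fcfg)

  keep <- vapply(seq_len(nrow(ps$pockets)), function(r) {
    prot <- proteins[[ps$pockets$protein_id[r]]]
    protein_passes(prot, fcfg)$pass &&
      ps$pockets$probability[r] >= fcfg$probability_threshold &&
      pocket_mean_plddt(ps$pockets$residues[[r]], prot) >= fcfg$min_pocket_plddt &&
      pocket_mean_pae(ps$pockets$residues[[r]], prot) <= fcfg$max_pocket_pae
  }, TRUE)
  expect_equal(got$pockets$pocket_id, ps$pockets$pocket_id[keep])
  expect_gt(nrow(got$pockets), 0)
  expect_lt(nrow(got$pockets), nrow(ps$pockets))

  twice <- filter_cohort(got$pockets, proteins, fcfg)
  expect_equal(twice$pockets, got$pockets)
})

test_that("recall is non-increasing in the threshold and recovers planting", {
  pockets <- rbind(make_pocket("p1", "P1", 1:10, 0.9),
                   make_pocket("p2", "P2", 1:10, 0.3))
  sites <- rbind(make_site("s1", "P1", 5:8), make_site("s2", "P2", 5:8))
  rc <- recall_vs_threshold(pockets, sites, c(0.2, 0.5, 0.95))
  expect_equal(rc$recall, c(1, 0.5, 0))
  expect_true(all(diff(rc$recall) <= 0))

  # no overlap anywhere: recall 0 at every threshold
  far <- rbind(make_site("s1", "P1", 90:95), make_site("s2", "P2", 90:95))
  rc0 <- recall_vs_threshold(pockets, far, c(0, 0.5, 1))
  expect_equal(rc0$recall, c(0, 0, 0))

  expect_error(recall_vs_threshold(pockets, sites[0, ], 0.5), "no known sites")

  # planted recall at the 0.5 cut is recovered on a synthetic cohort
  cfg_s <- synthetic_config(seed = 77, proteins_per_species = 300,
                            site_rate = 12, pocket_rate = 2,
                            baseline_found_rate = 0.6, enrichment_odds = c())
  proteins <- generate_proteome(cfg_s, "SP01", with_atoms = FALSE)
  ps <- generate_pockets_and_sites(cfg_s, proteins)
  rc <- recall_vs_threshold(ps$pockets, ps$sites, 0)
  expect_gt(nrow(ps$sites), 2000)
  expect_lt(abs(rc$recall - 0.6), 0.02)
})
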