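# Site splitting, overlap matching, ontology ascent, enrichment
# statistics and group contrasts.

test_that("inter-chain sites split into spatial components", {
  # two 4-residue groups with all inter-group distances > 12 A
  coords <- list(A = rbind(matrix(c(0, 0, 0), 4, 3, byrow = TRUE) +
                             cbind(3.8 * (0:3), 0, 0),
                           cbind(3.8 * (0:3), 100, 0)))
  site <- known_site_table("s", "P1", list(residue_set("A", 1:8)),
                           "CHEBI:90001")
  parts <- split_interchain_site(site, coords)
  expect_equal(nrow(parts), 2)
  expect_equal(sort(unlist(lapply(parts$residues, function(r) r$index))), 1:8)

  # collinear residues 11 A apart chain into one component
  coords2 <- list(A = cbind(11 * (0:7), 0, 0))
  parts2 <- split_interchain_site(site, coords2)
  expect_equal(nrow(parts2), 1)
  expect_equal(parts2$site_id, "s")

  # components below the residue minimum are dropped
  coords3 <- list(A = rbind(cbind(3.8 * (0:5), 0, 0),
                            cbind(3.8 * (0:1), 100, 0)))
  parts3 <- split_interchain_site(site, coords3)
  expect_equal(nrow(parts3), 1)
  expect_equal(nrow(parts3$residues[[1]]), 6)

  expect_error(split_interchain_site(site, list(A = cbind(0, 0, 0))),
               "missing C-alpha")
})

test_that("component splitting matches a union-find oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n <- 30
    xyz <- matrix(runif(n * 3, 0, 40), n)
    site <- known_site_table("s", "P1", list(residue_set("A", 1:n)), NA)
    parts <- split_interchain_site(site, list(A = xyz), min_residues = 1L)
    d <- as.matrix(dist(xyz))
    edges <- which(d <= 12 & upper.tri(d), arr.ind = TRUE)
    oracle <- uf_components(n, edges)
    expect_equal(nrow(parts), length(unique(oracle)))
    got_sets <- lapply(parts$residues, function(r) sort(r$index))
    want_sets <- unname(lapply(split(1:n, oracle), sort))
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(want_sets, paste, "", collapse = ","))
    # output residue sets partition the input
    expect_setequal(unlist(got_sets), 1:n)
  }
})

test_that("overlap matching requires one shared residue on the same protein", {
  pockets <- make_pocket("p1", "P1", 10:20)
  expect_true(match_known_to_predicted(
    make_site("s", "P1", 10:20), pockets)$found)
  expect_false(match_known_to_predicted(
    make_site("s", "P1", 30:35), pockets)$found)
  # exactly one shared residue counts
  m <- match_known_to_predicted(make_site("s", "P1", 20:25), pockets)
  expect_true(m$found)
  expect_equal(m$matched_pockets[[1]], "p1")
  # same residues on a different protein never match
  expect_false(match_known_to_predicted(
    make_site("s", "P2", 10:20), pockets)$found)
})

test_that("ontology ascent assigns every reachable class", {
  ont <- synthetic_ontology()
  # an id that is itself a root: zero-step ascent
  expect_equal(assign_compound_class("CHEBI:36914", ont), "Inorganic ions")
  # no path to any root
  expect_equal(assign_compound_class("CHEBI:90999", ont), "Other compounds")
  # ATP ascends to the nucleotide root through an intermediate
  expect_equal(assign_compound_class("CHEBI:30616", ont),
               "Nucleobases, nucleosides & nucleotides")
  # multi-parent ids may reach several classes
  multi <- compound_ontology(
    children = c("CHEBI:1", "CHEBI:1"),
    parents = c("CHEBI:18059", "CHEBI:36914")
  )
  expect_setequal(assign_compound_class("CHEBI:1", multi),
                  c("Lipids", "Inorganic ions"))
  cyc <- compound_ontology(children = c("CHEBI:1", "CHEBI:2"),
                           parents = c("CHEBI:2", "CHEBI:1"))
  expect_error(assign_compound_class("CHEBI:1", cyc), "cycle")
})

test_that("sample odds ratios and Fisher p-values are exact", {
  # zero cells force 0 or Inf
  expect_equal(sample_odds_ratio(0, 7, 100, 100), 0)
  expect_true(is.infinite(sample_odds_ratio(5, 0, 100, 100)))
  expect_error(sample_odds_ratio(101, 7, 100, 100), "exceed")

  # Fisher p equals hypergeometric enumeration on small tables
  found <- c(rep(TRUE, 3), rep(FALSE, 3))
  classes <- list("X", "X", "Y", "X", "Y", "Y")
  enr <- enrichment_table(found, classes)
  px <- enr$p_value[enr$class_name == "X"]
  expect_equal(px, fisher_p_enum(2, 1, 1, 2), tolerance = 1e-12)
})

test_that("adjusted p-values are monotone and never below raw values", {
  set.seed(7)
  found <- runif(400) < 0.5
  classes <- lapply(seq_along(found), function(i) {
    sample(LETTERS[1:6], sample(1:2, 1))
  })
  enr <- enrichment_table(found, classes)
  expect_true(all(enr$p_adj >= enr$p_value - 1e-12))
  ord <- order(enr$p_value)
  expect_true(all(diff(enr$p_adj[ord]) >= -1e-12))
  expect_true(all(enr$p_adj <= 1))
  # multi-class sites: per-class totals may exceed the unique-site totals
  expect_gte(sum(enr$n_found), sum(found))
})

test_that("domain context categories cover all interface cases", {
  doms <- domain_table(c("P1", "P1"), c("IPR1", "IPR2"), c(10, 50),
                       c(30, 80), c(FALSE, TRUE))
  expect_equal(classify_pocket_domains(residue_set("A", 1:5), doms)$category,
               "no_domain")
  expect_equal(classify_pocket_domains(residue_set("A", 12:20), doms)$category,
               "single_domain")
  out <- classify_pocket_domains(residue_set("A", c(25:30, 50:55)), doms)
  expect_equal(out$category, "inter_domain")
  expect_setequal(out$domain_ids, c("IPR1", "IPR2"))
  expect_false(out$duf)
  expect_equal(classify_pocket_domains(residue_set("A", c(28:32, 40:44)),
                                       doms)$category, "domain_no_domain")
  duf <- classify_pocket_domains(residue_set("A", 55:60), doms)
  expect_true(duf$duf)
})

test_that("group contrasts produce pooled-SD effect sizes", {
  # hand-computed: {0,1} vs {1,2} -> pooled SD sqrt(0.5), d = -sqrt(2)
  expect_equal(cohens_d(c(0, 1), c(1, 2)), -sqrt(2))

  df <- data.frame(v = c(1, 2, 3, 1, 2, 3))
  ct <- contrast_groups(df, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(ct$cohens_d, 0)

  # planted standardized shift recovered at n = 5000 per group
  set.seed(123)
  x <- rnorm(5000, mean = 0.74); y <- rnorm(5000)
  ct2 <- contrast_groups(data.frame(p = c(x, y)),
                         rep(c(TRUE, FALSE), each = 5000))
  expect_lt(abs(ct2$cohens_d - 0.74), 0.05)
  expect_lt(ct2$p_value, 1e-10)
  expect_equal(ct2$median_group1, median(x))
})
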