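# pocketome

Statistics for comparative, multi-species surveys of predicted protein
binding pockets ("pocketomes"). The package is aimed at structural
bioinformaticians who already run the heavy upstream tools — proteome-scale
structure prediction, pocket prediction, pairwise pocket alignment, pocket
embedding networks, fold clustering — and need the downstream analysis to be
reproducible and tested:

* **Quality filtering** of proteins (fragments, length < 100, failed
  membrane-model checks) and pockets (ligandability probability ≥ 0.5,
  mean pLDDT ≥ 70, mean PAE ≤ 10 Å);
* **Pocket descriptors**: Kyte–Doolittle hydropathy (GRAVY), aromatic
  fraction, net charge at pH 7, and relative solvent-accessible surface
  area by Shrake–Rupley sphere-point sampling normalised by theoretical
  maximum ASA;
* **Ligand-class enrichment** among recovered ("found") annotated sites:
  sample odds ratios `(a/b)/((F−a)/(NF−b))` on unique-site totals,
  two-sided Fisher exact tests, Benjamini–Yekutieli FDR;
* **Per-species pocket-similarity clustering**: max-normalised score
  graphs, alignment-based singletons, Leiden communities (CPM,
  resolution 0.01), and three null models (degree-preserving rewiring,
  same-density random graphs, score-matrix permutation);
* **The proteome→pocketome scaling law**: ordinary least squares of
  `ln N_pockets` on `ln N_FS` across species, whose slope `a` in
  `N_pockets ∝ N_FS^a` measures whether pocket diversity grows
  sub-linearly (`a < 1`) with fold diversity;
* **Entropy maps** over 2D projections (exact t-SNE, PCA, FastICA) of
  128-d pocket embeddings: per grid bin, `S = −Σ p_i ln p_i` over kingdom
  or species labels, with sparse bins masked;
* A **synthetic-data module** that generates every pipeline input with
  plantable structure (enrichment odds, community sizes, singleton
  fractions, scaling exponents, kingdom mixtures), so the whole analysis
  is testable without any download.

## Worked example

Odds ratios from the bundled reference survey counts (11 species, 22,371
unique annotated sites, 52.1% recovered):

```r
library(pocketome)
tot <- reference_found_totals()
cc  <- reference_class_counts()
or  <- sapply(seq_len(nrow(cc)), function(i)
  sample_odds_ratio(cc$n_found[i], cc$n_not_found[i], tot$found, tot$not_found))
data.frame(class = cc$class_name, found = cc$n_found,
           not_found = cc$n_not_found, odds_ratio = round(or, 2))[1:4, ]
#>                            class found not_found odds_ratio
#> 1 Nucleobases, nucleosides & nuc  8092      2244       8.55
#> 2                 Inorganic ions  1191      7265       0.05
#> 3                Other compounds  1114       296       3.72
#> 4    Carbohydrates & derivatives   548       103       5.08
```

Nucleotide-binding sites are strongly enriched among recovered sites
(they are deep, hallmark pockets); inorganic-ion sites — small,
charge-driven, often flat — are strongly depleted.

A synthetic six-species ensemble with a planted scaling exponent of 0.5,
clustered and fitted end to end:

```r
cfg <- synthetic_config(seed = 1, n_species = 6)
ens <- generate_similarity_ensemble(cfg)
stats <- do.call(rbind, lapply(ens$sims, function(sim) {
  r <- leiden_communities(build_graph(sim), singletons = find_singletons(sim))
  species_cluster_stats(sim$species, ens$n_fs[[sim$species]],
                        r$n_unique, r$n_communities)
}))
fit_power_law(stats)
#> <scaling_fit: slope 0.509, intercept 1.328, r 1.000, n 6>

null_scaling(ens$sims, ens$n_fs, "degree_preserving",
             n_replicates = 3, seed = 2)
#> degree-preserving null: a = 0.657 +/- 0.013
```

The fitted exponent recovers the planted 0.5; degree-preserving
randomisation destroys community reuse and pushes the null exponent
toward 1 — diversity grows faster in the null than in the structured
graph, the signature of a pocketome diversity plateau.

A complete synthetic input tree and the full pipeline:

```r
cfg <- synthetic_config(seed = 2, n_species = 2, proteins_per_species = 5)
write_synthetic_inputs(cfg, "inputs/")
run_pipeline(pipeline_config("inputs/", "out/", seed = 4))
```

writes per-stage TSVs (filter summary, enrichment, descriptors,
clustering, projection, entropy grid) plus `summary.json`.

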