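---
title: "Methods: comparative analysis of predicted binding-pocket repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of predicted binding-pocket repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketome)
```

## The problem

A species' *pocketome* is the set of small-molecule binding sites carried
by its proteome. With predicted structures available for entire
proteomes, pocket-prediction tools can propose candidate binding sites
at proteome scale, and pocket-comparison tools can quantify how similar
those sites are to one another. This package implements the downstream
statistics of such a survey: it consumes the outputs of the upstream
tools (pocket tables, model-confidence data, pairwise pocket-alignment
scores, pocket embedding vectors, fold-cluster assignments) and turns
them into filtered cohorts, physicochemical descriptors, ligand-class
enrichment tables, per-species clusterings with null models, a
cross-species scaling exponent, and label-entropy maps over embedding
projections. The upstream tools themselves (structure prediction,
pocket prediction, pocket alignment, embedding networks, fold
clustering) are out of scope; their outputs are file-format contracts.

Because real inputs at survey scale are bulky and tool-dependent, the
package ships a first-class synthetic-data module that emulates every
input with controllable statistical structure. All statistical claims
made by the test suite are claims about these synthetic regimes; the
section on the generator below states exactly what is and is not
emulated.

## Filtering model

Proteins are excluded when they are database fragments, shorter than
100 residues (pocket predictors under-predict on very short chains), or
membrane proteins passing fewer than six of six external
membrane-model quality checks (consumed as an integer per protein,
never recomputed). Pockets are excluded when their ligandability
probability is below 0.5, or their model confidence is poor: mean
per-residue pLDDT below 70, or mean predicted aligned error (PAE) above
10 Å. Conventions fixed here and tested:

* the probability cut is inclusive (a pocket at exactly 0.5 passes);
* confidence exclusion is strict (mean pLDDT exactly 70 or mean PAE
  exactly 10 Å passes), matching the inequality direction in which the
  thresholds are quoted;
* the pocket PAE is the mean over **all ordered residue pairs** of the
  pocket, diagonal included, on the stored matrix — PAE is directional
  and is never symmetrised;
* a pocket on a failing protein is removed regardless of its own scores.

`recall_vs_threshold()` reports, for a threshold grid, the fraction of
annotated sites (at least 4 residues) overlapped by any pocket at or
above the threshold; it is non-increasing by construction.

## Pocket descriptors

Five descriptors are computed per pocket from its lining residues, plus
the two confidence means and the residue count:

* **hydropathy** — mean Kyte–Doolittle value (GRAVY);
* **aromaticity** — relative frequency of Phe/Trp/Tyr;
* **net charge** at pH 7 — Asp/Glu −1, Lys/Arg +1, His +0.5, others 0;
* **relative SASA** — Shrake–Rupley solvent-accessible surface area
  (probe 1.4 Å, 960 sphere points per atom by default), summed over
  pocket residues and divided by the **sum** of the per-residue-type
  theoretical maximum ASA values (Tien et al. theoretical column).
  Sum-over-sum gives a single well-defined ratio per pocket rather than
  a mean of noisy per-residue ratios.

Numerical choices for SASA: the sphere-point quadrature grid is
oriented in the molecule's principal-axes frame with third-moment sign
fixing, which makes the computed areas invariant under rigid rotation
and translation of the input coordinates to floating-point precision —
a lab-frame grid would only be invariant to about one part in the
point count. SASA is computed on the whole protein, not the isolated
pocket; pocket-only computation would count interior contact surface
as accessible and systematically inflate the ratio. Non-standard
residue codes are rejected with an error rather than silently skipped,
since predicted model files contain only the 20 standard residues.

## Annotated-site processing and enrichment

Annotated sites spanning several chains are split by building a graph
on the site residues with edges at Cα–Cα distance ≤ 12 Å (inclusive —
the boundary convention is fixed and documented here) and taking
connected components; components below 4 residues are dropped. A site
is **found** when it shares at least one (chain, index) residue with a
same-protein predicted pocket.

Ligands are mapped to compound classes by ascending the
compound-ontology parent relation transitively and collecting every
class whose root set is reached; a ligand reaching no root is "Other
compounds", and one ligand may belong to several classes. Enrichment
of each class among found sites uses the 2×2 table
`[[a, b], [F − a, NF − b]]`, where `a`/`b` are the class's found and
not-found counts and `F`/`NF` the **unique-site** totals. Because of
multi-class ligands the per-class counts may sum to more than `F`;
totals are deliberately kept at unique sites, which is the convention
under which the bundled reference counts reproduce their published
odds ratios. The odds ratio is the sample (cross-product) estimate
`(a/b) / ((F−a)/(NF−b))` — not the conditional maximum-likelihood
estimate that `fisher.test()` reports — with zero cells giving 0 or
infinity as the formula forces. P-values are two-sided Fisher exact
tests, adjusted with Benjamini–Yekutieli, which controls the false
discovery rate under arbitrary dependence (the per-class tests share
their margins, so independence cannot be assumed).

Singleton/non-singleton descriptor contrasts use Welch's two-sample
t-test (the variant is not critical: the reported effect size is
Cohen's d with pooled standard deviation, which is
variant-independent) and report group medians.

Domain context categories are mutually exclusive with the precedence:
`no_domain` (no residue in any domain interval), then
`domain_no_domain` (at least one residue inside and one outside),
then `inter_domain` (all residues covered, ≥ 2 distinct domain ids),
else `single_domain`; the DUF flag is set when all assigned domains
are domains of unknown function.

## Similarity graphs, clustering and null models

Per species, raw pairwise alignment scores (absent entry = the pair
cannot be aligned) are normalised by the species maximum. Two graphs
are kept: a weighted graph over all scored pairs and an unweighted
graph with an edge where the normalised score **strictly** exceeds
0.1. **Singletons** are defined on the raw scores — no nonzero
alignment to any other pocket — before normalisation or thresholding;
nodes isolated only by the 0.1 cut are tracked separately as
"threshold-isolated" and are not counted as singletons or communities.

Communities are found with the Leiden algorithm under the constant
Potts model (CPM) objective at resolution 0.01 (modularity is
available via the `weighted`/objective arguments of the underlying
igraph call but CPM is the cited function's default objective);
degree-0 nodes are held out before clustering and never merged. The
unique-pocket count of a species is communities plus singletons.

Three null models are provided: degree-preserving rewiring by double
edge swaps, same-density uniform random graphs, and symmetric
permutation of the score multiset over random off-diagonal positions.
The rewiring budget defaults to 10 × |E| attempted swaps: a constant
number of swap attempts cannot mix graphs whose edge counts span
orders of magnitude across species, so the budget scales with the
edge count (it is configurable for anyone wanting a literal small
budget).

The community-size histogram's log-log slope is fitted by ordinary
least squares weighted by bin frequency; unweighted log-count
regression is dominated by the one-count tail bins, whose log counts
are pure noise.

## The scaling law

Across species, the unique-pocket count is regressed on the
fold-cluster count on natural-log scales:
`ln N_pockets = intercept + a · ln N_FS`. The slope `a` is the scaling
exponent (`a < 1` means sub-linear growth of pocketome diversity with
proteome diversity), the intercept is reported on the natural-log
scale, and the Pearson correlation is computed on the log-log pairs.
Natural logarithms are used throughout; the slope is base-invariant
but the intercept is only meaningful with the base stated.
Fold-cluster counts are always an input column (from file or the
generator), never computed — fold clustering is an external tool's
job. `null_scaling()` re-randomises every species' graph, re-clusters,
recounts and refits per replicate, reporting the mean and standard
deviation of the null slope.

## Embedding projections and binned entropy

128-dimensional pocket embedding vectors are projected to 2D by exact
t-SNE (O(n²) dense implementation: per-row bandwidth search to the
target perplexity, early exaggeration 12 for 250 iterations, momentum
switch 0.5 → 0.8, learning rate `max(n/12, 50)`), PCA, or FastICA
(symmetric decorrelation, logcosh contrast). The dense t-SNE
formulation is appropriate at the cohort sizes the package projects
per call (thousands of pockets); it is deterministic given the seed.

The label-entropy map overlays a regular grid (default 50 × 50 over
the projection bounding box; the geometry is a package default, not an
external convention) and computes per bin the Shannon entropy
`S = −Σ p_i ln p_i` of the label distribution, with `p_i` the fraction
of the bin's pockets carrying label `i` among the `N` categories
present in the whole dataset, `0 · ln 0 := 0`, and natural logs (so
`0 ≤ S ≤ ln N`). Bins with fewer than 20 pockets are masked: no
robust entropy estimate exists there, and the masked-bin count is
monotone in the threshold by construction.

## The synthetic-data generator

The generator is the package's study-condition definition; its
defaults are fixed and the tests interrogate them.

* **Proteomes** — i.i.d. sequences over the 20 amino acids; Cα traces
  are clash-avoiding 3.8 Å random walks; per-residue confidence is
  `100 × Beta(7, 1)` (median ≈ 90, matching well-modelled proteomes);
  PAE grows with sequence separation towards 5 Å plus non-negative
  noise. Five pseudo-atoms per residue support SASA. A 5% fragment
  share, a 20% membrane-protein share (4–6 passed checks) and a
  lognormal length law with mass below 100 residues give the filters
  real work.
* **Pockets and sites** — pockets are spatial balls of residues around
  a seed residue with lognormal sizes of median 24; annotated sites
  have median 6. Each site draws a ligand class from frequencies
  shaped like a real annotation corpus (nucleotides and inorganic ions
  dominant), then its recovery status from a Bernoulli law whose
  per-class rates are solved (least squares on the logit scale) so
  that every class named in `enrichment_odds` realises exactly its
  planted odds ratio *versus the complement of all other classes*;
  unnamed classes stay at the baseline rate of 0.5. The default
  planted odds (8.55, 0.05, 5.08, 5.97, 0.17 for nucleotides,
  inorganic ions, carbohydrates, hemes and hetero-nuclear clusters)
  span strong enrichment to strong depletion. Found sites are placed
  inside a pocket, missed sites disjoint from all pockets, and sites
  are only placed on pocket-bearing proteins so the planted odds are
  realised without structural bias.
* **Similarity ensembles** — fold-cluster counts are log-spaced over
  500–5000 across 11 species; total pockets grow linearly with fold
  clusters (0.5 pockets per fold cluster) while planted unique pockets
  follow `round(4 · N_FS^0.5)` — the sub-linear planted exponent of
  0.5. Sixty percent of the unique budget is singletons; the rest are
  communities with truncated power-law sizes (exponent 2, cap 300)
  adjusted to the exact pocket budget, so community sizes grow with
  species size, emulating the crowding of pocket space in larger
  proteomes. Each community is a ring plus two random chords per node
  (minimum within-degree ≈ 4), which keeps every node above the CPM
  detachment threshold `γ(n − 1) ≤ 3` at resolution 0.01 up to the
  size cap — planted communities are therefore recovered essentially
  whole, and the infeasible corner (singleton budget leaving fewer
  than two pockets per community) raises an error rather than bending
  the planting. Scores are uniform on [3, 10], so the 0.1
  max-normalised edge cut can never split a planted community. Under
  degree-preserving rewiring this planting produces null exponents
  around 0.6 against planted 0.5: community structure is destroyed,
  community counts become proportional to (linear) pocket counts, and
  the null slope moves toward 1 — the qualitative ordering the real
  survey statistic shows.
* **Embeddings** — 128-d Gaussian mixtures. With shared components the
  local kingdom entropy approaches `ln(number of kingdoms)`; with one
  component per kingdom it collapses to 0.

All generators are pure functions of the configuration and master
seed, with per-stage streams derived by fixed offsets.

What the generator does **not** emulate: real fold geometry and
sequence–structure coupling, realistic alignment-score distributions
(planted scores are uniform and block-structured), inter-species
pocket homology, correlated annotation noise, and multi-chain
complexes. Passing tests therefore demonstrate the correctness and
calibration of the statistics under controlled regimes, not the
biological conclusions one would draw from real surveys.

## Problem sizes

The test suite and the acceptance script run the synthetic regimes at
deliberately modest sizes — species with hundreds to a few thousand
pockets, ensembles of 6–11 species, 10–100 replicates for recovery
studies, 60–960 sphere points for SASA — chosen so the full suite
completes in well under two minutes of statistics-heavy computation
while keeping Monte-Carlo error far inside the asserted tolerances.

## Known limitations

* Residue numbering is assumed to agree between structure models and
  annotations (true for model-database monomers); no renumbering is
  attempted.
* UMAP is not offered as a projection method (no suitable
  implementation among the package's dependencies); t-SNE, PCA and ICA
  cover the local/global spectrum used in practice.
* The exact t-SNE is quadratic in the number of pockets; cohorts far
  beyond ~10⁴ pockets need subsampling.
* `fisher.test()`'s conditional-MLE odds ratio will differ from the
  reported sample odds ratio; only the latter is used, by design.
* Multi-model structure files and mmCIF writing are unsupported.
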