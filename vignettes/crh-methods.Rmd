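---
title: "Cis-regulatory hubs: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cis-regulatory hubs: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crhub)
```

## The model and its assumptions

`crhub` links distal regulatory elements to genes with the
activity-by-contact (ABC) score and organises the resulting links into
cis-regulatory hubs (CRHs). The ingredients are deliberately simple:

* **Activity** of a candidate element (a DNAse peak) is the geometric mean
  of its DNAse accessibility signal and its H3K27ac occupancy signal. The
  geometric mean encodes an AND: a peak with no acetylation has zero
  activity and can never form a functional link, which is how the model
  separates *active* elements from merely accessible *candidate* elements.
* **Contact** is the binned intra-chromosomal Hi-C count between the
  element's bin and the TSS's bin, at the matrix's resolution (10-kb bins
  by default). Same-bin pairs read the diagonal entry. Scoring uses raw
  counts by default; `balance()` provides a doubly-stochastic scaling for
  workflows that want normalised matrices, and `compute_abc_scores()`
  accepts either. This order of preference — raw for scoring, balanced
  elsewhere — reflects how the score was used in the analyses the package
  reproduces, and differs from the original ABC formulation; it is a flag,
  not a hard-coded choice.
* **Score**: for gene *g*, each candidate element within the scoring window
  contributes `activity * contact`, normalised by the sum over all
  candidate elements in the window. Scores therefore sum to one per gene
  (or are all zero when nothing in the window has signal and contact — a
  warning, not an error). The denominator includes *all* candidate
  elements in the window, not only those that end up functional, and does
  not include the gene's own promoter; an `include`-promoter variant of
  the original model can be emulated by adding the promoter as an element.
* **Functional pairs and hubs**: a pair is functional when its score
  reaches the threshold (boundary inclusive — scores are real-valued, so
  ties are measure-zero, and inclusiveness makes the rule deterministic).
  CRHs are the connected components of the bipartite graph of functional
  pairs. Nothing finer than connectivity is inferred: no community
  detection, no edge weighting.

The model assumes bulk contact maps (a hub may merge contacts from
distinct cell subpopulations), assumes peak signal is comparable across
elements, and treats strand as irrelevant (contacts and peaks are
unstranded; strand is carried through but ignored by overlap logic).

## Coordinates and interval logic

All coordinates are 0-based, half-open `[start, end)` — the BED convention
of every format the package reads (BED3/6, narrowPeak, bedGraph). Touching
intervals do not overlap; one shared base is an overlap. SNP files use the
conventional 1-based `BP` column and are converted at the boundary by
`read_snps()`/`write_snps()`. Overlap queries and merging are delegated to
IRanges behind tidy, tibble-in/tibble-out wrappers.

## Tunable parameters

| parameter | default | units | why this value |
|---|---|---|---|
| promoter width | 500 | bp | promoters are defined as 500 bp around the annotated TSS; implemented symmetrically (±250 bp) since sidedness is a convention, and clipped at position 0 |
| scoring window | 5,000,000 | bp | ±2.5 Mb around the TSS; element membership decided by midpoint |
| bin size | 10,000 | bp | working Hi-C resolution |
| ABC threshold | 0.012 | score | yields ~4.5 distal elements per connected gene on real neuronal data; recalibrate with `calibrate_threshold()` on new data |
| calibration target, bounds | 4.51, [2, 5] | elements/gene | the published calibration recipe: mean distal elements per gene between two and five, as close to 4.51 as the score ladder allows; ties between equally good thresholds break toward the larger one (fewer pairs) |
| contact pseudocount | 0 | counts | no pseudocount in the reproduced analysis; exposed for robustness experiments |
| balance tolerance, max iterations | 1e-8, 1000 | relative, — | occupied-row sums must agree to 1e-8; matrices without total support (no self-interaction diagonal) can fail to converge and error with the residual |
| heritability-annotation extension | 500 | bp | elements are widened by 500 bp each side and merged before SNPs are annotated, to absorb background activity around elements |
| hub strata | ≤3, (3, 25], >25 | promoters | small/medium/large hub strata, boundaries closed as printed |
| state-combination coverage | 0.8 | fraction | a hub's chromatin-state "signature" is the minimal prefix of states, by bp of overlap, reaching 80% of its total state coverage |

## Statistical layer: conventions and numerics

* **Fisher's exact test** (`fisher_exact_2x2`) computes the two-sided p as
  the sum of hypergeometric probabilities no larger than the observed
  table's, with a 1e-7 relative slack to absorb floating-point ties. The
  odds ratio is the sample cross-product ratio, *not* the conditional MLE
  that `stats::fisher.test()` reports, because published enrichment tables
  use the former; the Haldane–Anscombe +0.5 correction applies to all
  cells exactly when some cell is zero, and the 95% CI is Woolf's normal
  approximation on the (possibly corrected) table. The test suite checks
  the p-values against full enumeration for every table with N ≤ 30 and
  against `fisher.test` on random tables.
* **BH selection** wraps `stats::p.adjust`; gene-level association
  p-values are thresholded at adjusted p ≤ 0.05.
* **Rank tests** wrap `stats::wilcox.test`, forcing exact enumeration for
  small tie-free samples (≤10 pairs; min group ≤ 8) and the tie-corrected
  normal approximation without continuity correction otherwise. The rank
  correlation reported throughout is Spearman's rho (Pearson correlation
  of mid-ranks).
* **Logistic regression** of gene disease status is an ordinary
  binomial GLM (IRLS) on RNA level, connection count, an active-distal
  covariate and monogamy. The active-distal covariate is the *indicator*
  of a gene's proportion of active distal elements exceeding the
  across-gene 90th percentile; the raw proportion is available behind
  `active_distal = "raw"`, since the verbal description of this covariate
  admits both readings. Apparent perfect separation (|coefficient| > 15 on
  the logit scale) is an error advising penalisation rather than a silent
  huge OR; constant covariates error too.
* **ICC** uses the one-way ANOVA method of moments with the unbalanced
  correction `n0 = (N − Σn_i²/N)/(k − 1)`, truncating a negative
  between-group variance at zero. It is cross-checked against the REML
  fit from `lme4` in the tests. The estimator is noisy when groups are
  tiny; interpret fixture-scale ICCs accordingly.
* **Degenerate inputs**: empty interval sets overlap nothing (not an
  error); a gene with no in-window element simply yields no pairs; a 2×2
  table with an empty margin errors; percentiles use the nearest-rank
  rule.

## Annotation overlap: geometric choices

Where the verbal definitions left geometry open, the package fixes it as
follows and reports enough to audit the choice. A hub's compartment
category is decided by its two *farthest* elements (minimal start, maximal
end); each is assigned to the compartment block it overlaps most, with
ties broken toward A for determinism, and the category distribution is
reported both over all hubs and conditional on assignment. Hub–TAD
overlap uses the hub's span interval (leftmost to rightmost node), and any
disjoint TAD set is accepted regardless of the caller that produced it.
Chromatin-state "signal" is bp of overlap — state segmentations carry no
score column. The role taxonomy (monogamous / 1-1-N / polygamous) is the
one internally consistent reading of the verbal definitions: monogamous
means a two-node hub, 1-1-N a degree-1 node in a larger hub, polygamous
degree ≥ 2; because published role percentages are not reproducible under
any single denominator, `role_census()` reports proportions over both the
full node set and the ≥3-node-hub subset.

## The synthetic generator

`simulate_crh_dataset()` emulates the statistical structure of the real
inputs so every downstream stage is testable offline:

* **Geometry.** Chromosomes are tiled into 500-kb loci whose content is
  confined to the central 100 kb; loci alternate between planted hubs,
  candidate-promoter territory and candidate-element territory. Background
  contacts follow `Poisson(rate · (d+1)^(−α))` and are sampled only within
  300 kb of the diagonal, so content in different loci has exactly zero
  contact. This makes planted hubs separable *by construction*: designated
  edges receive an additive contact boost sized as
  `ceiling(hub_boost / activity)` (equalising their score numerators), so
  every designated edge clears the threshold while cross-hub scores are
  structurally zero. A dry-run ABC computation validates the separation
  and errors, rather than silently producing an unrecoverable fixture, if
  the boost cannot meet the requested threshold. Within-hub background
  contacts may add extra edges inside a hub — they change the edge set,
  never the node partition, which is what recovery is scored on
  (adjusted Rand index via `mclust`).
* **Signals.** Peak signals are lognormal; H3K27ac is zero outside the
  active fraction (by default exactly the planted hub elements), so
  candidate elements are accessible-but-inactive, as in the real element
  taxonomy.
* **Phenotypes.** SNP p-values are Uniform(0,1) outside planted risk
  elements and `Beta(a, 1)` inside, with
  `a = 1 + log(risk_effect)/log(p_ref)` so the significant fraction at the
  reference threshold is `risk_effect` times baseline. Expression is a
  hub-level random-intercept model calibrated to `icc_true`; disease
  status is drawn from a logistic model on the gene covariates with the
  configured coefficients, and gene-level association p-values are drawn
  so that BH selection recovers the planted flags; DEG labels are
  Bernoulli at separate in-hub/out-of-hub rates.
* **Defaults as study conditions.** Two chromosomes of 20 Mb, 300 genes,
  1,500 peaks, 40 planted hubs from monogamous pairs up to a 5×15 hub, SNP
  density 2×10⁻⁴/bp (enough clumped SNPs inside the toy genome's ~1 Mb of
  element territory for enrichment counts to be informative), DEG rates
  0.35 in hubs versus 0.08 outside, ICC 0.25. The default fixture runs
  end-to-end in about a second.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: linkage disequilibrium between SNPs (each SNP
is independent), sequence content, inter-chromosomal contacts,
normalisation artifacts of real balancing pipelines, overlapping or
nested regulatory elements across loci, cross-tissue variation, and the
possibility that real hubs are *not* cleanly separable — the planted
geometry guarantees recoverability, so recovery tests validate the
machinery, not the biological identifiability of hubs.

## Problem sizes in the test and acceptance suites

The suites choose sizes that make the statistics meaningful at interactive
speed: planted-recovery runs use the default fixture over seeds 1–20;
normalisation and calibration checks use a 1-chromosome fixture (40 genes,
150 peaks, 10 hubs); the null calibration of the SNP enrichment test uses
1,000 replicates of 1,000 SNPs at threshold 0.05 (counts large enough that
the exact test's discreteness does not bite); logistic coverage uses 200
replicates of n = 5,000; ICC recovery uses 200 groups × 10 for the pure
estimator and an 80-hub × 8-promoter layout for the generator-level check.
Fisher exactness is verified for *all* 2×2 tables with N ≤ 30.

## Known limitations

* Only intra-chromosomal contacts are modelled; trans contacts are out of
  scope by construction.
* The balancing step is a generic doubly-stochastic scaling meeting a
  row-sum tolerance, not a numerically faithful Knight–Ruiz
  implementation; matrices lacking total support fail with an error.
* Heritability analysis stops at annotation preparation (thin-annot
  output); the LD-score regression itself requires genome-wide LD
  reference panels and is not attempted.
* Gene-level association input is consumed as a p-value table; the 3D
  SNP-to-gene aggregation that produces it is upstream of this package,
  as are GWAS clumping and compartment/TAD/FIRE/state calling.
* The ICC moment estimator is variable for hubs with one or two genes;
  results on small fixtures should be read as order-of-magnitude.
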