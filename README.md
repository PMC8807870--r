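# crhub: cis-regulatory hubs from activity-by-contact maps

Noncoding risk variants for polygenic disorders such as schizophrenia
concentrate in distal regulatory DNA, and assigning those elements to the
genes they control is the central obstacle between a GWAS hit and a
mechanism. `crhub` implements a 3D-genomics answer: score every candidate
distal element against every promoter with the activity-by-contact (ABC)
model, keep the functional links, and read off **cis-regulatory hubs
(CRHs)** — the connected components of the resulting bipartite
promoter/distal-element graph. Hubs are then characterised topologically,
situated relative to A/B compartments, TADs, FIREs and chromatin states, and
interrogated with the disease-genetics statistics that make them useful:
SNP enrichment and fold enrichment, associated-gene enrichment, logistic
models of gene disease status, expression intraclass correlation within
hubs, heritability-annotation preparation, and linkage of noncoding SNPs to
differentially expressed genes.

The package is aimed at statistical geneticists and regulatory genomicists
who have binned intra-chromosomal Hi-C contacts, DNAse/H3K27ac peaks, a TSS
annotation and GWAS summary data, and want a tested, seeded, end-to-end
pipeline rather than a pile of one-off scripts.

## The model

For a candidate element *e* (a DNAse peak) and a gene *g*, with element
activity defined as the geometric mean of accessibility and acetylation
signal,

```
A_e = sqrt(DNAse_e * H3K27ac_e)

ABC(e, g) = A_e * C_eg / sum over e' in W(g) of A_e' * C_e'g
```

where `C_eg` is the binned Hi-C contact count between the element and the
TSS (10-kb bins) and `W(g)` is the set of candidate elements whose midpoint
lies within a 5-Mb window centred on the TSS. Scores therefore sum to one
per gene. A pair is *functional* when `ABC(e, g) >= 0.012`; the threshold
can be re-derived on new data by `calibrate_threshold()`, which scans the
observed scores for the value whose mean number of distal elements per
connected gene is closest to 4.51 while staying between two and five. CRHs
are the connected components of the functional-pair graph; a two-node
component is a monogamous pair, a degree-1 node in a larger hub is in a
1-1-N relationship, and nodes with two or more connections are polygamous.

## Worked example

The seeded generator builds a complete toy dataset — genes, peaks with
lognormal signals, distance-decay contact matrices with planted hub
contacts, annotation tracks, SNPs and expression — so the whole pipeline
runs in seconds with no downloads:

```r
library(crhub)

sim   <- simulate_crh_dataset(fixture_config(seed = 42))
pairs <- compute_abc_scores(sim$landscape$elements,
                            sim$landscape$promoters, sim$contacts)
pairs <- threshold_pairs(pairs, 0.012)
crhs  <- build_crhs(functional_pairs(pairs),
                    promoters = sim$landscape$promoters)
crhs
#> <crh_set> 40 hubs, 240 nodes (70 promoters / 170 distal), 281 edges
#>   hub size: median 4 elements, range 2-20
```

The 40 planted hubs are recovered exactly (the fixture's `truth` slot keeps
the planted partition; `recovery_ari()` returns 1 here). `tidy(crhs)` gives
one row per hub with its promoter/distal counts, complexity (edge count),
distal proportion, mean inter-element distance and genomic span;
`glance(crhs)` the global census. Enrichment of hub elements in FIREs
against candidate (non-hub) DNAse peaks:

```r
fun_el <- dplyr::distinct(functional_pairs(pairs), chrom,
                          start = element_start, end = element_end,
                          id = element_id)
cand <- build_candidate_sets(dplyr::mutate(sim$landscape$elements,
                                           id = element_id),
                             fun_el, sim$landscape$genes, crhs)
region_set_enrichment(fun_el, cand$candidate_distal,
                      sim$landscape$annotations$fires)
#> <crh_enrichment> OR = 3.23 [2.32, 4.5], two-sided Fisher p = 1.32e-11
```

meaning hub elements overlap contact hotspots about three times as often as
matched candidate elements — the planted structure, detected. Expression
variance shared within hubs:

```r
icc_fit(dplyr::filter(sim$phenotypes$genes, in_crh), rna_level, hub_id)
#> <crh_icc> ICC = 0.108 (sigma2_between = 0.146, sigma2_within = 1.21; 40 groups, 70 obs)
```

i.e., on this small fixture about 11% of expression variance sits between
hubs (the generator's target is 0.25; with 40 groups of one to five genes
the moment estimator is this variable — the acceptance script uses a larger
layout). `autoplot(crhs)`, `plot_degree_profile(crhs)` and
`plot_enrichment_forest()` draw the standard figures, and
`run_crh_pipeline(pipeline_config(seed = 1), outdir = "out")` orchestrates
every stage (simulate, abc, crh, overlap, enrich, deglink, report) with
manifests and byte-reproducible outputs.

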