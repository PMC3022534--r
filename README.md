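# synexpr

Synexpression clustering and functional enrichment for curated,
ontology-anchored gene expression annotations.

## The problem

High-throughput RNA in situ hybridization atlases record, for thousands
of genes, *where* a transcript is seen: each gene receives curated
annotations on an anatomy ontology (structure, ordinal strength
strong / moderate / weak / not detected, and pattern homogeneous /
regional / single cell). Two analysis questions follow directly:

1. **Synexpression**: which genes share an expression territory across
   anatomical structures — and hence are candidates for shared
   regulation or function?
2. **Function**: do the resulting co-expression clusters share
   functional annotation (GO-like terms, protein domains, phenotypes,
   cytogenetic position) more often than chance, given that functional
   terms are heavily interdependent?

`synexpr` implements this analysis as a reusable pipeline for anyone
working with annotation-based (rather than intensity-based) expression
data: atlas curators, developmental biologists mining an ISH resource,
and methodologists who need a benchmarked reference implementation.

## The method

- **Maximal propagation.** Annotations live at mixed ontology depths. For
  each gene, every term `t` is assigned
  `v(t) = max{ raw(u) : u = t or u a descendant of t }`,
  so parent structures acquire the values of their parts and profiles
  become comparable across genes annotated at different resolutions.
- **Gene categories.** A gene is *not detected* (no signal anywhere),
  *ubiquitous* (homogeneous signal on a root term, or detected in ≥ 90%
  of leaf structures), or *regional* otherwise. Only regional genes are
  clustered.
- **Clustering.** Profiles are compared with the centered Pearson
  correlation `r`; genes are agglomerated by unweighted average linkage
  on the distance `d = 1 − r`, and the tree is cut into the maximal
  subtrees whose merges all satisfy mean cross-pair correlation
  `r ≥ r_min` (default 0.7). Cluster quality is summarised by the mean
  pairwise correlation, and cluster content by the **expression
  occupancy** matrix: the fraction of a cluster's genes expressed in
  each structure.
- **Enrichment.** Each cluster with ≥ 10 genes is tested per functional
  term with the upper-tail hypergeometric probability
  `P(X ≥ k)` for overlap `k`, cluster size `n`, term total `K` and
  universe `N` (the clustered genes). Because terms are interdependent,
  threshold-level significance is calibrated by permutation: whole
  per-gene annotation bundles are shuffled across genes (preserving
  within-gene term co-occurrence), the count of tests with `p ≤ α` is
  recomputed per permutation, and the add-one permutation p-value
  `(1 + b) / (1 + m)` is reported.
- **Benchmarking.** A synthetic-data generator plants known
  synexpression modules (disjoint leaf-term signatures) and enriched
  functional terms with full ground truth; recovery is scored by greedy
  Jaccard matching of modules to clusters.

## Worked example

The numbered scripts under `analysis/` run the whole study
(`Rscript analysis/01_simulate.R` … `05_score_recovery.R`), writing
tables under `results/`. The same analysis in five lines:

```r
library(synexpr)
ds  <- generate_dataset(synthetic_config(seed = 1))
res <- run_pipeline(ds$ontology, ds$annotations, ds$functional,
                    n_perm = 1000, seed = 1)
print(res)
print(score_recovery(res$clusters, ds$truth))
```

which prints:

```
synexpr_pipeline:
  300 annotated genes: 249 regional / 12 ubiquitous / 39 not detected
  matrix: 249 genes x 120 terms
  clusters (r >= 0.70): 38 reported, 71 singletons, 10 of >= 10 genes
  enrichment: 700 tests
recovered 10/10 modules at Jaccard >= 0.80; pair co-clustering 0.839
```

Reading: of 300 simulated genes, 249 classify as regional and enter
clustering over 120 informative anatomy terms; the r ≥ 0.7 cut yields
38 multi-gene clusters of which the 10 largest (≥ 10 genes) correspond
one-to-one to the 10 planted modules. The strongest enrichment hits are
the planted functional terms (e.g. `k = 11` of a 12-gene cluster
carrying a term with `K = 13` in a universe of 249, `p ≈ 2e-16`), and
calibration puts the observed count of sub-threshold tests far outside
the permutation distribution (`perm_p = 1/1001` at `α = 0.001`).

`res$occupancy` holds the cluster-by-structure occupancy fractions;
`write_pipeline_results(res, dir)` exports every table as commented,
reproducible TSV plus the merge tree in Newick format.

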