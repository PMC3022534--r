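---
title: "Synexpression analysis of ontology-anchored expression annotations: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synexpression analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synexpr)
```

This vignette is the package's account of its own methods: the models
and procedures, the parameters that matter and why they default where
they do, what the synthetic benchmark does and does not establish, and
the numerical choices a careful reader will want spelled out.

## 1. Data model

The input is a curated annotation table — one row per (gene, anatomical
term) with an ordinal strength (`not_detected < weak < moderate <
strong`) and an optional pattern (`homogeneous`, `regional`,
`single_cell`) — placed on an anatomy ontology: a DAG of terms joined by
`is_a` and `part_of` links. Both link types are treated identically
throughout, because both license the same inference (signal in a part is
signal in the whole); the package never distinguishes them after
parsing.

Strengths are encoded numerically by `strength_encoding()`, default
0/1/2/3. The encoding is deliberately unceremonious: downstream
comparison uses the centered Pearson correlation, which is invariant to
positive per-gene rescaling, so any strictly increasing encoding with
`not_detected = 0` that is a positive multiple of another yields
bit-identical correlation structure (this is asserted by test). Note the
invariance is to *scalings*, not general affine maps, at the encoding
level: an additive offset would have to apply to unannotated terms too,
which stay at 0 by definition. At the level of a complete gene profile,
the correlation is exactly invariant under per-gene affine maps
`x -> a*x + b` with `a > 0`, and the tests check both statements
separately.

## 2. Maximal propagation

Annotators work at whatever ontology depth the image supports, so raw
profiles from different genes are not directly comparable. Propagation
assigns every term the maximum of its own raw value and all values below
it:

`v(t) = max( raw(t), max_{d in descendants(t)} raw(d) )`

with absent annotations reading 0. The implementation is one
children-first topological sweep, but the *contract* is the
descendant-max closure, and the tests enforce the contract, not the
sweep: on random DAGs the output is compared exactly against brute-force
reachability enumeration. Useful consequences, each property-tested:
propagation is monotone (parents dominate children), idempotent, and
independent of term iteration order.

A propagated profile makes root-adjacent terms nearly constant across
genes. The default column policy `drop_empty` therefore removes root
terms and terms expressed in no gene before clustering; `leaves_only`
and explicit term lists are available where a fixed annotation space is
wanted.

## 3. Expression categories

Genes are classified once, before clustering:

* **not_detected** — no record above `not_detected`;
* **ubiquitous** — a detected `homogeneous` record on a root term, or
  detected annotation covering at least `coverage_fraction` (default
  0.9) of leaf terms;
* **regional** — otherwise.

In the source atlases this call is a curator judgment; a threshold has
to stand in for it here, so it is exposed as a parameter rather than
buried. 0.9 is strict enough that a gene annotated across most of the
embryo does not masquerade as regional, and in the synthetic benchmark
the planted module genes always classify regional (verified post hoc in
the tests). Only regional genes enter clustering: ubiquitous profiles
correlate with everything and would glue clusters together.

## 4. Clustering

* **Distance**: `d = 1 - r`, with `r` the centered Pearson correlation.
  `1 - |r|` is deliberately not offered as a default: anticorrelated
  genes are not synexpressed.
* **Linkage**: unweighted (proportional) average linkage — the distance
  between clusters is the mean over all cross pairs — so every merge
  height `h` reads as "mean cross-pair correlation `1 - h`". The
  implementation is the Lance–Williams recurrence; correctness is
  established against a from-scratch O(n³) re-agglomeration oracle that
  recomputes every cross-pair mean from the original distances, and
  cross-checked against `stats::hclust(method = "average")` cophenetic
  distances on tie-free instances. Ties in the minimum distance are
  broken by the lexicographically smallest pair of cluster
  representatives (a cluster represented by its smallest original leaf
  index), so results are reproducible across platforms.
* **Cut**: flat clusters are the maximal subtrees whose merge heights
  all satisfy `h <= 1 - r_min`. Because average-linkage heights are
  monotone, this is a single union-find pass over the merge list. The
  comparison uses a 1e-12 slack purely to absorb floating-point
  representation of the threshold; it is not a tunable. Raising `r_min`
  can only refine the partition (property-tested). Groups below
  `min_report_size` (default 2) are reported as singletons; both the
  multi-gene cluster count and the singleton count are emitted, since
  "number of clusters" is ambiguous between the two conventions.
* **Occupancy**: `occ(c, t) = |{g in c : v(g, t) > 0}| / |c|`, the
  fraction of a cluster's genes expressed in a structure — the natural
  summary for reading a cluster's territory.

`r_min` defaults to 0.7: high enough that a 12-gene cluster's profiles
visibly share a territory, low enough to tolerate ordinal-strength
noise. `min_enrich_size` defaults to 10 — below that, enrichment tests
are underpowered and dominated by single-gene annotations.

## 5. Enrichment and permutation calibration

Each (cluster ≥ 10 genes, namespace, term with `K ≥ 1`) triple is tested
with the exact upper-tail hypergeometric probability, `stats::phyper`
under the hood, verified against exhaustive subset enumeration for all
small cases. The universe is the clustered gene set — the set the
clusters were actually drawn from; no genome-wide background is assumed
because none is supplied by the data model. DAG-structured namespaces
are closed under ancestors (`propagate_functional()`) before testing,
making term interdependencies explicit; flat namespaces (domains,
phenotype terms used as labels, cytogenetic bands) pass through.

Raw per-term p-values are reported uncorrected. The multiplicity story
is handled at the threshold level, as follows: for each namespace and
threshold `α`, count observed tests with `p ≤ α`; then repeat on
permuted data where whole per-gene annotation bundles (all namespaces at
once) are reassigned by a uniform permutation of the universe. Keeping
bundles intact preserves within-gene term co-occurrence, so the null
respects the annotation dependence structure; per-term totals `K`,
cluster sizes and the universe are all conserved — only the overlap
counts vary. Significance is the add-one estimator
`perm_p = (1 + #{permuted count ≥ observed}) / (1 + n_perm)`,
which is never zero, is conservative, and is reproducible given
`(seed, n_perm)`; permutation `i` uses `seed + i`, so any single
permutation is independently replayable. Super-uniformity under the null
(`P(perm_p ≤ α) ≤ α`) is tested by nesting the calibration inside an
outer null loop at small `n_perm`. Default thresholds are
`{0.05, 0.01, 0.001, 1e-4}`; `n_perm` defaults to 10,000, with larger
values a configuration choice.

## 6. The synthetic benchmark

`generate_dataset()` emulates the statistical structure of a curated
atlas, not its imagery:

* a complete anatomy tree (depth 4, branching 3: 121 terms, 81 leaves) —
  deep enough that propagation does real work, small enough that a full
  study runs in seconds;
* 10 modules × 12 genes, each module annotated to its own 6 disjoint
  signature leaves with probability 0.9 per (gene, term), strengths
  drawn moderate/strong at 0.3/0.7;
* background annotation of strength `weak` at rate 0.02 per (gene,
  leaf) for all genes, plus 180 noise genes carrying only background —
  so clusters must be found against a realistically sparse, unstructured
  floor; small fractions of noise genes (5% each) are emitted as
  ubiquitous or silent so the classifier sees all three categories;
* 5% of detected annotations corrupted (deleted or strength-redrawn),
  emulating curation noise;
* per namespace, one planted functional term per module (annotating its
  module at 0.9, everyone else at 0.02) among 25 background terms.

All annotations are planted on leaves only, so internal-term signal
exists *only* through propagation — every run exercises the ontology
stage. Everything derives from one seed; identical configurations give
byte-identical outputs.

What passing the benchmark shows: the pipeline recovers planted
co-annotation structure through ordinal encoding, propagation,
correlation, linkage, cut, and detects planted functional signal at the
correct calibrated level, with the null rejection rate at its nominal
5%. What it does not show: robustness to the failure modes of real
atlases — correlated annotator bias, structured missingness by
tissue, probe failures, modules with overlapping territories or graded
boundaries. The `signature_overlap` knob exists for the latter but the
default benchmark keeps signatures disjoint so that recovery targets
are unambiguous.

Validation study sizes (chosen to make each check sharp at interactive
cost): oracle equivalence on 100 random ≤ 15-leaf linkage instances and
200 random ≤ 50-term DAGs; recovery and enrichment power over 20
generator seeds; null calibration over 50 signal-free datasets at
`n_perm = 99` (p-value granularity 1/100); one `n_perm = 1000`
calibration of the observed dataset.

## 7. Degenerate inputs and edge behaviour

* Zero-variance gene profiles make the correlation undefined; the
  primitive refuses them by name, and the pipeline drops them with a
  warning before clustering.
* An ontology with no roots (including an empty edge table) fails
  validation outright, as do cycles and dangling parent references.
* Duplicate (gene, term) records collapse by maximum — consistent with
  maximal propagation, under which repeated sightings can only raise a
  value.
* `k = 0` overlaps score `p = 1` exactly; the permutation p-value is
  bounded in `[1/(n_perm+1), 1]` by construction.
* A threshold cut that leaves no multi-gene cluster is a valid result:
  outputs are written with headers and zero rows, not errors.

## 8. Known limitations

* The ubiquitous/regional boundary is a single coverage threshold; real
  curator judgment is multi-criterion.
* The `pattern` field is carried through but does not weight the
  expression value; whether, e.g., single-cell signal should count less
  is left to the encoding, which is user-replaceable.
* The permutation calibration speaks at the threshold level per
  namespace, as designed; it does not produce per-term corrected
  p-values, and the raw per-term values should be read accordingly.
* Average linkage is O(n²) in memory; the intended scale is thousands of
  genes, not millions.
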