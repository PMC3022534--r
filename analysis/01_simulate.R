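#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Emulates the statistical structure of a curated ISH annotation atlas:
# a 121-term anatomy tree (depth 4, branching 3), 10 planted
# synexpression modules of 12 genes annotated to disjoint 6-leaf
# signatures, 180 noise genes with sparse background annotation, and two
# flat functional namespaces with one planted enriched term per module.
# All downstream stages read the TSV files written here.

suppressPackageStartupMessages(library(synexpr))

seed <- 1
cfg <- synthetic_config(seed = seed)
ds <- generate_dataset(cfg)
print(ds)

out <- file.path("results", "data")
write_dataset(ds, out)
cat("wrote dataset and ground truth to", out, "\n")
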