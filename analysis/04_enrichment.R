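#!/usr/bin/env Rscript
# Stage 4: functional enrichment of the synexpression clusters. Every
# cluster of >= 10 genes is tested against each functional term with the
# upper-tail hypergeometric probability (universe = clustered genes),
# and the burden of the many interdependent tests is calibrated by
# permuting whole per-gene annotation bundles (1,000 permutations).

suppressPackageStartupMessages(library(synexpr))

seed <- 1
data_dir <- file.path("results", "data")
ont <- parse_edge_table(file.path(data_dir, "ontology_edges.tsv"))
recs <- read_annotations(file.path(data_dir, "annotations.tsv"),
                         ontology = ont)
fun <- read_functional(file.path(data_dir, "functional.tsv"))

res <- run_pipeline(ont, recs, fun,
                    thresholds = c(0.05, 0.01, 0.001, 1e-4),
                    n_perm = 1000, seed = seed)

top <- res$enrichment[res$enrichment$p_hyper < 1e-4, ]
cat(sprintf("%d of %d tests reach p < 1e-4; strongest:\n",
            nrow(top), nrow(res$enrichment)))
print(utils::head(top[order(top$p_hyper), ], 5), row.names = FALSE)
cat("\npermutation calibration:\n")
print(res$calibration, row.names = FALSE)

out <- file.path("results", "enrichment")
write_pipeline_results(res, out)
cat("wrote enrichment and calibration tables to", out, "\n")
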