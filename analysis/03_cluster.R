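#!/usr/bin/env Rscript
# Stage 3: synexpression clustering. Centered Pearson correlations
# between regional gene profiles, average-linkage agglomeration, flat
# cut at r >= 0.7, and the cluster-by-structure expression occupancy.

suppressPackageStartupMessages(library(synexpr))

data_dir <- file.path("results", "data")
ont <- parse_edge_table(file.path(data_dir, "ontology_edges.tsv"))
recs <- read_annotations(file.path(data_dir, "annotations.tsv"),
                         ontology = ont)

res <- run_pipeline(ont, recs, params = clustering_params(r_min = 0.7))
print(res)
cat(sprintf("mean intra-cluster correlation: %.3f\n",
            mean(res$clusters$mean_r)))

out <- file.path("results", "clustering")
write_pipeline_results(res, out)
cat("wrote clusters, occupancy and merge tree to", out, "\n")
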