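#!/usr/bin/env Rscript
# Stage 5: score the clustering against the planted ground truth. Each
# planted module is matched to its best cluster by Jaccard index
# (greedy, one cluster per module); a module counts as recovered at
# Jaccard >= 0.8.

suppressPackageStartupMessages(library(synexpr))

data_dir <- file.path("results", "data")
ont <- parse_edge_table(file.path(data_dir, "ontology_edges.tsv"))
recs <- read_annotations(file.path(data_dir, "annotations.tsv"),
                         ontology = ont)
truth_tab <- utils::read.delim(file.path(data_dir, "truth_modules.tsv"),
                               comment.char = "#",
                               stringsAsFactors = FALSE)
truth <- list(modules = split(truth_tab$gene_id, truth_tab$module_id))

res <- run_pipeline(ont, recs)
rec <- score_recovery(res$clusters, truth)
print(rec)
print(rec$per_module, row.names = FALSE)

out <- file.path("results", "recovery")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
write_tsv(rec$per_module, file.path(out, "recovery.tsv"),
          comments = sprintf("recovered %d/%d at jaccard>=%.2f",
                             rec$n_recovered, rec$n_modules,
                             rec$jaccard_min))
cat("wrote recovery report to", out, "\n")
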