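#' Run the full synexpression analysis pipeline
#'
#' Executes the stages in order: classify genes into the three
#' expression categories, keep the regional subset, build the propagated
#' gene-by-term matrix, compute centered Pearson correlations, cluster
#' by average linkage, cut at the correlation threshold, compute cluster
#' expression occupancy, and — when functional annotations are supplied
#' — test clusters of at least `params$min_enrich_size` genes for
#' functional-term enrichment, optionally calibrating threshold-level
#' significance by bundle permutation.
#'
#' @param ontology a `term_ontology`.
#' @param annotations expression annotation records (see
#'   [read_annotations()]).
#' @param functional optional functional annotation data.frame.
#' @param params a [clustering_params()].
#' @param encoding a [strength_encoding()].
#' @param coverage_fraction leaf-coverage bound for the ubiquitous
#'   category (default 0.9).
#' @param term_policy,min_genes column-space policy for the matrix
#'   (defaults `"drop_empty"`, 1).
#' @param dag_ontologies named list of ontologies for DAG-structured
#'   functional namespaces; those namespaces are closed under ancestors
#'   before testing.
#' @param thresholds,n_perm,seed calibration settings; calibration runs
#'   only when `functional` is given, `n_perm >= 1` and a seed is
#'   supplied.
#' @return list of class `synexpr_pipeline` with elements
#'   `classification`, `matrix`, `cor`, `tree`, `clusters`, `occupancy`,
#'   `enrichment`, `calibration`, `log`.
#' @export
run_pipeline <- function(ontology, annotations, functional = NULL,
                         params = clustering_params(),
                         encoding = strength_encoding(),
                         coverage_fraction = 0.9,
                         term_policy = "drop_empty", min_genes = 1,
                         dag_ontologies = list(),
                         thresholds = c(0.05, 0.01, 0.001, 1e-4),
                         n_perm = 0, seed = NULL) {
  log <- list()
  annotations <- check_annotation_records(annotations)
  log$n_genes_annotated <- length(unique(annotations$gene_id))

  cls <- classify_genes(annotations, ontology, coverage_fraction)
  log$category_counts <- table(factor(cls, levels = c("regional",
                                                      "ubiquitous",
                                                      "not_detected")))
  regional <- names(cls)[cls == "regional"]
  if (length(regional) == 0L) {
    stop("no regional genes: nothing to cluster", call. = FALSE)
  }
  log$n_regional <- length(regional)

  recs <- annotations[annotations$gene_id %in% regional, , drop = FALSE]
  m <- build_matrix(recs, ontology, encoding = encoding, propagate = TRUE,
                    term_policy = term_policy, min_genes = min_genes)
  # constant profiles carry no correlation signal; drop them up front
  v <- apply(m, 1L, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance gene profile(s): ",
            paste(rownames(m)[v == 0], collapse = ", "), call. = FALSE)
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("fewer than two clusterable genes", call. = FALSE)
  log$matrix_dim <- dim(m)

  cr <- correlation_matrix(m)
  tree <- average_linkage(1 - cr)
  clusters <- cut_at_correlation(tree, params, cr)
  log$n_clusters <- length(clusters$clusters)
  log$n_singletons <- length(clusters$singletons)
  log$n_clusters_enrich <- sum(lengths(clusters$clusters) >=
                                 params$min_enrich_size)
  occ <- occupancy(clusters, m)

  enr <- NULL
  calib <- NULL
  if (!is.null(functional) && nrow(functional) > 0) {
    fun <- propagate_functional(functional, dag_ontologies)
    universe <- rownames(m)
    fun <- fun[fun$gene_id %in% universe, , drop = FALSE]
    enr <- enrich(clusters, fun, universe, params$min_enrich_size)
    log$n_enrichment_tests <- nrow(enr)
    if (n_perm >= 1 && !is.null(seed)) {
      calib <- calibrate(clusters, fun, universe, thresholds = thresholds,
                         n_perm = n_perm, seed = seed,
                         min_enrich_size = params$min_enrich_size)
    }
  }

  structure(list(classification = cls, matrix = m, cor = cr, tree = tree,
                 clusters = clusters, occupancy = occ, enrichment = enr,
                 calibration = calib, log = log, params = params,
                 seed = seed),
            class = "synexpr_pipeline")
}

#' @export
print.synexpr_pipeline <- function(x, ...) {
  cc <- x$log$category_counts
  cat("synexpr_pipeline:\n")
  cat(sprintf("  %d annotated genes: %d regional / %d ubiquitous / %d not detected\n",
              x$log$n_genes_annotated, cc[["regional"]],
              cc[["ubiquitous"]], cc[["not_detected"]]))
  cat(sprintf("  matrix: %d genes x %d terms\n",
              x$log$matrix_dim[1], x$log$matrix_dim[2]))
  cat(sprintf("  clusters (r >= %.2f): %d reported, %d singletons, %d of >= %d genes\n",
              x$params$r_min, x$log$n_clusters, x$log$n_singletons,
              x$log$n_clusters_enrich, x$params$min_enrich_size))
  if (!is.null(x$enrichment)) {
    cat(sprintf("  enrichment: %d tests\n", nrow(x$enrichment)))
  }
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' Emits `classification.tsv`, `clusters.tsv`, `occupancy.tsv` (4
#' decimal fractions), `enrichment.tsv`, `calibration.tsv`,
#' `run_log.tsv` and the merge tree as `tree.nwk`. Every TSV starts with
#' comment headers recording the tool version, the clustering
#' parameters and the seed, so a run is replayable from its outputs.
#' Output is deterministic for a fixed input and seed.
#'
#' @param result a `synexpr_pipeline`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  stopifnot(inherits(result, "synexpr_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(pkg_version_string(),
           sprintf("r_min=%g min_report_size=%d min_enrich_size=%d",
                   result$params$r_min, result$params$min_report_size,
                   result$params$min_enrich_size),
           paste0("seed=", if (is.null(result$seed)) "NA" else result$seed))
  write_tsv(data.frame(gene_id = names(result$classification),
                       category = unname(result$classification),
                       stringsAsFactors = FALSE),
            file.path(dir, "classification.tsv"), hdr)
  write_tsv(as.data.frame(result$clusters),
            file.path(dir, "clusters.tsv"), hdr)
  occ <- round(result$occupancy, 4)
  write_tsv(data.frame(cluster_id = rownames(occ), occ,
                       check.names = FALSE, stringsAsFactors = FALSE),
            file.path(dir, "occupancy.tsv"), hdr)
  if (!is.null(result$enrichment)) {
    write_tsv(result$enrichment, file.path(dir, "enrichment.tsv"), hdr)
  }
  if (!is.null(result$calibration)) {
    write_tsv(result$calibration, file.path(dir, "calibration.tsv"), hdr)
  }
  lg <- result$log
  write_tsv(data.frame(
    key = c("n_genes_annotated", "n_regional", "n_clustered_genes",
            "n_terms", "n_clusters", "n_singletons", "n_clusters_enrich",
            "n_regional_cat", "n_ubiquitous_cat", "n_not_detected_cat"),
    value = c(lg$n_genes_annotated, lg$n_regional, lg$matrix_dim[1],
              lg$matrix_dim[2], lg$n_clusters, lg$n_singletons,
              lg$n_clusters_enrich,
              lg$category_counts[["regional"]],
              lg$category_counts[["ubiquitous"]],
              lg$category_counts[["not_detected"]]),
    stringsAsFactors = FALSE), file.path(dir, "run_log.tsv"), hdr)
  export_newick(result$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}
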