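#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` term-annotated genes in a
#' cluster of size `n` drawn without replacement from a universe of `N`
#' genes of which `K` carry the term.
#'
#' @param k observed overlap count(s).
#' @param n cluster size(s).
#' @param K term-annotated genes in the universe.
#' @param N universe size.
#' @return P(X >= k), exact; 1 when `k = 0`.
#' @export
hypergeom_upper <- function(k, n, K, N) {
  args <- cbind(k = k, n = n, K = K, N = N)  # recycles
  if (any(!is_whole(args))) {
    stop("hypergeometric arguments must be integers", call. = FALSE)
  }
  k <- args[, "k"]; n <- args[, "n"]; K <- args[, "K"]; N <- args[, "N"]
  if (any(k < 0 | K < 0 | n < 0 | N < 0) ||
      any(k > pmin(n, K)) || any(n > N) || any(K > N)) {
    stop("hypergeometric arguments violate 0 <= k <= min(n, K), n <= N, K <= N",
         call. = FALSE)
  }
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  unname(pmin(p, 1))
}

check_functional <- function(annotations) {
  req <- c("gene_id", "namespace", "term_id")
  stopifnot(is.data.frame(annotations), all(req %in% names(annotations)))
  unique(annotations[, req])
}

#' Read a functional annotation table
#'
#' Tab-delimited with header columns `gene_id`, `namespace`, `term_id`;
#' duplicate triples are dropped.
#'
#' @param file path to the TSV.
#' @return deduplicated data.frame of annotations.
#' @export
read_functional <- function(file) {
  parsed <- read_tsv_lines(file)
  req <- c("gene_id", "namespace", "term_id")
  if (!all(req %in% parsed$header)) {
    stop("functional table must have header columns gene_id, namespace, term_id",
         call. = FALSE)
  }
  col <- match(req, parsed$header)
  n_fields <- length(parsed$header)
  for (i in seq_along(parsed$rows)) {
    r <- parsed$rows[[i]]
    if (length(r) != n_fields || any(!nzchar(r[col]))) {
      stop("malformed functional row at line ", parsed$lines[i],
           call. = FALSE)
    }
  }
  m <- do.call(rbind, parsed$rows)
  if (is.null(m)) {
    return(data.frame(gene_id = character(), namespace = character(),
                      term_id = character(), stringsAsFactors = FALSE))
  }
  check_functional(data.frame(gene_id = m[, col[1L]],
                              namespace = m[, col[2L]],
                              term_id = m[, col[3L]],
                              stringsAsFactors = FALSE))
}

#' True-path closure of DAG-structured functional annotations
#'
#' For namespaces organised as a DAG (GO-like), annotation to a term
#' implies annotation to all of its ancestors; this closure makes the
#' implied annotations explicit before testing. Flat namespaces (domain,
#' phenotype, cytoband) pass through unchanged.
#'
#' @param annotations functional annotation data.frame.
#' @param ontologies named list mapping DAG namespace -> `term_ontology`.
#' @param dag_namespaces namespaces to treat as DAG-structured (default:
#'   the names of `ontologies`); declaring one without supplying its
#'   ontology is an error.
#' @return deduplicated annotations closed under ancestors.
#' @export
propagate_functional <- function(annotations, ontologies = list(),
                                 dag_namespaces = names(ontologies)) {
  annotations <- check_functional(annotations)
  if (is.null(dag_namespaces)) dag_namespaces <- character(0)
  missing_ont <- setdiff(dag_namespaces, names(ontologies))
  if (length(missing_ont)) {
    stop("DAG namespace(s) without an ontology: ",
         paste(missing_ont, collapse = ", "), call. = FALSE)
  }
  pieces <- list(annotations)
  for (ns in intersect(dag_namespaces, unique(annotations$namespace))) {
    ont <- ontologies[[ns]]
    sub <- annotations[annotations$namespace == ns, , drop = FALSE]
    anc <- lapply(stats::setNames(nm = unique(sub$term_id)),
                  function(t) ancestors(ont, t))
    extra <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
      a <- anc[[sub$term_id[i]]]
      if (!length(a)) return(NULL)
      data.frame(gene_id = sub$gene_id[i], namespace = ns, term_id = a,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(extra)) pieces[[length(pieces) + 1L]] <- extra
  }
  out <- unique(do.call(rbind, pieces))
  rownames(out) <- NULL
  out
}

# namespace-wise term x gene incidence over the universe
incidence_by_namespace <- function(annotations, universe) {
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  lapply(split(ann, ann$namespace), function(sub) {
    terms <- sort(unique(sub$term_id))
    inc <- matrix(FALSE, nrow = length(terms), ncol = length(universe),
                  dimnames = list(terms, universe))
    inc[cbind(match(sub$term_id, terms), match(sub$gene_id, universe))] <- TRUE
    inc
  })
}

#' Hypergeometric enrichment of functional terms in clusters
#'
#' Tests every (cluster, namespace, term) combination for which the
#' cluster holds at least `min_enrich_size` genes and the term annotates
#' at least one universe gene. The universe is the clustered gene set.
#'
#' @param clusters a `cluster_set`.
#' @param annotations functional annotation data.frame (apply
#'   [propagate_functional()] first for DAG namespaces).
#' @param universe character vector of gene ids the clusters were drawn
#'   from; annotations are restricted to it.
#' @param min_enrich_size smallest cluster size tested (default 10).
#' @return data.frame with columns `cluster_id`, `namespace`,
#'   `term_id`, `k`, `n`, `K`, `N`, `p_hyper`, sorted by (namespace,
#'   cluster_id, p_hyper).
#' @export
enrich <- function(clusters, annotations, universe, min_enrich_size = 10) {
  stopifnot(inherits(clusters, "cluster_set"))
  annotations <- check_functional(annotations)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (anyDuplicated(universe)) stop("universe has duplicate gene ids",
                                    call. = FALSE)
  N <- length(universe)
  big <- clusters$clusters[lengths(clusters$clusters) >= min_enrich_size]
  outside <- setdiff(unlist(big, use.names = FALSE), universe)
  if (length(outside)) {
    stop("cluster gene(s) outside the universe: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  inc <- incidence_by_namespace(annotations, universe)
  res <- list()
  for (ns in names(inc)) {
    m <- inc[[ns]]
    Kv <- rowSums(m)
    for (id in names(big)) {
      genes <- big[[id]]
      n <- length(genes)
      kv <- rowSums(m[, genes, drop = FALSE])
      res[[length(res) + 1L]] <- data.frame(
        cluster_id = as.integer(id), namespace = ns,
        term_id = rownames(m), k = as.integer(kv), n = n,
        K = as.integer(Kv), N = N,
        p_hyper = hypergeom_upper(kv, n, Kv, N),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(cluster_id = integer(), namespace = character(),
                      term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_hyper = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$namespace, out$cluster_id, out$p_hyper,
                   out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Permute gene labels while keeping annotation bundles intact
#'
#' Draws one uniform random permutation of the universe and reassigns
#' each gene's complete annotation bundle (all namespaces at once) to
#' the permuted gene id. Because a bundle moves as a unit, within-gene
#' term co-occurrence — the interdependency structure among, e.g., GO
#' terms — is preserved exactly; only the association between bundles
#' and clusters is randomised. Per-term universe counts K and the
#' multiset of bundle sizes are conserved.
#'
#' @param annotations functional annotation data.frame; every gene must
#'   belong to `universe`.
#' @param universe character vector of gene ids.
#' @param seed integer seed; the same seed yields the identical
#'   permutation. The caller's RNG state is left untouched.
#' @return the annotation data.frame with permuted `gene_id`.
#' @export
permute_bundles <- function(annotations, universe, seed) {
  annotations <- check_functional(annotations)
  outside <- setdiff(unique(annotations$gene_id), universe)
  if (length(outside)) {
    stop("annotations reference gene(s) outside the universe: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  pi_map <- with_seed(seed, stats::setNames(sample(universe), universe))
  annotations$gene_id <- unname(pi_map[annotations$gene_id])
  annotations
}

#' Permutation calibration of threshold-level enrichment significance
#'
#' For each namespace and p-value threshold alpha, counts the observed
#' enrichment tests with `p_hyper <= alpha`, recomputes that count on
#' `n_perm` bundle-permuted datasets, and reports the add-one permutation
#' p-value `(1 + #\{permuted count >= observed\}) / (1 + n_perm)`. This
#' calibrates the burden of many interdependent tests without assuming
#' independence between terms.
#'
#' @param clusters a `cluster_set`.
#' @param annotations functional annotations (closed form for DAG
#'   namespaces).
#' @param universe clustered gene ids.
#' @param thresholds p-value thresholds in (0, 1).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer master seed; permutation i uses `seed + i`.
#' @param min_enrich_size forwarded to [enrich()].
#' @return data.frame with columns `namespace`, `alpha`,
#'   `observed_count`, `perm_mean`, `perm_max`, `perm_p`, `n_perm`,
#'   `seed`.
#' @export
calibrate <- function(clusters, annotations, universe,
                      thresholds = c(0.05, 0.01, 0.001, 1e-4),
                      n_perm = 10000, seed, min_enrich_size = 10) {
  stopifnot(all(thresholds > 0 & thresholds < 1), n_perm >= 1)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  count_hits <- function(e, namespaces) {
    m <- matrix(0L, nrow = length(thresholds), ncol = length(namespaces),
                dimnames = list(NULL, namespaces))
    for (ns in namespaces) {
      p <- e$p_hyper[e$namespace == ns]
      m[, ns] <- vapply(thresholds, function(a) sum(p <= a), integer(1))
    }
    m
  }
  obs <- enrich(clusters, annotations, universe, min_enrich_size)
  namespaces <- sort(unique(annotations$namespace))
  obs_counts <- count_hits(obs, namespaces)
  exceed <- matrix(0L, nrow = length(thresholds), ncol = length(namespaces),
                   dimnames = list(NULL, namespaces))
  perm_sum <- exceed
  perm_max <- exceed
  for (i in seq_len(n_perm)) {
    pa <- permute_bundles(annotations, universe,
                          (seed + i) %% .Machine$integer.max)
    ei <- enrich(clusters, pa, universe, min_enrich_size)
    ci <- count_hits(ei, namespaces)
    exceed <- exceed + (ci >= obs_counts)
    perm_sum <- perm_sum + ci
    perm_max <- pmax(perm_max, ci)
  }
  out <- expand.grid(alpha = thresholds, namespace = namespaces,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- cbind(match(out$alpha, thresholds),
               match(out$namespace, namespaces))
  data.frame(namespace = out$namespace, alpha = out$alpha,
             observed_count = as.integer(obs_counts[idx]),
             perm_mean = perm_sum[idx] / n_perm,
             perm_max = as.integer(perm_max[idx]),
             perm_p = (1 + exceed[idx]) / (1 + n_perm),
             n_perm = n_perm, seed = seed,
             stringsAsFactors = FALSE)
}
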