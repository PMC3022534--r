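#' Configuration for the synthetic benchmark generator
#'
#' Defines the study conditions under which the pipeline is exercised: a
#' complete anatomy tree, gene modules whose annotations concentrate on
#' small disjoint signature term sets (planted synexpression groups)
#' against sparse background annotation, and functional namespaces in
#' which each module carries planted enriched terms.
#'
#' @param seed integer seed; mandatory, all draws flow from it.
#' @param ontology_depth levels below the root of the complete anatomy
#'   tree (default 4).
#' @param branching children per internal term (default 3), giving
#'   `branching^ontology_depth` leaves.
#' @param n_modules number of planted synexpression modules (default 10).
#' @param module_size genes per module (default 12).
#' @param signature_size leaf terms in each module's signature
#'   (default 6).
#' @param p_signal probability that a module gene is annotated to a
#'   given signature term, and that a planted functional term annotates
#'   a given module gene (default 0.9).
#' @param p_background per-(gene, leaf) background annotation
#'   probability (default 0.02).
#' @param n_noise_genes genes with only background structure
#'   (default 180).
#' @param strength_signal probabilities of `moderate`/`strong` for
#'   signature annotations (default `c(moderate = 0.3, strong = 0.7)`).
#' @param flip_rate per-annotation corruption probability; a corrupted
#'   detected annotation is either deleted or has its strength redrawn
#'   (default 0.05).
#' @param n_namespaces flat functional namespaces to emit (default 2).
#' @param planted_terms_per_module planted enriched terms per module in
#'   each namespace (default 1; 0 gives a null functional dataset).
#' @param n_background_terms non-planted functional terms per namespace,
#'   each annotating genes at `p_background` (default 25).
#' @param p_noise_ubiquitous fraction of noise genes emitted as
#'   root-homogeneous (ubiquitous) instead of background-annotated
#'   (default 0.05).
#' @param p_noise_silent fraction of noise genes emitted with no
#'   detected signal (default 0.05).
#' @param signature_overlap signature terms shared between consecutive
#'   modules (default 0, keeping recovery targets unambiguous).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             ontology_depth = 4, branching = 3,
                             n_modules = 10, module_size = 12,
                             signature_size = 6,
                             p_signal = 0.9, p_background = 0.02,
                             n_noise_genes = 180,
                             strength_signal = c(moderate = 0.3,
                                                 strong = 0.7),
                             flip_rate = 0.05,
                             n_namespaces = 2,
                             planted_terms_per_module = 1,
                             n_background_terms = 25,
                             p_noise_ubiquitous = 0.05,
                             p_noise_silent = 0.05,
                             signature_overlap = 0) {
  if (missing(seed) || !is_whole(seed)) {
    stop("an integer seed is mandatory", call. = FALSE)
  }
  cfg <- mget(names(formals(synthetic_config)))
  if (ontology_depth < 2 || branching < 2) {
    stop("need ontology_depth >= 2 and branching >= 2", call. = FALSE)
  }
  probs <- c(p_signal, p_background, flip_rate, p_noise_ubiquitous,
             p_noise_silent)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  sizes <- c(n_modules, module_size, signature_size)
  if (any(sizes < 1) || n_noise_genes < 0 || n_namespaces < 0 ||
      planted_terms_per_module < 0 || n_background_terms < 0) {
    stop("sizes must be positive", call. = FALSE)
  }
  if (!all(c("moderate", "strong") %in% names(strength_signal)) ||
      abs(sum(strength_signal) - 1) > 1e-8) {
    stop("strength_signal must be probabilities over moderate/strong summing to 1",
         call. = FALSE)
  }
  if (signature_overlap < 0 || signature_overlap >= signature_size) {
    stop("signature_overlap must lie in [0, signature_size)", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a complete anatomy tree
#'
#' A single-rooted complete tree with `branching` children per internal
#' term down to `ontology_depth` levels, connected by `part_of` links;
#' for the defaults (depth 4, branching 3) this is 121 terms with 81
#' leaves. Construction is deterministic.
#'
#' @param config a [synthetic_config()].
#' @return a `term_ontology`.
#' @export
generate_ontology <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  b <- config$branching
  depth <- config$ontology_depth
  n_terms <- sum(b ^ (0:depth))
  ids <- sprintf("EMB:%04d", seq_len(n_terms))
  child <- parent <- character(0)
  # breadth-first labelling: children of term i are contiguous
  next_id <- 2L
  frontier <- 1L
  for (level in seq_len(depth)) {
    new_frontier <- integer(0)
    for (p in frontier) {
      kids <- next_id:(next_id + b - 1L)
      child <- c(child, ids[kids])
      parent <- c(parent, rep(ids[p], b))
      new_frontier <- c(new_frontier, kids)
      next_id <- next_id + b
    }
    frontier <- new_frontier
  }
  term_ontology(
    data.frame(term_id = ids,
               name = sprintf("structure %d", seq_len(n_terms)),
               stringsAsFactors = FALSE),
    data.frame(child_id = child, parent_id = parent,
               relation = "part_of", stringsAsFactors = FALSE)
  )
}

sample_strength <- function(n, strength_signal) {
  sample(c("moderate", "strong"), n, replace = TRUE,
         prob = strength_signal[c("moderate", "strong")])
}

#' Generate a synthetic annotated dataset with ground truth
#'
#' Plants `n_modules` disjoint gene modules, each annotated to its own
#' signature of leaf terms with probability `p_signal` (strengths drawn
#' from `strength_signal`), over background leaf annotations of strength
#' `weak` at rate `p_background`. Noise genes carry only background
#' structure, except for configurable fractions emitted as ubiquitous
#' (root-homogeneous) or silent so that all three expression categories
#' occur. A fraction `flip_rate` of detected annotations is corrupted by
#' deletion or strength redraw. Functional namespaces are flat: each
#' module receives planted terms annotating its genes at `p_signal` and
#' the rest of the universe at `p_background`, alongside background
#' terms. Annotations are planted on leaves only, so internal-term
#' signal arises solely through maximal propagation.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset` with elements `ontology`,
#'   `annotations`, `functional`, `truth` (module gene sets, signature
#'   term sets, planted functional terms) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ont <- generate_ontology(config)
  leaves <- ontology_leaves(ont)
  stride <- config$signature_size - config$signature_overlap
  need <- (config$n_modules - 1L) * stride + config$signature_size
  if (need > length(leaves)) {
    stop("module signatures need ", need, " leaves but the tree has only ",
         length(leaves), call. = FALSE)
  }
  n_genes <- config$n_modules * config$module_size + config$n_noise_genes
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  module_ids <- sprintf("M%02d", seq_len(config$n_modules))

  out <- with_seed(config$seed, {
    modules <- stats::setNames(lapply(seq_len(config$n_modules), function(m) {
      gene_ids[((m - 1L) * config$module_size + 1L):(m * config$module_size)]
    }), module_ids)
    noise_genes <- gene_ids[(config$n_modules * config$module_size + 1L):
                              n_genes]
    leaf_perm <- sample(leaves)
    signatures <- stats::setNames(lapply(seq_len(config$n_modules),
                                         function(m) {
      start <- (m - 1L) * stride + 1L
      sort(leaf_perm[start:(start + config$signature_size - 1L)])
    }), module_ids)

    recs <- list()
    add <- function(gene, term, strength, pattern) {
      recs[[length(recs) + 1L]] <<- data.frame(
        gene_id = gene, term_id = term, strength = strength,
        pattern = pattern, stringsAsFactors = FALSE)
    }

    # signature annotations
    for (m in module_ids) {
      for (g in modules[[m]]) {
        keep <- stats::runif(config$signature_size) < config$p_signal
        terms <- signatures[[m]][keep]
        if (length(terms)) {
          add(g, terms, sample_strength(length(terms),
                                        config$strength_signal), "regional")
        }
      }
    }

    # noise-gene categories
    n_noise <- length(noise_genes)
    u <- stats::runif(n_noise)
    noise_ubiq <- noise_genes[u < config$p_noise_ubiquitous]
    noise_silent <- noise_genes[u >= config$p_noise_ubiquitous &
                                  u < config$p_noise_ubiquitous +
                                    config$p_noise_silent]
    noise_bg <- setdiff(noise_genes, c(noise_ubiq, noise_silent))

    # background annotations on non-signature leaves, strength weak
    bg_genes <- c(unlist(modules, use.names = FALSE), noise_bg)
    module_of <- stats::setNames(
      rep(module_ids, each = config$module_size),
      unlist(modules, use.names = FALSE))
    for (g in bg_genes) {
      cand <- leaves
      if (g %in% names(module_of)) {
        cand <- setdiff(cand, signatures[[module_of[[g]]]])
      }
      hit <- cand[stats::runif(length(cand)) < config$p_background]
      if (length(hit)) add(g, hit, "weak", "regional")
    }

    for (g in noise_ubiq) add(g, ont$roots[1L], "moderate", "homogeneous")
    for (g in noise_silent) add(g, ont$roots[1L], "not_detected",
                                NA_character_)

    ann <- do.call(rbind, recs)

    # flip corruption of detected annotations
    detected <- which(ann$strength != "not_detected")
    flip <- detected[stats::runif(length(detected)) < config$flip_rate]
    if (length(flip)) {
      del <- flip[stats::runif(length(flip)) < 0.5]
      redraw <- setdiff(flip, del)
      if (length(redraw)) {
        ann$strength[redraw] <- sample(c("weak", "moderate", "strong"),
                                       length(redraw), replace = TRUE)
      }
      if (length(del)) ann <- ann[-del, , drop = FALSE]
    }

    # genes losing every record get an explicit not-detected root record
    # so the generated gene universe stays complete
    lost <- setdiff(gene_ids, unique(ann$gene_id))
    for (g in lost) {
      ann <- rbind(ann, data.frame(gene_id = g, term_id = ont$roots[1L],
                                   strength = "not_detected",
                                   pattern = NA_character_,
                                   stringsAsFactors = FALSE))
    }
    ann <- ann[order(match(ann$gene_id, gene_ids)), , drop = FALSE]
    rownames(ann) <- NULL

    # functional namespaces (flat)
    fun <- list()
    truth_fun <- list()
    ns_ids <- sprintf("NS%d", seq_len(config$n_namespaces))
    for (ns in ns_ids) {
      for (m in module_ids) {
        for (j in seq_len(config$planted_terms_per_module)) {
          term <- sprintf("%s:%s_planted%d", ns, m, j)
          hit_mod <- modules[[m]][stats::runif(config$module_size) <
                                    config$p_signal]
          others <- setdiff(gene_ids, modules[[m]])
          hit_bg <- others[stats::runif(length(others)) <
                             config$p_background]
          hits <- c(hit_mod, hit_bg)
          if (length(hits)) {
            fun[[length(fun) + 1L]] <- data.frame(
              gene_id = hits, namespace = ns, term_id = term,
              stringsAsFactors = FALSE)
          }
          truth_fun[[length(truth_fun) + 1L]] <- data.frame(
            module_id = m, namespace = ns, term_id = term,
            stringsAsFactors = FALSE)
        }
      }
      for (j in seq_len(config$n_background_terms)) {
        term <- sprintf("%s:BG%03d", ns, j)
        hits <- gene_ids[stats::runif(n_genes) < config$p_background]
        if (length(hits)) {
          fun[[length(fun) + 1L]] <- data.frame(
            gene_id = hits, namespace = ns, term_id = term,
            stringsAsFactors = FALSE)
        }
      }
    }
    functional <- if (length(fun)) do.call(rbind, fun) else
      data.frame(gene_id = character(), namespace = character(),
                 term_id = character(), stringsAsFactors = FALSE)
    rownames(functional) <- NULL
    truth_functional <- if (length(truth_fun)) do.call(rbind, truth_fun) else
      data.frame(module_id = character(), namespace = character(),
                 term_id = character(), stringsAsFactors = FALSE)

    list(annotations = ann, functional = functional,
         truth = list(modules = modules, signatures = signatures,
                      functional = truth_functional),
         genes = gene_ids)
  })

  structure(c(out, list(ontology = ont, config = config)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$genes), "genes (",
      x$config$n_modules, "modules x", x$config$module_size, "genes +",
      x$config$n_noise_genes, "noise ),",
      nrow(x$annotations), "annotation records,",
      nrow(x$functional), "functional annotations, seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Score recovery of planted modules by found clusters
#'
#' Matches each planted module to its best found cluster by Jaccard
#' index, greedily on descending Jaccard with every cluster used at most
#' once. A module counts as recovered when its matched Jaccard reaches
#' `jaccard_min`.
#'
#' @param found a `cluster_set` (or plain list of gene id vectors).
#' @param truth the `truth` element of a `synthetic_dataset` (or any
#'   list with a `modules` element).
#' @param jaccard_min recovery threshold on the Jaccard index
#'   (default 0.8).
#' @return list of class `recovery_report`: `per_module` data.frame
#'   (`module_id`, `cluster_id`, `jaccard`, `recovered`), `n_recovered`,
#'   `n_modules`, and `pair_coclustering`, the fraction of truly
#'   co-module gene pairs placed in the same found cluster.
#' @export
score_recovery <- function(found, truth, jaccard_min = 0.8) {
  clusters <- if (inherits(found, "cluster_set")) found$clusters else found
  modules <- truth$modules
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  if (length(clusters)) {
    jm <- sapply(clusters, function(cl) {
      vapply(modules, jacc, numeric(1), b = cl)
    })
    jm <- matrix(jm, nrow = length(modules),
                 dimnames = list(names(modules), names(clusters)))
  } else {
    jm <- matrix(numeric(0), nrow = length(modules), ncol = 0,
                 dimnames = list(names(modules), NULL))
  }
  match_cl <- stats::setNames(rep(NA_character_, length(modules)),
                              names(modules))
  best_j <- stats::setNames(numeric(length(modules)), names(modules))
  if (ncol(jm) > 0) {
    pairs <- expand.grid(module = rownames(jm), cluster = colnames(jm),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pairs$j <- jm[cbind(pairs$module, pairs$cluster)]
    pairs <- pairs[order(-pairs$j, pairs$module, pairs$cluster), ]
    used_cl <- character(0)
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      if (p$j <= 0) break
      if (is.na(match_cl[p$module]) && !(p$cluster %in% used_cl)) {
        match_cl[p$module] <- p$cluster
        best_j[p$module] <- p$j
        used_cl <- c(used_cl, p$cluster)
      }
    }
  }
  per_module <- data.frame(
    module_id = names(modules), cluster_id = unname(match_cl),
    jaccard = unname(best_j),
    recovered = unname(best_j) >= jaccard_min,
    stringsAsFactors = FALSE)
  # fraction of within-module gene pairs co-clustered in a found cluster
  cl_of <- stats::setNames(
    rep(names(clusters), lengths(clusters)),
    unlist(clusters, use.names = FALSE))
  tot <- 0L; hit <- 0L
  for (m in names(modules)) {
    g <- modules[[m]]
    if (length(g) < 2L) next
    cp <- utils::combn(g, 2L)
    tot <- tot + ncol(cp)
    a <- cl_of[cp[1L, ]]; b <- cl_of[cp[2L, ]]
    hit <- hit + sum(!is.na(a) & !is.na(b) & a == b)
  }
  structure(list(per_module = per_module,
                 n_recovered = sum(per_module$recovered),
                 n_modules = length(modules),
                 jaccard_min = jaccard_min,
                 pair_coclustering = if (tot > 0) hit / tot else NA_real_),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovered %d/%d modules at Jaccard >= %.2f; pair co-clustering %.3f\n",
              x$n_recovered, x$n_modules, x$jaccard_min,
              x$pair_coclustering))
  invisible(x)
}

#' Write a synthetic dataset to TSV files
#'
#' Emits the same formats the readers consume: `ontology_edges.tsv`,
#' `annotations.tsv`, `functional.tsv`, plus the ground truth
#' `truth_modules.tsv`, `truth_signatures.tsv` and
#' `truth_functional.tsv`. Every file carries comment headers recording
#' the tool version and the generator seed.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(pkg_version_string(), paste0("seed=", dataset$config$seed))
  write_edge_table(dataset$ontology, file.path(dir, "ontology_edges.tsv"),
                   hdr)
  ann <- dataset$annotations
  ann$pattern[is.na(ann$pattern)] <- ""
  write_tsv(ann, file.path(dir, "annotations.tsv"), hdr)
  write_tsv(dataset$functional, file.path(dir, "functional.tsv"), hdr)
  tm <- data.frame(
    module_id = rep(names(dataset$truth$modules),
                    lengths(dataset$truth$modules)),
    gene_id = unlist(dataset$truth$modules, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(tm, file.path(dir, "truth_modules.tsv"), hdr)
  ts <- data.frame(
    module_id = rep(names(dataset$truth$signatures),
                    lengths(dataset$truth$signatures)),
    term_id = unlist(dataset$truth$signatures, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(ts, file.path(dir, "truth_signatures.tsv"), hdr)
  write_tsv(dataset$truth$functional, file.path(dir, "truth_functional.tsv"),
            hdr)
  invisible(dir)
}
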