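strength_levels <- c("not_detected", "weak", "moderate", "strong")
pattern_levels <- c("homogeneous", "regional", "single_cell")

#' Ordinal strength encoding
#'
#' Maps the four curated strength levels onto numeric expression values.
#' The default 0/1/2/3 is the simplest strictly increasing map with 0
#' for "not detected"; because gene profiles are later compared with the
#' centered Pearson correlation, which is invariant to per-gene positive
#' rescaling, any positive multiple of an admissible encoding yields the
#' identical correlation structure.
#'
#' @param not_detected,weak,moderate,strong numeric values, strictly
#'   increasing, with `not_detected` equal to 0.
#' @return named numeric vector of class `strength_encoding`.
#' @export
strength_encoding <- function(not_detected = 0, weak = 1, moderate = 2,
                              strong = 3) {
  v <- c(not_detected = not_detected, weak = weak, moderate = moderate,
         strong = strong)
  if (any(!is.finite(v))) stop("encoding values must be finite", call. = FALSE)
  if (v[["not_detected"]] != 0) {
    stop("not_detected must encode to 0", call. = FALSE)
  }
  if (any(diff(v) <= 0)) {
    stop("encoding must be strictly increasing with strength", call. = FALSE)
  }
  structure(v, class = "strength_encoding")
}

#' Read a curated expression annotation table
#'
#' The table is tab-delimited with a mandatory header containing columns
#' `gene_id`, `term_id`, `strength` and optionally `pattern`. Strength
#' and pattern tokens are matched case-insensitively; an empty pattern
#' cell is allowed.
#'
#' @param file path to the annotation TSV.
#' @param ontology optional `term_ontology`; if supplied, records whose
#'   `term_id` is absent from the ontology trigger a collected warning
#'   (or an error when `strict = TRUE`).
#' @param strict logical; reject unknown anatomy terms instead of
#'   warning.
#' @return data.frame with columns `gene_id`, `term_id`, `strength`,
#'   `pattern` (`NA` where absent), in file order.
#' @export
read_annotations <- function(file, ontology = NULL, strict = FALSE) {
  parsed <- read_tsv_lines(file)
  req <- c("gene_id", "term_id", "strength")
  if (!all(req %in% parsed$header)) {
    stop("annotation table must have header columns gene_id, term_id, strength",
         call. = FALSE)
  }
  has_pattern <- "pattern" %in% parsed$header
  col <- match(c(req, if (has_pattern) "pattern"), parsed$header)
  n_fields <- length(parsed$header)
  n <- length(parsed$rows)
  gene <- term <- strength <- pattern <- character(n)
  for (i in seq_len(n)) {
    r <- parsed$rows[[i]]
    # a trailing empty pattern field may be dropped by the line split
    if (length(r) == n_fields - 1L && has_pattern &&
        col[4L] == n_fields) {
      r <- c(r, "")
    }
    if (length(r) != n_fields || any(!nzchar(r[col[1:3]]))) {
      stop("malformed annotation row at line ", parsed$lines[i],
           call. = FALSE)
    }
    s <- tolower(r[col[3L]])
    if (!s %in% strength_levels) {
      stop("unknown strength token '", r[col[3L]], "' at line ",
           parsed$lines[i], call. = FALSE)
    }
    p <- if (has_pattern) tolower(r[col[4L]]) else ""
    if (nzchar(p) && !p %in% pattern_levels) {
      stop("unknown pattern token '", r[col[4L]], "' at line ",
           parsed$lines[i], call. = FALSE)
    }
    gene[i] <- r[col[1L]]
    term[i] <- r[col[2L]]
    strength[i] <- s
    pattern[i] <- if (nzchar(p)) p else NA_character_
  }
  out <- data.frame(gene_id = gene, term_id = term, strength = strength,
                    pattern = pattern, stringsAsFactors = FALSE)
  if (!is.null(ontology)) {
    unknown <- setdiff(unique(out$term_id), term_ids(ontology))
    if (length(unknown)) {
      msg <- paste0("annotation references term(s) absent from the ontology: ",
                    paste(unknown, collapse = ", "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  out
}

check_annotation_records <- function(records) {
  req <- c("gene_id", "term_id", "strength")
  stopifnot(is.data.frame(records), all(req %in% names(records)))
  bad <- setdiff(unique(records$strength), strength_levels)
  if (length(bad)) {
    stop("unknown strength level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!"pattern" %in% names(records)) records$pattern <- NA_character_
  records
}

#' Classify a gene's overall expression category
#'
#' Collapses a gene's annotation records into one of the three atlas
#' categories: `not_detected` (no record above "not detected"),
#' `ubiquitous` (a detected homogeneous record on a root term, or
#' detected annotation covering at least `coverage_fraction` of the
#' ontology's leaf terms), or `regional` (detected in a limited set of
#' discrete locations) otherwise.
#'
#' @param records annotation records for a single gene.
#' @param ontology a `term_ontology`.
#' @param coverage_fraction leaf-coverage fraction above which a
#'   detected gene counts as ubiquitous (default 0.9).
#' @return one of `"not_detected"`, `"ubiquitous"`, `"regional"`.
#' @export
classify_gene <- function(records, ontology, coverage_fraction = 0.9) {
  records <- check_annotation_records(records)
  if (length(unique(records$gene_id)) > 1L) {
    stop("classify_gene expects records for a single gene", call. = FALSE)
  }
  detected <- records$strength != "not_detected"
  if (!any(detected)) return("not_detected")
  pat <- records$pattern
  root_homog <- any(detected & !is.na(pat) & pat == "homogeneous" &
                      records$term_id %in% ontology$roots)
  if (root_homog) return("ubiquitous")
  leaves <- ontology_leaves(ontology)
  covered <- unique(records$term_id[detected])
  if (length(leaves) > 0L &&
      length(intersect(covered, leaves)) / length(leaves) >=
        coverage_fraction) {
    return("ubiquitous")
  }
  "regional"
}

#' Classify every annotated gene
#'
#' @param records annotation records for any number of genes.
#' @inheritParams classify_gene
#' @return named character vector of categories, one entry per gene in
#'   order of first appearance.
#' @export
classify_genes <- function(records, ontology, coverage_fraction = 0.9) {
  records <- check_annotation_records(records)
  genes <- unique(records$gene_id)
  idx <- split(seq_len(nrow(records)),
               factor(records$gene_id, levels = genes))
  vapply(genes, function(g) {
    classify_gene(records[idx[[g]], , drop = FALSE], ontology,
                  coverage_fraction)
  }, character(1))
}

#' Regionally expressed genes
#'
#' The subset of annotated genes whose overall category is `regional`;
#' only these enter synexpression clustering.
#'
#' @inheritParams classify_genes
#' @return character vector of gene ids in input order.
#' @export
select_genes_regional <- function(records, ontology,
                                  coverage_fraction = 0.9) {
  cls <- classify_genes(records, ontology, coverage_fraction)
  names(cls)[cls == "regional"]
}

#' Build the (propagated) gene-by-term expression matrix
#'
#' Encodes each gene's annotation records numerically, collapses
#' duplicate (gene, term) records by maximum, optionally applies maximal
#' upward propagation through the ontology, and restricts the column
#' space by a term-selection policy.
#'
#' @param records annotation records (see [read_annotations()]).
#' @param ontology a `term_ontology`; every annotated term must belong
#'   to it.
#' @param encoding a [strength_encoding()].
#' @param propagate logical; apply [propagate_max()] per gene (default
#'   `TRUE`).
#' @param term_policy,terms,min_genes forwarded to [select_terms()];
#'   default policy `"all"` keeps every ontology term as a column.
#' @return numeric matrix with gene rows and term columns.
#' @export
build_matrix <- function(records, ontology,
                         encoding = strength_encoding(),
                         propagate = TRUE, term_policy = "all",
                         terms = NULL, min_genes = 1) {
  records <- check_annotation_records(records)
  if (nrow(records) == 0L) stop("empty matrix: no annotation records",
                                call. = FALSE)
  unknown <- setdiff(unique(records$term_id), term_ids(ontology))
  if (length(unknown)) {
    stop("annotation references term(s) absent from the ontology: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  genes <- unique(records$gene_id)
  ids <- term_ids(ontology)
  m <- matrix(0, nrow = length(genes), ncol = length(ids),
              dimnames = list(genes, ids))
  vals <- unclass(encoding)[records$strength]
  # duplicate (gene, term) records collapse by maximum value
  key <- paste(records$gene_id, records$term_id, sep = "\r")
  agg <- tapply(vals, key, max)
  gt <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  m[cbind(match(gt[, 1L], genes), match(gt[, 2L], ids))] <- as.numeric(agg)
  if (propagate) m <- propagate_matrix(ontology, m)
  select_terms(m, ontology, policy = term_policy, terms = terms,
               min_genes = min_genes)
}

#' Restrict the column space of an expression matrix
#'
#' @param matrix gene-by-term numeric matrix.
#' @param ontology the `term_ontology` the columns live in (needed to
#'   identify roots and leaves).
#' @param policy one of `"all"`, `"drop_empty"` (remove root terms —
#'   propagation makes them uninformative — and terms expressed in fewer
#'   than `min_genes` genes), or `"leaves_only"`. Ignored when an
#'   explicit `terms` list is given.
#' @param terms optional explicit term list; the result has exactly
#'   these columns in list order, and an unknown term is an error.
#' @param min_genes minimum number of genes with value > 0 for a column
#'   to survive `drop_empty` (default 1).
#' @return the column-filtered matrix, original column order preserved.
#' @export
select_terms <- function(matrix, ontology,
                         policy = c("drop_empty", "all", "leaves_only"),
                         terms = NULL, min_genes = 1) {
  stopifnot(is.matrix(matrix))
  if (!is.null(terms)) {
    unknown <- setdiff(terms, colnames(matrix))
    if (length(unknown)) {
      stop("explicit term list contains unknown term(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    return(matrix[, terms, drop = FALSE])
  }
  policy <- match.arg(policy)
  if (policy == "all") return(matrix)
  if (policy == "leaves_only") {
    keep <- colnames(matrix) %in% ontology_leaves(ontology)
    return(matrix[, keep, drop = FALSE])
  }
  keep <- !(colnames(matrix) %in% ontology$roots) &
    colSums(matrix > 0) >= min_genes
  matrix[, keep, drop = FALSE]
}

#' Write an expression matrix as TSV
#'
#' @param matrix gene-by-term numeric matrix.
#' @param path output path.
#' @param comments optional comment header lines.
#' @export
write_matrix <- function(matrix, path, comments = character()) {
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, comments)
}
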