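#' Construct a term ontology
#'
#' A term ontology is a directed acyclic graph of terms connected by
#' `is_a` / `part_of` parent links. It serves both as the anatomical
#' coordinate system for expression annotations (e.g. an EMAP-style
#' embryo anatomy tree) and as the structure of GO-like functional
#' namespaces. Both relation types transmit expression values upward
#' identically: annotation at a child implies annotation of the whole.
#'
#' @param terms data.frame with columns `term_id` and `name`.
#' @param edges data.frame with columns `child_id`, `parent_id`,
#'   `relation` (each relation one of `"is_a"`, `"part_of"`).
#' @return An object of class `term_ontology` with elements `terms`
#'   (named character vector id -> name), `edges`, `roots`, and
#'   internal adjacency indices.
#' @details Validation enforces: unique term ids, every parent id
#'   resolving to a declared term, an acyclic parent graph, and at
#'   least one root (a term with no parents).
#' @export
term_ontology <- function(terms, edges) {
  stopifnot(is.data.frame(terms), all(c("term_id", "name") %in% names(terms)))
  stopifnot(is.data.frame(edges) || is.null(edges))
  if (is.null(edges)) {
    edges <- data.frame(child_id = character(), parent_id = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  ids <- as.character(terms$term_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate term id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(ids) == 0L) {
    stop("ontology has no terms and therefore zero roots", call. = FALSE)
  }
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel)) {
    stop("unsupported relation(s): ", paste(bad_rel, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(c(edges$child_id, edges$parent_id)), ids)
  if (length(unknown)) {
    stop("edge references undeclared term id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  edges <- unique(edges[, c("child_id", "parent_id", "relation")])
  g <- igraph::graph_from_data_frame(
    edges[, c("child_id", "parent_id")], directed = TRUE,
    vertices = data.frame(name = ids)
  )
  if (!igraph::is_dag(g)) {
    stop("parent links contain a cycle", call. = FALSE)
  }
  has_parent <- ids %in% edges$child_id
  roots <- ids[!has_parent]
  if (length(roots) == 0L) {
    stop("ontology has zero roots", call. = FALSE)
  }
  # children-first order: every edge child -> parent goes left to right
  topo <- names(igraph::topo_sort(g, mode = "out"))
  parents_of <- split(edges$parent_id, factor(edges$child_id, levels = ids))
  children_of <- split(edges$child_id, factor(edges$parent_id, levels = ids))
  structure(list(
    terms = stats::setNames(as.character(terms$name), ids),
    edges = edges,
    roots = roots,
    topo = topo,
    parents_of = parents_of,
    children_of = children_of,
    graph = g
  ), class = "term_ontology")
}

#' @export
print.term_ontology <- function(x, ...) {
  cat("term_ontology:", length(x$terms), "terms,",
      nrow(x$edges), "parent links,",
      length(x$roots), "root(s),",
      length(ontology_leaves(x)), "leaves\n")
  invisible(x)
}

term_ids <- function(ontology) names(ontology$terms)

#' Leaf terms of an ontology
#'
#' Terms with no children; in an anatomy ontology these are the finest
#' structures available to annotators.
#' @param ontology a `term_ontology`.
#' @return character vector of term ids.
#' @export
ontology_leaves <- function(ontology) {
  ids <- term_ids(ontology)
  ids[!(ids %in% ontology$edges$parent_id)]
}

check_term <- function(ontology, term) {
  if (length(term) != 1L || !term %in% term_ids(ontology)) {
    stop("unknown term id: ", paste(term, collapse = ", "), call. = FALSE)
  }
}

#' Transitive descendants of a term
#'
#' All terms from which `term` is reachable along child-to-parent links,
#' excluding `term` itself.
#' @param ontology a `term_ontology`.
#' @param term a single term id.
#' @return character vector of term ids (possibly empty).
#' @export
descendants <- function(ontology, term) {
  check_term(ontology, term)
  v <- names(igraph::subcomponent(ontology$graph, term, mode = "in"))
  setdiff(v, term)
}

#' Transitive ancestors of a term
#'
#' @inheritParams descendants
#' @return character vector of term ids (possibly empty).
#' @export
ancestors <- function(ontology, term) {
  check_term(ontology, term)
  v <- names(igraph::subcomponent(ontology$graph, term, mode = "out"))
  setdiff(v, term)
}

#' Maximal upward propagation of expression values
#'
#' Implements the maximal-propagation rule used to place annotation-level
#' expression values on the whole anatomical tree: every parent term
#' acquires the values of its child terms, so the value at term `t`
#' becomes the maximum of its own raw value and the raw values of all of
#' its descendants. Terms without a raw value default to 0 (not
#' detected).
#'
#' @param ontology a `term_ontology`.
#' @param raw named numeric vector of raw values (names are term ids;
#'   values finite and >= 0).
#' @return named numeric vector defined on every term carrying a raw
#'   value and on all ancestors of such terms, in ontology term order.
#' @details Computed by a single children-first topological sweep;
#'   equivalent to taking, for each term, the maximum over its
#'   descendant closure. The operation is monotone (no value decreases,
#'   and a parent's value is at least each child's) and idempotent.
#' @export
propagate_max <- function(ontology, raw) {
  if (length(raw) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stop("raw values must be named by term id", call. = FALSE)
  }
  unknown <- setdiff(names(raw), term_ids(ontology))
  if (length(unknown)) {
    stop("raw values reference unknown term(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop("raw values must be finite and >= 0", call. = FALSE)
  }
  ids <- term_ids(ontology)
  vals <- stats::setNames(numeric(length(ids)), ids)
  vals[names(raw)] <- pmax(vals[names(raw)], raw)
  for (v in ontology$topo) {
    ps <- ontology$parents_of[[v]]
    if (length(ps)) {
      vals[ps] <- pmax(vals[ps], vals[[v]])
    }
  }
  touched <- unique(c(names(raw), unlist(
    lapply(names(raw), function(t) ancestors(ontology, t)),
    use.names = FALSE
  )))
  vals[ids[ids %in% touched]]
}

# Column-wise maximal propagation of a gene x term matrix whose columns
# span all ontology terms. Same contract as propagate_max applied per row.
propagate_matrix <- function(ontology, m) {
  stopifnot(identical(colnames(m), term_ids(ontology)))
  for (v in ontology$topo) {
    ps <- ontology$parents_of[[v]]
    for (p in ps) {
      m[, p] <- pmax(m[, p], m[, v])
    }
  }
  m
}

#' Parse an OBO 1.2 subset into a term ontology
#'
#' Reads `[Term]` stanzas and honours the tags `id`, `name`, `is_a`,
#' `relationship: part_of` and `is_obsolete` (obsolete terms are
#' skipped). All other tags and stanza types are ignored.
#'
#' @param file path to an OBO file (or a connection).
#' @return a `term_ontology`.
#' @export
parse_obo <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  term_open <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (is.null(cur) || cur$obsolete) return(terms)
    if (is.null(cur$id)) stop("[Term] stanza without id", call. = FALSE)
    terms[[length(terms) + 1L]] <- cur
    terms
  }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      term_open <- identical(ln, "[Term]")
      if (term_open) {
        cur <- list(id = NULL, name = NULL, parents = character(),
                    relations = character(), obsolete = FALSE)
      }
      next
    }
    if (!term_open || !nzchar(ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) next
    tag <- m[2L]
    val <- m[3L]
    val <- sub("\\s*!.*$", "", val)  # strip trailing comment
    if (tag == "id") {
      cur$id <- trimws(val)
    } else if (tag == "name") {
      cur$name <- trimws(val)
    } else if (tag == "is_a") {
      cur$parents <- c(cur$parents, trimws(val))
      cur$relations <- c(cur$relations, "is_a")
    } else if (tag == "relationship") {
      parts <- strsplit(trimws(val), "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[1L] == "part_of") {
        cur$parents <- c(cur$parents, parts[2L])
        cur$relations <- c(cur$relations, "part_of")
      }
    } else if (tag == "is_obsolete") {
      cur$obsolete <- isTRUE(trimws(val) == "true")
    }
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0L) {
    stop("no [Term] stanzas found", call. = FALSE)
  }
  ids <- vapply(terms, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate term id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  nms <- vapply(terms, function(t) if (is.null(t$name)) t$id else t$name,
                character(1))
  edges <- do.call(rbind, lapply(terms, function(t) {
    if (!length(t$parents)) return(NULL)
    data.frame(child_id = t$id, parent_id = t$parents,
               relation = t$relations, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(child_id = character(), parent_id = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  term_ontology(data.frame(term_id = ids, name = nms,
                           stringsAsFactors = FALSE), edges)
}

#' Parse a child/parent TSV edge table into a term ontology
#'
#' Expects a header row with columns `child_id`, `parent_id`,
#' `relation`; lines starting with `#` are treated as comments. Term
#' names default to the term ids.
#'
#' @param file path to a tab-delimited edge table.
#' @return a `term_ontology`.
#' @export
parse_edge_table <- function(file) {
  parsed <- read_tsv_lines(file)
  req <- c("child_id", "parent_id", "relation")
  if (!all(req %in% parsed$header)) {
    stop("edge table must have header columns child_id, parent_id, relation",
         call. = FALSE)
  }
  col <- match(req, parsed$header)
  n_fields <- length(parsed$header)
  rows <- vector("list", length(parsed$rows))
  for (i in seq_along(parsed$rows)) {
    r <- parsed$rows[[i]]
    if (length(r) != n_fields || any(!nzchar(r[col]))) {
      stop("malformed edge row at line ", parsed$lines[i], call. = FALSE)
    }
    if (!r[col[3L]] %in% c("is_a", "part_of")) {
      stop("unsupported relation '", r[col[3L]], "' at line ",
           parsed$lines[i], call. = FALSE)
    }
    rows[[i]] <- r[col]
  }
  if (length(rows) == 0L) {
    # an edge table with no rows declares no terms at all
    stop("ontology has no terms and therefore zero roots", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  edges <- data.frame(child_id = m[, 1L], parent_id = m[, 2L],
                      relation = m[, 3L], stringsAsFactors = FALSE)
  ids <- unique(c(edges$child_id, edges$parent_id))
  term_ontology(data.frame(term_id = ids, name = ids,
                           stringsAsFactors = FALSE), edges)
}

#' Write an ontology as a TSV edge table
#'
#' @param ontology a `term_ontology`.
#' @param path output file path.
#' @param comments optional character vector of comment header lines.
#' @return the path, invisibly.
#' @export
write_edge_table <- function(ontology, path, comments = character()) {
  write_tsv(ontology$edges, path, comments)
}
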