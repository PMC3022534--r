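# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the code paths they are used to check.

# --- fixtures -------------------------------------------------------------

chain_ontology <- function(ids = c("A", "B", "C"), relation = "is_a") {
  # ids[1] is the root; each subsequent id is a child of its predecessor
  term_ontology(
    data.frame(term_id = ids, name = ids, stringsAsFactors = FALSE),
    data.frame(child_id = ids[-1L], parent_id = ids[-length(ids)],
               relation = relation, stringsAsFactors = FALSE))
}

# random DAG edge table: term i may take parents among terms 1..i-1,
# which rules out cycles by construction; term 1 is always a root
random_dag_edges <- function(n, max_parents = 3) {
  ids <- sprintf("T%02d", seq_len(n))
  child <- parent <- character(0)
  for (i in 2:n) {
    k <- sample(0:min(max_parents, i - 1L), 1L)
    if (k > 0) {
      ps <- sample(seq_len(i - 1L), k)
      child <- c(child, rep(ids[i], k))
      parent <- c(parent, ids[ps])
    }
  }
  list(ids = ids,
       edges = data.frame(child_id = child, parent_id = parent,
                          relation = sample(c("is_a", "part_of"),
                                            length(child), replace = TRUE),
                          stringsAsFactors = FALSE))
}

random_dag_ontology <- function(n, max_parents = 3) {
  d <- random_dag_edges(n, max_parents)
  term_ontology(data.frame(term_id = d$ids, name = d$ids,
                           stringsAsFactors = FALSE), d$edges)
}

# --- graph oracles --------------------------------------------------------

# exhaustive reachability: all terms below `term`, by repeated frontier
# expansion over the raw edge list
oracle_descendants <- function(edges, term) {
  out <- character(0)
  frontier <- term
  repeat {
    kids <- unique(edges$child_id[edges$parent_id %in% frontier])
    new <- setdiff(kids, c(out, term))
    if (!length(new)) break
    out <- c(out, new)
    frontier <- new
  }
  sort(out)
}

oracle_ancestors <- function(edges, term) {
  out <- character(0)
  frontier <- term
  repeat {
    ps <- unique(edges$parent_id[edges$child_id %in% frontier])
    new <- setdiff(ps, c(out, term))
    if (!length(new)) break
    out <- c(out, new)
    frontier <- new
  }
  sort(out)
}

# per-term maximum over the descendant closure (the propagation contract)
oracle_propagate <- function(edges, all_ids, raw) {
  val <- function(t) if (t %in% names(raw)) raw[[t]] else 0
  vapply(all_ids, function(t) {
    max(c(val(t), vapply(oracle_descendants(edges, t), val, numeric(1))))
  }, numeric(1))
}

# --- clustering oracle ----------------------------------------------------

# naive O(n^3) agglomeration recomputing every cross-pair mean from the
# original distance matrix at each step; same tie-break contract as the
# implementation (smallest representative-leaf pair)
oracle_average_linkage <- function(D) {
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  nodes <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- length(members)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        d <- mean(D[members[[i]], members[[j]]])
        ra <- min(members[[i]]); rb <- min(members[[j]])
        k1 <- min(ra, rb); k2 <- max(ra, rb)
        better <- is.null(best) || d < best$d ||
          (d == best$d && (k1 < best$k1 ||
                             (k1 == best$k1 && k2 < best$k2)))
        if (better) {
          best <- list(d = d, i = if (ra < rb) i else j,
                       j = if (ra < rb) j else i, k1 = k1, k2 = k2)
        }
      }
    }
    merge[s, ] <- c(nodes[best$i], nodes[best$j])
    height[s] <- best$d
    members[[best$i]] <- c(members[[best$i]], members[[best$j]])
    nodes[best$i] <- s
    members[[best$j]] <- NULL
    nodes <- nodes[-best$j]
  }
  list(merge = merge, height = height)
}

# --- hypergeometric oracle ------------------------------------------------

# exhaustive enumeration of all C(N, n) draws; probability that at least
# k of the n drawn genes fall among the K tagged ones
oracle_hyper_upper <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# --- misc -----------------------------------------------------------------

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

ann_df <- function(gene, term, strength, pattern = NA_character_) {
  n <- max(length(gene), length(term), length(strength))
  data.frame(gene_id = rep(gene, length.out = n),
             term_id = rep(term, length.out = n),
             strength = rep(strength, length.out = n),
             pattern = rep(pattern, length.out = n),
             stringsAsFactors = FALSE)
}
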