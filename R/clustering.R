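#' Clustering parameters
#'
#' @param r_min correlation threshold for the flat tree cut; a cluster
#'   only contains merges whose average cross-pair correlation is at
#'   least `r_min` (default 0.7).
#' @param min_report_size smallest gene count for a reported cluster;
#'   smaller groups are returned as singletons (default 2).
#' @param min_enrich_size smallest cluster size admitted to functional
#'   enrichment testing (default 10, to ensure sufficient annotation).
#' @return list of class `clustering_params`.
#' @export
clustering_params <- function(r_min = 0.7, min_report_size = 2,
                              min_enrich_size = 10) {
  if (!(r_min > -1 && r_min < 1)) {
    stop("r_min must lie in (-1, 1)", call. = FALSE)
  }
  if (!(min_enrich_size >= min_report_size && min_report_size >= 1)) {
    stop("need min_enrich_size >= min_report_size >= 1", call. = FALSE)
  }
  structure(list(r_min = r_min, min_report_size = min_report_size,
                 min_enrich_size = min_enrich_size),
            class = "clustering_params")
}

#' Centered Pearson correlation of two expression profiles
#'
#' @param x,y numeric vectors of equal length >= 2 with nonzero
#'   variance.
#' @return correlation in \[-1, 1\].
#' @export
pearson_centered <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("x and y must have equal length >= 2", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("profiles must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero-variance profile: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Gene-by-gene correlation matrix
#'
#' @param matrix gene-by-term numeric matrix; every row must vary
#'   across the selected terms.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2L, ncol(matrix) >= 2L)
  v <- apply(matrix, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene profile(s): ",
         paste(rownames(matrix)[v == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(matrix))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Average-linkage agglomeration of a distance matrix
#'
#' Unweighted (UPGMA-style) average linkage: the distance between two
#' clusters is the mean over all cross pairs. Under the synexpression
#' distance d = 1 - r this makes every merge height interpretable as
#' 1 minus the mean cross-pair correlation. Ties in the minimum distance
#' are broken deterministically by the smallest (left, right) pair of
#' cluster representatives, a cluster being represented by its smallest
#' original leaf index.
#'
#' @param distances square symmetric matrix (or `dist`) with zero
#'   diagonal; typically `1 - correlation_matrix(m)`.
#' @return an object of class `hclust` (merge matrix, non-decreasing
#'   heights, leaf order and labels), so the standard dendrogram tools
#'   apply.
#' @export
average_linkage <- function(distances) {
  d <- as.matrix(distances)
  n <- nrow(d)
  stopifnot(n >= 2L, ncol(d) == n)
  if (max(abs(d - t(d))) > 1e-9) {
    stop("distance matrix is asymmetric beyond 1e-9", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must have zero diagonal", call. = FALSE)
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d <- (d + t(d)) / 2
  diag(d) <- Inf

  active <- rep(TRUE, n)
  size <- rep(1L, n)
  node <- -seq_len(n)          # hclust node id of the cluster in each slot
  rep_leaf <- seq_len(n)       # smallest original leaf index per slot
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    dmin <- min(d[active, active])
    cand <- which(d == dmin & outer(active, active, `&`), arr.ind = TRUE)
    # orient each candidate pair by representative, then take the
    # lexicographically smallest (left, right) representative pair
    a <- cand[, 1L]; b <- cand[, 2L]
    lo <- ifelse(rep_leaf[a] < rep_leaf[b], a, b)
    hi <- ifelse(rep_leaf[a] < rep_leaf[b], b, a)
    ord <- order(rep_leaf[lo], rep_leaf[hi])
    i <- lo[ord[1L]]; j <- hi[ord[1L]]
    merge[s, ] <- c(node[i], node[j])
    height[s] <- dmin
    # Lance-Williams update for unweighted average linkage
    others <- which(active); others <- others[others != i & others != j]
    if (length(others)) {
      dn <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[i, others] <- dn
      d[others, i] <- dn
    }
    size[i] <- size[i] + size[j]
    node[i] <- s
    rep_leaf[i] <- min(rep_leaf[i], rep_leaf[j])
    active[j] <- FALSE
    d[j, ] <- Inf
    d[, j] <- Inf
  }

  ord_of <- vector("list", n - 1L)
  expand <- function(x) if (x < 0L) -x else ord_of[[x]]
  for (s in seq_len(n - 1L)) {
    ord_of[[s]] <- c(expand(merge[s, 1L]), expand(merge[s, 2L]))
  }
  structure(list(merge = merge, height = height,
                 order = ord_of[[n - 1L]], labels = labels,
                 method = "average", call = match.call(),
                 dist.method = "1 - centered Pearson"),
            class = "hclust")
}

#' Cut a merge tree into flat synexpression clusters
#'
#' Flat clusters are the maximal subtrees all of whose internal merge
#' heights are at most `1 - r_min`, so within every reported cluster
#' each agglomeration step joined groups with mean cross-pair
#' correlation >= `r_min`. Groups smaller than `min_report_size` are
#' returned as singletons. Cluster ids are assigned 1..k in decreasing
#' size, ties broken by the smallest member gene id.
#'
#' @param tree an `hclust` object from [average_linkage()].
#' @param params a [clustering_params()].
#' @param cor optional correlation matrix (dimnames matching the tree
#'   labels) used to record each cluster's mean pairwise correlation.
#' @return list of class `cluster_set` with elements `clusters` (named
#'   list of gene id vectors), `singletons`, `mean_r`, `params`.
#' @export
cut_at_correlation <- function(tree, params = clustering_params(),
                               cor = NULL) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  h_max <- 1 - params$r_min
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # representative leaf of each internal node, for leaf-level union-find
  first_leaf <- integer(max(n - 1L, 1L))
  leaf_of <- function(x) if (x < 0L) -x else first_leaf[x]
  for (s in seq_len(n - 1L)) {
    first_leaf[s] <- leaf_of(tree$merge[s, 1L])
    # average-linkage heights are monotone, so a merge below the cut
    # height always has both child subtrees below it as well
    if (tree$height[s] <= h_max + 1e-12) {
      a <- find(leaf_of(tree$merge[s, 1L]))
      b <- find(leaf_of(tree$merge[s, 2L]))
      parent[a] <- b
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(tree$labels, comp)
  sizes <- lengths(groups)
  multi <- groups[sizes >= params$min_report_size]
  singletons <- sort(unlist(groups[sizes < params$min_report_size],
                            use.names = FALSE))
  if (is.null(singletons)) singletons <- character(0)
  multi <- lapply(multi, sort)
  if (length(multi)) {
    first_gene <- vapply(multi, `[[`, character(1), 1L)
    ord <- order(-lengths(multi), first_gene)
    multi <- multi[ord]
    names(multi) <- as.character(seq_along(multi))
  } else {
    multi <- stats::setNames(list(), character(0))
  }
  mean_r <- rep(NA_real_, length(multi))
  names(mean_r) <- names(multi)
  if (!is.null(cor) && length(multi)) {
    for (id in names(multi)) {
      sub <- cor[multi[[id]], multi[[id]]]
      mean_r[id] <- mean(sub[upper.tri(sub)])
    }
  }
  structure(list(clusters = multi, singletons = singletons,
                 mean_r = mean_r, params = params, n_genes = n),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters of >=",
      x$params$min_report_size, "genes,",
      length(x$singletons), "singletons,",
      x$n_genes, "genes total\n")
  if (length(x$clusters)) {
    cat("  sizes:", paste(lengths(x$clusters), collapse = " "), "\n")
  }
  invisible(x)
}

#' Cluster membership as a data.frame
#'
#' @param x a `cluster_set`.
#' @param ... unused.
#' @return data.frame with columns `cluster_id`, `gene_id`,
#'   `cluster_size`, `mean_intra_r`.
#' @export
as.data.frame.cluster_set <- function(x, ...) {
  if (!length(x$clusters)) {
    return(data.frame(cluster_id = integer(), gene_id = character(),
                      cluster_size = integer(), mean_intra_r = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(names(x$clusters), function(id) {
    g <- x$clusters[[id]]
    data.frame(cluster_id = as.integer(id), gene_id = g,
               cluster_size = length(g),
               mean_intra_r = unname(x$mean_r[id]),
               stringsAsFactors = FALSE)
  }))
}

#' Expression occupancy of clusters
#'
#' For each cluster and anatomical term: the number of cluster genes
#' expressed in the term (propagated value > 0) divided by the cluster
#' size, giving a fraction in \[0, 1\].
#'
#' @param clusters a `cluster_set`.
#' @param matrix the propagated gene-by-term expression matrix the
#'   clusters were derived from.
#' @return numeric matrix with cluster-id rows and term columns.
#' @export
occupancy <- function(clusters, matrix) {
  stopifnot(inherits(clusters, "cluster_set"), is.matrix(matrix))
  missing <- setdiff(unlist(clusters$clusters, use.names = FALSE),
                     rownames(matrix))
  if (length(missing)) {
    stop("cluster gene(s) missing from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- matrix(0, nrow = length(clusters$clusters), ncol = ncol(matrix),
                dimnames = list(names(clusters$clusters), colnames(matrix)))
  for (id in names(clusters$clusters)) {
    g <- clusters$clusters[[id]]
    out[id, ] <- colMeans(matrix[g, , drop = FALSE] > 0)
  }
  out
}

#' Export a merge tree as Newick
#'
#' Branch lengths follow the merge heights, so tip-to-ancestor path
#' lengths reproduce the dendrogram geometry.
#'
#' @param tree an `hclust` object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
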