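test_that("upper-tail hypergeometric probability is exact", {
  expect_equal(hypergeom_upper(0, 5, 4, 10), 1.0)
  # exhaustive count: 66 of the 252 five-gene draws from 10 hit >= 3 of 4
  expect_equal(hypergeom_upper(3, 5, 4, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_upper(3, 3, 3, 3), 1.0)
  expect_error(hypergeom_upper(5, 4, 10, 20), "violate")
  expect_error(hypergeom_upper(1, 5, 4, 3), "violate")
  expect_error(hypergeom_upper(0.5, 5, 4, 10), "integer")
  # monotone non-increasing in k
  p <- hypergeom_upper(0:4, 6, 4, 12)
  expect_true(all(diff(p) <= 0))
})

test_that("true-path closure matches brute-force ancestor enumeration", {
  ont <- chain_ontology(c("GO:top", "GO:mid", "GO:leaf"))
  ann <- data.frame(gene_id = "g1", namespace = "GO", term_id = "GO:leaf",
                    stringsAsFactors = FALSE)
  closed <- propagate_functional(ann, list(GO = ont))
  expect_equal(nrow(closed), 3)
  expect_setequal(closed$term_id, c("GO:top", "GO:mid", "GO:leaf"))

  flat <- data.frame(gene_id = c("g1", "g2"), namespace = "cytoband",
                     term_id = c("1q21", "2p12"), stringsAsFactors = FALSE)
  expect_identical(propagate_functional(flat), flat)

  expect_error(propagate_functional(ann, dag_namespaces = "GO"),
               "without an ontology")

  set.seed(3)
  d <- random_dag_edges(25)
  dont <- term_ontology(data.frame(term_id = d$ids, name = d$ids,
                                   stringsAsFactors = FALSE), d$edges)
  genes <- sprintf("g%d", 1:8)
  ann2 <- data.frame(
    gene_id = sample(genes, 30, replace = TRUE), namespace = "GO",
    term_id = sample(d$ids, 30, replace = TRUE), stringsAsFactors = FALSE)
  closed2 <- propagate_functional(ann2, list(GO = dont))
  for (g in genes) {
    direct <- unique(ann2$term_id[ann2$gene_id == g])
    want <- sort(unique(c(direct, unlist(lapply(direct, oracle_ancestors,
                                                edges = d$edges)))))
    expect_identical(sort(closed2$term_id[closed2$gene_id == g]), want)
  }
})

make_cluster_set <- function(groups) {
  names(groups) <- as.character(seq_along(groups))
  structure(list(clusters = groups, singletons = character(0),
                 mean_r = rep(NA_real_, length(groups)),
                 params = clustering_params(), n_genes =
                   length(unlist(groups))),
            class = "cluster_set")
}

test_that("enrichment counts come from set intersections and respect the size gate", {
  universe <- sprintf("g%03d", 1:100)
  cl <- make_cluster_set(list(universe[1:10], universe[11:19]))
  ann <- data.frame(gene_id = universe[1:10], namespace = "NS",
                    term_id = "T:full", stringsAsFactors = FALSE)
  e <- enrich(cl, ann, universe)
  # cluster of 9 genes is below the ten-gene testing floor
  expect_true(all(e$cluster_id == 1L))
  # term annotating exactly the cluster: the minimal attainable p
  row <- e[e$term_id == "T:full", ]
  expect_equal(row$k, 10)
  expect_equal(row$p_hyper, 1 / choose(100, 10), tolerance = 1e-12)
  expect_equal(row$p_hyper, hypergeom_upper(10, 10, 10, 100))

  expect_error(enrich(cl, ann, character(0)), "empty universe")

  # randomised fixture: k, K match direct intersections
  set.seed(8)
  ann2 <- data.frame(
    gene_id = sample(universe, 150, replace = TRUE),
    namespace = sample(c("A", "B"), 150, replace = TRUE),
    term_id = sample(sprintf("t%d", 1:6), 150, replace = TRUE),
    stringsAsFactors = FALSE)
  cl2 <- make_cluster_set(list(universe[1:12], universe[13:40]))
  e2 <- enrich(cl2, ann2, universe)
  for (i in seq_len(nrow(e2))) {
    with_term <- unique(ann2$gene_id[ann2$namespace == e2$namespace[i] &
                                       ann2$term_id == e2$term_id[i]])
    genes <- cl2$clusters[[as.character(e2$cluster_id[i])]]
    expect_equal(e2$k[i], length(intersect(genes, with_term)))
    expect_equal(e2$K[i], length(with_term))
    expect_equal(e2$N[i], 100)
    expect_equal(e2$p_hyper[i],
                 hypergeom_upper(e2$k[i], e2$n[i], e2$K[i], e2$N[i]))
  }
  # sorted by namespace, cluster, then significance
  expect_identical(order(e2$namespace, e2$cluster_id, e2$p_hyper),
                   seq_len(nrow(e2)))
})

test_that("hypergeometric p agrees with exhaustive enumeration at small N", {
  for (N in c(6, 9, 12)) {
    for (n in c(2, N %/% 2)) {
      for (K in c(1, N %/% 3, N - 1)) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeom_upper(k, n, K, N),
                       oracle_hyper_upper(k, n, K, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("bundle permutation conserves counts and is seed-reproducible", {
  universe <- sprintf("g%02d", 1:20)
  set.seed(99)
  ann <- data.frame(
    gene_id = sample(universe[1:15], 60, replace = TRUE),
    namespace = sample(c("GO", "dom"), 60, replace = TRUE),
    term_id = sample(sprintf("t%d", 1:8), 60, replace = TRUE),
    stringsAsFactors = FALSE)
  ann <- unique(ann)

  p1 <- permute_bundles(ann, universe, seed = 5)
  p2 <- permute_bundles(ann, universe, seed = 5)
  expect_identical(p1, p2)
  p3 <- permute_bundles(ann, universe, seed = 6)
  expect_false(identical(p1, p3))

  # per-term totals and the multiset of bundle sizes are conserved
  expect_identical(table(paste(p1$namespace, p1$term_id)),
                   table(paste(ann$namespace, ann$term_id)))
  expect_identical(sort(as.integer(table(p1$gene_id))),
                   sort(as.integer(table(ann$gene_id))))

  # a single-gene universe forces the identity
  solo <- data.frame(gene_id = "g1", namespace = "GO", term_id = "t1",
                     stringsAsFactors = FALSE)
  expect_identical(permute_bundles(solo, "g1", seed = 1), solo)

  expect_error(permute_bundles(ann, universe[1:5], seed = 1),
               "outside the universe")

  # the caller's RNG stream is untouched
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(permute_bundles(ann, universe, seed = 5))
  expect_identical(runif(3), before)
})

test_that("permutation calibration hits its boundary cases", {
  universe <- sprintf("g%03d", 1:100)
  cl <- make_cluster_set(list(universe[1:10]))
  # overwhelming planted signal: the observed count can never be matched
  strong <- data.frame(gene_id = universe[1:10], namespace = "NS",
                       term_id = "T:planted", stringsAsFactors = FALSE)
  cal <- calibrate(cl, strong, universe, thresholds = 1e-8,
                   n_perm = 100, seed = 4)
  expect_equal(cal$observed_count, 1L)
  expect_equal(cal$perm_p, 1 / 101)

  # no observed hits: every permutation ties, perm_p is 1
  diffuse <- data.frame(gene_id = universe, namespace = "NS",
                        term_id = "T:everywhere", stringsAsFactors = FALSE)
  cal0 <- calibrate(cl, diffuse, universe, thresholds = 1e-8,
                    n_perm = 20, seed = 4)
  expect_equal(cal0$observed_count, 0L)
  expect_equal(cal0$perm_p, 1.0)

  # reproducible given (seed, n_perm)
  cal2 <- calibrate(cl, strong, universe, thresholds = 1e-8,
                    n_perm = 100, seed = 4)
  expect_identical(cal, cal2)
  expect_true(all(cal$perm_p >= 1 / 101 & cal$perm_p <= 1))
})

test_that("under its own null the permutation p-value is super-uniform", {
  universe <- sprintf("g%02d", 1:30)
  cl <- make_cluster_set(list(universe[1:10], universe[11:22]))
  n_outer <- 120
  alpha_grid <- c(0.1, 0.25, 0.5)
  pp <- numeric(n_outer)
  set.seed(55)
  for (i in seq_len(n_outer)) {
    ann <- data.frame(
      gene_id = sample(universe, 40, replace = TRUE),
      namespace = "NS",
      term_id = sample(sprintf("t%d", 1:5), 40, replace = TRUE),
      stringsAsFactors = FALSE)
    ann <- unique(permute_bundles(ann, universe, seed = 7000 + i))
    cal <- calibrate(cl, ann, universe, thresholds = 0.1, n_perm = 19,
                     seed = 9000 + 20L * i)
    pp[i] <- cal$perm_p
  }
  for (a in alpha_grid) {
    # allow three Monte-Carlo standard errors above the nominal level
    slack <- 3 * sqrt(a * (1 - a) / n_outer)
    expect_lte(mean(pp <= a), a + slack)
  }
})
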