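test_that("centered Pearson matches direct evaluation of the formula", {
  expect_equal(pearson_centered(c(0, 1, 2, 3), c(1, 2, 3, 4)), 1.0)
  expect_equal(pearson_centered(c(1, 2, 3), c(3, 2, 1)), -1.0)
  # independent hand evaluation: sum(xc*yc) / sqrt(sum(xc^2) sum(yc^2))
  x <- c(0, 3, 1, 2); y <- c(0, 2, 2, 3)
  expect_equal(pearson_centered(x, y), 3.5 / sqrt(23.75), tolerance = 1e-12)
  expect_error(pearson_centered(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson_centered(1, 1), "length")
})

test_that("correlation matrix equals pairwise correlations and flags flat genes", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 1, 2, 2))
  r <- correlation_matrix(m)
  expect_equal(unname(r["a", "b"]), 1.0)

  set.seed(11)
  m2 <- matrix(rnorm(80), nrow = 10,
               dimnames = list(sprintf("g%02d", 1:10), NULL))
  r2 <- correlation_matrix(m2)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(r2[i, j], pearson_centered(m2[i, ], m2[j, ]),
                 tolerance = 1e-12)
  }
  expect_equal(r2, t(r2), tolerance = 1e-12)
  expect_equal(unname(diag(r2)), rep(1, 10))

  m3 <- rbind(ok = c(1, 2, 3), flat = c(2, 2, 2))
  expect_error(correlation_matrix(m3), "flat")
})

test_that("average linkage reproduces forced small merges", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- average_linkage(d2)
  expect_equal(t2$height, 0.4)
  expect_identical(sort(t2$merge[1, ]), c(-2L, -1L))

  d3 <- matrix(c(0, 0.1, 0.5,
                 0.1, 0, 0.5,
                 0.5, 0.5, 0), 3, 3)
  t3 <- average_linkage(d3)
  expect_equal(t3$height, c(0.1, 0.5))
  expect_identical(t3$merge, rbind(c(-1L, -2L), c(1L, -3L)))

  asym <- matrix(c(0, 0.2, 0.5, 0), 2, 2)
  expect_error(average_linkage(asym), "asymmetric")
})

test_that("average linkage agrees with brute-force re-agglomeration and hclust", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 12
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 2)
    d <- d + t(d)
    tree <- average_linkage(d)
    orc <- oracle_average_linkage(d)
    expect_identical(tree$merge, orc$merge)
    expect_equal(tree$height, orc$height, tolerance = 1e-12)
    # no inversions
    expect_true(all(diff(tree$height) >= -1e-12))
    # independent cross-check: same dendrogram geometry as stats::hclust
    rownames(d) <- colnames(d) <- sprintf("g%02d", 1:n)
    tree2 <- average_linkage(d)
    ref <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(as.matrix(stats::cophenetic(tree2))[rownames(d), rownames(d)],
                 as.matrix(stats::cophenetic(ref))[rownames(d), rownames(d)],
                 tolerance = 1e-9)
  }
})

test_that("the correlation cut yields tight flat clusters", {
  # two perfectly correlated pairs, strong anticorrelation across pairs
  m <- rbind(a1 = c(1, 2, 3, 4), a2 = c(2, 4, 6, 8),
             b1 = c(4, 3, 2, 1), b2 = c(9, 7, 5, 3))
  r <- correlation_matrix(m)
  cl <- cut_at_correlation(average_linkage(1 - r),
                           clustering_params(r_min = 0.7), r)
  expect_equal(length(cl$clusters), 2)
  got <- unname(lapply(cl$clusters, sort))
  expect_true(any(vapply(got, identical, logical(1), c("a1", "a2"))))
  expect_true(any(vapply(got, identical, logical(1), c("b1", "b2"))))
  expect_true(all(cl$mean_r >= 0.7))

  # all genes identical in profile: one cluster holding everything
  m1 <- matrix(rep(c(0, 1, 3, 2), each = 5), nrow = 5,
               dimnames = list(sprintf("g%d", 1:5), NULL))
  r1 <- correlation_matrix(m1)
  cl1 <- cut_at_correlation(average_linkage(1 - r1), clustering_params())
  expect_equal(lengths(cl1$clusters), c(`1` = 5L))
  expect_identical(cl1$singletons, character(0))
})

test_that("cluster ids rank by size and the partition covers all genes", {
  set.seed(21)
  m <- matrix(rnorm(15 * 8), nrow = 15,
              dimnames = list(sprintf("g%02d", 1:15), NULL))
  r <- correlation_matrix(m)
  cl <- cut_at_correlation(average_linkage(1 - r),
                           clustering_params(r_min = 0.2), r)
  all_genes <- c(unlist(cl$clusters, use.names = FALSE), cl$singletons)
  expect_setequal(all_genes, rownames(m))
  expect_equal(anyDuplicated(all_genes), 0)
  expect_true(all(diff(lengths(cl$clusters)) <= 0))
})

test_that("raising the correlation threshold only refines the partition", {
  set.seed(33)
  m <- matrix(rnorm(20 * 10), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  r <- correlation_matrix(m)
  tree <- average_linkage(1 - r)
  membership <- function(cl) {
    groups <- c(cl$clusters, as.list(cl$singletons))
    out <- rep(NA_integer_, 20)
    names(out) <- rownames(m)
    for (i in seq_along(groups)) out[groups[[i]]] <- i
    out
  }
  prev <- membership(cut_at_correlation(tree,
                                        clustering_params(r_min = -0.5)))
  for (rmin in c(-0.2, 0.1, 0.4, 0.7, 0.9)) {
    cur <- membership(cut_at_correlation(tree,
                                         clustering_params(r_min = rmin,
                                                           min_report_size = 1)))
    # genes together at the stricter threshold were together before
    for (grp in split(names(cur), cur)) {
      expect_equal(length(unique(prev[grp])), 1)
    }
    prev <- cur
  }
})

test_that("occupancy equals the per-cell expression fraction", {
  m <- matrix(0, nrow = 8, ncol = 3,
              dimnames = list(sprintf("g%d", 1:8), c("t1", "t2", "t3")))
  m[, "t1"] <- 1
  m[1:4, "t2"] <- 2
  cl <- structure(list(clusters = list(`1` = sprintf("g%d", 1:8)),
                       singletons = character(0),
                       mean_r = c(`1` = NA_real_),
                       params = clustering_params(), n_genes = 8),
                  class = "cluster_set")
  occ <- occupancy(cl, m)
  expect_equal(unname(occ["1", ]), c(1, 0.5, 0))

  set.seed(9)
  m2 <- matrix(rbinom(60, 1, 0.4) * runif(60), nrow = 10,
               dimnames = list(sprintf("g%02d", 1:10), sprintf("t%d", 1:6)))
  cl2 <- structure(list(clusters = list(`1` = sprintf("g%02d", 1:4),
                                        `2` = sprintf("g%02d", 5:10)),
                        singletons = character(0),
                        mean_r = c(`1` = NA_real_, `2` = NA_real_),
                        params = clustering_params(), n_genes = 10),
                   class = "cluster_set")
  occ2 <- occupancy(cl2, m2)
  for (id in c("1", "2")) {
    for (t in colnames(m2)) {
      g <- cl2$clusters[[id]]
      expect_equal(occ2[id, t], sum(m2[g, t] > 0) / length(g))
    }
  }
  cl2$clusters$`1` <- c(cl2$clusters$`1`, "missing")
  expect_error(occupancy(cl2, m2), "missing")
})

test_that("row-affine transforms leave the correlation structure unchanged", {
  set.seed(17)
  m <- matrix(sample(0:3, 12 * 9, replace = TRUE), nrow = 12,
              dimnames = list(sprintf("g%02d", 1:12), NULL))
  m <- m + matrix(rnorm(12 * 9, sd = 0.01), nrow = 12)  # break flat rows
  r <- correlation_matrix(m)
  a <- runif(12, 0.5, 4); b <- rnorm(12)
  r2 <- correlation_matrix(m * a + b)
  expect_equal(r, r2, tolerance = 1e-12)
})
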