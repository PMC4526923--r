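test_that("disjoint cliques collapse to one cluster each", {
  tri <- make_graph(c("a", "b", "c", "d", "e", "f"),
                    c("a", "b", "a", "d", "e", "d"),
                    c("b", "c", "c", "e", "f", "f"),
                    rep(1, 6))
  cl <- mcl_cluster(tri)
  expect_length(cl$clusters, 2L)
  expect_length(cl$singletons, 0L)
  expect_setequal(cl$clusters$c1, c("a", "b", "c"))
  expect_setequal(cl$clusters$c2, c("d", "e", "f"))
})

test_that("an isolated node becomes a singleton beside an edge pair", {
  g <- make_graph(c("x", "y", "z"), "x", "y", 1)
  cl <- mcl_cluster(g)
  expect_length(cl$clusters, 1L)
  expect_setequal(cl$clusters$c1, c("x", "y"))
  expect_equal(cl$singletons, "z")
})

test_that("bridged 4-cliques split at inflation 1.5 (numeric oracle)", {
  g <- bridged_cliques_graph()
  cl <- mcl_cluster(g, inflation = 1.5)
  expect_length(cl$clusters, 2L)
  expect_setequal(cl$clusters[[1]], paste0("A", 1:4))
  expect_setequal(cl$clusters[[2]], paste0("B", 1:4))

  # independent plain-matrix iteration of expansion/inflation/pruning
  nodes <- g$nodes
  A <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(g$edges))) {
    A[g$edges$from[r], g$edges$to[r]] <- g$edges$weight[r]
    A[g$edges$to[r], g$edges$from[r]] <- g$edges$weight[r]
  }
  diag(A) <- apply(A, 2, max)
  M <- sweep(A, 2, colSums(A), "/")
  for (it in 1:200) {
    M <- M %*% M
    M <- M^1.5
    M <- sweep(M, 2, colSums(M), "/")
    M[M < 1e-5] <- 0
    M <- sweep(M, 2, colSums(M), "/")
  }
  # flow must not cross the bridge in the limit
  expect_equal(sum(M[paste0("A", 1:4), paste0("B", 1:4)]), 0)
  expect_equal(sum(M[paste0("B", 1:4), paste0("A", 1:4)]), 0)
})

test_that("columns stay stochastic to 1e-12 through every iteration", {
  g <- bridged_cliques_graph()
  cl <- mcl_cluster(g, inflation = 1.5)
  expect_lt(cl$max_colsum_dev, 1e-12)
})

test_that("partition invariant and determinism hold on random graphs", {
  set.seed(31)
  for (k in 1:10) {
    n <- sample(5:12, 1)
    nodes <- sprintf("n%02d", 1:n)
    pairs <- utils::combn(nodes, 2)
    keep <- runif(ncol(pairs)) < 0.3
    if (!any(keep)) next
    g <- make_graph(nodes, pairs[1, keep], pairs[2, keep],
                    runif(sum(keep), 0.1, 2))
    cl <- mcl_cluster(g)
    all_ids <- c(unlist(cl$clusters), cl$singletons)
    expect_setequal(all_ids, nodes)
    expect_equal(anyDuplicated(all_ids), 0L)
    expect_true(all(lengths(cl$clusters) >= 2))
    cl2 <- mcl_cluster(g)
    expect_identical(cl, cl2)
  }
})

test_that("higher inflation never coarsens the bridged-cliques fixture", {
  g <- bridged_cliques_graph()
  n_fine <- length(mcl_cluster(g, inflation = 5)$clusters)
  n_coarse <- length(mcl_cluster(g, inflation = 1.2)$clusters)
  expect_gte(n_fine, n_coarse)
})

test_that("invalid graphs are rejected", {
  g <- make_graph(c("a", "b"), "a", "b", -1)
  expect_error(mcl_cluster(g), "positive")
  g2 <- make_graph(c("a", "b"), "a", "a", 1)
  expect_error(mcl_cluster(g2), "self-edges")
})

test_that("clusterings serialise to the node/cluster TSV", {
  g <- make_graph(c("x", "y", "z"), "x", "y", 1)
  cl <- mcl_cluster(g)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_clustering_tsv(cl, f)
  df <- read.delim(f, stringsAsFactors = FALSE)
  expect_setequal(df$node_id, c("x", "y", "z"))
  expect_equal(df$cluster_id[df$node_id == "z"], "singleton")
})
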