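test_that("Jaccard distance matches hand-enumerated set arithmetic", {
  # |{B,C}| / |{A,B,C,D}| = 2/4
  expect_equal(jaccard_distance(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard_distance(c("A", "B"), c("A", "B")), 0)
  expect_equal(jaccard_distance("A", "B"), 1)
  # duplicates within a set do not count twice
  expect_equal(jaccard_distance(c("A", "A", "B"), c("B", "B")), 0.5)
  expect_error(jaccard_distance(character(), character()), "undefined")
})

test_that("distance matrix equals the pairwise set-arithmetic oracle", {
  for (seed in 1:10) {
    edges <- random_edges(sample(3:20, 1), sample(10:50, 1),
                          p = runif(1, 0.1, 0.6), seed = seed + 500)
    adj <- build_adjacency(as_interaction_table(edges))
    D <- jaccard_matrix(adj)
    O <- oracle_jaccard(edges)
    expect_equal(D[rownames(O), colnames(O)], O, tolerance = 0)
  }
})

test_that("distance matrix is a proper metric on every generated instance", {
  for (seed in 1:6) {
    edges <- random_edges(10, 30, p = 0.3, seed = seed + 900)
    D <- jaccard_matrix(build_adjacency(as_interaction_table(edges)))
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, nrow(D)))
    # triangle inequality over all ordered triples
    expect_equal(count_triangle_violations(D), 0)
  }
})

test_that("identical and disjoint target columns hit the distance extremes", {
  adj <- build_adjacency(as_interaction_table(edge_df(
    c("m1", "m1", "m2", "m2", "m3"),
    c("gA", "gB", "gA", "gB", "gC"))))
  D <- jaccard_matrix(adj)
  expect_equal(D["m1", "m2"], 0)
  expect_equal(D["m1", "m3"], 1)
  expect_equal(D["m2", "m3"], 1)
})

test_that("gene row order of the adjacency does not affect distances", {
  edges <- random_edges(6, 20, seed = 31)
  adj <- build_adjacency(as_interaction_table(edges))
  D1 <- jaccard_matrix(adj)
  perm <- adj[sample(nrow(adj)), , drop = FALSE]
  class(perm) <- class(adj)
  D2 <- jaccard_matrix(perm)
  expect_equal(D2[rownames(D1), colnames(D1)], D1)
})

test_that("empty target columns are dropped with a warning before Eq. of distance", {
  adj <- build_adjacency(as_interaction_table(
    edge_df(c("m1", "m2"), c("gA", "gB"))))
  padded <- cbind(unclass(adj), m0 = 0L)
  class(padded) <- c("mirna_adjacency", class(padded))
  expect_warning(D <- jaccard_matrix(padded), "no targets")
  expect_equal(sort(colnames(D)), c("m1", "m2"))
  only_one <- cbind(unclass(adj)[, 1, drop = FALSE])
  expect_error(jaccard_matrix(only_one), "nothing to cluster")
})

test_that("clustering merges the closest pair first and honors tie rules", {
  D <- matrix(0.9, 3, 3, dimnames = list(c("m1", "m2", "m3"),
                                         c("m1", "m2", "m3")))
  diag(D) <- 0
  D["m1", "m2"] <- D["m2", "m1"] <- 0.1
  tree <- cluster_mirnas(D)
  expect_s3_class(tree, "hclust")
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))  # {m1, m2} first
  expect_equal(tree$height[1], 0.1)
  # identical miRNAs merge at height zero
  D0 <- matrix(c(0, 0, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(cluster_mirnas(D0)$height, 0)
  # non-finite distances are rejected
  Dbad <- D; Dbad[1, 3] <- NA
  expect_error(cluster_mirnas(Dbad), "non-finite")
  expect_error(cluster_mirnas(D[1, 1, drop = FALSE]), "nothing to cluster")
})

test_that("merge heights agree with stats::hclust on tie-free matrices", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:9, 1)
    D <- matrix(0, n, n, dimnames = list(sprintf("m%d", 1:n),
                                         sprintf("m%d", 1:n)))
    D[lower.tri(D)] <- runif(n * (n - 1) / 2)
    D <- D + t(D)
    for (lk in c("complete", "average", "single")) {
      mine <- cluster_mirnas(D, lk)
      ref <- stats::hclust(stats::as.dist(D), method = lk)
      expect_equal(sort(mine$height), sort(ref$height))
      expect_true(all(diff(mine$height) >= -1e-12))  # monotone heights
      for (k in 2:(n - 1)) {
        expect_true(identical_partitions_test(stats::cutree(mine, k),
                                              stats::cutree(ref, k)))
      }
    }
  }
})

test_that("clustering is invariant to interaction row order", {
  edges <- random_edges(8, 30, seed = 77)
  t1 <- cluster_mirnas(jaccard_matrix(build_adjacency(
    as_interaction_table(edges))))
  t2 <- cluster_mirnas(jaccard_matrix(build_adjacency(
    as_interaction_table(edges[rev(seq_len(nrow(edges))), ]))))
  expect_equal(t1$height, t2$height)
  expect_equal(t1$merge, t2$merge)
  expect_equal(t1$labels, t2$labels)
})

test_that("Newick export carries midpoint branch lengths and survives a round trip", {
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("m1", "m2"), c("m1", "m2")))
  nwk <- export_newick(cluster_mirnas(D2))
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("m1", "m2"))
  expect_equal(unname(phy$edge.length), c(0.2, 0.2))

  D <- matrix(0.9, 3, 3, dimnames = list(c("m1", "m2", "m3"),
                                         c("m1", "m2", "m3")))
  diag(D) <- 0; D["m1", "m2"] <- D["m2", "m1"] <- 0.1
  tree <- cluster_mirnas(D)
  tf <- tempfile(fileext = ".nwk")
  export_newick(tree, tf)
  phy3 <- ape::read.tree(tf)
  expect_setequal(phy3$tip.label, c("m1", "m2", "m3"))
  # topology ((m1,m2),m3): m1 and m2 are siblings
  pair <- ape::getMRCA(phy3, c("m1", "m2"))
  expect_false(pair == ape::getMRCA(phy3, c("m1", "m3")))
})
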