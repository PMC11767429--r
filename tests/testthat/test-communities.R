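# directed clique among nodes (low index -> high index keeps it acyclic)
clique_edges <- function(nodes) {
  pr <- t(utils::combn(nodes, 2))
  edge_df(pr[, 1], pr[, 2])
}

test_that("disjoint cliques and isolated nodes partition as expected", {
  # two disjoint triangles -> two clusters of three
  tri <- rbind(clique_edges(c("a1", "a2", "a3")),
               clique_edges(c("b1", "b2", "b3")))
  p <- leiden_partition(make_bn(tri), seed = 1)
  expect_identical(sum(p$clusters$cluster > 0), 2L)
  expect_length(unique(p$membership[c("a1", "a2", "a3")]), 1L)
  expect_length(unique(p$membership[c("b1", "b2", "b3")]), 1L)
  expect_false(p$membership[["a1"]] == p$membership[["b1"]])

  # five isolated nodes plus one edge: cluster 0 of size 5, one 2-node cluster
  net <- make_bn(edge_df("x", "y"), nodes = c("x", "y", paste0("i", 1:5)))
  p2 <- leiden_partition(net, seed = 1)
  expect_identical(sum(p2$membership == 0L), 5L)
  expect_identical(unname(p2$membership[c("x", "y")]), c(1L, 1L))
})

test_that("a ring of four 6-cliques with single bridges is recovered at resolution 1", {
  cliques <- lapply(1:4, function(k) sprintf("c%d_%d", k, 1:6))
  edges <- do.call(rbind, lapply(cliques, clique_edges))
  bridges <- edge_df(sapply(1:4, function(k) cliques[[k]][6]),
                     sapply(c(2:4, 1), function(k) cliques[[k]][1]))
  p <- leiden_partition(make_bn(rbind(edges, bridges)), seed = 7,
                        resolution = 1)
  expect_identical(sum(p$clusters$cluster > 0), 4L)
  for (cl in cliques)
    expect_length(unique(p$membership[cl]), 1L)
})

test_that("partitions are stable under node relabeling up to cluster ids", {
  tri <- rbind(clique_edges(c("a1", "a2", "a3")),
               clique_edges(c("b1", "b2", "b3")), edge_df("a3", "b1"))
  net <- make_bn(tri)
  p1 <- leiden_partition(net, seed = 3)
  relabel <- c(a1 = "z9", a2 = "z8", a3 = "z7", b1 = "z6", b2 = "z5",
               b3 = "z4")
  tri2 <- edge_df(unname(relabel[tri$parent]), unname(relabel[tri$child]))
  p2 <- leiden_partition(make_bn(tri2), seed = 3)
  # same partition structure: co-membership is preserved
  for (u in names(relabel)) for (v in names(relabel))
    expect_identical(p1$membership[[u]] == p1$membership[[v]],
                     p2$membership[[relabel[[u]]]] ==
                       p2$membership[[relabel[[v]]]])
})

test_that("clusters are categorized by their undirected path to the Diet node", {
  ed <- rbind(edge_df("Diet", "a"), edge_df("a", "b"), edge_df("c", "d"))
  net <- make_bn(ed, nodes = c("a", "b", "c", "d", "iso", "Diet"),
                 diet = "Diet")
  p <- categorize_clusters(leiden_partition(net, seed = 1), net)
  catof <- function(nd) p$clusters$category[p$clusters$cluster ==
                                              p$membership[[nd]]]
  expect_identical(catof("a"), "connected")   # direct child of Diet
  expect_identical(catof("b"), "connected")   # indirect, via a
  expect_identical(catof("c"), "not-connected")
  expect_identical(p$clusters$category[p$clusters$cluster == 0L], "isolated")
  # without a Diet node, nothing is connected
  net2 <- make_bn(edge_df("a", "b"), nodes = c("a", "b"))
  p2 <- categorize_clusters(leiden_partition(net2, seed = 1), net2)
  expect_identical(unique(p2$clusters$category), "not-connected")
})

test_that("coverage statistics add up and respect planted shares", {
  samples <- paste0("s", 1:6)
  # all nodes in connected clusters -> connected share 100%
  ed <- rbind(edge_df("Diet", "a"), edge_df("a", "b"))
  net <- make_bn(ed, nodes = c("a", "b", "Diet"), diet = "Diet")
  t1 <- toy_counts(matrix(rpois(12, 20) + 1, 2, 6), taxa = c("a", "b"),
                   samples = samples)
  p <- categorize_clusters(leiden_partition(net, seed = 1), net)
  cov <- coverage_stats(p, t1)
  expect_equal(cov$by_category$abun_pct[cov$by_category$category ==
                                          "connected"], 100)
  # two equal-abundance taxa, one isolated -> isolated share 50%
  net2 <- make_bn(edge_df("u", "v"), nodes = c("u", "v", "iso"))
  t2 <- toy_counts(rbind(rep(4, 6), rep(2, 6), rep(6, 6)),
                   taxa = c("u", "v", "iso"), samples = samples)
  p2 <- categorize_clusters(leiden_partition(net2, seed = 1), net2)
  cov2 <- coverage_stats(p2, t2)
  expect_equal(cov2$by_category$abun_pct[cov2$by_category$category ==
                                           "isolated"], 50)
  expect_equal(cov2$total_modelled_pct, 100)
  # a clustered node missing from the table is an error
  expect_error(coverage_stats(p2, t1), "missing from the count table")
  # core participation in nodes and edges
  core <- structure(list(C = c("u", "iso"), B = "u", A = character(),
                         fraction = 0.5), class = "core_set")
  cov3 <- coverage_stats(p2, t2, core)
  expect_identical(cov3$edge_core$with_core, 1L)
  expect_identical(cov3$by_category$n_core[cov3$by_category$category ==
                                             "isolated"], 1L)
})
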