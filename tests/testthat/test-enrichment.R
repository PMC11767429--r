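test_that("the upper-tail hypergeometric handles boundaries and validates bounds", {
  expect_identical(hypergeom_upper_tail(0, 10, 50, 100), 1)
  # all-successes background: any draw is certain
  expect_identical(hypergeom_upper_tail(3, 5, 100, 100), 1)
  expect_error(hypergeom_upper_tail(6, 5, 50, 100), "k > n")
  expect_error(hypergeom_upper_tail(2, 101, 50, 100), "n > N_bg")
  expect_error(hypergeom_upper_tail(2, 5, 101, 100), "K > N_bg")
  expect_error(hypergeom_upper_tail(2, 5, 1, 100), "k > K")
  expect_error(hypergeom_upper_tail(1.5, 5, 50, 100), "integers")
})

test_that("hypergeometric tail matches brute-force pmf summation on random tuples", {
  set.seed(31)
  for (i in 1:200) {
    N <- sample(5:150, 1); n <- sample(N, 1); K <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    brute <- sum(exp(lchoose(K, k:min(n, K)) + lchoose(N - K, n - (k:min(n, K))) -
                       lchoose(N, n)))
    if (k == 0) brute <- 1
    expect_equal(hypergeom_upper_tail(k, n, K, N), brute, tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up formula", {
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_equal(bh_adjust(0.37), 0.37)
  # hand-computed: p_(i) * m / i then running minimum from the top
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.02, 0.02, 0.02)), c(0.02, 0.02, 0.02))
  expect_equal(bh_adjust(c(0.001, 0.5, 0.04)), c(0.003, 0.5, 0.06))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_partition <- function(membership) {
  structure(list(membership = membership,
                 clusters = data.frame(cluster = sort(unique(membership)),
                                       category = NA_character_),
                 edges = edge_df(character(), child = character()),
                 diet = NULL),
            class = "cluster_partition")
}

test_that("planted cluster enrichment is detected against the background", {
  taxa <- sprintf("g%02d", 1:12)
  memb <- stats::setNames(c(rep(1L, 6), rep(2L, 6)), taxa)
  ann <- lapply(stats::setNames(taxa, taxa), function(tx) "pw_bg")
  ann[taxa[1:6]] <- lapply(ann[taxa[1:6]], c, "pw_rare")
  pw <- data.frame(pathway_id = c("pw_bg", "pw_rare"),
                   name = c("background", "rare planted"),
                   level2 = c("L", "L"), K = c(1500L, 10L),
                   stringsAsFactors = FALSE)
  catalog <- annotation_catalog(ann, pw, n_bg = 3000L)
  res <- enrich_clusters(make_partition(memb), catalog)
  hit <- res[res$cluster == 1L & res$pathway_id == "pw_rare", ]
  expect_true(hit$significant)
  expect_identical(hit$ratio, "6/6")
  expect_false(any(res$pathway_id == "pw_rare" & res$cluster == 2L))
  # p_adj is BH within the cluster and never below p
  expect_true(all(res$p_adj >= res$p - 1e-15))
  # result order is invariant to cluster-internal taxon order
  res2 <- enrich_clusters(make_partition(memb[c(6:1, 12:7)]), catalog)
  expect_equal(res[order(res$cluster, res$pathway_id), ],
               res2[order(res2$cluster, res2$pathway_id), ],
               ignore_attr = TRUE)
})

test_that("clusters without annotated members produce no rows", {
  memb <- stats::setNames(c(1L, 1L, 2L, 2L), c("a", "b", "c", "d"))
  pw <- data.frame(pathway_id = "p1", name = "one", level2 = "L", K = 5L,
                   stringsAsFactors = FALSE)
  catalog <- annotation_catalog(list(a = "p1", b = "p1"), pw, n_bg = 100L)
  expect_message(res <- enrich_clusters(make_partition(memb), catalog),
                 "cluster 2")
  expect_identical(unique(res$cluster), 1L)
})

test_that("model comparison reports shared functions and taxon overlap", {
  taxa <- sprintf("g%02d", 1:10)
  memb <- stats::setNames(rep(1L, 10), taxa)
  ann <- lapply(stats::setNames(taxa, taxa), function(tx) character())
  # five pathways; both models test all, two shared significant by design
  pwids <- paste0("p", 1:5)
  pw <- data.frame(pathway_id = pwids, name = paste("path", 1:5),
                   level2 = "L", K = c(12L, 12L, 12L, 2000L, 2000L),
                   stringsAsFactors = FALSE)
  for (tx in taxa) ann[[tx]] <- pwids
  catalog <- annotation_catalog(
    ann, pw, n_bg = 3000L,
    phylum = stats::setNames(rep("Pseudomonadota", 10), taxa))
  enr <- enrich_clusters(make_partition(memb), catalog)
  # identical inputs: everything shared, full overlap
  cmp_same <- compare_models(enr, enr, make_partition(memb),
                             make_partition(memb), catalog)
  expect_setequal(cmp_same$shared, enr$pathway_id[enr$significant])
  expect_true(all(cmp_same$taxa_overlap$jaccard == 1))
  # disjoint significant sets: nothing shared
  enr_b <- enr; enr_b$significant <- FALSE
  cmp_disj <- compare_models(enr, enr_b, make_partition(memb),
                             make_partition(memb), catalog)
  expect_length(cmp_disj$shared, 0L)
  expect_identical(cmp_disj$n_total, length(unique(
    enr$pathway_id[enr$significant])))
})

test_that("a constructed two-model toy yields the expected shared counts", {
  # model A significant: p1..p5 ; model B significant: p1, p2, p6..p9
  # shared = {p1, p2}; taxa: A expresses p1 via g1, B via g1 and g10
  taxa <- sprintf("g%02d", 1:10)
  pwids <- paste0("p", 1:9)
  pw <- data.frame(pathway_id = pwids, name = pwids, level2 = "L",
                   K = rep(10L, 9), stringsAsFactors = FALSE)
  ann <- list(g01 = c("p1", "p2"), g02 = "p3", g03 = "p4", g04 = "p5",
              g05 = "p6", g06 = "p7", g07 = "p8", g08 = "p9",
              g09 = "p2", g10 = "p1")
  catalog <- annotation_catalog(ann, pw, n_bg = 3000L)
  part_a <- make_partition(stats::setNames(rep(1L, 4), taxa[1:4]))
  part_b <- make_partition(stats::setNames(rep(1L, 6),
                                           c("g01", "g05", "g06", "g07",
                                             "g08", "g10")))
  row <- function(cl, pid, k, n) data.frame(
    cluster = cl, pathway_id = pid, name = pid, level2 = "L", k = k, n = n,
    cluster_size = n, K = 10L, N_bg = 3000L, ratio = paste0(k, "/", n),
    bg_ratio = paste0(10, "/", 3000),
    p = hypergeom_upper_tail(k, n, 10, 3000), p_adj = 0.01,
    significant = TRUE, stringsAsFactors = FALSE)
  enr_a <- do.call(rbind, lapply(c("p1", "p2", "p3", "p4", "p5"),
                                 function(p) row(1L, p, 1L, 4L)))
  enr_b <- do.call(rbind, lapply(c("p1", "p2", "p6", "p7", "p8", "p9"),
                                 function(p) row(1L, p, 1L, 6L)))
  cmp <- compare_models(enr_a, enr_b, part_a, part_b, catalog)
  expect_setequal(cmp$shared, c("p1", "p2"))
  expect_identical(cmp$n_total, 9L)
  ov <- cmp$taxa_overlap
  # p1: A contributes g01, B contributes g01 + g10 -> one shared of two
  expect_identical(ov$n_shared[ov$pathway_id == "p1"], 1L)
  expect_equal(ov$jaccard[ov$pathway_id == "p1"], 0.5)
  # p2: only g01 in A, only g01 in B (g09 is not in B's cluster)
  expect_equal(ov$jaccard[ov$pathway_id == "p2"], 1)
  expect_true(all(c("genus", "phylum", "pathway", "model") %in%
                    colnames(cmp$sankey)))
})
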