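planted_pair <- function(n = 300, seed = 21, coef = 0.8) {
  set.seed(seed)
  x <- rzinb(n, 0.15, 50, 2)
  y <- rzinb(n, 0.15, 40 * exp(coef * (log1p(x) - log1p(50))), 2)
  z <- rzinb(n, 0.15, 30, 2)
  toy_counts(rbind(x, y, z), taxa = c("X", "Y", "Z"),
             samples = paste0("s", seq_len(n)))
}

test_that("a planted dependence is learned and an independent taxon stays out", {
  tab <- planted_pair()
  net <- learn_structure(tab, seed = 1, restarts = 3)
  net <- score_and_filter_edges(net, tab)
  expect_identical(skeleton(net$edges), "X~Y")
  expect_true(all(net$edges$mi_p < 0.05))
  expect_true(all(net$edges$bic_delta < 0))
})

test_that("a planted chain is recovered without the shortcut arc", {
  set.seed(22)
  n <- 300
  x <- rzinb(n, 0.1, 50, 2)
  y <- rzinb(n, 0.1, 40 * exp(0.8 * (log1p(x) - log1p(50))), 2)
  z <- rzinb(n, 0.1, 30 * exp(0.8 * (log1p(y) - log1p(40))), 2)
  tab <- toy_counts(rbind(x, y, z), taxa = c("X", "Y", "Z"),
                    samples = paste0("s", 1:n))
  net <- score_and_filter_edges(learn_structure(tab, seed = 2, restarts = 3),
                                tab)
  expect_true(all(c("X~Y", "Y~Z") %in% skeleton(net$edges)))
  expect_false("X~Z" %in% skeleton(net$edges))
})

test_that("the learned graph is acyclic and invariant to sample and taxon order", {
  tab <- planted_pair(n = 120, seed = 23)
  net <- learn_structure(tab, seed = 3, restarts = 2)
  g <- as_igraph_bn(net)
  expect_true(igraph::is_dag(g))
  # permuted samples and reversed taxon rows give the same edge set
  set.seed(24)
  perm <- sample(ncol(tab))
  net2 <- learn_structure(tab[rev(rownames(tab)), perm], seed = 3,
                          restarts = 2)
  expect_identical(net$edges[c("parent", "child")],
                   net2$edges[c("parent", "child")])
})

test_that("edge filtering is monotone in the MI threshold and keeps empty nets empty", {
  tab <- planted_pair(n = 150, seed = 25)
  net <- learn_structure(tab, seed = 4, restarts = 2)
  loose <- score_and_filter_edges(net, tab, mi_alpha = 0.05)
  tight <- score_and_filter_edges(net, tab, mi_alpha = 0.001)
  loose_keys <- paste(loose$edges$parent, loose$edges$child)
  tight_keys <- paste(tight$edges$parent, tight$edges$child)
  expect_true(all(tight_keys %in% loose_keys))
  empty <- make_bn(edge_df(character(), child = character()),
                   nodes = c("a", "b"))
  expect_identical(nrow(score_and_filter_edges(empty, planted_pair(n = 50),
                                               mi_alpha = 0.05)$edges), 0L)
})

test_that("the Diet variable enters as a root and its children are found", {
  set.seed(26)
  n_per <- 60
  samples <- paste0("s", 1:(2 * n_per))
  meta <- toy_meta(samples, trial = rep("T1", 2 * n_per),
                   diet = rep(c("ctrl", "treat"), each = n_per))
  resp <- c(rzinb(n_per, 0.1, 15, 2), rzinb(n_per, 0.1, 90, 2)) # diet-shifted
  flat <- rzinb(2 * n_per, 0.1, 40, 2)
  tab <- toy_counts(rbind(resp, flat), taxa = c("resp", "flat"),
                    samples = samples)
  net <- learn_structure(tab, meta, seed = 5, restarts = 3)
  net <- score_and_filter_edges(net, tab, meta)
  expect_false("Diet" %in% net$edges$child)
  expect_true(any(net$edges$parent == "Diet" & net$edges$child == "resp"))
  net <- edge_signs(net, tab, meta)
  d_edge <- net$edges[net$edges$parent == "Diet" & net$edges$child == "resp", ]
  expect_identical(d_edge$sign, "+") # treat level has the larger mean
})

test_that("edge signs follow monotone and antitone couplings", {
  set.seed(27)
  n <- 200
  x <- rzinb(n, 0.1, 50, 3)
  up <- x + rpois(n, 5)
  down <- max(x) - x + rpois(n, 2)
  tab <- toy_counts(rbind(x, up, down), taxa = c("x", "up", "down"),
                    samples = paste0("s", 1:n))
  net <- make_bn(edge_df(c("x", "x"), c("up", "down")))
  net <- edge_signs(net, tab)
  expect_identical(net$edges$sign[net$edges$child == "up"], "+")
  expect_identical(net$edges$sign[net$edges$child == "down"], "-")
})

test_that("hierarchy metrics count parent roles per node", {
  net <- make_bn(edge_df(c("a", "a", "b"), c("b", "c", "c")),
                 nodes = c("a", "b", "c", "iso"))
  h <- hierarchy_metrics(net)
  rownames(h) <- h$node
  expect_identical(h["a", "degree"], 2L)
  expect_equal(h["a", "parent_pct"], 100)
  expect_identical(h["b", "degree"], 2L)
  expect_equal(h["b", "parent_pct"], 50)
  expect_identical(h["iso", "degree"], 0L)
  expect_true(is.na(h["iso", "parent_pct"]))
})

test_that("marginal node models are stored as ZINB parameter sets", {
  tab <- planted_pair(n = 100, seed = 28)
  net <- learn_structure(tab, seed = 6, restarts = 1)
  expect_named(net$node_params, sort(rownames(tab)))
  for (pz in net$node_params) {
    expect_s3_class(pz, "zinb_fit")
    expect_true(pz$pi >= 0 && pz$pi <= 1)
    expect_true(pz$mu > 0 && pz$theta > 0)
  }
})
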