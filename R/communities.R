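#' Leiden community detection on a learned network
#'
#' Partitions the taxon nodes of a network into densely connected
#' communities with the Leiden algorithm (modularity objective) on the
#' undirected, unweighted projection of the taxon-taxon skeleton.
#' Isolated nodes (degree 0 in the full network, Diet edges included)
#' are assigned to the reserved cluster 0 before Leiden runs; the Diet
#' variable node belongs to no cluster, its edges counting only toward
#' isolation and the later connectivity categorization. Cluster ids >= 1
#' are ordered by decreasing summed relative abundance when a count
#' table is supplied (by decreasing size otherwise).
#'
#' @param net A `micronet_bn` network.
#' @param counts Optional count matrix used to order clusters by summed
#'   relative abundance.
#' @param resolution Leiden resolution parameter (default 1.0).
#' @param seed RNG seed; the partition is deterministic for a fixed
#'   seed.
#' @return Object of class `cluster_partition`: `membership` (named
#'   integer vector, node -> cluster id, 0 = isolated), `clusters`
#'   (per-cluster data.frame with `category`, filled by
#'   [categorize_clusters()]), plus the edge list for downstream
#'   statistics.
#' @export
leiden_partition <- function(net, counts = NULL, resolution = 1, seed = 1L) {
  stopifnot(inherits(net, "micronet_bn"))
  taxa <- setdiff(net$nodes, net$diet)
  deg_nodes <- unique(c(net$edges$parent, net$edges$child))
  isolated <- setdiff(taxa, deg_nodes)
  connected_taxa <- intersect(taxa, deg_nodes)

  membership <- stats::setNames(rep(0L, length(taxa)), taxa)
  if (length(connected_taxa) > 0L) {
    tt <- net$edges[net$edges$parent %in% taxa & net$edges$child %in% taxa, ,
                    drop = FALSE]
    g <- igraph::graph_from_data_frame(
      tt[, c("parent", "child")], directed = FALSE,
      vertices = data.frame(name = connected_taxa))
    g <- igraph::simplify(g)
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10L)
    memb <- igraph::membership(cl)
    membership[names(memb)] <- as.integer(memb)
  }

  # renumber clusters >= 1 by decreasing abundance (or size), cluster 0 fixed
  ids <- sort(unique(membership[membership > 0L]))
  if (length(ids) > 0L) {
    key <- vapply(ids, function(id) {
      members <- names(membership)[membership == id]
      if (is.null(counts)) length(members)
      else sum(rowMeans(relative_abundance(counts)[
        intersect(members, rownames(counts)), , drop = FALSE]))
    }, numeric(1L))
    ord <- ids[order(-key, ids)]
    remap <- stats::setNames(seq_along(ord), ord)
    membership[membership > 0L] <-
      as.integer(remap[as.character(membership[membership > 0L])])
  }

  clusters <- data.frame(cluster = sort(unique(membership)),
                         stringsAsFactors = FALSE)
  clusters$size <- vapply(clusters$cluster, function(id)
    sum(membership == id), integer(1L))
  clusters$category <- NA_character_
  clusters$category[clusters$cluster == 0L] <- "isolated"

  structure(list(membership = membership, clusters = clusters,
                 edges = net$edges, diet = net$diet,
                 resolution = resolution, seed = seed),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("Cluster partition:", length(x$membership), "nodes in",
      sum(x$clusters$cluster > 0L), "clusters (+ cluster 0 with",
      sum(x$membership == 0L), "isolated nodes)\n")
  invisible(x)
}

#' Categorize clusters by connectivity to the experimental variable
#'
#' A cluster is "connected" when any member has an undirected path to
#' the variable node (direct or indirect); cluster 0 stays "isolated";
#' everything else is "not-connected". Without a variable node all
#' non-isolated clusters are "not-connected".
#'
#' @param p A [leiden_partition()] result.
#' @param net The `micronet_bn` network the partition came from.
#' @param variable Name of the variable node (default the network's Diet
#'   node).
#' @return The partition with `clusters$category` filled in.
#' @export
categorize_clusters <- function(p, net, variable = net$diet) {
  stopifnot(inherits(p, "cluster_partition"), inherits(net, "micronet_bn"))
  reachable <- character()
  if (!is.null(variable) && variable %in% net$nodes && nrow(net$edges) > 0L) {
    g <- igraph::graph_from_data_frame(net$edges[, c("parent", "child")],
                                       directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    comp <- igraph::components(g)
    vcomp <- comp$membership[[variable]]
    reachable <- names(comp$membership)[comp$membership == vcomp]
  }
  cat_of <- function(id) {
    if (id == 0L) return("isolated")
    members <- names(p$membership)[p$membership == id]
    if (any(members %in% reachable)) "connected" else "not-connected"
  }
  p$clusters$category <- vapply(p$clusters$cluster, cat_of, character(1L))
  p
}

#' Abundance and core coverage statistics per cluster category
#'
#' Summarizes, per connectivity category (isolated / connected /
#' not-connected) and per cluster: summed mean relative abundance (in
#' percent of the total population), node counts, core-taxon counts and
#' the number of network edges with or without a core participant. The
#' category shares always add up to the total abundance share of the
#' modelled taxa.
#'
#' @param p A categorized [cluster_partition].
#' @param t Count matrix containing every clustered node.
#' @param core Optional [core_filter()] result; core membership uses the
#'   level-C set.
#' @return List with `by_category`, `by_cluster` and `edge_core`
#'   data.frames.
#' @export
coverage_stats <- function(p, t, core = NULL) {
  stopifnot(inherits(p, "cluster_partition"))
  t <- validate_counts(t)
  nodes <- names(p$membership)
  missing <- setdiff(nodes, rownames(t))
  if (length(missing) > 0L)
    stop("clustered node(s) missing from the count table: ",
         paste(missing, collapse = ", "))
  ra <- relative_abundance(t) * 100
  node_share <- rowMeans(ra)[nodes]
  core_taxa <- if (is.null(core)) character() else core$C

  cl <- p$clusters
  cl$abun_pct <- vapply(cl$cluster, function(id)
    sum(node_share[p$membership == id]), numeric(1L))
  cl$n_core <- vapply(cl$cluster, function(id)
    sum(names(p$membership)[p$membership == id] %in% core_taxa), integer(1L))

  cats <- c("isolated", "connected", "not-connected")
  by_cat <- data.frame(category = cats, stringsAsFactors = FALSE)
  by_cat$abun_pct <- vapply(cats, function(cc)
    sum(cl$abun_pct[cl$category == cc]), numeric(1L))
  by_cat$n_nodes <- vapply(cats, function(cc)
    sum(cl$size[cl$category == cc]), integer(1L))
  by_cat$n_core <- vapply(cats, function(cc)
    sum(cl$n_core[cl$category == cc]), integer(1L))

  ed <- p$edges
  edge_core <- data.frame(
    n_edges = nrow(ed),
    with_core = if (nrow(ed) > 0L)
      sum(ed$parent %in% core_taxa | ed$child %in% core_taxa) else 0L)
  edge_core$without_core <- edge_core$n_edges - edge_core$with_core

  list(by_category = by_cat, by_cluster = cl, edge_core = edge_core,
       total_modelled_pct = sum(cl$abun_pct))
}
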