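#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N_bg, K, n)`: the probability of
#' drawing at least `k` annotated units in a sample of `n` from a
#' background of `N_bg` units of which `K` carry the annotation. This is
#' the over-representation test behind the per-cluster pathway
#' enrichment ("GeneRatio" k/n against "BgRatio" K/N_bg). `k = 0` gives
#' `p = 1`.
#'
#' @param k Observed annotated hits in the selection, `0 <= k <= min(n, K)`.
#' @param n Selection size, `n <= N_bg`.
#' @param K Background annotated count, `K <= N_bg`.
#' @param N_bg Background size.
#' @return Upper-tail probability in `(0, 1]`. Vectorized over its
#'   arguments.
#' @export
hypergeom_upper_tail <- function(k, n, K, N_bg) {
  args <- cbind(k, n, K, N_bg)
  if (anyNA(args) || any(args != floor(args)))
    stop("k, n, K, N_bg must be integers")
  k <- args[, 1L]; n <- args[, 2L]; K <- args[, 3L]; N_bg <- args[, 4L]
  if (any(k < 0) || any(n < 0) || any(K < 0) || any(N_bg < 1))
    stop("arguments out of bounds: need k, n, K >= 0 and N_bg >= 1")
  if (any(k > n)) stop("arguments out of bounds: k > n")
  if (any(n > N_bg)) stop("arguments out of bounds: n > N_bg")
  if (any(K > N_bg)) stop("arguments out of bounds: K > N_bg")
  if (any(k > K)) stop("arguments out of bounds: k > K")
  p <- stats::phyper(k - 1, K, N_bg - K, n, lower.tail = FALSE)
  p[k == 0] <- 1
  unname(p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment with monotonicity enforcement, capped
#' at 1 (delegates to [stats::p.adjust()]). An empty input returns an
#' empty vector.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-cluster hypergeometric pathway enrichment
#'
#' For each cluster and each pathway annotated to at least one cluster
#' member, tests whether the pathway is over-represented among the
#' cluster's annotated members relative to the catalog background. The
#' selection size `n` counts only the annotated cluster members (the
#' GeneRatio denominator convention); raw cluster size is reported
#' alongside. BH correction is applied within each cluster's tested
#' pathway set by default, or globally with `scope = "global"`.
#' Clusters without annotated members are skipped with a message.
#'
#' @param p A [cluster_partition] (cluster 0 included).
#' @param catalog An [annotation_catalog()].
#' @param alpha Significance threshold on the adjusted p-value.
#' @param scope `"cluster"` (BH within cluster, default) or `"global"`.
#' @return data.frame with one row per (cluster, pathway): `cluster`,
#'   `pathway_id`, `name`, `level2`, `k`, `n`, `cluster_size`, `K`,
#'   `N_bg`, `ratio`, `bg_ratio`, `p`, `p_adj`, `significant`.
#' @export
enrich_clusters <- function(p, catalog, alpha = 0.05,
                            scope = c("cluster", "global")) {
  stopifnot(inherits(p, "cluster_partition"),
            inherits(catalog, "annotation_catalog"))
  scope <- match.arg(scope)
  rows <- list()
  for (id in sort(unique(p$membership))) {
    members <- names(p$membership)[p$membership == id]
    annotated <- intersect(members, names(catalog$taxa))
    n <- length(annotated)
    if (n == 0L) {
      message("cluster ", id, " has no annotated members; skipped")
      next
    }
    hits <- table(unlist(lapply(catalog$taxa[annotated], unique),
                         use.names = FALSE))
    pw <- catalog$pathways[match(names(hits), catalog$pathways$pathway_id), ]
    k <- as.integer(hits)
    pv <- hypergeom_upper_tail(k, n, pw$K, catalog$n_bg)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = id, pathway_id = pw$pathway_id, name = pw$name,
      level2 = pw$level2, k = k, n = n, cluster_size = length(members),
      K = pw$K, N_bg = catalog$n_bg,
      ratio = paste0(k, "/", n), bg_ratio = paste0(pw$K, "/", catalog$n_bg),
      p = pv, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(cluster = integer(), pathway_id = character(),
                      name = character(), level2 = character(),
                      k = integer(), n = integer(), cluster_size = integer(),
                      K = integer(), N_bg = integer(), ratio = character(),
                      bg_ratio = character(), p = numeric(),
                      p_adj = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  if (scope == "cluster") {
    res$p_adj <- stats::ave(res$p, res$cluster,
                            FUN = function(v) bh_adjust(v))
  } else {
    res$p_adj <- bh_adjust(res$p)
  }
  res$significant <- res$p_adj < alpha
  res <- res[order(res$cluster, res$p_adj, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare the enriched functions of two network models
#'
#' Given the enrichment results of two networks (e.g. a NOPAP-style and
#' a PAP-style model), reports (i) the significantly enriched pathways
#' shared between, or exclusive to, the two models; (ii) for each shared
#' pathway, the taxa contributing to it in each model and their overlap;
#' and (iii) a genus -> phylum -> pathway long table suitable for
#' Sankey-style reporting.
#'
#' @param a,b Enrichment tables from [enrich_clusters()].
#' @param partition_a,partition_b The cluster partitions behind `a` and
#'   `b` (used to resolve contributing taxa).
#' @param catalog The shared [annotation_catalog()].
#' @return List with `shared`, `only_a`, `only_b` (pathway id vectors),
#'   `n_total` (distinct significant pathways over both models),
#'   `taxa_overlap` (per shared pathway: contributing taxa counts and
#'   Jaccard overlap) and `sankey` (long genus/phylum/pathway/model
#'   table).
#' @export
compare_models <- function(a, b, partition_a, partition_b, catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  sig_a <- unique(a$pathway_id[a$significant])
  sig_b <- unique(b$pathway_id[b$significant])
  shared <- sort(intersect(sig_a, sig_b))
  contributors <- function(enr, part, pid) {
    cl <- enr$cluster[enr$significant & enr$pathway_id == pid]
    members <- names(part$membership)[part$membership %in% cl]
    annotated <- intersect(members, names(catalog$taxa))
    sort(annotated[vapply(catalog$taxa[annotated],
                          function(pw) pid %in% pw, logical(1L))])
  }
  overlap <- lapply(shared, function(pid) {
    ta <- contributors(a, partition_a, pid)
    tb <- contributors(b, partition_b, pid)
    inter <- intersect(ta, tb)
    uni <- union(ta, tb)
    data.frame(pathway_id = pid, n_a = length(ta), n_b = length(tb),
               n_shared = length(inter),
               jaccard = if (length(uni) > 0) length(inter) / length(uni)
                         else NA_real_,
               stringsAsFactors = FALSE)
  })
  taxa_overlap <- if (length(overlap) > 0L) do.call(rbind, overlap)
    else data.frame(pathway_id = character(), n_a = integer(),
                    n_b = integer(), n_shared = integer(),
                    jaccard = numeric(), stringsAsFactors = FALSE)
  sankey <- do.call(rbind, lapply(shared, function(pid) {
    nm <- catalog$pathways$name[catalog$pathways$pathway_id == pid]
    rows <- lapply(c(a = "a", b = "b"), function(side) {
      enr <- if (side == "a") a else b
      part <- if (side == "a") partition_a else partition_b
      tx <- contributors(enr, part, pid)
      if (length(tx) == 0L) return(NULL)
      data.frame(genus = tx,
                 phylum = if (is.null(catalog$phylum)) NA_character_
                          else unname(catalog$phylum[tx]),
                 pathway_id = pid, pathway = nm, model = side,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  if (is.null(sankey))
    sankey <- data.frame(genus = character(), phylum = character(),
                         pathway_id = character(), pathway = character(),
                         model = character(), stringsAsFactors = FALSE)
  rownames(sankey) <- NULL
  list(shared = shared,
       only_a = sort(setdiff(sig_a, sig_b)),
       only_b = sort(setdiff(sig_b, sig_a)),
       n_total = length(union(sig_a, sig_b)),
       taxa_overlap = taxa_overlap,
       sankey = sankey)
}
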