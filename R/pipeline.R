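#' Run the full microbiota meta-analysis pipeline
#'
#' Orchestrates every stage from one configuration: joint validation,
#' descriptive TSS profile, shared taxa across trials, the nested core
#' filter, PLS-DA with permutation validation and outlier flagging,
#' abundance-weighted normalization, Bayesian-network learning (a pooled
#' diet-free network plus diet-conditioned networks over configurable
#' trial subsets), MI/BIC edge filtering, edge signs, Leiden clustering
#' with diet-connectivity categorization and coverage statistics,
#' per-cluster pathway enrichment, and the cross-network comparison of
#' enriched functions. All randomness flows from one root seed through
#' fixed per-stage offsets.
#'
#' @param config List (or path to a YAML file) with entries:
#'   * `counts`, `metadata`, `catalog`: in-memory objects or file paths
#'     (counts TSV; metadata TSV; catalog as `list(annotations, pathways,
#'     n_bg)` paths);
#'   * `networks`: named list of trial-label vectors defining the
#'     diet-conditioned networks (default `NOPAP` = all non-PAP trials,
#'     `PAP` = the PAP trial, mirroring the two-model comparison);
#'   * thresholds `fraction` (0.5), `vip` (1.2), `mi_alpha` (0.05),
#'     `enrich_alpha` (0.05), `nperm` (500), `ncomp` (2), `restarts`
#'     (5), `max_indegree` (3), `resolution` (1), `seed` (1);
#'   * optional `out_dir` to write all stage outputs as TSV/GraphML.
#' @return Object of class `micronet_run`: a machine-readable summary
#'   with all stage outputs.
#' @export
run_full <- function(config) {
  cfg <- load_run_config(config)
  counts <- cfg$counts
  meta <- validate_metadata(cfg$metadata, counts)
  catalog <- cfg$catalog
  seed <- cfg$seed

  # descriptive profile + shared taxa across trials
  trials <- unique(meta$trial)
  per_trial <- lapply(stats::setNames(trials, trials), function(tr)
    counts[, meta$sample[meta$trial == tr], drop = FALSE])
  shared <- shared_taxa(per_trial)

  # core microbiota on the taxa shared by every trial
  core_tab <- counts[shared$shared, , drop = FALSE]
  core <- core_filter(core_tab, meta, fraction = cfg$fraction)
  core_sum <- core_summary(core, counts, meta)

  # discriminant analysis of the trial profiles
  x <- t(tss_scale(counts))
  pls <- fit_plsda(x, meta$trial, ncomp = cfg$ncomp)
  vip_sel <- vip_select(pls, cfg$vip)
  outliers <- hotelling_outliers(pls)
  perm <- permutation_test(x, meta$trial, ncomp = cfg$ncomp,
                           nperm = cfg$nperm, seed = seed + 11L)

  # Bayesian networks: pooled diet-free + diet-conditioned subsets
  build_net <- function(sub_counts, sub_meta, seed_off) {
    norm <- drop_zero_taxa(normalize_eq1(sub_counts))$counts
    net <- learn_structure(norm, sub_meta, seed = seed + seed_off,
                           restarts = cfg$restarts,
                           max_indegree = cfg$max_indegree)
    net <- score_and_filter_edges(net, norm, sub_meta,
                                  mi_alpha = cfg$mi_alpha)
    net <- edge_signs(net, norm, sub_meta)
    part <- leiden_partition(net, counts = norm,
                             resolution = cfg$resolution,
                             seed = seed + seed_off + 1L)
    part <- categorize_clusters(part, net)
    cov <- coverage_stats(part, norm, core)
    enr <- enrich_clusters(part, catalog, alpha = cfg$enrich_alpha)
    list(counts = norm, net = net, partition = part, coverage = cov,
         enrichment = enr)
  }
  pooled <- build_net(counts, NULL, 100L)
  nets <- list()
  off <- 200L
  for (nm in names(cfg$networks)) {
    keep <- meta$trial %in% cfg$networks[[nm]]
    if (!any(keep)) stop("network '", nm, "' selects no samples")
    nets[[nm]] <- build_net(counts[, meta$sample[keep], drop = FALSE],
                            meta[keep, , drop = FALSE], off)
    off <- off + 100L
  }

  comparison <- NULL
  if (length(nets) >= 2L) {
    nm <- names(nets)[1:2]
    comparison <- compare_models(nets[[nm[1L]]]$enrichment,
                                 nets[[nm[2L]]]$enrichment,
                                 nets[[nm[1L]]]$partition,
                                 nets[[nm[2L]]]$partition, catalog)
  }

  run <- structure(list(
    config = cfg[setdiff(names(cfg), c("counts", "metadata", "catalog"))],
    shared = shared, core = core, core_summary = core_sum,
    plsda = pls, vip_selected = vip_sel, outliers = outliers,
    permutation = perm,
    pooled = pooled, networks = nets, comparison = comparison,
    summary = list(
      n_taxa = nrow(counts), n_samples = ncol(counts),
      shared_taxa = length(shared$shared),
      core_sizes = c(C = length(core$C), B = length(core$B),
                     A = length(core$A)),
      core_share_pct = core_sum$share,
      n_vip = length(vip_sel),
      r2y = pls$R2Y[pls$ncomp], q2 = pls$Q2[pls$ncomp],
      p_r2y = perm$p_r2y, p_q2 = perm$p_q2,
      pooled_net = net_counts(pooled),
      networks = lapply(nets, net_counts),
      shared_functions = if (!is.null(comparison))
        length(comparison$shared) else NA_integer_,
      total_functions = if (!is.null(comparison))
        comparison$n_total else NA_integer_)),
    class = "micronet_run")
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

net_counts <- function(b) {
  cat_share <- stats::setNames(b$coverage$by_category$abun_pct,
                               b$coverage$by_category$category)
  list(n_nodes = length(b$net$nodes), n_edges = nrow(b$net$edges),
       n_clusters = sum(b$partition$clusters$cluster > 0L),
       modelled_pct = b$coverage$total_modelled_pct,
       connected_pct = unname(cat_share["connected"]),
       isolated_pct = unname(cat_share["isolated"]),
       n_significant = sum(b$enrichment$significant))
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(fraction = 0.5, vip = 1.2, mi_alpha = 0.05,
                   enrich_alpha = 0.05, nperm = 500L, ncomp = 2L,
                   restarts = 5L, max_indegree = 3L, resolution = 1,
                   seed = 1L, out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("counts", "metadata", "catalog"))
    if (is.null(config[[nm]])) stop("config is missing '", nm, "'")
  if (is.character(config$counts))
    config$counts <- read_count_table(config$counts)
  if (is.character(config$metadata))
    config$metadata <- read_metadata(config$metadata)
  if (!inherits(config$catalog, "annotation_catalog")) {
    cc <- config$catalog
    config$catalog <- read_annotations(cc$annotations, cc$pathways,
                                       n_bg = cc$n_bg)
  }
  if (is.null(config$networks)) {
    trials <- unique(config$metadata$trial)
    pap <- grepl("^PAP", trials)
    config$networks <-
      if (any(pap) && any(!pap))
        list(NOPAP = trials[!pap], PAP = trials[pap])
      else stats::setNames(lapply(trials, identity), trials)
  }
  config
}

write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, nm) utils::write.table(
    x, file.path(dir, nm), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(data.frame(region = names(run$shared$regions),
                n = as.integer(run$shared$regions)), "venn.tsv")
  wt(run$core_summary$table, "core.tsv")
  wt(data.frame(feature = names(vip_scores(run$plsda)),
                vip = unname(vip_scores(run$plsda))), "vip.tsv")
  for (nm in names(run$networks)) {
    sub <- file.path(dir, paste0("net_", nm))
    write_network(run$networks[[nm]]$net, sub)
    wt(run$networks[[nm]]$enrichment, file.path(paste0("net_", nm),
                                                "enrichment.tsv"))
    part <- run$networks[[nm]]$partition
    wt(data.frame(node = names(part$membership),
                  cluster = unname(part$membership)),
       file.path(paste0("net_", nm), "clusters.tsv"))
    wt(run$networks[[nm]]$coverage$by_category,
       file.path(paste0("net_", nm), "coverage.tsv"))
  }
  write_network(run$pooled$net, file.path(dir, "net_pooled"))
  if (!is.null(run$comparison)) {
    wt(run$comparison$taxa_overlap, "comparison_taxa_overlap.tsv")
    wt(run$comparison$sankey, "comparison_sankey.tsv")
  }
  invisible(dir)
}

#' @export
print.micronet_run <- function(x, ...) {
  s <- x$summary
  cat("micronet pipeline run\n")
  cat(sprintf("  %d taxa x %d samples; %d taxa shared by all trials\n",
              s$n_taxa, s$n_samples, s$shared_taxa))
  cat(sprintf("  core microbiota: C=%d, B=%d, A=%d (C covers %.1f%% of abundance)\n",
              s$core_sizes["C"], s$core_sizes["B"], s$core_sizes["A"],
              s$core_share_pct["C"]))
  cat(sprintf("  PLS-DA: R2Y=%.3f (p=%.3g), Q2=%.3f (p=%.3g), %d VIP features\n",
              s$r2y, s$p_r2y, s$q2, s$p_q2, s$n_vip))
  pn <- s$pooled_net
  cat(sprintf("  pooled network: %d nodes, %d edges, %d clusters\n",
              pn$n_nodes, pn$n_edges, pn$n_clusters))
  for (nm in names(s$networks)) {
    b <- s$networks[[nm]]
    cat(sprintf("  %s network: %d nodes, %d edges, %d clusters; %.2f%% modelled, %.2f%% diet-connected\n",
                nm, b$n_nodes, b$n_edges, b$n_clusters, b$modelled_pct,
                if (is.null(b$connected_pct) || is.na(b$connected_pct)) 0
                else b$connected_pct))
  }
  if (!is.na(s$shared_functions))
    cat(sprintf("  enriched functions: %d total, %d shared between models\n",
                s$total_functions, s$shared_functions))
  invisible(x)
}
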