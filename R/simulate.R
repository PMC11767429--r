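#' Configuration for the synthetic microbiota generator
#'
#' Defines the study conditions emulated by [simulate_dataset()]: a
#' multi-trial feeding design with diet groups nested in trials,
#' ZINB-distributed taxon counts, planted high-prevalence core taxa,
#' diet-dependent abundance shifts, a planted parent-child dependency
#' DAG on the log1p scale, and planted pathway enrichments over an
#' annotation background.
#'
#' Taxa are laid out in four blocks with self-describing ids:
#' `core_*` (high prevalence in every diet group), `dag_*` (members of
#' the planted dependency DAG, low zero-inflation so the dependencies
#' are identifiable), `diet_*` (group-specific mean shifts of
#' `exp(diet_lfc)` with alternating sign) and `bg_*` (sparse background
#' taxa). Trials differ by a mild lognormal per-taxon composition shift
#' and background taxa may be absent from entire trials, which makes the
#' three-trial shared-taxa Venn and the level-B core filter non-trivial.
#'
#' @param n_taxa Total taxa.
#' @param trials Named list: trial label -> character vector of diet
#'   group labels (default a three-trial layout with two groups each).
#' @param samples_per_group Samples per (trial, diet group) cell.
#' @param core_taxa Number of planted core taxa.
#' @param core_prevalence Target per-group presence probability of core
#'   taxa (must be attainable given the NB zero mass, else an error).
#' @param core_mu_range Range of core NB means.
#' @param dag_taxa,dag_edges Size of the planted dependency DAG.
#' @param edge_coef Magnitude of the parent-child coefficient on the
#'   log1p scale (signs alternate).
#' @param diet_taxa Number of diet-affected taxa.
#' @param diet_lfc Log fold change of diet-affected means between the
#'   diet groups of a trial (signs alternate across taxa).
#' @param mu_range,theta_range,pi_range Baseline ZINB parameter ranges
#'   for background taxa.
#' @param trial_presence_prob Probability a background taxon occurs in
#'   any given trial at all.
#' @param trial_shift_sd SD of the lognormal per-taxon, per-trial
#'   composition shift.
#' @param n_pathways Number of background pathways in the annotation
#'   catalog.
#' @param n_bg Annotation background size.
#' @param bg_k_range Range of background per-pathway counts K.
#' @param annotations_per_taxon Background pathways drawn per taxon.
#' @param seed Default seed used by [simulate_dataset()].
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_taxa = 40L,
                       trials = list("NOPAP-PP" = c("CTRL", "PP"),
                                     "NOPAP-SCP" = c("CTRL", "SCP"),
                                     "PAP" = c("CTRL", "PAP")),
                       samples_per_group = 15L,
                       core_taxa = 8L, core_prevalence = 0.9,
                       core_mu_range = c(30, 120),
                       dag_taxa = 10L, dag_edges = 8L, edge_coef = 0.8,
                       diet_taxa = 6L, diet_lfc = 1.5,
                       mu_range = c(5, 80), theta_range = c(0.5, 3),
                       pi_range = c(0.65, 0.9),
                       trial_presence_prob = 0.7, trial_shift_sd = 0.3,
                       n_pathways = 24L, n_bg = 3364L,
                       bg_k_range = c(20L, 400L),
                       annotations_per_taxon = 3L,
                       seed = 1L) {
  cfg <- list(n_taxa = as.integer(n_taxa), trials = trials,
              samples_per_group = as.integer(samples_per_group),
              core_taxa = as.integer(core_taxa),
              core_prevalence = core_prevalence,
              core_mu_range = core_mu_range,
              dag_taxa = as.integer(dag_taxa),
              dag_edges = as.integer(dag_edges), edge_coef = edge_coef,
              diet_taxa = as.integer(diet_taxa), diet_lfc = diet_lfc,
              mu_range = mu_range, theta_range = theta_range,
              pi_range = pi_range,
              trial_presence_prob = trial_presence_prob,
              trial_shift_sd = trial_shift_sd,
              n_pathways = as.integer(n_pathways), n_bg = as.integer(n_bg),
              bg_k_range = bg_k_range,
              annotations_per_taxon = as.integer(annotations_per_taxon),
              seed = as.integer(seed))
  if (cfg$core_taxa + cfg$dag_taxa + cfg$diet_taxa > cfg$n_taxa)
    stop("core_taxa + dag_taxa + diet_taxa exceeds n_taxa")
  if (!(cfg$core_prevalence > 0 && cfg$core_prevalence <= 1))
    stop("core_prevalence must lie in (0, 1]")
  if (cfg$dag_edges > 0L && cfg$dag_taxa < 2L)
    stop("a planted DAG needs at least 2 taxa")
  max_edges <- cfg$dag_taxa * (cfg$dag_taxa - 1L) / 2L
  if (cfg$dag_edges > max_edges)
    stop("dag_edges exceeds the acyclic maximum for dag_taxa")
  if (length(cfg$trials) < 1L || is.null(names(cfg$trials)))
    stop("trials must be a named list of diet group vectors")
  # feasibility: core prevalence must be reachable given the NB zero mass
  # (core taxa draw theta in [1, 3]; the worst case is theta = 1 at the
  # smallest core mean)
  nb0_max <- stats::dnbinom(0, size = 1, mu = min(cfg$core_mu_range))
  if (cfg$core_prevalence > 1 - nb0_max + 1e-12 && cfg$core_taxa > 0L)
    stop("infeasible core prevalence: NB zero mass too large at the ",
         "configured core mu/theta")
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-trial microbiota dataset with planted ground truth
#'
#' Draws a taxa-by-sample count table, sample metadata, an annotation
#' catalog and the generator's ground truth under a [sim_config()].
#' Parents are sampled before children in topological order; a child's
#' NB mean is its baseline mean multiplied by
#' `exp(coef * (log1p(parent) - log1p(mu_parent)))` per parent edge.
#' Output is byte-identical for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed override (defaults to `cfg$seed`).
#' @return List with `counts`, `metadata`, `catalog`, `truth` (core
#'   sets A/B/C by construction, planted edge list with signs, the
#'   diet-affected taxa, and the planted (module, pathway) enrichments)
#'   and `config`.
#' @export
simulate_dataset <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)

  meta <- do.call(rbind, lapply(names(cfg$trials), function(tr) {
    do.call(rbind, lapply(cfg$trials[[tr]], function(g)
      data.frame(trial = tr, diet = g,
                 n = cfg$samples_per_group, stringsAsFactors = FALSE)))
  }))
  meta <- meta[rep(seq_len(nrow(meta)), meta$n), c("trial", "diet")]
  meta$sample <- sprintf("S%03d", seq_len(nrow(meta)))
  meta <- meta[c("sample", "trial", "diet")]
  rownames(meta) <- NULL
  n_samples <- nrow(meta)

  blocks <- c(rep("core", cfg$core_taxa), rep("dag", cfg$dag_taxa),
              rep("diet", cfg$diet_taxa),
              rep("bg", cfg$n_taxa - cfg$core_taxa - cfg$dag_taxa -
                    cfg$diet_taxa))
  ids <- character(cfg$n_taxa)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    ids[idx] <- sprintf("%s_%02d", b, seq_along(idx))
  }

  theta <- stats::runif(cfg$n_taxa, cfg$theta_range[1L], cfg$theta_range[2L])
  mu <- stats::runif(cfg$n_taxa, cfg$mu_range[1L], cfg$mu_range[2L])
  pi <- stats::runif(cfg$n_taxa, cfg$pi_range[1L], cfg$pi_range[2L])
  # core taxa: solve pi for the target presence probability
  core_idx <- which(blocks == "core")
  if (length(core_idx) > 0L) {
    mu[core_idx] <- stats::runif(length(core_idx), cfg$core_mu_range[1L],
                                 cfg$core_mu_range[2L])
    theta[core_idx] <- stats::runif(length(core_idx), 1, 3)
    nb0 <- stats::dnbinom(0, size = theta[core_idx], mu = mu[core_idx])
    pi_core <- 1 - cfg$core_prevalence / (1 - nb0)
    if (any(pi_core < 0))
      stop("infeasible core prevalence for the drawn NB parameters")
    pi[core_idx] <- pi_core
  }
  dag_idx <- which(blocks == "dag")
  if (length(dag_idx) > 0L) {
    mu[dag_idx] <- stats::runif(length(dag_idx), 30, 80)
    theta[dag_idx] <- stats::runif(length(dag_idx), 1.5, 3)
    pi[dag_idx] <- stats::runif(length(dag_idx), 0.05, 0.2)
  }
  diet_idx <- which(blocks == "diet")
  if (length(diet_idx) > 0L) {
    mu[diet_idx] <- stats::runif(length(diet_idx), 20, 60)
    theta[diet_idx] <- stats::runif(length(diet_idx), 1, 3)
    pi[diet_idx] <- stats::runif(length(diet_idx), 0.05, 0.25)
  }

  # mild per-trial composition shift; background taxa may skip whole trials
  trial_names <- names(cfg$trials)
  shift <- matrix(exp(stats::rnorm(cfg$n_taxa * length(trial_names), 0,
                                   cfg$trial_shift_sd)),
                  cfg$n_taxa, length(trial_names),
                  dimnames = list(ids, trial_names))
  present_in_trial <- matrix(TRUE, cfg$n_taxa, length(trial_names),
                             dimnames = list(ids, trial_names))
  bg_idx <- which(blocks == "bg")
  if (length(trial_names) > 1L) {
    for (i in bg_idx) {
      if (stats::runif(1) > cfg$trial_presence_prob) {
        keep <- sample(length(trial_names),
                       sample(length(trial_names) - 1L, 1L))
        present_in_trial[i, -keep] <- FALSE
      }
    }
  }

  # planted DAG: edges point from lower to higher dag index (acyclic)
  edges <- data.frame(parent = character(), child = character(),
                      coef = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  if (cfg$dag_edges > 0L) {
    pairs <- utils::combn(seq_along(dag_idx), 2L)
    pick <- sample(ncol(pairs), cfg$dag_edges)
    coefs <- cfg$edge_coef * rep_len(c(1, -1), cfg$dag_edges)
    edges <- data.frame(parent = ids[dag_idx[pairs[1L, pick]]],
                        child = ids[dag_idx[pairs[2L, pick]]],
                        coef = coefs,
                        sign = ifelse(coefs > 0, "+", "-"),
                        stringsAsFactors = FALSE)
  }

  # diet effects: alternate up/down in the non-first diet group of a trial
  diet_sign <- rep_len(c(1, -1), length(diet_idx))
  diet_effect <- stats::setNames(diet_sign * cfg$diet_lfc, ids[diet_idx])

  # sample counts in topological order (dag parents first)
  counts <- matrix(0, cfg$n_taxa, n_samples, dimnames = list(ids, meta$sample))
  # dag block is already topologically ordered (edges go low -> high index)
  topo <- c(setdiff(seq_len(cfg$n_taxa), dag_idx), sort(dag_idx))
  first_group <- vapply(meta$trial, function(tr) cfg$trials[[tr]][1L],
                        character(1L))
  is_shifted_group <- meta$diet != first_group
  for (i in topo) {
    tx <- ids[i]
    mu_vec <- rep(mu[i], n_samples) * shift[i, meta$trial]
    mu_vec[!present_in_trial[i, meta$trial]] <- 0
    if (tx %in% names(diet_effect))
      mu_vec <- mu_vec * exp(diet_effect[[tx]] * is_shifted_group)
    pa <- edges$parent[edges$child == tx]
    for (p in pa) {
      cf <- edges$coef[edges$parent == p & edges$child == tx]
      mu_vec <- mu_vec * exp(cf * (log1p(counts[p, ]) - log1p(mu[ids == p])))
    }
    pos <- mu_vec > 0
    y <- numeric(n_samples)
    if (any(pos))
      y[pos] <- rzinb(sum(pos), pi[i], pmax(mu_vec[pos], 1e-8), theta[i])
    counts[i, ] <- y
  }

  catalog <- simulate_catalog(cfg, ids, blocks)
  truth <- simulate_truth(cfg, ids, blocks, pi, mu, theta, edges,
                          diet_effect, present_in_trial, catalog)
  list(counts = counts, metadata = meta, catalog = catalog$catalog,
       truth = truth, config = cfg)
}

# annotation catalog with planted enrichments for the dag and core blocks
simulate_catalog <- function(cfg, ids, blocks) {
  pw_ids <- sprintf("pw%03d", seq_len(cfg$n_pathways))
  K <- sample(seq(cfg$bg_k_range[1L], cfg$bg_k_range[2L]), cfg$n_pathways,
              replace = TRUE)
  level2 <- sample(c("Metabolism", "Genetic information processing",
                     "Environmental information processing",
                     "Organismal systems"),
                   cfg$n_pathways, replace = TRUE)
  planted <- character()
  planted_for <- character()
  for (b in c("dag", "core")) {
    if (sum(blocks == b) == 0L) next
    pid <- sprintf("pw_planted_%s", b)
    pw_ids <- c(pw_ids, pid)
    K <- c(K, 12L)
    level2 <- c(level2, "Planted module")
    planted <- c(planted, pid)
    planted_for <- c(planted_for, b)
  }
  pathways <- data.frame(pathway_id = pw_ids,
                         name = paste("Pathway", pw_ids),
                         level2 = level2, K = as.integer(K),
                         stringsAsFactors = FALSE)
  bg_pool <- pathways$pathway_id[seq_len(cfg$n_pathways)]
  taxa <- lapply(stats::setNames(ids, ids), function(tx) {
    ann <- sample(bg_pool, min(cfg$annotations_per_taxon, length(bg_pool)))
    b <- blocks[ids == tx]
    if (b %in% planted_for) ann <- c(ann, sprintf("pw_planted_%s", b))
    sort(unique(ann))
  })
  phylum <- stats::setNames(
    sample(c("Pseudomonadota", "Bacillota", "Actinomycetota", "Bacteroidota"),
           length(ids), replace = TRUE), ids)
  list(catalog = annotation_catalog(taxa, pathways, n_bg = cfg$n_bg,
                                    phylum = phylum),
       planted = data.frame(module = planted_for, pathway_id = planted,
                            stringsAsFactors = FALSE))
}

# ground truth from the configured (designed) presence probabilities
simulate_truth <- function(cfg, ids, blocks, pi, mu, theta, edges,
                           diet_effect, present_in_trial, catalog) {
  # designed presence probability per (taxon, trial), ignoring parent and
  # diet modulation (both mean-preserving on average)
  nb0 <- stats::dnbinom(0, size = theta, mu = mu)
  pres <- (1 - pi) * (1 - nb0)
  designed <- outer(pres, rep(1, ncol(present_in_trial))) * present_in_trial
  dimnames(designed) <- dimnames(present_in_trial)
  core_C <- ids[rowMeans(designed) > 0.5]
  core_B <- ids[apply(designed > 0.5, 1L, all)]
  core_A <- core_B # designed presence is constant across groups in a trial
  list(core_A = sort(core_A), core_B = sort(core_B), core_C = sort(core_C),
       edges = edges,
       diet_taxa = names(diet_effect),
       diet_sign = ifelse(diet_effect > 0, "+", "-"),
       enriched = catalog$planted,
       blocks = stats::setNames(blocks, ids))
}

#' Deterministic bundled toy dataset
#'
#' A 20-taxa by 30-sample dataset (3 trials x 2 diet groups x 5
#' samples) with all planted features -- core taxa, a dependency DAG,
#' diet effects and planted pathway enrichments -- regenerated from a
#' fixed seed, for examples and tests.
#'
#' @return The [simulate_dataset()] bundle.
#' @export
fixture_small <- function() {
  cfg <- sim_config(n_taxa = 20L, samples_per_group = 5L,
                    core_taxa = 4L, dag_taxa = 6L, dag_edges = 5L,
                    diet_taxa = 4L, n_pathways = 12L, seed = 2024L)
  simulate_dataset(cfg)
}
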