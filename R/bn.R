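#' Bayesian network structure learning over microbial abundances
#'
#' Learns a directed acyclic graph over taxon nodes (plus an optional
#' discrete "Diet" node) by greedy hill-climbing that maximizes a total
#' BIC score, with seeded random restarts. Node-local scores use a
#' hurdle formulation consistent with the zero-inflated negative binomial
#' marginals: a Bernoulli zero indicator plus a zero-truncated negative
#' binomial whose log-mean is linear in `log1p(parent abundance)` and in
#' diet indicators when Diet is a parent. Normalized abundances are
#' rounded to the nearest integer for the count likelihoods. The Diet
#' node encodes the experimental variable and is constrained to be a
#' root (no parents, never a child).
#'
#' The learned edge set is invariant to sample order and, through
#' lexicographic node ordering and deterministic tie-breaking, to taxon
#' order.
#'
#' @param t Normalized count matrix (taxa x samples); apply
#'   [normalize_eq1()] and [drop_zero_taxa()] first.
#' @param meta Optional sample metadata; when given, the `diet` column
#'   enters as the discrete Diet root node.
#' @param seed Integer seed controlling the random restarts.
#' @param restarts Number of hill-climbing restarts (first starts from
#'   the empty graph, the rest from random sparse DAGs).
#' @param max_indegree Maximum number of parents per node.
#' @param max_iter Maximum accepted moves per climb.
#' @return Object of class `micronet_bn` with fields `nodes`, `edges`
#'   (parent/child data.frame, unscored), `diet` (variable node name or
#'   NULL), `node_params` (per-taxon [fit_zinb()] marginals), and the
#'   attained network `score`.
#' @seealso [score_and_filter_edges()], [edge_signs()],
#'   [hierarchy_metrics()]
#' @export
learn_structure <- function(t, meta = NULL, seed = 1L, restarts = 5L,
                            max_indegree = 3L, max_iter = 500L) {
  dat <- bn_prepare(t, meta)
  taxa <- dat$taxa
  cache <- new.env(hash = TRUE, parent = emptyenv())
  ls_fun <- function(child, parents)
    cached_score(child, parents, dat, cache)

  best <- NULL
  for (r in seq_len(restarts)) {
    parents <- stats::setNames(rep(list(character()), length(taxa)), taxa)
    if (r > 1L) {
      set.seed(seed + r * 131L)
      parents <- random_start(taxa, dat$diet_node, max_indegree)
    }
    parents <- hill_climb(parents, dat, ls_fun, max_indegree, max_iter)
    total <- sum(vapply(taxa, function(ch) ls_fun(ch, parents[[ch]]),
                        numeric(1L)))
    if (is.null(best) || total > best$score + 1e-9)
      best <- list(parents = parents, score = total)
  }

  edges <- parents_to_edges(best$parents)
  node_params <- lapply(stats::setNames(taxa, taxa), function(tx)
    fit_zinb(dat$y[tx, ], max_iter = 100L))
  structure(list(nodes = c(taxa, dat$diet_node),
                 edges = edges,
                 diet = dat$diet_node,
                 diet_levels = if (!is.null(dat$diet)) levels(dat$diet),
                 node_params = node_params,
                 score = best$score,
                 seed = seed, restarts = restarts,
                 max_indegree = max_indegree),
            class = "micronet_bn")
}

bn_prepare <- function(t, meta = NULL) {
  t <- validate_counts(t)
  if (ncol(t) < 8L) stop("need at least 8 samples to learn a network")
  taxa <- sort(rownames(t))
  y <- round(t[taxa, , drop = FALSE])
  diet <- NULL
  diet_node <- NULL
  if (!is.null(meta)) {
    meta <- validate_metadata(meta, t)
    diet <- factor(meta$diet)
    if (nlevels(diet) < 2L)
      stop("Diet variable needs at least 2 levels")
    diet_node <- "Diet"
    if ("Diet" %in% taxa) stop("taxon id 'Diet' collides with the variable node")
  }
  list(y = y, taxa = taxa, diet = diet, diet_node = diet_node,
       n = ncol(y))
}

cached_score <- function(child, parents, dat, cache) {
  key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
  got <- cache[[key]]
  if (!is.null(got)) return(got)
  val <- taxon_node_score(child, sort(parents), dat)
  cache[[key]] <- val
  val
}

# BIC-style local score (higher is better): hurdle loglik - 0.5 * npar * log(n)
taxon_node_score <- function(child, parents, dat) {
  y <- dat$y[child, ]
  tax_par <- setdiff(parents, "Diet")
  Z <- matrix(1, dat$n, 1L)
  if (length(tax_par) > 0L)
    Z <- cbind(Z, t(log1p(dat$y[tax_par, , drop = FALSE])))
  if ("Diet" %in% parents)
    Z <- cbind(Z, class_dummy(dat$diet)[, -1L, drop = FALSE])
  fit <- hurdle_nb_loglik(y, Z)
  npar <- 1L + ncol(Z) + 1L # zero probability + count coefficients + theta
  fit$ll - 0.5 * npar * log(dat$n)
}

# loglik of the hurdle model: Bernoulli zero part + truncated NB count part
hurdle_nb_loglik <- function(y, Z) {
  n <- length(y)
  pos <- y > 0
  n1 <- sum(pos)
  p0 <- 1 - n1 / n
  ll_bin <- 0
  if (n1 > 0L && n1 < n) ll_bin <- (n - n1) * log(p0) + n1 * log(1 - p0)
  if (n1 == 0L) return(list(ll = ll_bin))
  m <- ncol(Z)
  if (n1 < m + 2L) { # too few positives to support covariates
    Zp <- matrix(1, n1, 1L)
  } else {
    Zp <- Z[pos, , drop = FALSE]
  }
  yp <- y[pos]
  mz <- ncol(Zp)
  nll <- function(par) {
    beta <- par[seq_len(mz)]
    th <- exp(par[mz + 1L])
    if (!is.finite(th) || th <= 0) return(1e10)
    mu <- exp(pmin(as.vector(Zp %*% beta), 30))
    if (any(!is.finite(mu)) || any(mu <= 0)) return(1e10)
    pz <- pmin((th / (th + mu))^th, 1 - 1e-12)
    s <- sum(stats::dnbinom(yp, size = th, mu = mu, log = TRUE) - log1p(-pz))
    if (!is.finite(s)) 1e10 else -s
  }
  init <- c(log(mean(yp)), rep(0, mz - 1L), 0)
  opt <- tryCatch(
    stats::optim(init, nll, method = "BFGS", control = list(maxit = 200L)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value))
    opt <- stats::optim(init, nll, method = "Nelder-Mead",
                        control = list(maxit = 1000L))
  list(ll = ll_bin - opt$value)
}

# multinomial score of the root Diet node (constant over structures with
# the root constraint; kept out of the search total)
diet_node_score <- function(diet) {
  tab <- table(diet)
  sum(tab * log(tab / sum(tab))) - 0.5 * (nlevels(diet) - 1L) * log(length(diet))
}

random_start <- function(taxa, diet_node, max_indegree) {
  parents <- stats::setNames(rep(list(character()), length(taxa)), taxa)
  k <- length(taxa)
  cand <- c(taxa, diet_node)
  for (i in seq_len(k)) {
    from <- sample(cand, 1L)
    to <- sample(taxa, 1L)
    if (from == to || from %in% parents[[to]]) next
    if (length(parents[[to]]) >= max_indegree) next
    if (creates_cycle(parents, from, to)) next
    parents[[to]] <- c(parents[[to]], from)
  }
  parents
}

# would adding from -> to create a directed cycle? (i.e. to reaches from)
creates_cycle <- function(parents, from, to) {
  if (!(from %in% names(parents))) return(FALSE) # Diet is a root
  stack <- from
  seen <- character()
  while (length(stack) > 0L) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd == to) return(TRUE)
    if (nd %in% seen) next
    seen <- c(seen, nd)
    ps <- parents[[nd]]
    stack <- c(stack, ps[ps %in% names(parents)])
  }
  FALSE
}

hill_climb <- function(parents, dat, ls_fun, max_indegree, max_iter) {
  taxa <- dat$taxa
  cand_parents <- c(taxa, dat$diet_node)
  cur_score <- vapply(taxa, function(ch) ls_fun(ch, parents[[ch]]),
                      numeric(1L))
  for (it in seq_len(max_iter)) {
    best_delta <- 1e-6
    best_move <- NULL
    for (child in taxa) {
      cur <- parents[[child]]
      # additions
      if (length(cur) < max_indegree) {
        for (par in cand_parents) {
          if (par == child || par %in% cur) next
          if (creates_cycle(parents, par, child)) next
          delta <- ls_fun(child, c(cur, par)) - cur_score[[child]]
          if (delta > best_delta) {
            best_delta <- delta
            best_move <- list(type = "add", from = par, to = child)
          }
        }
      }
      # deletions and reversals
      for (par in cur) {
        s_del <- ls_fun(child, setdiff(cur, par))
        delta <- s_del - cur_score[[child]]
        if (delta > best_delta) {
          best_delta <- delta
          best_move <- list(type = "del", from = par, to = child)
        }
        if (par %in% taxa && length(parents[[par]]) < max_indegree) {
          tmp <- parents
          tmp[[child]] <- setdiff(cur, par)
          if (!creates_cycle(tmp, child, par)) {
            delta_rev <- (s_del - cur_score[[child]]) +
              (ls_fun(par, c(parents[[par]], child)) - cur_score[[par]])
            if (delta_rev > best_delta) {
              best_delta <- delta_rev
              best_move <- list(type = "rev", from = par, to = child)
            }
          }
        }
      }
    }
    if (is.null(best_move)) break
    mv <- best_move
    if (mv$type == "add") {
      parents[[mv$to]] <- c(parents[[mv$to]], mv$from)
    } else if (mv$type == "del") {
      parents[[mv$to]] <- setdiff(parents[[mv$to]], mv$from)
    } else {
      parents[[mv$to]] <- setdiff(parents[[mv$to]], mv$from)
      parents[[mv$from]] <- c(parents[[mv$from]], mv$to)
      cur_score[[mv$from]] <- ls_fun(mv$from, parents[[mv$from]])
    }
    cur_score[[mv$to]] <- ls_fun(mv$to, parents[[mv$to]])
  }
  parents
}

parents_to_edges <- function(parents) {
  pr <- unlist(lapply(names(parents), function(ch)
    stats::setNames(parents[[ch]], rep(ch, length(parents[[ch]])))))
  if (length(pr) == 0L)
    return(data.frame(parent = character(), child = character(),
                      sign = character(), mi_p = numeric(),
                      bic_delta = numeric(), stringsAsFactors = FALSE))
  df <- data.frame(parent = unname(pr), child = names(pr),
                   sign = NA_character_, mi_p = NA_real_,
                   bic_delta = NA_real_, stringsAsFactors = FALSE)
  df <- df[order(df$parent, df$child), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Score edges by MI and BIC and filter weak arcs
#'
#' For every learned arc, computes (a) the mutual-information
#' independence-test p-value between the endpoint variables and (b) the
#' BIC delta: the change in the network BIC score caused by removing the
#' arc (negative means removal worsens the network, i.e. the arc is
#' supported). Arcs are retained when `MI p-value < mi_alpha` and
#' `BIC delta < 0`. Tightening `mi_alpha` can only remove edges, never
#' add them.
#'
#' @param net A [learn_structure()] result.
#' @param t The normalized count matrix the network was learned from.
#' @param meta Sample metadata (required when the network has a Diet
#'   node).
#' @param mi_alpha Significance threshold on the MI test p-value.
#' @return The network with `edges` reduced to the retained arcs and
#'   annotated with `mi_p` and `bic_delta`; the full scored table of all
#'   tested arcs is kept in `edge_scores`.
#' @export
score_and_filter_edges <- function(net, t, meta = NULL, mi_alpha = 0.05) {
  stopifnot(inherits(net, "micronet_bn"))
  dat <- bn_prepare(t, meta)
  edges <- net$edges
  if (nrow(edges) == 0L) {
    net$edge_scores <- edges
    return(net)
  }
  parents <- edges_to_parents(edges, dat$taxa)
  mi_p <- numeric(nrow(edges))
  bic_delta <- numeric(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    pa <- edges$parent[i]; ch <- edges$child[i]
    xv <- if (identical(pa, "Diet")) dat$diet else dat$y[pa, ]
    mi_p[i] <- mutual_information_test(xv, dat$y[ch, ])$p_value
    with_arc <- taxon_node_score(ch, sort(parents[[ch]]), dat)
    without <- taxon_node_score(ch, sort(setdiff(parents[[ch]], pa)), dat)
    bic_delta[i] <- without - with_arc
  }
  edges$mi_p <- mi_p
  edges$bic_delta <- bic_delta
  edges$retained <- mi_p < mi_alpha & bic_delta < 0
  net$edge_scores <- edges
  net$edges <- edges[edges$retained,
                     c("parent", "child", "sign", "mi_p", "bic_delta"),
                     drop = FALSE]
  rownames(net$edges) <- NULL
  net$mi_alpha <- mi_alpha
  net
}

edges_to_parents <- function(edges, taxa) {
  parents <- stats::setNames(rep(list(character()), length(taxa)), taxa)
  for (i in seq_len(nrow(edges)))
    parents[[edges$child[i]]] <- c(parents[[edges$child[i]]], edges$parent[i])
  parents
}

#' Assign interaction signs to network edges
#'
#' Taxon-taxon arcs get the sign of the Spearman rank correlation of the
#' endpoint abundances; Diet-taxon arcs get the sign of the difference in
#' the child's mean abundance between the last and first diet level (in
#' the declared factor ordering). A zero or undefined correlation is
#' reported as "+" and flagged ambiguous.
#'
#' @param net A scored network ([score_and_filter_edges()]).
#' @param t Normalized count matrix.
#' @param meta Sample metadata (required with a Diet node).
#' @return The network with `sign` (and `ambiguous`) filled in on its
#'   edges.
#' @export
edge_signs <- function(net, t, meta = NULL) {
  stopifnot(inherits(net, "micronet_bn"))
  dat <- bn_prepare(t, meta)
  edges <- net$edges
  if (nrow(edges) == 0L) return(net)
  sgn <- character(nrow(edges))
  amb <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    pa <- edges$parent[i]; ch <- edges$child[i]
    if (identical(pa, "Diet")) {
      lv <- levels(dat$diet)
      d <- mean(dat$y[ch, dat$diet == lv[length(lv)]]) -
        mean(dat$y[ch, dat$diet == lv[1L]])
      rho <- d
    } else {
      rho <- suppressWarnings(
        stats::cor(dat$y[pa, ], dat$y[ch, ], method = "spearman"))
    }
    if (is.na(rho) || rho == 0) {
      sgn[i] <- "+"; amb[i] <- TRUE
    } else {
      sgn[i] <- if (rho > 0) "+" else "-"
    }
  }
  net$edges$sign <- sgn
  net$edges$ambiguous <- amb
  net
}

#' Node hierarchy metrics
#'
#' Per node: the centrality degree (total number of edges the node is
#' involved in) and the parent percentage (share of those edges in which
#' the node acts as parent), undefined (NA) for isolated nodes.
#'
#' @param net A `micronet_bn` network.
#' @return data.frame with columns `node`, `degree`, `parent_pct`.
#' @export
hierarchy_metrics <- function(net) {
  stopifnot(inherits(net, "micronet_bn"))
  nodes <- net$nodes
  out_deg <- table(factor(net$edges$parent, levels = nodes))
  in_deg <- table(factor(net$edges$child, levels = nodes))
  degree <- as.integer(out_deg + in_deg)
  parent_pct <- ifelse(degree > 0, 100 * as.integer(out_deg) / degree,
                       NA_real_)
  data.frame(node = nodes, degree = degree, parent_pct = parent_pct,
             stringsAsFactors = FALSE)
}

#' Convert a learned network to an igraph object
#'
#' @param net A `micronet_bn` network.
#' @return A directed igraph graph carrying edge attributes `sign`,
#'   `mi_p`, `bic_delta`.
#' @export
as_igraph_bn <- function(net) {
  stopifnot(inherits(net, "micronet_bn"))
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  g
}

#' Write a network to an edge-list TSV and a GraphML file
#'
#' @param net A `micronet_bn` network.
#' @param dir Output directory (created if missing).
#' @return Named character vector with the two written paths, invisibly.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "micronet_bn"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edge_path <- file.path(dir, "edges.tsv")
  cols <- c("parent", "child", "sign", "mi_p", "bic_delta")
  utils::write.table(net$edges[, cols, drop = FALSE], edge_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gml_path <- file.path(dir, "network.graphml")
  g <- as_igraph_bn(net)
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(edges = edge_path, graphml = gml_path))
}

#' Read a network edge list written by [write_network()]
#'
#' @param path Path to `edges.tsv`.
#' @return data.frame with columns `parent`, `child`, `sign`, `mi_p`,
#'   `bic_delta`.
#' @export
read_network_edges <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE,
                    colClasses = c(parent = "character", child = "character",
                                   sign = "character"))
}

#' @export
print.micronet_bn <- function(x, ...) {
  cat("Bayesian network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges", if (!is.null(x$diet)) "(with Diet variable)" else "", "\n")
  cat("  network BIC score:", format(x$score, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.micronet_bn <- function(object, ...) {
  print(object)
  h <- hierarchy_metrics(object)
  cat("  isolated nodes:", sum(h$degree == 0), "\n")
  if (nrow(object$edges) > 0L && !all(is.na(object$edges$sign))) {
    cat("  edge signs:", sum(object$edges$sign == "+", na.rm = TRUE), "+ /",
        sum(object$edges$sign == "-", na.rm = TRUE), "-\n")
  }
  invisible(object)
}

#' @export
plot.micronet_bn <- function(x, ...) {
  g <- as_igraph_bn(x)
  deg <- igraph::degree(g)
  igraph::plot.igraph(g, vertex.size = 4 + 2 * sqrt(deg),
                      vertex.label.cex = 0.6, edge.arrow.size = 0.3, ...)
  invisible(x)
}
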