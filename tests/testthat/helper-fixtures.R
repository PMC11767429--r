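# shared builders for tests: tiny tables, metadata and hand-made networks

toy_counts <- function(values, taxa = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(taxa)) taxa <- paste0("tax", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(taxa, samples)
  m
}

toy_meta <- function(samples, trial, diet = trial) {
  data.frame(sample = samples, trial = trial, diet = diet,
             stringsAsFactors = FALSE)
}

# hand-built network object (bypasses learning) for graph-level tests
make_bn <- function(edges, nodes = NULL, diet = NULL) {
  if (is.null(nodes))
    nodes <- sort(unique(c(edges$parent, edges$child, diet)))
  for (col in c("sign", "mi_p", "bic_delta"))
    if (is.null(edges[[col]]))
      edges[[col]] <- rep(if (col == "sign") NA_character_ else NA_real_,
                          nrow(edges))
  structure(list(nodes = nodes, edges = edges, diet = diet,
                 node_params = list(), score = NA_real_),
            class = "micronet_bn")
}

edge_df <- function(parent, child, ...) {
  data.frame(parent = parent, child = child, ..., stringsAsFactors = FALSE)
}

# undirected skeleton of an edge data.frame, as sorted "a~b" strings
skeleton <- function(edges) {
  if (nrow(edges) == 0L) return(character())
  unique(paste(pmin(edges$parent, edges$child),
               pmax(edges$parent, edges$child), sep = "~"))
}

skeleton_f1 <- function(est, truth) {
  tp <- length(intersect(est, truth))
  if (length(est) + length(truth) == 0L) return(NA_real_)
  2 * tp / (length(est) + length(truth))
}

# independent ZINB matrix (no structure), taxa x samples
null_zinb_matrix <- function(n_taxa, n, seed) {
  set.seed(seed)
  m <- t(vapply(seq_len(n_taxa), function(i)
    rzinb(n, stats::runif(1, 0.2, 0.4), stats::runif(1, 20, 80),
          stats::runif(1, 1, 3)), numeric(n)))
  dimnames(m) <- list(sprintf("t%02d", seq_len(n_taxa)),
                      paste0("s", seq_len(n)))
  m
}
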