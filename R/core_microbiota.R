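#' Taxa shared between experiments, with Venn region counts
#'
#' A taxon "occurs" in a table when its row sum is positive. Returns the
#' taxa occurring in every table plus the count of taxa in each Venn
#' region (each non-empty subset of tables whose members, and only they,
#' contain the taxon).
#'
#' @param tables Named list of two or more count matrices.
#' @return List with `shared` (character vector of taxa occurring in all
#'   tables) and `regions` (named integer vector; names are
#'   `&`-joined table names).
#' @export
shared_taxa <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("need at least two count tables")
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be named")
  occ <- lapply(tables, function(t) {
    t <- validate_counts(t)
    if (ncol(t) == 0L || nrow(t) == 0L) stop("empty count table")
    rownames(t)[rowSums(t) > 0]
  })
  all_taxa <- unique(unlist(occ, use.names = FALSE))
  member <- vapply(occ, function(o) all_taxa %in% o, logical(length(all_taxa)))
  member <- matrix(member, nrow = length(all_taxa),
                   dimnames = list(all_taxa, names(tables)))
  pattern <- apply(member, 1L, function(m)
    paste(sort(names(tables)[m]), collapse = "&"))
  nm <- names(tables)
  all_patterns <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(sort(nm), k, paste, collapse = "&", simplify = FALSE)))
  regions <- stats::setNames(integer(length(all_patterns)), all_patterns)
  tab <- table(pattern)
  regions[names(tab)] <- as.integer(tab)
  shared <- all_taxa[rowSums(member) == length(tables)]
  list(shared = sort(shared), regions = regions)
}

#' Nested prevalence filter defining the core microbiota
#'
#' Applies an increasing-restriction prevalence gradient over the samples:
#' level C keeps taxa present (count > 0) in more than a fraction `f` of
#' all pooled samples; level B keeps the level-C taxa exceeding `f` within
#' every trial; level A keeps the level-B taxa exceeding `f` within every
#' diet group of every trial. "More than" is a strict inequality, so
#' presence in exactly half of the samples does not qualify. The nesting
#' A <= B <= C holds by construction, and the filter is invariant under
#' sample reordering and any per-sample positive rescaling.
#'
#' @param t Count matrix (taxa x samples), typically restricted to the
#'   taxa shared by all trials first (see [shared_taxa()]).
#' @param meta Sample metadata (`sample`, `trial`, `diet`).
#' @param fraction Presence threshold fraction `f`, strict; default 0.5.
#' @return An object of class `core_set`: list with character vectors
#'   `C`, `B`, `A` and a per-taxon prevalence table.
#' @export
core_filter <- function(t, meta, fraction = 0.5) {
  t <- validate_counts(t)
  meta <- validate_metadata(meta, t)
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1")
  present <- t > 0
  prev_all <- rowMeans(present)
  C <- rownames(t)[prev_all > fraction]

  trials <- unique(meta$trial)
  prev_trial <- vapply(trials, function(tr) {
    idx <- meta$trial == tr
    if (!any(idx)) stop("trial with zero samples: ", tr)
    rowMeans(present[, idx, drop = FALSE])
  }, numeric(nrow(t)))
  prev_trial <- matrix(prev_trial, nrow = nrow(t),
                       dimnames = list(rownames(t), trials))
  B <- C[apply(prev_trial[C, , drop = FALSE] > fraction, 1L, all)]

  grp <- interaction(meta$trial, meta$diet, drop = TRUE, sep = "/")
  prev_grp <- vapply(levels(grp), function(g) {
    idx <- grp == g
    if (!any(idx)) stop("group with zero samples: ", g)
    rowMeans(present[, idx, drop = FALSE])
  }, numeric(nrow(t)))
  prev_grp <- matrix(prev_grp, nrow = nrow(t),
                     dimnames = list(rownames(t), levels(grp)))
  A <- B[apply(prev_grp[B, , drop = FALSE] > fraction, 1L, all)]

  structure(list(C = sort(C), B = sort(B), A = sort(A),
                 fraction = fraction,
                 prevalence = cbind(pooled = prev_all, prev_trial, prev_grp)),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat("Core microbiota (presence > ", x$fraction * 100, "% of samples):\n",
      "  C (pooled):           ", length(x$C), " taxa\n",
      "  B (every trial):      ", length(x$B), " taxa\n",
      "  A (every diet group): ", length(x$A), " taxa\n", sep = "")
  invisible(x)
}

#' Abundance summary of the core microbiota
#'
#' For each core taxon, the mean relative abundance (in percent) per trial
#' and overall, together with the summed share of the total bacterial
#' population covered by each core level.
#'
#' @param core A [core_filter()] result.
#' @param t Count matrix used for abundance (raw or normalized).
#' @param meta Sample metadata.
#' @return List with `table` (per-taxon data.frame, percentages) and
#'   `share` (named vector: summed mean relative abundance of levels C, B
#'   and A, in percent).
#' @export
core_summary <- function(core, t, meta) {
  stopifnot(inherits(core, "core_set"))
  t <- validate_counts(t)
  meta <- validate_metadata(meta, t)
  ra <- relative_abundance(t) * 100
  trials <- unique(meta$trial)
  taxa <- core$C
  per_trial <- vapply(trials, function(tr)
    rowMeans(ra[taxa, meta$trial == tr, drop = FALSE]), numeric(length(taxa)))
  per_trial <- matrix(per_trial, nrow = length(taxa),
                      dimnames = list(taxa, trials))
  tab <- data.frame(taxon = taxa,
                    level = ifelse(taxa %in% core$A, "A",
                                   ifelse(taxa %in% core$B, "B", "C")),
                    per_trial,
                    overall = rowMeans(ra[taxa, , drop = FALSE]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  share <- c(C = sum(colMeans_safe(ra, core$C)),
             B = sum(colMeans_safe(ra, core$B)),
             A = sum(colMeans_safe(ra, core$A)))
  list(table = tab, share = share)
}

# mean relative abundance of a taxon subset; zero-length subset -> 0
colMeans_safe <- function(ra, taxa) {
  if (length(taxa) == 0L) return(0)
  rowMeans(ra[taxa, , drop = FALSE])
}
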