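#' Total-sum scaling made proportional to sequencing depth
#'
#' Scales each sample column to proportions (total-sum scaling) and then
#' multiplies by the mean raw sample depth of the table, so every column
#' sums to the same count-like depth. Used for the descriptive taxonomic
#' profile; the network stage uses [normalize_eq1()] instead.
#'
#' @param t Count matrix (taxa x samples).
#' @return Normalized matrix with all column sums equal to the mean input
#'   depth.
#' @export
tss_scale <- function(t) {
  t <- validate_counts(t)
  depth <- colSums(t)
  if (any(depth == 0))
    stop("zero-depth sample: ", paste(colnames(t)[depth == 0], collapse = ", "))
  out <- sweep(t, 2L, depth, "/") * mean(depth)
  validate_counts(out)
}

#' Abundance-weighted depth normalization for network modelling
#'
#' Rescales each raw count by the taxon's total abundance across all
#' samples divided by the sample's sequencing depth:
#' \deqn{NC_{ij} = X_{ij} \frac{\sum_{n=1}^{N} X_{in}}{\sum_{t=1}^{T} X_{tj}}}
#' where \eqn{X_{ij}} is the raw count of taxon \eqn{i} in sample \eqn{j},
#' \eqn{N} the number of samples and \eqn{T} the number of taxa. Zeros map
#' to zeros and output row \eqn{i} stays proportional to input row
#' \eqn{i} within every sample.
#'
#' @param t Raw count matrix (taxa x samples).
#' @return Normalized matrix of the same shape.
#' @export
normalize_eq1 <- function(t) {
  t <- validate_counts(t)
  depth <- colSums(t)
  if (any(depth == 0))
    stop("zero-depth sample: ", paste(colnames(t)[depth == 0], collapse = ", "))
  out <- t * (rowSums(t) %o% (1 / depth))
  validate_counts(out)
}

#' Drop taxa with zero total count
#'
#' Removes taxa whose row sum is exactly zero (taxa absent from every
#' sample after normalization); retained rows are untouched.
#'
#' @param t Count matrix (taxa x samples).
#' @return List with elements `counts` (the filtered matrix) and `report`
#'   (removed taxon ids plus per-sample depth before/after).
#' @export
drop_zero_taxa <- function(t) {
  t <- validate_counts(t)
  zero <- rowSums(t) == 0
  if (all(zero)) stop("all taxa have zero total count; nothing to analyze")
  report <- list(removed = rownames(t)[zero],
                 depth_before = colSums(t),
                 depth_after = colSums(t[!zero, , drop = FALSE]),
                 method = "zero-taxon filter")
  list(counts = t[!zero, , drop = FALSE], report = report)
}

#' Per-sample relative abundance
#'
#' Scales each sample column to sum to 1. Idempotent.
#'
#' @param t Count matrix (taxa x samples).
#' @return Matrix of proportions, each column summing to 1.
#' @export
relative_abundance <- function(t) {
  t <- validate_counts(t)
  depth <- colSums(t)
  if (any(depth == 0))
    stop("zero-depth sample: ", paste(colnames(t)[depth == 0], collapse = ", "))
  sweep(t, 2L, depth, "/")
}
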