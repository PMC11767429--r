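#' Read a taxa-by-sample count table
#'
#' Parses a tab-separated count table with taxa as rows and samples as
#' columns: the first column holds taxon identifiers, the header row holds
#' sample identifiers. Lines starting with `#` are ignored, so BIOM-style
#' TSV exports from common amplicon tools drop in directly.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (taxa x samples) with taxon row names and
#'   sample column names. All values are non-negative.
#' @seealso [write_count_table()], [read_metadata()]
#' @export
read_count_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop("count table must have a taxon id column and at least one sample column")
  taxa <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(taxa))
    stop("duplicated taxon id: ", paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicated sample id: ", paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- suppressWarnings(vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw), dimnames = list(taxa, samples))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric count at taxon '%s', sample '%s'",
                 taxa[bad[1L, 1L]], samples[bad[1L, 2L]]))
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative count at taxon '%s', sample '%s'",
                 taxa[neg[1L, 1L]], samples[neg[1L, 2L]]))
  validate_counts(vals)
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]: writes a `taxon` id column followed by
#' one column per sample.
#'
#' @param x Count matrix (taxa x samples) with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  x <- validate_counts(x)
  df <- data.frame(taxon = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a count matrix
#'
#' Checks the invariants every pipeline stage relies on: a numeric matrix
#' with unique taxon row names and unique sample column names, and no
#' negative or missing values. Raw tables are integer counts; normalized
#' tables are non-negative reals.
#'
#' @param x Matrix to validate.
#' @return `x`, unchanged, if valid.
#' @export
validate_counts <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("counts must carry taxon row names and sample column names")
  if (anyDuplicated(rownames(x)))
    stop("duplicated taxon id: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicated sample id: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x)) stop("counts contain missing values")
  if (any(x < 0)) stop("counts contain negative values")
  x
}

#' Read sample metadata
#'
#' Reads the per-sample design table: columns `sample`, `trial` (feeding
#' trial label, e.g. NOPAP-PP / NOPAP-SCP / PAP) and `diet` (diet group
#' within trial).
#'
#' @param path Path to a TSV file with header `sample`, `trial`, `diet`.
#' @return A data.frame with character columns `sample`, `trial`, `diet`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample", "trial", "diet")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  if (anyDuplicated(df$sample))
    stop("duplicated sample id in metadata: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  empty <- df$trial == "" | is.na(df$trial) | df$diet == "" | is.na(df$diet)
  if (any(empty))
    stop("sample(s) missing trial or diet label: ",
         paste(df$sample[empty], collapse = ", "))
  validate_metadata(df)
}

#' Validate sample metadata, optionally against a count table
#'
#' Enforces unique samples, non-empty trial/diet labels and at least two
#' samples per trial. When `counts` is supplied, additionally requires the
#' sample sets of the two tables to coincide exactly (the joint check run
#' before any analysis stage).
#'
#' @param meta Metadata data.frame (`sample`, `trial`, `diet`).
#' @param counts Optional count matrix to validate against.
#' @return `meta`, with samples ordered as in `counts` when given.
#' @export
validate_metadata <- function(meta, counts = NULL) {
  if (!all(c("sample", "trial", "diet") %in% colnames(meta)))
    stop("metadata must have columns sample, trial, diet")
  if (anyDuplicated(meta$sample))
    stop("duplicated sample id in metadata")
  tab <- table(meta$trial)
  if (any(tab < 2L))
    stop("every trial needs at least 2 samples; offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  if (!is.null(counts)) {
    counts <- validate_counts(counts)
    only_counts <- setdiff(colnames(counts), meta$sample)
    only_meta <- setdiff(meta$sample, colnames(counts))
    if (length(only_counts) || length(only_meta))
      stop("sample sets differ between counts and metadata; ",
           "missing from metadata: [", paste(only_counts, collapse = ", "),
           "]; missing from counts: [", paste(only_meta, collapse = ", "), "]")
    meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}

#' Construct a taxon-to-pathway annotation catalog
#'
#' The catalog stands in for a PICRUSt2/KEGG inferred metagenome: a map
#' from taxon ids to pathway ids, pathway descriptions with a level-2
#' category, and the enrichment background -- the background size `n_bg`
#' and the per-pathway background count `K` (the "BgRatio" numerator).
#' The background is taken as given, never recomputed from the dataset,
#' because reference backgrounds are typically external sequence
#' collections.
#'
#' @param taxa Named list: taxon id -> character vector of pathway ids.
#' @param pathways data.frame with columns `pathway_id`, `name`, `level2`
#'   and optionally `K` (background count). When `K` is absent it is
#'   computed from `taxa`.
#' @param n_bg Background size (number of annotated units). Defaults to
#'   the number of annotated taxa when `K` is computed from `taxa`.
#' @param phylum Optional named character vector: taxon id -> phylum.
#' @return An object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(taxa, pathways, n_bg = NULL, phylum = NULL) {
  stopifnot(is.list(taxa), !is.null(names(taxa)), is.data.frame(pathways))
  if (!all(c("pathway_id", "name", "level2") %in% colnames(pathways)))
    stop("pathways needs columns pathway_id, name, level2")
  if (anyDuplicated(pathways$pathway_id))
    stop("duplicated pathway id: ",
         paste(unique(pathways$pathway_id[duplicated(pathways$pathway_id)]),
               collapse = ", "))
  used <- unique(unlist(taxa, use.names = FALSE))
  unknown <- setdiff(used, pathways$pathway_id)
  if (length(unknown) > 0L)
    stop("annotation references undeclared pathway(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(pathways$K)) {
    counts <- table(factor(unlist(lapply(taxa, unique), use.names = FALSE),
                           levels = pathways$pathway_id))
    pathways$K <- as.integer(counts)
    if (is.null(n_bg)) n_bg <- length(taxa)
  } else if (is.null(n_bg)) {
    stop("n_bg must be given when pathway background counts K are supplied")
  }
  n_bg <- as.integer(n_bg)
  if (is.na(n_bg) || n_bg <= 0L) stop("n_bg must be a positive integer")
  if (any(pathways$K > n_bg))
    stop("background count K exceeds n_bg for pathway(s): ",
         paste(pathways$pathway_id[pathways$K > n_bg], collapse = ", "))
  structure(list(taxa = lapply(taxa, unique), pathways = pathways,
                 n_bg = n_bg, phylum = phylum),
            class = "annotation_catalog")
}

#' Read an annotation catalog from TSV files
#'
#' `annotations.tsv` has one row per (taxon, pathway) pair with columns
#' `taxon`, `pathway_id` and an optional `phylum` column supporting
#' genus-to-phylum reporting. `pathways.tsv` declares each pathway
#' (`pathway_id`, `name`, `level2`) with an optional background count
#' column `K`.
#'
#' @param annotations_path Path to the taxon-pathway table.
#' @param pathways_path Path to the pathway description table.
#' @param n_bg Background size; required when `pathways.tsv` carries `K`,
#'   otherwise defaults to the number of annotated taxa.
#' @return An [annotation_catalog()] object.
#' @export
read_annotations <- function(annotations_path, pathways_path, n_bg = NULL) {
  ann <- utils::read.table(annotations_path, sep = "\t", header = TRUE,
                           quote = "", comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("taxon", "pathway_id") %in% colnames(ann)))
    stop("annotations need columns taxon, pathway_id")
  pw <- utils::read.table(pathways_path, sep = "\t", header = TRUE,
                          quote = "", comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  taxa <- split(ann$pathway_id, ann$taxon)
  phylum <- NULL
  if ("phylum" %in% colnames(ann)) {
    first <- !duplicated(ann$taxon)
    phylum <- stats::setNames(ann$phylum[first], ann$taxon[first])
  }
  annotation_catalog(taxa, pw, n_bg = n_bg, phylum = phylum)
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("Annotation catalog:", length(x$taxa), "annotated taxa,",
      nrow(x$pathways), "pathways, background size", x$n_bg, "\n")
  invisible(x)
}
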