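#' Expression study container
#'
#' Bundles a log2 probe-by-sample expression matrix with its probe-to-gene
#' annotation and per-sample group and batch labels. This is the object every
#' stage of the panel-discovery workflow consumes and returns.
#'
#' @param matrix Numeric matrix, probes in rows, samples in columns, log2
#'   intensity units. Row and column names are taken from `probe_ids` /
#'   `sample_ids` when supplied, otherwise from `dimnames(matrix)`.
#' @param gene_symbols Character vector, one gene symbol per probe. Several
#'   probes may interrogate the same gene (many-to-one).
#' @param group Factor or character, one histopathological group per sample
#'   (e.g. DA, AA, GBM).
#' @param batch Factor or character, one cohort-of-origin label per sample.
#' @param probe_ids,sample_ids Optional explicit identifiers; must be unique.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `matrix`, `probe_ids`, `gene_symbols`, `sample_ids`, `group`, `batch`.
#' @export
expression_study <- function(matrix, gene_symbols, group, batch,
                             probe_ids = rownames(matrix),
                             sample_ids = colnames(matrix)) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix (probes x samples)")
  }
  if (is.null(probe_ids)) probe_ids <- paste0("probe_", seq_len(nrow(matrix)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(matrix)))
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(matrix)) {
    stop("length(probe_ids) must equal nrow(matrix)")
  }
  if (length(sample_ids) != ncol(matrix)) {
    stop("length(sample_ids) must equal ncol(matrix)")
  }
  if (anyDuplicated(probe_ids)) stop("duplicate probe ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(gene_symbols) != nrow(matrix)) {
    stop("one gene symbol per probe is required")
  }
  if (length(group) != ncol(matrix) || length(batch) != ncol(matrix)) {
    stop("every sample needs exactly one group and one batch label")
  }
  if (anyNA(matrix)) stop("expression matrix contains missing values")
  if (anyNA(group) || anyNA(batch)) stop("missing group or batch label")
  dimnames(matrix) <- list(probe_ids, sample_ids)
  structure(
    list(
      matrix = matrix,
      probe_ids = probe_ids,
      gene_symbols = as.character(gene_symbols),
      sample_ids = sample_ids,
      group = factor(group),
      batch = factor(batch)
    ),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "expression_study: %d probes (%d genes) x %d samples\n",
    nrow(x$matrix), length(unique(x$gene_symbols)), ncol(x$matrix)
  ))
  cat("groups: ", paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                        collapse = ", "), "\n", sep = "")
  cat("batches:", paste(levels(x$batch), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$matrix)

#' Read an expression study from three TSV files
#'
#' The exchange format is plain TSV: a matrix file (header row of sample ids,
#' first column `probe_id`), an annotation file (`probe_id`, `gene_symbol`)
#' and a metadata file (`sample_id`, `group`, `batch`). Probes lacking a gene
#' symbol and Affymetrix control probes (ids prefixed `AFFX`) are dropped
#' with a message; column (sample) order of the matrix file is preserved.
#'
#' @param matrix_path,annotation_path,metadata_path Paths to the three files.
#' @return A validated [expression_study()].
#' @export
read_study <- function(matrix_path, annotation_path, metadata_path) {
  for (p in c(matrix_path, annotation_path, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE,
                              colClasses = "character")
  if (ncol(mat_df) < 2L) stop("matrix file needs a probe_id column and >=1 sample")
  probe_ids <- mat_df[[1L]]
  sample_ids <- colnames(mat_df)[-1L]
  if (anyDuplicated(probe_ids)) stop("duplicate probe ids in matrix file")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in matrix file")
  vals <- suppressWarnings(vapply(mat_df[-1L], as.numeric,
                                  numeric(nrow(mat_df))))
  vals <- matrix(vals, nrow = nrow(mat_df),
                 dimnames = list(probe_ids, sample_ids))
  if (anyNA(vals)) stop("non-numeric or missing cell in matrix file")

  ann <- utils::read.delim(annotation_path, colClasses = "character")
  if (!all(c("probe_id", "gene_symbol") %in% colnames(ann))) {
    stop("annotation file must have columns probe_id, gene_symbol")
  }
  meta <- utils::read.delim(metadata_path, colClasses = "character")
  if (!all(c("sample_id", "group", "batch") %in% colnames(meta))) {
    stop("metadata file must have columns sample_id, group, batch")
  }
  missing_samples <- setdiff(sample_ids, meta$sample_id)
  if (length(missing_samples)) {
    stop("samples absent from metadata: ", paste(missing_samples, collapse = ", "))
  }
  meta <- meta[match(sample_ids, meta$sample_id), ]

  gene <- ann$gene_symbol[match(probe_ids, ann$probe_id)]
  drop <- is.na(gene) | gene == "" | startsWith(probe_ids, "AFFX")
  if (any(drop)) {
    message(sum(drop), " probe(s) dropped: no gene symbol or control probe")
  }
  expression_study(
    matrix = vals[!drop, , drop = FALSE],
    gene_symbols = gene[!drop],
    group = meta$group,
    batch = meta$batch,
    probe_ids = probe_ids[!drop],
    sample_ids = sample_ids
  )
}

#' Write an expression study to the three-file TSV exchange format
#'
#' @param study An [expression_study()].
#' @param matrix_path,annotation_path,metadata_path Output paths.
#' @return `study`, invisibly.
#' @export
write_study <- function(study, matrix_path, annotation_path, metadata_path) {
  stopifnot(inherits(study, "expression_study"))
  mat_df <- data.frame(probe_id = study$probe_ids, study$matrix,
                       check.names = FALSE)
  utils::write.table(mat_df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(probe_id = study$probe_ids, gene_symbol = study$gene_symbols),
    annotation_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(sample_id = study$sample_ids,
               group = as.character(study$group),
               batch = as.character(study$batch)),
    metadata_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(study)
}

#' Row-subset a study to a requested, ordered set of probes
#'
#' @param study An [expression_study()].
#' @param probe_ids Probe identifiers to keep, in the requested order.
#' @return A new study with only those probes; sample metadata untouched.
#' @export
subset_probes <- function(study, probe_ids) {
  stopifnot(inherits(study, "expression_study"))
  idx <- match(probe_ids, study$probe_ids)
  if (anyNA(idx)) {
    stop("unknown probe id(s): ",
         paste(utils::head(probe_ids[is.na(idx)], 5L), collapse = ", "))
  }
  expression_study(
    matrix = study$matrix[idx, , drop = FALSE],
    gene_symbols = study$gene_symbols[idx],
    group = study$group,
    batch = study$batch,
    probe_ids = study$probe_ids[idx],
    sample_ids = study$sample_ids
  )
}

#' Column-subset a study to a set of samples
#'
#' @param study An [expression_study()].
#' @param sample_ids Sample identifiers to keep, in the requested order.
#' @return A new study with only those samples.
#' @export
subset_samples <- function(study, sample_ids) {
  stopifnot(inherits(study, "expression_study"))
  idx <- match(sample_ids, study$sample_ids)
  if (anyNA(idx)) stop("unknown sample id(s)")
  expression_study(
    matrix = study$matrix[, idx, drop = FALSE],
    gene_symbols = study$gene_symbols,
    group = as.character(study$group)[idx],
    batch = as.character(study$batch)[idx],
    probe_ids = study$probe_ids,
    sample_ids = study$sample_ids[idx]
  )
}
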