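#' Gene panel container
#'
#' An ordered set of unique discriminatory genes, the probes contributing to
#' each, and the direction of differential expression (which side of which
#' comparison the gene is overexpressed in).
#'
#' @param genes Character vector of unique gene symbols.
#' @param probes List of character vectors, the contributing probe ids per
#'   gene (same length as `genes`).
#' @param direction Character vector per gene, e.g. `"up_in_GBM"`.
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(genes, probes, direction) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("panel genes must be unique")
  if (length(probes) != length(genes) || length(direction) != length(genes)) {
    stop("probes and direction must align with genes")
  }
  all_probes <- unlist(probes, use.names = FALSE)
  if (anyDuplicated(all_probes)) {
    stop("every probe must map to exactly one panel gene")
  }
  structure(
    list(genes = genes, probes = probes, direction = as.character(direction)),
    class = "gene_panel"
  )
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel: %d genes, %d probes\n",
              length(x$genes), length(unlist(x$probes))))
  invisible(x)
}

#' @export
length.gene_panel <- function(x) length(x$genes)

#' Write a gene panel as TSV
#'
#' Columns `gene`, `probes` (comma-joined) and `direction`; re-reading with
#' [read_panel()] reproduces the panel exactly.
#'
#' @param panel A non-empty [gene_panel()].
#' @param path Output path.
#' @return `panel`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  if (length(panel$genes) == 0L) stop("refusing to write an empty panel")
  df <- data.frame(
    gene = panel$genes,
    probes = vapply(panel$probes, paste, character(1L), collapse = ","),
    direction = panel$direction
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(panel)
}

#' Read a gene panel written by [write_panel()]
#'
#' @param path Path to a panel TSV.
#' @return A [gene_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character")
  gene_panel(
    genes = df$gene,
    probes = strsplit(df$probes, ",", fixed = TRUE),
    direction = df$direction
  )
}
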