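#' Non-redundant gene catalog with per-sample read counts
#'
#' Bundles the catalog gene descriptions (id, length) with the matrix of
#' per-sample mapped read counts.  Counts are normally non-negative
#' integers from an external read counter; real-valued expected counts are
#' accepted too so that the synthetic generator's noise-free validation
#' mode (exact expected multinomial counts) can flow through the same
#' code path.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param length_bp Integer vector of gene lengths (>= 1).
#' @param counts Numeric matrix of read counts, genes x samples, with
#'   sample colnames; rows must align with `gene_id`.
#' @return A `gene_catalog`: list with tibble `$genes` (gene_id,
#'   length_bp) and matrix `$counts` (rownames = gene ids).
#' @export
gene_catalog <- function(gene_id, length_bp, counts) {
  gene_id <- as.character(gene_id)
  length_bp <- as.numeric(length_bp)
  if (anyDuplicated(gene_id)) {
    stop_sodamag("duplicate gene ids: ",
                 paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "),
                 class = "sodamag_validation_error")
  }
  if (any(!is.finite(length_bp)) || any(length_bp < 1)) {
    stop_sodamag("gene lengths must be >= 1 bp",
                 class = "sodamag_validation_error")
  }
  if (!is.matrix(counts) || nrow(counts) != length(gene_id)) {
    stop_sodamag("counts must be a genes x samples matrix aligned with ",
                 "gene_id", class = "sodamag_validation_error")
  }
  if (is.null(colnames(counts))) {
    stop_sodamag("counts must have sample colnames",
                 class = "sodamag_validation_error")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_sodamag("read counts must be finite and non-negative",
                 class = "sodamag_validation_error")
  }
  rownames(counts) <- gene_id
  structure(list(
    genes = tibble::tibble(gene_id = gene_id, length_bp = length_bp),
    counts = counts
  ), class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene catalog: %d genes x %d samples\n",
              nrow(x$genes), ncol(x$counts)))
  invisible(x)
}

#' Filter a gene catalog on length and read support
#'
#' Removes genes shorter than `min_length_bp` (short open reading frames
#' are enriched for pseudogenes) and genes with fewer than
#' `min_total_reads` reads summed across all samples (singleton support is
#' likely misassembly).  Both removals are strict: a gene of exactly
#' `min_length_bp` with exactly `min_total_reads` total reads is retained.
#' Gene order is preserved.
#'
#' @param catalog A [gene_catalog()].
#' @param min_length_bp Minimum retained gene length (default 100 bp).
#' @param min_total_reads Minimum retained total read support (default 2).
#' @return The filtered `gene_catalog` (possibly with zero genes).
#' @export
filter_genes <- function(catalog, min_length_bp = 100,
                         min_total_reads = 2) {
  assert_scalar_number(min_length_bp, "min_length_bp")
  assert_scalar_number(min_total_reads, "min_total_reads")
  keep <- catalog$genes$length_bp >= min_length_bp &
    rowSums(catalog$counts) >= min_total_reads
  gene_catalog(catalog$genes$gene_id[keep],
               catalog$genes$length_bp[keep],
               catalog$counts[keep, , drop = FALSE])
}

#' Length-normalised relative gene abundance
#'
#' Per sample, each gene's mapped read count is divided by its length and
#' the resulting length-normalised counts are renormalised to per-sample
#' fractions: `a[g, s] = (r[g, s] / L[g]) / sum_g'(r[g', s] / L[g'])`.
#' Any fixed per-sample sequencing-depth factor cancels, so the profile is
#' invariant to uniform read-depth scaling.  All-zero samples stay
#' all-zero.
#'
#' @param catalog A filtered [gene_catalog()].
#' @return An [abundance_matrix()] (genes x samples, normalization
#'   `"fraction"`).
#' @export
gene_abundance <- function(catalog) {
  norm <- catalog$counts / catalog$genes$length_bp
  cs <- colSums(norm)
  nz <- cs > 0
  norm[, nz] <- sweep(norm[, nz, drop = FALSE], 2, cs[nz], "/")
  abundance_matrix(norm, "fraction")
}

#' Write / read a gene catalog as TSV
#'
#' Columns: `gene_id`, `length_bp`, then one column per sample.
#'
#' @param catalog A [gene_catalog()].
#' @param path File path.
#' @return `write_gene_counts()` returns `path` invisibly;
#'   `read_gene_counts()` the reconstructed catalog.
#' @export
write_gene_counts <- function(catalog, path) {
  df <- data.frame(gene_id = catalog$genes$gene_id,
                   length_bp = catalog$genes$length_bp,
                   catalog$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_gene_counts
#' @export
read_gene_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(df))) {
    stop_sodamag("gene count table needs gene_id and length_bp columns",
                 class = "sodamag_format_error")
  }
  counts <- as.matrix(df[, setdiff(names(df), c("gene_id", "length_bp")),
                         drop = FALSE])
  gene_catalog(df$gene_id, df$length_bp, counts)
}
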