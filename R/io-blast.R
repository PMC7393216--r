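#' Read / write tabular homology hit tables
#'
#' Parses the 12-column tab-separated homology search dialect (BLAST
#' `-outfmt 6` / DIAMOND default: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore), with an optional
#' 13th column carrying the subject taxid (DIAMOND taxonmap-style output).
#' The dialect is auto-detected from the column count; mixed files are
#' rejected.  Malformed lines are never dropped silently: parsing stops
#' with an error naming each offending line number.
#'
#' @param path Path to a tab-separated hit table.
#' @return A tibble with columns `query_id`, `subject_id`, `pident`,
#'   `align_len`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`, `taxid` (`NA` when the file has no
#'   taxid column).  An empty file yields a zero-row tibble.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) {
    stop_sodamag("no such file: ", path, class = "sodamag_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (!all(ncols %in% c(12L, 13L))) {
    bad <- which(!ncols %in% c(12L, 13L))
    stop_sodamag("hit table lines with wrong column count (need 12 or ",
                 "13): line(s) ", paste(head(bad, 10L), collapse = ", "),
                 class = "sodamag_format_error")
  }
  if (length(unique(ncols)) != 1L) {
    stop_sodamag("hit table mixes 12- and 13-column lines",
                 class = "sodamag_format_error")
  }
  has_taxid <- ncols[[1L]] == 13L
  mat <- do.call(rbind, fields)
  num <- function(j, name, integer = FALSE) {
    v <- suppressWarnings(as.numeric(mat[, j]))
    if (anyNA(v)) {
      bad <- which(is.na(v))
      stop_sodamag("non-numeric ", name, " at line(s) ",
                   paste(head(bad, 10L), collapse = ", "),
                   class = "sodamag_format_error")
    }
    if (integer) as.integer(v) else v
  }
  hits <- tibble::tibble(
    query_id   = mat[, 1L],
    subject_id = mat[, 2L],
    pident     = num(3L, "percent identity"),
    align_len  = num(4L, "alignment length", integer = TRUE),
    mismatch   = num(5L, "mismatch count", integer = TRUE),
    gapopen    = num(6L, "gap open count", integer = TRUE),
    qstart     = num(7L, "qstart", integer = TRUE),
    qend       = num(8L, "qend", integer = TRUE),
    sstart     = num(9L, "sstart", integer = TRUE),
    send       = num(10L, "send", integer = TRUE),
    evalue     = num(11L, "evalue"),
    bitscore   = num(12L, "bitscore"),
    taxid      = if (has_taxid) num(13L, "taxid", integer = TRUE)
                 else NA_integer_
  )
  if (any(hits$bitscore < 0) || any(hits$evalue < 0)) {
    stop_sodamag("bitscore and evalue must be non-negative",
                 class = "sodamag_format_error")
  }
  hits
}

#' @rdname read_blast_tab
#' @param hits A hit tibble as returned by [read_blast_tab()].
#' @return `write_blast_tab()` returns `path` invisibly.  The taxid column
#'   is written (13-column dialect) whenever any taxid is non-missing.
#' @export
write_blast_tab <- function(hits, path) {
  hits <- as_tibble(hits)
  with_taxid <- any(!is.na(hits$taxid))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(hits) > 0) {
    lines <- sprintf(
      "%s\t%s\t%.17g\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.17g\t%.17g",
      hits$query_id, hits$subject_id, hits$pident, hits$align_len,
      hits$mismatch, hits$gapopen, hits$qstart, hits$qend, hits$sstart,
      hits$send, hits$evalue, hits$bitscore)
    if (with_taxid) lines <- paste(lines, hits$taxid, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

empty_hits <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(), pident = numeric(),
    align_len = integer(), mismatch = integer(), gapopen = integer(),
    qstart = integer(), qend = integer(), sstart = integer(),
    send = integer(), evalue = numeric(), bitscore = numeric(),
    taxid = integer())
}
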