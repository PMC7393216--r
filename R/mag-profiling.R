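#' Set of metagenome-assembled genomes (MAGs)
#'
#' Bundles the contig-to-MAG memberships with contig lengths, per-sample
#' contig coverages, and per-MAG quality estimates (completeness and
#' contamination, as from a marker-gene QC tool).
#'
#' @param contigs Tibble/data.frame with columns `contig_id`, `mag_id`,
#'   `length_bp` (contig ids unique, lengths >= 1).
#' @param coverage Numeric matrix of per-sample mean coverage, contigs x
#'   samples, rownames = contig ids, colnames = sample ids.
#' @param quality Tibble/data.frame with columns `mag_id`,
#'   `completeness` (0-100), `contamination` (>= 0) and optionally
#'   `taxonomy_label`.
#' @return A `mag_set` (list with `$contigs`, `$coverage`, `$quality`).
#' @export
mag_set <- function(contigs, coverage, quality) {
  contigs <- as_tibble(contigs)
  quality <- as_tibble(quality)
  need <- c("contig_id", "mag_id", "length_bp")
  if (!all(need %in% names(contigs))) {
    stop_sodamag("contigs needs columns: ", paste(need, collapse = ", "),
                 class = "sodamag_validation_error")
  }
  if (anyDuplicated(contigs$contig_id)) {
    stop_sodamag("duplicate contig ids",
                 class = "sodamag_validation_error")
  }
  if (any(contigs$length_bp < 1)) {
    stop_sodamag("contig lengths must be >= 1",
                 class = "sodamag_validation_error")
  }
  if (!is.matrix(coverage) || nrow(coverage) != nrow(contigs) ||
      (nrow(coverage) > 0 &&
         (is.null(rownames(coverage)) ||
            !setequal(rownames(coverage), contigs$contig_id)))) {
    stop_sodamag("coverage must be a matrix with rownames matching ",
                 "contig ids", class = "sodamag_validation_error")
  }
  if (any(coverage < 0)) {
    stop_sodamag("coverages must be non-negative",
                 class = "sodamag_validation_error")
  }
  if (!all(c("mag_id", "completeness", "contamination") %in%
           names(quality))) {
    stop_sodamag("quality needs mag_id, completeness, contamination",
                 class = "sodamag_validation_error")
  }
  if (any(quality$completeness < 0 | quality$completeness > 100) ||
      any(quality$contamination < 0)) {
    stop_sodamag("completeness must lie in [0, 100] and contamination ",
                 "must be >= 0", class = "sodamag_validation_error")
  }
  if (!all(contigs$mag_id %in% quality$mag_id)) {
    stop_sodamag("every contig's mag_id must appear in quality",
                 class = "sodamag_validation_error")
  }
  coverage <- coverage[contigs$contig_id, , drop = FALSE]
  structure(list(contigs = contigs, coverage = coverage,
                 quality = quality), class = "mag_set")
}

#' @export
print.mag_set <- function(x, ...) {
  cat(sprintf("MAG set: %d MAGs, %d contigs, %d samples\n",
              nrow(x$quality), nrow(x$contigs), ncol(x$coverage)))
  invisible(x)
}

#' Subset a MAG set to selected MAGs
#'
#' @param mags A [mag_set()].
#' @param mag_ids Character vector of MAG ids to keep.
#' @return The subsetted `mag_set`.
#' @export
subset_mags <- function(mags, mag_ids) {
  keep <- mags$contigs$mag_id %in% mag_ids
  mag_set(mags$contigs[keep, , drop = FALSE],
          mags$coverage[mags$contigs$contig_id[keep], , drop = FALSE],
          mags$quality[mags$quality$mag_id %in% mag_ids, , drop = FALSE])
}

#' Quality-filter MAGs on completeness and contamination
#'
#' Keeps MAGs with completeness strictly above `min_completeness` and
#' contamination strictly below `max_contamination` (both thresholds are
#' strict, so a MAG at completeness exactly 50 is rejected).  The
#' near-complete subset uses the stricter convention of completeness > 90
#' and contamination < 5.
#'
#' @param mags A [mag_set()].
#' @param min_completeness Lower completeness bound (default 50, strict).
#' @param max_contamination Upper contamination bound (default 10, strict).
#' @return List with `mag_set` elements `passed` and `near_complete`
#'   (the latter always a subset of the former under the defaults).
#' @export
qc_filter_mags <- function(mags, min_completeness = 50,
                           max_contamination = 10) {
  q <- mags$quality
  pass <- q$mag_id[q$completeness > min_completeness &
                     q$contamination < max_contamination]
  near <- q$mag_id[q$completeness > 90 & q$contamination < 5]
  list(passed = subset_mags(mags, pass),
       near_complete = subset_mags(mags, intersect(near, pass)))
}

#' Coverage-based MAG abundance
#'
#' Per MAG and sample, the abundance is the sum of each contig's coverage
#' multiplied by its length, divided by the genome size (sum of binned
#' contig lengths): the length-weighted mean contig coverage
#' `A[m, s] = sum_i(c[i, s] * l[i]) / G[m]`.
#'
#' @param mags A QC-passed [mag_set()].
#' @return An [abundance_matrix()] (MAGs x samples, normalization `"raw"`).
#' @export
mag_abundance <- function(mags) {
  w <- mags$coverage * mags$contigs$length_bp
  per_mag <- rowsum(w, group = mags$contigs$mag_id)
  sizes <- rowsum(mags$contigs$length_bp, group = mags$contigs$mag_id)
  if (any(sizes < 1)) {
    stop_sodamag("MAG with zero total length",
                 class = "sodamag_validation_error")
  }
  abundance_matrix(per_mag / as.vector(sizes[rownames(per_mag), ]),
                   "raw")
}

#' Scale per-sample abundances to 100 and flag abundant MAGs
#'
#' Within each sample, abundances are divided by the sample maximum and
#' multiplied by 100 (the top MAG always scores 100); a MAG is called
#' abundant in a sample when its scaled abundance is strictly greater
#' than `threshold`.  A MAG at exactly the threshold is not abundant;
#' ties for the sample maximum all score 100 and are all flagged.
#' Because only within-sample ratios enter, the calls are invariant to
#' rescaling any sample's raw column by a positive constant.
#'
#' @param abund A raw-scale [abundance_matrix()] (MAGs x samples).
#' @param threshold Scaled-abundance cutoff (default 50, strict `>`).
#' @return A tibble with columns `mag_id`, `sample_id`,
#'   `relative_abundance` (0-100) and `is_abundant`.  Samples whose
#'   abundances are all zero produce no calls (with a warning).
#' @export
scale_and_flag_abundant <- function(abund, threshold = 50) {
  assert_scalar_number(threshold, "threshold")
  v <- as_plain_matrix(abund)
  mx <- apply(v, 2, max)
  dead <- mx <= 0
  if (any(dead)) {
    warning("sample(s) with all-zero abundance skipped: ",
            paste(colnames(v)[dead], collapse = ", "), call. = FALSE)
    v <- v[, !dead, drop = FALSE]
    mx <- mx[!dead]
  }
  scaled <- sweep(v, 2, mx / 100, "/")
  tibble::tibble(
    mag_id = rep(rownames(scaled), times = ncol(scaled)),
    sample_id = rep(colnames(scaled), each = nrow(scaled)),
    relative_abundance = as.vector(scaled),
    is_abundant = as.vector(scaled) > threshold)
}

#' Fraction of total coverage captured by the abundant MAGs
#'
#' For each sample, the summed raw abundance of the union of MAGs called
#' abundant in at least one sample, divided by the summed raw abundance
#' of all MAGs.
#'
#' @param abund Raw [abundance_matrix()] (MAGs x samples).
#' @param calls Optional tibble from [scale_and_flag_abundant()]; used to
#'   derive `abundant_union` when that is not given.
#' @param abundant_union Optional character vector of MAG ids abundant in
#'   at least one sample.
#' @return Named numeric vector of per-sample fractions in \[0, 1\].
#' @export
abundant_coverage_share <- function(abund, calls = NULL,
                                    abundant_union = NULL) {
  if (is.null(abundant_union)) {
    if (is.null(calls)) {
      stop_sodamag("supply calls or abundant_union",
                   class = "sodamag_parameter_error")
    }
    abundant_union <- unique(calls$mag_id[calls$is_abundant])
  }
  v <- as_plain_matrix(abund)
  total <- colSums(v)
  part <- colSums(v[rownames(v) %in% abundant_union, , drop = FALSE])
  share <- ifelse(total > 0, part / total, NA_real_)
  setNames(share, colnames(v))
}

#' Read / write MAG coverage and quality tables
#'
#' The coverage table is entity-major TSV with columns `contig_id`,
#' `mag_id`, `length_bp` and one coverage column per sample; the quality
#' table has columns `mag_id`, `completeness`, `contamination` and
#' optional `taxonomy_label`.
#'
#' @param coverage_path,quality_path File paths.
#' @return `read_mag_set()` returns a [mag_set()].
#' @export
read_mag_set <- function(coverage_path, quality_path) {
  cov <- utils::read.delim(coverage_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("contig_id", "mag_id", "length_bp")
  if (!all(need %in% names(cov))) {
    stop_sodamag("coverage table needs columns: ",
                 paste(need, collapse = ", "),
                 class = "sodamag_format_error")
  }
  m <- as.matrix(cov[, setdiff(names(cov), need), drop = FALSE])
  rownames(m) <- cov$contig_id
  quality <- utils::read.delim(quality_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
  mag_set(cov[, need], m, quality)
}

#' @rdname read_mag_set
#' @param mags A [mag_set()].
#' @export
write_mag_set <- function(mags, coverage_path, quality_path) {
  df <- data.frame(mags$contigs, mags$coverage, check.names = FALSE)
  utils::write.table(df, coverage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(mags$quality, quality_path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(c(coverage_path, quality_path))
}
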