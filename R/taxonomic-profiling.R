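#' Retain top-scoring homology hits per query
#'
#' Applies the e-value gate, then keeps, for each query, every hit whose
#' bitscore is within `top_percent` percent of that query's best bitscore
#' (inclusive boundary, i.e. `bitscore >= (1 - top_percent/100) * best`,
#' matching DIAMOND's `--top` semantics).  Ties for the best bitscore are
#' all retained, so the result does not depend on input ordering.
#'
#' @param hits A hit tibble (see [read_blast_tab()]).
#' @param top_percent Width of the retained bitscore band (default 10).
#' @param max_evalue Maximum e-value (default 1e-5).
#' @return The filtered hit tibble, ordered by query then decreasing
#'   bitscore.  Queries whose hits all fail the e-value gate disappear
#'   (they become unassigned downstream).
#' @export
retain_top_hits <- function(hits, top_percent = 10, max_evalue = 1e-5) {
  assert_scalar_number(top_percent, "top_percent")
  assert_scalar_number(max_evalue, "max_evalue")
  if (top_percent < 0) {
    stop_sodamag("top_percent must be non-negative",
                 class = "sodamag_parameter_error")
  }
  hits <- as_tibble(hits)
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  best <- tapply(hits$bitscore, hits$query_id, max)
  cutoff <- (1 - top_percent / 100) * best[hits$query_id]
  hits <- hits[hits$bitscore >= cutoff, , drop = FALSE]
  hits[order(hits$query_id, -hits$bitscore), , drop = FALSE]
}

#' LCA taxonomy assignment for gene queries
#'
#' Assigns each query gene the lowest common ancestor (LCA) of the taxids
#' of its retained hits: the deepest taxonomy node lying on the root path
#' of every hit taxid.  Hits whose taxid is missing or not resolvable
#' against the tree are dropped with a single warning giving the count;
#' queries left with zero usable hits are reported unassigned.
#'
#' @param hits A hit tibble, already filtered by [retain_top_hits()].
#' @param tree A [taxonomy_tree()].
#' @param queries Optional character vector of all query ids of interest;
#'   queries absent from `hits` are reported unassigned.  Defaults to the
#'   queries present in `hits`.
#' @return A tibble with columns `gene_id`, `taxid` (`NA` = unassigned)
#'   and `n_hits_used`.
#' @export
lca_assign <- function(hits, tree, queries = NULL) {
  hits <- as_tibble(hits)
  resolvable <- !is.na(hits$taxid) &
    as.character(hits$taxid) %in% names(tree$parent)
  n_dropped <- sum(!resolvable)
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d hit(s) with unresolvable taxids",
                    n_dropped), call. = FALSE)
    hits <- hits[resolvable, , drop = FALSE]
  }
  if (is.null(queries)) queries <- unique(hits$query_id)
  by_query <- split(hits$taxid, hits$query_id)
  taxid <- rep(NA_integer_, length(queries))
  n_used <- integer(length(queries))
  for (i in seq_along(queries)) {
    ids <- by_query[[queries[[i]]]]
    if (!is.null(ids) && length(ids) > 0L) {
      taxid[[i]] <- tax_lca(tree, ids)
      n_used[[i]] <- length(ids)
    }
  }
  tibble::tibble(gene_id = as.character(queries), taxid = taxid,
                 n_hits_used = n_used)
}

#' Aggregate gene abundances into a rank-level taxon profile
#'
#' Sums each gene's relative abundance into its assignment's ancestor at
#' the requested rank (the mOTU-style aggregation: a taxon's abundance is
#' the sum of the abundances of all genes assigned to it).  Genes that
#' are unassigned, or whose LCA sits above the requested rank, are pooled
#' under `"unclassified"` rather than redistributed, so column sums are
#' conserved exactly.  Taxa that never reach `min_relative` in any sample
#' are relabelled `"other"` (relabelling only; no mass moves).
#'
#' @param gene_abund Gene-level [abundance_matrix()] (`fraction`).
#' @param assignments Tibble from [lca_assign()].
#' @param tree A [taxonomy_tree()].
#' @param rank Target rank name; must exist in the tree's rank vocabulary.
#' @param min_relative Display-retention threshold as a fraction (default
#'   0.001, i.e. 0.1%); a taxon is kept under its own name if it exceeds
#'   the threshold in at least one sample.
#' @return An [abundance_matrix()] (taxa x samples, `fraction`), entities
#'   named by taxon scientific name plus `"other"` / `"unclassified"`.
#' @export
aggregate_taxon_profile <- function(gene_abund, assignments, tree, rank,
                                    min_relative = 0.001) {
  if (!rank %in% tax_ranks(tree)) {
    stop_sodamag("unknown rank: ", rank,
                 class = "sodamag_parameter_error")
  }
  assert_scalar_number(min_relative, "min_relative")
  idx <- match(rownames(gene_abund), assignments$gene_id)
  gene_tax <- assignments$taxid[idx]
  label <- rep("unclassified", nrow(gene_abund))
  has_tax <- !is.na(gene_tax)
  anc <- vapply(gene_tax[has_tax], function(id) {
    tax_ancestor_at_rank(tree, id, rank)
  }, integer(1))
  named <- !is.na(anc)
  label[has_tax][named] <- tree$name[as.character(anc[named])]
  sums <- rowsum(as_plain_matrix(gene_abund), group = label)
  taxa <- setdiff(rownames(sums), "unclassified")
  low <- taxa[apply(sums[taxa, , drop = FALSE] < min_relative, 1, all)]
  if (length(low) > 0L) {
    label2 <- rownames(sums)
    label2[label2 %in% low] <- "other"
    sums <- rowsum(sums, group = label2)
  }
  ord <- setdiff(rownames(sums), c("other", "unclassified"))
  ord <- ord[order(-rowSums(sums[ord, , drop = FALSE]))]
  ord <- c(ord, intersect(c("other", "unclassified"), rownames(sums)))
  abundance_matrix(sums[ord, , drop = FALSE],
                   normalization_state(gene_abund))
}

#' Shannon diversity per sample
#'
#' Shannon index `H = -sum(p * ln p)` over entities with `p > 0`, computed
#' with [vegan::diversity()] (natural log, the ecology convention).
#' Raw-scale matrices are normalised to fractions internally; all-zero
#' samples have no defined diversity and are reported `NA`.
#'
#' @param profile An [abundance_matrix()] (fraction or raw).
#' @return A tibble with columns `sample_id` and `shannon`.
#' @export
shannon_index <- function(profile) {
  v <- as_plain_matrix(profile)
  h <- vegan::diversity(t(v), index = "shannon")
  h[colSums(v) == 0] <- NA_real_
  tibble::tibble(sample_id = colnames(v), shannon = unname(h))
}
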