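#' Pairwise Pearson correlations between entity abundance profiles
#'
#' For every unordered pair of entities (rows), the Pearson correlation
#' `r` across samples and a two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom
#' (`n` = sample count, identical for all pairs).  Correlations are
#' computed on the raw abundance scale.  Entities with zero variance have
#' no defined correlation and are skipped with a warning.
#'
#' @param abund An [abundance_matrix()] (entities x samples), `n >= 3`.
#' @return A tibble with columns `mag_a`, `mag_b`, `r`, `p`, `n`, one row
#'   per unordered pair.
#' @export
pairwise_correlation <- function(abund) {
  v <- as_plain_matrix(abund)
  n <- ncol(v)
  if (n < 3L) {
    stop_sodamag("need at least 3 samples to correlate, have ", n,
                 class = "sodamag_parameter_error")
  }
  sds <- apply(v, 1, stats::sd)
  flat <- sds == 0 | is.na(sds)
  if (any(flat)) {
    warning("skipping zero-variance entities: ",
            paste(rownames(v)[flat], collapse = ", "), call. = FALSE)
    v <- v[!flat, , drop = FALSE]
  }
  if (nrow(v) < 2L) {
    return(tibble::tibble(mag_a = character(), mag_b = character(),
                          r = numeric(), p = numeric(), n = integer()))
  }
  r <- stats::cor(t(v))
  r <- pmin(pmax(r, -1), 1)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[idx]
  tstat <- rv * sqrt((n - 2) / pmax(1 - rv^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rv) == 1] <- 0
  tibble::tibble(
    mag_a = rownames(v)[idx[, 1L]],
    mag_b = rownames(v)[idx[, 2L]],
    r = rv, p = p, n = n)
}

#' Threshold correlations into a co-occurrence network
#'
#' Keeps pairs satisfying both gates strictly: `r > min_r` and
#' `p < max_p` (a pair at exactly `r = min_r` is excluded).  The result
#' is an undirected simple edge list without self-loops.
#'
#' @param correlations Tibble from [pairwise_correlation()].
#' @param min_r Correlation threshold (default 0.9, strict `>`).
#' @param max_p p-value threshold (default 0.01, strict `<`); no multiple
#'   testing adjustment is applied by default.
#' @param p_adjust_method Optional [stats::p.adjust()] method applied to
#'   the p-values before thresholding (default `"none"`).
#' @return The edge tibble (`mag_a`, `mag_b`, `r`, `p`, `n`).
#' @export
build_network <- function(correlations, min_r = 0.9, max_p = 0.01,
                          p_adjust_method = "none") {
  assert_scalar_number(min_r, "min_r")
  assert_scalar_number(max_p, "max_p")
  cors <- as_tibble(correlations)
  p <- stats::p.adjust(cors$p, method = p_adjust_method)
  keep <- cors$r > min_r & p < max_p & cors$mag_a != cors$mag_b
  edges <- cors[keep, , drop = FALSE]
  key <- paste(pmin(edges$mag_a, edges$mag_b),
               pmax(edges$mag_a, edges$mag_b))
  edges[!duplicated(key), , drop = FALSE]
}

#' Extract co-occurrence modules (connected components)
#'
#' Modules are the connected components of the thresholded network.
#' They are named `M1`, `M2`, ... in order of decreasing member count,
#' ties broken by the lexicographically smallest member id, so naming is
#' deterministic.  Nodes with no edges are labelled `"Uc"`
#' (unclassified in any module).
#'
#' @param edges Edge tibble from [build_network()].
#' @param nodes Optional character vector of all node ids under study
#'   (needed to report isolated nodes); defaults to the nodes incident
#'   to at least one edge.
#' @return A tibble with columns `mag_id` and `module_id`.
#' @export
extract_modules <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edges$mag_a, edges$mag_b)))
  } else {
    nodes <- as.character(nodes)
    missing <- setdiff(unique(c(edges$mag_a, edges$mag_b)), nodes)
    if (length(missing) > 0L) {
      stop_sodamag("edges reference nodes outside `nodes`: ",
                   paste(head(missing, 10L), collapse = ", "),
                   class = "sodamag_validation_error")
    }
  }
  if (length(nodes) == 0L) {
    return(tibble::tibble(mag_id = character(), module_id = character()))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("mag_a", "mag_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  membership <- comp$membership
  groups <- split(names(membership), membership)
  sizes <- lengths(groups)
  smallest <- vapply(groups, function(m) min(m), "")
  real <- sizes >= 2L
  ord <- order(-sizes[real], smallest[real])
  module_of <- setNames(rep("Uc", length(nodes)), nodes)
  comps <- groups[real][ord]
  for (i in seq_along(comps)) {
    module_of[comps[[i]]] <- paste0("M", i)
  }
  tibble::tibble(mag_id = nodes, module_id = unname(module_of[nodes]))
}

#' Summarize module abundance by sample group
#'
#' Sums raw abundance over all members of each module and all samples in
#' each group.  Small modules listed in `other_modules` are pooled into
#' an `"Other"` row and nodes outside any module into `"Uc"`, so the
#' grand total over the table equals the per-group total of the whole
#' abundance matrix (mass conservation).
#'
#' @param abund Raw [abundance_matrix()] (entities x samples).
#' @param modules Tibble from [extract_modules()].
#' @param groups Named character vector mapping every sample id to a
#'   group label (e.g. brine / sediment).
#' @param other_modules Character vector of module ids to pool as
#'   `"Other"` (default none).
#' @return A tibble with columns `group`, `module`, `abundance`.
#' @export
summarize_modules <- function(abund, modules, groups,
                              other_modules = character()) {
  v <- as_plain_matrix(abund)
  unknown <- setdiff(names(groups), colnames(v))
  if (length(unknown) > 0L) {
    stop_sodamag("groups name unknown sample(s): ",
                 paste(unknown, collapse = ", "),
                 class = "sodamag_validation_error")
  }
  uncovered <- setdiff(colnames(v), names(groups))
  if (length(uncovered) > 0L) {
    stop_sodamag("groups must cover all samples; missing: ",
                 paste(uncovered, collapse = ", "),
                 class = "sodamag_validation_error")
  }
  mod <- setNames(modules$module_id, modules$mag_id)[rownames(v)]
  mod[is.na(mod)] <- "Uc"
  mod[mod %in% other_modules] <- "Other"
  by_module <- rowsum(v, group = mod)
  by_both <- t(rowsum(t(by_module), group = groups[colnames(v)]))
  out <- expand.grid(module = rownames(by_both),
                     group = colnames(by_both),
                     stringsAsFactors = FALSE)
  tibble::tibble(group = out$group, module = out$module,
                 abundance = as.vector(by_both))
}

#' Write a network edge list as TSV
#'
#' Columns: `mag_a`, `mag_b`, `r`, `p`.
#'
#' @param edges Edge tibble from [build_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(as.data.frame(edges[, c("mag_a", "mag_b", "r", "p")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a network with module membership as GraphML
#'
#' Node attribute `module` carries the module id (including `"Uc"`).
#'
#' @param edges Edge tibble from [build_network()].
#' @param modules Tibble from [extract_modules()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(edges, modules, path) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges[, c("mag_a", "mag_b", "r", "p")]),
    directed = FALSE,
    vertices = data.frame(name = modules$mag_id,
                          module = modules$module_id))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
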