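#' Rooted taxonomy tree
#'
#' A rooted tree of taxids with ranks and names, supporting root-path and
#' lowest-common-ancestor (LCA) queries.  The root is the unique node whose
#' parent is itself (or missing).  Construction validates the structure:
#' every non-root parent must exist and no cycles are permitted.
#'
#' @param taxid Integer vector of node ids (unique, positive).
#' @param parent Integer vector of parent taxids (same length); the root
#'   may point at itself or be `NA`.
#' @param rank Character vector of rank names (e.g. `"phylum"`).
#' @param name Optional character vector of scientific names; defaults to
#'   the taxid as text.
#' @return A `taxonomy_tree`: list with named vectors `parent`, `rank`,
#'   `name` (names are taxids as character) and the `root` taxid.
#' @examples
#' tr <- taxonomy_tree(taxid = c(1, 2, 3),
#'                     parent = c(1, 1, 2),
#'                     rank = c("root", "genus", "species"))
#' tax_lca(tr, c(2, 3))
#' @export
taxonomy_tree <- function(taxid, parent, rank, name = NULL) {
  taxid <- as.integer(taxid)
  parent <- as.integer(parent)
  if (anyNA(taxid) || any(taxid <= 0L)) {
    stop_sodamag("taxids must be positive integers",
                 class = "sodamag_structural_error")
  }
  if (anyDuplicated(taxid)) {
    stop_sodamag("duplicate taxids: ",
                 paste(unique(taxid[duplicated(taxid)]), collapse = ", "),
                 class = "sodamag_structural_error")
  }
  n <- length(taxid)
  if (length(parent) != n || length(rank) != n) {
    stop_sodamag("taxid, parent and rank must have equal length",
                 class = "sodamag_structural_error")
  }
  if (is.null(name)) name <- as.character(taxid)
  parent[is.na(parent)] <- taxid[is.na(parent)]
  roots <- taxid[parent == taxid]
  if (length(roots) != 1L) {
    stop_sodamag("tree must have exactly one root, found ",
                 length(roots), class = "sodamag_structural_error")
  }
  orphan <- !(parent %in% taxid)
  if (any(orphan)) {
    stop_sodamag("orphan parent taxid(s): ",
                 paste(unique(parent[orphan]), collapse = ", "),
                 class = "sodamag_structural_error")
  }
  key <- as.character(taxid)
  tree <- structure(list(
    parent = setNames(parent, key),
    rank = setNames(as.character(rank), key),
    name = setNames(as.character(name), key),
    root = roots
  ), class = "taxonomy_tree")
  detect_cycles(tree)
  tree
}

detect_cycles <- function(tree) {
  n <- length(tree$parent)
  for (id in as.integer(names(tree$parent))) {
    seen <- integer(0)
    cur <- id
    steps <- 0L
    while (cur != tree$root) {
      if (steps > n) {
        stop_sodamag("cycle detected in taxonomy involving taxids: ",
                     paste(seen, collapse = " -> "),
                     class = "sodamag_structural_error")
      }
      seen <- c(seen, cur)
      cur <- tree$parent[[as.character(cur)]]
      steps <- steps + 1L
    }
  }
  invisible(tree)
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy tree: %d nodes, root %d, ranks: %s\n",
              length(x$parent), x$root,
              paste(unique(x$rank), collapse = ", ")))
  invisible(x)
}

#' @rdname taxonomy_tree
#' @param tree A `taxonomy_tree`.
#' @param id A taxid present in the tree.
#' @return `tax_root_path()` returns the integer taxid path from the root
#'   down to `id` (inclusive).
#' @export
tax_root_path <- function(tree, id) {
  id <- as.integer(id)
  if (!as.character(id) %in% names(tree$parent)) {
    stop_sodamag("taxid ", id, " not in tree",
                 class = "sodamag_structural_error")
  }
  path <- id
  cur <- id
  while (cur != tree$root) {
    cur <- tree$parent[[as.character(cur)]]
    path <- c(cur, path)
  }
  path
}

#' @rdname taxonomy_tree
#' @param ids Integer vector of taxids.
#' @return `tax_lca()` returns the deepest taxid ancestral to all of
#'   `ids` (the last node shared by their root paths).
#' @export
tax_lca <- function(tree, ids) {
  ids <- unique(as.integer(ids))
  if (length(ids) == 0L) return(NA_integer_)
  common <- tax_root_path(tree, ids[[1L]])
  for (id in ids[-1L]) {
    p <- tax_root_path(tree, id)
    k <- min(length(common), length(p))
    shared <- which(common[seq_len(k)] == p[seq_len(k)])
    common <- common[seq_len(max(shared))]
  }
  common[[length(common)]]
}

#' @rdname taxonomy_tree
#' @param rank_name Rank to ascend to (e.g. `"phylum"`).
#' @return `tax_ancestor_at_rank()` returns the ancestor of `id` (possibly
#'   `id` itself) holding rank `rank_name`, or `NA` if the root path does
#'   not pass through that rank (i.e. the node sits above it).
#' @export
tax_ancestor_at_rank <- function(tree, id, rank_name) {
  path <- tax_root_path(tree, id)
  at <- path[tree$rank[as.character(path)] == rank_name]
  if (length(at) == 0L) NA_integer_ else at[[length(at)]]
}

#' @rdname taxonomy_tree
#' @export
tax_ranks <- function(tree) unique(unname(tree$rank))

# readers / writers -----------------------------------------------------------

#' Read a taxonomy from NCBI dump or 4-column TSV
#'
#' Accepts either the NCBI `nodes.dmp` pipe-delimited dialect (fields
#' separated by `\t|\t`: taxid, parent, rank, ...) or a 4-column TSV
#' (taxid, parent, rank, name).  The dialect is auto-detected per file.
#' For the dump dialect, names can be attached from a `names.dmp`-style
#' file (only `scientific name` entries are used); otherwise names default
#' to the taxid as text.
#'
#' @param nodes_path Path to the nodes file.
#' @param names_path Optional path to a names file (dump dialect only).
#' @return A validated [taxonomy_tree()].
#' @export
read_taxonomy <- function(nodes_path, names_path = NULL) {
  if (!file.exists(nodes_path)) {
    stop_sodamag("no such file: ", nodes_path, class = "sodamag_io_error")
  }
  lines <- readLines(nodes_path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop_sodamag("empty taxonomy file", class = "sodamag_format_error")
  }
  if (grepl("\t|\t", lines[[1L]], fixed = TRUE)) {
    fields <- strsplit(sub("\t\\|$", "", lines), "\t|\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short) > 0L) {
      stop_sodamag("nodes.dmp line(s) with fewer than 3 fields: ",
                   paste(head(short, 10L), collapse = ", "),
                   class = "sodamag_format_error")
    }
    taxid <- as.integer(vapply(fields, `[[`, "", 1L))
    parent <- as.integer(vapply(fields, `[[`, "", 2L))
    rank <- vapply(fields, `[[`, "", 3L)
    name <- NULL
    if (!is.null(names_path)) {
      name <- read_names_dmp(names_path, taxid)
    }
    taxonomy_tree(taxid, parent, rank, name)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 4L)
    if (length(bad) > 0L) {
      stop_sodamag("taxonomy TSV line(s) without 4 columns: ",
                   paste(head(bad, 10L), collapse = ", "),
                   class = "sodamag_format_error")
    }
    taxonomy_tree(
      taxid = vapply(fields, `[[`, "", 1L),
      parent = vapply(fields, `[[`, "", 2L),
      rank = vapply(fields, `[[`, "", 3L),
      name = vapply(fields, `[[`, "", 4L))
  }
}

read_names_dmp <- function(names_path, taxid) {
  if (!file.exists(names_path)) {
    stop_sodamag("no such file: ", names_path, class = "sodamag_io_error")
  }
  lines <- readLines(names_path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(sub("\t\\|$", "", lines), "\t|\t", fixed = TRUE)
  keep <- vapply(fields, function(f) {
    length(f) >= 4L && trimws(f[[4L]]) == "scientific name"
  }, logical(1))
  ids <- as.integer(vapply(fields[keep], `[[`, "", 1L))
  nms <- vapply(fields[keep], `[[`, "", 2L)
  out <- as.character(taxid)
  hit <- match(taxid, ids)
  out[!is.na(hit)] <- nms[hit[!is.na(hit)]]
  out
}

#' @rdname read_taxonomy
#' @param tree A `taxonomy_tree`.
#' @param path Output path for the 4-column TSV dialect.
#' @return `write_taxonomy()` returns `path` invisibly; re-reading yields
#'   an identical parent map.
#' @export
write_taxonomy <- function(tree, path) {
  ids <- names(tree$parent)
  writeLines(paste(ids, tree$parent, tree$rank[ids], tree$name[ids],
                   sep = "\t"),
             con <- file(path, "w", encoding = "UTF-8"))
  close(con)
  invisible(path)
}
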