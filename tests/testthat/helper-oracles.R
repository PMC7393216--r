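# Independent oracles and small fixture builders used across the suite.

# random rooted tree: node i's parent is drawn among nodes 1..(i-1), so
# the structure is acyclic by construction
random_tree <- function(n_nodes, ranks = c("root", "phylum", "genus",
                                           "species")) {
  taxid <- seq_len(n_nodes)
  parent <- c(1L, vapply(seq_len(n_nodes - 1L) + 1L, function(i) {
    sample.int(i - 1L, 1L)
  }, integer(1)))
  rank <- c("root", sample(ranks[-1L], n_nodes - 1L, replace = TRUE))
  taxonomy_tree(taxid, parent, rank)
}

# brute-force LCA: intersect the full ancestor SETS of all query taxids
# and return the member with maximal depth (independent formulation from
# the implementation's aligned root-path prefix)
oracle_lca <- function(tree, ids) {
  ancestors_of <- function(id) {
    out <- id
    while (id != tree$root) {
      id <- tree$parent[[as.character(id)]]
      out <- c(out, id)
    }
    out
  }
  sets <- lapply(unique(ids), ancestors_of)
  common <- Reduce(intersect, sets)
  depth <- vapply(common, function(id) length(ancestors_of(id)),
                  integer(1))
  common[[which.max(depth)]]
}

# union-find connected components, independent of igraph
oracle_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$mag_a[[i]])
    rb <- find(edges$mag_b[[i]])
    if (ra != rb) parent[[ra]] <- rb
  }
  split(nodes, vapply(nodes, find, ""))
}

# three-rank chain fixture: root(1) -> genus(2) -> two species (3, 4)
chain_tree <- function() {
  taxonomy_tree(taxid = c(1, 2, 3, 4),
                parent = c(1, 1, 2, 2),
                rank = c("root", "genus", "species", "species"),
                name = c("root", "G", "X", "Y"))
}

make_hit <- function(query, taxid, bitscore = 200, evalue = 1e-50) {
  tibble::tibble(query_id = query, subject_id = paste0("ref_", taxid),
                 pident = 98, align_len = 100L, mismatch = 0L,
                 gapopen = 0L, qstart = 1L, qend = 100L, sstart = 1L,
                 send = 100L, evalue = evalue, bitscore = bitscore,
                 taxid = as.integer(taxid))
}

random_abund <- function(n_entities, n_samples, seed) {
  withr::with_seed(seed, {
    m <- matrix(rlnorm(n_entities * n_samples), nrow = n_entities,
                dimnames = list(sprintf("e%02d", seq_len(n_entities)),
                                sprintf("s%02d", seq_len(n_samples))))
    abundance_matrix(m, "raw")
  })
}
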