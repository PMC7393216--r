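make_catalog <- function(lengths, counts) {
  gene_catalog(sprintf("g%d", seq_along(lengths)), lengths, counts)
}

test_that("gene filters apply strict length and read-support cutoffs", {
  counts <- matrix(c(1000, 1, 2, 0), 4, 1,
                   dimnames = list(NULL, "s1"))
  cat <- make_catalog(c(99, 5000, 100, 100), counts)
  kept <- filter_genes(cat)
  # short gene removed despite deep coverage; singleton removed despite
  # length; both boundary values (100 bp, 2 reads) retained
  expect_equal(kept$genes$gene_id, "g3")
  expect_equal(kept$genes$length_bp, 100)
})

test_that("gene abundance is length-normalised and depth-invariant", {
  counts <- matrix(c(100, 50), 2, 1, dimnames = list(NULL, "s1"))
  ab <- gene_abundance(make_catalog(c(1000, 500), counts))
  expect_equal(unname(unclass(ab)[, 1]), c(0.5, 0.5))
  expect_equal(normalization_state(ab), "fraction")

  one <- gene_abundance(make_catalog(200, matrix(7, 1, 1,
                          dimnames = list(NULL, "s1"))))
  expect_equal(unclass(one)[1, 1], 1)

  withr::local_seed(5)
  counts <- matrix(rpois(40, 30), 10, 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  lens <- sample(100:2000, 10)
  a1 <- gene_abundance(make_catalog(lens, counts))
  scaled <- sweep(counts, 2, c(1, 10, 3, 0.5), "*")
  a2 <- gene_abundance(make_catalog(lens, scaled))
  expect_equal(unclass(a1), unclass(a2))

  counts[, 2] <- 0
  a3 <- gene_abundance(make_catalog(lens, counts))
  expect_equal(unname(colSums(a3)[2]), 0)
})

test_that("duplicate gene ids are rejected", {
  expect_error(
    gene_catalog(c("g", "g"), c(100, 100),
                 matrix(1, 2, 1, dimnames = list(NULL, "s"))),
    "duplicate", class = "sodamag_validation_error")
})

test_that("top-hit retention keeps the inclusive bitscore band", {
  hits <- rbind(make_hit("q", 1, bitscore = 100),
                make_hit("q", 2, bitscore = 91),
                make_hit("q", 3, bitscore = 89))
  kept <- retain_top_hits(hits)
  expect_setequal(kept$bitscore, c(100, 91))

  single <- make_hit("q", 1, evalue = 1e-6)
  expect_equal(nrow(retain_top_hits(single)), 1L)

  late <- make_hit("q", 1, evalue = 1e-3)
  expect_equal(nrow(retain_top_hits(late)), 0L)

  expect_error(retain_top_hits(hits, top_percent = -1),
               class = "sodamag_parameter_error")

  # tied best hits are all retained regardless of order
  tied <- rbind(make_hit("q", 2, bitscore = 100),
                make_hit("q", 1, bitscore = 100))
  expect_equal(nrow(retain_top_hits(tied)), 2L)
})

test_that("top-hit retention never empties a query that passes e-value", {
  withr::local_seed(21)
  for (i in 1:50) {
    hits <- do.call(rbind, lapply(1:5, function(j) {
      make_hit("q", j, bitscore = runif(1, 10, 400))
    }))
    expect_gte(nrow(retain_top_hits(hits)), 1L)
  }
})

test_that("LCA assignment follows the taxonomy structure", {
  tree <- chain_tree()
  one <- lca_assign(make_hit("g1", 3), tree)
  expect_equal(one$taxid, 3L)

  two <- lca_assign(rbind(make_hit("g1", 3), make_hit("g1", 4)), tree)
  expect_equal(two$taxid, 2L)   # sister species collapse to the genus

  wide <- taxonomy_tree(c(1, 2, 3), c(1, 1, 1),
                        c("root", "phylum", "phylum"))
  res <- lca_assign(rbind(make_hit("g1", 2), make_hit("g1", 3)), wide)
  expect_equal(res$taxid, 1L)   # only the root is shared

  none <- lca_assign(make_hit("g1", 3)[0, ], tree, queries = "g1")
  expect_true(is.na(none$taxid))

  expect_warning(
    bad <- lca_assign(rbind(make_hit("g1", 3), make_hit("g1", 99)),
                      tree),
    "unresolvable")
  expect_equal(bad$taxid, 3L)
})

test_that("LCA agrees with the set-intersection oracle on random cases", {
  withr::local_seed(99)
  for (i in 1:200) {
    tree <- random_tree(sample(5:25, 1))
    ids <- sample(as.integer(names(tree$parent)),
                  sample(1:4, 1), replace = TRUE)
    hits <- do.call(rbind, lapply(ids, function(t) make_hit("q", t)))
    expect_equal(lca_assign(hits, tree)$taxid, oracle_lca(tree, ids))
  }
})

test_that("taxon profiles aggregate, conserve mass and pool rare taxa", {
  tree <- taxonomy_tree(
    taxid = c(1, 10, 11, 100, 101),
    parent = c(1, 1, 1, 10, 11),
    rank = c("root", "phylum", "phylum", "species", "species"),
    name = c("root", "Proteobacteria", "Euryarchaeota", "spA", "spB"))
  counts <- matrix(c(60, 40), 2, 1, dimnames = list(NULL, "s1"))
  cat <- gene_catalog(c("g1", "g2"), c(100, 100), counts)
  ab <- gene_abundance(cat)
  asg <- tibble::tibble(gene_id = c("g1", "g2"),
                        taxid = c(100L, 101L), n_hits_used = 1L)
  prof <- aggregate_taxon_profile(ab, asg, tree, "phylum")
  expect_equal(unclass(prof)["Proteobacteria", "s1"], 0.6)
  expect_equal(unclass(prof)["Euryarchaeota", "s1"], 0.4)

  # all genes in one phylum
  asg1 <- tibble::tibble(gene_id = c("g1", "g2"),
                         taxid = c(100L, 100L), n_hits_used = 1L)
  prof1 <- aggregate_taxon_profile(ab, asg1, tree, "phylum")
  expect_equal(unclass(prof1)["Proteobacteria", "s1"], 1.0)

  # a taxon below 0.1% everywhere is relabelled "other"; mass conserved
  counts2 <- matrix(c(9995, 5), 2, 1, dimnames = list(NULL, "s1"))
  ab2 <- gene_abundance(gene_catalog(c("g1", "g2"), c(100, 100),
                                     counts2))
  prof2 <- aggregate_taxon_profile(ab2, asg, tree, "phylum")
  expect_true("other" %in% rownames(prof2))
  expect_false("Euryarchaeota" %in% rownames(prof2))
  expect_equal(unname(colSums(prof2)), 1)

  expect_error(aggregate_taxon_profile(ab, asg, tree, "order"),
               "unknown rank", class = "sodamag_parameter_error")
})

test_that("profile aggregation conserves column sums on random data", {
  withr::local_seed(17)
  for (i in 1:25) {
    tree <- random_tree(20)
    n_genes <- 30
    counts <- matrix(rpois(n_genes * 4, 20), n_genes, 4,
                     dimnames = list(NULL, paste0("s", 1:4)))
    cat <- make_catalog(sample(100:1000, n_genes, TRUE), counts)
    ab <- gene_abundance(cat)
    asg <- tibble::tibble(
      gene_id = cat$genes$gene_id,
      taxid = sample(as.integer(names(tree$parent)), n_genes, TRUE),
      n_hits_used = 1L)
    prof <- aggregate_taxon_profile(ab, asg, tree, "species",
                                    min_relative = 0.01)
    expect_equal(colSums(prof), colSums(ab), tolerance = 1e-9)
  }
})

test_that("Shannon index matches closed forms and merge monotonicity", {
  single <- abundance_matrix(matrix(1, 1, 1,
                                    dimnames = list("e", "s")),
                             "fraction")
  expect_equal(shannon_index(single)$shannon, 0)

  uniform <- abundance_matrix(
    matrix(0.25, 4, 1, dimnames = list(letters[1:4], "s")), "fraction")
  expect_equal(shannon_index(uniform)$shannon, log(4))

  zero <- abundance_matrix(
    matrix(c(1, 0), 1, 2, dimnames = list("e", c("s1", "s2"))), "raw")
  expect_true(is.na(shannon_index(zero)$shannon[2]))

  withr::local_seed(31)
  for (i in 1:20) {
    p <- rlnorm(10)
    m <- abundance_matrix(matrix(p / sum(p), 10, 1,
                                 dimnames = list(letters[1:10], "s")),
                          "fraction")
    merged <- unclass(m)
    merged[1, ] <- merged[1, ] + merged[2, ]
    merged <- abundance_matrix(merged[-2, , drop = FALSE], "fraction")
    expect_lte(shannon_index(merged)$shannon,
               shannon_index(m)$shannon + 1e-12)
  }
})
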