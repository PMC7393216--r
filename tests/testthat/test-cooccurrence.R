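abund_from_rows <- function(rows, samples = 18) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), paste0("s", seq_len(ncol(m))))
  abundance_matrix(m, "raw")
}

test_that("pairwise correlations match the t-transform p-values", {
  x <- seq_len(18) + 0.5
  ab <- abund_from_rows(list(a = x, b = x * 3, c = max(x) + 1 - x))
  cors <- pairwise_correlation(ab)
  ab_pair <- cors[cors$mag_a == "a" & cors$mag_b == "b", ]
  expect_equal(ab_pair$r, 1)
  expect_equal(ab_pair$p, 0)
  ac_pair <- cors[cors$mag_a == "a" & cors$mag_b == "c", ]
  expect_equal(ac_pair$r, -1)

  # at n = 18 a correlation of exactly 0.9 gives t = 8.26 and p << 0.01,
  # so the r gate is the binding one
  r <- 0.9; n <- 18
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(tstat, 8.26, tolerance = 1e-3)
  expect_lt(2 * pt(tstat, df = n - 2, lower.tail = FALSE), 0.01)

  expect_error(
    pairwise_correlation(abundance_matrix(
      matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
      "raw")),
    "at least 3", class = "sodamag_parameter_error")

  flat <- abund_from_rows(list(a = x, b = rep(2, 18), c = x^2))
  expect_warning(cf <- pairwise_correlation(flat), "zero-variance")
  expect_false("b" %in% c(cf$mag_a, cf$mag_b))

  # p-values agree with cor.test on random profiles
  withr::local_seed(2)
  ab2 <- random_abund(4, 10, seed = 2)
  cors2 <- pairwise_correlation(ab2)
  for (i in seq_len(nrow(cors2))) {
    ct <- cor.test(unclass(ab2)[cors2$mag_a[i], ],
                   unclass(ab2)[cors2$mag_b[i], ])
    expect_equal(cors2$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(cors2$p[i], ct$p.value, tolerance = 1e-12)
  }
})

test_that("network edges require both gates strictly", {
  cors <- tibble::tibble(
    mag_a = c("a", "a", "a"), mag_b = c("b", "c", "d"),
    r = c(0.95, 0.95, 0.9), p = c(1e-6, 0.02, 1e-6), n = 18L)
  edges <- build_network(cors)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$mag_b, "b")   # p = 0.02 and r = 0.9 both rejected
})

test_that("modules equal the union-find oracle and are named stably", {
  tri <- tibble::tibble(
    mag_a = c("a", "b", "c", "x", "y", "z"),
    mag_b = c("b", "c", "a", "y", "z", "x"))
  mods <- extract_modules(tri)
  expect_equal(as.vector(table(mods$module_id)), c(3L, 3L))
  # equal sizes: tie broken by smallest member, so a/b/c are M1
  expect_equal(unique(mods$module_id[mods$mag_id %in% c("a", "b", "c")]),
               "M1")

  none <- extract_modules(tri[0, ], nodes = c("a", "b"))
  expect_equal(unique(none$module_id), "Uc")

  # canonical partition signature, for oracle comparison
  signature <- function(groups) {
    sort(unname(vapply(groups,
                       function(g) paste(sort(g), collapse = ","), "")))
  }

  # exhaustive: every graph on 4 labelled nodes
  nodes4 <- c("a", "b", "c", "d")
  all_pairs <- t(combn(nodes4, 2))
  for (mask in 0:(2^nrow(all_pairs) - 1)) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(nrow(all_pairs)) - 1)))
    edges <- tibble::tibble(mag_a = all_pairs[on, 1],
                            mag_b = all_pairs[on, 2])
    mods <- extract_modules(edges, nodes = nodes4)
    got <- split(mods$mag_id, mods$module_id)
    want <- oracle_components(nodes4, edges)
    want_real <- Filter(function(g) length(g) > 1, want)
    want_uc <- unlist(Filter(function(g) length(g) == 1, want))
    expect_equal(signature(got[names(got) != "Uc"]),
                 signature(want_real))
    expect_setequal(as.character(got[["Uc"]]), as.character(want_uc))
  }

  # random graphs up to 8 nodes
  withr::local_seed(55)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    nodes <- letters[seq_len(n)]
    pairs <- t(combn(nodes, 2))
    on <- runif(nrow(pairs)) < 0.25
    edges <- tibble::tibble(mag_a = pairs[on, 1], mag_b = pairs[on, 2])
    mods <- extract_modules(edges, nodes = nodes)
    got <- split(mods$mag_id, mods$module_id)
    want <- Filter(function(g) length(g) > 1,
                   oracle_components(nodes, edges))
    expect_equal(signature(got[names(got) != "Uc"]), signature(want))
  }
})

test_that("module summaries conserve group totals", {
  ab <- random_abund(10, 6, seed = 30)
  groups <- setNames(rep(c("brine", "sediment"), each = 3),
                     colnames(ab))
  mods <- tibble::tibble(
    mag_id = rownames(ab),
    module_id = c(rep("M1", 4), rep("M2", 2), rep("M3", 2),
                  rep("Uc", 2)))
  tab <- summarize_modules(ab, mods, groups, other_modules = "M3")
  expect_setequal(unique(tab$module), c("M1", "M2", "Other", "Uc"))
  for (g in c("brine", "sediment")) {
    expect_equal(sum(tab$abundance[tab$group == g]),
                 sum(unclass(ab)[, names(groups)[groups == g]]),
                 tolerance = 1e-9)
  }

  # single module containing all MAGs equals the whole-matrix group sums
  all_mod <- tibble::tibble(mag_id = rownames(ab), module_id = "M1")
  tab2 <- summarize_modules(ab, all_mod, groups)
  expect_equal(sum(tab2$abundance[tab2$module == "M1"]),
               sum(unclass(ab)))

  # a singleton module's row is that MAG's group-summed abundance
  solo <- tibble::tibble(mag_id = rownames(ab),
                         module_id = c("M1", rep("Uc", 9)))
  tab3 <- summarize_modules(ab, solo, groups)
  expect_equal(tab3$abundance[tab3$module == "M1" &
                                tab3$group == "brine"],
               sum(unclass(ab)[1, 1:3]))

  expect_error(
    summarize_modules(ab, mods, c(bad_sample = "brine")),
    class = "sodamag_validation_error")
})

test_that("planted perfect pairs are recovered and null pairs are not", {
  hits <- 0L; false_edges <- 0L; n_rep <- 200L
  for (s in seq_len(n_rep)) {
    withr::with_seed(1000 + s, {
      base <- rlnorm(18, 0, 1)
      noise <- function() 1 + rnorm(18, 0, 0.01 / 3)  # <=1% magnitude
      m <- rbind(p1 = base * noise(), p2 = 3 * base * noise(),
                 q1 = rlnorm(18), q2 = rlnorm(18))
      colnames(m) <- paste0("s", 1:18)
      edges <- build_network(
        pairwise_correlation(abundance_matrix(m, "raw")))
      key <- paste(edges$mag_a, edges$mag_b)
      if ("p1 p2" %in% key) hits <- hits + 1L
      if (any(grepl("q1 q2|q2 q1", key))) false_edges <- false_edges + 1L
    })
  }
  expect_gte(hits / n_rep, 0.99)
  expect_lte(false_edges / n_rep, 0.01)
})

test_that("edge lists and GraphML exports are written", {
  ab <- abund_from_rows(list(a = 1:18 + 0.0, b = (1:18) * 2,
                             c = rlnorm(18)))
  edges <- build_network(pairwise_correlation(ab))
  mods <- extract_modules(edges, nodes = rownames(ab))
  ep <- withr::local_tempfile(fileext = ".tsv")
  gp <- withr::local_tempfile(fileext = ".graphml")
  write_edge_list(edges, ep)
  expect_equal(read.delim(ep)$mag_a, edges$mag_a)
  write_graphml(edges, mods, gp)
  g <- igraph::read_graph(gp, format = "graphml")
  expect_setequal(igraph::V(g)$module, mods$module_id)
})
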