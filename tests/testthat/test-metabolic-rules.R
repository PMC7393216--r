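call_status <- function(calls, pathway) {
  calls$status[calls$pathway == pathway]
}

test_that("default rules call pathways from marker inventories", {
  calls <- evaluate_ruleset(list(
    cbb = c("prk", "rbcL", "rbcS"),
    ttr = c("ttrA", "ttrB"),            # ttrC not required
    empty = character(0)))
  cbb <- calls[calls$mag_id == "cbb", ]
  expect_equal(call_status(cbb, "cbb_carbon_fixation"), "present")
  expect_equal(call_status(cbb, "nitrogen_fixation"), "absent")
  ttr <- calls[calls$mag_id == "ttr", ]
  expect_equal(call_status(ttr, "tetrathionate_respiration"), "present")
  empty <- calls[calls$mag_id == "empty", ]
  expect_true(all(empty$status == "absent"))

  # long-format input and KO-id input give the same calls
  long <- tibble::tibble(mag_id = "cbb",
                         marker = c("K00855", "K01601", "K01602"))
  calls2 <- evaluate_ruleset(long)
  expect_equal(call_status(calls2, "cbb_carbon_fixation"), "present")
})

test_that("rule loading validates markers and syntax", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines('bad_rule: "prk & made_up_gene"', path)
  expect_error(load_ruleset(path), "made_up_gene",
               class = "sodamag_rule_error")
  writeLines('bad_syntax: "prk &&& ("', path)
  expect_error(load_ruleset(path), "parse",
               class = "sodamag_rule_error")
  expect_error(normalize_markers("K99999"),
               class = "sodamag_validation_error")
  expect_error(normalize_markers("notagene"),
               class = "sodamag_validation_error")
})

test_that("rule evaluation is monotone in the marker set", {
  withr::local_seed(61)
  vocab <- marker_vocabulary()
  rules <- default_ruleset()
  for (i in 1:30) {
    base <- sample(vocab, sample(0:10, 1))
    extra <- union(base, sample(vocab, 5))
    c1 <- evaluate_ruleset(list(m = base), rules)
    c2 <- evaluate_ruleset(list(m = extra), rules)
    # adding markers never flips present -> absent
    was_present <- c1$pathway[c1$status == "present"]
    expect_false(any(c2$status[c2$pathway %in% was_present] == "absent"))
  }
})

test_that("doxD calls are ambiguous without the DoxA small subunit", {
  calls <- evaluate_ruleset(list(lone = "doxD",
                                 paired = c("doxD", "doxA")))
  lone <- calls[calls$mag_id == "lone", ]
  expect_equal(call_status(lone, "thiosulfate_oxidation_doxD"),
               "ambiguous")
  expect_equal(lone$note[lone$pathway == "thiosulfate_oxidation_doxD"],
               "DoxA absent")
  paired <- calls[calls$mag_id == "paired", ]
  expect_equal(call_status(paired, "thiosulfate_oxidation_doxD"),
               "present")
})

test_that("dsr direction matches its exhaustive truth table", {
  # spelled-out rule, rebuilt independently of the implementation
  oracle <- function(set) {
    if (!("dsrA" %in% set) || !("dsrB" %in% set)) return("none")
    d <- "dsrD" %in% set
    efh <- all(c("dsrE", "dsrF", "dsrH") %in% set)
    if (d && !efh) return("reductive")
    if (efh && !d) return("oxidative")
    "ambiguous"
  }
  genes <- c("dsrA", "dsrB", "dsrD", "dsrE", "dsrF", "dsrH")
  for (mask in 0:(2^6 - 1)) {
    set <- genes[as.logical(bitwAnd(mask, 2^(0:5)))]
    expect_equal(dsr_direction(set), oracle(set), info = mask)
  }
  # named archetypes
  expect_equal(dsr_direction(c("dsrA", "dsrB", "dsrE", "dsrF", "dsrH")),
               "oxidative")
  expect_equal(dsr_direction(c("dsrA", "dsrB", "dsrD")), "reductive")
  expect_equal(dsr_direction(character(0)), "none")
  # relaxed subunit requirement
  expect_equal(dsr_direction(c("dsrA", "dsrB", "dsrE"),
                             efh_require = "any"), "oxidative")
})

test_that("glucan routes match their exhaustive truth table", {
  core <- c("gpi", "pfk", "fba", "tpi", "gap", "pgk", "gpm", "eno",
            "pk")
  oracle_route <- function(set) {
    phos <- all(c("pyg", "pgm") %in% set)
    hydro <- all(c("amy", "glk") %in% set)
    if (phos && hydro) "both"
    else if (phos) "phosphorolytic"
    else if (hydro) "hydrolytic"
    else "none"
  }
  entry <- c("pyg", "pgm", "amy", "glk")
  for (mask in 0:(2^4 - 1)) {
    for (with_core in c(TRUE, FALSE)) {
      set <- c(entry[as.logical(bitwAnd(mask, 2^(0:3)))],
               if (with_core) core)
      res <- glucan_route(set)
      expect_equal(res$route, oracle_route(set), info = mask)
      expect_equal(res$glycolysis_complete, with_core, info = mask)
    }
  }

  nha1 <- glucan_route(c("pyg", "pgm", core))
  expect_equal(nha1$route, "phosphorolytic")
  expect_true(nha1$glycolysis_complete)
  expect_length(nha1$missing_glycolysis_steps, 0)

  hydro <- glucan_route(c("amy", "glk", core))
  expect_equal(hydro$route, "hydrolytic")
  expect_true(hydro$glycolysis_complete)

  stranded <- glucan_route("pyg")
  expect_equal(stranded$route, "none")
  expect_true("pgm" %in% stranded$missing_glycolysis_steps)

  woese <- glucan_route(ko_profile_templates()$woesearchaeon)
  expect_false(woese$glycolysis_complete)
  expect_true("pfk" %in% woese$missing_glycolysis_steps)
})

test_that("archetype templates express their diagnostic phenotypes", {
  tpl <- ko_profile_templates()
  expect_equal(dsr_direction(tpl$sulfur_oxidizer_autotroph), "oxidative")
  expect_equal(dsr_direction(tpl$sulfate_reducer), "reductive")
  nha <- glucan_route(tpl$nanohaloarchaeon_NHA1)
  expect_equal(nha$route, "phosphorolytic")
  expect_true(nha$glycolysis_complete)
  expect_false("amy" %in% tpl$nanohaloarchaeon_NHA1)
  calls <- evaluate_ruleset(tpl["sulfate_reducer"])
  expect_equal(call_status(calls, "polysulfide_thiosulfate_respiration"),
               "present")
  expect_equal(call_status(calls, "wood_ljungdahl_carbon_fixation"),
               "present")
  hs <- evaluate_ruleset(tpl["heterotroph_sqr"])
  expect_equal(call_status(hs, "sulfide_oxidation"), "present")
})

test_that("presence/absence export widens calls correctly", {
  calls <- evaluate_ruleset(list(a = c("sqr"), b = character(0)))
  m <- potential_matrix(calls)
  expect_equal(m["a", "sulfide_oxidation"], 1L)
  expect_equal(m["b", "sulfide_oxidation"], 0L)
})
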