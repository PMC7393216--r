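#' Marker-gene vocabulary
#'
#' The declared set of marker gene symbols recognised by the rule engine:
#' carbon fixation (CBB: prk, rbcL, rbcS; Wood-Ljungdahl: cooS, acsB,
#' cdhD, cdhE), sulfur oxidation (sqr, fccB, soeA-C, soxB/Y/Z, doxD/doxA),
#' dissimilatory sulfite reductase subunits and accessories (dsrA, dsrB,
#' dsrD, dsrE, dsrF, dsrH), sulfur respiration (psrA_phsA, ttrA-C),
#' nitrogen fixation (nifH, nifD, nifK), hydrogenase (mvhA, mvhD, mvhG)
#' and glucan catabolism / glycolysis (amy, glk, pyg, pgm, gpi, pfk, fba,
#' tpi, gap, pgk, gpm, eno, pk).
#'
#' @return Character vector of valid marker ids.
#' @export
marker_vocabulary <- function() {
  c("prk", "rbcL", "rbcS",
    "sqr", "fccB",
    "dsrA", "dsrB", "dsrD", "dsrE", "dsrF", "dsrH",
    "soeA", "soeB", "soeC",
    "soxB", "soxY", "soxZ",
    "psrA_phsA",
    "ttrA", "ttrB", "ttrC",
    "nifH", "nifD", "nifK",
    "cooS", "acsB", "cdhD", "cdhE",
    "doxD", "doxA",
    "amy", "glk", "pyg", "pgm",
    "gpi", "pfk", "fba", "tpi", "gap", "pgk", "gpm", "eno", "pk",
    "mvhA", "mvhD", "mvhG")
}

#' Marker symbol / KEGG ortholog synonym table
#'
#' Maps each marker symbol to its common KEGG Orthology id, so marker
#' inventories may be supplied either as gene symbols or as KO ids.
#'
#' @return Tibble with columns `marker` and `ko`.
#' @export
marker_ko_map <- function() {
  path <- system.file("extdata", "marker_ko_map.tsv",
                      package = "sodamag", mustWork = TRUE)
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Normalise a marker inventory to the symbol vocabulary
#'
#' KO ids (pattern `K` + 5 digits) are translated through
#' [marker_ko_map()]; symbols are passed through.  Ids that are neither a
#' known KO nor a vocabulary symbol are rejected.
#'
#' @param markers Character vector of marker symbols and/or KO ids.
#' @return Character vector of unique vocabulary symbols.
#' @export
normalize_markers <- function(markers) {
  markers <- as.character(markers)
  map <- marker_ko_map()
  is_ko <- grepl("^K\\d{5}$", markers)
  out <- markers
  hit <- match(markers[is_ko], map$ko)
  if (anyNA(hit)) {
    stop_sodamag("unknown KO id(s): ",
                 paste(unique(markers[is_ko][is.na(hit)]), collapse = ", "),
                 class = "sodamag_validation_error")
  }
  out[is_ko] <- map$marker[hit]
  bad <- setdiff(out, marker_vocabulary())
  if (length(bad) > 0L) {
    stop_sodamag("unknown marker id(s): ", paste(bad, collapse = ", "),
                 class = "sodamag_validation_error")
  }
  unique(out)
}

#' Rule sets for metabolic potential
#'
#' A rule set maps pathway names to boolean expressions over marker
#' symbols, using `&`, `|`, `!` and parentheses (e.g.
#' `"prk & rbcL & rbcS"`).  `default_ruleset()` ships the package's
#' defaults (CBB cycle, Wood-Ljungdahl, sulfide / sulfite / thiosulfate
#' oxidation, polysulfide-thiosulfate and tetrathionate respiration,
#' nitrogen fixation, and the DoxD-based thiosulfate oxidation call that
#' carries an ambiguity caveat); `load_ruleset()` reads an editable YAML
#' file of `pathway: expression` entries.  Every referenced marker must
#' be in [marker_vocabulary()].
#'
#' @param path Path to a YAML rules file.
#' @return A `ruleset`: named list of parsed rule expressions.
#' @export
load_ruleset <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == "")) {
    stop_sodamag("rules file must be a named mapping",
                 class = "sodamag_rule_error")
  }
  rules <- lapply(names(raw), function(nm) {
    expr <- tryCatch(str2lang(raw[[nm]]), error = function(e) {
      stop_sodamag("rule '", nm, "' does not parse: ", raw[[nm]],
                   class = "sodamag_rule_error")
    })
    bad <- setdiff(all.vars(expr), marker_vocabulary())
    if (length(bad) > 0L) {
      stop_sodamag("rule '", nm, "' references unknown marker(s): ",
                   paste(bad, collapse = ", "),
                   class = "sodamag_rule_error")
    }
    expr
  })
  structure(setNames(rules, names(raw)), class = "ruleset")
}

#' @rdname load_ruleset
#' @export
default_ruleset <- function() {
  load_ruleset(system.file("extdata", "metabolic_rules.yaml",
                           package = "sodamag", mustWork = TRUE))
}

as_marker_sets <- function(markers) {
  if (is.data.frame(markers)) {
    if (!all(c("mag_id", "marker") %in% names(markers))) {
      stop_sodamag("marker table needs mag_id and marker columns",
                   class = "sodamag_validation_error")
    }
    markers <- split(markers$marker, markers$mag_id)
  }
  if (!is.list(markers) || is.null(names(markers))) {
    stop_sodamag("markers must be a mag_id -> marker-vector list or a ",
                 "long-format table", class = "sodamag_validation_error")
  }
  lapply(markers, normalize_markers)
}

#' Evaluate a rule set over per-MAG marker inventories
#'
#' Emits one call per MAG and pathway.  A pathway is `present` when its
#' boolean rule evaluates true over the MAG's marker set, else `absent`.
#' Rules that rest on `doxD` carry the thiosulfate-oxidation caveat: the
#' quinone-dependent thiosulfate dehydrogenase needs its small subunit
#' DoxA, so a `doxD`-positive MAG lacking `doxA` is called `ambiguous`
#' with note `"DoxA absent"`.
#'
#' @param markers Long tibble (`mag_id`, `marker`) or named list of
#'   marker vectors; symbols or KO ids.
#' @param rules A `ruleset` (default [default_ruleset()]).
#' @return A tibble with columns `mag_id`, `pathway`, `status`
#'   (`present` / `absent` / `ambiguous`) and `note`.
#' @export
evaluate_ruleset <- function(markers, rules = default_ruleset()) {
  sets <- as_marker_sets(markers)
  vocab <- marker_vocabulary()
  rows <- lapply(names(sets), function(mag) {
    have <- sets[[mag]]
    env <- list2env(setNames(as.list(vocab %in% have), vocab))
    status <- character(length(rules))
    note <- character(length(rules))
    for (i in seq_along(rules)) {
      present <- isTRUE(eval(rules[[i]], env))
      status[[i]] <- if (present) "present" else "absent"
      note[[i]] <- ""
      if (present && "doxD" %in% all.vars(rules[[i]]) &&
          !("doxA" %in% have)) {
        status[[i]] <- "ambiguous"
        note[[i]] <- "DoxA absent"
      }
    }
    tibble::tibble(mag_id = mag, pathway = names(rules),
                   status = status, note = note)
  })
  do.call(rbind, rows)
}

#' Direction of dissimilatory sulfur metabolism from DsrAB context
#'
#' A MAG carrying both `dsrA` and `dsrB` runs dissimilatory sulfite
#' reductase; the direction is diagnosed from the accessory genes:
#' `dsrD` without the full `dsrEFH` set marks the reductive
#' (sulfate/sulfite-reducing) type, `dsrEFH` (all three subunits, by
#' default) without `dsrD` marks the oxidative (reversed, rDsrAB) type.
#' Both or neither present is `ambiguous`; missing `dsrA` or `dsrB` is
#' `none`.
#'
#' @param markers Character vector of marker symbols / KO ids for one MAG.
#' @param efh_require How many of dsrE/dsrF/dsrH define the oxidative
#'   signal: `"all"` (default) or `"any"`.
#' @return One of `"reductive"`, `"oxidative"`, `"none"`, `"ambiguous"`.
#' @export
dsr_direction <- function(markers, efh_require = c("all", "any")) {
  efh_require <- match.arg(efh_require)
  have <- normalize_markers(markers)
  if (!all(c("dsrA", "dsrB") %in% have)) return("none")
  has_d <- "dsrD" %in% have
  efh <- c("dsrE", "dsrF", "dsrH") %in% have
  has_efh <- if (efh_require == "all") all(efh) else any(efh)
  if (has_d && !has_efh) return("reductive")
  if (has_efh && !has_d) return("oxidative")
  "ambiguous"
}

glycolysis_core_steps <- function(route) {
  # hexose-phosphate to pyruvate; entry steps handled by the route test.
  # Gpi is required for both entries (glucose-6-P must isomerise to
  # fructose-6-P); Glk is an entry step of the hydrolytic route only.
  c("gpi", "pfk", "fba", "tpi", "gap", "pgk", "gpm", "eno", "pk")
}

#' Glucan catabolic route and glycolysis completeness
#'
#' Types how a MAG can feed 1,4-alpha-glucans into glycolysis:
#' the phosphorolytic route needs glycogen phosphorylase (`pyg`) plus
#' phosphoglucomutase (`pgm`), the hydrolytic route needs alpha-amylase
#' (`amy`) plus glucokinase (`glk`).  Glycolysis is complete when every
#' step from hexose phosphate to pyruvate is present (`gpi`, `pfk`,
#' `fba`, `tpi`, `gap`, `pgk`, `gpm`, `eno`, `pk`); missing steps are
#' enumerated.
#'
#' @param markers Character vector of marker symbols / KO ids for one MAG.
#' @return List with elements `route` (`"phosphorolytic"`,
#'   `"hydrolytic"`, `"both"` or `"none"`), `glycolysis_complete`
#'   (logical) and `missing_glycolysis_steps` (character).
#' @export
glucan_route <- function(markers) {
  have <- normalize_markers(markers)
  phos <- all(c("pyg", "pgm") %in% have)
  hydro <- all(c("amy", "glk") %in% have)
  route <- if (phos && hydro) "both"
           else if (phos) "phosphorolytic"
           else if (hydro) "hydrolytic"
           else "none"
  missing <- setdiff(glycolysis_core_steps(route), have)
  if (route %in% c("none", "phosphorolytic") && !phos &&
      !("pgm" %in% have) && "pyg" %in% have) {
    # a phosphorylase without phosphoglucomutase strands glucose-1-P
    missing <- union("pgm", missing)
  }
  list(route = route,
       glycolysis_complete = length(setdiff(glycolysis_core_steps(route),
                                            have)) == 0L,
       missing_glycolysis_steps = missing)
}

#' Export metabolic calls as a presence/absence matrix
#'
#' Long-format calls from [evaluate_ruleset()] widened to a MAGs x
#' pathways 0/1 matrix (ambiguous counted as 0), for heatmap export.
#'
#' @param calls Tibble from [evaluate_ruleset()].
#' @return Integer matrix, MAGs in rows, pathways in columns.
#' @export
potential_matrix <- function(calls) {
  mags <- unique(calls$mag_id)
  paths <- unique(calls$pathway)
  m <- matrix(0L, length(mags), length(paths),
              dimnames = list(mags, paths))
  pres <- calls[calls$status == "present", , drop = FALSE]
  m[cbind(pres$mag_id, pres$pathway)] <- 1L
  m
}
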