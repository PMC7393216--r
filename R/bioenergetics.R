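#' Parse a stoichiometric reaction string
#'
#' Accepts equations of the form `"A + 2B -> C + 3D"` (separator `"->"`
#' or the unicode arrow), where each term is an optional positive
#' integer coefficient glued or spaced onto a species name (`"4H2O"`,
#' `"2 HCO3-"`).  Protons must be written as the species `"H+"`.
#'
#' @param text The reaction equation.
#' @param dg0_prime Standard-state Gibbs free energy change at pH 7
#'   (kJ per mole of reaction as written).
#' @param name Optional reaction name.
#' @return A `reaction`: list with `name`, named integer vectors
#'   `reactants` and `products`, and `dg0_prime`.
#' @examples
#' r <- parse_reaction("4H2 + SO42- + H+ -> HS- + 4H2O", -151.9)
#' net_proton_yield(r)
#' delta_g_at_ph(r, ph = 10)
#' @export
parse_reaction <- function(text, dg0_prime, name = NA_character_) {
  assert_scalar_number(dg0_prime, "dg0_prime")
  sides <- strsplit(gsub("\u2192", "->", text, fixed = TRUE), "->",
                    fixed = TRUE)[[1L]]
  if (length(sides) != 2L) {
    stop_sodamag("reaction must contain exactly one '->' arrow: ", text,
                 class = "sodamag_format_error")
  }
  parse_side <- function(side) {
    # terms are separated by a spaced plus; a glued trailing '+' belongs
    # to the species itself (e.g. "5H+")
    out <- trimws(strsplit(side, " + ", fixed = TRUE)[[1L]])
    out <- out[nzchar(out)]
    if (length(out) == 0L) {
      stop_sodamag("reaction side has no species: '", side, "'",
                   class = "sodamag_format_error")
    }
    coefs <- integer(0)
    species <- character(0)
    for (term in out) {
      m <- regmatches(term, regexec("^([0-9]*)\\s*([A-Za-z].*)$", term))[[1L]]
      if (length(m) != 3L || !nzchar(m[[3L]])) {
        stop_sodamag("unparseable species term: '", term, "'",
                     class = "sodamag_format_error")
      }
      coef <- if (nzchar(m[[2L]])) as.integer(m[[2L]]) else 1L
      if (is.na(coef) || coef <= 0L) {
        stop_sodamag("coefficient must be a positive integer in '", term,
                     "'", class = "sodamag_format_error")
      }
      coefs <- c(coefs, coef)
      species <- c(species, m[[3L]])
    }
    sums <- tapply(coefs, species, sum)
    setNames(as.integer(sums), names(sums))[unique(species)]
  }
  structure(list(name = name,
                 reactants = parse_side(sides[[1L]]),
                 products = parse_side(sides[[2L]]),
                 dg0_prime = dg0_prime),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  fmt <- function(v) paste(ifelse(v > 1, paste0(v, names(v)), names(v)),
                           collapse = " + ")
  cat(sprintf("%s: %s -> %s  (dG0' = %.4g kJ)\n",
              if (is.na(x$name)) "reaction" else x$name,
              fmt(x$reactants), fmt(x$products), x$dg0_prime))
  invisible(x)
}

#' Net proton yield of a reaction
#'
#' Product-side minus reactant-side stoichiometric coefficient of `H+`.
#'
#' @param rxn A [parse_reaction()] object.
#' @return Integer net proton yield (positive = protons released).
#' @export
net_proton_yield <- function(rxn) {
  get_h <- function(side) {
    if ("H+" %in% names(side)) as.integer(side[["H+"]]) else 0L
  }
  get_h(rxn$products) - get_h(rxn$reactants)
}

#' Energetics constants for the pH correction
#'
#' The proton-activity term shifts a reaction's free energy by
#' `m = ln(10) * R * T` kJ per mole of protons per pH unit.  The default
#' `per_ph_unit_kj = 5.6867` is calibrated so that a 3-unit shift (pH 7
#' to 10) contributes 17.06 kJ per proton, the convention used in the
#' soda-lake sulfur literature (it corresponds to T of about 297 K); the
#' 25 degree C textbook value 5.708 can be requested instead via
#' `ph_term_at_temperature(25)`.
#'
#' @param per_ph_unit_kj kJ per mole proton per pH unit (> 0).
#' @return List with element `per_ph_unit_kj`.
#' @export
energetics_constants <- function(per_ph_unit_kj = 5.6867) {
  assert_scalar_number(per_ph_unit_kj, "per_ph_unit_kj")
  if (per_ph_unit_kj <= 0) {
    stop_sodamag("per_ph_unit_kj must be positive",
                 class = "sodamag_parameter_error")
  }
  list(per_ph_unit_kj = per_ph_unit_kj)
}

#' @rdname energetics_constants
#' @param temperature_c Temperature in degrees Celsius.
#' @export
ph_term_at_temperature <- function(temperature_c = 25) {
  log(10) * 8.31446261815324e-3 * (temperature_c + 273.15)
}

#' pH-corrected Gibbs free energy of a reaction
#'
#' Shifts the biochemical-standard free energy (`dG0'`, defined at pH 7)
#' to another pH by correcting the proton activity only:
#' `dG(pH) = dG0' - nu * m * (pH - 7)`, with `nu` the net proton yield
#' and `m` the per-proton pH term.  All non-proton species stay at their
#' standard states (water activity 1).  At pH 7 the function returns
#' `dG0'` exactly; proton-releasing reactions (`nu > 0`) become strictly
#' more exergonic as pH rises and proton-consuming ones strictly less.
#'
#' @param rxn A [parse_reaction()] object.
#' @param ph Target pH.
#' @param constants An [energetics_constants()] list.
#' @return Free energy change in kJ per mole of reaction.
#' @export
delta_g_at_ph <- function(rxn, ph, constants = energetics_constants()) {
  assert_scalar_number(ph, "ph")
  rxn$dg0_prime -
    net_proton_yield(rxn) * constants$per_ph_unit_kj * (ph - 7)
}

#' Read a reaction table from TSV
#'
#' Columns: `name`, `equation`, `dg0_prime_kj`.
#'
#' @param path TSV path.
#' @return Named list of [parse_reaction()] objects.
#' @export
read_reactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "equation", "dg0_prime_kj")
  if (!all(need %in% names(df))) {
    stop_sodamag("reaction table needs columns: ",
                 paste(need, collapse = ", "),
                 class = "sodamag_format_error")
  }
  rxns <- Map(parse_reaction, df$equation, df$dg0_prime_kj, df$name)
  setNames(rxns, df$name)
}

#' Reference sulfur redox reactions
#'
#' The bundled set of four acetate- and hydrogen-driven sulfur-compound
#' reduction reactions (elemental sulfur, tetrathionate, sulfate x2) with
#' literature biochemical-standard free energies, used to compare the
#' thermodynamics of dissimilatory sulfur reduction at neutral versus
#' alkaline pH.
#'
#' @return Named list of [parse_reaction()] objects.
#' @export
sulfur_reactions <- function() {
  read_reactions(system.file("extdata", "sulfur_reactions.tsv",
                             package = "sodamag", mustWork = TRUE))
}

#' Tabulate pH-corrected free energies for a reaction set
#'
#' @param rxns Named list of reactions (default [sulfur_reactions()]).
#' @param ph Numeric vector of target pH values.
#' @param constants An [energetics_constants()] list.
#' @return Tibble with `name`, `dg0_prime_kj`, `net_proton_yield` and one
#'   `dg_ph<ph>_kj` column per requested pH.
#' @export
delta_g_table <- function(rxns = sulfur_reactions(), ph = 10,
                          constants = energetics_constants()) {
  out <- tibble::tibble(
    name = unname(vapply(rxns, function(r) r$name, "")),
    dg0_prime_kj = unname(vapply(rxns, function(r) r$dg0_prime, 0)),
    net_proton_yield = unname(vapply(rxns, net_proton_yield, 0L)))
  for (p in ph) {
    out[[sprintf("dg_ph%g_kj", p)]] <-
      unname(vapply(rxns, delta_g_at_ph, 0, ph = p,
                    constants = constants))
  }
  out
}

# ATP bookkeeping -------------------------------------------------------------

glycolysis_steps <- function(route) {
  entry <- switch(route,
    hydrolytic = list(
      c("Amy", 0L, 0L),   # alpha-amylase: hydrolysis, no phosphate capture
      c("Glk", -1L, 0L)), # glucokinase spends one ATP on free glucose
    phosphorolytic = list(
      c("Pyg", 0L, 0L),   # glucan phosphorylase uses inorganic phosphate
      c("Pgm", 0L, 0L)))  # phosphoglucomutase: Glc-1-P -> Glc-6-P
  common <- list(
    c("Gpi", 0L, 0L),
    c("Pfk", -1L, 0L),
    c("Fba", 0L, 0L),
    c("Tpi", 0L, 0L),
    c("Gap", 0L, 2L),     # 2x glyceraldehyde-3-P oxidation -> 2 NADH
    c("Pgk", 2L, 0L),
    c("Gpm", 0L, 0L),
    c("Eno", 0L, 0L),
    c("Pk", 2L, 0L))
  steps <- c(entry, common)
  tibble::tibble(
    enzyme = vapply(steps, `[[`, "", 1L),
    atp_delta = as.integer(vapply(steps, `[[`, "", 2L)),
    nadh_delta = as.integer(vapply(steps, `[[`, "", 3L)))
}

#' Substrate-level ATP yield of glucan catabolic routes
#'
#' Per glucosyl unit fed into glycolysis, lists every enzymatic step with
#' its ATP and NADH increments and the net substrate-level ATP yield.
#' The hydrolytic route (alpha-amylase then glucokinase) spends one ATP
#' to phosphorylate free glucose; the phosphorolytic route (glucan
#' phosphorylase then phosphoglucomutase) captures inorganic phosphate
#' instead, so it saves that ATP: net +3 versus +2, a difference of one
#' ATP per glucosyl unit.  NADH is recorded but not converted into ATP
#' equivalents (the comparison is substrate-level only).
#'
#' @param route `"phosphorolytic"` or `"hydrolytic"`.
#' @return An `atp_ledger`: list with `route`, tibble `steps` (`enzyme`,
#'   `atp_delta`, `nadh_delta`) and integer `net_atp`.
#' @export
glycolysis_atp_yield <- function(route = c("phosphorolytic",
                                           "hydrolytic")) {
  route <- match.arg(route)
  steps <- glycolysis_steps(route)
  structure(list(route = route, steps = steps,
                 net_atp = sum(steps$atp_delta)),
            class = "atp_ledger")
}

#' @export
print.atp_ledger <- function(x, ...) {
  cat(sprintf("%s route: net %+d ATP per glucosyl unit (%+d NADH)\n",
              x$route, x$net_atp, sum(x$steps$nadh_delta)))
  invisible(x)
}

#' @rdname glycolysis_atp_yield
#' @return `atp_route_difference()` returns the net-ATP difference
#'   phosphorolytic minus hydrolytic (one ATP per glucosyl unit).
#' @export
atp_route_difference <- function() {
  glycolysis_atp_yield("phosphorolytic")$net_atp -
    glycolysis_atp_yield("hydrolytic")$net_atp
}
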