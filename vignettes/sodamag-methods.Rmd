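---
title: "Methods and design notes for sodamag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for sodamag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodamag)
```

`sodamag` implements the quantitative layer that sits between the heavy
upstream machinery of a shotgun-metagenome study (assembly, ORF
calling, redundancy removal, read mapping, binning, quality estimation,
KO annotation — all out of scope here; their outputs are this package's
inputs) and ecological interpretation. This vignette explains each
model, the tunable parameters and their defaults, the numerical
conventions, and the design decisions that were genuinely open.

## Gene-catalog profiling

A catalog gene is a (length, per-sample read count) pair. Two filters
precede everything else: genes shorter than **100 bp** are removed
(short ORFs are enriched for pseudogenes and mispredictions) and genes
with fewer than **2 reads** summed over all samples are removed (a
singleton read is as likely misassembly as signal). Both cutoffs are
deliberately *retaining* at the boundary — a 100 bp gene with exactly 2
reads stays — because the underlying conventions are phrased as strict
removals ("< 100 bp", "< 2 reads") and boundary behaviour must be
reproducible, not incidental.

The abundance of gene $g$ in sample $s$ is

$$a_{g,s} = \frac{r_{g,s} / L_g}{\sum_{g'} r_{g',s} / L_{g'}},$$

i.e. length-normalised counts renormalised to per-sample fractions.
Read "counts divided by gene length" admits two orderings
(normalise-then-close or close-then-normalise); they differ only by a
per-sample constant, which cancels in every downstream relative
quantity, so the fraction form is used as the canonical one. The
profile is consequently invariant to uniform read-depth scaling of any
sample, which the tests assert as a property.

Taxonomy assignment retains, per query, hits passing an e-value gate
($\le 10^{-5}$) whose bitscore lies within the top **10%** band of that
query's best hit, with an *inclusive* boundary (matching the `--top`
semantics of the common aligners: a hit at exactly 90% of the best
bitscore is kept). Ties for the best bitscore are all kept so results
cannot depend on input order. The gene's taxid is the lowest common
ancestor (LCA) of the retained hit taxids — the deepest node on the
intersection of their root paths; the implementation uses the longest
common prefix of root-aligned paths and is tested against an
independent ancestor-set-intersection oracle on random trees.

Rank-level (mOTU-style) profiles sum gene abundances into each
assignment's ancestor at the requested rank. Genes that are unassigned,
or whose LCA sits *above* the rank, go to `unclassified` rather than
being redistributed: conservative and mass-conserving (column sums are
preserved exactly, a tested invariant). Taxa never exceeding **0.1%**
in any sample are relabelled `other`. The 0.1% rule is applied
any-sample (a taxon is kept under its own name if it exceeds the
threshold *somewhere*); the per-sample alternative would make the
entity set sample-dependent, which a single matrix cannot represent.
Shannon diversity uses natural logarithms (the ecology convention; the
computation delegates to `vegan::diversity`), with all-zero samples
reported `NA` rather than 0 — absence of data is not zero diversity.

## MAG abundance and abundant taxa

MAG quality gates are strict inequalities exactly as conventionally
printed: completeness $> 50$ and contamination $< 10$ (near-complete:
$> 90$ / $< 5$). A boundary MAG at completeness 50.0 is excluded.

MAG abundance is the length-weighted mean contig coverage,
$A_{m,s} = \sum_i c_{i,s} l_i / G_m$ with $G_m = \sum_i l_i$ the genome
size *as binned* — no completeness correction, since the normalising
genome size in the defining formula is the assembled one. The weighted
mean is bracketed by the contig coverage extremes (tested property).

Abundant-taxon detection scales each sample's abundances so the maximum
is 100 and flags values strictly above **50**. "Same niche" is read as
"same sample" (the scaling is per sample); grouping samples by habitat
instead is possible by pre-aggregating columns. The calls depend only
on within-sample ratios, hence are invariant to per-sample rescaling —
raw coverage works as well as any depth-normalised variant, which is
why raw is the default (the choice only matters for the coverage-share
summary, where raw is reported). Ties at the maximum all score 100 and
are all flagged.

## Co-occurrence networks

Pearson correlations are computed on **raw** MAG abundances across all
samples jointly (not on scaled-to-100 values, which would distort
correlations through the per-sample maxima). Two-sided p-values come
from $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom. Edges
require $r > 0.9$ *and* $p < 0.01$, both strict. At the survey scale of
$n = 18$ samples, $r = 0.9$ gives $t = 8.26$ and $p \approx 2.6\times
10^{-7}$, so the correlation gate is the binding one; the p-gate
matters only for smaller surveys. p-values are deliberately *not*
multiple-testing adjusted by default — the stated procedure uses raw
thresholds — but `build_network(p_adjust_method=)` exposes
`stats::p.adjust` for users who want it. Compositional-correlation
corrections (SparCC-style) are out of scope.

Modules are connected components of the thresholded graph, named
`M1, M2, ...` by decreasing size with ties broken by the
lexicographically smallest member (determinism); nodes without edges
are `Uc`. Component extraction delegates to `igraph`; the tests compare
it against a hand-written union-find oracle exhaustively over all
4-node graphs and on random graphs up to 8 nodes. Group summaries add
raw abundance over module members and group samples; `Other` pools
user-designated small modules and `Uc` the isolated nodes, so the table
total equals the matrix total (conservation, tested).

## Metabolic potential rules

The rule engine is declarative: a YAML file maps pathway names to
boolean expressions over a closed marker vocabulary, compiled and
validated at load (unknown markers are a compile error naming the
marker). The shipped defaults encode the usual marker conventions: CBB
= prk & rbcL & rbcS; Wood–Ljungdahl = cooS & acsB & cdhD & cdhE;
sulfide oxidation = sqr | fccB; sulfite oxidation = soeA & soeB & soeC;
Sox thiosulfate oxidation = soxB & soxY & soxZ;
polysulfide/thiosulfate respiration = psrA_phsA; tetrathionate
respiration = ttrA & ttrB (ttrC is often unannotated, so presence of
the AB catalytic pair suffices); nitrogen fixation = nifH & nifD &
nifK. AND/OR rules are monotone — adding markers never turns a call off
(tested as a property). Gene symbols and KEGG Orthology ids are
interchangeable through a bundled synonym table.

Two rules carry special structure. The **DsrAB direction rule**:
carrying dsrAB alone does not reveal whether sulfite is being reduced
or sulfide oxidised; dsrD without the full dsrEFH trio marks the
reductive type, dsrEFH without dsrD the oxidative (reversed, rDsrAB)
type; both or neither is `ambiguous`, and missing dsrA/dsrB is `none`.
"dsrEFH" requires all three subunits by default (`efh_require = "any"`
relaxes it). The **DoxD caveat**: the quinone-dependent thiosulfate
dehydrogenase is a two-subunit enzyme, so a doxD-positive MAG lacking
doxA is called `ambiguous` with the note "DoxA absent" rather than
present. Both rules are tested against exhaustive truth tables over all
marker subsets.

**Glucan routes.** Phosphorolytic entry requires pyg (glucan
phosphorylase) and pgm (phosphoglucomutase); hydrolytic entry requires
amy and glk. Glycolysis completeness requires every step from hexose
phosphate to pyruvate: gpi, pfk, fba, tpi, gap, pgk, gpm, eno, pk.
An open design point was whether gpi and glk belong to "complete
glycolysis": the package requires **gpi** (both entries pass
glucose-6-phosphate, which must isomerise to fructose-6-phosphate) but
not **glk** for the phosphorolytic route (phosphorolysis bypasses free
glucose entirely), and the shipped nanohaloarchaeal archetype includes
gpi accordingly. A MAG with pyg but no pgm strands glucose-1-phosphate;
pgm is then listed among the missing steps.

## Bioenergetics

Reactions are parsed from `"A + 2B -> C + 3D"` strings (spaced `+`
separators; coefficients glued or spaced; protons written `H+`). The pH
correction adjusts proton activity only:

$$\Delta G(\mathrm{pH}) = \Delta G^{0\prime} - \nu\, m\,
(\mathrm{pH} - 7),$$

with $\nu$ the net proton yield and all non-proton species held at
standard/biochemical-standard states (water activity 1). The default
per-proton term is $m = 5.6867$ kJ mol$^{-1}$ pH$^{-1}$ — equivalently
17.06 kJ per proton across the 7→10 shift, the calibration used in the
soda-lake sulfur literature; it corresponds to $\ln(10)RT$ at about
297 K. The 25 °C textbook value (5.708) is available via
`ph_term_at_temperature(25)`. The function is linear in pH with slope
$-\nu m$ and returns $\Delta G^{0\prime}$ exactly at pH 7; reactions
releasing protons become strictly more exergonic as pH rises, which is
the thermodynamic argument for why elemental-sulfur respiration (five
protons released per acetate) pays off in alkaline brines while sulfate
reduction (zero net protons) does not change. Extended Debye–Hückel
activity corrections, van 't Hoff temperature dependence and carbonate
speciation are out of scope.

The ATP ledger records substrate-level phosphorylation per glucosyl
unit. Hydrolytic entry: Amy 0, Glk −1, then Pfk −1, Pgk +2, Pk +2 ⇒
net +2. Phosphorolytic entry: Pyg 0 (inorganic phosphate is captured),
Pgm 0, then the same core ⇒ net +3. The difference is one ATP per
glucosyl unit. NADH (+2 at Gap in both routes) is recorded but not
converted into ATP equivalents — the comparison is substrate-level
only, as respiration-free fermentative lifestyles are exactly the case
of interest.

## The synthetic community generator

The generator emulates the study conditions the pipeline targets:
**18 samples** in two habitats (9 brine + 9 sediment), **40 taxa** by
default with one MAG each, a few dominant and many rare taxa, planted
correlated pairs as the symbiont signal, gene counts proportional to
taxon abundance × gene length, hit tables consistent with a 5-rank
taxonomy (two species per genus, so decoy hits have a sister species),
and KO inventories cycled over five archetype templates (autotrophic
sulfur oxidiser, sulfate reducer, phosphorolytic nanohaloarchaeon,
amylolytic woesearchaeon, sqr-only heterotroph).

Abundances are log-normal: rare taxa $\mathrm{lognorm}(0, 1)$; the
5 dominant taxa follow a **dominance-tier** model — per sample, one top
taxon at $100\times\mathrm{lognorm}(0, 0.3)$ over the rare mass, and
each other dominant taxon either co-abundant (uniform 0.6–1.0 of the
top, probability 0.3) or sub-dominant (uniform 0.02–0.4). The tiers
exist so that the *ground-truth* abundant/not-abundant labels sit away
from the 50%-of-maximum decision boundary: under multiplicative
observation noise, labels of a continuum model would flip for
boundary-straddling taxa and "exact recovery" would measure label
ambiguity instead of pipeline fidelity.

Planted pairs (defaults: one pair at $\rho = 1.0$, one at
$\rho = 0.98$, placed among rare taxa) are constructed to hit the
target *sample* correlation exactly before noise, by standardising the
partner vector, mixing in an orthogonalised residual, and applying a
positive affine map (affine maps preserve Pearson correlation). The
ground-truth module partition is computed from the noise-free truth
abundance matrix itself, because co-occurrence is a deterministic
functional of abundances: with heavy-tailed profiles, a chance
super-threshold correlation between two non-planted taxa is genuine
truth-level structure, and the planted pairs guarantee their own edges
within that partition.

Gene read counts are drawn per sample as a multinomial over genes
(default depth $10^5$) with probabilities proportional to taxon
abundance × gene length ÷ the taxon's gene count — the division
distributes each taxon's read mass over its genes so that the
mOTU-style *sum* of length-normalised gene abundances recovers the
taxon profile exactly; without it the recovered profile would be
weighted by catalog gene counts. `count_model = "expected"` replaces
the multinomial draw by its exact expectation (real-valued counts):
multinomial sampling is itself noise, and the zero-noise closed loop —
every stage recovering ground truth to $10^{-9}$ — needs a noise-free
count mode. That mode deliberately relaxes the integer-count invariant
and is documented as a validation device. Contig coverage is
`coverage_scale` (default 30) × taxon abundance, optionally with
multiplicative log-normal noise; decoy hits, when enabled, target the
sister species at 95% of the true hit's bitscore — inside the top-10%
band — so the LCA falls back to the genus, exercising that code path.

All randomness flows from the single spec seed (`withr::with_seed`);
the same spec yields byte-identical outputs, including the emitted
files.

### What the synthetic tests do and do not show

The generator provides planted truth for every stage, so the test suite
can assert exact zero-noise recovery, stable abundant-set recovery
under 5% coverage noise (≥95% exact-set agreement over 100 seeds) and
planted-edge recovery (≥90% of seeds at $\rho = 0.98$), and calibrated
false-edge rates for independent profiles. It does **not** model
compositional coupling between taxa, sequencing-depth differences
between samples, assembly chimerism, binning contamination, or
phylogenetically structured gene content; conclusions about those
failure modes require real data. Dataset-scale headline numbers of a
real survey (hundreds of MAGs, dozens of abundant taxa, module counts)
are functions of hundreds of gigabases of reads and are not
reproducible at desk scale; the suite instead verifies the identical
decision rules and formulas on data whose truth is known.

### Problem sizes used by the test suite

Deliberate desk-scale choices: 40 taxa × 18 samples for closed-loop
runs (gene depth $10^6$ in the expected-count mode so that no gene
falls under the 2-read filter), 100 seeds for the noisy-recovery rates,
1000 random tree/hit-set instances for the LCA oracle comparison, 200
replicates for the network recovery calibration, and exhaustive
enumeration for the rule truth tables and small-graph module oracle.

## Error handling conventions

All package errors are classed (`sodamag_format_error`,
`sodamag_structural_error`, `sodamag_validation_error`,
`sodamag_parameter_error`, `sodamag_rule_error`, `sodamag_io_error`) so
callers can condition on failure mode. Readers never silently drop
lines: malformed input stops with the offending line numbers.
Degenerate inputs follow one rule — *absence of signal is represented
as absence, not as zero*: all-zero samples stay all-zero under
normalisation, produce no abundant calls (with a warning), and have
`NA` Shannon diversity; zero-variance profiles are excluded from
correlation with a warning; unresolvable hit taxids are dropped with a
count, and queries left hitless become `unassigned` rather than being
guessed.
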