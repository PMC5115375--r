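---
title: "Simulating molecular-beacon DNA logic circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating molecular-beacon DNA logic circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mblogic)
```

## The model

`mblogic` simulates arithmetic logic circuits built on a single molecular
beacon (MB). The physical system has two fluorescence channels: FAM reports
whether the beacon hairpin is closed (quenched) or opened by a hybridized
input strand, and NMM reports the assembly of G-quadruplexes (G-4), either
folded intramolecularly from four guanine tracts on one unpaired region or
assembled as a split G-4 from tracts on the two overhangs flanking a duplex
junction. Inputs are bits by presence/absence; both channels are decoded at
a constant threshold of 0.4 in a positive (high = 1) or negative
(high = 0) logic convention.

Three modelling decisions define the package:

1. **Gapless duplex model.** Hybridizations are contiguous antiparallel
   windows — no bulges or internal loops. The circuits rely only on
   designed contiguous complementary blocks, so an exact, enumerable window
   search is both sufficient and fully testable. Coordinates are 1-based
   closed intervals, the convention of the R sequence-analysis ecosystem.

2. **Ordinal thermodynamics.** Windows are scored with the unified
   Watson–Crick nearest-neighbor ΔG°37 stack table (packaged as a data
   file), a duplex initiation penalty, and *flat* mismatch penalties
   (+1.5 kcal/mol internal, +0.75 terminal, G·T wobbles included). The
   platform uses mismatches ordinally — to weaken beacon–input duplexes
   below input–input duplexes — so only the stability ordering matters;
   a flat penalty preserves every such ordering with a two-parameter
   surface, and full mismatch tables could be swapped in through
   `thermo_params()` without any API change. Temperature is fixed at the
   37 °C table; no salt correction. Absolute energies are therefore not
   meaningful, and nothing downstream consumes them except by comparison.
   The hairpin loop penalty is a monotone table for loops of 3–30 nt,
   constant beyond.

3. **Winner-take-all equilibrium.** With one equivalent of each strand,
   the resolved state is the minimum-total-free-energy *matching* on the
   strand graph: each strand joins at most one intermolecular duplex, an
   unmatched beacon closes into its most stable perfect terminal stem, and
   unmatched inputs stay free. This discrete abstraction mirrors how such
   platforms are engineered — the strongest designed duplex is meant to
   out-compete all side reactions outright — makes every
   output an exact integer, and admits an exhaustive oracle
   (`brute_force_state()`, which enumerates all matchings explicitly and
   is tested against the branch-and-bound solver on hundreds of random
   sets). Ties between equal-energy matchings are broken by the
   lexicographically smallest sorted pair-name key, and `best_duplex()`
   ties by the earliest window start, so every state is deterministic.
   Three-strand branched complexes are out of scope; no circuit here
   needs them.

The beacon counts as *open* exactly when it is matched to an input whose
duplex free energy beats the hairpin free energy (margin configurable,
default 0) — the direct reading of the hairpin/duplex competition.

## G-quadruplex counting

`count_g_quadruplexes()` scores the unpaired regions of a resolved state
with `g4_config()` defaults: tracts are maximal runs of ≥ 3 G; a
quadruplex needs 4 tracts.

* **Junction rule.** For each end of each duplex, tracts on the two
  flanking unpaired overhangs lying within 15 nt of the junction are
  pooled; the junction contributes one split G-4 when the pool reaches 4.
  One count per junction: proximity is what lets split tracts co-fold, and
  the cap prevents double counting.
* **Intramolecular rule.** Any unpaired region (overhang, loop, or free
  strand) holding 4 tracts within a 30-nt span contributes one G-4.
* **Consumption.** A tract folds into at most one quadruplex: tracts
  counted at a junction are not re-counted intramolecularly. Without this
  rule a single 4-tract cassette sitting next to a junction would count
  twice — once by each rule — and the half-subtractor row (0,1) would
  read NMM = 2 instead of 1.
* Paired positions never contribute: hybridization sequesters tracts,
  which is how the designs *silence* a cassette by covering it.

The full subtractor's two-input combination leaves one 4-tract cassette on
each end of the dominant duplex, giving two G-4 equivalents
(NMM = 2 > 1) — realized deliberately as one split G-4 per junction,
which is the arrangement consistent with all eight truth-table rows.

## Readout and decoding

Normalization is structural, not fitted: FAM is 1 when the beacon is open
and the leak fraction otherwise (0 in noiseless simulation); NMM is the
integer quadruplex count in units of one G-4/NMM equivalent. Experimental
spectra are not tabulated anywhere, so fitting them is neither possible
nor needed — the circuits only require signals to fall on the right side
of the threshold. Decoding uses a strict inequality at 0.4 (the threshold convention leaves
exact equality undefined; it is flagged ambiguous when the non-strict mode
is chosen). A `noise_config()` (closed-beacon FAM
leak 0.10, multiplicative Gaussian noise, sd 0.05) exists purely for
fixture realism; designed states sit ≥ 0.4 from the threshold, so decoded
tables are invariant over thousands of noisy replicates, which the test
suite checks.

## The designer

The original strand sequences are unavailable, so `design_strands()`
generates functional stand-ins by seeded propose-and-check: each proposal
instantiates a per-circuit template and `check_design()` accepts it only
if, for *every* input combination, the intended matching is the exhaustive
optimum with a free-energy margin (default 2 kcal/mol), the beacon opens
exactly in the intended rows, the G-4 counts match the intended plan, no
unintended near-complementary window of ≥ 12 bp with ≤ 1 mismatch exists,
and every beacon–input duplex embeds exactly the prescribed mismatch
count. Accepted designs provably pass `verify_circuit()` — the
designer-checker closure the tests exercise.

Template geometry (lengths are `design_constraints()` parameters):

* **Beacon**: 6-bp stem + 20-nt loop, stem resampled until the closed
  hairpin is clearly stable (< −2 kcal/mol). Inputs share one 16-nt
  beacon-binding site complementary to the loop, with 1 (two-input
  circuits) or 2 (three-input circuits) central mismatching substitutions —
  internal, because terminal mismatches barely destabilize.
* **Half adder**: input 1 carries the literal 5′ split segment `GGGT`,
  input 2 the literal 3′ segment `TGGGTGGGTGGG`; an 18-bp perfect block
  brings 1 + 3 = 4 tracts together at one junction of the input–input
  duplex.
* **Half subtractor / comparator**: input 2 carries an intramolecular
  4-tract cassette that its partner covers (silences) in the (1,1) row.
  The comparator is the same strand set read with FAM in the negative
  convention — EQUAL = XNOR — and NMM positive — LESS; GREATER is derived
  as neither.
* **Full adder**: asymmetric tract payloads (1/3 split per pair) placed
  immediately adjacent to each pairing block so that exactly one junction
  of each pair duplex qualifies; the 2–3 block is longer (24 vs 18 bp) so
  that with all three inputs present the 2·3 duplex dominates and input 1
  is left to open the beacon.
* **Full subtractor**: inputs 2 and 3 carry 4-tract cassettes with
  different spacers (`GGGT`- vs `GGGA`-repeats, so their complements are
  distinct) at their 3′ ends; input 1 carries the two covering
  anti-cassette blocks; the 2·3 block is 34 bp so it out-competes the
  strong G-rich covering duplexes in the (1,1,1) row.
* Non-structural sequence is drawn from {A, C, T} with `CCC` rejected, so
  neither a random region nor its complement can seed a spurious guanine
  tract; blocks abutting a tract payload on the partner strand are
  additionally constrained not to extend the tract across the paired
  boundary. Input strands run 38–82 nt — three-input strands must house a
  beacon site, two pairing blocks and junction-proximal payloads, which
  does not fit in a minimal oligo; all lengths are configurable.

Designs are deterministic per seed, different across seeds, and every
accepted seed yields the same decoded truth tables — which is why the
reproduction script's outputs are seed-invariant.

## What the synthetic data do and do not show

The simulator and fixtures reproduce the *logic* of the platform: species
competition, quadruplex counting, threshold decoding, truth tables and the
arithmetic identities. They do not model reaction kinetics, concentration
dependence, buffer or temperature effects, fluorescence spectra, or gel
migration, and the designed sequences are stand-ins, not the original
oligos. Passing tests therefore demonstrate the internal consistency of
the designed mechanism under the stated thermodynamic model, not a
quantitative prediction of any particular wet-lab trace.

## Problem sizes and numerical choices

The test suite designs each circuit once (strand sets of 3–4 strands,
32–82 nt), checks the matching solver against the exhaustive oracle on 200
random 2–6-strand sets, re-decodes every circuit row under 1,000 noisy
replicates, and verifies free energies against an independent
position-by-position oracle. Energy comparisons use a 1e-9 kcal/mol
tolerance before tie-breaking; window enumeration is exact, so no other
numerics are approximate. Degenerate inputs (empty sets, single strands,
beacons without a stable stem) resolve to free-strand states with zero
total energy rather than erroring.

## Known limitations

Single-copy stoichiometry (no concentration grading of inputs), at most
one intermolecular duplex per strand, no pseudoknots or secondary
structure beyond the terminal-stem hairpin and gapless duplexes, flat
mismatch energetics, and no wobble stabilization. These are deliberate:
each is either immaterial to the circuits' logic or explicitly out of
scope for a discrete equilibrium model.
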