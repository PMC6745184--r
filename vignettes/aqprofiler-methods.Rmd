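---
title: "Methods and design of aqprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of aqprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqprofiler)
```

This vignette explains what each stage of the aquaporin annotation
pipeline computes, which assumptions it makes, which knobs matter, and
where the design was genuinely open.

## Anchored feature extraction

Aquaporin function is read from a small set of pore-lining residues: the
two NPA motifs in loops B and E, the ar/R selectivity filter (one residue
each from TM helix 2 and TM helix 5, two from loop E), the five Froger's
positions discriminating water- from glycerol-transporters, and nine
specificity-determining positions (SDPs) associated with non-aqua
substrates. These residues have no fixed absolute coordinates — they must
be located by homology. The pipeline's central operation is therefore
*anchored projection*: align the query globally against function-known
reference aquaporins, pick the best-scoring reference, and carry that
reference's 20 curated feature positions through the alignment columns to
the query.

Design choices, and why:

* **Pairwise anchoring instead of a multiple alignment.** A single
  best-scoring anchor gives a deterministic, individually testable
  projection. For a family as conserved as the MIPs the pairwise and
  multiple-alignment projections agree wherever the anchor is from the
  right subfamily; the nearest-anchor rule ensures that. A star-MSA mode
  was considered and rejected as untestable against exact ground truth.
* **Scoring:** BLOSUM62 with affine gap penalties, opening 10 and
  extension 0.5 per residue — classic protein-alignment defaults. The
  alignment itself is delegated to `Biostrings::pairwiseAlignment`
  (Needleman–Wunsch with end-gap penalties); the test suite pins its
  scores to an exhaustive alignment-path enumeration for short pairs, so
  the scoring convention is verified, not assumed.
* **Gap rule:** a reference position aligned to a query gap is reported
  *unresolved* (`"-"`), never guessed. Downstream, unresolved SDPs count
  as mismatches but are reported separately — conservative and auditable.
* **NPA cross-check:** when the hydropathy segmentation yields exactly six
  TM segments, the loop-B/loop-E N-P-X scan must agree with the projected
  NPA positions; a discrepancy produces a warning and the projection wins.
  With fewer or more than six predicted segments the scan intervals are
  undefined and only projection is used.

## Physicochemical profile

* **Molecular weight**: sum of *average* (not monoisotopic) residue
  masses plus one water (18.015 Da), reported in kDa; the initiator Met is
  retained. This matches how family-survey tables are normally computed.
* **Isoelectric point**: the unique root of the Henderson–Hasselbalch net
  charge, which is continuous and strictly decreasing in pH, found by
  bisection on [0, 14] iterated to below 1e-8 pH (far below the 0.01
  reporting resolution). The default pK set is the Bjellqvist/ExPASy one,
  including residue-specific N-terminal pKs; an EMBOSS set is available
  via `aqp_config(pk_set = "emboss")`. The tests check bisection against
  an independent 0.001-step grid scan and against `seqinr::computePI`.
* **Transmembrane segments**: Kyte–Doolittle hydropathy averaged over a
  centred window of 19 residues; maximal runs of window centres above 1.6
  are merged when separated by fewer than 4 residues, expanded by the
  half-window, dropped when shorter than 15 residues and trimmed (centred
  on the hydropathy peak) when longer than 30. These are standard settings
  for TM helices; all five are exposed in `aqp_config()`. This predictor
  is a deliberately simple, fully specified hydropathy method — it
  predicts segment intervals, not topology or signal peptides.

## Classification and nomenclature

Distance is `1 − fractional identity` over aligned non-gap columns of the
global alignment — no substitution-model correction, because subfamily
assignment only needs an ordering of distances and identity keeps the
matrix interpretable. Assignment is *nearest reference*: the query
inherits subfamily and class from the closest anchor, with a support value
(margin to the closest anchor of any other subfamily). This replaces
manual clade reading of a drawn tree and is equivalent whenever
subfamilies form separated clades, which the synthetic panel guarantees
and real MIP families empirically show.

Trees come from an in-package Saitou–Nei neighbor joining: iteratively
join the pair minimizing $(n-2)\,d_{ij} - r_i - r_j$, with the standard
branch-length formulas and negative lengths clamped to zero; ties break by
current row order, so the topology is deterministic. The implementation is
validated three ways: closed-form three-taxon solutions, recovery of the
generating topology from additive matrices up to 8 taxa, and agreement
both with an exhaustive least-squares topology search (4–5 taxa) and with
`ape::nj` on perturbed matrices.

Proposed names follow `<prefix><class>;<index>`: the nearest reference's
index when unused, otherwise the smallest free positive integer in the
class — which is exactly how family surveys rename duplicated annotations,
and guarantees distinct names for queries sharing a nearest reference.

## Substrate rules

The six per-substrate SDP patterns (ammonia, boric acid, CO₂, H₂O₂,
silicic acid, urea) ship as a plain TSV of nine slash-delimited
allowed-residue sets each. The decision rule is: 0 mismatches → `member`;
up to `max_novel` mismatches → `member_novel` with the novel (position,
residue) reported; more → `non_member`. The default `max_novel = 1`
reflects how single-substitution rows are reported as "novel-type"
transporters in the field's tables, which never list two-mismatch members;
the threshold is exposed in `aqp_config()`.

The package bundles the published SDP residue strings for the 35
*Eutrema salsugineum* aquaporins (`esaqp_sdp_table()`). Feeding every row
through the rule engine reproduces each row's block membership, and the
seven rows flagged as novel sites come back as `member_novel` at the
flagged position — this is the module's primary fixture. One caveat is
recorded in the data rather than special-cased in code: the prose account
of one novel ammonia row places the substitution at SDP4, while the
printed residues mismatch at SDP5; the bundled table follows the printed
residues. The ar/R and Froger columns are reported descriptively (e.g.,
the water-type F-H-T-R filter of PIPs) but do not enter substrate calls,
whose basis is the SDPs alone.

## Expression quantification

`ΔCt` for organ profiles is defined as `Ct(reference) − Ct(gene)` so that
`2^ΔCt` *increases* with abundance; the subtraction order is a convention
choice documented here because raw assay descriptions often leave it
implicit. Stress responses use the standard `2^−ΔΔCt` against a control
sample. Replicates are averaged within (gene, sample); the generator
emulates three biological × three technical replicates, with biological
noise shared across a cDNA sample's technical replicates. Both statistics
are invariant to adding a constant to all Ct values of a sample (tested),
and missing cells in the expression matrix stay `NA`, never imputed.

## Oocyte water permeability

The swelling model treats the oocyte as a sphere whose cross-sectional
image area gives `r = sqrt(area/pi)`, with

$$P_f = \frac{V_0 \; d(V/V_0)/dt}{S_0 \, V_w \, (Osm_{in} - Osm_{out})}$$

where `Vw = 18 cm³ mol⁻¹`. The initial slope is an ordinary least-squares
fit of relative volume against time over the first 10 minutes (window
configurable). Units are deliberately consistent rather than converted:
with areas in cm², times in minutes and osmolality in osmol cm⁻³, Pf
comes out in cm min⁻¹ (divide by 60 for cm s⁻¹); a dimensional-consistency
test pins this. Pf is computed per oocyte and group statistics are taken
over the per-oocyte estimates (one-way ANOVA plus Fisher LSD on the pooled
mean square) — per-oocyte fits rather than pooled means, because the
between-oocyte variance is what the LSD test needs.

The initial-slope method linearizes a process in which the surface area
grows as the oocyte swells; the estimate is accurate while the relative
volume change within the window stays small. The simulator integrates the
same ODE (`dV/dt = Pf·S(V)·Vw·ΔOsm`, forward Euler, 0.25-min steps, fixed
osmotic gradient) under a 5-fold bath dilution of a 200 mOsm L⁻¹ interior;
at the planted permeabilities used in the tests (up to 5e-3 cm min⁻¹) the
10-minute volume change is below 1%, and the noise-free round trip
recovers Pf within 0.3%. At much higher permeability-to-gradient products
the window average overestimates the initial slope — that is a property of
the published formula itself, and users with fast-swelling oocytes should
shorten `pf_window_minutes`.

## What the synthetic data does and does not emulate

The generators exist to give every stage inputs with *known truth*:

* `make_reference_panel()` / `make_query()` build 290-residue
  aquaporin-like proteins on a fixed layout — six 21-residue hydrophobic
  segments, hydrophilic loops, and all 20 features planted at canonical
  positions. Subfamily masters diverge 25% from a common backbone;
  anchors 3% from their master; queries mutate only non-feature positions,
  within region-appropriate alphabets (hydrophobic in TM, hydrophilic in
  loops, proline excluded from loops so N-P-X occurs only where planted).
  Background composition is uniform within those alphabets — no claim of
  biological realism. What passing tests show is that extraction,
  classification and the rule engine are *correct on sequences satisfying
  their assumptions*; they do not show robustness to domain rearrangements,
  long indels, fragmentary models or compositional bias, which real
  surveys must still screen for.
* `make_swelling_series()` and `make_ct_table()` simulate exactly the
  models the estimators assume (spherical swelling with constant gradient;
  log-linear Ct with Gaussian replicate noise), so round-trip tests are
  consistency checks of estimator-under-its-own-model, plus unbiasedness
  under symmetric noise.
* Every generator is a pure function of its seed (replay-identical), and
  generated objects pass the validation of the modules that consume them.

## Problem sizes and numerical conventions

The test and verification runs use: 100 planted queries (mutation rates
0–10%) for feature recovery; 16 queries against an 8-anchor panel for
classification; 200 random sequences for the isoelectric-point oracle;
50 additive 4–5-taxon matrices for the neighbor-joining oracle (plus
random trees up to 8 taxa for topology recovery); sequence pairs up to
length 8 for the exhaustive alignment oracle; 10 oocytes per group at
0.2% area noise for Pf group detection; and 200 simulated Ct tables at
0.2-cycle noise for fold-recovery bias. Coordinates are 1-based inclusive
throughout; traceback and tie-break rules (first maximum in input order)
are fixed so that identical inputs and configuration give byte-identical
outputs.

## Known limitations

* Anchored extraction inherits the anchor set's quality: a query whose
  true subfamily is missing from the panel will be projected from the
  wrong anchor, usually visible as low support and unresolved features.
* The hydropathy TM predictor is intentionally minimal; highly polar
  pore-lining helices in real aquaporins can merge or split segments,
  which is why NPA identification falls back to projection whenever the
  segment count is not six.
* Substrate calls are sequence patterns, not transport measurements; they
  rank candidates for assays such as the oocyte experiment, they do not
  replace them.
* The NJ tree carries no bootstrap support values: nearest-reference
  assignment, not clade confidence, is the classification mechanism here,
  and the support margin reported with each call serves that purpose.
  When clade confidence itself matters, use dedicated phylogenetic
  tooling on the exported distance matrix or Newick tree.
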