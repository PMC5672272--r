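---
title: "Karyotype measurement, asymmetry and 5S rDNA repeat analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype measurement, asymmetry and 5S rDNA repeat analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyometry)
```

karyometry implements the desk half of a comparative plant cytogenetics
study: everything that happens after chromosomes have been measured on
metaphase micrographs and marker signals (fluorochrome bands, rDNA FISH
sites, genomic in situ hybridisation blocks) have been assigned to arms.
The worked reference throughout is the karyotype of the two cultivated
*Canavalia* species — sword bean (*C. gladiata*) and jack bean
(*C. ensiformis*) — whose published per-pair measurement table ships with
the package (`canavalia_karyotypes()`).

## From arm measurements to a karyotype table

The primary input is a per-metaphase, per-homolog table of short- and
long-arm lengths in micrometres (`read_plates()`). Two input conventions
matter and are deliberately *not* computed by the package, only documented
for the measurer: satellite lengths are included in the arm that carries
them, and stretched secondary-constriction lengths are excluded. Arm
orientation is normalised on read (long >= short, swapping rather than
rejecting), and each pair must appear as exactly two homologs per plate.

Within a plate, homologs are averaged to a haploid value and each arm is
expressed as a relative length (RL), a percentage of the haploid
complement length, making plates comparable regardless of condensation
(`relative_lengths()`). Aggregation across plates (`aggregate_karyotype()`)
reports per-pair means and sample SDs (n − 1 denominator everywhere; a
population SD would understate the spread of five-plate samples and does
not reproduce the published interchromosomal index values) of RL, the arm
ratio AR = long/short and the centromeric index CI = 100·short/total. Two
reporting choices are intentional:

* the per-plate AR is the ratio of homolog-averaged arms, and the reported
  `ar_mean` is the *mean of per-plate ratios*, not the ratio of mean arms —
  this matches how "arm ratio ± SD" columns of karyotype tables are built;
* pairs are renumbered 1..n by decreasing mean total RL (ties broken by
  input pair id, so output is deterministic), the convention for arranging
  a karyotype by size.

The total haploid complement length (TCL, µm) is summarised separately
over the *k* most condensed plates (`total_complement_length()`,
`condensation_rank` 1 = most condensed), because karyotype length is
conventionally measured on well-condensed spreads. The plates used for
the measurement SDs and for TCL are therefore independent selections; the
package does not force them to coincide.

## Classification and the karyotype formula

Centromere position follows the Levan arm-ratio categories
(`levan_type()`): m (1.00–1.70], sm (1.70–3.00], st (3.00–7.00], t
(> 7.00). Boundary values are assigned to the lower category — a
closed-on-the-left convention chosen purely for determinism; no value in
the reference table sits on a boundary, so the choice is not testable
against published data. The strict median-point class (AR exactly 1) is
folded into m. Classification uses the aggregated `ar_mean` of each pair,
matching the single "Type" column of published tables, rather than
classifying per plate. The formula string (`karyotype_formula()`) counts
chromosomes (two per pair) by type, with satellited pairs carrying a
`-SAT` suffix, e.g. `2n = 22 = 18m + 4m-SAT`.

## The six-index asymmetry profile

`asymmetry_profile()` reports the six statistics conventionally quoted
per species, all computed from the haploid per-pair table (one value per
pair), never across plates:

* mean CI ± SD across the n pairs;
* A1 = 1 − mean(1/AR), the intrachromosomal (centromere-position) index;
* A2 = sd/mean of chromosome lengths, the interchromosomal (size
  heterogeneity) index — a coefficient of variation, so RL and µm inputs
  give identical values;
* As K% = 100 · Σlong / Σtotal, the long-arm share of the complement;
* AI = CV(length) · CV(CI) / 100, which couples both axes of asymmetry.
  Being a product, AI vanishes when *either* CV does;
* the Stebbins grid: row by largest/smallest chromosome ratio (< 2, 2–4,
  > 4), column by the proportion of chromosomes with AR > 2 (0, up to a
  half, more than a half, all). Boundary values again fall to the lower
  row/column for determinism.

All SDs and CVs are sample statistics; this is what reproduces the
published A2 values (0.18/0.19) and AI (1.63) from the printed table. The
profile is reported at 2 decimals by default (`digits = 2`), matching
conventional reporting. A caveat the tests encode: indices recomputed
from a *rounded* printed table differ slightly from values computed on
the raw micrometre measurements; for the reference karyotypes the
recomputed mean CI lands within 0.1 of the published 42.78 and AI within
0.03 of the published 1.23, and the package's checks use exactly those
tolerances rather than pretending the printed table is the raw data.

## Marker positions and sizes

A marker site is located by its arm and the percent distance of its
middle from the centromere, di = 100·d/a, with a the satellite-inclusive
arm length (`di_percent()`), and sized as a percent of the karyotype
length of the same plate (`size_percent()`). `marker_summary()`
aggregates sites across plates into per-arm and per-pair means ± SD and
complement totals per marker kind. Centromeric sites (e.g. centromeric
fluorochrome bands) contribute their full extent to pair and complement
totals; only for the per-arm display columns are they split evenly
between arms, since published tables list them in a single column and
any per-arm attribution would be arbitrary. The split preserves the
invariant short-arm total + long-arm total = complement total.

## Idiograms

`render_idiogram()` draws the aggregated karyotype as an SVG document:
one bar per pair, short arm up, centromere constrictions aligned on a
common baseline, a left ordinate axis in RL percent, optional SD
whiskers, and marker glyphs placed at their di positions with heights
proportional to their size percent. Satellited arms are drawn with a
schematic detached block (12% of the arm by default) separated by a thin
secondary-constriction gap — schematic because the measurement convention
records satellite-inclusive arm lengths but not satellite or SC lengths
themselves; set `satellite_fraction = 0` for plain bars. Output is
deterministic (numbers serialised at fixed precision, no timestamps), so
two renders of the same input are byte-identical — which is also how the
tests verify it. SVG is the only output format: it is lossless, diffable
and assertable by element counts; rasterisation is left to external
tools. `autoplot()` provides a quick ggplot2 equivalent for interactive
work.

## 5S rDNA repeat units

PCR across tandem 5S rDNA repeats with primers annealing inside the
conserved ~120-bp gene yields amplicons flanked by 40 bp of the gene's
3' portion at one end and 58 bp of its 5' portion at the other. A minor
amplicon spans one repeat junction (40 + NTS + 58); a major amplicon
spans a full unit (40 + NTS1 + gene + NTS2 + 58). `dissect_amplicon()`
fixes the two flanks, finds the internal gene as the best ungapped match
to a 120-bp consensus (accepted at >= 90% identity; the matched segment
must start AGG and end TCC, the conserved gene boundaries), and labels
the remainders NTS1/NTS2. Coordinates are 1-based inclusive throughout,
the GenBank convention.

Spacer comparisons use the package's own global aligner
(`global_align()`), a plain affine-gap Needleman–Wunsch/Gotoh with
deterministic tie-breaking (diagonal, then vertical, then horizontal) and
defaults match +1, mismatch −1, gap open −4 (charged on the first gap
position), extension −1 — near the classic progressive-aligner defaults.
Columns are counted after trimming terminal-gap runs (primer-anchored
amplicons have no meaningful overhangs); internal gap columns count as
variable and as non-identity, which is forced by published conventions in
which the variable-site denominator can exceed both sequence lengths.
`compare_nts_pairs()` compares two repeat units region-to-region (5'NTS
vs 5'NTS, 3'NTS vs 3'NTS) and pools the two alignments' counts into a
combined identity — the interpretation under which a published
two-species NTS comparison over 736 columns (361 + 375) is reproducible.
Because exact aligner settings behind published identity values are
rarely stated, the package's acceptance check on the pooled identity
carries a ±1 percentage-point allowance.

`find_promoter()` scans the 120-bp gene for the RNA polymerase III
type-1 internal control region (A-box, intermediate element, C-box) by
ungapped consensus matching; motifs below threshold are flagged absent
rather than raising errors. The default motif set and the default
`gene_consensus_5s()` template are synthetic: the template is anchored on
the two published 5S primer footprints with fixed filler elsewhere, and
is not the sequence of any real accession. For real annotation work,
supply a reference gene's motifs. GenBank accessions on disk can be read
with `read_genbank_seq()` (a minimal local ORIGIN-block reader; the
package performs no network access).

## The synthetic-data generator

`simulate_plates()` emulates exactly the measurement structure the
pipeline assumes: a per-plate condensation factor uniform on
[0.85, 1.15] (TCL varies between spreads; RL and AR are invariant to
it), arms derived from true RL/AR/TCL, and independent multiplicative
lognormal noise per arm and homolog with CV `noise_cv`. Defaults are the
reference study conditions: 11 metacentric pairs with the published
*C. gladiata* RL and AR vectors, TCL 40.46 µm, five plates, satellites
on the short arms of pairs 6 and 7, noise CV 2% — chosen once because it
produces SD columns of the same order as the published table's, and the
default seed is fixed at 0. `simulate_amplicons()` builds major and
minor amplicons with configurable spacer lengths (default 361 bp), GC
content (62%, hit exactly by construction of the base pool) and
between-copy divergence (default 10%, the order observed between the two
spacers of a repeat unit).

What the generator does *not* emulate, and hence what passing
parameter-recovery tests cannot show: homolog misassignment, correlated
measurement error within a plate, condensation-dependent differential
contraction (real chromosomes do not shrink proportionally), stretched
secondary constrictions, or the mosaic of repeat families behind real
GISH signals. Recovery tests demonstrate that the estimators are
consistent under the stated error model, not that the error model is
complete.

## Problem sizes and numerical choices

The test-suite simulations use five plates of eleven pairs, alignments
of a few hundred bases, 200 random karyotypes for the index oracles, and
100 simulated amplicons for the dissection round-trip — sizes chosen to
mirror the actual study scale, where a karyotype rests on five measured
metaphases. Index oracle equivalence is asserted to 1e-9; exhaustive
alignment enumeration (an exponential-path oracle) is run at sequence
lengths up to 6, with an independent aligner implementation serving as
the cross-check at lengths up to 12. Degenerate inputs are defined
rather than left to chance: a single plate yields SD 0, single-pair
complements are Stebbins "1A", equal-armed complements give A1 = 0 and
As K% = 50, and boundary arm ratios classify to the lower Levan
category.

## Known limitations

* Homolog pairing is taken from the input table; karyotyping raw
  measurements into pairs (an image/signal task) is out of scope.
* Published per-site di values cannot be recomputed from published
  tables (raw d and a are not printed); di is validated structurally and
  against simulated ground truth only.
* The aligner is quadratic-time, pure R: fine for spacer-scale (<= 1 kb)
  comparisons, not for genomic alignment.
* Only pairwise NTS comparison is supported; multi-sequence alignment
  and phylogenetics are out of scope.
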