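---
title: "ITS-2 barcoding and CBC species delimitation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ITS-2 barcoding and CBC species delimitation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(its2cbc)
```

## The model

The internal transcribed spacer 2 (ITS-2) separates the 5.8S and LSU
rRNA genes and folds into a conserved four-helix structure. Because the
molecule functions through its pairing, substitutions at paired positions
are constrained: a change that destroys a pairing is usually compensated
by a second change in the partner base. When two lineages have diverged
long enough for such a **compensatory base change** (CBC) to fix — both
partners differing while the pairing is retained, e.g. A–U against
G–C — they are, on the evidence assembled for many eukaryote groups,
almost always distinct biological species. A **hemi-CBC** (one partner
changed, pairing retained, e.g. G–C against G·U) is a weaker signal that
accumulates both within and between species.

This package operationalizes that model. Per-strain dot-bracket
structures are converted to base-pair tables (`buildPairTable()`); a
majority-rule consensus (`consensusPairing()`) fixes which column pairs
constitute the structure; the conserved barcode region is read off the
consensus — the first 14 pairs of the 5.8S/LSU stem, the first 5 of
Helix I, the first 11 of Helix II (including its pyrimidine–pyrimidine
mismatch) and every Helix III pair, each block counted from the helix
base outward — and each pair becomes a code: A–U = 1, U–A = 2, G–C = 3,
C–G = 4, G·U = 5, U·G = 6, mismatched pairing = 7, and deleted, unpaired
or single bases = 8. With the default helix geometry (14/5/11/43) the
barcode spans 73 positions.

Two codes in 1–6 are compared by expanding them to their ordered
nucleotide pairs: both nucleotides differing is a CBC, exactly one a
hemi-CBC. Codes 7 and 8 and ambiguity-derived unknowns make a position
non-comparable — a missing or mismatched pair asserts no substitution
event — except that 7–7 and 8–8 are identical by convention and are never
counted as changes. Species are then the single-linkage connected
components of the zero-CBC relation: any chain of pairwise CBC-free
strains forms one species, and any off-diagonal CBC splits. Single
linkage cannot fail, but it can merge non-transitive triples (a–b and
b–c CBC-free while a–c carries a CBC); we flag these in
`conflictFlags()` rather than erroring, because the species-as-lineage
reading requires a partition while the analyst needs to see the
ambiguity.

## Position axis and the treatment of lost pairs

Barcodes are compared on the consensus position axis and are never
re-aligned. Each consensus barcode pair carries its two alignment
columns; a strain is coded at that position by its own bases when its
structure holds exactly that column pair, and by 8 otherwise. This
matters: if a strain has lost one helix pair, taking "the first *n*
pairs" of its own helix would shift every downstream code off the axis
and manufacture spurious CBCs. Anchoring to consensus coordinates keeps
a lost pair local — it becomes a single 8 — which is also why
within-species haplotype variants, which differ only by missing base
pairs, never show CBCs. When the consensus itself has fewer pairs than a
block's quota, the shortfall is padded with placeholder positions coded
8 for every strain, so all barcodes share one axis.

## Tunable parameters

* **Consensus threshold** (fraction, default 0.5): a column pair enters
  the consensus when at least this fraction of strains fold it; ties at
  the threshold are retained, so the rule is deterministic. The original
  consensus-building practice involved manual curation, which is not
  reproducible; strict majority is the transparent stand-in.
* **K/θ threshold** (default 4): a between-block mean p-distance more
  than four times the reference block's within diversity flags a
  candidate species pair, the conventional criterion for this ratio. θ
  uses the reference block only (not pooled) and results are reported
  per ordered pair, so both choices stay visible; singleton blocks and
  zero diversity yield an undefined ratio, not an error.
* **Screening thresholds** (percent): species-level identification
  requires 100 % identity at 100 % coverage; 97 % is the floor below
  which a hit is unassigned; V4-only evidence additionally needs 99 %
  before structure-level interpretation is attempted, because V4 alone
  resolves little below that. Identity is computed from a deterministic
  ends-free global alignment (match +1, mismatch −1, gap open −2, gap
  extend −0.5) with terminal overhangs excluded from the denominator,
  approximating the "100 % coverage" BLAST criterion; IUPAC ambiguity
  letters count as mismatches, the conservative reading for barcodes
  that must be accurate. Screening runs against a local, user-supplied
  reference panel: live database tallies are database-version-dependent
  and irreproducible.
* **Growth fit** (R² gate 0.95, window ≥ 4 points): the maximal growth
  rate is the largest slope of log-fluorescence over any contiguous
  window of at least four observations whose coefficient of
  determination reaches the gate, expressed per day. Curves with no
  passing window (or no positive slope) are flagged no-growth with
  μ = 0 rather than erroring, since a culture failing to grow at 3.3 %
  NaCl is a result, not a defect. Rates per strain and salinity are
  medians of the replicates (four in the reference design).
* **Sensitivity cutoffs** (default 33/66): the three response classes —
  robust, intermediately sensitive, sensitive — are named qualitatively
  in the source literature without numeric boundaries; the defaults are
  explicitly arbitrary thirds and are configurable.

## The sensitivity statistic

For each strain, decline = (best rate over the optimal salinities, 0.2
and 0.6 % NaCl) − (worst rate over the pessimal salinities, 1.8, 2.5 and
3.3 %), floored at zero; sensitivity = 100 × decline / decline of the
reference strain, so the reference (chosen as the most sensitive strain)
scores exactly 100. The published phrasing — decline "from 0.2 and
0.6 %, respectively, to ... 1.8, 2.5 and 3.3 %, respectively" — is
ambiguous about which salinity pairs with which; we take the extremal
reading (best optimal minus worst pessimal) and report the per-salinity
rates alongside, so any other pairing can be recomputed from the output.
The statistic is invariant to a common rescaling of all rates, which the
tests assert.

## What the simulators emulate — and what they do not

`simulateBarcodePanel()` plants a known truth into an ITS-2-like
molecule: a 14-pair closing stem, Helix I, Helix II with its
pyrimidine–pyrimidine mismatch (coded 7 in every strain), Helix III, and
random loops and spacers (174 alignment columns under the default
geometry). Each species receives *private, disjoint* CBC and HCBC
positions, so the truth count between species *i* and *j* is the
arithmetic sum of their private counts — checkable without running the
classifier under test. Within-species variants differ only by unpairing
planted positions (code 8), mirroring haplotypes that differ through
missing base pairs. The default spec — seven species with variant counts
(3, 1, 3, 1, 1, 1, 2), twelve haplotypes, a 73-position barcode — has
the shape of the study panel this workflow was developed on.
`simulateGrowthCurves()` draws N₀·e^{μt} trajectories with
multiplicative lognormal noise (σ = 0.05 by default) on a 24 h grid over
10 days, six salinities × four replicates. `simulateQuerySet()` mutates
panel sequences to within ±0.5 points of target identities, placing
substitutions on unpaired columns (or planting a coordinated
two-substitution CBC on demand) so the expected screening class is known
by construction.

The simulators deliberately do **not** model several features of real
data: indel evolution and alignment uncertainty (all strains share one
gap-free coordinate frame), base-composition bias (backbones are uniform
over A/C/G/U), folding ambiguity (structures are inputs, not
predictions), intra-genomic ITS copy variation, or growth phenomena
outside the exponential phase (lag, saturation, death). Passing the
round-trip tests therefore demonstrates that the implementation is
faithful to its definitions — not that those definitions are robust to
misalignment or mis-folded input structures, which remain the analyst's
responsibility.

## Numerical choices and degenerate inputs

* Neighbor joining breaks Q-matrix ties by the lowest (row, column)
  index and clamps negative branch lengths to zero, recording the total
  clamped deficit on the tree; both rules make trees reproducible. The
  distance between two barcodes is the normalized Hamming distance on
  comparable positions — unknowns excluded, 8-vs-8 excluded, 8 against a
  real code counted as a difference — the simplest symmetric choice, as
  no metric for number codes is established.
* p-distances exclude columns with a gap or ambiguity in either sequence
  from numerator and denominator; a pair with zero comparable columns is
  an error rather than a silent zero.
* Parsers reject rather than repair: unbalanced brackets, pseudoknot
  alphabets, duplicate ids, unequal aligned lengths and
  structure/sequence gap disagreements all raise typed conditions.
* All simulator randomness flows through a locally seeded RNG whose
  state is restored afterwards, so generators are pure functions of
  spec + seed and never perturb a session's random stream.

## Problem sizes used in the validation suite

The package's own validation (test suite and `scripts/acceptance.R`)
runs the default 12-strain panel across 20 seeds, 200 random additive
matrices of up to 12 taxa for the neighbor-joining property, 50
replicate growth curves at 5 % noise, and five 5-query screening panels
— sizes chosen to exercise every rule and average over seed variation
while keeping a full run in well under a minute per stage.

## Known limitations

Exact reproduction of a hand-curated consensus structure from per-strain
foldings is not guaranteed — manual edits are unrecoverable — so
consensus-dependent results should be read relative to the majority
rule stated here. The documented V4/V9 alignment positions (616–845,
1631–1737) span 230 and 107 columns although companion prose calls the
regions 229 and 106 bp; the positions are treated as authoritative and
the one-column discrepancy is surfaced here rather than silently
corrected. K/θ is reported as a diagnostic only; it does not feed the
partition, which rests on CBCs alone.
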