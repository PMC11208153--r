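---
title: "Detecting interspecific introgressions by windowed competitive mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting interspecific introgressions by windowed competitive mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestryscan)
```

## The model

An introgression is a chromosomal segment transferred from a donor species
into a recipient species' genome through hybridization and backcrossing.
Along an introgressed segment, a cultivar's sequence is essentially the
donor's haplotype; elsewhere it is essentially the recipient's. The scan
turns that dichotomy into a per-window vote: cut the cultivar genome into
overlapping fixed-length windows, align each window competitively against a
concatenated recipient+donor reference, and ask which origin wins on
alignment score (residue matches). Three complications shape the rest of
the pipeline:

* **Low-divergence regions.** Where recipient and donor are nearly
  identical, the vote is meaningless. Such regions are masked beforehand by
  mapping recipient windows onto the donor: 200 kb tiles where more than
  half of the 10 kb windows (5 kb overlap) exceed an identity threshold are
  excluded from classification.
* **Noise.** A single window's vote can flip through alignment noise or
  local gene conversion. Two published rules suppress it: a *seed* rule
  (at least 10 consecutive donor windows) and a *smoothing* rule (sliding
  50-window intervals scored as the percentage of decided windows voting
  donor, with ≥ 70% introgressed, 30–70% ambiguous, < 30% recipient).
* **Coordinates.** Calls on the cultivar are projected back to the
  recipient reference through a synteny map built from uniquely and
  collinearly mapped windows, interpolating linearly between anchors and
  splitting at target-sequence discontinuities.

## Window geometry

The base geometry is a 10 kb window. The synteny map uses a 7.5 kb overlap
(2.5 kb step); the low-divergence scan a 5 kb overlap. For the competitive
trio scan the literature phrase "2.5 kb overlapping windows" is ambiguous
between overlap = 2.5 kb (step 7.5 kb) and step = 2.5 kb (overlap 7.5 kb).
We use **step = 2.5 kb**: with a 7.5 kb step the ≥ 10-consecutive-window
seed rule could never call anything shorter than ~77.5 kb, while observed
introgressions run down to ~50 kb; a 2.5 kb step puts the seed floor at
32.5 kb, consistent with that size range. Both geometries remain available
through `window_spec()`.

Trailing partial windows are dropped rather than emitted short, so identity
and coverage thresholds mean the same thing everywhere.

## Seed blocks, smoothing, and how they combine

The two published rules are complementary and neither suffices alone. The
smoothing intervals span 132.5 kb of sequence; they can never push a block
shorter than ~35 windows over the 70% threshold, and at the edges of a true
block they erode roughly (70% − 50%) × 50 = 10 windows (25 kb) per side,
because an edge window's surrounding interval only reaches 70% donor well
inside the block. The seed rule has sharp edges but no tolerance for
occasional interruption. `final_blocks()` therefore classifies each window
by its nearest-centre smoothing interval **and forces windows inside seed
runs to introgressed**: the union keeps the smoothing rule's robustness in
noisy regions and the seed rule's edge precision. On planted 300 kb blocks
this recovers calls at Jaccard ≈ 0.97 versus ≈ 0.85 for smoothing alone —
the measured reason for the design.

Masked windows break seed runs and are excluded from smoothing intervals;
ambiguous and unmapped windows break seed runs and count toward an
interval's 50 windows but not toward its decided denominator. The
percentage uses decided windows only, because "mapped with a higher score"
presupposes a comparable mapping on both sides; counting undecided windows
would conflate divergence with ancestry.

The published ambiguity band "30 > % donor < 70" is read as
30 ≤ pct < 70 → ambiguous, pct < 30 → recipient: the only reading that
makes the three classes exhaustive and mutually exclusive.

## The mask threshold and divergence

With a substitution-only divergence `d`, a recipient window aligned to the
donor has expected identity `1 − d`. The mask's identity threshold `t`
discriminates only when `1 − d < t ≤ 1`; setting `t = 1 − d` exactly puts
the binomial mean on the threshold and masks half the genome by coin flip.
The conventional `t = 0.98` therefore presupposes species background
divergence clearly above 2% — true for the cotton species pair it comes
from. For other worlds we use the rule **t = 1 − d/2**, the midpoint
between background identity and 1: at the simulator's default `d = 0.01`
this gives `t = 0.995`; at `d = 0.03` (the mask-recovery test world)
`t = 0.985 ≈ 0.98`. The threshold is a visible parameter
(`lowdiv_identity`), fixed a priori from the stated divergence, never
tuned to results. The upstream double filter sometimes described
(import-filter at identity 0.99, then count windows above 0.98) collapses
here to the single mask-time threshold; semantics are unchanged for any
`t` at or above the import filter.

## The builtin aligner

Real analyses of multi-Gb assemblies should import minimap2 PAF via
`read_paf()`; the builtin aligner exists so that desk-scale synthetic
genomes exercise the identical downstream contract with no external
binaries. It anchors exact 25-mers between window and target (dense sorted
index; seeds occurring > 64 times are skipped, which silently shields
tandem repeat arrays), groups anchors into diagonal runs, chains runs by
dynamic programming under a 50 bp diagonal drift band and 2 kb query-gap
bound, then counts matches by direct ungapped comparison along the chained
diagonals extended to the window boundaries. Identity is exact for
substitution-only divergence, and degrades gracefully under the simulator's
optional small-indel mode. Window-side seeds are sampled every 5 bases
(`stride`), which changes anchor density only, never match counts. On a
200 kb fixture the builtin aligner and minimap2 (asm10, k = 25, w = 20)
agree on all window placements within 5 bp and on identities within 1e-4.

Score equals residue matches (PAF column 10) — the only score present in
every PAF dialect. Under `nhits = 1`, an exact tie for best is dropped
from the filtered set but recorded, so the competitive classifier can
label the window ambiguous instead of unmapped; in practice exact ties
occur where recipient and donor are locally identical, which is precisely
the ambiguous situation.

Collinearity pruning is an explicit reimplementation of neighbourhood
monotonicity (block size 5 in a window of 10 hits, consecutive target gaps
≤ 250 kb ≈ 100 steps) rather than a call to an external synteny tool whose
internals are unspecified.

## Centromeres, telomeres, composition

Diagnostic 25-mers are canonicalized over strands (tandem arrays occur in
both orientations) and must occur ≥ 25 times starting inside the known
array union and never start outside it. Occurrence coverage is the union
of occurrence spans — "cover" is a base-coverage statement, so overlaps
are not double counted. Density is profiled in 250 kb blocks stepped at
50 kb, and blocks at or above 2.04% coverage merge into centromere calls.
The calibration utility reads "fifth quantile of the minimum peak density"
as the 5th percentile (linear interpolation) of per-chromosome peak
densities — a conservative low end of the peak distribution; the exact
published semantics are not recoverable, so the value is a plain parameter.

Telomere defaults (terminal 1 kb, ≥ 10 motif copies) are ours; only the
four motifs are inherited. Ten exact 7-mer copies in 1 kb is orders of
magnitude above random expectation (~1 kb × 4⁻⁷ ≈ 0.06 expected).

Hierarchical composition assigns every base exactly one class by priority
exon > Ty3 > other repeat > intron > other, so per-window fractions sum to
1 by construction; overlapping intervals within a layer are pre-merged.

## Permutation test

The null preserves each interval's length and chromosome, draws starts
uniformly, and forbids self-overlap among placed intervals (rejection
sampling, 1000 attempts per interval) — the standard conservative null for
overlap enrichment. The p-value is the add-one estimator
(1 + exceedances)/(n_perm + 1), which never returns zero and is uniform
under the null up to discreteness; 200 null replicates at n_perm = 500
pass a Kolmogorov–Smirnov uniformity check comfortably.

## What the simulator does and does not emulate

`simulate_trio()` states a world: i.i.d. uniform background, substitution-
only divergence at a stated rate (default 1%, mirroring the 98–99%
identity regime the filters target), coordinate-preserving donor-block
replacement (so truth needs no liftover and classification accuracy is
isolated from projection accuracy — projection is tested separately with
constructed anchor maps), one random monomer tiled into planted centromere
arrays, telomere motifs overwritten onto termini (chromosome length stays
exactly as configured), and cultivar-private substitutions at 0.1%. The
default scale (3 × 1 Mb, ~400 windows per chromosome) is the smallest
world in which every rule — 50-window smoothing included — can operate
with margins.

It does **not** emulate: indel-rich divergence (an optional small-indel
mode exists for robustness tests only: geometric lengths of mean 2 bp at
10% of the substitution rate), realistic repeat landscapes or Ty1/Ty3
family structure, homoeologous subgenomes, segmental duplication, or
coalescent haplotype structure. A green recovery test therefore
establishes that the pipeline implements its stated rules correctly on
data obeying its model assumptions — not that those assumptions hold in
any particular real genome. The planted low-divergence segments in the
mask-recovery world are deliberately not aligned to the 200 kb tile grid;
tile quantization then bounds attainable per-segment mask coverage, which
is why recovery is scored on aggregate truth coverage (≥ 80%).

## Numerical conventions

* All internal coordinates are 0-based half-open (BED convention);
  1-based rendering only at report serialization.
* Alignment identity = matches / block length, so gap-compressed
  differences count against identity.
* Strict versus inclusive inequalities follow the sources: mask rules are
  strict (> 50%, > 98%), classification is inclusive at 70 and 30, the
  centromere density rule is inclusive (≥ 2.04%), the seed rule is
  inclusive (≥ 10).
* Printed-summary arithmetic fixes rounding per statistic: percentages,
  ratios and folds round half away from zero; rates and per-group means
  truncate. Each convention is unit-tested; they are deliberate, not
  incidental.
* Nearest-centre assignment of windows to smoothing intervals breaks ties
  to the left interval.

## Known limitations

* The competitive vote cannot identify the source of "fourth-class"
  segments where the cultivar matches neither parent well; such windows
  surface as ambiguous or unmapped, not as a separate class.
* The mask threshold must be chosen against the background divergence (see
  above); there is no automatic calibration.
* Projection interpolates linearly between 10 kb anchors; structural
  rearrangement inside an anchor gap is invisible at that resolution.
* The builtin aligner has no affine-gap model; for indel-rich real data
  the PAF import path is authoritative.
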