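---
title: "Comparing radically divergent mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing radically divergent mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## The problem

In bivalves with doubly uniparental inheritance (DUI), two mitochondrial
lineages coexist: the female-transmitted F-type genome and the
male-transmitted M-type genome. The two can diverge enormously — well
beyond the range where standard homology search is reliable — and M-type
genomes sometimes lack genes entirely, carry long unassigned open reading
frames (ORFs), extend canonical genes, and rearrange gene order.

Deciding what such a genome *contains* therefore turns into a statistics
problem. When the nucleotide p-distance between two sequences exceeds
roughly 0.6, an optimal aligner will manufacture substantial apparent
identity between any two sequences of similar composition, so "the ORF
aligns to *nad5* at p = 0.65" is not evidence of homology by itself. The
package operationalizes the comparison:

* extract and align candidate pairs under explicit, reported parameters;
* measure divergence as uncorrected p-distance and as the Tamura
  3-parameter (T92) distance, which corrects for transition/transversion
  and GC-content bias;
* rank each observed distance against a null built from shuffled
  sequences of identical composition and length, realigned with the same
  parameters;
* compare gene orders via breakpoint distance and an exact, depth-bounded
  search for a minimal scenario of block moves;
* profile divergence and compositional skew in sliding windows.

A synthetic mitogenome simulator with machine-checkable truth tags makes
every stage testable without any sequence download.

## Alignment model

`global_align()` computes a true global (end-gap-penalized) alignment
under an affine gap model: a gap of length $k$ costs
$\mathrm{open} + k \cdot \mathrm{extend}$. Both penalties default to 3,
the setting used for all reported divergences; nucleotide scoring is
+1/−1 match/mismatch and amino-acid scoring uses BLOSUM62 unless another
matrix is named. The dynamic programming is delegated to
`Biostrings::pairwiseAlignment()`, whose gap accounting was verified
against these semantics; the test suite additionally checks optimal
scores against an exhaustive enumeration of all alignments for short
random pairs, at default and non-default penalties and at both levels.

Terminal gaps are penalized deliberately. When one gene carries a long
3' extension, the extension should appear as a terminal gap run in a
global alignment — that is the signal being measured — rather than being
silently clipped as a local aligner would.

Because the optimum of an affine-gap objective is a *score*, distances
must travel with their parameters: every distance table emitted by the
package echoes the alignment level and penalties that produced it.

## Distances

`p_distance()` excludes every column with a gap or ambiguity (N at
nucleotide level, X at amino-acid level) in either row — pairwise
deletion — and reports the fraction of differing sites among those
compared, split for nucleotides into transitions $P$ (A/G, C/T) and
transversions $Q$ with $p = P + Q$. Complete deletion is available by
flag; for a single pair the two coincide.

`tamura3p()` computes, with $\theta$ the GC fraction pooled over the
compared sites of both sequences and $h = 2\theta(1-\theta)$,

$$d = -h \ln\!\left(1 - \frac{P}{h} - Q\right) - \frac{1-h}{2}\,\ln(1 - 2Q).$$

$\theta$ is pooled across both rows because that estimator is symmetric
in the pair. When a log argument is non-positive (saturation) or $h = 0$
the distance is undefined; the result then carries a `saturated` flag
rather than a number, and tables propagate `NA`. The closed form is
pinned in the tests by a frozen high-precision spot value and by the
inequality $d \ge p$ wherever defined, with $d \to p$ as $p \to 0$.

One numerical subtlety, visible in the tests: at extreme divergence
(p ≈ 0.5) the affine-gap optimum of two equal-length sequences is
occasionally *not* the gapless alignment — a gap pair can buy a few
chance matches. When positional homology is known (as in the simulator's
exact replay), divergence is therefore measured on the fixed-column
alignment; the optimizing aligner is the estimator for real data, where
positional homology is unknown. The two coincide at moderate divergence.

## Windows and skew tracks

`sliding_divergence()` slides a window (default 100 columns, step 25)
over an alignment and reports per-window p-distance under pairwise
deletion, `NA` where a window has no comparable site. It localizes
homology breakpoints — a gene pair homologous for its first ~1.5 kb and
unrelated beyond shows a step profile whose jump the tests require to
fall within one window step of the planted boundary.

`skew_profile()` reports AT-skew $(A-T)/(A+T)$, GC-skew $(G-C)/(G+C)$,
or GC content relative to the genome average, in windows (default 200
bp, step 25) that wrap the circular origin. "Relative to the genome
average" is implemented as the signed difference, not a ratio: it is
scale-free for plotting and behaves at zero. Windows with an empty
denominator yield `NA`. Site masks restrict counting to chosen classes
— `noncoding` (outside every annotated feature; structural-RNA positions
belong to no mask class), `codon1`, `codon2`, `codon3` (counted along
each coding feature's own reading direction) — for "neutral site" style
tracks, conventionally with a wider window (e.g. 1000 bp), which the
caller passes explicitly. No attempt is made to infer four-fold
degeneracy; the masks are deliberately explicit rather than clever.

## The randomization null for homology

`randomization_test()` asks whether an observed inter-sequence distance
is distinguishably *smaller* than distances to unrelated sequences of
the same composition. The null shuffles the residues of the second
sequence (preserving composition and length exactly), realigns with
identical parameters, and records the p-distance; the default scheme
shuffles only one sequence so the first remains the fixed reference.
Significance is the left-tail empirical p-value with add-one correction,
$p = (\#\{d_{null} \le d_{obs}\} + 1)/(n_{reps}+1)$, which can never
report an unattainable zero. The statistic is uncorrected p (not T92):
it is the primary divergence measure, and the correction's saturation
region overlaps exactly the distances the null is needed for.

`homology_screen()` runs the test over an ORF-by-gene grid (for an
M-type genome: each unassigned ORF against each complex I gene of the
reference) and calls a pair homology-supported only below a
Bonferroni-corrected alpha across the grid. The correction is
deliberately conservative: alignment optimization alone pulls observed
distances below the null mean, so an uncorrected 5% threshold over 21
pairs would be expected to fire spuriously about once per screen.
Shuffled replicates are realigned rather than scored on fixed columns —
the null must be given the same optimization opportunity as the
observed pair, or it would be biased toward detection.

Calibration and power are property-tested: on unrelated random 200-aa
pairs the test fires at no more than twice the nominal 5% rate, on true
homologs at amino-acid p-distance 0.30 (300 aa) it detects at ≥ 95%
power, and the empirical p of a shuffled pair is approximately uniform.

## Gene orders

`canonical_order()` turns an annotated genome into a signed circular
gene order, strand-normalized and rotated to an anchor gene (cox1), so
deposited records differing only in rotation or reported strand compare
equal. `breakpoint_distance()` counts strand-aware circular adjacencies
present in one order but not the other, after restricting to the shared
label set (genes absent from one genome — the nadh set, the ORFs — are
dropped and counted).

`minimal_scenario()` searches for a shortest sequence of operations
transforming one order into the other. The operation model is block
relocation (a contiguous block moves, internal order preserved) and
pairwise element swap, the two moves actually observed between these
genomes; inversions are available by flag but excluded by default. The
search is exact: iterative deepening over the depth budget (default
bound 4) guarantees the first solution found is minimal within the
model. Branches are pruned when the breakpoint distance to the target
exceeds 4 per remaining operation — a block relocation changes at most
3 adjacencies, a swap of non-adjacent elements 4, so 4 is the admissible
per-operation bound and the prune never discards a minimal solution.
Exhaustive bounded rearrangement search is exponential in general; the
depth bound reflects the scientific claim being tested (a small number
of steps), not a heuristic shortcut, and `achieved = FALSE` is the
honest saturation signal.

## The simulator

`simulate_f_genome()` and `derive_m_genome()` generate a matched pair of
circular ~19.5–20.5 kb genomes emulating the study conditions of an
F/M-type comparison: a shared core of six protein-coding genes, two
rRNAs and twenty-two tRNAs; per-gene observed divergence 0.45 (inside
the 0.4–0.7 range at which the analysis operates); three planted
non-homologous ORFs of 3999/951/849 bp; a 999 bp in-frame 3' extension
bringing cox1 from 1701 to 2700 bp; the seven nadh genes deleted from
the M-like copy; and three gene-order moves (a three-feature block
relocation, a single-tRNA relocation, and a tRNA swap). Sequence
composition is AT-rich (A 0.35, C 0.12, G 0.18, T 0.35), as in
invertebrate mtDNA.

Two constructions make the truth *sharp* instead of statistical:

* **Exact planting** (the default mutation mode) flips exactly
  `round(p·L)` distinct sites per retained gene, transitions chosen over
  transversions at ratio `kappa` (default 2), with substitutions that
  would create an in-frame stop redirected to another base so coding
  genes keep translating cleanly. Replaying the truth table against the
  emitted pair must reproduce each per-gene p to the digit, and does.
  A `stochastic_jc` mode (independent per-site substitution) exists to
  exercise saturation behaviour; it is checked against binomial bounds
  instead.
* **Frame salting.** Every intergenic spacer is woven with a 12 bp
  cassette carrying stop codons in all six reading frames, and planted
  ORF bodies periodically include a four-codon block that is stop-free
  in the reading frame but stops all five other frames. Consequently no
  spurious unassigned ORF ≥ 300 bp can arise in, across, or inside the
  planted features, each planted ORF is preceded by an in-frame stop so
  the scanner recovers its exact coordinates, and the "exactly three
  unassigned ORFs at exactly the planted coordinates" property is
  deterministic across seeds rather than merely likely.

The gene-order moves are a fixed plan rather than random draws: two
random moves can compose into one (or cancel), which would make "the
minimal scenario equals the planted count" a flaky assertion. With the
fixed plan the minimal count is a verified constant.

What the simulator does **not** emulate — and hence what passing tests
do not show about real data: tRNA/rRNA secondary structure (placeholders
are random sequence of realistic length), codon-usage and amino-acid
composition of real mitochondrial proteins, split genes (cox2 or rRNA
fragments with relocated parts; the GenBank reader's multi-interval
support is exercised by hand-built fixtures instead), length variation
of intergenic repeats, and sequencing or assembly error. Results on real
genomes additionally depend on annotation quality, which the pipeline
reads as given and never re-infers.

## Other conventions and defaults

* Coordinates are 0-based half-open internally; GenBank's 1-based
  inclusive intervals are converted once at the parsing boundary.
  Origin-spanning features are two-interval features, never negative
  coordinates.
* ORF scanning defaults to start codons {ATG, ATA, ATT, GTG} — a
  deliberate restriction of table 5's six initiators to curb spurious
  starts — with stops {TAA, TAG} and a 300 bp minimum; reported lengths
  include the stop codon. All are configurable, and within a frame,
  candidates sharing a stop reduce to the longest.
* An ORF is "unassigned" when its overlap with every annotated non-ORF
  feature is below half its own length, computed on circular
  coordinates ignoring strand.
* Ambiguity code N is accepted in sequences and excluded from every
  distance by pairwise deletion.
* All randomness flows from explicit integer seeds; per-stage seeds are
  derived arithmetically from one top-level seed, and identical
  configuration plus seed reproduces every output byte-identically.
* Alignment traceback ties are resolved by the deterministic traceback
  of the underlying dynamic program; tie-breaking affects which optimal
  alignment is reported, never the score, and distances on real data
  should be read with that ±1-column freedom in mind.

## Problem sizes in the checks

The test and acceptance suites run at desk scale, chosen to keep the
properties sharp while the whole suite stays fast: 200 random pairs of
length ≤ 8 for the alignment oracle; 9 kb sequences for exact-p
recovery at p ∈ {0.1, 0.3, 0.5}; 100 pairs each (200 aa unrelated,
300 aa homologous) for null calibration and power; 50 simulator seeds
for ORF-recovery; full ~30-element orders for the scenario search; and
one full simulated pair for the end-to-end pipeline. The numbered
scripts under `analysis/` run the same stages narratively and leave
their tables under `results/`.

## Known limitations

* The scenario search's operation model excludes inversions by default;
  a genome pair that truly evolved through inversions will report a
  larger relocation/swap count or saturate.
* T92 assumes stationarity and a single GC parameter across the pair;
  at the divergences where the homology null operates, the correction
  is frequently saturated and flagged rather than reported.
* The homology screen's verdict is calibrated under its own null
  (shuffled composition-preserving sequences). Compositional biases
  shared between non-homologous sequences — pervasive in AT-rich
  mitogenomes — make the null conservative in exactly the direction
  that avoids false homology claims, which is the intended asymmetry.
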