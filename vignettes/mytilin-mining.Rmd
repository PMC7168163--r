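---
title: "Mining and characterizing mytilin-like antimicrobial peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and characterizing mytilin-like antimicrobial peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mytikit)
library(dplyr)
```

## The biological problem

Mytilins are short cationic antimicrobial peptides (AMPs) of marine mussel
hemocytes. Like mussel defensins and myticins they adopt the
cysteine-stabilized alpha-helix/beta-sheet (CS-αβ) fold: one helix and two
antiparallel beta strands pinned by four disulfide bonds in a
C1–C5 / C2–C6 / C3–C7 / C4–C8 pattern. Their precursors are tripartite:

1. an N-terminal **signal peptide** (~20 aa, hydrophobic core, small
   residues at the −3/−1 cleavage positions);
2. the **mature peptide** (32–38 aa, cysteine-rich, net charge usually
   +2 to +13);
3. an **anionic C-terminal extension** thought to neutralize the mature
   region's charge until release.

Because primary sequence conservation across genera is weak, discovering
new family members in assembled transcriptomes needs an *iterative*
homology screen (hits join the query set until the search converges), and
a family-specific profile hidden Markov model is the natural long-term
detector. This package implements that workflow end to end, with every
stage testable against (a) the thirty mature peptides bundled in
`mytilin_matures()` and (b) a synthetic-data generator that emulates the
family's precursor statistics.

## The cysteine-array classifier

The canonical mytilin array is `C-x3-C-x3-C-x4-C-x11-C-x-C-x-C-x2-C`. Two
systematic deviations occur in nature and are modeled explicitly:

* **Alternative arrays** keep the C1–C4 block (`x3, x4` spacing) and the
  C6..C8 terminal block, but displace C5 from its canonical position
  (adjacent to C6, on the second beta strand) towards C4 (first beta
  strand). Notably, the span between C4 and C6 holds 12 non-structural
  residues in *both* layouts — the arrays differ by where C5 sits inside
  that span, which changes the topology of the C1–C5 bond.
* **CCC arrays** carry an extra cysteine between C6 and C7, producing a
  `CCC` triad whose middle cysteine cannot pair intra-molecularly (its
  side chain points away from the fold) and is reported as unpaired.

`detect_cysteine_arrays()` therefore searches 8-cysteine subsets (an `x`
may itself be a cysteine — required by a 10-cysteine *M. californianus*
mature with a canonical backbone) in leftmost-first order, trying a strict
canonical template, then a relaxed one
(`g1 = 3, g2 = 3, g3 ∈ [2, 6], g4 ∈ [6, 16], g5 = 1, g6 ≤ 2, g7 = 2`) that
tolerates the loop-size variation seen across genera (a 32-aa *Trichomya*
mature has a 2-residue C3–C4 loop yet the same fold), then the alternative
template (`g2 = 3, g3 = 4`, displaced C5, intact terminal block). A mature
whose cysteines match a canonical array truncated before C8 is flagged
(`missing_c8`) rather than rejected — one *P. viridis* sequence has
exactly this structure. Nine-cysteine arrays without a CCC triad can have
two sterically plausible C5 positions; `assign_disulfides()` then returns
both complete pairings.

## Physico-chemical profiling

`net_charge()` uses the plain counting rule (+1 for K/R, −1 for D/E;
histidine, cysteine, tyrosine and termini ignored). This is the unique
simple rule that reproduces the reported net charge of **all thirty**
bundled matures, which the test suite asserts exhaustively.
`isoelectric_point()` solves the Henderson–Hasselbalch charge balance
(side chains D/E/C/Y/H/K/R plus free termini, EMBOSS pKa values: N-term
8.6, C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1) by
bisection on pH ∈ [0, 14] to |charge| < 1e−4; an independent fine-grid
scan oracle checks it to 1e−3. `sliding_pi_profile()` (window 15 aa,
leading-edge indexed, plotted at window centers) makes the
cationic-to-anionic shift at the mature/C-tail junction visible,
`plot_pi_profile()` draws it with the segment boundaries.

## Alignment machinery

Pairwise global/local alignment uses BLOSUM62 with affine gaps
(open 11, extend 1; a gap of length L costs 11 + L) through
`Biostrings::pairwiseAlignment()`, validated against a brute-force
enumeration oracle for short sequences. Identity percentages divide by
*all* aligned columns, including gapped ones — stated explicitly because
reported identity values rarely define their denominator.

`progressive_msa()` is a deterministic guide-tree progressive aligner:
pairwise identity distances → UPGMA (average linkage) → leaf-to-root
profile merging with an affine-gap profile-profile Needleman–Wunsch whose
column score is the count-weighted mean BLOSUM62 score. No iterative
refinement is attempted; at the scale of tens of short peptides the
cysteine scaffold aligns into conserved columns, which is what the
downstream model needs (the test suite asserts eight fully conserved
cysteine columns for four co-specific matures).

## The profile HMM

`build_profile_hmm()` assigns alignment columns with gap fraction < 0.5 to
match states. Match emissions use Henikoff position-based weighting
applied per column — every residue occurrence in a column with `r`
distinct types, of a type shared by `s` rows, contributes `1/(r·s)`, so a
column's observed counts always sum to one and duplicating a row changes
nothing (the property the test suite asserts) — plus a
background-proportional pseudocount of total mass 1. Transitions use the
per-sequence Henikoff weights (column contributions summed per row,
normalized to mean one) on per-row state paths, Laplace-smoothed. The
background is the Robinson–Robinson amino-acid frequency set; scores are
log2-odds (bits) against it.

Two scoring modes exist, and the distinction matters scientifically:

* `mode = "global"` requires a begin-to-end path. It is the stricter
  statistic and the one the path-enumeration oracle checks exhaustively on
  toy models.
* `mode = "local"` (default for scanning) is a uniform-fragment model —
  entry at any match state with probability `2 / (M (M + 1))`, exit after
  any match state, unaligned flanks emitted at background odds. This
  mirrors how profile searches are actually run and is robust to
  sub-family architecture differences: an alternative-array mature should
  not pay begin-to-end indel penalties against a canonical-dominated
  model just because its C5 moved.

`calibrate_hmm()` fits a Gumbel distribution by moment matching
(`lambda = pi / (sd * sqrt(6))`, `mu = mean − gamma/lambda`) to Viterbi
scores of seeded random sequences of background composition with lengths
resampled from the training rows; E-values are
`n_db (1 − exp(−exp(−lambda (s − mu))))`, so the median null score lands
near `n_db / 2` by construction. Moment matching was chosen over maximum
likelihood for dependency-free determinism. `dual_screen()` implements the
paired mytilin-vs-myticin screening rule: a peptide is labeled by the
model with the smaller E-value among those below 0.05, or `none` — a
single family model alone can pull in structurally related CS-αβ peptides
near the significance threshold, so the second model is what restores
discrimination.

## The iterative screen

`six_frame_orfs()` enumerates complete ATG..stop ORFs (≥ 60 aa) on all six
frames, collapsing nested starts to the longest ORF per stop, and mapping
reverse-strand hits to forward coordinates with negative frames. A leading
CTG/TTG is translated as leucine, not as an initiator methionine, so ORF
starts are exact.

`iterative_screen()` aligns every seed's **mature region** (the conserved
module — signal peptides and acidic tails carry mostly compositional
signal) against every candidate ORF translation with Smith–Waterman, and
thresholds an approximate E-value `K·m·n·exp(−lambda·S)`
(`K = 0.041`, `lambda = 0.267`, BLOSUM62-style constants) at 1e−3, where
`m` is the query length and `n` the *total translated database size* —
the sum of candidate ORF lengths, as translated database searches do.
Accepted ORFs are segmented by alignment to their best seed, gated on a
mytilin-classifiable (canonical or alternative) cysteine array in the
mature region — the reproducible stand-in for a manual "confirm the family
assignment by alignment" step — and join the seed list; iteration stops
when a pass adds nothing (or at `max_iter = 20`, with a warning). Decoy
ORFs that sneak past the score threshold are rejected by the array gate,
which is why the screen's precision does not degrade with corpus size.
Overlapping ORFs are resolved by keeping the longest per (transcript,
frame) cluster. `novelty_filter()` applies the strict <95%-identity
novelty rule against a set of known peptides.

## Segmentation

`predict_signal_cleavage()` scans candidate cleavage positions 15–30 and
scores hydrophobic-core content (residues among A/I/L/V/F/M/W in the 11
positions before the candidate) plus small-residue bonuses at −1
(A/G/S/C, +2) and −3 (A/G/S/V/C, +1), breaking ties towards position 20 —
a von Heijne-style (3, −1) rule without a trained model. Candidates whose
core holds fewer than five hydrophobic residues are rejected; if none
qualifies the sequence has "no plausible signal peptide".

The mature/C-tail boundary is never called ab initio: it is mapped through
a global alignment to an annotated reference (`segment_by_alignment()`),
with boundaries landing on query gaps snapped towards the mature-region
interior, and references below 25% identity refused. For heterogeneous
sets, one annotated reference per sub-family is the intended usage — a
cross-family reference can fall below the identity floor, exactly as a
too-distant reference should.

## The synthetic-data generator

`synth_cohort()` emulates the family's statistics so every downstream
stage has ground truth:

* **Two diverged families** (*Mytilus*-like: 60% of the cohort, canonical
  arrays dominant, mature charge target +7; *Perna*-like: alternative/CCC
  arrays dominant, charge target +3), each derived from a family ancestor
  by per-site filler mutation (rate 0.3). Kind proportions are allocated
  deterministically and interleaved, so any split of the cohort sees every
  array kind.
* **Scaffold-anchored homology.** Filler residues are organized in
  segments anchored at the structural cysteines (prefix, the three
  N-terminal loops, the 12-residue C4..C6 span with C5 embedded at a
  kind-dependent offset, the C6–C7 loop — replaced by the extra cysteine
  in CCC arrays — and the terminal loop). Homologous positions therefore
  flank the same cysteines across kinds, as in real families, and a
  multiple alignment of a mixed cohort aligns the scaffold correctly.
  Length variation (32–38 aa) goes into the prefix ahead of C1, keeping
  the C-terminus anchored at C8 as in the real matures.
* **Exact targets.** Mature and C-tail net charges are driven exactly to
  their (jittered) targets by a charge-adjustment pass whose replacement
  positions come from the seeded RNG stream — not from a fixed scan order,
  which would stamp identical cationic hotspots onto every sequence and
  fabricate similarity.
* **Signal peptides** place the hydrophobic core (I/L/F/M/W only — A and V
  are excluded there so the −3/−1 bonuses stay unique to the true site) at
  positions (len−12)..(len−3), making the true cleavage site the score
  maximum of the heuristic by construction.
* **Decoys**: residue shuffles of cohort matures (hardest composition
  controls), plus myticin-like and defensin-like templates with fixed
  cysteine spacings, (4,3,4,7,0,3,4) and (5,3,3,9,1,4,2), that match
  neither mytilin template.
* **Transcripts** embed back-translated precursors (fixed
  most-frequent-codon table, TAA stop) between random untranslated flanks
  stripped of ATG/CAT so recorded ORF starts are the true leftmost starts;
  a third of the embeddings go on the reverse strand.

What the generator does *not* emulate: real codon usage, sequencing or
assembly error, alternative splicing, allelic variation, and real
inter-family sequence composition. Passing the synthetic benchmarks
therefore demonstrates algorithmic correctness under the family's
statistical structure, not performance on raw field data.

`synth_chained_corpus()` builds the corpus that proves iteration matters:
five close homologs share the seed's N-terminal mature block (C1..C4) with
fresh C-terminal blocks; three remote homologs carry a close homolog's
C-terminal block behind a fresh N-terminal block with a shortened C3–C4
loop and different signal-peptide/tail lengths. Remotes thus align
strongly only to their parent close homolog — a single-pass search accepts
only the close tier, while the iterative screen recovers all eight.

## Benchmark experiments and problem sizes

The test suite and `scripts/acceptance.R` run, at fixed seeds:

* the thirty-row reproduction of net charges, the Perna CCC census
  (13 of 15) and maximum charge (+11), and the length validator that must
  flag the two documented inconsistencies (a 34-residue sequence printed
  with length 43; a 38-residue sequence described as 39 aa in text);
* profile-HMM separation: a 60-mytilin cohort split 30 train / 30
  held-out, scored against 60 decoys — the ranking must separate the
  groups perfectly (empirical AUC 1.0);
* screen recall/precision 100%/100% on the chained-divergence corpus;
* segmentation recovery within ±1 residue for ≥90% of a 50-precursor
  cohort (heuristic signal-peptide call + alignment-mapped mature end,
  one reference per family);
* Hobohm-2 post-condition (no retained pair under the 0.1 threshold) on
  one hundred random 20-vertex graphs, with a greedy-replay oracle;
* exhaustive-enumeration oracles for the alignment DP (lengths ≤ 6
  global, ≤ 5 local) and the profile-HMM forward/Viterbi recursions
  (M ≤ 3, sequences ≤ 4, both scoring modes);
* exact neighbor-joining recovery of random additive 4–6 taxon trees,
  cross-checked against an independent NJ implementation.

These sizes keep the default suite fast while leaving each check
statistically meaningful; all are regenerated in code at run time.

## Numerical and design choices

* BLOSUM62 + gap 11/1 is the single source of truth wherever a matrix is
  unstated; the redundancy distance `1 − S(a,b)/min(S(a,a), S(b,b))` is
  normalized by the smaller self-score so identity gives 0 and the measure
  stays in [0, 1].
* Hobohm-2 ties (equal neighbor counts) remove the lexicographically
  greatest id; the algorithm itself does not prescribe a tie-break, and
  reproducibility requires one.
* Neighbor joining breaks minimal-Q ties towards the smallest sorted pair
  of cluster ids and clamps negative branch lengths to zero (with a
  message). Bayesian inference, model selection and posterior supports are
  deliberately out of scope: NJ is deterministic, exact on additive
  matrices, and sufficient for clade-level claims on synthetic data.
* The CCC middle cysteine is excluded from the structural eight *before*
  template matching, via leftmost-subset preference rather than a special
  case: dropping the middle cysteine is the only choice that matches the
  terminal-block spacing.
* Degenerate inputs: empty sequences are I/O errors; matures with fewer
  than two cysteines classify noncanonical with empty pairings;
  single-sequence "alignments" are 1-row MSAs; single-value pI profiles
  cover sequences shorter than the window.

## Known limitations

* The signal-peptide heuristic is a scoring rule, not a trained model; on
  real precursors a dedicated predictor remains preferable.
* The screen's E-value is a fixed-constant Karlin–Altschul approximation,
  adequate for thresholding at 1e−3, not a calibrated statistic.
* The profile HMM does not implement hmmer's multi-hit model, null2
  correction or its exact E-value calibration, so bit scores and E-values
  are not comparable to hmmer output number-for-number.
* Identity percentages against alignments produced by other programs will
  differ with the aligner's column choices; reported cross-study identity
  values should be treated as approximate.
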