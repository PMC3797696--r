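---
title: "Methods: chromosome-centered somatic lesion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome-centered somatic lesion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromscan)
```

This vignette documents the models, parameter choices and numerical
conventions behind `chromscan`, and states what the synthetic-data tests
do and do not establish about real data.

## Data model and coordinate conventions

All genomic intervals are **0-based half-open** in memory and in segment
and BED files; per-base depth files and variant positions are **1-based**
on disk (matching `samtools depth` and variant-table conventions) and
converted at the I/O boundary. This makes interval arithmetic (overlap,
length, adjacency) free of off-by-one cases; the only conversions happen
in readers and writers, which are round-trip tested.

Readers reject out-of-contract input rather than coercing it, and every
parse or validation error names the offending line. Depth tracks are
sparse: a position absent from the file stays absent, it is never
zero-filled, so integer depth totals are preserved exactly.

Chromosome names are matched as literal strings; no `chr`-prefix
normalisation is attempted.

## Exact association test

Lesion–phenotype association uses Fisher's exact test computed from
hypergeometric point probabilities. For a 2×2 table with margins fixed,
the probability of each table is computed in log space via `lchoose()`
(no overflow for any realistic cohort), and the two-sided p-value follows
the **minimum-likelihood rule**: the sum of the probabilities of all
tables whose point probability does not exceed the observed one, with a
relative tie tolerance of `1e-7`. This is the convention of the widely
used exact-test calculators and of `stats::fisher.test`, which serves as
an independent cross-check in the test suite (the implementation itself
never calls it). Final p-values are clamped to [0, 1].

Both one-sided tails are reported. Note that a fixed-direction one-sided
p-value is *not* bounded by the two-sided p-value: when the observed cell
lies below the mode of the hypergeometric distribution the upper tail
approaches 1 while the minimum-likelihood two-sided p is small. The
guaranteed relation, asserted in the tests, is
`min(p_lower, p_upper) <= p_two_sided`.

The odds ratio is the sample ratio `ad/bc`, reported as infinite when
`bc = 0`; no confidence interval or mid-p correction is attempted.

### Counting units

The default counting unit is the **sample**; a cohort can also be counted
per **patient**, in which case a patient with two lesion-bearing samples
contributes once and takes the diagnosis of its first-listed sample.
Whether published association tests of this kind were computed per sample
or per patient is usually unstated; both groupings are exposed so the
choice is explicit. Grouping for the leukemic-transformation contrast
treats myelofibrotic and accelerated-phase MPN samples as chronic phase
(they have not transformed to AML); the mapping lives in a data table
(`mpn_phase_map()`), not in code.

### Recurrence deduplication

When several samples of one patient were profiled, a persistent lesion
appears once per sample. `dedupe_recurrent()` collapses same-kind,
same-chromosome segments from different samples of one patient when their
reciprocal overlap is at least 0.9, keeping the earliest sample's
coordinates. The threshold is a judgement call — published lesion plots
show recurrence only visually — and 0.9 collapses re-detections of the
same event while keeping genuinely nested or shifted lesions distinct.
Cross-patient merging never happens.

## Common deleted regions

The support profile formalises the visual stacking of lesion bars: for
one lesion kind, the number of distinct samples covering each base.
Same-sample overlapping segments are merged first, so a sample
contributes at most 1 per base. The profile is computed by an event-point
sweep over segment boundaries (O(n log n)); the test suite proves it
equal to per-base brute-force counting on random instances.

A **CDR** is a maximal run of breakpoint intervals with a common covering
sample set whose support is (a) at least `min_support` (default 2, the
smallest count that makes a region "common") and (b) strictly greater
than the support of both flanking intervals. This "locally maximal
support" definition reproduces the *minimal common region* reading of
stacked deletion plots: each cluster of overlapping deletions contributes
the core interval shared by the most samples. Two consequences are worth
noting:

* adjacent plateaus of equal support but different covering sets are not
  merged and neither is reported (neither is a strict local maximum);
  this tie case is essentially a coin-flip boundary and flagging nothing
  is the conservative choice;
* extending any reported CDR by one breakpoint provably reduces its
  support, which the tests verify directly with the per-base oracle.

Gene annotation attaches every gene model overlapping a CDR by ≥ 1 bp, in
genomic order. Statistical significance of CDRs (GISTIC-style q-values)
is out of scope; the association of a CDR with a phenotype can be tested
with `associate_lesions()` and a region predicate.

Profiles for gains and UPDs use the same machinery via the `kind`
argument.

## Focal copy-number calling from exome coverage

The caller follows the chromosome-normalised control-pool design:

1. **Normalisation**: each sample's per-base depth is divided by the
   summed depth over all bases of the analysed chromosome in that sample.
   Normalisation is deliberately per-chromosome, not genome-wide — the
   analysis is chromosome-centered and this keeps a single aneuploidy
   elsewhere in the genome from shifting every ratio.
2. **Reference**: the per-position median of ≥ 3 (default pool size 8)
   normalised controls, at positions present in every control. Controls
   must carry a wild-type copy of the chromosome and share the library
   chemistry of the case — one pool per chemistry batch.
3. **Ratio**: `log2(case / reference)` at shared positions. The default
   `pseudocount = 0` masks positions where either track is zero rather
   than adding a constant: normalised per-position values are of order
   1/(number of covered positions), so any pseudocount of comparable size
   would compress true ratios (a 1.5× duplication would fall from
   log2(1.5) ≈ 0.585 toward log2(1.25) ≈ 0.32 and under the calling
   threshold). A positive pseudocount remains available and should stay
   well below the typical normalised value.
4. **Calling**: restricted to targeted bases, the ratio is smoothed by a
   running median over 51 positions (index space over the ordered
   targeted positions — the natural neighbourhood for sparse exome
   coverage), and maximal runs with |smoothed ratio| ≥ 0.4 and consistent
   sign are reported. Runs of the same sign separated by ≤ 50 targeted
   positions merge; runs shorter than 100 positions are dropped. The 0.4
   threshold sits between 0 and the fully clonal heterozygous-duplication
   expectation 0.585; 100 positions is well below a single ~500 bp exon
   so a one-exon event is callable, yet large enough that median-smoothed
   noise at 20× depth essentially never sustains a run. All four values
   are configuration, not constants; no published threshold exists for
   this design, so these defaults are the package's own and are recorded
   in the run manifest.

Call boundaries always lie on observed positions and calls never extend
outside targets. The closed-form expectations (log2 1.5× ≈ 0.585,
hemizygous deletion ≈ −1) are recovered on synthetic spikes at 100×
within ±0.05 and ±0.1 respectively. One geometric caveat, visible in the
tests: with chromosome-total normalisation the spike itself inflates the
normaliser by its share of total coverage, so on a very small target
panel the in-spike ratio is biased low; the effect scales with
(spike length)/(panel length) and is negligible on a real exome. The
synthetic panels used for calibration therefore contain ~100 targets
(~26 kb), keeping the bias below 0.02.

## Residue-level annotation

`annotate_tandem_duplication()` distinguishes frameshifts (length not a
multiple of 3), codon-aligned in-frame duplications (whole-residue span
reported, e.g. a 513 nt duplication starting at a codon boundary at
residue 528 duplicates residues 528–698), and codon-internal in-frame
duplications, which create novel codons at the shifted junction and are
reported as insertions. The insertion is located by translating the
mutated CDS and taking the longest common prefix with the reference
protein; repeats therefore resolve to the most C-terminal placement, the
HGVS convention (the canonical 6 nt example inserts Val-Asp after residue
390). The full-translation route doubles as the test oracle for the
codon-aligned case.

Only the standard genetic code is supported (no selenocysteine or
alternative codes); translation uses plain codon-table semantics with no
initiator-codon special-casing, so a variant at codon 1 reports e.g.
`M1V`. Protein positions are 1-based including the initiator methionine.
Genome-to-CDS liftover across introns is out of scope: the annotator
works on a user-supplied CDS, and no reference transcript sequence is
bundled.

## Dosage-mechanism classification

At a locus with `k` total copies, `m` of them mutant, in a clone
comprising fraction `c` of cells (the rest diploid wild type), the
expected VAF is `m·c / (k·c + 2(1 − c))`. Each mechanism fixes `(k, m)`:

| mechanism | k | m | VAF at c = 1 |
|---|---|---|---|
| heterozygous | 2 | 1 | 1/2 |
| UPD_homozygous | 2 | 2 | 1 |
| gain_amplified_mutant | 3 | 2 | 2/3 |
| gain_retained_wildtype | 3 | 1 | 1/3 |
| hemizygous_deleted_locus | 1 | 1 | 1 |

The candidate set depends on the lesion kind overlapping the variant:
`none` admits only the heterozygous state; `UPD` admits the homozygous
state plus a lesion-independent heterozygote; `GAIN` admits the two
three-copy states (with three copies the locus has no 1/2 state); `DEL`
admits the hemizygous state plus a lesion-independent heterozygote.
Candidates are scored by the binomial log-likelihood of the alternate
read count; when clonality is unknown it is profiled over a grid
(0.05–1.00, step 0.05, the resolution justified by read depths of
~20–100). Model VAFs are shrunk into `[err, 1 − err]` with `err = 0.01`
so that a fully clonal homozygote retains finite likelihood when a stray
reference read appears — without the floor, a single reference read would
veto the homozygous state outright.

A call is `ambiguous` when the winner beats the runner-up by less than
2 natural-log units (≈ e² likelihood ratio). The margin prevents
overcalling at the 1/2 vs 2/3 boundary at moderate depth, and correctly
declares the genuinely unidentifiable cases — a VAF of 0.5 inside a UPD
fits both a clonal heterozygote and a half-clonal homozygote, and no read
count can separate them. At depth 80 and full clonality every class is
recovered with ≥ 95% accuracy (tested over 5 seeds × 500 variants per
class); at clonality 0.5 the states converge and accuracy degrades — this
is reported by a test but deliberately not asserted against a bound.
`compound_heterozygous` is never emitted from read counts: it is
established from colony data.

Phase classification from colony tables is rule-based and exact on
noise-free tables: only the two single-mutant classes → trans (compound
heterozygous); double-mutant plus wild type only → cis; one single-mutant
class → single variant; anything mixed, or wild-type colonies alongside
both single-mutant classes, → inconclusive. Fewer than 10 colonies is
flagged as underpowered and returns inconclusive. Hemizygous-deletion
dosage calls name the mechanism only; any haploinsufficiency
interpretation is left to the analyst.

## Synthetic data: what it emulates, what it does not

The generators are first-class, tested code and define the study
conditions for all stochastic tests:

* `simulate_cohort()` plants exactly `n_with_lesion` carriers per
  diagnosis (1–3 segments each, kinds drawn at the 30:11:17
  deletion:gain:UPD mix of a large chromosome-11 survey, log-uniform
  lengths 0.5–67.5 Mb on a 135 Mb chromosome). The default layout
  (`myeloid_cohort_template()`) is the 813-sample cohort structure with
  52 carriers.
* `simulate_depth_tracks()` draws per-base depths as
  Poisson(depth × target weight × copy ratio) with Gamma-distributed
  per-target capture weights (shape 20, mean 1, cv ≈ 0.22) shared by case
  and controls of a batch; spikes multiply the case rate inside the
  spiked interval. Defaults: depth 100×, pool of 8 controls.
* `simulate_clone_observations()` draws alternate reads binomially from
  the error-floored mechanism VAF; `simulate_colony_table()` draws colony
  counts multinomially from the planted phase.
* `simulate_cdr_segments()` gives every sample a deletion containing a
  planted core (default 50 kb on a 10 Mb toy chromosome — large enough
  for CDR geometry, small enough for per-base oracles) with
  exponential flanks, and records the realised minimal common region so
  recovery can be checked exactly.

One global seed fans out to fixed per-stream sub-seeds (weights, case,
each control), so enlarging the control pool never perturbs the case
draw, and identical configuration plus seed yields byte-identical files.

What the generators do **not** emulate: GC and mappability structure in
coverage (no wave artifacts), correlated noise between neighbouring
positions, array segmentation error in segment boundaries, contamination
or index hopping, linkage between variants, and multi-lesion interaction
on one chromosome. Passing the synthetic suite therefore demonstrates
correctness of the algorithms under the stated noise model, not
robustness to every artifact of real exomes; on real data the coverage
caller in particular would benefit from GC correction, which is
deliberately out of scope.

## Problem sizes and runtime

The test suite runs the exact-test oracle exhaustively over all 2×2
tables with total N ≤ 60, the sweep-line oracle over 500 random segments
on a 10 kb chromosome, the focal caller over 100 spiked and 100 spike-free
seeds (~26 kb panel, 100×), and the dosage grid over 5 seeds × 500
variants × 5 mechanisms — sizes chosen so the full suite completes in a
few minutes on one CPU while keeping every Monte-Carlo bound (≥ 95/100
detections, ≤ 5/100 false positives, ≥ 95% per-class accuracy) meaningful.

## Known limitations

* The exact test covers 2×2 tables only (no r×c generalisation).
* CDR boundaries are reported at segment-breakpoint resolution; no
  significance measure is attached.
* The coverage caller reports intervals at observed-position resolution;
  base-pair breakpoints of an event (and events smaller than
  `min_positions`) are out of reach by design.
* The dosage model assumes one aberrant clone plus diploid wild-type
  cells; nested subclones and multi-lesion loci (e.g. UPD of a gained
  arm) are not modelled.
* The colony-table rules assume colonies genotype a single amplicon
  spanning both variants; allele dropout is not modelled beyond the
  inconclusive class.
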