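---
title: "Methods: the baserecal error model and its diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the baserecal error model and its diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A Phred quality score `Q` asserts that the base call is wrong with
probability `10^(-Q/10)`. Reported scores from short-read sequencers are
systematically miscalibrated, and the miscalibration is machine-, run- and
cycle-specific, so it cannot be corrected by a fixed lookup. `baserecal`
estimates the error probability of every base from the data themselves: it
labels bases in a training region as errors by comparison to the
reference, fits a logistic regression of the error indicator on read-level
covariates, and rewrites every quality in the BAM from the model's
predicted probabilities.

The approach assumes (i) the alignments in the training region are
substantially correct, (ii) reference mismatches in that region are
predominantly sequencing errors once variant-like positions are removed,
and (iii) the covariates available from the read alone — reported quality,
read mean quality, read position, base identity — carry most of the
predictable structure in the error rate. Assumption (i) is inherited by
every alignment-based recalibrator; (ii) is enforced by the filters below;
(iii) is an approximation discussed under Limitations.

# Training-set construction

`recal_fit()` collects one record per aligned (CIGAR match/mismatch) base
in the training region. Insertions, soft clips and deletions contribute
nothing; unmapped, secondary and duplicate reads are skipped for training
(though every record is rewritten at output time). Three filters then
protect the error labels:

* **Known variants.** All bases at positions in the user-supplied variant
  list are removed — removal is position-wise, not allele-wise.
* **Unlabelable bases.** A base called `N`, or aligned over an `N` in the
  reference, has no meaningful error label and is dropped.
* **The coverage-dependent threshold.** At each position,
  `thresh = max(nerr, nraf × coverage)` with defaults `nerr = 2`,
  `nraf = 0.05`. If the non-reference base count *strictly* exceeds
  `thresh`, every base at the position is removed. The point is not to
  relabel those bases as correct but to drop the position: a pileup where
  many reads agree on a non-reference allele is evidence of a novel
  variant or a systematic alignment artifact, either of which would
  poison the labels. Note the two regimes: an absolute error cap at low
  coverage, an allele-frequency cap at high coverage. (The crossover
  between the two regimes sits at `nerr/nraf = 40×` coverage with the
  defaults; descriptions of this filter sometimes place it at 60×, but the
  formula is what is implemented.)

Three boundary decisions are deliberate and tested: coverage counts
training-eligible bases (after N-dropping and variant exclusion), because
those are the labels the filter protects; a position with exactly `thresh`
errors is kept (the comparison is strict); and `thresh` is used as a real
number — `nraf × coverage` is never rounded.

# The regression model

With `Y(i) = I{base i ≠ reference}`, the model is

```
logit P(Y = 1) = β0 + β1 X1 + β2 X2 + β3 X3 + β4 X4
              + β5 X5 + β6 X6 + β7 X7 + Σ_m β(7+m) I{X4 = fp_m}
```

* `X1` — reported quality. The dominant covariate; if reported scores were
  calibrated its coefficient would be `-ln(10)/10 ≈ -0.23` with all others 0.
* `X2 = I{X1 = 0}` — many base callers use Q0 as a "randomly called base"
  sentinel, which breaks the log-linear relation; the indicator lets Q0
  bases float free instead of dragging the slope. Q0 bases are *not*
  excluded from training or from rewriting.
* `X3` — mean quality over all bases of the containing read (clipped bases
  included), capturing whole-read quality collapse.
* `X4` — read position, 1-based offset within the stored read.
* `X5..X7` — indicators of base A, C, G; T (and N, which never reaches the
  design matrix) is the reference category.
* Flagged positions `fp_1 < … < fp_k`: read cycles whose error count
  strictly exceeds `flag_multiplier` (default 1.5) times the mean error
  count per cycle. Errors pile up at read ends for instrument-chemistry
  reasons; the indicators give those cycles their own intercepts where the
  linear `X4` term cannot bend enough.

**Estimation.** Maximum-likelihood logistic regression via binomial IRLS
(`stats::glm.fit`), relative-deviance convergence tolerance `1e-8`, at most
25 iterations; no regularization. The training set is split into
contiguous, input-order slices of at most `subset_size = 1e7` bases; one
fit per slice; the final coefficient vector is the element-wise median
across slices. Contiguous slicing (rather than random subsampling) makes
the fit reproducible without an RNG, and the median damps the influence of
an aberrant slice. A covariate that is constant within a slice — typically
a flagged-position indicator that never fires there — is dropped from that
slice and treated as missing when medians are taken; a covariate constant
in *every* slice gets coefficient 0, with a message.

**Degenerate inputs.** A slice with a single response class is skipped
with a warning; if every slice fails, fitting aborts with an error rather
than returning a vacuous model. An empty post-filter training set, or one
with no errors at all, is an error for the same reason.

**Prediction and the Phred floor.** Probabilities are the inverse logit of
the linear predictor, clamped to `[1e-12, 1 - 1e-12]` so they are strictly
inside (0, 1) even when the linear predictor saturates in double
precision. Qualities are `floor(-10·log10(p))`, clamped to `[0, q_max]`.
`q_max = 60` (p = 1e-6) by default: the training data can essentially
never support rates below that, and an uncapped transform would let an
extreme linear predictor print absurd scores. Rewriting a BAM needs only
read-level covariates, so *every* base of every record — clipped, unmapped,
duplicate — is recalibrated, and no reference is needed at apply time.

At prediction time `X3` is computed from the *original* qualities, the
scale the model was trained on, not from running-recalibrated values.

# Diagnostics

The calibration table groups bases by assigned score `q` and records the
count, relative frequency `f(q)`, error count and empirical quality
`e(q) = -10·log10(error rate)`. The frequency-weighted squared error

```
FWSE = Σ_q f(q) (q - e(q))²
```

is zero exactly when every score matches its observed error rate.
Empirical qualities enter FWSE unrounded; rounding is for display only. A
bin observed with zero errors has no finite empirical quality; it is
capped at `q_max` and marked (`zero_errors`), and still contributes
`f(q)·(q - q_max)²` — dropping such bins would let a model hide mass in
scores "too good to measure". This capping choice matters only when
low-count bins exist; at the training sizes recommended the high-frequency
bins dominate FWSE.

Discrimination is assessed on the non-reference bases of a (test) region,
split by position: known-variant positions supply the variant class,
provided at least `max(3, nraf × coverage)` non-reference bases support
them (weakly supported "known variants" may be errors); all other
positions supply the error class, provided they pass the same
`max(nerr, nraf × coverage)` cap as training (positions above it may be
novel variants). The AUC is the tie-corrected rank-sum estimator —
exactly the probability that a random variant base outscores a random
error base, ties counted one half. Both class filters reuse the training
threshold machinery deliberately, mirroring the parallel construction of
the two rules.

The four-panel figure shows (A) errors by read position with the flagging
threshold, (B) the before/after quality distributions, and (C)/(D)
reported versus empirical quality with points shaded by frequency and the
FWSE annotated.

# The simulator

`simulate_bam()` generates what the method needs to be tested against,
with per-base truth labels: fixed-length (default 76 bp), single-end,
ungapped reads uniform over a synthetic reference; reported qualities
drawn from a distribution with almost half the mass near Q40 and a small
Q0/Q2 tail; true error probabilities equal to
`distortion(10^(-q/10)) × position_multiplier(cycle)`, with the default
distortion inflating the implied probability tenfold and the default
multiplier flat over the first 80% of cycles rising linearly to 6× at the
last; planted heterozygous variants (default allele frequency 0.5); and
systematic sites where every overlapping read carries the alternate
allele — the pathological pileup the position filter exists for. The truth
table separates sequencing errors from variant-site bases, so tests can
measure calibration against actual errors rather than reference
mismatches.

What the simulator does **not** emulate: indels and clipping in reads
(the reader's CIGAR handling is tested separately on hand-built
alignments), mapping errors other than the systematic-site idealization,
quality-string autocorrelation along a read, GC or dinucleotide context
effects, and paired-end structure. Passing tests therefore demonstrate
that the estimator recovers the generating model and that the pipeline's
bookkeeping is exact — not that the seven-covariate family captures
everything in real Illumina data.

Study sizes used by the test suite and the acceptance script: a 100 kb
reference at 50,000 reads (~38× coverage, ~3.8 million training bases,
one regression slice) for the end-to-end calibration and discrimination
checks, 200,000 rows across four slices for parameter recovery, and
pileups of ≤ 10,000 bases for the brute-force oracle comparisons. These
sizes give stable estimates (the binomial noise on per-bin error rates is
well below the effects being measured) while keeping a full run in the
low minutes on one CPU.

# Open choices, resolved

* **Read position orientation.** For reverse-strand reads, "read position"
  could mean sequencing cycle (requiring a flip) or the offset as stored
  in the BAM. We use the stored offset. On real reverse reads the
  end-of-cycle error enrichment appears at the *start* of the stored
  sequence, which dilutes the flagged-position covariates; users with
  heavily strand-asymmetric data should be aware. Flipping is a possible
  future extension; it would not change any other component.
* **MaxTrain** counts bases *collected*, before filtering — "train on the
  first N bases of the region" is the contract, so changing filter
  parameters does not silently shift the training window.
* **Coverage basis for `thresh`** — training-eligible bases, as argued
  above, not raw pileup depth.
* **Model transport.** The JSON model document stores coefficients,
  flagged positions, filter parameters, region and the calibration
  tables, so "train once, apply to many BAMs" requires no refitting and
  survives sessions.

# Limitations

Recalibration quality is bounded by alignment quality: mismatches caused
by misplaced reads inflate the error labels, and the position filter only
removes the systematic cases. The model deliberately omits dinucleotide
and cycle-context covariates; on data where context effects dominate,
residual miscalibration will remain. FWSE comparisons across data sets
are only meaningful for the same binning of scores. Finally, the
discrimination analysis inherits the known-variant list's blind spots:
novel variants that pass the error-class filter are scored as errors.
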