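---
title: "Detecting explicit sequence awareness from SRTT latencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting explicit sequence awareness from SRTT latencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srttaware)
```

## The problem

In a serial reaction time task (SRTT) a subject presses one of four keys
matching the location of a visual cue, while an unannounced short sequence
(7, 10 or 13 elements) repeats seamlessly underneath the stream.  Most
subjects speed up gradually through implicit learning; a minority
incidentally *discover* the sequence, and from that moment can anticipate
upcoming cues, producing an abrupt, large drop in response latency —
sometimes to negative values when a press precedes the stimulus.  Knowing
*when* that discovery happens, without asking and thereby spoiling its
incidental character, is what this package is for: an individualized,
purely behavioral change-point indicator of explicit awareness, plus the
machinery to validate it against simulated ground truth and to relate its
timing to per-block ERP component amplitudes.

## The threshold model

Each subject supplies a baseline: the first 45 key presses (the embedded
5-block design, "exp1") or a dedicated 35-key random block (the EEG
design, "exp2").  With baseline mean $m$ and standard deviation $s$, the
individualized threshold at magnitude $z$ is

$$ T = m - z \, s . $$

Latencies are averaged per *sequence repetition* (one full pass through
the embedded sequence).  Because a repetition mean on 7–13 presses is
noisy, the quantity compared against $T$ is the one-sided 95% upper
confidence bound of that mean,

$$ U_r = \bar{x}_r + t_{0.95,\,n_r-1} \frac{s_r}{\sqrt{n_r}} , $$

so a repetition only counts as below threshold when the subject's
*plausible* mean is below it.  A subject is classified EXP (explicitly
aware) at the first repetition where $U_r < T$ (first-occurrence rule) or,
more stringently and by default, at the second repetition of the first
consecutive pair with $U_r < T$ (two-consecutive rule).  Anyone never
qualifying is NOEXP; their block of lowest z-scored performance is kept as
the block of interest for neural correlation.  The default magnitude is
$z = 1.85$, the smallest value that perfectly separated the development
cohort under the two-consecutive rule; `sweep_z()` re-examines the whole
grid $z \in \{0.50, 0.51, \dots, 2.50\}$ (201 values) and reports
sensitivity $TP/(TP+FN)$ and specificity $TN/(TN+FP)$ per $z$ and rule.

Numerical conventions worth stating:

* Qualification is a strict inequality; a bound exactly at threshold does
  not qualify.
* The Student-t bound is used rather than a normal bound because $n_r$ is
  7–13; with $n_r \le 1$ or zero spread the bound collapses to the mean.
* The confidence-bound form (t vs normal, one- vs two-sided) is a design
  choice of this package; only the confidence level is inherent to the
  method.  It is configurable via `conf_level`.
* A zero-SD baseline makes z-scores meaningless and is a hard error;
  noise-free synthetic fixtures should pass `z_scores = FALSE` and
  classify on the raw latency scale, which is the same affine comparison.
* A repetition with no recorded response inherits the previous
  repetition's mean and is flagged `imputed`.
* Onset is attributed to the *second* repetition of the qualifying pair
  (the repetition at which the consistency requirement is met); the first
  is retained as `first_of_pair`.

## Sequence generation

Stimulus sequences are pseudorandom under two constraints: no two adjacent
elements repeat, and no three-element window runs across three adjacent
fingers monotonically (2-3-4, 4-3-2, …).  Because the sequence tiles
seamlessly (inter-stimulus interval 0, no boundary marker), both
constraints are enforced *cyclically*, across the wrap from last to first
element — whether the original constraint was cyclic or linear is not
documented, and the cyclic reading is the safe one since a violation at
the wrap is experienced by the subject identically to one inside the
sequence.  The run rule is the most literal reading of "three consecutive
fingers"; a stricter variant (any permutation of three adjacent fingers)
is available via `monotone_run = "any_adjacent"`.  Generation is rejection
sampling with a 10,000-attempt cap: valid sequences are dense at the
design lengths (for example, a large fraction of all $4^7$ candidates
survive), so rejection converges in a handful of draws, and the cap turns
a genuinely infeasible parameter set into an explicit error instead of a
hang.

## What the simulator emulates — and what it does not

`simulate_cohort()` is a first-class module, not a test fixture: it
defines the study conditions under which the classifier's operating
characteristics are measured.  Per subject it draws a baseline mean
(455 ± 35 ms across subjects) and a trial SD (40 ± 8 ms), matching the
baseline scale of the behavioral cohorts, then generates every trial as

latency = baseline mean + z-profile × baseline SD + Gaussian trial noise.

The z-profile encodes the two learning processes: a gradual linear drift
reaching −1.1 z by the final repetition (implicit learning, all subjects),
and for EXP subjects a post-onset transition that brings the final z to
−4.0 — an immediate step of half the shift followed by a 2-block linear
ramp ("abrupt but not instantaneous"; `step_fraction` and `ramp_blocks`
are configurable, with `ramp_blocks = 0` giving a pure step).  The group
targets −4.0 and −1.1 are the reported final z-scores of aware and
unaware subjects; onset blocks are drawn from an early/late mixture split
at block 20 with 5:4 odds, mirroring the observed Early/Late learner
split.  Accuracy is ~97%; unrecorded responses are near zero in the EEG
design and ~15% under the exp1 emulation, where responses outside the
750 ms window cannot be recorded.  A false-negative archetype (`n_fn`)
generates subjects who recall the sequence but whose drop is too shallow
to cross a typical threshold.

`simulate_erp()` produces per-block component amplitude series, not
waveforms: baseline level + Gaussian bump around a peak block + noise.
For EXP subjects the peak block is a coupling-weighted mixture of
(onset + component lag) and a uniform draw over blocks 3–27; coupling 1
ties peaks exactly to behavior, coupling 0 reduces them to the NOEXP
case (uniform).  Default lags 0, 2, 4, 4 for P3, late N1, P2 and early N1
emulate the posterior-to-anterior progression of peak activity during
discovery.  All subjects additionally receive a P3 trend proportional to
per-block mean latency, emulating the global P3 decline that accompanies
the general speed-up.  `series_to_epochs()` can expand a series into
synthetic half-sine epochs to exercise the signed-area path end to end.

Deliberate simplifications: trial noise is white Gaussian
(within-subject autocorrelation of real reaction times is not modelled);
anticipatory negative latencies arise only when the drop is large
relative to the baseline mean; ERP series are generated at the block
level rather than as continuous EEG.  Passing recovery tests on these
cohorts therefore demonstrates that the classifier recovers the *assumed*
generative structure — it cannot certify behavior on real data whose
noise structure differs.

## ERP quantification

Component amplitudes are quantified by the signed-area method over fixed
windows and electrode groups: early N1 100–140 ms (F1, FZ, F2), late N1
140–170 ms (P1, P3, P2, P4), P2 180–210 ms (C1A, CZA, C1, CZ), P3
275–375 ms (C1, CZ, C2, C1P, CPZ, C2P).  The electrode-group channels are
averaged sample-wise and the waveform is integrated by the trapezoid rule
over the closed window $[t_\mathrm{start}, t_\mathrm{end}]$, keeping only
the portion whose sign matches the component polarity (rectified area,
the default — this makes a constant 1 µV deflection over a 40 ms window
equal exactly 40 µV·ms and makes areas add across adjacent windows); a
net-integral variant is available via `method = "net"` since the exact
formula is a known ambiguity of the method.  Epochs must be
baseline-corrected over the 100 ms pre-stimulus window.  Peak-block
analysis is restricted to blocks 3–27 by default, excluding the initial
pacing-adaptation peak; ties resolve to the earliest block.  Units are
µV·ms throughout.

## Neurobehavioral correlation

The behavioral variable is the block of interest (onset block for EXP,
lowest-z block for NOEXP); the neural variable is the peak-amplitude
block per component.  Correlation is Spearman's rho on mid-ranks, with
*exact* permutation p-values for $n \le 8$ — at group sizes of ~9
subjects the t-approximation is unreliable, and after excluding false
negatives groups routinely land at $n = 8$ — and the t-approximation
above that (the cutoff is configurable).  Holm correction is applied
within each group across the component family.  False-negative subjects
(full recall, classified NOEXP) are excluded from both groups, as their
neural timing has no defined behavioral anchor.

The P3-vs-latency analysis is a deliberately simplified descriptive
version of what would properly be a linear mixed model: each subject
contributes an independent least-squares slope, intercept and Pearson r,
summarized per group.  It answers "does P3 amplitude track latency within
subjects" without the machinery of random-effect inference, which is
off-the-shelf elsewhere and not this package's contribution.  Likewise
`peak_order_summary()` reports the per-subject ordering of component
peaks (canonical tie-break P3 → late N1 → P2 → early N1) and group mean
peak blocks descriptively, rather than fitting timing contrasts.

## Validation strategy and problem sizes

The test-suite checks fall into three tiers.  Exact oracles: the sequence
validator against exhaustive enumeration of all candidate sequences up to
length 8; classification onsets against a brute-force scan; peak blocks
against argmax; Spearman rho/p against full permutation enumeration;
signed areas against closed-form integrals.  Structural properties:
determinism under fixed seeds, the subset relation between the two rules,
monotonicity of sensitivity/specificity along the z grid, z-transform
invertibility, partition completeness.  Statistical recovery at the
study's design points: 100 simulated cohorts for the sweep properties, 50
cohorts for threshold recovery (mean sensitivity ≥ 0.9, specificity
≥ 0.95, estimated onset within ±1 block of truth for ≥ 90% of detected
subjects), 200 ERP draws for the uncoupled null and 100 cohorts for the
coupled/uncoupled contrast.  These sizes keep the full suite around a
minute on one core while leaving Monte-Carlo standard errors well inside
the asserted margins.

## A worked run

```{r, eval = FALSE}
lay <- build_block_layout("exp2", generate_sequence(7, rng_seed = 1),
                          rng_seed = 1)
coh <- simulate_cohort(cohort_config(rng_seed = 1), lay)
res <- classify_cohort(coh, lay, threshold_model(1.85, "two_consecutive"))
tr  <- cohort_truth(coh)
score_cohort(res$classifications, tr$truth_recall, tr$subject_id)

sw <- sweep_z(res$summaries, tr$truth_recall)
erp <- simulate_erp(coh, erp_sim_config(coupling = 0.9))
neurobehavioral_correlation(res$classifications, peak_block_table(erp),
                            setNames(tr$truth_recall, tr$subject_id))
```

`run_pipeline(pipeline_config(rng_seed = 1))` performs the same stages
and writes every table, the ground-truth sidecar (which the classifier
never reads — enforced by interface separation, and checked in the
tests), a sweep CSV and a summary JSON into a run directory,
byte-identically across re-runs of the same configuration.

## Known limitations

* The classifier presumes a stable baseline; a subject who is already
  fast or highly variable at baseline gets a correspondingly forgiving or
  strict threshold — that individualization is the point, but it makes
  the method sensitive to baseline contamination (e.g. awareness arising
  *during* an embedded baseline).
* Shallow, slow awareness (a recalling subject without an abrupt drop)
  is invisible to any latency threshold; such false negatives are a known
  failure mode and are modelled explicitly.
* The exact-permutation Spearman p is factorial in n and capped at the
  small-sample regime it exists for.
* ERP handling starts from epoched, baseline-corrected averages;
  acquisition, filtering, artifact removal and source localization are
  out of scope.
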