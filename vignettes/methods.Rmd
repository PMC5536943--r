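---
title: "Phasic and tonic ensemble coding analyses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasic and tonic ensemble coding analyses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lecensemble)
```

## The experimental design this package analyses

`lecensemble` implements the complete analysis chain for multi-block trace
eyeblink conditioning electrophysiology: single units recorded in the lateral
entorhinal cortex (LEC) while a rat works through six blocks of trials in a
fixed daily sequence. Each block presents a conditioned stimulus (CS; a 100 ms
tone or light) either alone (20 trials) or paired with a periorbital
stimulation (US) delivered 600 ms after CS onset (50 trials), in one of two
visually distinct conditioning boxes. Three task variables distinguish the
blocks: stimulus **R**elationship (CS-alone vs CS-US), CS **M**odality
(auditory vs visual) and **E**nvironment (Box 1 vs Box 2). Trials are
separated by 20-40 s inter-trial intervals (ITIs).

Two timescales of coding are quantified. *Phasic* coding is a firing-rate
change inside the 600 ms window from CS onset to US onset. *Tonic* coding is
a sustained, block-specific rate offset measured in the 9 s window before CS
onset. Because the shortest ITI is 20 s, that window always starts at least
11 s after the previous trial ends, keeping slowly decaying post-US activity
out of the tonic estimate. We interpret the stated 20-40 s interval range as
running from the end of one trial to the next CS onset; this is the only
reading under which the guaranteed 11 s margin holds, and the trial layout in
`make_schedule()` enforces it by construction.

All event times are in seconds from session start and every analysis window
is half-open `[start, end)`, so a spike exactly on a boundary is counted
once.

## The synthetic-session generator

No public recordings accompany this design, so the package ships a generator
(`simulate_session()`) whose defaults *are* the study conditions: 210 trials
in six blocks, 250 cells, EMG at 10 kHz. It exists as first-class, tested
code because every downstream statistic can then be validated against known
ground truth.

**Spiking.** Cells fire as piecewise-homogeneous Poisson processes. Each cell
carries one tonic rate per block (log-normal baseline, median 0.8 Hz,
matching the sub-2 Hz regime of the recorded population) and a multiplicative
phasic gain (default 3) applied inside the trial window for the 45.2% of
cells drawn as CS-responding. A cell's ground-truth category (one of
`Non-S, R, M, E, R+M, R+E, M+E, R+M+E`) determines *exactly* which block
contrasts differ: for each flag the rate factor `1 + effect_size` multiplies
one side of the corresponding contrast. The preferred side is drawn at
random per cell. That choice matters: if every selective cell preferred the
same side, the population would be homogeneous and ensemble state vectors
would carry no across-cell correlation structure at all (Pearson r is
invariant to shifts common to all cells); recorded populations differentiate
in both directions. The default category mixture is the empirical tonic
mixture of the recorded population, dominated by conjunctive `R+M+E` cells.

Poisson spiking is an explicit modelling choice — the source analyses never
model spike generation — because it matches the low-rate regime and yields
closed-form oracles (window counts are Poisson with mean rate x duration,
tested directly). The phasic response is a flat rate step over the 600 ms
window rather than a latency-resolved PSTH shape; every statistic in scope
consumes window-mean rates, so a shaped PSTH would add parameters without
changing any tested quantity. Tonic rates switch to a new block's value at
the end of the previous block's last trial, i.e. the ITI preceding a block
belongs to that block — this is what lets the transition analyses observe
prospective, pre-CS changes.

**EMG.** The eyelid signal is Gaussian noise band-passed 250-4500 Hz (the
realizable version of the 250-5000 Hz acquisition band at a 10 kHz rate),
with conditioned responses simulated as amplitude bursts (default 5x) in the
200 ms before US onset on trials drawn per-block as CR trials (defaults 0.7
on paired, 0.15 on CS-alone blocks, mirroring well-trained performance).
CS-alone trials use the virtual US-equivalent time `cs_onset + 0.6`.

What the generator does *not* emulate: spike-waveform shape and sorting
artefacts, cross-cell correlations (the analyses themselves assume a pooled
pseudo-population that ignores them), latency-structured phasic responses,
non-Poisson interval statistics, and real EMG artefacts (movement, chewing).
Passing tests therefore validate the *statistical machinery* under the
design's sampling conditions, not robustness to those nuisances.

## Conditioned-response scoring

The instantaneous EMG amplitude is the absolute value of the analytic signal
(Hilbert envelope), computed via the standard FFT construction after
band-passing. Scoring uses per-trial padded segments (0.25 s margins) so
filter and Hilbert edge transients never touch a scoring window. Per trial,
the pre-CS value averages the envelope over the 200 ms before CS onset and
the CR value over the 200 ms before (real or virtual) US onset. The session
threshold T is the mean of all pre-CS values plus one SD (population
convention, ddof = 0; the source text does not specify the divisor — the
choice moves T by under 1% at 200 trials and is configurable). The label
rule: discard if pre-CS > 1.3 T; CR if pre-CS <= T and CR value > 1.1 T; if
T < pre-CS <= 1.3 T, CR only when (CR - T) >= 5 x (pre-CS - T). CR% is CRs
over valid trials per block. The same rule applied to the 480-280 ms pre-CS
control window yields pre-CR%. "All pre-CS values" is read session-wide (the
most literal scope); a per-block threshold is available via
`cr_detection_params(threshold_scope = "block")`.

## Single-unit statistics

**CS-responsiveness.** The statistic is the absolute difference between a
unit's mean trial-window rate (600 ms) and mean pre-CS rate (1 s). The null
re-assigns, per trial, the two rates to the two period labels — a
within-trial swap, the most literal reading of randomly assigning each rate
to either period — and the test is significant when the observed statistic
exceeds the upper 5% order-statistic quantile of 1000 re-assignments. A unit
is CS-responding if significant in at least one of six blocks (family-wise
inflation acknowledged: the procedure is reproduced, not corrected).

**Differential index.** `DI = |Fr1 - Fr2| / (Fr1 + Fr2)` on
across-trial mean rates. The chance level is the upper 5% quantile of DIs
recomputed under label shuffles (1000), and `DI_corrected = DI - chance`;
a unit is selective when the corrected value exceeds zero. The quantile is
fixed as the `ceil((1 - alpha) * n)`-th order statistic so corrected values
are reproducible; both permutation tests expose `exact = TRUE`, replacing
Monte Carlo draws by full enumeration (all label subsets / all sign
patterns), which the test suite checks against independent brute-force
oracles. Cells with zero spikes in every window of a contrast have an
undefined DI and are excluded from that contrast.

**Contrasts and the 8-way category.** Relationship compares each CS-alone
block with the paired block sharing its CS and box (three pairs; selective if
any pair is). Modality pools alone and paired trials of the two CS types in
the box that saw both; Environment pools the CS modality presented in both
boxes. Pooling follows the results-section reading ("regardless of whether it
was a CS-alone or CS-US paired trial"). Raised flags combine into the
category label, `Non-S` when none. The same classification runs on
trial-window rates (phasic, the analogue of the CS-evoked table) and on 9 s
ITI rates (tonic).

**Bin-size sweep.** The tonic classification is re-run on rates from one
9 s bin, four 2.25 s bins, or eight 1.125 s bins. The per-partition
"proportion of selective cells" is the mean over bins of the per-bin
selective fraction — the source does not state the aggregation; this choice
reduces to the full-window test for one bin and reproduces the reported
monotone decline with shrinking bins (noisier rate estimates lose power,
and `any-bin` aggregation would instead inflate with bin count).

**Stability (KLD).** Per block, the 9 s ITI is cut into fifteen 600 ms bins
and bin rates averaged over trials; the within-block divergence is the
median over blocks of `KLD(profile || uniform-15)` in bits. Transposing,
the between-block divergence is the median over the 15 bins of
`KLD(six-block vector || uniform-6)`. All-zero profiles have undefined KLD
and are excluded from the medians with a notice. Tonic coding predicts
`between > within` for nearly all coding cells, which the generator
reproduces.

**CR correlation.** Within each paired block having at least 20 CR and 20
non-CR trials, 20 trials per type are subsampled and the shuffle-corrected
DI computed between them, for trial-window and ITI rates separately.

## Ensemble analyses

State vectors are per-trial (or per-ITI) population rate vectors,
max-normalised per cell over the declared scope; silent cells in that scope
are dropped with a notice, and the normalisation is idempotent.

**Block-pair correlations.** Per repeat, ten trials per block are averaged
into one state vector per block, cells normalised by their max across the
six vectors, and Pearson r computed for the two block pairs of each
category (Modality, Environment, Relationship), plus the odd/even
within-block control (None, upper reference) and the fully disjoint pairs
(All, lower reference). Twenty repeats give 40 r values per category. ITI
runs draw one random 600 ms bin per trial from the 9 s window, re-drawn
every repeat (the fixed-bin variant is a one-line change; re-drawing was
chosen as it matches the stated "randomly selected" bins and averages out
bin-placement noise).

**ITI correlation matrix and Similarity Scores.** One hundred subsampled
cells give a 210 x 210 Pearson matrix over ITI state vectors. At each of
the five block transitions the template is the last ITI of the earlier
block; the Between-block score averages its r with the first 19 ITIs of the
next block and the Within-block score with the 19 ITIs preceding the
template. Transitions are typed by what changes across them — environment
(E), environment + modality (E+M), or contingency only (R). The sliding
trend analysis sorts cells by recording session, runs the same scores on
49-cell windows advanced by 10 cells (one deterministic pass per window:
with the window fixed there is no subsampling randomness left), and
regresses the within-minus-between difference on window index by OLS; the
p-value is the usual t-test on the slope.

## Decoding

Per run, 200 subsampled cells form trial x cell feature matrices (trial
window, or one random 600 ms ITI bin per trial fixed within the run). Cost
and gamma of an RBF-kernel SVM (libsvm via `e1071`, one-vs-one multiclass)
are grid-searched with 5-fold stratified CV on all trials normalised per
cell over all trials; the grids default to `2^{-5..15}` (cost) and
`2^{-15..3}` (gamma) in steps of 4 in the exponent, and both the grids and
the CV scheme are recorded in the result provenance because the source
states only that a range of values was searched. Each of 20 resamples then
draws 20 trials per block, renormalises per cell over those 120 trials (the
double normalisation is deliberate and matches the described procedure),
trains on a stratified half and tests on the other half: 60 tests x 20
resamples = 1200 predictions per run. Binary collapses relabel blocks by
modality, environment or relationship before training.

Chance levels: the 6-way problem is balanced, so label shuffling yields
1/6. The binary collapses are *imbalanced by design* (e.g. four auditory
vs two visual blocks), so the correct chance reference for a shuffled-label
classifier is the no-information rate — the majority-class share, 2/3 —
not 1/2; the test suite asserts against that rate. Accuracy confidence
bounds use the number of distinct trials (210) rather than the 1200
correlated test instances.

## Numerical choices and degenerate inputs

* Permutation quantiles are order statistics (no interpolation); ties make
  the tests conservative on discrete counts, which the calibration check
  (type-I error within the 99% binomial CI of 0.05 at 500 null cells)
  absorbs.
* Grid-search ties break toward the smallest cost, then smallest gamma.
* `differential_index(0, 0)`, constant vectors in `pearson_r()`, all-zero
  KLD profiles and silent cells are all surfaced as errors, `NA`s or logged
  exclusions — never silently dropped.
* Invalid session files (unsorted spikes, US on an unpaired block, trials
  outside the recording span, non-finite EMG) are rejected at read/write
  time; analysis validity depends on alignment.

## Problem sizes used by the test suite

Unit tests run on reduced six-block schedules (10-20 trials per block) and
populations of 12-40 cells; the acceptance checks run the full 210-trial
schedule with the 250-cell default population, 500-cell calibration runs at
1000 shuffles, and decoding with 200 subsampled cells. These sizes were
chosen so the complete suite exercises the study-scale pipeline while
remaining comfortable on a single CPU.

## Known limitations

* The pipeline is a faithful re-implementation validated on synthetic
  ground truth; headline percentages from the original recordings are not
  reproducible without those recordings and are not asserted.
* Routine downstream inference (repeated-measures ANOVA, Kruskal-Wallis,
  KS tests, Tukey HSD, Bonferroni t-tests) operates on the emitted tables
  with standard R functions and is deliberately out of scope.
* The generator switches tonic rates instantaneously at every block
  boundary. Contingency-only (R) transitions therefore also show a
  between-block similarity drop, whereas recorded ensembles shift gradually
  there (the contingency change only reveals itself once the US arrives).
  The asserted ordering — between(E+M) < between(E) < within — is
  unaffected; modelling cue-dependent transition latency would require a
  learning model that is out of scope.
* The generator's block-order default mirrors the majority block sequence;
  arbitrary orders are supported via `block_specs()`, and sessions whose
  order deviates should be excluded by the caller before transition
  analyses, as done in the original restriction to same-order animals.
* Spike sorting, acquisition formats and histology are out of scope; the
  package starts from spike-time tables.
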