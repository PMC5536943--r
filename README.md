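# lecensemble

Analysis pipeline for **phasic and tonic neural ensemble coding in
multi-block trace eyeblink conditioning**. The package targets
electrophysiologists analysing single-unit recordings (e.g. from the lateral
entorhinal cortex) collected while an animal works through six blocks of
trials that cross three task variables — stimulus **R**elationship (CS-alone
vs CS-US paired), CS **M**odality (auditory vs visual) and **E**nvironment
(conditioning Box 1 vs 2) — with 20–40 s inter-trial intervals (ITIs).

It implements, end to end:

* **CR scoring from eyelid EMG** — Hilbert-envelope amplitude; session
  threshold `T = mean + SD` of all pre-CS values; a trial is discarded if
  pre-CS > 1.3 T, a CR if pre-CS ≤ T and the pre-US value > 1.1 T, and in
  the intermediate band a CR only if `(CR − T) ≥ 5 (pre − T)`; CR% and
  pre-CR% per block.
* **Single-unit selectivity** — CS-responsiveness by within-trial
  permutation of trial-window vs pre-CS rates; the differential index
  `DI = |Fr₁ − Fr₂| / (Fr₁ + Fr₂)` with shuffle correction
  (`DI_corr = DI − Q₀.₉₅(shuffled)`; selective iff `DI_corr > 0`, 1000
  shuffles); the 8-way R/M/E category for both the 600 ms trial window and
  the 9 s tonic ITI window; ITI bin-size sweeps.
* **Firing-rate stability** — within- vs between-block Kullback–Leibler
  divergence, `D_KL(P‖Q) = Σᵢ P(i) log₂ P(i)/Q(i)`, on fifteen 600 ms ITI
  bins × six blocks.
* **Ensemble state-vector analyses** — max-normalised population vectors,
  block-pair Pearson correlations with odd/even and fully-disjoint
  references, the 210 × 210 ITI correlation matrix, within/between-block
  Similarity Scores at block transitions, and the session-sliding OLS trend.
* **Pseudo-population decoding** — RBF-kernel SVM (libsvm via `e1071`),
  grid-searched cost/gamma, 20 runs × 20 train/test resamples (1200 test
  predictions per run), 6-way and binary collapses.
* **A synthetic-session generator** — piecewise-homogeneous Poisson spiking
  with per-block tonic rates and phasic gains constructed so that exactly a
  cell's labelled contrasts differ, plus band-limited EMG with CR bursts —
  so every stage is testable against ground truth without any recordings.

## Worked example

Simulate a study-scale session (210 trials, here 120 cells) and run the
tonic analyses:

```r
library(lecensemble)

sess <- simulate_session(pop_config = population_config(n_cells = 120),
                         seed = 42, emg = FALSE)
cfg <- analysis_config(rng_seed = 42)

# 8-way tonic selectivity categories (9 s ITI window)
tab <- selectivity_table(sess, cfg, periods = "iti")
table(tab$category)[selectivity_categories()]
#> Non-S     R     M     E   R+M   R+E   M+E R+M+E
#>     1     8     7     2    20    21     5    56

# firing-rate stability: between- vs within-block KLD
stab <- stability_table(sess, cfg)
mean(stab$kld_difference > 0)   # fraction of cells with between > within
#> 1

# ensemble similarity across block transitions
sc <- similarity_scores(sess, cfg, n_repeats = 20, seed = 7)
aggregate(cbind(within, between) ~ type, sc, function(x) round(mean(x), 3))
#>   type within between
#> 1    E  0.762  -0.201
#> 2  E+M  0.797  -0.519
#> 3    R  0.810   0.165

# 6-way block decoding
d <- decode(sess, decoding_spec(n_cells_subsampled = 100, n_runs = 2),
            cfg, seed = 8)
mean(d$results$accuracy)
#> 1
```

Read: nearly all generated cells carry a tonic block code (conjunctive
`R+M+E` dominating, as in the default mixture), every cell fluctuates less
within a block than across blocks, ensemble similarity collapses across
transitions that change the environment (and drops most when the modality
changes too: between −0.519 under E+M vs −0.201 under E), and the six blocks
are decodable near ceiling from 100-cell pseudo-population vectors. With the
recovered categories matching the generator's ground truth for 98% of cells.

`run_pipeline(out_dir = "out")` chains every stage (behaviour → selectivity
→ stability → ensemble → decoding) and writes the CSV tables
(`cr_scores.csv`, `selectivity.csv`, `stability.csv`,
`ensemble_blockpair.csv`, `iti_matrix.csv`, `similarity_scores.csv`,
`decoding_results.csv`, `confusion_matrices.csv`, …). Real sessions load
from plain CSV/JSON via `read_session()`; see `?read_session` for the
column contracts.

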