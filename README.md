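# drivefatigue

EEG brain-network and oculomotor analysis of driving fatigue, for
researchers studying vigilance decline on simulated or instrumented drives
and interventions that counteract it.

Long monotonous driving leaves a characteristic EEG signature: theta-band
(4–8 Hz) activity synchronizes across the scalp, beta power falls relative
to theta and alpha, and lateral eye movements become sparse. This package
implements the full analysis chain for a two-condition (normal driving vs. a
man-machine response-mode intervention, "MRM"), seven-stage study design:

- **Band extraction** — an orthonormal, periodized wavelet-packet transform
  (4 levels, db16 by default) decomposes each channel into 4 Hz nodes at a
  128 Hz working rate; theta/alpha/beta are reconstructed from the nodes and
  node energies satisfy Parseval's identity
  `sum_j E_ij = sum_t f(t)^2`.
- **Functional brain networks** — pairwise Pearson correlations of theta-band
  channel signals, thresholded at `r > T` into a binary graph; per-node
  clustering `C_i = E_i / (D_i (D_i - 1) / 2)`, characteristic path length
  `L`, and global efficiency `G = mean(1 / L_ij)`. The threshold can be fixed
  or selected by a significance sweep over `T = 0.01, 0.035, ..., 0.485`:
  the midpoint of the intersection of the intervals where all six
  stage-1-vs-stage-k contrasts of `C` and of `G` are significant (intervals
  ending at `[0.26, 0.435]` select `T = 0.3475`).
- **Spectral fatigue ratio** — `beta / (theta + alpha)` from the same
  wavelet-packet bands, summarized over P3/P4.
- **Eye-movement detection** — a 20-sample sliding-window slope statistic
  `K_i = (y(x_{i+20}) - y(x_i)) / 20` on the raw F3/F4 pair; an event
  requires `|K| > 2` µV/sample on both channels with opposite signs and
  window correlation `r < -0.85` (lateral saccades deflect F3 and F4 in
  opposite directions; common-mode blinks are rejected).
- **Group statistics** — two-tailed t tests (pooled/Welch/paired), critical
  values, Spearman stage trends, response-error summaries.
- **Synthetic study generator** — a deterministic, seedable simulator of the
  full 12-subject × 2-condition × 7-stage design (band-limited Gaussian
  components with fatigue-scheduled powers, scheduled theta coupling,
  injected anti-correlated ocular events, Samn–Perelli scores, binomial
  response errors), used to validate every stage of the pipeline.

I/O: recordings as CSV (one row per channel, JSON metadata sidecar) or
16-bit EDF; aggregated results as a study-table CSV.

## Worked example

```r
library(drivefatigue)

cfg   <- sim_config(n_subjects = 4, stages = 7, fs = 128,
                    epoch_seconds = 30, seed = 42)
study <- simulate_study(cfg, keep_recordings = FALSE)
res   <- analyze_study(study, threshold = 0.3475)
summary(res)
```

```
Driving-fatigue study analysis: 56 epochs, network threshold T = 0.3475

Stage trends (Spearman rho of stage vs per-stage mean):
  normal.C               rho = +0.991
  normal.G               rho = +1.000
  normal.power_ratio     rho = -1.000
  normal.eye_rate        rho = -0.955
  normal.sq_score        rho = +0.955
  mrm.C                  rho = +0.579
  mrm.G                  rho = +0.955
  mrm.power_ratio        rho = -1.000
  mrm.eye_rate           rho = -0.536
  mrm.sq_score           rho = +0.883

Condition comparisons (normal vs MRM stage means, alpha = 0.05):
      column     t df       p t_crit significant
           C  2.63 12 0.02201   2.18        TRUE
           G  2.91 12 0.01312   2.18        TRUE
 power_ratio -2.42 12 0.03250   2.18        TRUE
    eye_rate -3.79 12 0.00257   2.18        TRUE
    sq_score  1.48 12 0.16510   2.18       FALSE
```

Reading the output: under normal driving, network synchrony (`C`, `G`) rises
monotonically across the seven stages while the spectral ratio and the
eye-movement rate fall — the fatigue pattern. Every MRM trend is flatter,
and the 7-vs-7 stage-mean t tests (df = 12, pooled) find the between-mode
difference significant for all four EEG-derived indices. `res$table` holds
the per-epoch values (one row per subject × condition × stage);
`plot(res)` draws the four stage-trend panels.

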