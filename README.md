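# fnirslat

Sensor-level classification of real and imagined hand movement from
functional near-infrared spectroscopy (fNIRS) recordings of the primary
motor cortex, using hemispheric lateralization of the hemodynamic
response.

`fnirslat` is for researchers building or evaluating simple, parameter-free
fNIRS brain–computer-interface pipelines: it implements the full chain from
dual-wavelength optical density to a per-trial left/right/uncertain
decision, plus its statistical evaluation, and ships a synthetic session
generator so every stage can be exercised and tested without human data.

## The method

A 20-channel montage covers left (channels 1–10) and right (11–20) motor
cortex with a mirror pairing `i ↔ i + 10`. For each trial (5 s baseline,
15 s task, 15 s rest; command at *t* = 5 s):

1. **Reconstruction.** Optical-density changes at 785/850 nm are converted
   to oxy-/deoxyhemoglobin concentration changes (HbO, HbR) with the
   modified Beer–Lambert law; a zero-phase 4th-order Butterworth band-pass
   (0.01–0.1 Hz) removes drift, Mayer waves (~0.1 Hz), respiration
   (~0.25 Hz) and heartbeat (~1 Hz); each trial is baseline-corrected
   against its own 5-s pre-command mean.
2. **Mapping.** Per channel, the task-window average
   `⟨H_i⟩_T` over `T = [5, 20)` s is computed; pairwise differences
   `dH_ij = ⟨H_i⟩ − ⟨H_j⟩` are sign-filtered (positive for HbO, negative
   for HbR), and only entries in the fourth quartile of each matrix's
   empirical CDF (`F ≥ 0.75`) are kept, giving sparse connectivity
   matrices `δH` whose strongest rows identify the informative symmetric
   pairs (typically `{2,7,8} ↔ {12,17,18}`).
3. **Classification.** For each selected pair, the left-minus-right
   window-averaged differences `⟨ΔH_HbO⟩_T`, `⟨ΔH_HbR⟩_T` are computed.
   A pair with `⟨ΔH_HbO⟩ > 0 ∧ ⟨ΔH_HbR⟩ < 0` votes right (`CR += 1`);
   the mirrored pattern votes left (`CL += 1`). The trial label is
   `right` if `CR > CL`, `left` if `CR < CL`, else `uncertain`.
4. **Evaluation.** With right-hand trials as the positive class:
   `TPF = TP/(TP+FN)·100`, `TNF = TN/(TN+FP)·100`, `FPF = 100 − TNF`;
   the hard-label classifier yields a two-segment ROC
   `(0,0)–(FPF,TPF)–(100,100)` and its trapezoid AUC; k-fold
   cross-validation (default `k = 10`, 20 trials per held-out subsample)
   re-runs the channel-selection stage on each training split.

## Worked example

A synthetic 20-trial motor-imagery session at SNR 1 (a deliberately hard
operating point), end to end:

```r
library(fnirslat)
cfg <- pipeline_config(condition = "imagery", snr = 1,
                       trials_per_condition = 10, seed = 7)
report <- run_pipeline(cfg)
print(report)
#> == fnirslat pipeline report ==
#> pairs: 7:17 8:18 2:12
#> confusion (right = positive): TP 7  FP 3  TN 7  FN 3  (uncertain 5, policy error)
#> TPF 70.0%  TNF 70.0%  FPF 30.0%  accuracy 70.0%
#> ROC AUC: 0.700
```

Reading the output: the mapping stage recovered the three injected
informative pairs (2:12, 7:17, 8:18) from the data alone; of the 20
trials, 14 were classified correctly, 5 were uncertain (tied evidence,
charged as errors under the default policy) and 1 was wrong; sensitivity
and specificity are both 70 % at this small n and low SNR, giving a
two-segment ROC with AUC 0.70. At the package's standard surrogate
operating points (200 trials, seed 42) the same pipeline reaches 100 %
sensitivity for execution at SNR 3 and 89 % overall accuracy for imagery
at SNR 1 — numbers computed by `scripts/acceptance.R` below.

The command line mirrors the R API (`simulate`, `preprocess`, `map`,
`classify`, `evaluate`, `run`), e.g.:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec/fnirslat", package="fnirslat"))')" \
  simulate --condition execution --trials 10 --seed 1 --out session.tsv
```

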