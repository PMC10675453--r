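# counet

Cardiac output (CO) estimation from paired photoplethysmography (PPG) and
invasive arterial pressure (ART) waveforms with a dual-channel 1-D U-Net
regression model.

## The problem

CO — the blood volume one ventricle ejects per minute, ~4.5–6 L/min at
rest — is central to hemodynamic management, but the thermodilution gold
standard requires a pulmonary artery catheter. PPG and ART are monitored
routinely and carry complementary information about pump function and
vascular state. `counet` learns the waveform → CO mapping end to end: a
4-level one-dimensional U-Net (convolutional encoder/decoder with skip
connections) augmented with two bidirectional LSTM layers at the
bottleneck and one before the fully connected scalar head, trained with
MSE loss on 2048-sample (4.096 s at 500 Hz) dual-channel segments.

The package is aimed at researchers validating deep pulse-contour
methods: it ships the full chain — a physiologically structured waveform
simulator with a known ground-truth law `CO = HR · SV / 1000`,
`SV = a + b · PP` (pulse pressure PP in mmHg), Butterworth 0.5–10 Hz
band-pass preprocessing, segmentation around each CO reading, a
seven-rule segment quality screen, CPU training/prediction, and a
method-comparison statistics suite: bias, population SD of differences,
95% limits of agreement (bias ± 1.96·SD), MAE/MSE/RMSE, RMSNE and
percentage error (PE = 100 · 1.96·SD / mean reference CO; < 30% is the
Critchley clinical-acceptability criterion), Pearson r, Bland–Altman
data and the identity-line least-squares fit.

## Worked example

Simulate a small cohort, run the full pipeline under one seed, and read
the agreement report (a few minutes on one CPU at this reduced scale):

```r
library(counet)

cfg <- pipeline_config(
  n_cases = 20,
  model = model_config(input_length = 128, base_filters = 8,
                       bottleneck_lstm_units = 16, head_lstm_units = 16),
  train = train_config(epochs = 30),
  seed  = 42
)
res <- run_pipeline(cfg)
res$agreement
```

```
Agreement over 108 pairs (mean reference CO 4.941 L/min)
  bias  +0.008 L/min   std 0.131   LOA [-0.250, +0.265]
  MAE 0.106   MSE 0.017   RMSE 0.132 L/min
  RMSNE 2.7%   PE 5.2% (clinically acceptable, < 30%)   Pearson r 0.992
```

Read: on held-out synthetic segments the model's predictions deviate from
the reference CO by +0.008 L/min on average, 95% of individual
differences fall within [−0.25, +0.27] L/min, and the percentage error of
5.2% is far below the 30% clinical-acceptability bound — at desk scale
the network recovers the simulator's waveform→CO law almost exactly
(r = 0.99). The manifest carries the stage-by-stage bookkeeping:

```r
str(res$manifest[c("n_cases_read", "n_segment_candidates",
                   "n_boundary_dropped", "n_qc_kept",
                   "n_train", "n_test", "best_epoch")])
```

```
List of 7
 $ n_cases_read        : int 20
 $ n_segment_candidates: int 600   # 30 CO readings per 60-s case
 $ n_boundary_dropped  : int 60    # readings lacking full 2048-sample context
 $ n_qc_kept           : int 540
 $ n_train             : int 432   # floor(0.8 * 540)
 $ n_test              : int 108
 $ best_epoch          : int 30
```

Individual stages are exported too: `generate_dataset()`,
`inject_artifact()` (targeted per-rule QC violations),
`bandpass_filter()`, `segment_record()`, `screen_dataset()`,
`build_model()` / `train_model()` / `predict_co()`,
`compute_agreement()` / `bland_altman()` / `identity_fit()`, and CSV/YAML
I/O (`write_case_csv()`, `read_run_config()`). A thin CLI wrapper lives
at `inst/cli/counet.R` (`simulate`, `run`, `evaluate`).

## Scientific notes

See `vignettes/cardiac-output-estimation.Rmd` for the model and training
protocol, the quality-screen thresholds and their reading, the
synthetic-data generator's beat model and priors (and what passing tests
on it do and do not show), numerical choices, and known limitations.
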