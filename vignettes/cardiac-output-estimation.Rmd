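---
title: "Estimating cardiac output from PPG and arterial pressure waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cardiac output from PPG and arterial pressure waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cardiac output (CO) — the blood volume one ventricle ejects per minute,
normally around 4.5–6 L/min — is a central hemodynamic variable, but its
clinical gold standard (pulmonary-artery-catheter thermodilution) is
invasive enough that it is reserved for critically ill patients. Two
routinely monitored signals carry related information at far lower risk:
the photoplethysmogram (PPG), an optical measure of subcutaneous blood
volume, and the invasive arterial pressure waveform (ART), whose peak and
trough are systolic and diastolic pressure. Classical pulse-contour
formulas extract hand-crafted features (pulse pressure, areas under the
curve) from one of these signals; `counet` instead learns the mapping
end to end with a dual-channel one-dimensional U-Net regression model,
using a commercial CO monitor's readings as the reference label.

The package provides the entire chain — simulation, preprocessing, quality
screening, model, agreement analysis — so the method can be exercised and
validated on synthetic data with a known ground truth, and applied
unchanged to real exported records with the same CSV schema.

## Data model and preprocessing

A *case* is 60 s of paired PPG/ART at 500 Hz plus CO readings every 2 s
(`extract_middle_window()` trims longer records to their middle 60 s;
cases with missing samples in that window are dropped, and every drop is
counted and logged). Each CO reading anchors one candidate *segment*: the
2048 samples (4.096 s) centred on the reading — long enough for a full
respiratory cycle at ~0.25 Hz, and a multiple of 16 as four factor-2
pooling stages require. Candidates lacking full context at the record
edges are dropped and counted.

Both channels are band-pass filtered with a second-order Butterworth
filter, 0.5–10 Hz. Filtering is zero-phase (forward–backward) by default:
the model consumes both channels jointly, and a causal pass would shift
their morphology against each other; a causal mode remains available
(`filter_config(zero_phase = FALSE)`). Model inputs are min–max scaled to
[0, 1] per segment per channel. CO labels are scaled through the *fixed*
physiologic bounds 2–10 L/min rather than the dataset range, so the
inverse map is data independent and saved models are portable.

## The seven-rule quality screen

Quality control runs on the **raw** windows — the 0.5 Hz high-pass removes
the DC level, so absolute thresholds are only meaningful before filtering.
A segment is kept only if all of the following hold (`qc_config()`
defaults):

| rule | threshold | rationale |
|---|---|---|
| `co_range` | 2–10 L/min | physiologic range of CO |
| `art_amplitude` | every sample in 30–200 mmHg | admissible pressure band |
| `ppg_amplitude` | every sample in 10–100 a.u. | admissible PPG band |
| `art_peak_to_peak` | ≥ 30 mmHg | pulse pressure below 30 mmHg is unreliable |
| `ppg_peak_to_peak` | ≥ 20 a.u. | near-flat PPG carries no pulse information |
| `ppg_slew` | adjacent diff ≤ 20 a.u. | blood volume cannot jump in 2 ms |
| `art_slew` | adjacent diff ≤ 30 mmHg | pressure cannot jump in 2 ms |
| `completeness` | no missing samples | empty cells in the source export |

Two readings of the rules were genuinely open and are fixed here: the slew
screens use *absolute* adjacent differences (catching both polarities),
and the amplitude screens require *every* sample in band, not just the
extrema — otherwise they would duplicate the peak-to-peak rules. A segment
failing several rules counts once in `n_failed` but in each rule's tally,
so failure attribution stays honest. Rejected segments are dropped, never
repaired.

## The model

`build_model()` assembles a 4-level encoder/decoder U-Net adapted to
one-dimensional signals. Each encoder level is a same-padded convolution
(kernel 3) + rectifier followed by factor-2 max pooling; channel counts
start at `base_filters` (16 by default) and double per level while the
temporal length halves, so level *k* sees length `input_length / 2^k`.
The decoder mirrors this with nearest-neighbour upsampling + convolution,
concatenating the matching encoder features (skip connections) before a
second convolution. Two bidirectional LSTM layers sit at the bottleneck,
where the sequence is short and summarizing long-range temporal structure
is cheapest; one further bidirectional LSTM reads the full-resolution
decoded sequence, and its two final states feed a single fully connected
unit producing the scalar CO estimate (flattening the whole sequence into
the dense layer would explode the parameter count for no benefit).

Training (`train_config()`) minimizes mean-squared error on the scaled
labels with Adam at learning rate 0.001 and batch size 32, tracking mean
absolute error as the metric; the optimizer choice is the community
default for this architecture family, the other protocol values are the
package defaults. Data are split 8:2 into training and test at the
segment level (`split_dataset()`; a `split_level = "case"` option keeps
whole cases on one side — segment-level splitting leaks case identity
between sides and is kept as the default only because it matches the
protocol the reference statistics assume). Ten percent of the training
set (`round(0.1 * n)`) is held out for validation; by default one fixed
subset serves all epochs, because re-sampling the hold-out each epoch
(available as `val_mode = "per_epoch_resample"`) makes the "best
validation epoch" criterion noisy. The returned weights are those of the
epoch with the smallest validation loss.

All convolution and LSTM forward/backward passes are implemented in the
package (R with compiled kernels for the sequential recurrences and tap
shifts); every gradient is validated against central finite differences
in the test suite to 1e-7 absolute, which is the strongest available
oracle for the training machinery.

## The synthetic-data generator

`generate_case()` builds waveforms from a beat-level model: ART beats are
an asymmetric cosine-rise/exponential-decay pulse between diastolic and
systolic pressure; PPG beats are a two-Gaussian pulse (systolic peak plus
dicrotic bump). A respiratory oscillation (0.25 Hz, 3 mmHg on ART, 2 a.u.
on PPG) and white noise (SD 0.5) are added, and heart rate and pulse
pressure drift slowly within a record so CO varies between readings.

The ground-truth law is `CO = HR × SV / 1000` with stroke volume
`SV = 23 + 0.8 × PP` mL — a monotone, learnable waveform-to-CO relation.
Because model inputs are min–max normalized per segment, absolute pulse
pressure is invisible to the model; the ART beat therefore also encodes
SV in its *morphology*: the systolic (ejection) fraction of the beat
widens with SV, as left-ventricular ejection time does physiologically.
The PPG beat shape is deliberately fixed, so the PPG channel carries rate
but not stroke-volume information — which is what makes the dual-channel
versus PPG-only comparison structurally meaningful on synthetic data.

Population spread comes from per-case priors (`case_priors()`): heart
rate ~ N(77, 15²) clipped to [45, 120] bpm, pulse pressure ~ N(52, 17²)
clipped to [32, 90] mmHg, diastolic pressure ~ N(70, 8²). Under the
stroke-volume law these imply CO ≈ 5.0 ± 1.45 L/min (delta method,
`co_prior_moments()`), truncated to [2, 10] — close to the 5.01 ± 1.60
L/min of intra-operative cohorts. Matching the cohort SD exactly would
require adding per-case variation that the waveform does not encode,
which would put a hard ceiling on achievable recovery; the priors were
chosen once on these physiological grounds.

What the simulator does *not* attempt: biophysical pulse-wave propagation
(no Windkessel dynamics, no wave reflections), motion artifacts with
realistic spectra, sensor drift, or arrhythmias. Passing the recovery
tests therefore shows that the pipeline and model are wired correctly and
can extract a morphology-plus-rate signal from normalized dual-channel
input — it does not certify performance on clinical recordings.

`inject_artifact()` produces targeted violations — one QC rule each — for
every screening rule (slew spikes, flat PPG, compressed pulse pressure,
slow out-of-band excursions, out-of-range CO, missing samples), each
engineered not to trip neighbouring rules (ramps outside the affected
window, bump slopes far below the slew limits).

## Numerical and design choices

* CO reading *k* is anchored at waveform sample `round(k × 2 s × 500 Hz)`
  (1-based), i.e. stamped at the end of its averaging interval, and its
  window is the 1024 samples before and 1024 from the anchor. Real-world
  exports with a different alignment convention only need their
  timestamps mapped to this anchoring when read (`read_case_csv()` does
  this from the CO timestamps).
* With this convention a default 60-s case yields 30 candidate segments
  of which 27 survive (the first reading lacks leading context, the last
  two lack trailing context).
* The agreement module (`compute_agreement()`) uses the signed mean
  difference as bias and the population (1/n) standard deviation of the
  differences; the limits of agreement are bias ± 1.96 × SD. RMSNE and
  percentage error are reported in percent of the mean reference CO *of
  the evaluated pairs*. Pearson correlation on a constant sequence is an
  explicit error, never a silent zero.
* Zero peak-to-peak channels, non-finite samples reaching the filter, and
  architecture/length mismatches all raise classed validation errors
  naming the offending field; nothing is dropped silently
  (`log_event()` records every rejection with its reason, visible with
  `options(counet.verbose = TRUE)`).
* One global pipeline seed fans out deterministically to per-stage seeds
  (simulation, split, initialization, training), so identical seeds give
  bit-identical runs and any stage can be re-run standalone.

## Problem sizes used in the shipped experiments

The package's own validation experiments (test suite and
`scripts/acceptance.R`) run at a reduced scale chosen for a single CPU:
75 simulated cases (≈ 2,000 segments), 60 training epochs, windows
subsampled to `input_length = 128` (integer stride 16 from the 2048-point
window), 8 base filters and 16 LSTM units. At this scale the held-out
Pearson correlation between predicted and ground-truth CO is ≈ 0.99 and
the dual-channel model's test MSE is roughly two orders of magnitude
below the PPG-only model's. The full-size configuration (2048-point
inputs, 16 base filters, 64 LSTM units, 500 epochs) is the package
default and runs unchanged, just longer.

## Known limitations

* The synthetic waveform → CO relation is imposed, not physical; recovery
  results quantify pipeline correctness, not clinical accuracy.
* Segment-level splitting (the default, matching the reference protocol)
  leaks case identity across train/test; use `split_level = "case"` for
  honest generalization estimates on real data.
* Repeated segments from one case are treated as independent pairs in the
  agreement analysis (no repeated-measures correction of the limits of
  agreement), and no confidence intervals are reported for the limits.
* The exact layer widths of the reference architecture are not public;
  `model_config()` declares this package's defaults, all overridable.
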