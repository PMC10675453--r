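#' Simulation configuration for one synthetic case
#'
#' Describes a single synthetic monitoring episode: paired PPG and arterial
#' pressure (ART) waveforms sampled at `sampling_rate`, with a cardiac
#' oscillation near `heart_rate`/60 Hz, a respiratory oscillation near
#' `respiratory_rate`/60 Hz, and reference cardiac output (CO) readings every
#' `co_interval_s` seconds.
#'
#' The simulator's ground-truth law ties CO to the waveforms through
#' `CO = HR * SV / 1000` (L/min) with stroke volume
#' `SV = sv_intercept + sv_slope * PP` (mL), where `PP` is the arterial pulse
#' pressure `systolic_mmHg - diastolic_mmHg`. Because model inputs are min-max
#' normalized per segment, absolute pulse pressure is not visible to the
#' model; the ART beat therefore also encodes SV in its morphology (the
#' systolic ejection fraction of the beat widens with SV, as left-ventricular
#' ejection time does physiologically). Heart rate and pulse pressure drift
#' slowly over the record (`hr_drift`, `pp_drift`, relative amplitudes) so CO
#' varies between readings within a case.
#'
#' @param sampling_rate Sampling frequency in Hz (default 500).
#' @param duration_s Record length in seconds (default 60).
#' @param heart_rate Mean heart rate in beats/min (default 75).
#' @param respiratory_rate Respiratory rate in cycles/min (default 15,
#'   i.e. 0.25 Hz).
#' @param systolic_mmHg,diastolic_mmHg Arterial pressure extremes in mmHg
#'   (defaults 120 / 70). `diastolic_mmHg` must be below `systolic_mmHg`.
#' @param ppg_baseline,ppg_amplitude PPG level and pulse amplitude in
#'   arbitrary units (defaults 50 / 30, keeping clean samples inside the
#'   10-100 a.u. screening band).
#' @param noise_sd Additive white-noise standard deviation per channel
#'   (default 0.5, in each channel's units).
#' @param co_interval_s Spacing of CO readings in seconds (default 2).
#' @param sv_intercept,sv_slope Coefficients of the stroke-volume law in mL
#'   and mL/mmHg (defaults 23 and 0.8).
#' @param hr_drift,pp_drift Relative amplitude of the slow within-record
#'   drift of heart rate and pulse pressure (defaults 0.02 and 0.03; set to
#'   0 for a stationary record).
#' @param resp_amp_art,resp_amp_ppg Amplitude of the additive respiratory
#'   oscillation on each channel (3 mmHg, 2 a.u.).
#' @param co_noise_sd Standard deviation of the reference-monitor noise added
#'   to the CO readings in L/min (default 0.05).
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   case bit for bit.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_case()], [generate_dataset()]
#' @export
sim_config <- function(sampling_rate = 500, duration_s = 60, heart_rate = 75,
                       respiratory_rate = 15, systolic_mmHg = 120,
                       diastolic_mmHg = 70, ppg_baseline = 50,
                       ppg_amplitude = 30, noise_sd = 0.5, co_interval_s = 2,
                       sv_intercept = 23, sv_slope = 0.8, hr_drift = 0.02,
                       pp_drift = 0.03, resp_amp_art = 3, resp_amp_ppg = 2,
                       co_noise_sd = 0.05, seed = 1L) {
  check_number(sampling_rate, "sampling_rate", lower = 1e-9)
  check_number(duration_s, "duration_s", lower = 1e-9)
  check_number(co_interval_s, "co_interval_s", lower = 1e-9)
  check_number(heart_rate, "heart_rate", lower = 20, upper = 250)
  check_number(respiratory_rate, "respiratory_rate", lower = 1, upper = 80)
  check_number(systolic_mmHg, "systolic_mmHg", lower = 1)
  check_number(diastolic_mmHg, "diastolic_mmHg", lower = 1)
  if (diastolic_mmHg >= systolic_mmHg) {
    abort_validation("field 'diastolic_mmHg' must be below 'systolic_mmHg'",
                     field = "diastolic_mmHg")
  }
  check_number(ppg_baseline, "ppg_baseline", lower = 0)
  check_number(ppg_amplitude, "ppg_amplitude", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(sv_intercept, "sv_intercept")
  check_number(sv_slope, "sv_slope")
  check_number(hr_drift, "hr_drift", lower = 0, upper = 0.5)
  check_number(pp_drift, "pp_drift", lower = 0, upper = 0.5)
  check_number(resp_amp_art, "resp_amp_art", lower = 0)
  check_number(resp_amp_ppg, "resp_amp_ppg", lower = 0)
  check_number(co_noise_sd, "co_noise_sd", lower = 0)
  check_number(seed, "seed")
  structure(
    list(sampling_rate = sampling_rate, duration_s = duration_s,
         heart_rate = heart_rate, respiratory_rate = respiratory_rate,
         systolic_mmHg = systolic_mmHg, diastolic_mmHg = diastolic_mmHg,
         ppg_baseline = ppg_baseline, ppg_amplitude = ppg_amplitude,
         noise_sd = noise_sd, co_interval_s = co_interval_s,
         sv_intercept = sv_intercept, sv_slope = sv_slope,
         hr_drift = hr_drift, pp_drift = pp_drift,
         resp_amp_art = resp_amp_art, resp_amp_ppg = resp_amp_ppg,
         co_noise_sd = co_noise_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Physiologic CO bounds used for label screening, truncation and scaling.
CO_MIN <- 2
CO_MAX <- 10

# Asymmetric arterial beat shape on [0, 1): cosine rise to 1 at phase `p`,
# exponential decay back to exactly 0 at wrap, so consecutive beats join
# continuously. `p` is the systolic (ejection) fraction of the beat.
art_beat_shape <- function(u, p, tau = 0.3) {
  e1 <- exp(-(1 - p) / tau)
  ifelse(u < p,
         0.5 * (1 - cos(pi * u / p)),
         (exp(-(u - p) / tau) - e1) / (1 - e1))
}

# Two-Gaussian PPG beat (systolic peak + dicrotic bump), fixed morphology:
# the PPG channel intentionally carries rate but not stroke-volume shape
# information.
ppg_beat_shape <- function(u) {
  exp(-0.5 * ((u - 0.32) / 0.10)^2) + 0.45 * exp(-0.5 * ((u - 0.62) / 0.12)^2)
}

# Systolic fraction of the ART beat as a function of stroke volume (mL).
systolic_fraction <- function(sv) {
  pmin(pmax(0.10 + 0.002 * sv, 0.12), 0.42)
}

#' Generate one synthetic PPG/ART/CO case
#'
#' Produces a [waveform record][generate_case] with `duration_s *
#' sampling_rate` samples per channel and one CO reading every
#' `co_interval_s` seconds, the first at `t = co_interval_s`. CO reading `k`
#' is anchored at waveform sample `round(k * co_interval_s * sampling_rate)`
#' (1-based), i.e. the reading is stamped at the end of its averaging
#' interval. `true_co` holds the noise-free ground truth
#' `HR(t) * SV(t) / 1000` at each reading; `co_values` adds monitor noise.
#' Both are truncated to the physiologic range 2-10 L/min.
#'
#' @param config A [sim_config()].
#' @return A list of class `waveform_record` with elements `case_id`, `ppg`,
#'   `art`, `co_values`, `co_sample_indices` (1-based), `true_co`,
#'   `sampling_rate`, `co_interval_s`.
#' @examples
#' rec <- generate_case(sim_config(seed = 1))
#' length(rec$ppg)        # 30000 samples (60 s at 500 Hz)
#' length(rec$co_values)  # 30 readings
#' @export
generate_case <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort_validation("'config' must be a sim_config object", field = "config")
  }
  fs <- config$sampling_rate
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(config$seed, {
    phase_hr <- stats::runif(1, 0, 2 * pi)
    phase_pp <- stats::runif(1, 0, 2 * pi)
    phase_resp <- stats::runif(1, 0, 2 * pi)

    hr_t <- config$heart_rate *
      (1 + config$hr_drift * sin(2 * pi * t / config$duration_s + phase_hr))
    pp0 <- config$systolic_mmHg - config$diastolic_mmHg
    pp_t <- pp0 *
      (1 + config$pp_drift * sin(2 * pi * t / config$duration_s + phase_pp))
    sv_t <- config$sv_intercept + config$sv_slope * pp_t

    # cardiac phase in cycles; beat phase = fractional part
    phi <- cumsum(hr_t / 60) / fs
    u <- phi - floor(phi)

    f_resp <- config$respiratory_rate / 60
    resp <- sin(2 * pi * f_resp * t + phase_resp)

    p_sys <- systolic_fraction(sv_t)
    art <- config$diastolic_mmHg + pp_t * art_beat_shape(u, p_sys) +
      config$resp_amp_art * resp +
      stats::rnorm(n, sd = config$noise_sd)

    g <- ppg_beat_shape(u)
    gn <- (g - min(g)) / (max(g) - min(g)) - 0.5
    ppg <- config$ppg_baseline +
      config$ppg_amplitude * gn * (1 + 0.05 * resp) +
      config$resp_amp_ppg * sin(2 * pi * f_resp * t + phase_resp + 0.5) +
      stats::rnorm(n, sd = config$noise_sd)

    n_co <- floor(config$duration_s / config$co_interval_s)
    co_idx <- round(seq_len(n_co) * config$co_interval_s * fs)
    co_idx <- co_idx[co_idx >= 1 & co_idx <= n]
    true_co <- hr_t[co_idx] * sv_t[co_idx] / 1000
    true_co <- pmin(pmax(true_co, CO_MIN), CO_MAX)
    co_values <- true_co + stats::rnorm(length(co_idx), sd = config$co_noise_sd)
    co_values <- pmin(pmax(co_values, CO_MIN), CO_MAX)

    structure(
      list(case_id = sprintf("sim_%08d", config$seed),
           ppg = ppg, art = art,
           co_values = co_values,
           co_sample_indices = as.integer(co_idx),
           true_co = true_co,
           sampling_rate = fs,
           co_interval_s = config$co_interval_s),
      class = "waveform_record"
    )
  })
}

#' Population priors for a synthetic dataset
#'
#' Per-case physiological parameters are drawn from truncated normal priors.
#' With the defaults the implied population CO is approximately 5.0 +/- 1.45
#' L/min (before truncation to 2-10 L/min), close to the 5.01 +/- 1.60 L/min
#' typical of intra-operative cohorts.
#'
#' @param hr_mean,hr_sd,hr_min,hr_max Heart-rate prior (beats/min).
#' @param pp_mean,pp_sd,pp_min,pp_max Pulse-pressure prior (mmHg).
#' @param dia_mean,dia_sd,dia_min,dia_max Diastolic-pressure prior (mmHg).
#' @param ppg_baseline_mean,ppg_baseline_sd PPG baseline prior (a.u.).
#' @param ppg_amplitude_mean,ppg_amplitude_sd,ppg_amplitude_min,ppg_amplitude_max
#'   PPG pulse-amplitude prior (a.u.).
#' @return An object of class `case_priors`.
#' @export
case_priors <- function(hr_mean = 77, hr_sd = 15, hr_min = 45, hr_max = 120,
                        pp_mean = 52, pp_sd = 17, pp_min = 32, pp_max = 90,
                        dia_mean = 70, dia_sd = 8, dia_min = 50, dia_max = 95,
                        ppg_baseline_mean = 50, ppg_baseline_sd = 5,
                        ppg_amplitude_mean = 30, ppg_amplitude_sd = 4,
                        ppg_amplitude_min = 22, ppg_amplitude_max = 45) {
  structure(as.list(environment()), class = "case_priors")
}

#' Analytic moments of the prior CO distribution
#'
#' First-order (delta-method) mean and standard deviation of
#' `CO = HR * (sv_intercept + sv_slope * PP) / 1000` under independent
#' heart-rate and pulse-pressure priors, ignoring truncation. Used to check
#' that simulated datasets match their configured population.
#'
#' @param priors A [case_priors()].
#' @param sv_intercept,sv_slope Stroke-volume law coefficients (see
#'   [sim_config()]).
#' @return A list with elements `mean` and `sd` (L/min).
#' @export
co_prior_moments <- function(priors = case_priors(), sv_intercept = 23,
                             sv_slope = 0.8) {
  sv_mu <- sv_intercept + sv_slope * priors$pp_mean
  mu <- priors$hr_mean * sv_mu / 1000
  d_hr <- sv_mu / 1000
  d_pp <- priors$hr_mean * sv_slope / 1000
  v <- d_hr^2 * priors$hr_sd^2 + d_pp^2 * priors$pp_sd^2 +
    (sv_slope / 1000)^2 * priors$hr_sd^2 * priors$pp_sd^2
  list(mean = mu, sd = sqrt(v))
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic dataset of cases
#'
#' Draws case-specific heart rate, pressures and PPG levels from
#' [case_priors()] and simulates each case with [generate_case()]. Fully
#' reproducible: the same `seed` yields identical records.
#'
#' @param base_config A [sim_config()] providing everything the priors do not
#'   override (sampling rate, duration, noise, stroke-volume law, ...).
#' @param n_cases Number of cases (>= 1).
#' @param seed Integer seed for the dataset draw.
#' @param priors A [case_priors()].
#' @return A list of `waveform_record` objects.
#' @export
generate_dataset <- function(base_config = sim_config(), n_cases, seed = 1L,
                             priors = case_priors()) {
  if (!is.numeric(n_cases) || length(n_cases) != 1L || n_cases < 1) {
    abort_validation("field 'n_cases' must be >= 1", field = "n_cases")
  }
  n_cases <- as.integer(n_cases)
  params <- with_seed(seed, {
    data.frame(
      hr = rnorm_trunc(n_cases, priors$hr_mean, priors$hr_sd,
                       priors$hr_min, priors$hr_max),
      pp = rnorm_trunc(n_cases, priors$pp_mean, priors$pp_sd,
                       priors$pp_min, priors$pp_max),
      dia = rnorm_trunc(n_cases, priors$dia_mean, priors$dia_sd,
                        priors$dia_min, priors$dia_max),
      ppg_base = rnorm_trunc(n_cases, priors$ppg_baseline_mean,
                             priors$ppg_baseline_sd, 40, 60),
      ppg_amp = rnorm_trunc(n_cases, priors$ppg_amplitude_mean,
                            priors$ppg_amplitude_sd,
                            priors$ppg_amplitude_min,
                            priors$ppg_amplitude_max),
      case_seed = sample.int(.Machine$integer.max - 1L, n_cases)
    )
  })
  lapply(seq_len(n_cases), function(i) {
    cfg <- sim_config(
      sampling_rate = base_config$sampling_rate,
      duration_s = base_config$duration_s,
      heart_rate = params$hr[i],
      respiratory_rate = base_config$respiratory_rate,
      systolic_mmHg = params$dia[i] + params$pp[i],
      diastolic_mmHg = params$dia[i],
      ppg_baseline = params$ppg_base[i],
      ppg_amplitude = params$ppg_amp[i],
      noise_sd = base_config$noise_sd,
      co_interval_s = base_config$co_interval_s,
      sv_intercept = base_config$sv_intercept,
      sv_slope = base_config$sv_slope,
      hr_drift = base_config$hr_drift,
      pp_drift = base_config$pp_drift,
      resp_amp_art = base_config$resp_amp_art,
      resp_amp_ppg = base_config$resp_amp_ppg,
      co_noise_sd = base_config$co_noise_sd,
      seed = params$case_seed[i]
    )
    rec <- generate_case(cfg)
    rec$case_id <- sprintf("case_%04d", i)
    rec
  })
}
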