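#' @title Synthetic DEAP-shaped EEG
#' @name synthetic
#' @description
#' The generator emits two-class (relaxed vs sad) trials in the exact DEAP
#' preprocessed shape — 128 Hz, 63 s (3-s baseline + 60-s stimulus), rated
#' on the 1-9 valence/arousal scales — with controllable Low/High Alpha
#' oscillator amplitudes, a class-specific amplitude change at a
#' configurable onset time, pink background noise and inter-channel
#' correlation. It exists so the whole pipeline, including the parameter-
#' recovery tests of the ERA search, runs with no external dataset.
NULL

#' Synthetic-data configuration
#'
#' Before `onset_s` (seconds after stimulus start) both classes share the
#' base amplitudes; from the onset each class applies its own, so placing a
#' High Alpha boost for the relaxed class at 45 s confines the separating
#' signal to the final 15 s of the stimulus (the 4th of 4 period groups).
#'
#' @param fs Sampling rate in Hz.
#' @param total_s,baseline_s Trial and baseline durations in seconds.
#' @param n_channels 2 (O1/O2) or 32 (full DEAP montage).
#' @param base_low_amp,base_high_amp Shared pre-onset Low/High Alpha
#'   oscillator amplitudes in microvolts.
#' @param relaxed,sad Per-class lists `list(low_alpha_amp, high_alpha_amp,
#'   onset_s)`: post-onset amplitudes and the onset time.
#' @param noise_amp Pink-noise RMS amplitude in microvolts.
#' @param pink_exponent Spectral exponent of the 1/f^a background.
#' @param inter_channel_corr Correlation of the oscillatory component
#'   between channels, in \[0, 1\].
#' @param onset_ramp_s Linear ramp length of the amplitude step in seconds.
#' @param n_trials_per_class Trials per class.
#' @param seed Master seed; every trial derives its own stream from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs = 128, total_s = 63, baseline_s = 3,
                         n_channels = 2,
                         base_low_amp = 10, base_high_amp = 10,
                         relaxed = list(low_alpha_amp = 10,
                                        high_alpha_amp = 20, onset_s = 45),
                         sad = list(low_alpha_amp = 10,
                                    high_alpha_amp = 10, onset_s = 45),
                         noise_amp = 10, pink_exponent = 1,
                         inter_channel_corr = 0.8, onset_ramp_s = 1,
                         n_trials_per_class = 20, seed = 1) {
  for (cl in list(relaxed, sad)) {
    if (cl$onset_s < 0 || cl$onset_s > total_s - baseline_s)
      stop("onset_s must lie in [0, ", total_s - baseline_s,
           "] seconds after stimulus start")
    if (cl$low_alpha_amp < 0 || cl$high_alpha_amp < 0)
      stop("amplitudes must be >= 0")
  }
  if (!(n_channels %in% c(2L, 32L)))
    stop("n_channels must be 2 (O1/O2) or 32 (DEAP montage)")
  if (inter_channel_corr < 0 || inter_channel_corr > 1)
    stop("inter_channel_corr must be in [0, 1]")
  if (n_trials_per_class < 1) stop("n_trials_per_class must be >= 1")
  structure(list(fs = fs, total_s = total_s, baseline_s = baseline_s,
                 n_channels = as.integer(n_channels),
                 base_low_amp = base_low_amp, base_high_amp = base_high_amp,
                 relaxed = relaxed, sad = sad,
                 noise_amp = noise_amp, pink_exponent = pink_exponent,
                 inter_channel_corr = inter_channel_corr,
                 onset_ramp_s = onset_ramp_s,
                 n_trials_per_class = as.integer(n_trials_per_class),
                 seed = seed),
            class = "synth_config")
}

# unit-RMS pink (1/f^a) noise of length n via spectral shaping
.pink_noise <- function(n, exponent = 1) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1))          # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)            # symmetric over positive/negative freqs
  X <- X * f^(-exponent / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# amplitude envelope: base before onset, class level after, linear ramp
.envelope <- function(n, fs, baseline_s, onset_s, ramp_s, base, post) {
  t <- (seq_len(n) - 1) / fs
  t_on <- baseline_s + onset_s
  frac <- pmin(pmax((t - t_on) / max(ramp_s, 1e-9), 0), 1)
  base + (post - base) * frac
}

# one sub-band oscillator: amplitude-jittered sinusoid, random freq/phase
.oscillator <- function(n, fs, freq_range) {
  f <- stats::runif(1, freq_range[1], freq_range[2])
  phase <- stats::runif(1, 0, 2 * pi)
  jit_phase <- stats::runif(1, 0, 2 * pi)
  t <- (seq_len(n) - 1) / fs
  jitter <- 1 + 0.2 * sin(2 * pi * 0.1 * t + jit_phase)  # slow +-20% AM
  sin(2 * pi * f * t + phase) * jitter
}

#' Generate one synthetic trial
#'
#' Signal = pink noise + Low Alpha (8-10 Hz) and High Alpha (11-13 Hz)
#' amplitude-modulated oscillators with randomized frequency and phase.
#' Class-specific amplitudes apply from `baseline_s + onset_s` (linear
#' ramp). Channels share each oscillator through the configured
#' inter-channel correlation (`rho * common + sqrt(1 - rho^2) * private`);
#' noise is independent per channel. Deterministic per `(cfg$seed,
#' trial_seed)`.
#'
#' @param class_name `"relaxed"` or `"sad"`.
#' @param cfg A [synth_config()].
#' @param trial_seed Integer distinguishing trials under one master seed.
#' @return A [recording()].
#' @export
generate_trial <- function(class_name, cfg, trial_seed = 1) {
  if (!class_name %in% c("relaxed", "sad"))
    stop("unknown class '", class_name, "' (use relaxed or sad)")
  cls <- cfg[[class_name]]
  n <- round(cfg$total_s * cfg$fs)
  rho <- cfg$inter_channel_corr
  ch_names <- if (cfg$n_channels == 2) c("O1", "O2") else deap_channels()
  env_low <- .envelope(n, cfg$fs, cfg$baseline_s, cls$onset_s,
                       cfg$onset_ramp_s, cfg$base_low_amp, cls$low_alpha_amp)
  env_high <- .envelope(n, cfg$fs, cfg$baseline_s, cls$onset_s,
                        cfg$onset_ramp_s, cfg$base_high_amp,
                        cls$high_alpha_amp)
  samples <- .with_seed((cfg$seed * 10007L + trial_seed) %% 2147483647L, {
    common_low <- .oscillator(n, cfg$fs, c(8, 10))
    common_high <- .oscillator(n, cfg$fs, c(11, 13))
    m <- matrix(0, nrow = cfg$n_channels, ncol = n)
    for (ch in seq_len(cfg$n_channels)) {
      osc_low <- rho * common_low +
        sqrt(1 - rho^2) * .oscillator(n, cfg$fs, c(8, 10))
      osc_high <- rho * common_high +
        sqrt(1 - rho^2) * .oscillator(n, cfg$fs, c(11, 13))
      noise <- if (cfg$noise_amp > 0)
        cfg$noise_amp * .pink_noise(n, cfg$pink_exponent) else 0
      m[ch, ] <- env_low * osc_low + env_high * osc_high + noise
    }
    m
  })
  recording(samples, fs = cfg$fs, channel_names = ch_names,
            baseline_s = cfg$baseline_s, subject_id = "SYN1",
            trial_id = sprintf("%s-%03d", class_name, trial_seed))
}

#' Generate a two-class synthetic recording set
#'
#' Relaxed and sad trials are interleaved; relaxed trials get ratings
#' (valence 7, arousal 3) mapping to the LAHV quadrant, sad trials
#' (valence 3, arousal 3) mapping to LALV.
#'
#' @param cfg A [synth_config()].
#' @return A [recording_set()] of `2 * n_trials_per_class` recordings,
#'   writable through [write_recording_set()].
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  recs <- list(); val <- numeric(0); aro <- numeric(0)
  for (i in seq_len(cfg$n_trials_per_class)) {
    recs[[length(recs) + 1L]] <- generate_trial("relaxed", cfg, 2L * i - 1L)
    val <- c(val, 7); aro <- c(aro, 3)
    recs[[length(recs) + 1L]] <- generate_trial("sad", cfg, 2L * i)
    val <- c(val, 3); aro <- c(aro, 3)
  }
  recording_set(recs, data.frame(valence = val, arousal = aro))
}
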