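#' Protocol configuration for the synthetic cohort
#'
#' Describes the balloon-inflation protocol emulated by the simulator: a
#' baseline phase followed by stepwise intracranial pressure (ICP) targets,
#' each held for a fixed duration. Defaults correspond to the study
#' conditions: 5 min baseline around 12.4 mmHg, then four 6-min injury steps
#' at 20/30/40/50 mmHg, single-channel EEG at 250 Hz, 30 subjects.
#'
#' Hemodynamic traces (ICP/MAP/HR) are generated at `hemo_fs` (default
#' 10 Hz), a deliberate reduction of the original 1 kHz acquisition: the
#' analysis only ever consumes epoch-mean values, for which 10 Hz is ample.
#'
#' @param baseline_duration Baseline phase length in seconds.
#' @param injury_step_duration Length of each injury step in seconds
#'   (including the initial ramp).
#' @param icp_targets Strictly increasing ICP plateau targets in mmHg.
#' @param baseline_icp_mean Mean baseline ICP in mmHg.
#' @param eeg_fs EEG sampling rate in Hz (must be an integer multiple of
#'   `hemo_fs` and at least twice the top of the gamma band).
#' @param hemo_fs Sampling rate of the ICP/MAP/HR traces in Hz.
#' @param n_subjects Number of subjects in a generated cohort.
#' @param ramp_duration Linear ramp length at the start of each step, s.
#' @param icp_jitter_sd SD of the additive Gaussian ICP jitter, mmHg.
#' @param subject_amp_sd SD (log scale) of the per-subject log-normal EEG
#'   amplitude factor.
#' @param subject_weight_sd SD of the per-subject jitter added to the band
#'   weights before renormalization.
#' @param include_recovery Append a recovery phase with suppressed
#'   (flattened) EEG while ICP ramps back to baseline. Off by default:
#'   recovery EEG is not analyzable in this model and is excluded from the
#'   analysis protocol.
#' @param recovery_duration Recovery phase length in seconds.
#' @param seed Default master seed used by [generate_cohort()].
#' @return An object of class `protocol_config` (a validated list).
#' @export
protocol_config <- function(baseline_duration = 300,
                            injury_step_duration = 360,
                            icp_targets = c(20, 30, 40, 50),
                            baseline_icp_mean = 12.4,
                            eeg_fs = 250,
                            hemo_fs = 10,
                            n_subjects = 30,
                            ramp_duration = 30,
                            icp_jitter_sd = 1.5,
                            subject_amp_sd = 0.15,
                            subject_weight_sd = 0.02,
                            include_recovery = FALSE,
                            recovery_duration = 360,
                            seed = 42L) {
  stopifnot(baseline_duration > 0, injury_step_duration > 0,
            hemo_fs > 0, eeg_fs > 0, n_subjects >= 1,
            ramp_duration >= 0, ramp_duration < injury_step_duration,
            icp_jitter_sd >= 0, recovery_duration > 0)
  if (length(icp_targets) > 0 && any(diff(icp_targets) <= 0))
    stop("icp_targets must be strictly increasing")
  if (eeg_fs %% hemo_fs != 0)
    stop("eeg_fs must be an integer multiple of hemo_fs")
  if (eeg_fs < 2 * 47)
    stop("eeg_fs must satisfy Nyquist for the highest generated band (47 Hz)")
  structure(list(
    baseline_duration = baseline_duration,
    injury_step_duration = injury_step_duration,
    icp_targets = icp_targets,
    baseline_icp_mean = baseline_icp_mean,
    eeg_fs = eeg_fs,
    hemo_fs = hemo_fs,
    n_subjects = as.integer(n_subjects),
    ramp_duration = ramp_duration,
    icp_jitter_sd = icp_jitter_sd,
    subject_amp_sd = subject_amp_sd,
    subject_weight_sd = subject_weight_sd,
    include_recovery = include_recovery,
    recovery_duration = recovery_duration,
    seed = as.integer(seed)
  ), class = "protocol_config")
}

#' ICP bin index
#'
#' Maps ICP values (mmHg) to the five analysis bins:
#' `<20`, `[20,30)`, `[30,40)`, `[40,50)`, `>=50`.
#'
#' @param icp Numeric vector of ICP values in mmHg.
#' @return Integer vector of bin indices in 1..5.
#' @export
icp_bin <- function(icp) {
  findInterval(icp, c(20, 30, 40, 50)) + 1L
}

#' Names of the five ICP bins
#' @return Character vector of length 5.
#' @export
icp_bin_labels <- function() {
  c("icp_lt20", "icp_20_30", "icp_30_40", "icp_40_50", "icp_ge50")
}

band_names <- c("delta", "theta", "alpha", "beta", "gamma")

#' Spectral profile of the synthetic EEG
#'
#' A spectral profile specifies, for each of the five ICP bins, the relative
#' power weights of the five conventional EEG bands and the target RMS
#' amplitude of the signal, plus the fraction of total variance carried by a
#' pink-noise (1/f) background common to all bins.
#'
#' @param band_weights 5x5 numeric matrix (rows = ICP bins low to high,
#'   columns = delta/theta/alpha/beta/gamma); each row must sum to 1.
#' @param amplitude_scale Positive numeric vector of length 5: target RMS
#'   amplitude (micro-volts) per ICP bin.
#' @param pink_noise_fraction Fraction of variance in the pink background,
#'   in `[0, 1)`.
#' @return An object of class `spectral_profile`.
#' @export
spectral_profile <- function(band_weights, amplitude_scale,
                             pink_noise_fraction = 0.3) {
  band_weights <- as.matrix(band_weights)
  stopifnot(nrow(band_weights) == 5, ncol(band_weights) == 5,
            length(amplitude_scale) == 5, all(amplitude_scale > 0),
            pink_noise_fraction >= 0, pink_noise_fraction < 1,
            all(band_weights >= 0))
  if (any(abs(rowSums(band_weights) - 1) > 1e-8))
    stop("each band_weights row must sum to 1")
  dimnames(band_weights) <- list(icp_bin_labels(), band_names)
  structure(list(band_weights = band_weights,
                 amplitude_scale = setNames(amplitude_scale, icp_bin_labels()),
                 pink_noise_fraction = pink_noise_fraction),
            class = "spectral_profile")
}

#' Default ICP-dependent spectral profile
#'
#' Band weights shift monotonically from slow- to fast-dominated activity as
#' ICP rises (theta share falls, beta/gamma shares rise) and the overall RMS
#' amplitude grows, emulating the reported tendency of the higher-frequency
#' components (>= 13 Hz) to increase under intracranial hypertension.
#' Amplitudes track the reported per-bin EEG magnitudes (roughly 32 to
#' 42 micro-volts RMS).
#'
#' @return A `spectral_profile`.
#' @export
default_spectral_profile <- function() {
  w <- rbind(
    c(0.440, 0.145, 0.175, 0.220, 0.020),
    c(0.425, 0.135, 0.182, 0.230, 0.028),
    c(0.385, 0.120, 0.185, 0.270, 0.040),
    c(0.350, 0.105, 0.185, 0.305, 0.055),
    c(0.270, 0.080, 0.190, 0.380, 0.080))
  spectral_profile(w, c(32.5, 33.5, 37.5, 38.0, 41.5), 0.3)
}

#' Flat (signal-free) spectral profile
#'
#' Identical band weights and amplitude in every ICP bin: the EEG carries no
#' information about ICP. Used as the negative control for the pipeline.
#'
#' @return A `spectral_profile`.
#' @export
flat_spectral_profile <- function() {
  w <- matrix(rep(c(0.440, 0.145, 0.175, 0.220, 0.020), each = 5), 5, 5)
  spectral_profile(w, rep(35, 5), 0.3)
}

## Deterministic (noise-free) ICP mean profile at hemo-trace resolution,
## plus tiling phase annotations. Sample i sits at centred time (i-0.5)/fs.
icp_mean_profile <- function(config) {
  fs <- config$hemo_fs
  segs <- list()
  phases <- data.frame(phase = character(), start_s = numeric(),
                       end_s = numeric(), stringsAsFactors = FALSE)
  t0 <- 0
  level <- config$baseline_icp_mean
  segs[[1]] <- rep(config$baseline_icp_mean,
                   round(config$baseline_duration * fs))
  phases <- rbind(phases, data.frame(phase = "baseline", start_s = 0,
                                     end_s = config$baseline_duration))
  t0 <- config$baseline_duration
  for (target in config$icp_targets) {
    n_step <- round(config$injury_step_duration * fs)
    n_ramp <- round(config$ramp_duration * fs)
    tt <- (seq_len(n_step) - 0.5) / fs
    seg <- ifelse(tt < config$ramp_duration & n_ramp > 0,
                  level + (target - level) * tt / config$ramp_duration,
                  target)
    segs[[length(segs) + 1]] <- seg
    phases <- rbind(phases, data.frame(
      phase = paste0("step_", target), start_s = t0,
      end_s = t0 + config$injury_step_duration))
    t0 <- t0 + config$injury_step_duration
    level <- target
  }
  if (config$include_recovery && length(config$icp_targets) > 0) {
    n_rec <- round(config$recovery_duration * fs)
    tt <- (seq_len(n_rec) - 0.5) / fs
    seg <- level + (config$baseline_icp_mean - level) *
      pmin(tt / config$recovery_duration, 1)
    segs[[length(segs) + 1]] <- seg
    phases <- rbind(phases, data.frame(phase = "recovery", start_s = t0,
                                       end_s = t0 + config$recovery_duration))
    t0 <- t0 + config$recovery_duration
  }
  list(mean = unlist(segs), phases = phases, duration = t0)
}

#' Generate a piecewise ICP trace
#'
#' Baseline around the configured baseline mean, then for each injury step a
#' linear ramp (`ramp_duration`, default 30 s) followed by a plateau at the
#' step target, with additive Gaussian jitter throughout.
#'
#' @param config A [protocol_config()].
#' @param seed Integer RNG seed.
#' @return A list with `icp` (mmHg, at `hemo_fs`), `fs`, `time` (centred
#'   sample times, s), and `phases` (data frame `phase`, `start_s`, `end_s`
#'   tiling the record).
#' @export
generate_icp_trace <- function(config, seed = config$seed) {
  prof <- icp_mean_profile(config)
  set.seed(seed)
  icp <- prof$mean + rnorm(length(prof$mean), 0, config$icp_jitter_sd)
  list(icp = icp, fs = config$hemo_fs,
       time = (seq_along(icp) - 0.5) / config$hemo_fs,
       phases = prof$phases)
}

## Per-bin anchors for MAP (mmHg) and HR (beats/min), rising with ICP.
## MAP anchors are the monotone envelope of the reported per-bin means.
map_anchors <- c(90.2, 91.6, 101.1, 101.1, 120.1)
hr_anchors  <- c(96.1, 103.2, 104.9, 114.8, 134.8)

#' Generate MAP and HR traces consistent with an ICP protocol
#'
#' Hemodynamics follow the ICP bin of the noise-free protocol profile:
#' mean arterial pressure and heart rate step up with the ICP bin toward
#' their high-ICP anchors, with additive Gaussian jitter.
#'
#' @param config A [protocol_config()].
#' @param seed Integer RNG seed.
#' @return List with `map` and `hr` numeric vectors at `hemo_fs`.
#' @export
generate_hemo_traces <- function(config, seed = config$seed + 1L) {
  prof <- icp_mean_profile(config)
  bin <- icp_bin(prof$mean)
  set.seed(seed)
  n <- length(bin)
  list(map = map_anchors[bin] + rnorm(n, 0, 5),
       hr  = hr_anchors[bin] + rnorm(n, 0, 6))
}

## Unit-variance noise confined to [lo, hi) Hz via FFT brick-wall masking.
## shape = "flat" gives a flat in-band spectrum; "pink" gives 1/f power.
bandlimited_noise <- function(n, fs, lo, hi, shape = c("flat", "pink")) {
  shape <- match.arg(shape)
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f_eff <- pmin(f, fs - f)
  keep <- f_eff >= lo & f_eff < hi
  gain <- as.numeric(keep)
  if (shape == "pink")
    gain[keep] <- 1 / sqrt(f_eff[keep])
  y <- Re(fft(X * gain, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) stop("degenerate band-limited noise (empty band?)")
  y / s
}

#' Generate a synthetic EEG record from an ICP trace
#'
#' The signal is a pink-noise background plus five band-limited stochastic
#' oscillators (delta/theta/alpha/beta/gamma). At every sample the band
#' weights and the target RMS amplitude are looked up from the spectral
#' profile using the concurrent ICP bin, so the spectral composition tracks
#' the ICP level. Fully reproducible from the seed.
#'
#' @param icp_trace ICP trace in mmHg sampled at `hemo_fs`.
#' @param profile A [spectral_profile()].
#' @param fs EEG sampling rate, Hz (>= 100).
#' @param seed Integer RNG seed.
#' @param hemo_fs Sampling rate of `icp_trace`, Hz.
#' @param suppression Optional per-hemo-sample multiplicative amplitude
#'   envelope (e.g. to flatten the EEG during a recovery phase).
#' @return Numeric vector of EEG samples (micro-volts) of length
#'   `length(icp_trace) * fs / hemo_fs`.
#' @export
generate_eeg <- function(icp_trace, profile, fs = 250, seed = 1L,
                         hemo_fs = 10, suppression = NULL) {
  if (length(icp_trace) == 0) stop("icp_trace must be non-empty")
  if (fs < 100) stop("fs too low to represent the gamma band (need >= 100 Hz)")
  if (fs %% hemo_fs != 0) stop("fs must be an integer multiple of hemo_fs")
  up <- fs / hemo_fs
  n <- length(icp_trace) * up
  bin <- rep(icp_bin(icp_trace), each = up)
  w <- profile$band_weights[bin, , drop = FALSE]       # n x 5
  amp <- profile$amplitude_scale[bin]
  if (!is.null(suppression)) {
    stopifnot(length(suppression) == length(icp_trace))
    amp <- amp * rep(suppression, each = up)
  }
  pf <- profile$pink_noise_fraction
  edges <- c(0.5, 4, 8, 13, 30, 47)
  set.seed(seed)
  x <- sqrt(pf) * bandlimited_noise(n, fs, 0.5, 47, "pink")
  for (b in seq_len(5)) {
    osc <- bandlimited_noise(n, fs, edges[b], edges[b + 1], "flat")
    x <- x + sqrt((1 - pf) * w[, b]) * osc
  }
  as.numeric(amp * x)
}

#' Generate one synthetic subject record
#'
#' Applies per-subject random effects to the spectral profile (a log-normal
#' amplitude factor and Gaussian jitter on the band weights, renormalized),
#' then generates ICP, MAP, HR and EEG traces.
#'
#' @param config A [protocol_config()].
#' @param profile A [spectral_profile()].
#' @param subject_id Character id.
#' @param seed Integer RNG seed for this subject.
#' @return An object of class `subject_record`: a list with `subject_id`,
#'   `eeg`, `eeg_fs`, `icp`, `map`, `hr`, `hemo_fs`, `phases`.
#' @export
generate_subject <- function(config, profile, subject_id, seed) {
  set.seed(seed)
  amp_factor <- rlnorm(1, 0, config$subject_amp_sd)
  w <- profile$band_weights +
    matrix(rnorm(25, 0, config$subject_weight_sd), 5, 5)
  w <- pmax(w, 0.005)
  w <- w / rowSums(w)
  subj_profile <- spectral_profile(w, profile$amplitude_scale * amp_factor,
                                   profile$pink_noise_fraction)
  trace <- generate_icp_trace(config, seed + 1L)
  hemo <- generate_hemo_traces(config, seed + 2L)
  ## the EEG spectral state follows the protocol's underlying ICP level,
  ## not the superimposed measurement jitter
  icp_state <- icp_mean_profile(config)$mean
  suppression <- NULL
  if (config$include_recovery) {
    rec <- trace$phases[trace$phases$phase == "recovery", ]
    if (nrow(rec) == 1) {
      suppression <- rep(1, length(trace$icp))
      suppression[trace$time >= rec$start_s] <- 0.2
    }
  }
  eeg <- generate_eeg(icp_state, subj_profile, fs = config$eeg_fs,
                      seed = seed + 3L, hemo_fs = config$hemo_fs,
                      suppression = suppression)
  structure(list(subject_id = subject_id, eeg = eeg, eeg_fs = config$eeg_fs,
                 icp = trace$icp, map = hemo$map, hr = hemo$hr,
                 hemo_fs = config$hemo_fs, phases = trace$phases),
            class = "subject_record")
}

#' Generate a synthetic cohort
#'
#' @param config A [protocol_config()].
#' @param profile A [spectral_profile()]; default [default_spectral_profile()].
#' @param seed Master seed; per-subject seeds are derived deterministically
#'   from it.
#' @return An object of class `cohort`: a list of `subject_record`s.
#' @export
generate_cohort <- function(config = protocol_config(),
                            profile = default_spectral_profile(),
                            seed = config$seed) {
  seed <- as.integer(seed)
  records <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    subj_seed <- as.integer((abs(as.numeric(seed)) + 7919 * i) %% 2000000000)
    records[[i]] <- generate_subject(config, profile,
                                     sprintf("pig_%02d", i), subj_seed)
  }
  structure(records, class = "cohort")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record %s: %.0f s EEG @ %g Hz, %d hemo samples @ %g Hz>\n",
              x$subject_id, length(x$eeg) / x$eeg_fs, x$eeg_fs,
              length(x$icp), x$hemo_fs))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort of %d subjects>\n", length(x)))
  invisible(x)
}
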