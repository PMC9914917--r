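#' Band-pass filter specification
#'
#' Zero-phase Butterworth band-pass applied forward and backward
#' ([signal::filtfilt]), so the filtered record has no group delay.
#'
#' @param low_cut Lower passband edge, Hz.
#' @param high_cut Upper passband edge, Hz.
#' @param order Butterworth design order (per direction).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 0.5, high_cut = 47, order = 4) {
  stopifnot(low_cut > 0, high_cut > low_cut, order >= 1)
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order)), class = "filter_spec")
}

## One filtering pass with the filter initialized at its steady-state
## response to a constant input equal to the first sample, so a constant
## signal produces its exact steady-state output with no start-up
## transient (the initialization used by MATLAB/scipy filtfilt).
filter_steady <- function(b, a, x) {
  x0 <- x[1]
  y_ss <- x0 * sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x0, length(b) - 1),
                            init.y = rep(y_ss, length(a) - 1)))
}

## Zero-phase forward-backward filtering with odd-reflection padding.
zero_phase_filter <- function(b, a, x) {
  nfact <- 3 * (max(length(a), length(b)) - 1)
  if (length(x) <= nfact)
    stop(sprintf("signal too short to filter (need > %d samples)", nfact))
  left <- 2 * x[1] - x[(nfact + 1):2]
  right <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - nfact)]
  xp <- c(left, x, right)
  y <- filter_steady(b, a, xp)
  y <- rev(filter_steady(b, a, rev(y)))
  y[(nfact + 1):(nfact + length(x))]
}

#' Zero-phase band-pass filter a signal
#'
#' Butterworth band-pass applied forward and backward with
#' odd-reflection padding and steady-state initial conditions, so the
#' output has zero group delay and no start-up transient (a constant
#' input maps to its steady-state response, which for a band-pass is 0).
#'
#' @param x Numeric signal (micro-volts).
#' @param fs Sampling rate, Hz; must exceed `2 * high_cut`.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec()) {
  if (fs <= 2 * spec$high_cut)
    stop("sampling rate too low for the requested passband")
  bf <- signal::butter(spec$order,
                       c(spec$low_cut, spec$high_cut) / (fs / 2),
                       type = "pass")
  zero_phase_filter(bf$b, bf$a, x)
}

#' Epoch segmentation specification
#'
#' @param epoch_length Epoch length in seconds.
#' @param overlap Overlap between consecutive epochs, seconds
#'   (stride = `epoch_length - overlap`).
#' @param stabilization_exclusion Seconds excluded at the start of every
#'   injury step (hemodynamic stabilization).
#' @return Object of class `epoch_spec`.
#' @export
epoch_spec <- function(epoch_length = 2.0, overlap = 1.5,
                       stabilization_exclusion = 60) {
  stopifnot(epoch_length > 0, overlap >= 0, overlap < epoch_length,
            stabilization_exclusion >= 0)
  structure(list(epoch_length = epoch_length, overlap = overlap,
                 stride = epoch_length - overlap,
                 stabilization_exclusion = stabilization_exclusion),
            class = "epoch_spec")
}

#' Cut a signal into fixed-length overlapping epochs
#'
#' Epochs start at 0, stride, 2*stride, ...; every epoch holds exactly
#' `epoch_length * fs` samples and no partial trailing epoch is returned.
#' A signal shorter than one epoch yields zero epochs.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param spec An [epoch_spec()].
#' @return List with `starts` (epoch start times, s) and `samples`
#'   (matrix, `epoch_length * fs` rows by `n_epochs` columns).
#' @export
segment_epochs <- function(x, fs, spec = epoch_spec()) {
  n_samp <- round(spec$epoch_length * fs)
  dur <- length(x) / fs
  if (dur < spec$epoch_length)
    return(list(starts = numeric(0),
                samples = matrix(numeric(0), n_samp, 0)))
  n_ep <- floor((dur - spec$epoch_length) / spec$stride + 1e-9) + 1
  starts <- (seq_len(n_ep) - 1) * spec$stride
  idx0 <- round(starts * fs)              # 0-based first sample
  idx <- outer(seq_len(n_samp), idx0, `+`)
  list(starts = starts, samples = matrix(x[idx], nrow = n_samp))
}

#' Synchronize hemodynamics with epochs and attach IICP labels
#'
#' Each epoch's ICP/MAP/HR value is the mean of the trace samples whose
#' centred time falls inside the half-open epoch window
#' `[start, start + epoch_length)`. The binary IICP label is 1 when the
#' epoch-mean ICP is greater than or equal to `threshold` (inclusive).
#' The phase label is the phase at the epoch's start time.
#'
#' @param epochs Result of [segment_epochs()].
#' @param icp,map,hr Hemodynamic traces at `hemo_fs`.
#' @param hemo_fs Trace sampling rate, Hz.
#' @param phases Phase annotation data frame (`phase`, `start_s`, `end_s`).
#' @param threshold IICP threshold in mmHg (default 25, inclusive).
#' @param epoch_length Epoch length, s.
#' @param subject_id Subject identifier carried into the table.
#' @return Object of class `epoch_table`: list with `meta` (data frame
#'   `subject_id`, `start_s`, `phase`, `mean_icp`, `mean_map`, `mean_hr`,
#'   `iicp_label`) and `samples` (matrix, one column per epoch).
#' @export
synchronize_and_label <- function(epochs, icp, map, hr, hemo_fs, phases,
                                  threshold = 25, epoch_length = 2.0,
                                  subject_id = "subject") {
  starts <- epochs$starts
  n_ep <- length(starts)
  trace_dur <- length(icp) / hemo_fs
  if (n_ep > 0 && max(starts) + epoch_length > trace_dur + 1e-9)
    stop("hemodynamic traces do not cover all epoch windows")
  ## sample i centred at (i - 0.5)/hemo_fs lies in [s, s+L) iff
  ## i in (s*fs + 0.5, (s+L)*fs + 0.5]
  a <- floor(starts * hemo_fs + 0.5 + 1e-9) + 1
  b <- ceiling((starts + epoch_length) * hemo_fs + 0.5 - 1e-9) - 1
  b <- pmin(b, length(icp))
  seg_mean <- function(x) {
    cs <- c(0, cumsum(x))
    (cs[b + 1] - cs[a]) / (b - a + 1)
  }
  mean_icp <- seg_mean(icp)
  mean_map <- seg_mean(map)
  mean_hr <- seg_mean(hr)
  phase_idx <- findInterval(starts, phases$start_s)
  meta <- data.frame(
    subject_id = rep(subject_id, n_ep),
    start_s = starts,
    phase = phases$phase[phase_idx],
    mean_icp = mean_icp,
    mean_map = mean_map,
    mean_hr = mean_hr,
    iicp_label = as.integer(mean_icp >= threshold),
    stringsAsFactors = FALSE)
  structure(list(meta = meta, samples = epochs$samples,
                 epoch_length = epoch_length, threshold = threshold),
            class = "epoch_table")
}

#' Remove stabilization epochs at the start of each injury step
#'
#' Drops every epoch whose window intersects the first
#' `stabilization_exclusion` seconds of any injury step (phases named
#' `step_*`). Baseline epochs are retained in full, except those whose
#' window reaches into an exclusion zone.
#'
#' @param table An `epoch_table`.
#' @param spec An [epoch_spec()] providing `stabilization_exclusion`.
#' @param phases Phase annotations for the subject.
#' @return The filtered `epoch_table`.
#' @export
apply_exclusions <- function(table, spec, phases) {
  excl <- spec$stabilization_exclusion
  if (excl <= 0) return(table)
  steps <- phases[grepl("^step_", phases$phase), , drop = FALSE]
  keep <- rep(TRUE, nrow(table$meta))
  L <- table$epoch_length
  for (k in seq_len(nrow(steps))) {
    z0 <- steps$start_s[k]
    z1 <- z0 + excl
    hit <- table$meta$start_s < z1 & (table$meta$start_s + L) > z0
    keep <- keep & !hit
  }
  table$meta <- table$meta[keep, , drop = FALSE]
  rownames(table$meta) <- NULL
  table$samples <- table$samples[, keep, drop = FALSE]
  table
}

#' Filter, segment, synchronize and label one subject record
#'
#' Convenience wrapper running the whole preprocessing chain on a
#' `subject_record`: whole-record zero-phase band-pass, epoch segmentation,
#' hemodynamic synchronization, IICP labelling and stabilization exclusion.
#'
#' @param record A `subject_record`.
#' @param fspec A [filter_spec()].
#' @param espec An [epoch_spec()].
#' @param threshold IICP threshold, mmHg.
#' @return An `epoch_table`.
#' @export
preprocess_subject <- function(record, fspec = filter_spec(),
                               espec = epoch_spec(), threshold = 25) {
  filtered <- bandpass_filter(record$eeg, record$eeg_fs, fspec)
  epochs <- segment_epochs(filtered, record$eeg_fs, espec)
  tab <- synchronize_and_label(epochs, record$icp, record$map, record$hr,
                               record$hemo_fs, record$phases,
                               threshold = threshold,
                               epoch_length = espec$epoch_length,
                               subject_id = record$subject_id)
  apply_exclusions(tab, espec, record$phases)
}
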