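#' EEG band definition
#'
#' Conventional qEEG bands tiling the 0.5-47 Hz passband: delta 0.5-4,
#' theta 4-8, alpha 8-13, beta 13-30, gamma 30-47 Hz. Bands must be
#' contiguous and non-overlapping; each band is half-open `[lo, hi)`.
#'
#' @param delta,theta,alpha,beta,gamma Numeric `c(lo, hi)` pairs, Hz.
#' @return Object of class `band_definition`: named list of `c(lo, hi)`.
#' @export
band_definition <- function(delta = c(0.5, 4), theta = c(4, 8),
                            alpha = c(8, 13), beta = c(13, 30),
                            gamma = c(30, 47)) {
  bands <- list(delta = delta, theta = theta, alpha = alpha,
                beta = beta, gamma = gamma)
  for (b in bands) stopifnot(length(b) == 2, b[1] < b[2])
  edges <- unlist(bands)
  lo <- edges[seq(1, 9, 2)]
  hi <- edges[seq(2, 10, 2)]
  if (any(abs(hi[-5] - lo[-1]) > 1e-9))
    stop("bands must be contiguous and non-overlapping")
  structure(bands, class = "band_definition")
}

hann_window <- function(m) 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1) / m)

## Welch PSD of every column of M. Returns list(freq, psd) with psd a
## (m/2+1) x ncol matrix; one-sided density in units^2/Hz.
welch_psd_matrix <- function(M, fs, seg_seconds = 1, overlap = 0.5) {
  n <- nrow(M)
  m <- round(seg_seconds * fs)
  if (n < m) stop("need at least one full Welch segment of samples")
  step <- max(1L, round(m * (1 - overlap)))
  offsets <- seq(0L, n - m, by = step)
  w <- hann_window(m)
  U <- sum(w^2)
  half <- floor(m / 2)
  acc <- matrix(0, half + 1, ncol(M))
  for (o in offsets) {
    S <- M[(o + 1):(o + m), , drop = FALSE] * w
    X <- mvfft(S)
    acc <- acc + Mod(X[1:(half + 1), , drop = FALSE])^2
  }
  psd <- acc / (length(offsets) * fs * U)
  ## one-sided: double everything except DC (and Nyquist when m even)
  dbl <- rep(2, half + 1)
  dbl[1] <- 1
  if (m %% 2 == 0) dbl[half + 1] <- 1
  list(freq = (0:half) * fs / m, psd = psd * dbl)
}

#' Welch power spectral density of one epoch
#'
#' One-sided Welch estimate with 1-s Hann segments and 50% overlap
#' (defaults). The integral of the density approximates the signal
#' variance (Parseval consistency).
#'
#' @param x Numeric samples (>= 1 s).
#' @param fs Sampling rate, Hz.
#' @param seg_seconds Welch segment length, s.
#' @param overlap Fractional segment overlap in `[0, 1)`.
#' @return List with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
power_spectrum <- function(x, fs, seg_seconds = 1, overlap = 0.5) {
  if (length(x) == 0) stop("empty input")
  if (length(x) < seg_seconds * fs) stop("need at least 1 s of samples")
  res <- welch_psd_matrix(matrix(x, ncol = 1), fs, seg_seconds, overlap)
  list(freq = res$freq, psd = as.numeric(res$psd))
}

#' Absolute and relative band powers from a power spectrum
#'
#' Band power is the integral of the density over `[lo, hi)`; relative
#' power is each band's share of the summed five-band power (i.e. of total
#' 0.5-47 Hz power with default bands), so relative powers sum to 1.
#'
#' @param spectrum List with `freq` and `psd` (from [power_spectrum()]).
#' @param bands A [band_definition()].
#' @return List with `power` and `rel` (named numeric vectors) and `total`.
#' @export
band_powers <- function(spectrum, bands = band_definition()) {
  freq <- spectrum$freq
  df <- freq[2] - freq[1]
  p <- vapply(bands, function(b) {
    if (b[2] > max(freq) + df / 2)
      stop("band extends beyond the spectrum's frequency range")
    sel <- freq >= b[1] & freq < b[2]
    sum(spectrum$psd[sel]) * df
  }, numeric(1))
  total <- sum(p)
  rel <- if (total > 0) p / total else p * 0
  list(power = p, rel = rel, total = total)
}

#' Band-ratio qEEG indices
#'
#' From the five absolute band powers computes:
#' * `thetapr` = theta / total, `gammapr` = gamma / total (fractions);
#' * `dtabr` = log10((delta + theta) / (alpha + beta));
#' * `deltar` = log10(delta / (theta + alpha + beta + gamma)).
#'
#' Powers are floored at `1e-12 * total` before the log ratios.
#'
#' @param power Named numeric vector of the five band powers.
#' @return Named numeric vector `deltar`, `dtabr`, `thetapr`, `gammapr`.
#' @export
ratio_features <- function(power) {
  total <- sum(power)
  if (!is.finite(total) || total <= 0)
    stop("all-zero epoch: band ratios undefined")
  p <- pmax(power, 1e-12 * total)
  c(deltar = log10(p[["delta"]] /
                     (p[["theta"]] + p[["alpha"]] + p[["beta"]] + p[["gamma"]])),
    dtabr = log10((p[["delta"]] + p[["theta"]]) /
                    (p[["alpha"]] + p[["beta"]])),
    thetapr = power[["theta"]] / total,
    gammapr = power[["gamma"]] / total)
}

## Zero-phase brick-wall band-pass via FFT bin masking. Works on a matrix
## (one epoch per column). Exact band edges, no ripple, no group delay --
## appropriate for short fixed-length epochs.
fft_bandpass_matrix <- function(M, fs, lo, hi) {
  n <- nrow(M)
  f <- (seq_len(n) - 1) * fs / n
  f_eff <- pmin(f, fs - f)
  mask <- as.numeric(f_eff >= lo & f_eff < hi)
  X <- mvfft(M) * mask
  Re(mvfft(X, inverse = TRUE)) / n
}

#' Time-domain qEEG features of one epoch
#'
#' `magnitude` is the RMS amplitude of the epoch; `sd_<band>` is the
#' standard deviation of the epoch after zero-phase band-limiting to that
#' band (FFT brick-wall). All scale linearly with the signal amplitude.
#'
#' @param x Epoch samples (>= 2 s).
#' @param fs Sampling rate, Hz.
#' @param bands A [band_definition()].
#' @return Named numeric vector: `magnitude`, `sd_delta`, `sd_theta`,
#'   `sd_alpha`, `sd_beta`, `sd_gamma`.
#' @export
time_domain_features <- function(x, fs, bands = band_definition()) {
  if (length(x) < 2 * fs) stop("epoch must be at least 2 s long")
  M <- matrix(x, ncol = 1)
  out <- c(magnitude = sqrt(mean(x^2)))
  for (b in names(bands)) {
    xb <- fft_bandpass_matrix(M, fs, bands[[b]][1], bands[[b]][2])
    out[paste0("sd_", b)] <- sd(xb)
  }
  out
}

#' Log energy entropy of an epoch
#'
#' `sum_i log(x_i^2 + eps)` with natural log and `eps = 1e-12`.
#'
#' @param x Epoch samples.
#' @param eps Stabilizing floor added to each squared sample.
#' @return Scalar.
#' @export
log_energy_entropy <- function(x, eps = 1e-12) {
  if (length(x) == 0) stop("empty epoch")
  sum(log(x^2 + eps))
}

#' Feature registry: the candidate qEEG feature bank
#'
#' The first ten names form the selected panel of indices reported per ICP
#' bin (magnitude, band ratios, log energy entropy, band SDs); the rest are
#' additional candidates the ranking stage can draw on (remaining relative
#' powers, spectral entropy, 95% spectral edge frequency, line length,
#' zero-crossing rate, Hjorth mobility/complexity).
#'
#' @return Character vector of 20 feature names in canonical order.
#' @export
feature_registry <- function() {
  c("magnitude", "deltar", "dtabr", "thetapr", "gammapr",
    "log_energy_entropy", "sd_theta", "sd_alpha", "sd_beta", "sd_gamma",
    "rel_delta", "rel_alpha", "rel_beta", "sd_delta",
    "spectral_entropy", "sef95", "line_length", "zero_crossings",
    "hjorth_mobility", "hjorth_complexity")
}

#' The ten selected-panel feature names
#' @return Character vector of 10 names.
#' @export
selected_panel <- function() feature_registry()[1:10]

col_var <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  colSums(M^2) / (n - 1) - n / (n - 1) * mu^2
}

#' Extract the qEEG feature table from an epoch table
#'
#' Computes every requested feature for every epoch (vectorized across
#' epochs) and returns one row per epoch with the epoch metadata followed
#' by the feature columns in `bank` order. A pure function of its inputs.
#'
#' @param table An `epoch_table` (see [synchronize_and_label()]).
#' @param fs EEG sampling rate, Hz.
#' @param bands A [band_definition()].
#' @param bank Character vector of feature names (subset of
#'   [feature_registry()]).
#' @return Data frame: `subject_id`, `start_s`, `phase`, `mean_icp`,
#'   `mean_map`, `mean_hr`, `iicp_label`, then one column per feature.
#' @export
extract_feature_table <- function(table, fs, bands = band_definition(),
                                  bank = feature_registry()) {
  unknown <- setdiff(bank, feature_registry())
  if (length(unknown) > 0)
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         "; registry: ", paste(feature_registry(), collapse = ", "))
  M <- table$samples
  n_ep <- ncol(M)
  n <- nrow(M)
  if (n_ep == 0) {
    out <- table$meta
    for (f in bank) out[[f]] <- numeric(0)
    return(out)
  }
  ## spectral features from the Welch PSD
  sp <- welch_psd_matrix(M, fs)
  df <- sp$freq[2] - sp$freq[1]
  P <- matrix(0, 5, n_ep, dimnames = list(names(bands), NULL))
  for (b in names(bands)) {
    sel <- sp$freq >= bands[[b]][1] & sp$freq < bands[[b]][2]
    P[b, ] <- colSums(sp$psd[sel, , drop = FALSE]) * df
  }
  total <- colSums(P)
  if (any(total <= 0)) stop("all-zero epoch encountered")
  rel <- sweep(P, 2, total, "/")
  Pf <- pmax(P, rep(1e-12 * total, each = 5))
  feats <- list(
    thetapr = rel["theta", ],
    gammapr = rel["gamma", ],
    rel_delta = rel["delta", ],
    rel_alpha = rel["alpha", ],
    rel_beta = rel["beta", ],
    deltar = log10(Pf["delta", ] /
                     (Pf["theta", ] + Pf["alpha", ] + Pf["beta", ] + Pf["gamma", ])),
    dtabr = log10((Pf["delta", ] + Pf["theta", ]) /
                    (Pf["alpha", ] + Pf["beta", ])))
  ## in-band spectral entropy and spectral edge frequency
  inband <- sp$freq >= bands[[1]][1] & sp$freq < bands[[5]][2]
  Pin <- sp$psd[inband, , drop = FALSE]
  fin <- sp$freq[inband]
  ptot <- colSums(Pin)
  prel <- sweep(Pin, 2, ptot, "/")
  plog <- prel * log(pmax(prel, 1e-300))
  feats$spectral_entropy <- -colSums(plog) / log(nrow(Pin))
  cs <- apply(Pin, 2, cumsum)
  below <- colSums(cs < rep(0.95 * ptot, each = nrow(Pin)))
  feats$sef95 <- fin[pmin(below + 1, length(fin))]
  ## time-domain features
  feats$magnitude <- sqrt(colMeans(M^2))
  for (b in names(bands)) {
    xb <- fft_bandpass_matrix(M, fs, bands[[b]][1], bands[[b]][2])
    feats[[paste0("sd_", b)]] <- sqrt(colSums(xb^2) / (n - 1))
  }
  feats$log_energy_entropy <- colSums(log(M^2 + 1e-12))
  D1 <- diff(M)
  feats$line_length <- colMeans(abs(D1))
  sgn <- M >= 0
  feats$zero_crossings <- colSums(sgn[-1, , drop = FALSE] !=
                                    sgn[-n, , drop = FALSE]) / (n / fs)
  v0 <- col_var(M)
  v1 <- col_var(D1 * fs)
  v2 <- col_var(diff(D1) * fs^2)
  feats$hjorth_mobility <- sqrt(v1 / v0)
  feats$hjorth_complexity <- sqrt(v2 / v1) / sqrt(v1 / v0)
  out <- table$meta
  for (f in bank) out[[f]] <- as.numeric(feats[[f]])
  out
}
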