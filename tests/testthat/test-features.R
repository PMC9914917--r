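test_that("Welch spectrum localizes tones and conserves power", {
  fs <- 250
  x <- sine_epoch(10, fs)
  sp <- power_spectrum(x, fs)
  expect_equal(sp$freq[which.max(sp$psd)], 10)
  df <- sp$freq[2] - sp$freq[1]
  expect_equal(sum(sp$psd) * df, var(x), tolerance = 0.05)
  expect_true(all(sp$psd >= 0))
  expect_error(power_spectrum(numeric(0), fs), "empty")
  expect_error(power_spectrum(rnorm(100), fs), "at least 1 s")
})

test_that("averaged white-noise spectrum is flat", {
  fs <- 250
  set.seed(42)
  acc <- 0
  for (i in 1:100) {
    sp <- power_spectrum(rnorm(2 * fs), fs)
    acc <- acc + sp$psd
  }
  freq <- power_spectrum(rnorm(2 * fs), fs)$freq
  sel <- freq >= 1 & freq <= 45
  expect_lt(max(acc[sel]) / min(acc[sel]), 2)
})

test_that("equal-amplitude 2 Hz and 40 Hz tones split power equally", {
  fs <- 250
  x <- sine_epoch(2, fs, seconds = 4) + sine_epoch(40, fs, seconds = 4)
  bp <- band_powers(power_spectrum(x, fs))
  expect_equal(bp$power[["delta"]], bp$power[["gamma"]], tolerance = 0.05)
})

test_that("band powers capture in-band tones and sum to one", {
  fs <- 250
  for (case in list(c(6, "theta"), c(35, "gamma"))) {
    bp <- band_powers(power_spectrum(sine_epoch(as.numeric(case[1]), fs), fs))
    expect_gte(bp$rel[[case[2]]], 0.95)
    expect_equal(sum(bp$rel), 1, tolerance = 1e-9)
  }
  # five equal-amplitude tones, one per band centre
  x <- sine_epoch(2, fs, 4) + sine_epoch(6, fs, 4) + sine_epoch(10, fs, 4) +
    sine_epoch(20, fs, 4) + sine_epoch(38, fs, 4)
  bp <- band_powers(power_spectrum(x, fs))
  expect_true(all(abs(bp$rel - 0.2) < 0.03))
  # band outside the spectrum range
  wide <- band_definition(gamma = c(30, 200))
  expect_error(band_powers(power_spectrum(sine_epoch(10, fs), fs), wide),
               "beyond")
})

test_that("ratio features match their closed forms", {
  eq <- c(delta = 2, theta = 2, alpha = 2, beta = 2, gamma = 2)
  rf <- ratio_features(eq)
  expect_equal(rf[["dtabr"]], 0)
  expect_equal(rf[["thetapr"]], 0.2)
  rf2 <- ratio_features(c(delta = 1, theta = 1, alpha = 5, beta = 5,
                          gamma = 0))
  expect_equal(rf2[["dtabr"]], log10(2 / 10), tolerance = 1e-9)
  pure_theta <- c(delta = 0, theta = 10, alpha = 0, beta = 0, gamma = 0)
  expect_gte(ratio_features(pure_theta)[["thetapr"]], 0.95)
  expect_error(ratio_features(c(delta = 0, theta = 0, alpha = 0, beta = 0,
                                gamma = 0)), "all-zero")
})

test_that("time-domain features are exact on constructed epochs", {
  fs <- 250
  z <- time_domain_features(rep(0, 2 * fs), fs)
  expect_true(all(z == 0))
  x <- sine_epoch(10, fs)
  tf <- time_domain_features(x, fs)
  expect_equal(tf[["magnitude"]], 1 / sqrt(2), tolerance = 0.02)
  expect_equal(tf[["sd_alpha"]], 1 / sqrt(2), tolerance = 0.02)
  expect_lt(tf[["sd_beta"]], 0.05)
  # homogeneity: scaling the epoch scales every feature
  tf3 <- time_domain_features(3 * x, fs)
  expect_equal(as.numeric(tf3), 3 * as.numeric(tf), tolerance = 1e-9)
  expect_error(time_domain_features(rnorm(100), fs), "at least 2 s")
})

test_that("log energy entropy matches brute-force summation", {
  expect_equal(log_energy_entropy(rep(1, 500)), 500 * log(1 + 1e-12))
  expect_equal(log_energy_entropy(rep(exp(1), 500)), 1000, tolerance = 1e-6)
  set.seed(3)
  x <- rnorm(500)
  brute <- 0
  for (v in x) brute <- brute + log(v^2 + 1e-12)
  expect_equal(log_energy_entropy(x), brute, tolerance = 1e-9)
  expect_error(log_energy_entropy(numeric(0)), "empty")
})

test_that("feature table extraction conserves rows and respects the bank", {
  fs <- 250
  phases <- data.frame(phase = "baseline", start_s = 0, end_s = 300)
  set.seed(8)
  ep <- segment_epochs(rnorm(300 * fs, sd = 20), fs)
  tab <- synchronize_and_label(ep, rep(12, 3000), rep(90, 3000),
                               rep(100, 3000), 10, phases)
  ft <- extract_feature_table(tab, fs)
  expect_equal(nrow(ft), 597)
  expect_true(all(feature_registry() %in% names(ft)))
  # relative powers (incl. thetapr/gammapr) sum to one on every epoch
  rel_sum <- ft$rel_delta + ft$thetapr + ft$rel_alpha + ft$rel_beta +
    ft$gammapr
  expect_true(all(abs(rel_sum - 1) < 1e-6))
  # restricted bank projects columns
  ft1 <- extract_feature_table(tab, fs, bank = "thetapr")
  expect_equal(ncol(ft1), ncol(tab$meta) + 1)
  expect_error(extract_feature_table(tab, fs, bank = "nonsense"),
               "unknown feature")
  # pure function: identical output on identical input
  expect_identical(ft, extract_feature_table(tab, fs))
})

test_that("vectorized extraction agrees with single-epoch operations", {
  fs <- 250
  set.seed(12)
  ep <- segment_epochs(rnorm(6 * fs, sd = 15), fs)
  phases <- data.frame(phase = "baseline", start_s = 0, end_s = 6)
  tab <- synchronize_and_label(ep, rep(12, 60), rep(90, 60), rep(100, 60),
                               10, phases)
  ft <- extract_feature_table(tab, fs)
  for (j in c(1, 4, 9)) {
    x <- ep$samples[, j]
    bp <- band_powers(power_spectrum(x, fs))
    rf <- ratio_features(bp$power)
    td <- time_domain_features(x, fs)
    expect_equal(ft$thetapr[j], rf[["thetapr"]], tolerance = 1e-10)
    expect_equal(ft$gammapr[j], rf[["gammapr"]], tolerance = 1e-10)
    expect_equal(ft$dtabr[j], rf[["dtabr"]], tolerance = 1e-10)
    expect_equal(ft$deltar[j], rf[["deltar"]], tolerance = 1e-10)
    expect_equal(ft$magnitude[j], td[["magnitude"]], tolerance = 1e-10)
    expect_equal(ft$sd_beta[j], td[["sd_beta"]], tolerance = 1e-8)
    expect_equal(ft$log_energy_entropy[j], log_energy_entropy(x),
                 tolerance = 1e-9)
  }
})
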