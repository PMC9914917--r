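# Independent oracles and small fixtures shared across tests.

# Brute-force AUC: concordant-pair counting with half-credit for ties.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Confusion metrics recomputed from first principles, independently of
# confusion_metrics().
oracle_metrics <- function(tp, fp, tn, fn) {
  div0 <- function(a, b) if (b == 0) 0 else a / b
  n <- tp + fp + tn + fn
  mccd <- sqrt(as.numeric(tp + fp)) * sqrt(tp + fn) * sqrt(tn + fp) *
    sqrt(tn + fn)
  c(accuracy = (tp + tn) / n,
    sensitivity = div0(tp, tp + fn),
    specificity = div0(tn, tn + fp),
    precision = div0(tp, tp + fp),
    f1 = div0(2 * tp, 2 * tp + fp + fn),
    mcc = if (mccd == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / mccd)
}

# A sinusoid epoch sampled at fs, starting at t = 1/fs.
sine_epoch <- function(freq, fs = 250, seconds = 2, amplitude = 1) {
  amplitude * sin(2 * pi * freq * seq(1 / fs, seconds, by = 1 / fs))
}

# Small fast protocol for pipeline-level tests: 1 min baseline + two 2-min
# steps, 4 subjects.
fast_protocol <- function(n_subjects = 4, seed = 7L) {
  protocol_config(baseline_duration = 60, injury_step_duration = 120,
                  icp_targets = c(30, 50), ramp_duration = 10,
                  n_subjects = n_subjects, seed = seed)
}

# Planted two-class dataset: `n_informative` features with a class-mean
# shift, the rest pure noise.
planted_dataset <- function(n = 200, d = 10, n_informative = 2,
                            shift = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * d), n, d)
  X[, seq_len(n_informative)] <- X[, seq_len(n_informative)] +
    outer(y, rep(shift, n_informative))
  colnames(X) <- sprintf("f%02d", seq_len(d))
  list(X = X, y = y)
}

# Union length of a set of fixed-length windows (retained-coverage oracle).
window_union <- function(starts, len) {
  if (length(starts) == 0) return(0)
  st <- sort(starts)
  total <- 0
  cur_s <- st[1]
  cur_e <- st[1] + len
  for (s in st[-1]) {
    if (s <= cur_e) cur_e <- max(cur_e, s + len)
    else { total <- total + cur_e - cur_s; cur_s <- s; cur_e <- s + len }
  }
  total + cur_e - cur_s
}
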