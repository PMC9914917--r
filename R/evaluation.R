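#' Confusion counts from labels and predictions
#'
#' @param truth,pred Integer 0/1 vectors.
#' @return Named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  c(tp = sum(truth == 1 & pred == 1),
    fp = sum(truth == 0 & pred == 1),
    tn = sum(truth == 0 & pred == 0),
    fn = sum(truth == 1 & pred == 0))
}

#' Binary classification metrics from confusion counts
#'
#' Standard closed forms for accuracy, sensitivity (recall), specificity,
#' precision, F1 and the Matthews correlation coefficient. Any ratio with
#' a zero denominator is reported as 0 and the result is flagged
#' `degenerate` (the standard convention for MCC with a zero factor).
#'
#' @param tp,fp,tn,fn Non-negative counts; the total must be positive.
#' @return List: `accuracy`, `sensitivity`, `specificity`, `precision`,
#'   `f1`, `mcc`, `degenerate`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (n == 0) stop("all confusion counts are zero")
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  mcc_den2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den2 == 0) { degenerate <- TRUE; 0 } else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(mcc_den2)
  list(accuracy = (tp + tn) / n, sensitivity = sens, specificity = spec,
       precision = prec, f1 = f1, mcc = mcc, degenerate = degenerate)
}

#' ROC curve and AUC
#'
#' AUC is computed by the midrank (Mann-Whitney) formula, so tied scores
#' contribute 1/2. ROC points are produced at every distinct score
#' threshold from continuous scores.
#'
#' @param scores Numeric class-1 scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return List with `auc` and `roc` (data frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  cum_tp <- cumsum(labels[ord] == 1)
  cum_fp <- cumsum(labels[ord] == 0)
  last_of_thr <- cumsum(rle(scores[ord])$lengths)
  roc <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, cum_fp[last_of_thr] / n0),
                    tpr = c(0, cum_tp[last_of_thr] / n1))
  list(auc = auc, roc = roc)
}

#' Cluster-bootstrap confidence interval
#'
#' Resamples whole subjects (clusters) with replacement, recomputes the
#' statistic on each resample, and reports the percentile interval. Used
#' because epochs within a subject are strongly dependent, so epoch-level
#' resampling would be anti-conservative. Resamples on which the statistic
#' is undefined (`NA`) are redrawn, up to a cap.
#'
#' @param stat_fn Function taking a data frame and returning a scalar.
#' @param data Data frame with a `subject_id` column.
#' @param n_boot Number of bootstrap draws.
#' @param seed RNG seed.
#' @param level Interval coverage level.
#' @return Numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(stat_fn, data, n_boot = 1000, seed = 1L,
                         level = 0.95) {
  subjects <- unique(data$subject_id)
  if (length(subjects) < 2) {
    ## no between-cluster variance is estimable; interval degenerates
  }
  rows_by_subj <- split(seq_len(nrow(data)), data$subject_id)
  set.seed(seed)
  stats <- numeric(n_boot)
  draws <- 0
  i <- 1
  while (i <= n_boot) {
    if (draws > 10 * n_boot)
      stop("statistic undefined on too many bootstrap resamples")
    draws <- draws + 1
    pick <- sample(subjects, length(subjects), replace = TRUE)
    idx <- unlist(rows_by_subj[as.character(pick)], use.names = FALSE)
    s <- stat_fn(data[idx, , drop = FALSE])
    if (is.na(s)) next
    stats[i] <- s
    i <- i + 1
  }
  a <- (1 - level) / 2
  as.numeric(quantile(stats, c(a, 1 - a), names = FALSE))
}

#' Subject-level derivation/validation split
#'
#' First `n_derivation` subjects (cohort order) form the derivation group,
#' the rest the validation group — mirroring a 70/30 (21/9) split of a
#' 30-subject cohort.
#'
#' @param subject_ids Character vector of all subject ids, in cohort order.
#' @param n_derivation Number of derivation subjects (default 70%).
#' @return Object of class `split_plan`: list `derivation`, `validation`.
#' @export
split_plan <- function(subject_ids, n_derivation = round(0.7 * length(subject_ids))) {
  subject_ids <- unique(subject_ids)
  stopifnot(n_derivation >= 1, n_derivation < length(subject_ids))
  structure(list(derivation = subject_ids[seq_len(n_derivation)],
                 validation = subject_ids[-seq_len(n_derivation)]),
            class = "split_plan")
}

## midrank AUC without the ROC staircase (hot path)
auc_stat <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- length(labels) - n1
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## The seven metrics from confusion counts + scores; NA where undefined.
seven_metrics <- function(tp, fp, tn, fn, scores, labels) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  den2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  auc <- if (tp + fn == 0 || tn + fp == 0) NA_real_ else
    auc_stat(scores, labels)
  c(accuracy = (tp + tn) / (tp + fp + tn + fn),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    precision = div(tp, tp + fp),
    f1 = div(2 * tp, 2 * tp + fp + fn),
    mcc = if (den2 == 0) NA_real_ else
      (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den2),
    auc = auc)
}

## assemble the seven metrics (+ cluster-bootstrap CIs) for one
## score/label set. The bootstrap resamples subjects with replacement,
## working from per-subject confusion counts and score vectors so each
## draw is cheap; draws on which a metric is undefined are dropped from
## that metric's percentile interval.
holdout_report <- function(scores, meta, threshold, n_boot, seed,
                           level = 0.95) {
  pred <- as.integer(scores >= threshold)
  truth <- meta$iicp_label
  cm <- confusion_counts(truth, pred)
  metrics <- confusion_metrics(cm["tp"], cm["fp"], cm["tn"], cm["fn"])
  ra <- roc_auc(scores, truth)
  point <- c(unlist(metrics[1:6]), auc = ra$auc)
  rows_by <- split(seq_along(scores), meta$subject_id)
  subjects <- names(rows_by)
  cnt <- t(vapply(rows_by, function(ix)
    confusion_counts(truth[ix], pred[ix]), numeric(4)))
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 7)
  for (b in seq_len(n_boot)) {
    pick <- sample(length(subjects), length(subjects), replace = TRUE)
    cc <- colSums(cnt[pick, , drop = FALSE])
    idx <- unlist(rows_by[pick], use.names = FALSE)
    boot[b, ] <- seven_metrics(cc["tp"], cc["fp"], cc["tn"], cc["fn"],
                               scores[idx], truth[idx])
  }
  a <- (1 - level) / 2
  ci <- t(apply(boot, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE,
                names = FALSE))
  dimnames(ci) <- list(names(point), c("low", "high"))
  list(counts = cm, metrics = point, ci = ci, roc = ra$roc,
       n_epochs = nrow(meta), n_subjects = length(subjects))
}

#' Evaluate trained models on the held-out validation subjects
#'
#' Applies the frozen normalization and feature selection to the
#' validation epochs, scores each model, and reports the seven metrics
#' (accuracy, sensitivity, specificity, precision, F1, MCC, AUC) with
#' cluster-bootstrap 95% CIs, plus the confusion counts and ROC points.
#' A hard leakage guard verifies that no validation subject participated
#' in normalization fitting, NCA subsampling or model training.
#'
#' @param models Named list of `iicp_model`s.
#' @param feature_table Full feature table (raw features + metadata).
#' @param plan A [split_plan()].
#' @param normalization The [fit_minmax()] parameters fitted on derivation.
#' @param selected Character vector of selected feature names.
#' @param n_boot Bootstrap draws for the CIs.
#' @param seed Bootstrap seed.
#' @return List with per-model `reports` and a Table-style `comparison`
#'   data frame (one row per model, point estimates with CI bounds).
#' @export
evaluate_holdout <- function(models, feature_table, plan, normalization,
                             selected, n_boot = 1000, seed = 1L) {
  if (length(intersect(plan$derivation, plan$validation)) > 0)
    stop("leakage: subject(s) present in both derivation and validation")
  guard <- function(subjects, what) {
    bad <- intersect(subjects, plan$validation)
    if (length(bad) > 0)
      stop("leakage: validation subject(s) used in ", what, ": ",
           paste(bad, collapse = ", "))
  }
  guard(normalization$fit_subjects, "normalization fitting")
  for (m in models) guard(m$train_subjects, "model training")
  val <- feature_table[feature_table$subject_id %in% plan$validation, ,
                       drop = FALSE]
  if (nrow(val) == 0) stop("no validation epochs found")
  Xv <- apply_minmax(normalization,
                     val[, names(normalization$min), drop = FALSE])
  Xv <- Xv[, selected, drop = FALSE]
  reports <- lapply(models, function(m) {
    scores <- predict_proba(m, Xv)
    holdout_report(scores, val, m$spec$threshold, n_boot, seed)
  })
  comparison <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    row <- data.frame(model = nm, stringsAsFactors = FALSE)
    for (met in names(r$metrics)) {
      row[[met]] <- as.numeric(r$metrics[[met]])
      row[[paste0(met, "_lo")]] <- r$ci[met, "low"]
      row[[paste0(met, "_hi")]] <- r$ci[met, "high"]
    }
    row
  }))
  list(reports = reports, comparison = comparison)
}
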