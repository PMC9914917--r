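test_that("confusion metrics match closed forms", {
  m <- confusion_metrics(30, 10, 50, 10)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 50 / 60, tolerance = 1e-4)
  expect_equal(m$accuracy, 0.80)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$mcc, 1400 / 2400, tolerance = 1e-4)
  expect_false(m$degenerate)
  # perfect prediction
  p <- confusion_metrics(40, 0, 60, 0)
  expect_true(all(unlist(p[1:6]) == 1))
  # all-negative predictor on mixed labels: flagged degenerate
  d <- confusion_metrics(0, 0, 60, 40)
  expect_equal(d$sensitivity, 0)
  expect_equal(d$mcc, 0)
  expect_true(d$degenerate)
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
})

test_that("confusion metrics agree with an independent recomputation", {
  set.seed(77)
  for (i in 1:1000) {
    cts <- rpois(4, lambda = sample(c(1, 5, 50), 1))
    if (sum(cts) == 0) next
    got <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    ref <- oracle_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(unlist(got[1:6]), ref, tolerance = 1e-12)
  }
})

test_that("AUC equals brute-force pair counting (with ties)", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.6, 0.4, 0.5, 0.3), c(1, 1, 0, 0))$auc, 0.75)
  set.seed(5)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(scores, labels)$auc,
                 brute_force_auc(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(6)
  scores <- runif(200)
  labels <- rbinom(200, 1, plogis(3 * scores - 1.5))
  base <- roc_auc(scores, labels)$auc
  for (f in list(function(s) 10 * s - 2, function(s) exp(s),
                 function(s) s^3, plogis)) {
    expect_equal(roc_auc(f(scores), labels)$auc, base, tolerance = 1e-12)
  }
})

test_that("AUC of label-independent scores concentrates at 1/2", {
  set.seed(8)
  n <- 10000
  expect_lt(abs(roc_auc(runif(n), rbinom(n, 1, 0.5))$auc - 0.5), 0.02)
})

test_that("ROC points are a valid staircase from (0,0) to (1,1)", {
  set.seed(9)
  r <- roc_auc(runif(50), rbinom(50, 1, 0.5))$roc
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1)
  expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("AUC agrees with pROC on a shared instance", {
  set.seed(10)
  scores <- runif(300)
  labels <- rbinom(300, 1, plogis(4 * scores - 2))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("cluster bootstrap is deterministic and degenerates correctly", {
  df <- data.frame(subject_id = rep("s1", 50),
                   truth = rbinom(50, 1, 0.5))
  df$pred <- df$truth
  acc <- function(d) mean(d$truth == d$pred)
  ci <- bootstrap_ci(acc, df, n_boot = 100, seed = 1L)
  expect_equal(ci[1], ci[2])  # single cluster: no between-cluster variance
  df2 <- data.frame(subject_id = rep(sprintf("s%d", 1:5), each = 20))
  df2$truth <- rbinom(100, 1, 0.5)
  df2$pred <- rbinom(100, 1, 0.5)
  c1 <- bootstrap_ci(acc, df2, n_boot = 200, seed = 7L)
  c2 <- bootstrap_ci(acc, df2, n_boot = 200, seed = 7L)
  expect_identical(c1, c2)
  expect_lte(c1[1], c1[2])
})

test_that("cluster-bootstrap CI covers the truth for a constant predictor", {
  # 9 clusters x 200 epochs of Bernoulli(0.5) labels, always-positive
  # predictor: accuracy is ~0.5 and the 95% CI should cover it in at
  # least 90% of replications (percentile cluster bootstraps run a
  # little below nominal with few clusters)
  set.seed(20)
  acc <- function(d) mean(d$truth == d$pred)
  covered <- 0
  n_rep <- 200
  for (rep_i in seq_len(n_rep)) {
    df <- data.frame(subject_id = rep(sprintf("s%d", 1:9), each = 200),
                     truth = rbinom(1800, 1, 0.5), pred = 1L)
    ci <- bootstrap_ci(acc, df, n_boot = 500, seed = rep_i)
    if (ci[1] <= 0.5 && ci[2] >= 0.5) covered <- covered + 1
  }
  expect_gte(covered, 0.9 * n_rep)
})

test_that("split plan and leakage guards reject subject overlap", {
  ids <- sprintf("pig_%02d", 1:30)
  plan <- split_plan(ids)
  expect_length(plan$derivation, 21)
  expect_length(plan$validation, 9)
  expect_length(intersect(plan$derivation, plan$validation), 0)
  expect_setequal(c(plan$derivation, plan$validation), ids)
  bad_plan <- structure(list(derivation = ids[1:21], validation = ids[21:30]),
                        class = "split_plan")
  d <- planted_dataset(n = 300, seed = 3)
  ft <- as.data.frame(d$X)
  ft$subject_id <- rep(ids, each = 10)
  ft$iicp_label <- d$y
  norm <- fit_minmax(d$X, fit_subjects = ids[1:21])
  model <- train_model(model_spec("LR"), apply_minmax(norm, d$X)[1:210, ],
                       d$y[1:210], train_subjects = ids[1:21])
  expect_error(
    evaluate_holdout(list(LR = model), ft, bad_plan, norm,
                     colnames(d$X), n_boot = 10),
    "leakage")
  # model trained on a validation subject is also rejected
  leaky <- train_model(model_spec("LR"), apply_minmax(norm, d$X),
                       d$y, train_subjects = ids)
  expect_error(
    evaluate_holdout(list(LR = leaky), ft, plan, norm,
                     colnames(d$X), n_boot = 10),
    "leakage")
})

test_that("holdout evaluation produces coherent reports", {
  set.seed(44)
  ids <- sprintf("s%02d", 1:10)
  n_per <- 40
  subject <- rep(ids, each = n_per)
  subj_shift <- rep(rnorm(10, sd = 0.3), each = n_per)
  y <- rbinom(length(subject), 1, 0.5)
  X <- cbind(sig = y * 1.5 + subj_shift + rnorm(length(subject)),
             noise = rnorm(length(subject)))
  ft <- as.data.frame(X)
  ft$subject_id <- subject
  ft$iicp_label <- y
  plan <- split_plan(ids, n_derivation = 7)
  deriv <- ft$subject_id %in% plan$derivation
  norm <- fit_minmax(X[deriv, ], fit_subjects = plan$derivation)
  m <- train_model(model_spec("LR"), apply_minmax(norm, X[deriv, ]),
                   y[deriv], train_subjects = subject[deriv])
  ev <- evaluate_holdout(list(LR = m), ft, plan, norm, c("sig", "noise"),
                         n_boot = 100, seed = 2L)
  r <- ev$reports$LR
  expect_equal(sum(r$counts), r$n_epochs)
  expect_equal(r$n_subjects, 3)
  expect_true(all(r$metrics[c("accuracy", "sensitivity", "specificity",
                              "precision", "f1", "auc")] >= 0))
  expect_gt(r$metrics[["auc"]], 0.6)
  # CI brackets the point estimate
  for (met in rownames(r$ci)) {
    expect_lte(r$ci[met, "low"], r$metrics[[met]] + 1e-9)
    expect_gte(r$ci[met, "high"], r$metrics[[met]] - 1e-9)
  }
  expect_equal(ev$comparison$model, "LR")
})
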