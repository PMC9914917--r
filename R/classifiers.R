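#' Classifier model specification
#'
#' The four configurations used for IICP prediction:
#' * `LR` — logistic regression (binomial GLM, logit link);
#' * `NB` — naive Bayes with Gaussian-kernel-smoothed class-conditional
#'   densities per feature (normal-reference bandwidth);
#' * `SVM` — support vector machine with Gaussian (RBF) kernel, kernel
#'   scale 1.7 and box constraint 1 (i.e. `gamma = 1 / 1.7^2`, `cost = 1`);
#' * `RF` — random-subspace ensemble of 30 decision trees, each grown on a
#'   random subset of `ceiling(sqrt(d))` features.
#'
#' @param algorithm One of `"LR"`, `"NB"`, `"SVM"`, `"RF"`.
#' @param threshold Decision threshold on the class-1 score.
#' @param seed Seed used where fitting is stochastic.
#' @param n_learners Ensemble size for `RF`.
#' @param kernel_scale SVM kernel scale.
#' @param box_constraint SVM box constraint (cost).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("LR", "NB", "SVM", "RF"),
                       threshold = 0.5, seed = 1L, n_learners = 30L,
                       kernel_scale = 1.7, box_constraint = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(threshold > 0, threshold < 1, n_learners >= 1,
            kernel_scale > 0, box_constraint > 0)
  structure(list(algorithm = algorithm, threshold = threshold,
                 seed = as.integer(seed), n_learners = as.integer(n_learners),
                 kernel_scale = kernel_scale,
                 box_constraint = box_constraint),
            class = "model_spec")
}

## kernel-density naive Bayes ---------------------------------------------

fit_kernel_nb <- function(X, y) {
  classes <- sort(unique(y))
  dens <- lapply(classes, function(cl) {
    lapply(seq_len(ncol(X)), function(j) {
      v <- X[y == cl, j]
      if (length(unique(v)) < 2 || sd(v) == 0) {
        list(degenerate = TRUE, at = v[1])
      } else {
        d <- density(v, bw = bw.nrd(v), n = 512, cut = 3)
        list(degenerate = FALSE, x = d$x, y = d$y)
      }
    })
  })
  names(dens) <- as.character(classes)
  list(classes = classes, priors = table(y) / length(y), dens = dens)
}

predict_kernel_nb <- function(fit, X) {
  n <- nrow(X)
  logpost <- sapply(seq_along(fit$classes), function(ci) {
    cl <- as.character(fit$classes[ci])
    lp <- rep(log(as.numeric(fit$priors[cl])), n)
    for (j in seq_len(ncol(X))) {
      dj <- fit$dens[[cl]][[j]]
      if (dj$degenerate) {
        lp <- lp + ifelse(abs(X[, j] - dj$at) < 1e-9, 0, log(1e-9))
      } else {
        f <- approx(dj$x, dj$y, xout = X[, j], rule = 2)$y
        lp <- lp + log(pmax(f, 1e-12))
      }
    }
    lp
  })
  m <- apply(logpost, 1, max)
  post <- exp(logpost - m)
  post <- post / rowSums(post)
  post[, which(fit$classes == 1)]
}

## random-subspace tree ensemble ------------------------------------------

fit_subspace_ensemble <- function(X, y, n_learners, seed) {
  d <- ncol(X)
  m <- ceiling(sqrt(d))
  set.seed(seed)
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  lapply(seq_len(n_learners), function(b) {
    feats <- sample(colnames(X), m)
    tree <- rpart::rpart(.y ~ ., data = df[, c(feats, ".y")],
                         method = "class",
                         control = rpart::rpart.control(
                           cp = 0.001, minsplit = 40, maxdepth = 10))
    list(features = feats, tree = tree)
  })
}

predict_subspace_ensemble <- function(learners, X) {
  df <- as.data.frame(X)
  probs <- vapply(learners, function(l)
    predict(l$tree, df, type = "prob")[, "1"], numeric(nrow(df)))
  rowMeans(matrix(probs, nrow = nrow(df)))
}

## --------------------------------------------------------------------------

#' Train a classifier on selected, normalized features
#'
#' @param spec A [model_spec()].
#' @param X Numeric matrix of the selected normalized features (columns
#'   named).
#' @param y Binary labels (0/1); both classes must be present.
#' @param train_subjects Optional character vector of the subject ids the
#'   rows come from (leakage provenance, checked by [evaluate_holdout()]).
#' @return Object of class `iicp_model`.
#' @export
train_model <- function(spec, X, y, train_subjects = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names")
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  set.seed(spec$seed)
  fit <- switch(spec$algorithm,
    LR = {
      df <- as.data.frame(X)
      df$.y <- y
      glm(.y ~ ., data = df, family = binomial())
    },
    NB = fit_kernel_nb(X, y),
    SVM = e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                     gamma = 1 / spec$kernel_scale^2,
                     cost = spec$box_constraint,
                     probability = TRUE, scale = FALSE),
    RF = fit_subspace_ensemble(X, y, spec$n_learners, spec$seed))
  structure(list(spec = spec, fit = fit, features = colnames(X),
                 train_subjects = unique(train_subjects)),
            class = "iicp_model")
}

#' Predict class-1 scores
#'
#' @param model An `iicp_model`.
#' @param X Feature matrix with exactly the columns the model was trained
#'   on (order-corrected automatically; missing columns are an error).
#' @return Numeric vector of class-1 scores in `[0, 1]`.
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  missing_cols <- setdiff(model$features, colnames(X))
  if (length(missing_cols) > 0)
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  X <- X[, model$features, drop = FALSE]
  scores <- switch(model$spec$algorithm,
    LR = as.numeric(predict(model$fit, as.data.frame(X),
                            type = "response")),
    NB = predict_kernel_nb(model$fit, X),
    SVM = {
      pr <- predict(model$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    RF = predict_subspace_ensemble(model$fit, X))
  as.numeric(pmin(pmax(scores, 0), 1))
}

#' Predict hard labels at the spec threshold
#'
#' @param model An `iicp_model`.
#' @param X Feature matrix.
#' @return Integer 0/1 labels.
#' @export
predict_label <- function(model, X) {
  as.integer(predict_proba(model, X) >= model$spec$threshold)
}

#' Grouped k-fold cross-validation
#'
#' Folds partition the grouping units (subjects by default) so that no
#' group contributes epochs to both the training and test side of a fold;
#' fold sizes differ by at most one group. An epoch-level (ungrouped) mode
#' is available for comparison.
#'
#' @param spec A [model_spec()].
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param groups Group (subject) id per row.
#' @param k Number of folds (>= 2, <= number of groups).
#' @param seed Seed for the fold shuffle.
#' @param grouped Partition groups (`TRUE`, default) or rows (`FALSE`).
#' @return Data frame with one row per fold: confusion counts, the six
#'   confusion metrics and AUC.
#' @export
cross_validate <- function(spec, X, y, groups, k = 5, seed = 1L,
                           grouped = TRUE) {
  X <- as.matrix(X)
  if (k < 2) stop("k must be at least 2")
  units <- if (grouped) unique(groups) else seq_len(nrow(X))
  if (k > length(units)) stop("k exceeds the number of groups")
  set.seed(seed)
  shuffled <- sample(units)
  ## chunk the shuffled units into k blocks whose sizes differ by <= 1
  sizes <- rep(floor(length(units) / k), k)
  sizes[seq_len(length(units) %% k)] <- sizes[seq_len(length(units) %% k)] + 1
  fold_id <- rep(seq_len(k), times = sizes)
  unit_fold <- setNames(fold_id, shuffled)
  row_fold <- if (grouped) unit_fold[as.character(groups)]
              else unit_fold[as.character(seq_len(nrow(X)))]
  res <- lapply(seq_len(k), function(f) {
    test <- row_fold == f
    model <- train_model(spec, X[!test, , drop = FALSE], y[!test])
    scores <- predict_proba(model, X[test, , drop = FALSE])
    pred <- as.integer(scores >= spec$threshold)
    cm <- confusion_counts(y[test], pred)
    metrics <- confusion_metrics(cm["tp"], cm["fp"], cm["tn"], cm["fn"])
    data.frame(fold = f, n_test = sum(test), t(cm),
               t(unlist(metrics[1:6])),
               auc = roc_auc(scores, y[test])$auc)
  })
  do.call(rbind, res)
}
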