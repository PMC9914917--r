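#' Fit min-max normalization parameters
#'
#' Learns per-feature minimum and maximum on the derivation rows. The
#' transform maps the derivation minimum to 0 and maximum to 1 and is then
#' applied unchanged to validation data (values outside the derivation
#' range map outside `[0, 1]`; no clipping). A constant column maps to 0
#' with a warning.
#'
#' @param X Numeric matrix or data frame of features (rows = epochs).
#' @param fit_subjects Optional character vector recording which subjects
#'   the parameters were fitted on (leakage provenance).
#' @return Object of class `minmax_params`.
#' @export
fit_minmax <- function(X, fit_subjects = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to fit normalization")
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  const <- maxs <= mins
  if (any(const))
    warning("constant feature column(s) map to 0: ",
            paste(colnames(X)[const], collapse = ", "))
  structure(list(min = mins, max = maxs, constant = const,
                 fit_subjects = fit_subjects),
            class = "minmax_params")
}

#' Apply min-max normalization
#'
#' @param params A [fit_minmax()] result.
#' @param X Matrix or data frame with the same feature columns.
#' @return Normalized numeric matrix.
#' @export
apply_minmax <- function(params, X) {
  X <- as.matrix(X)
  if (!identical(colnames(X), names(params$min)))
    X <- X[, names(params$min), drop = FALSE]
  rng <- params$max - params$min
  rng[params$constant] <- 1
  out <- sweep(sweep(X, 2, params$min), 2, rng, "/")
  out[, params$constant] <- 0
  out
}

#' NCA configuration
#'
#' @param lambda Ridge penalty on the squared weights; `NULL` means
#'   `1 / n` where `n` is the number of rows actually fitted.
#' @param sigma Kernel length scale on normalized features.
#' @param max_iter Gradient-ascent iteration cap.
#' @param tol Stop when the objective improves by less than this.
#' @param subsample Maximum number of epochs used for the O(n^2) fit
#'   (stratified by label, and by subject when available).
#' @param seed Seed controlling the subsample.
#' @return Object of class `nca_config`.
#' @export
nca_config <- function(lambda = NULL, sigma = 1, max_iter = 100,
                       tol = 1e-6, subsample = 2000, seed = 1L) {
  stopifnot(is.null(lambda) || lambda >= 0, sigma > 0, max_iter >= 1,
            tol > 0, subsample >= 2)
  structure(list(lambda = lambda, sigma = sigma,
                 max_iter = as.integer(max_iter), tol = tol,
                 subsample = as.integer(subsample), seed = as.integer(seed)),
            class = "nca_config")
}

## Pairwise per-feature L1 distances, stacked as an n^2 x d matrix so the
## objective and gradient reduce to two matrix-vector products.
nca_precompute <- function(X, y, sigma) {
  n <- nrow(X)
  d <- ncol(X)
  KM <- matrix(0, n * n, d)
  for (r in seq_len(d))
    KM[, r] <- as.vector(abs(outer(X[, r], X[, r], `-`))) / sigma
  same <- outer(y, y, `==`) * 1   # numeric: cheaper in the hot loop
  list(KM = KM, same = same, n = n, d = d)
}

## Objective and gradient of diagonal (feature-weighting) NCA, in the
## fscnca convention (mean leave-one-out soft accuracy, ridge penalty):
##   F(w) = (1/n) sum_i p_i - lambda * sum_r w_r^2,
##   p_ij = exp(-d_ij) / sum_{k != i} exp(-d_ik),
##   d_ij = sum_r w_r^2 |x_ir - x_jr| / sigma,
##   p_i  = sum_{j : y_j = y_i} p_ij.
## Averaging the accuracy term keeps lambda = 1/n meaningfully strong at
## any n; with a summed accuracy the same lambda is n times weaker and
## the objective rewards sharp-softmax overfitting onto noise features.
nca_value_grad <- function(w, pre, lambda, want_grad = TRUE) {
  n <- pre$n
  D <- matrix(pre$KM %*% (w^2), n, n)
  E <- exp(-D)
  diag(E) <- 0
  Z <- rowSums(E)
  Z[Z == 0] <- 1
  P <- E / Z
  p_i <- rowSums(P * pre$same)
  value <- mean(p_i) - lambda * sum(w^2)
  if (!want_grad) return(list(value = value))
  W <- P * p_i - P * pre$same
  g <- (2 / n) * w * as.numeric(crossprod(pre$KM, as.vector(W))) -
    2 * lambda * w
  list(value = value, gradient = g)
}

#' NCA objective value and gradient
#'
#' Exposes the regularized diagonal-NCA objective used by [nca_fit()] so
#' its analytic gradient can be verified independently (e.g. against
#' finite differences).
#'
#' @param w Weight vector (length = number of features).
#' @param X Normalized feature matrix.
#' @param y Labels (any type; compared for equality).
#' @param lambda Ridge penalty.
#' @param sigma Kernel length scale.
#' @return List with `value` and `gradient`.
#' @export
nca_objective <- function(w, X, y, lambda = 1 / nrow(X), sigma = 1) {
  pre <- nca_precompute(as.matrix(X), y, sigma)
  nca_value_grad(w, pre, lambda)
}

#' Fit diagonal NCA feature weights
#'
#' Maximizes the leave-one-out soft classification accuracy minus a ridge
#' penalty by gradient ascent with a backtracking step size, so the
#' objective trajectory is non-decreasing. Weights are initialized at 1;
#' the sign of a weight is irrelevant (only squares enter the model), so
#' absolute values are returned.
#'
#' @param X Normalized feature matrix (no missing values).
#' @param y Binary labels; both classes must be present.
#' @param cfg An [nca_config()].
#' @return List with `weights` (named, non-negative), `objective`
#'   (per-iteration trajectory), `iterations`, `converged`.
#' @export
nca_fit <- function(X, y, cfg = nca_config()) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values")
  if (length(unique(y)) < 2) stop("need at least two classes")
  n <- nrow(X)
  lambda <- if (is.null(cfg$lambda)) 1 / n else cfg$lambda
  pre <- nca_precompute(X, y, cfg$sigma)
  w <- rep(1, ncol(X))
  cur <- nca_value_grad(w, pre, lambda)
  traj <- cur$value
  step <- 1
  converged <- FALSE
  it <- 0
  while (it < cfg$max_iter) {
    it <- it + 1
    improved <- FALSE
    while (step > 1e-12) {
      w_new <- w + step * cur$gradient
      val_new <- nca_value_grad(w_new, pre, lambda, want_grad = FALSE)$value
      if (val_new >= cur$value) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    gain <- val_new - cur$value
    w <- w_new
    cur <- nca_value_grad(w, pre, lambda)
    traj <- c(traj, cur$value)
    step <- min(step * 1.5, 1e6)
    if (gain < cfg$tol) { converged <- TRUE; break }
  }
  weights <- abs(w)
  names(weights) <- colnames(X)
  list(weights = weights, objective = traj, iterations = it,
       converged = converged)
}

## Stratified subsample of row indices: proportional allocation over the
## interaction of label and (optionally) subject.
stratified_subsample <- function(n_total, size, y, subjects = NULL,
                                 seed = 1L) {
  if (n_total <= size) return(seq_len(n_total))
  strata <- if (is.null(subjects)) as.character(y)
            else paste(subjects, y, sep = ":")
  set.seed(seed)
  idx_by <- split(seq_len(n_total), strata)
  take <- vapply(idx_by, function(ix)
    max(1L, as.integer(round(length(ix) / n_total * size))), integer(1))
  picked <- unlist(mapply(function(ix, k) {
    if (length(ix) <= k) ix else sample(ix, k)
  }, idx_by, take, SIMPLIFY = FALSE), use.names = FALSE)
  if (length(picked) > size) picked <- sort(sample(picked, size))
  sort(picked)
}

#' NCA feature weights on (a stratified subsample of) an epoch set
#'
#' Wrapper around [nca_fit()] that first draws a label/subject-stratified
#' subsample of at most `cfg$subsample` epochs, for O(n^2) tractability on
#' large epoch tables. Deterministic given `cfg$seed`.
#'
#' @param X Normalized feature matrix.
#' @param y Binary labels.
#' @param cfg An [nca_config()].
#' @param subjects Optional subject ids (one per row) for stratification.
#' @return As [nca_fit()], plus `rows_used`.
#' @export
nca_feature_weights <- function(X, y, cfg = nca_config(), subjects = NULL) {
  X <- as.matrix(X)
  idx <- stratified_subsample(nrow(X), cfg$subsample, y, subjects, cfg$seed)
  fit <- nca_fit(X[idx, , drop = FALSE], y[idx], cfg)
  fit$rows_used <- idx
  fit
}

#' Two-sample pooled-variance t-test p-values per feature
#'
#' Classical Student's t-test (pooled variance, two-sided) of each feature
#' between the two label classes. Features with zero pooled variance
#' return p = 1 when the class means are equal (with a warning), p = 0
#' otherwise.
#'
#' @param X Feature matrix or data frame.
#' @param y Binary labels; both classes need >= 2 rows.
#' @return Named numeric vector of p-values in `[0, 1]`.
#' @export
ttest_pvalues <- function(X, y) {
  X <- as.matrix(X)
  cls <- sort(unique(y))
  if (length(cls) != 2) stop("need exactly two classes")
  i1 <- y == cls[2]
  n1 <- sum(i1); n0 <- sum(!i1)
  if (n1 < 2 || n0 < 2) stop("both classes need at least 2 rows")
  m1 <- colMeans(X[i1, , drop = FALSE])
  m0 <- colMeans(X[!i1, , drop = FALSE])
  v1 <- apply(X[i1, , drop = FALSE], 2, var)
  v0 <- apply(X[!i1, , drop = FALSE], 2, var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  p <- numeric(ncol(X))
  names(p) <- colnames(X)
  zero <- se == 0
  if (any(zero)) {
    warning("zero-variance feature(s): ",
            paste(colnames(X)[zero], collapse = ", "))
    p[zero] <- ifelse(m1[zero] == m0[zero], 1, 0)
  }
  tt <- (m1[!zero] - m0[!zero]) / se[!zero]
  p[!zero] <- 2 * pt(-abs(tt), df = n1 + n0 - 2)
  p
}

#' Select the top-k features by NCA weight with a t-test filter
#'
#' Features with p >= `alpha` are removed first; the survivors are ranked
#' by descending NCA weight (ties broken by their order in the input,
#' i.e. registry order) and the top `k` are selected. Fewer than `k`
#' survivors are allowed with a warning; zero survivors is an error.
#'
#' @param weights Named NCA weights.
#' @param p_values Named p-values, aligned with `weights`.
#' @param k Number of features to select.
#' @param alpha Significance threshold for the t-test filter.
#' @return Object of class `selection_result`: list with `selected`
#'   (ordered names) and `ranking` (data frame with `feature`, `weight`,
#'   `p_value`, `selected`, `rank`).
#' @export
select_features <- function(weights, p_values, k = 10, alpha = 0.05) {
  stopifnot(length(weights) == length(p_values))
  if (!identical(names(weights), names(p_values)))
    stop("weights and p_values must be aligned by name")
  ok <- p_values < alpha
  if (!any(ok)) stop("no feature passes the p < ", alpha, " filter")
  ord <- order(-weights, seq_along(weights))     # stable registry tie-break
  ord <- ord[ok[ord]]
  sel <- head(ord, k)
  if (length(sel) < k)
    warning(length(sel), " feature(s) survive the filter; requested ", k)
  ranking <- data.frame(
    feature = names(weights),
    weight = as.numeric(weights),
    p_value = as.numeric(p_values),
    selected = seq_along(weights) %in% sel,
    rank = NA_integer_,
    stringsAsFactors = FALSE)
  ranking$rank[sel] <- seq_along(sel)
  structure(list(selected = names(weights)[sel], ranking = ranking),
            class = "selection_result")
}

#' Serialize a selection result to JSON
#'
#' @param sr A `selection_result`.
#' @param path Output path.
#' @param config Optional list echoed under `config`.
#' @return `path`, invisibly.
#' @export
selection_to_json <- function(sr, path, config = NULL) {
  payload <- list(
    features = setNames(lapply(seq_len(nrow(sr$ranking)), function(i) {
      r <- sr$ranking[i, ]
      list(weight = r$weight, p_value = r$p_value,
           selected = r$selected,
           rank = if (is.na(r$rank)) NULL else r$rank)
    }), sr$ranking$feature),
    selected = sr$selected,
    config = config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
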