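test_that("min-max normalization maps the derivation range to [0, 1]", {
  X <- cbind(a = c(2, 4, 6), b = c(1, 1, 2))
  p <- fit_minmax(X)
  expect_equal(as.numeric(apply_minmax(p, X)[, "a"]), c(0, 0.5, 1))
  # constant column maps to 0 with a warning
  Xc <- cbind(a = c(5, 5, 5))
  expect_warning(pc <- fit_minmax(Xc), "constant")
  expect_equal(as.numeric(apply_minmax(pc, Xc)), c(0, 0, 0))
  # out-of-range validation values extrapolate (no clipping)
  expect_gt(apply_minmax(p, cbind(a = 7, b = 1))[1, "a"], 1)
  expect_error(fit_minmax(X[1, , drop = FALSE]), "at least 2 rows")
})

test_that("NCA analytic gradient matches central finite differences", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(80), 20, 4)
    y <- rep(c(0, 1), 10)
    w <- runif(4, 0.3, 1.5)
    o <- nca_objective(w, X, y)
    h <- 1e-5
    fd <- vapply(1:4, function(r) {
      e <- replace(rep(0, 4), r, h)
      (nca_objective(w + e, X, y)$value -
         nca_objective(w - e, X, y)$value) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(o$gradient - fd) / pmax(abs(fd), 1e-8)), 1e-4)
  }
})

test_that("strong regularization shrinks all NCA weights to zero", {
  d <- planted_dataset(n = 60, seed = 4)
  fit <- nca_fit(d$X, d$y, nca_config(lambda = 1e6))
  expect_lt(max(fit$weights), 1e-3)
})

test_that("the NCA objective is non-decreasing over iterations", {
  for (seed in c(2, 5)) {
    d <- planted_dataset(n = 80, seed = seed)
    fit <- nca_fit(d$X, d$y)
    expect_true(all(diff(fit$objective) >= -1e-10))
  }
})

test_that("NCA ranks planted informative features on top", {
  hits <- 0
  for (seed in 1:5) {
    d <- planted_dataset(n = 200, d = 10, n_informative = 2, shift = 2,
                         seed = seed)
    fit <- nca_fit(d$X, d$y)
    top2 <- names(sort(fit$weights, decreasing = TRUE))[1:2]
    if (setequal(top2, c("f01", "f02"))) hits <- hits + 1
  }
  expect_gte(hits, 4)
  expect_error(nca_fit(planted_dataset(n = 20)$X, rep(1, 20)),
               "two classes")
})

test_that("NCA subsampling is stratified and seed-deterministic", {
  d <- planted_dataset(n = 500, seed = 6)
  subj <- rep(sprintf("s%d", 1:10), each = 50)
  cfg <- nca_config(subsample = 100, seed = 3L)
  f1 <- nca_feature_weights(d$X, d$y, cfg, subjects = subj)
  f2 <- nca_feature_weights(d$X, d$y, cfg, subjects = subj)
  expect_identical(f1, f2)
  expect_lte(length(f1$rows_used), 100)
  # every subject contributes
  expect_length(unique(subj[f1$rows_used]), 10)
})

test_that("pooled t-test p-values match stats::t.test and handle degeneracy", {
  set.seed(9)
  X <- cbind(u = rnorm(40), v = c(rnorm(20), rnorm(20, 1)))
  y <- rep(c(0, 1), each = 20)
  p <- ttest_pvalues(X, y)
  for (j in colnames(X)) {
    ref <- t.test(X[y == 1, j], X[y == 0, j], var.equal = TRUE)$p.value
    expect_equal(p[[j]], ref, tolerance = 1e-12)
  }
  # strong separation
  Xs <- cbind(s = c(rnorm(100, 0), rnorm(100, 2)))
  ys <- rep(c(0, 1), each = 100)
  expect_lt(ttest_pvalues(Xs, ys)[["s"]], 1e-6)
  # identical values in both classes
  expect_warning(pd <- ttest_pvalues(cbind(k = rep(1, 40)), y),
                 "zero-variance")
  expect_equal(pd[["k"]], 1)
  expect_error(ttest_pvalues(X, rep(0, 40)), "two classes")
})

test_that("null-feature p-values are uniform under label permutation", {
  set.seed(14)
  x <- matrix(rnorm(60), ncol = 1)
  colnames(x) <- "f"
  y0 <- rep(c(0, 1), each = 30)
  ps <- vapply(1:1000, function(i) ttest_pvalues(x, sample(y0))[[1]],
               numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("selection applies the joint weight/p-value rule", {
  w <- setNames(seq(12, 1), paste0("f", 1:12))
  p <- setNames(rep(0.01, 12), paste0("f", 1:12))
  sel <- select_features(w, p, k = 10)
  expect_equal(sel$selected, paste0("f", 1:10))
  # top-weight feature with p = 0.2 is excluded despite its weight
  p2 <- p
  p2["f1"] <- 0.2
  sel2 <- select_features(w, p2, k = 10)
  expect_false("f1" %in% sel2$selected)
  expect_equal(sel2$selected[1], "f2")
  # shortfall yields a warning, zero survivors an error
  p3 <- setNames(c(rep(0.01, 6), rep(0.5, 6)), paste0("f", 1:12))
  expect_warning(sel3 <- select_features(w, p3, k = 10), "survive")
  expect_length(sel3$selected, 6)
  expect_error(select_features(w, setNames(rep(0.9, 12), names(w))),
               "no feature")
})

test_that("selection is invariant to affine feature rescaling", {
  d <- planted_dataset(n = 150, seed = 11)
  run_selection <- function(X) {
    norm <- fit_minmax(X)
    Xn <- apply_minmax(norm, X)
    fit <- nca_fit(Xn, d$y, nca_config(max_iter = 40))
    p <- ttest_pvalues(Xn, d$y)
    select_features(fit$weights, p, k = 5)$selected
  }
  X2 <- d$X
  X2[, 3] <- 100 * X2[, 3] - 7
  X2[, 8] <- -0.01 * X2[, 8]
  sel_a <- run_selection(d$X)
  # after min-max, a positive affine map changes nothing; a negative one
  # only mirrors the column, which leaves weights and p-values unchanged
  sel_b <- run_selection(X2)
  expect_identical(sel_a, sel_b)
})

test_that("selection serializes to JSON with ranks", {
  dir <- withr::local_tempdir()
  w <- setNames(c(3, 2, 1), c("a", "b", "c"))
  p <- setNames(c(0.01, 0.2, 0.04), c("a", "b", "c"))
  sel <- suppressWarnings(select_features(w, p, k = 2))
  path <- selection_to_json(sel, file.path(dir, "sel.json"))
  back <- jsonlite::read_json(path)
  expect_equal(unlist(back$selected), c("a", "c"))
  expect_equal(back$features$a$rank, 1)
  expect_null(back$features$b$rank)
})
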