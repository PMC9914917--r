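#' Full run configuration
#'
#' Bundles the per-stage configurations with a single master seed from
#' which every stage seed is derived deterministically.
#'
#' @param protocol A [protocol_config()].
#' @param profile A [spectral_profile()].
#' @param fspec A [filter_spec()].
#' @param espec An [epoch_spec()].
#' @param bands A [band_definition()].
#' @param bank Candidate feature names.
#' @param nca An [nca_config()] (its `seed` is overridden by the derived
#'   stage seed).
#' @param iicp_threshold IICP threshold, mmHg.
#' @param k_select Number of features to select.
#' @param alpha t-test significance threshold.
#' @param n_derivation Number of derivation subjects.
#' @param algorithms Classifier algorithms to train.
#' @param train_subsample Maximum number of derivation epochs used to train
#'   the classifiers (stratified by label and subject); overlapping epochs
#'   are highly redundant, so a subsample retains essentially all the
#'   information at a fraction of the cost.
#' @param n_boot Bootstrap draws for the evaluation CIs.
#' @param run_cv Also run grouped 5-fold cross-validation on the
#'   derivation group.
#' @param seed Master seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(protocol = protocol_config(),
                       profile = default_spectral_profile(),
                       fspec = filter_spec(),
                       espec = epoch_spec(),
                       bands = band_definition(),
                       bank = feature_registry(),
                       nca = nca_config(),
                       iicp_threshold = 25,
                       k_select = 10,
                       alpha = 0.05,
                       n_derivation = round(0.7 * protocol$n_subjects),
                       algorithms = c("LR", "NB", "SVM", "RF"),
                       train_subsample = 6000,
                       n_boot = 1000,
                       run_cv = FALSE,
                       seed = protocol$seed) {
  structure(list(protocol = protocol, profile = profile, fspec = fspec,
                 espec = espec, bands = bands, bank = bank, nca = nca,
                 iicp_threshold = iicp_threshold, k_select = k_select,
                 alpha = alpha, n_derivation = n_derivation,
                 algorithms = algorithms,
                 train_subsample = train_subsample, n_boot = n_boot,
                 run_cv = run_cv, seed = as.integer(seed)),
            class = "run_config")
}

stage_seed <- function(seed, stage) {
  ## double arithmetic: integer +/* would overflow for seeds near 2^31
  as.integer((abs(as.numeric(seed)) + 1009 * stage) %% 2000000000)
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[qeegicp] %s", sprintf(fmt, ...)))
}

#' Run the full IICP prediction pipeline
#'
#' Generates (or accepts) a synthetic cohort, preprocesses every subject,
#' extracts the qEEG feature table, fits min-max normalization and
#' NCA + t-test feature selection on the derivation subjects only, trains
#' the requested classifiers, and evaluates them on the held-out
#' validation subjects. When `out_dir` is given, all stage artifacts are
#' written there (EDF + CSV per subject, feature table CSV, selection
#' JSON, model bundles, evaluation reports); reruns with the same
#' configuration and seed reproduce the text artifacts byte-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Optional artifact directory.
#' @param cohort Optional pre-generated cohort (skips simulation).
#' @param verbose Log stage boundaries with row counts and timings.
#' @return List: `feature_table`, `plan`, `normalization`, `nca`,
#'   `p_values`, `selection`, `models`, `evaluation`, `cv` (optional),
#'   `config`, `config_hash`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         cohort = NULL, verbose = TRUE) {
  t_start <- Sys.time()
  seed <- config$seed
  hash <- config_hash(config)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("config_hash=%s package=qeegicp %s", hash,
                   as.character(utils::packageVersion("qeegicp")))

  ## stage 1: cohort -------------------------------------------------------
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$protocol, config$profile,
                              seed = stage_seed(seed, 1L))
    pipeline_log(verbose, "simulated cohort of %d subjects", length(cohort))
  }
  if (!is.null(out_dir)) {
    cdir <- file.path(out_dir, "cohort")
    dir.create(cdir, showWarnings = FALSE)
    manifest <- do.call(rbind, lapply(cohort, function(rec) {
      edf <- file.path(cdir, paste0(rec$subject_id, ".edf"))
      csv <- file.path(cdir, paste0(rec$subject_id, "_traces.csv"))
      write_edf(edf, rec$eeg, rec$eeg_fs,
                recording_id = paste("qeegicp synthetic", stamp))
      write_subject_csv(csv, rec, header_comment = stamp)
      data.frame(subject_id = rec$subject_id, edf = basename(edf),
                 traces = basename(csv), stringsAsFactors = FALSE)
    }))
    plan0 <- split_plan(manifest$subject_id, config$n_derivation)
    manifest$group <- ifelse(manifest$subject_id %in% plan0$derivation,
                             "derivation", "validation")
    con <- file(file.path(cdir, "manifest.csv"), "w")
    writeLines(paste0("# ", stamp), con)
    write.csv(manifest, con, row.names = FALSE)
    close(con)
  }

  ## stage 2+3: preprocessing and feature extraction -----------------------
  t0 <- Sys.time()
  feature_table <- do.call(rbind, lapply(cohort, function(rec) {
    tab <- preprocess_subject(rec, config$fspec, config$espec,
                              threshold = config$iicp_threshold)
    extract_feature_table(tab, rec$eeg_fs, config$bands, config$bank)
  }))
  rownames(feature_table) <- NULL
  pipeline_log(verbose, "extracted %d epochs x %d features in %.1f s",
               nrow(feature_table), length(config$bank),
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir))
    write_stamped_csv(feature_table, file.path(out_dir, "features.csv"),
                      stamp)

  ## stage 4: split, normalize, select -------------------------------------
  plan <- split_plan(unique(feature_table$subject_id), config$n_derivation)
  deriv <- feature_table$subject_id %in% plan$derivation
  Xraw <- as.matrix(feature_table[, config$bank, drop = FALSE])
  y <- feature_table$iicp_label
  norm <- fit_minmax(Xraw[deriv, , drop = FALSE],
                     fit_subjects = plan$derivation)
  Xn <- apply_minmax(norm, Xraw)
  nca_cfg <- config$nca
  nca_cfg$seed <- stage_seed(seed, 4L)
  t0 <- Sys.time()
  nca <- nca_feature_weights(Xn[deriv, , drop = FALSE], y[deriv], nca_cfg,
                             subjects = feature_table$subject_id[deriv])
  pvals <- ttest_pvalues(Xn[deriv, , drop = FALSE], y[deriv])
  selection <- select_features(nca$weights, pvals,
                               k = config$k_select, alpha = config$alpha)
  pipeline_log(verbose, "selected %d features in %.1f s: %s",
               length(selection$selected),
               as.numeric(difftime(Sys.time(), t0, units = "secs")),
               paste(selection$selected, collapse = ", "))
  if (!is.null(out_dir))
    selection_to_json(selection, file.path(out_dir, "selection.json"),
                      config = list(config_hash = hash,
                                    k = config$k_select,
                                    alpha = config$alpha))

  ## stage 5: train models --------------------------------------------------
  t0 <- Sys.time()
  deriv_idx <- which(deriv)
  sub_idx <- deriv_idx[stratified_subsample(
    length(deriv_idx), config$train_subsample, y[deriv_idx],
    feature_table$subject_id[deriv_idx], seed = stage_seed(seed, 5L))]
  Xtr <- Xn[sub_idx, selection$selected, drop = FALSE]
  ytr <- y[sub_idx]
  subj_tr <- feature_table$subject_id[sub_idx]
  models <- setNames(lapply(config$algorithms, function(alg) {
    train_model(model_spec(alg, seed = stage_seed(seed, 6L)),
                Xtr, ytr, train_subjects = subj_tr)
  }), config$algorithms)
  pipeline_log(verbose, "trained %d models on %d epochs in %.1f s",
               length(models), length(ytr),
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    mdir <- file.path(out_dir, "models")
    dir.create(mdir, showWarnings = FALSE)
    for (nm in names(models)) {
      jsonlite::write_json(
        c(models[[nm]]$spec, list(config_hash = hash,
                                  features = models[[nm]]$features)),
        file.path(mdir, paste0("model_", nm, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      saveRDS(models[[nm]], file.path(mdir, paste0("model_", nm, ".rds")))
    }
  }

  ## optional grouped CV on derivation -------------------------------------
  cv <- NULL
  if (config$run_cv) {
    cv <- setNames(lapply(config$algorithms, function(alg) {
      cross_validate(model_spec(alg, seed = stage_seed(seed, 6L)),
                     Xtr, ytr, subj_tr, k = 5,
                     seed = stage_seed(seed, 7L))
    }), config$algorithms)
  }

  ## stage 6: holdout evaluation --------------------------------------------
  t0 <- Sys.time()
  evaluation <- evaluate_holdout(models, feature_table, plan, norm,
                                 selection$selected,
                                 n_boot = config$n_boot,
                                 seed = stage_seed(seed, 8L))
  pipeline_log(verbose, "evaluated %d validation epochs in %.1f s",
               evaluation$reports[[1]]$n_epochs,
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    edir <- file.path(out_dir, "eval")
    dir.create(edir, showWarnings = FALSE)
    write_stamped_csv(evaluation$comparison,
                      file.path(edir, "metrics_by_model.csv"), stamp)
    for (nm in names(evaluation$reports)) {
      r <- evaluation$reports[[nm]]
      jsonlite::write_json(
        list(model = nm, config_hash = hash,
             counts = as.list(r$counts),
             metrics = as.list(r$metrics),
             ci = apply(r$ci, 1, as.list),
             n_epochs = r$n_epochs, n_subjects = r$n_subjects),
        file.path(edir, paste0("report_", nm, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_stamped_csv(r$roc, file.path(edir, paste0("roc_", nm, ".csv")),
                        stamp)
      cmat <- data.frame(truth = c(1, 1, 0, 0),
                         predicted = c(1, 0, 1, 0),
                         count = as.numeric(r$counts[c("tp", "fn", "fp",
                                                       "tn")]))
      write_stamped_csv(cmat,
                        file.path(edir, paste0("confusion_", nm, ".csv")),
                        stamp)
    }
  }
  pipeline_log(verbose, "pipeline complete in %.1f s",
               as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  list(feature_table = feature_table, plan = plan, normalization = norm,
       nca = nca, p_values = pvals, selection = selection, models = models,
       evaluation = evaluation, cv = cv, config = config,
       config_hash = hash)
}

## md5 of the serialized configuration (base R via tools::md5sum)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config), collapse = ""), tmp)
  as.character(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", stamp), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a stamped CSV artifact
#'
#' @param path CSV written by the pipeline (leading `#` metadata line).
#' @return Data frame.
#' @export
read_stamped_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
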