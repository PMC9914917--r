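#!/usr/bin/env Rscript

# Stage 4 — classifier training and holdout evaluation.
#
# Trains LR / kernel-NB / RBF-SVM / random-subspace-RF on a stratified
# subsample of the derivation epochs (selected features only), runs
# grouped 5-fold CV on the derivation group, then evaluates the frozen
# models on the 9 held-out validation subjects with cluster-bootstrap
# 95% CIs. Writes the per-model metric table, ROC points and confusion
# matrices under results/eval/.

library(qeegicp)

seed <- 42L
out <- "results"

# rerun the full pipeline so every stage uses its frozen upstream state
res <- run_pipeline(run_config(seed = seed, run_cv = TRUE),
                    out_dir = file.path(out, "pipeline"))

cmp <- res$evaluation$comparison
write.csv(cmp, file.path(out, "metrics_by_model.csv"), row.names = FALSE)

cv_tab <- do.call(rbind, lapply(names(res$cv), function(m) {
  cbind(model = m, res$cv[[m]])
}))
write.csv(cv_tab, file.path(out, "cv_by_fold.csv"), row.names = FALSE)

message("holdout performance (validation subjects):")
print(cmp[, c("model", "accuracy", "sensitivity", "specificity",
              "precision", "f1", "mcc", "auc")], digits = 3)
message("derivation 5-fold CV mean AUC:")
print(vapply(res$cv, function(d) mean(d$auc), numeric(1)), digits = 3)
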