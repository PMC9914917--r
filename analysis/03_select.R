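#!/usr/bin/env Rscript

# Stage 3 — feature ranking and selection on the derivation group.
#
# Min-max normalization fitted on the 21 derivation subjects, diagonal
# NCA ranking on a stratified 2000-epoch subsample, pooled t-test filter
# at p < 0.05, top-10 selection. Writes results/selection.json and a
# ranking table.

library(qeegicp)

seed <- 42L
out <- "results"
features <- read.csv(file.path(out, "features.csv"))

plan <- split_plan(unique(features$subject_id))
deriv <- features$subject_id %in% plan$derivation
X <- as.matrix(features[, feature_registry()])
norm <- fit_minmax(X[deriv, ], fit_subjects = plan$derivation)
Xn <- apply_minmax(norm, X)

nca <- nca_feature_weights(Xn[deriv, ], features$iicp_label[deriv],
                           nca_config(seed = seed),
                           subjects = features$subject_id[deriv])
pvals <- ttest_pvalues(Xn[deriv, ], features$iicp_label[deriv])
sel <- select_features(nca$weights, pvals, k = 10)

selection_to_json(sel, file.path(out, "selection.json"))
write.csv(sel$ranking[order(-sel$ranking$weight), ],
          file.path(out, "feature_ranking.csv"), row.names = FALSE)

message("selected: ", paste(sel$selected, collapse = ", "))
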