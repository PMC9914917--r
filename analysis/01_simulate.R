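#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohort.
#
# Generates the default 30-subject cohort: 5 min baseline around
# 12.4 mmHg, then four 6-min balloon-inflation steps targeting
# 20/30/40/50 mmHg, with single-channel EEG at 250 Hz whose spectral
# composition shifts toward the faster bands as ICP rises. Writes one EDF
# + traces CSV per subject and a cohort manifest under results/cohort/.

library(qeegicp)

seed <- 42L
out <- "results"
dir.create(file.path(out, "cohort"), recursive = TRUE, showWarnings = FALSE)

cfg <- protocol_config(seed = seed)
profile <- default_spectral_profile()
cohort <- generate_cohort(cfg, profile)

plan <- split_plan(vapply(cohort, `[[`, "", "subject_id"))
manifest <- do.call(rbind, lapply(cohort, function(rec) {
  write_edf(file.path(out, "cohort", paste0(rec$subject_id, ".edf")),
            rec$eeg, rec$eeg_fs)
  write_subject_csv(file.path(out, "cohort",
                              paste0(rec$subject_id, "_traces.csv")), rec)
  data.frame(subject_id = rec$subject_id,
             edf = paste0(rec$subject_id, ".edf"),
             traces = paste0(rec$subject_id, "_traces.csv"),
             group = ifelse(rec$subject_id %in% plan$derivation,
                            "derivation", "validation"),
             minutes = length(rec$eeg) / rec$eeg_fs / 60)
}))
write.csv(manifest, file.path(out, "cohort", "manifest.csv"),
          row.names = FALSE)

message(sprintf("simulated %d subjects (%.0f min of EEG each), %d/%d split",
                nrow(manifest), manifest$minutes[1],
                length(plan$derivation), length(plan$validation)))
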