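#!/usr/bin/env Rscript
# Stage 3: how detections move between the seven tissue-overlap classes
# as the cohort grows. Reads the stage tables written by stage 2 and
# reports: consecutive-step overlap at the eQTL vs eSNP level, creation
# into the all-tissue class vs the tissue-specific classes, the
# distance/strength contrast between shared and specific eQTLs, and the
# specificity trend. Writes summary tables under results/dynamics/.

library(eqtlsat)

run_dir <- "results/run"
out <- "results/dynamics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
stopifnot(file.exists(file.path(run_dir, "class_counts.tsv")))

ov <- read.delim(file.path(run_dir, "overlaps.tsv"))
cons <- aggregate(value ~ level, ov[ov$kind == "consecutive", ],
                  function(v) mean(v, na.rm = TRUE))
cat("mean consecutive-step overlap (pooled over tissues/replicates):\n")
print(cons)
write.table(cons, file.path(out, "consecutive_overlap.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

rates <- read.delim(file.path(run_dir, "rates.tsv"))
created <- aggregate(creation ~ class, rates, sum)
cat("\ntotal creations per class (new detections entering the analysis):\n")
print(created[order(-created$creation), ])
write.table(created, file.path(out, "creations_by_class.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ds <- read.delim(file.path(run_dir, "distance_strength.tsv"))
ds_last <- aggregate(cbind(mean_abs_delta_mb, mean_neglog10p) ~ class,
                     ds[ds$class %in% c("ABC", "ONLY_A", "ONLY_B", "ONLY_C"), ],
                     function(v) mean(v, na.rm = TRUE))
cat("\nshared (ABC) vs specific eQTLs at the largest subsample:\n")
print(ds_last)
write.table(ds_last, file.path(out, "distance_strength_by_class.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sp <- read.delim(file.path(run_dir, "specificity.tsv"))
sp_trend <- aggregate(cbind(pct_specific, pct_shared_all) ~ tissue + step + n,
                      sp, function(v) mean(v, na.rm = TRUE))
cat("\nreplicate-averaged specificity at the first and last step:\n")
print(sp_trend[sp_trend$step %in% c(1, 20), ])
write.table(sp_trend, file.path(out, "specificity_trend.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nwrote", out, "\n")
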