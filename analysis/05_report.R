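#!/usr/bin/env Rscript
# Stage 5: one-screen summary of the whole run, assembled by re-reading
# the stage tables (every number here is traceable to a TSV under
# results/run/). Writes results/summary.tsv.

library(eqtlsat)

summary_df <- report_summary("results/run")
print(summary_df, digits = 3)
write.table(summary_df, "results/summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/summary.tsv\n")
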