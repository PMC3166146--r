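#!/usr/bin/env Rscript
# Stage 4: the scaling law. Fits sqrt(q) = alpha + beta * ln(n) per
# tissue and replicate from the stage-2 manifest, reports R^2 and the
# extrapolated counts at reference cohort sizes, and computes
# sliding-window slopes per overlap class (rising slope = accelerating
# detection, falling slope = saturation). Writes results/scaling/.

library(eqtlsat)

run_dir <- "results/run"
out <- "results/scaling"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
m <- read.delim(file.path(run_dir, "runs", "manifest.tsv"))

fits <- do.call(rbind, lapply(split(m, list(m$tissue, m$replicate)), function(s) {
  f <- fit_scaling_law(s$n, s$q)
  data.frame(tissue = s$tissue[1], replicate = s$replicate[1],
             alpha = f$alpha, beta = f$beta, r_squared = f$r_squared,
             pred_744 = predict_count(f, 744),
             pred_612 = predict_count(f, 612),
             pred_569 = predict_count(f, 569))
}))
rownames(fits) <- NULL
cat("per-replicate scaling-law fits with extrapolations:\n")
print(fits, digits = 4)
summ <- aggregate(cbind(alpha, beta, r_squared) ~ tissue, fits,
                  function(v) c(mean = mean(v), sd = sd(v)))
cat("\nper-tissue mean +/- sd of the coefficients:\n")
print(summ, digits = 4)
write.table(fits, file.path(out, "fits.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# sliding-window slopes of the class-count series (replicate 1)
cc <- read.delim(file.path(run_dir, "class_counts.tsv"))
cc1 <- cc[cc$replicate == 1, ]
sw <- do.call(rbind, lapply(split(cc1, cc1$class), function(s) {
  s <- s[order(s$step), ]
  w <- sliding_window_slope(s$n, s$count, window = 10)
  cbind(class = s$class[1], w)
}))
cat("\nsliding-window (10-step) slope range per class:\n")
print(aggregate(slope ~ class, sw, function(v) c(first = v[1], last = v[length(v)])),
      digits = 3)
write.table(sw, file.path(out, "sliding_window_slopes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nwrote", out, "\n")
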