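#' Run the full saturation analysis end to end
#'
#' Orchestrates simulate (or accept a prebuilt cohort) -> nested
#' subsample series of per-tissue cis-eQTL scans -> overlap-class
#' trajectories, transition rates and overlap curves -> per-tissue
#' scaling-law fits, and writes every stage as TSV under `out_dir`
#' together with a manifest recording the seed and parameters. The whole
#' run is deterministic given `seed`.
#'
#' @param config A [sim_config()] (ignored when `cohort` is supplied).
#' @param cohort Optional prebuilt `eqtl_cohort`.
#' @param sizes Subsample sizes; default 20 log-spaced steps from
#'   `n_min` to the cohort size.
#' @param n_min Smallest subsample size (default 50).
#' @param k Number of steps (default 20).
#' @param replicates Number of independent subsample series (default 1).
#' @param fdr_target,n_permutations,window_bp,maf_threshold Scan
#'   parameters (see [call_cis_eqtls()]).
#' @param seed Master seed for subsampling and permutations.
#' @param out_dir Output directory; `NULL` keeps everything in memory.
#' @param write_cohort_files Also write the cohort itself (VCF etc.).
#' @param verbose Progress messages.
#' @return Object of class `pipeline_result`: `cohort`, `series`,
#'   `trajectories` (one `class_trajectory` per replicate), `rates`,
#'   `overlaps`, `summaries` (distance/strength per class), `specificity`
#'   (per step), `fits`, `params`.
#' @export
run_pipeline <- function(config = sim_config(), cohort = NULL,
                         sizes = NULL, n_min = 50L, k = 20L,
                         replicates = 1L, fdr_target = 0.10,
                         n_permutations = 10L, window_bp = 1e6,
                         maf_threshold = 0.05, seed = 1L,
                         out_dir = NULL, write_cohort_files = FALSE,
                         verbose = FALSE) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  n_total <- length(cohort$sample_ids)
  if (is.null(sizes)) sizes <- log_spaced_sizes(n_min, n_total, k)
  series <- run_series(cohort, sizes = sizes, replicates = replicates,
                       fdr_target = fdr_target,
                       n_permutations = n_permutations,
                       window_bp = window_bp,
                       maf_threshold = maf_threshold, seed = seed,
                       verbose = verbose)
  trajectories <- lapply(seq_len(replicates), function(r)
    class_trajectory(series, r))
  rates <- do.call(rbind, lapply(seq_len(replicates), function(r)
    cbind(replicate = r, rate_series(trajectories[[r]]))))
  overlaps <- do.call(rbind, lapply(seq_len(replicates), function(r)
    do.call(rbind, lapply(series$tissues, function(t)
      overlap_curves(series, t, r)))))
  summaries <- do.call(rbind, lapply(seq_len(replicates), function(r)
    cbind(replicate = r,
          distance_strength_summary(series, trajectories[[r]],
                                    step = length(sizes), replicate = r))))
  specificity <- do.call(rbind, lapply(seq_len(replicates), function(r)
    do.call(rbind, lapply(seq_along(sizes), function(i)
      cbind(replicate = r, step = i, n = sizes[i],
            specificity_percentages(trajectories[[r]], i))))))
  fits <- fit_series(series)
  res <- structure(
    list(cohort = cohort, series = series, trajectories = trajectories,
         rates = rates, overlaps = overlaps, summaries = summaries,
         specificity = specificity, fits = fits,
         params = list(sizes = sizes, replicates = replicates,
                       fdr_target = fdr_target,
                       n_permutations = n_permutations,
                       window_bp = window_bp,
                       maf_threshold = maf_threshold, seed = seed)),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(res, out_dir, write_cohort_files)
  res
}

#' @keywords internal
write_pipeline <- function(res, out_dir, write_cohort_files = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  p <- res$params
  manifest <- data.frame(
    key = c("seed", "replicates", "fdr_target", "n_permutations",
            "window_bp", "maf_threshold", "n_individuals", "n_steps",
            "sizes"),
    value = c(p$seed, p$replicates, p$fdr_target, p$n_permutations,
              p$window_bp, p$maf_threshold,
              length(res$cohort$sample_ids), length(p$sizes),
              paste(p$sizes, collapse = ",")),
    stringsAsFactors = FALSE)
  wt(manifest, "manifest.tsv")
  write_series(res$series, file.path(out_dir, "runs"))
  counts <- do.call(rbind, lapply(seq_along(res$trajectories), function(r) {
    tr <- res$trajectories[[r]]
    data.frame(replicate = r,
               step = rep(seq_along(tr$sizes), times = 7),
               n = rep(tr$sizes, times = 7),
               class = rep(overlap_classes(), each = length(tr$sizes)),
               count = as.vector(tr$counts), stringsAsFactors = FALSE)
  }))
  wt(counts, "class_counts.tsv")
  wt(res$rates, "rates.tsv")
  wt(res$overlaps, "overlaps.tsv")
  wt(res$summaries, "distance_strength.tsv")
  wt(res$specificity, "specificity.tsv")
  wt(res$fits, "scaling_fits.tsv")
  if (write_cohort_files)
    write_cohort(res$cohort, file.path(out_dir, "cohort"))
  invisible(out_dir)
}

#' Summarise a pipeline run directory
#'
#' Re-reads the stage TSVs written by [run_pipeline()] and assembles a
#' compact human-readable summary: per tissue and replicate the fitted
#' scaling-law coefficients and R^2, the eQTL count at the first and last
#' step, the tissue-specific share at the first and last step, and the
#' mean consecutive overlap fractions at the eQTL and eSNP level.
#'
#' @param run_dir Directory written by a completed [run_pipeline()] call.
#' @return data.frame, one row per (tissue, replicate).
#' @export
report_summary <- function(run_dir) {
  need <- c("manifest.tsv", "scaling_fits.tsv", "runs/manifest.tsv",
            "specificity.tsv", "overlaps.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run directory ", run_dir, "; missing: ",
         paste(missing, collapse = ", "))
  fits <- utils::read.delim(file.path(run_dir, "scaling_fits.tsv"))
  fits <- fits[!is.na(fits$replicate), , drop = FALSE]
  series_m <- utils::read.delim(file.path(run_dir, "runs", "manifest.tsv"))
  spec <- utils::read.delim(file.path(run_dir, "specificity.tsv"))
  ov <- utils::read.delim(file.path(run_dir, "overlaps.tsv"))
  k <- max(series_m$step)
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    t <- fits$tissue[i]; r <- fits$replicate[i]
    sm <- series_m[series_m$tissue == t & series_m$replicate == r, ]
    sp <- spec[spec$tissue == t & spec$replicate == r, ]
    ovc <- ov[ov$tissue == t & ov$replicate == r & ov$kind == "consecutive", ]
    data.frame(
      tissue = t, replicate = r,
      alpha = fits$alpha[i], beta = fits$beta[i],
      r_squared = fits$r_squared[i],
      q_first = sm$q[sm$step == 1], q_last = sm$q[sm$step == k],
      pct_specific_first = sp$pct_specific[sp$step == 1],
      pct_specific_last = sp$pct_specific[sp$step == k],
      mean_consec_overlap_eqtl = mean(ovc$value[ovc$level == "eqtl"],
                                      na.rm = TRUE),
      mean_consec_overlap_esnp = mean(ovc$value[ovc$level == "esnp"],
                                      na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
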