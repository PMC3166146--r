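#' Subsample sizes equally spaced on the log scale
#'
#' `n_i = round(exp(ln n_min + (i-1) * (ln n_max - ln n_min) / (k-1)))`,
#' so consecutive sizes have an (approximately, after rounding) constant
#' ratio and both endpoints are exact.
#'
#' @param n_min Smallest size (>= 3).
#' @param n_max Largest size (the full cohort).
#' @param k Number of steps (default 20).
#' @return Integer vector of `k` strictly increasing sizes.
#' @export
log_spaced_sizes <- function(n_min = 50L, n_max, k = 20L) {
  stopifnot(n_min >= 3L, n_max > n_min, k >= 2L)
  sizes <- round(exp(seq(log(n_min), log(n_max), length.out = k)))
  sizes[1] <- n_min
  sizes[k] <- n_max
  if (anyDuplicated(sizes))
    stop("log-spaced sizes collide after rounding; choose a smaller k")
  as.integer(sizes)
}

#' Nested random subsamples of a cohort
#'
#' Builds `N_1 subset of ... subset of N_K` by taking the first `n_i`
#' elements of a single seeded permutation of the sample ids. This is
#' distributionally identical to starting from the full cohort and
#' removing a uniformly random set of individuals at each step, and it
#' makes the series reproducible from one seed.
#'
#' @param sample_ids Character vector of all cohort sample ids.
#' @param sizes Strictly increasing sizes, max equal to
#'   `length(sample_ids)`.
#' @param seed Integer seed.
#' @return Object of class `subsample_series`: list with `sizes`,
#'   `subsets` (list of id vectors), `seed`.
#' @export
nested_subsamples <- function(sample_ids, sizes, seed = 1L) {
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0L)) stop("sizes must be strictly increasing")
  if (max(sizes) > length(sample_ids))
    stop("largest size exceeds cohort size")
  set.seed(seed)
  perm <- sample(sample_ids)
  subsets <- lapply(sizes, function(n) perm[seq_len(n)])
  structure(list(sizes = sizes, subsets = subsets, seed = seed),
            class = "subsample_series")
}

#' @keywords internal
#' Deterministic sub-seed for one (replicate, step, tissue) scan, bounded
#' below 2^31 so it is a valid R integer seed.
derive_seed <- function(master, replicate, step, tissue_index) {
  as.integer((as.numeric(master) * 7919 + replicate * 104729 +
                step * 1009 + tissue_index) %% 2147483647L)
}

#' Run per-step, per-tissue cis-eQTL scans over nested subsample series
#'
#' For each replicate an independent nested series is drawn (distinct
#' sub-seed), and every (step, tissue) combination gets a full scan with
#' the MAF filter recomputed on that step's subset. All randomness is
#' derived deterministically from `seed`.
#'
#' @param cohort An `eqtl_cohort`.
#' @param sizes Subsample sizes (default: 20 log-spaced steps from 50 to
#'   the cohort size).
#' @param replicates Number of independent series (default 5).
#' @param fdr_target,n_permutations,window_bp,maf_threshold Scan
#'   parameters, see [call_cis_eqtls()].
#' @param seed Master seed.
#' @param verbose Print progress lines.
#' @return Object of class `series_result`: `sizes`, `tissues`, `manifest`
#'   (data.frame: replicate, step, n, tissue, q, s, p_threshold), `scans`
#'   (nested list `[[replicate]][[step]][[tissue]]` of `scan_result`),
#'   `series` (the subsample series per replicate), and the parameters.
#' @export
run_series <- function(cohort, sizes = NULL, replicates = 5L,
                       fdr_target = 0.10, n_permutations = 10L,
                       window_bp = 1e6, maf_threshold = 0.05,
                       seed = 1L, verbose = FALSE) {
  if (is.null(sizes))
    sizes <- log_spaced_sizes(50L, length(cohort$sample_ids), 20L)
  tissues <- names(cohort$expression)
  k <- length(sizes)
  manifest <- list()
  scans <- vector("list", replicates)
  series_list <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    series <- nested_subsamples(cohort$sample_ids, sizes,
                                seed = derive_seed(seed, r, 0L, 0L))
    series_list[[r]] <- series
    scans[[r]] <- vector("list", k)
    for (i in seq_len(k)) {
      scans[[r]][[i]] <- vector("list", length(tissues))
      names(scans[[r]][[i]]) <- tissues
      for (ti in seq_along(tissues)) {
        t <- tissues[ti]
        res <- call_cis_eqtls(cohort, t, samples = series$subsets[[i]],
                              fdr_target = fdr_target,
                              n_permutations = n_permutations,
                              seed = derive_seed(seed, r, i, ti),
                              window_bp = window_bp,
                              maf_threshold = maf_threshold)
        scans[[r]][[i]][[t]] <- res
        manifest[[length(manifest) + 1L]] <- data.frame(
          replicate = r, step = i, n = sizes[i], tissue = t,
          q = nrow(res$eqtls), s = length(unique(res$eqtls$snp_id)),
          p_threshold = res$p_threshold, stringsAsFactors = FALSE)
        if (verbose)
          message(sprintf("rep %d step %2d (n=%3d) tissue %s: q=%d",
                          r, i, sizes[i], t, nrow(res$eqtls)))
      }
    }
  }
  structure(list(sizes = sizes, tissues = tissues,
                 manifest = do.call(rbind, manifest),
                 scans = scans, series = series_list,
                 params = list(fdr_target = fdr_target,
                               n_permutations = n_permutations,
                               window_bp = window_bp,
                               maf_threshold = maf_threshold,
                               replicates = replicates, seed = seed)),
            class = "series_result")
}

#' @export
print.series_result <- function(x, ...) {
  cat(sprintf("series_result: %d replicate(s), %d steps (n %d..%d), tissues %s\n",
              length(x$scans), length(x$sizes), min(x$sizes), max(x$sizes),
              paste(x$tissues, collapse = ", ")))
  print(utils::head(x$manifest, 6))
  invisible(x)
}

#' Sets of detected eQTL transcripts (or lead eSNPs) per step
#'
#' @param series A `series_result`.
#' @param tissue Tissue label.
#' @param replicate Replicate index (default 1).
#' @param level `"eqtl"` (transcript ids, the eQTL identity) or `"esnp"`
#'   (lead SNP ids).
#' @return List of character vectors, one per step.
#' @export
detected_sets <- function(series, tissue, replicate = 1L,
                          level = c("eqtl", "esnp")) {
  level <- match.arg(level)
  lapply(series$scans[[replicate]], function(step) {
    e <- step[[tissue]]$eqtls
    if (level == "eqtl") unique(e$transcript_id) else unique(e$snp_id)
  })
}

#' Write a series run to disk
#'
#' Layout: `runs/rep{r}/step{i}/{tissue}.tsv` plus a top-level
#' `manifest.tsv` (replicate, step, n, tissue, q, s, p_threshold).
#'
#' @param series A `series_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(series$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (r in seq_along(series$scans)) {
    for (i in seq_along(series$scans[[r]])) {
      d <- file.path(dir, sprintf("rep%d", r), sprintf("step%02d", i))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (t in names(series$scans[[r]][[i]]))
        write_scan_tsv(series$scans[[r]][[i]][[t]],
                       file.path(d, paste0(t, ".tsv")))
    }
  }
  invisible(dir)
}
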