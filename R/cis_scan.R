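#' Minor allele frequency of one genotype column
#'
#' @param g Integer vector of allele-count genotypes (0/1/2, NA = missing).
#' @return `min(f, 1 - f)` where `f` is the alternate-allele frequency over
#'   non-missing diploid calls; always in `[0, 0.5]`.
#' @export
compute_maf <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0L) stop("cannot compute MAF: all genotypes missing")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Filter SNPs by minor allele frequency on a sample subset
#'
#' A SNP is retained iff its MAF, computed on the given subset only, is
#' strictly greater than `threshold`. The filter is recomputed for every
#' subsample: a SNP common in the full cohort may drop out of a small
#' subset and vice versa.
#'
#' @param genotypes Individuals x SNPs matrix.
#' @param threshold MAF threshold (default 0.05); strict `>` is applied.
#' @param samples Optional character/integer subset of rows.
#' @return Character vector of retained SNP ids (column names).
#' @export
filter_snps_by_maf <- function(genotypes, threshold = 0.05, samples = NULL) {
  G <- if (is.null(samples)) genotypes else genotypes[samples, , drop = FALSE]
  if (nrow(G) == 0L) stop("empty sample subset")
  nm <- colSums(!is.na(G))
  if (any(nm == 0L)) stop("SNP with all genotypes missing in subset")
  f <- colSums(G, na.rm = TRUE) / (2 * nm)
  maf <- pmin(f, 1 - f)
  colnames(G)[maf > threshold]
}

#' Kruskal-Wallis rank test of expression across genotype groups
#'
#' Computes the tie-corrected H statistic over the non-empty genotype
#' groups and a p-value from the chi-square upper tail with
#' `df = (#non-empty groups) - 1`. Fewer than two non-empty groups, or a
#' constant response, yields `H = 0, p = 1` (not testable, treated as no
#' association rather than an error). Pairs with missing genotype are
#' dropped.
#'
#' @param y Numeric response (expression values).
#' @param g Integer grouping (genotype 0/1/2; NA dropped pairwise).
#' @return List with `h`, `p`, `df`, `n` (observations used).
#' @export
kruskal_wallis <- function(y, g) {
  ok <- !is.na(g) & !is.na(y)
  y <- y[ok]; g <- g[ok]
  n <- length(y)
  groups <- unique(g)
  if (n < 3L || length(groups) < 2L)
    return(list(h = 0, p = 1, df = 0L, n = n))
  r <- rank(y)
  tie_t <- table(y)
  C <- 1 - sum(tie_t^3 - tie_t) / (n^3 - n)
  if (C <= 0) return(list(h = 0, p = 1, df = length(groups) - 1L, n = n))
  rs <- tapply(r, g, sum)
  ns <- tapply(rep(1L, n), g, sum)
  h <- (12 / (n * (n + 1))) * sum(rs^2 / ns) - 3 * (n + 1)
  h <- h / C
  df <- length(groups) - 1L
  list(h = h, p = stats::pchisq(h, df, lower.tail = FALSE), df = df, n = n)
}

#' @keywords internal
#' Vectorised KW scan of one transcript against a window of SNPs, for the
#' observed ranks and any number of sample-permuted rank columns at once.
#' Gwin must be NA-free; Rmat is n x K (column 1 = observed ranks).
#' Returns list(H, P: p x K matrices; df: length-p vector, NA = untestable).
kw_window_matrix <- function(Gwin, Rmat, tie_corr) {
  n <- nrow(Gwin)
  I0 <- Gwin == 0L; I1 <- Gwin == 1L; I2 <- Gwin == 2L
  n0 <- colSums(I0); n1 <- colSums(I1); n2 <- colSums(I2)
  S0 <- crossprod(I0, Rmat); S1 <- crossprod(I1, Rmat); S2 <- crossprod(I2, Rmat)
  term <- matrix(0, nrow(S0), ncol(S0))
  nz0 <- n0 > 0L; nz1 <- n1 > 0L; nz2 <- n2 > 0L
  if (any(nz0)) term[nz0, ] <- term[nz0, ] + S0[nz0, , drop = FALSE]^2 / n0[nz0]
  if (any(nz1)) term[nz1, ] <- term[nz1, ] + S1[nz1, , drop = FALSE]^2 / n1[nz1]
  if (any(nz2)) term[nz2, ] <- term[nz2, ] + S2[nz2, , drop = FALSE]^2 / n2[nz2]
  H <- (12 / (n * (n + 1))) * term - 3 * (n + 1)
  k_groups <- nz0 + nz1 + nz2
  df <- ifelse(k_groups >= 2L, k_groups - 1L, NA_integer_)
  if (tie_corr <= 0) {
    H[] <- 0
    P <- matrix(1, nrow(H), ncol(H))
  } else {
    H <- H / tie_corr
    H[H < 0] <- 0  # numerical guard
    P <- stats::pchisq(H, df, lower.tail = FALSE)
  }
  P[is.na(df), ] <- NA_real_
  H[is.na(df), ] <- NA_real_
  list(H = H, P = P, df = df)
}

#' @keywords internal
#' Window index (lo:hi into a sorted position vector) per transcript.
cis_window_index <- function(pos, tss, window_bp) {
  lo <- findInterval(tss - window_bp - 0.5, pos) + 1L
  hi <- findInterval(tss + window_bp + 0.5, pos)
  cbind(lo = lo, hi = hi)
}

#' Lead cis association of one transcript
#'
#' Tests every retained SNP whose position lies within
#' `[tss - window_bp, tss + window_bp]` (inclusive) with the
#' Kruskal-Wallis test and returns the smallest-p SNP. Ties on p are
#' broken by smaller `|distance|`, then lexicographic SNP id, so the lead
#' is deterministic.
#'
#' @param y Expression values for the transcript (aligned to genotype rows).
#' @param genotypes Individuals x SNPs matrix (already MAF-filtered).
#' @param snp_pos Positions of the genotype columns (sorted increasing).
#' @param tss Transcription start site (1-based bp).
#' @param window_bp Half-width of the cis window (default 1e6).
#' @return One-row data.frame (snp_id, h, p, distance_bp, n_used) or NULL
#'   when no testable SNP lies in the window.
#' @export
scan_transcript <- function(y, genotypes, snp_pos, tss, window_bp = 1e6) {
  stopifnot(length(snp_pos) == ncol(genotypes))
  win <- which(snp_pos >= tss - window_bp & snp_pos <= tss + window_bp)
  if (length(win) == 0L) return(NULL)
  Gwin <- genotypes[, win, drop = FALSE]
  if (anyNA(Gwin)) {
    stats_list <- lapply(seq_along(win), function(j)
      kruskal_wallis(y, Gwin[, j]))
    p <- vapply(stats_list, `[[`, 0, "p")
    h <- vapply(stats_list, `[[`, 0, "h")
    nu <- vapply(stats_list, `[[`, 0L, "n")
    df <- vapply(stats_list, `[[`, 0L, "df")
    p[df < 1L] <- NA_real_
  } else {
    r <- rank(y)
    tt <- table(y)
    C <- 1 - sum(tt^3 - tt) / (length(y)^3 - length(y))
    kw <- kw_window_matrix(Gwin, matrix(r, ncol = 1), C)
    p <- kw$P[, 1]; h <- kw$H[, 1]
    nu <- rep(length(y), length(win))
  }
  testable <- which(!is.na(p))
  if (length(testable) == 0L) return(NULL)
  dist <- snp_pos[win] - tss
  ids <- colnames(genotypes)[win]
  o <- testable[order(p[testable], abs(dist[testable]), ids[testable])][1]
  data.frame(snp_id = ids[o], h = h[o], p = p[o],
             distance_bp = dist[o], n_used = nu[o],
             stringsAsFactors = FALSE)
}

#' Permutation-based FDR threshold over pooled lead p-values
#'
#' For each candidate threshold `p*` (every observed lead p-value),
#' estimates `FDR(p*)` as the average number of permutation lead p-values
#' at or below `p*` per permutation, divided by the number of observed
#' lead p-values at or below `p*`. The curve is made monotone by a running
#' maximum from the smallest p upward, and the threshold is the largest
#' observed `p*` with monotone FDR at most `fdr_target` (0 when none
#' qualifies, i.e. nothing is reported).
#'
#' @param obs_p Observed lead p-values (NA entries dropped).
#' @param perm_p Matrix (or vector) of lead p-values from permuted scans;
#'   one column per permutation.
#' @param fdr_target Target FDR (default 0.10).
#' @return List: `p_threshold`, `fdr_at_threshold`, and the per-candidate
#'   table `curve` (p, fdr, fdr_monotone).
#' @export
fdr_threshold <- function(obs_p, perm_p, fdr_target = 0.10) {
  obs_p <- obs_p[!is.na(obs_p)]
  if (length(obs_p) == 0L) stop("no observed lead p-values")
  if (is.matrix(perm_p)) {
    n_perm <- ncol(perm_p)
    perm_vals <- as.vector(perm_p)
  } else {
    n_perm <- 1L
    perm_vals <- perm_p
  }
  perm_vals <- sort(perm_vals[!is.na(perm_vals)])
  cand <- sort(unique(obs_p))
  n_obs_le <- findInterval(cand, sort(obs_p))
  n_perm_le <- findInterval(cand, perm_vals)
  fdr <- (n_perm_le / n_perm) / n_obs_le
  fdr_mono <- cummax(fdr)
  ok <- which(fdr_mono <= fdr_target)
  thr <- if (length(ok)) cand[max(ok)] else 0
  list(p_threshold = thr,
       fdr_at_threshold = if (length(ok)) fdr_mono[max(ok)] else NA_real_,
       curve = data.frame(p = cand, fdr = fdr, fdr_monotone = fdr_mono))
}

#' @keywords internal
#' One tissue scan: observed leads for every transcript plus lead p-values
#' under n_perm sample-label permutations of the expression matrix. The
#' permutation repeats the full scan including lead-SNP selection.
#' genotypes must already be restricted to the sample subset and to
#' MAF-retained SNPs, with snp_pos sorted.
scan_tissue_leads <- function(genotypes, snp_pos, expr, tss_vec,
                              window_bp = 1e6, perm_idx = NULL) {
  n <- nrow(genotypes)
  nt <- nrow(expr)
  n_perm <- if (is.null(perm_idx)) 0L else ncol(perm_idx)
  win <- cis_window_index(snp_pos, tss_vec, window_bp)
  ids_all <- colnames(genotypes)
  has_na <- anyNA(genotypes)
  leads <- data.frame(transcript_id = rownames(expr),
                      snp_id = NA_character_, h = NA_real_, p = NA_real_,
                      distance_bp = NA_real_, n_used = NA_integer_,
                      stringsAsFactors = FALSE)
  perm_p <- if (n_perm > 0L) matrix(NA_real_, nt, n_perm) else NULL
  for (i in seq_len(nt)) {
    lo <- win[i, 1L]; hi <- win[i, 2L]
    if (lo > hi) next
    cols <- lo:hi
    y <- expr[i, ]
    Gwin <- genotypes[, cols, drop = FALSE]
    dist <- snp_pos[cols] - tss_vec[i]
    ids <- ids_all[cols]
    if (has_na && anyNA(Gwin)) {
      # slow path: pairwise-complete per SNP, permutations re-ranked
      pick <- function(yy) {
        st <- lapply(seq_along(cols), function(j) kruskal_wallis(yy, Gwin[, j]))
        p <- vapply(st, `[[`, 0, "p")
        df <- vapply(st, `[[`, 0L, "df")
        p[df < 1L] <- NA_real_
        list(p = p, h = vapply(st, `[[`, 0, "h"),
             n = vapply(st, `[[`, 0L, "n"))
      }
      obs <- pick(y)
      if (all(is.na(obs$p))) next
      o <- order(obs$p, abs(dist), ids, na.last = TRUE)[1]
      leads[i, -1] <- list(ids[o], obs$h[o], obs$p[o], dist[o], obs$n[o])
      if (n_perm > 0L) {
        for (k in seq_len(n_perm))
          perm_p[i, k] <- suppressWarnings(min(pick(y[perm_idx[, k]])$p,
                                               na.rm = TRUE))
      }
    } else {
      r <- rank(y)
      tt <- table(y)
      C <- 1 - sum(tt^3 - tt) / (n^3 - n)
      Rmat <- matrix(r, n, 1L + n_perm)
      if (n_perm > 0L)
        for (k in seq_len(n_perm)) Rmat[, k + 1L] <- r[perm_idx[, k]]
      kw <- kw_window_matrix(Gwin, Rmat, C)
      p_obs <- kw$P[, 1L]
      if (all(is.na(p_obs))) next
      o <- order(p_obs, abs(dist), ids, na.last = TRUE)[1]
      leads[i, -1] <- list(ids[o], kw$H[o, 1L], p_obs[o], dist[o], n)
      if (n_perm > 0L) {
        Pp <- kw$P[, -1L, drop = FALSE]
        perm_p[i, ] <- suppressWarnings(apply(Pp, 2, min, na.rm = TRUE))
      }
    }
  }
  if (!is.null(perm_p)) perm_p[!is.finite(perm_p)] <- NA_real_
  list(leads = leads, perm_p = perm_p)
}

#' Call cis eQTLs in one tissue for one sample subset
#'
#' Composes the full per-tissue analysis: restrict to the subset, drop
#' SNPs whose subset MAF does not exceed `maf_threshold`, find each
#' transcript's lead SNP by Kruskal-Wallis over its cis window, estimate
#' the reporting p-value threshold at `fdr_target` by re-running the
#' entire scan (lead-SNP selection included) on `n_permutations`
#' sample-label shuffles of the expression matrix, and retain the leads at
#' or below the threshold. Deterministic given `seed`.
#'
#' @param cohort An `eqtl_cohort` (see [simulate_cohort()] /
#'   [read_cohort()]).
#' @param tissue Tissue label, a name of `cohort$expression`.
#' @param samples Optional character vector of sample ids (subset); default
#'   all.
#' @param fdr_target Target false discovery rate (default 0.10).
#' @param n_permutations Number of expression permutations (default 10).
#' @param seed Integer seed for the permutation shuffles.
#' @param window_bp Cis-window half-width (default 1e6).
#' @param maf_threshold Subset MAF must strictly exceed this (default 0.05).
#' @return Object of class `scan_result`: `eqtls` (significant leads, one
#'   row per transcript: transcript_id, tissue, snp_id, h, p, distance_bp,
#'   n_used), `leads` (all leads incl. non-significant), `p_threshold`,
#'   `fdr_target`, `n_permutations`, `n` (subset size), `n_snps_retained`,
#'   `tissue`.
#' @export
call_cis_eqtls <- function(cohort, tissue, samples = NULL,
                           fdr_target = 0.10, n_permutations = 10L,
                           seed = 1L, window_bp = 1e6,
                           maf_threshold = 0.05) {
  if (!tissue %in% names(cohort$expression))
    stop("unknown tissue: ", tissue)
  if (is.null(samples)) samples <- cohort$sample_ids
  if (!all(samples %in% cohort$sample_ids))
    stop("samples not in cohort")
  samples <- cohort$sample_ids[cohort$sample_ids %in% samples]
  G <- cohort$genotypes[samples, , drop = FALSE]
  keep <- filter_snps_by_maf(G, maf_threshold)
  Gk <- G[, keep, drop = FALSE]
  pos <- cohort$snps$pos[match(keep, cohort$snps$id)]
  expr <- cohort$expression[[tissue]][, samples, drop = FALSE]
  tss <- cohort$transcripts$tss[match(rownames(expr), cohort$transcripts$id)]
  if (anyNA(tss)) stop("transcripts missing from TSS annotation")
  n <- length(samples)
  set.seed(seed)
  perm_idx <- if (n_permutations > 0L)
    vapply(seq_len(n_permutations), function(k) sample.int(n), integer(n))
  else NULL
  sc <- scan_tissue_leads(Gk, pos, expr, tss, window_bp, perm_idx)
  obs <- sc$leads[!is.na(sc$leads$p), , drop = FALSE]
  if (nrow(obs) == 0L) stop("no testable transcript in scan")
  thr <- if (n_permutations > 0L)
    fdr_threshold(obs$p, sc$perm_p, fdr_target)
  else list(p_threshold = 1, fdr_at_threshold = NA_real_, curve = NULL)
  sig <- obs[obs$p <= thr$p_threshold, , drop = FALSE]
  sig <- data.frame(transcript_id = sig$transcript_id,
                    tissue = rep(tissue, nrow(sig)),
                    sig[, c("snp_id", "h", "p", "distance_bp", "n_used")],
                    stringsAsFactors = FALSE)
  rownames(sig) <- NULL
  res <- list(eqtls = sig, leads = sc$leads,
              p_threshold = thr$p_threshold, fdr_target = fdr_target,
              n_permutations = n_permutations, n = n,
              n_snps_retained = length(keep), tissue = tissue)
  class(res) <- "scan_result"
  res
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "scan_result: tissue %s, n = %d, %d SNPs retained, %d cis eQTLs at FDR %.0f%% (p <= %.3g)\n",
    x$tissue, x$n, x$n_snps_retained, nrow(x$eqtls),
    100 * x$fdr_target, x$p_threshold))
  invisible(x)
}

#' Write a scan result as TSV
#'
#' One row per transcript lead; `significant` marks the eQTLs reported at
#' the scan's FDR. The p-value threshold is recorded in a `#` header
#' comment.
#'
#' @param result A `scan_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tissue=%s n=%d p_threshold=%.17g fdr_target=%g n_permutations=%d",
                     result$tissue, result$n, result$p_threshold,
                     result$fdr_target, result$n_permutations), con)
  df <- result$leads
  df$tissue <- result$tissue
  df$significant <- as.integer(!is.na(df$p) & df$p <= result$p_threshold)
  df <- df[, c("transcript_id", "tissue", "snp_id", "h", "p",
               "distance_bp", "n_used", "significant")]
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
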