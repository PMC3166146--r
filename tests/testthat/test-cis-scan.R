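test_that("minor allele frequency is computed over non-missing diploid calls", {
  expect_equal(compute_maf(c(0, 0, 1, 2)), 0.375)
  expect_equal(compute_maf(c(2, 2, 2, 2)), 0)
  expect_equal(compute_maf(c(0, 0, 0, 0, 1)), 0.1)
  expect_equal(compute_maf(c(0, NA, 1)), 0.25)
  expect_error(compute_maf(c(NA, NA)), "missing")
})

test_that("MAF filter is strict and recomputed on the subsample", {
  # 10 samples, one alt allele: f = 0.05 exactly -> removed (strict >)
  G <- cbind(border = c(1L, rep(0L, 9)), common = rep(1L, 10),
             mono = rep(0L, 10))
  rownames(G) <- sprintf("i%02d", 1:10)
  expect_identical(filter_snps_by_maf(G, 0.05), "common")
  expect_identical(filter_snps_by_maf(G, 0), c("border", "common"))
  # a SNP common in the full set can vanish from a nested subset: the
  # carriers of the minor allele all sit outside the first 4 samples
  G2 <- cbind(rare = c(rep(0L, 4), rep(1L, 6)))
  rownames(G2) <- sprintf("i%02d", 1:10)
  expect_identical(filter_snps_by_maf(G2, 0.05), "rare")
  expect_identical(filter_snps_by_maf(G2, 0.05,
                                      samples = sprintf("i%02d", 1:4)),
                   character(0))
})

test_that("Kruskal-Wallis matches the hand-computed fixture and degenerates safely", {
  # ranks 1..6, rank sums 3/7/11 over groups of 2:
  # H = 12/(6*7) * (9/2 + 49/2 + 121/2) - 3*7 = 4.5714...
  kw <- kruskal_wallis(1:6, c(0, 0, 1, 1, 2, 2))
  expect_equal(kw$h, 32 / 7, tolerance = 1e-12)
  expect_equal(kw$p, stats::pchisq(32 / 7, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(kw$h, 4), 4.5714)
  expect_equal(kw$p, 0.1017, tolerance = 1e-3)

  # constant response: all ranks tied, defined as no association
  expect_equal(kruskal_wallis(rep(3.5, 6), c(0, 0, 1, 1, 2, 2)),
               list(h = 0, p = 1, df = 2L, n = 6L))
  # fewer than two genotype groups: not testable, no association
  expect_equal(kruskal_wallis(1:5, rep(1, 5))$p, 1)
  # permuting the response within genotype groups leaves H unchanged
  y <- c(10, 20, 1, 2, 5, 6)
  g <- c(0, 0, 1, 1, 2, 2)
  expect_equal(kruskal_wallis(y, g)$h,
               kruskal_wallis(c(20, 10, 2, 1, 6, 5), g)$h)
})

test_that("Kruskal-Wallis agrees with stats::kruskal.test including ties", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    g <- sample(0:2, n, replace = TRUE)
    y <- round(stats::rnorm(n), sample(0:1, 1))  # rounding induces ties
    if (length(unique(g)) < 2 || length(unique(y)) < 2) next
    ref <- stats::kruskal.test(y, factor(g))
    kw <- kruskal_wallis(y, g)
    expect_equal(kw$h, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-12)
    expect_equal(kw$df, unname(ref$parameter))
  }
})

test_that("KW p-values are calibrated on null data", {
  set.seed(41)
  n <- 100
  p <- replicate(2500, {
    kruskal_wallis(stats::rnorm(n), stats::rbinom(n, 2, 0.3))$p
  })
  rate <- mean(p < 0.05)
  ci_half <- 3 * sqrt(0.05 * 0.95 / 2500)
  expect_lt(abs(rate - 0.05), ci_half)
})

test_that("lead-SNP selection equals the brute-force window minimum", {
  co <- simulate_cohort(small_config(seed = 13, ld_rho = 0.3))
  G <- co$genotypes
  pos <- co$snps$pos
  for (i in c(1, 5, 17, 33)) {
    tss <- co$transcripts$tss[i]
    y <- co$expression$A[i, ]
    lead <- scan_transcript(y, G, pos, tss)
    win <- which(pos >= tss - 1e6 & pos <= tss + 1e6)
    expect_gt(length(win), 1)
    brute_p <- vapply(win, function(j) {
      g <- factor(G[, j])
      if (nlevels(g) < 2) NA_real_
      else stats::kruskal.test(y, g)$p.value
    }, 0)
    o <- order(brute_p, abs(pos[win] - tss), colnames(G)[win],
               na.last = TRUE)[1]
    expect_identical(lead$snp_id, colnames(G)[win][o])
    expect_equal(lead$p, brute_p[o], tolerance = 1e-10)
    expect_equal(lead$distance_bp, pos[win][o] - tss)
  }
})

test_that("lead-SNP tie-breaking and trivial windows behave as specified", {
  # single SNP in window: returned regardless of p
  G <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L), 6, 1,
              dimnames = list(paste0("i", 1:6), "only"))
  lead <- scan_transcript(stats::rnorm(6), G, 500L, 400L, window_bp = 1000)
  expect_identical(lead$snp_id, "only")
  # two identical SNP columns: equal p, closer one wins
  G2 <- matrix(rep(c(0L, 1L, 2L), 4), 6, 2,
               dimnames = list(paste0("i", 1:6), c("far", "near")))
  lead2 <- scan_transcript(c(1, 2, 3, 4, 5, 6), G2, c(5000L, 1500L), 1000L,
                           window_bp = 1e4)
  expect_identical(lead2$snp_id, "near")
  # no SNP in window
  expect_null(scan_transcript(stats::rnorm(6), G, 500L, 1e7))
})

test_that("permutation FDR threshold matches hand enumeration", {
  # observed leads 0.001, 0.02, 0.5; one permutation gives 0.3, 0.6, 0.9:
  # FDR(0.001) = 0/1, FDR(0.02) = 0/2, FDR(0.5) = 1/3 > 0.1 -> threshold 0.02
  res <- fdr_threshold(c(0.001, 0.02, 0.5),
                       matrix(c(0.3, 0.6, 0.9), ncol = 1), 0.10)
  expect_equal(res$p_threshold, 0.02)
  expect_equal(res$curve$fdr, c(0, 0, 1 / 3))
  expect_equal(sum(c(0.001, 0.02, 0.5) <= res$p_threshold), 2)
  # target 1: everything is retained
  res1 <- fdr_threshold(c(0.001, 0.02, 0.5),
                        matrix(c(0.3, 0.6, 0.9), ncol = 1), 1)
  expect_equal(res1$p_threshold, 0.5)
  # no qualifying threshold -> 0 (empty result)
  res0 <- fdr_threshold(c(0.5, 0.6), matrix(c(0.01, 0.02), ncol = 1), 0.1)
  expect_equal(res0$p_threshold, 0)
  # monotone curve is non-decreasing in p
  set.seed(51)
  obs <- stats::runif(50)
  perm <- matrix(stats::runif(500), ncol = 10)
  curve <- fdr_threshold(obs, perm, 0.1)$curve
  expect_true(all(diff(curve$fdr_monotone) >= 0))
  expect_error(fdr_threshold(numeric(0), perm), "no observed")
})

test_that("noise-free cohorts are fully recovered with the causal SNP as lead", {
  co <- simulate_cohort(noiseless_config())
  truth <- co$architecture
  for (t in c("A", "B", "C")) {
    res <- call_cis_eqtls(co, t, n_permutations = 10, seed = 5)
    expected <- truth$transcript_id[truth[[paste0("b_", t)]] != 0]
    expect_setequal(res$eqtls$transcript_id, expected)
    # no LD, no noise: the lead SNP is the causal SNP
    found <- res$eqtls[match(expected, res$eqtls$transcript_id), ]
    expect_identical(found$snp_id,
                     truth$causal_snp[match(expected, truth$transcript_id)])
  }
})

test_that("null cohorts yield (close to) empty scans and scans are deterministic", {
  pp <- stats::setNames(c(1, rep(0, 7)), names(default_pattern_probs()))
  co <- simulate_cohort(small_config(seed = 17, pattern_probs = pp))
  res <- call_cis_eqtls(co, "A", n_permutations = 10, seed = 9)
  expect_lte(nrow(res$eqtls), 2)

  res2 <- call_cis_eqtls(co, "A", n_permutations = 10, seed = 9)
  expect_identical(res$leads, res2$leads)
  expect_identical(res$p_threshold, res2$p_threshold)
})

test_that("each transcript yields at most one lead and FDR tightening shrinks the set", {
  co <- simulate_cohort(small_config(seed = 23))
  res10 <- call_cis_eqtls(co, "B", fdr_target = 0.10, n_permutations = 10,
                          seed = 2)
  expect_false(anyDuplicated(res10$eqtls$transcript_id) > 0)
  res05 <- call_cis_eqtls(co, "B", fdr_target = 0.05, n_permutations = 10,
                          seed = 2)
  res20 <- call_cis_eqtls(co, "B", fdr_target = 0.20, n_permutations = 10,
                          seed = 2)
  expect_true(all(res05$eqtls$transcript_id %in% res10$eqtls$transcript_id))
  expect_true(all(res10$eqtls$transcript_id %in% res20$eqtls$transcript_id))
  expect_true(all(abs(res10$eqtls$distance_bp) <= 1e6))
  expect_true(all(res10$eqtls$p > 0 & res10$eqtls$p <= 1))
})

test_that("scan TSVs round-trip the lead table and threshold", {
  co <- simulate_cohort(small_config(seed = 29))
  res <- call_cis_eqtls(co, "C", n_permutations = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scan_tsv(res, path)
  hdr <- readLines(path, n = 1)
  expect_match(hdr, "p_threshold=")
  df <- utils::read.delim(path, comment.char = "#")
  expect_equal(sum(df$significant), nrow(res$eqtls))
  expect_equal(df$p[match(res$eqtls$transcript_id, df$transcript_id)],
               res$eqtls$p)
})
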