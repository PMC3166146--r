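# Shared fixtures, built in code at test time.

# Small, fast cohort for unit tests: dense SNPs on a short chromosome so
# every cis window is well populated.
small_config <- function(seed = 7, ...) {
  args <- list(n_individuals = 80L, n_snps = 300L, n_transcripts = 40L,
               chrom_length_bp = 8e6, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Noise-free cohort with large effects: every causal transcript should be
# detected with the causal SNP as lead (no LD, no noise).
noiseless_config <- function(seed = 11) {
  small_config(seed = seed, ld_rho = 0, noise_sd = 0,
               effect_mu = log(2), effect_sigma = 0.1,
               maf_range = c(0.2, 0.5),
               pattern_probs = c(none = 0.2, onlyA = 0.2, onlyB = 0.1,
                                 onlyC = 0.1, AB = 0.1, BC = 0.05,
                                 CA = 0.05, ABC = 0.2))
}

# Moderate cohort + 8-step series used by several dynamics tests; built
# once per test run.
moderate_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(sim_config(n_individuals = 200L, n_snps = 800L,
                                       n_transcripts = 120L,
                                       chrom_length_bp = 2e7, seed = 19))
      cache <<- run_pipeline(cohort = co, n_min = 40L, k = 8L,
                             replicates = 1L, seed = 19)
    }
    cache
  }
})

# The full default study design (400 individuals, 300 transcripts, 2,000
# SNPs, 20 log-spaced steps 50..400, 10-permutation 10% FDR scans, one
# replicate); shared by the acceptance tests.
default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(sim_config(seed = 1))
      cache <<- run_pipeline(cohort = co, replicates = 1L, seed = 1)
    }
    cache
  }
})

# Handcrafted 2-sample / 2-SNP VCF used by the reader tests.
write_tiny_vcf <- function(path,
                           gts = c("0/0", "0/1", "1/1", "0|1")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
    paste(c("chr1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            gts[1], gts[2]), collapse = "\t"),
    paste(c("chr1", "250", "rs2", "A", "G", ".", "PASS", ".", "GT",
            gts[3], gts[4]), collapse = "\t"))
  writeLines(lines, path)
  path
}
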