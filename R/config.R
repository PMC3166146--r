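#' Simulation configuration for a synthetic three-tissue cohort
#'
#' Bundles every knob of the cohort generator. The defaults describe a
#' desk-scale obese-cohort stand-in: 400 individuals, 2,000 SNPs on one
#' 50 Mb chromosome, 300 expression traits profiled in three tissues
#' (A, B, C; think omental adipose, subcutaneous adipose, liver), with a
#' cis architecture in which effects shared across tissues are stronger
#' and sit closer to the transcription start site than tissue-specific
#' ones.
#'
#' @param n_individuals Number of individuals.
#' @param n_snps Number of biallelic SNPs on the single synthetic chromosome.
#' @param n_transcripts Number of expression traits.
#' @param chrom_length_bp Chromosome length in base pairs.
#' @param maf_range Length-2 numeric, bounds (low, high) of the uniform
#'   distribution population allele frequencies are drawn from; must lie in
#'   (0, 0.5].
#' @param ld_rho Probability in `[0, 1)` that a haplotype copies the allele of
#'   the previous SNP instead of drawing a fresh one; 0 gives independent
#'   SNPs, values near 1 give long stretches of near-perfect LD.
#' @param pattern_probs Named numeric vector of probabilities over the eight
#'   cis-architecture patterns `none, onlyA, onlyB, onlyC, AB, BC, CA, ABC`;
#'   must sum to 1. The default makes tissues A and B (the two adipose
#'   depots) share more eQTLs with each other than either does with C.
#' @param effect_mu,effect_sigma Log-normal parameters of the absolute
#'   genetic effect `|b|` (per-allele shift in expression units).
#' @param shared_boost Multiplicative factor (>= 1) applied to `|b|` when the
#'   pattern covers two or more tissues.
#' @param shared_distance_mean_bp Mean of the exponential distribution of the
#'   causal-SNP/TSS distance for shared patterns; tissue-specific causal SNPs
#'   are placed uniformly over the whole cis window instead.
#' @param noise_sd Residual standard deviation of expression per tissue.
#' @param seed Integer RNG seed; every draw of the generator is reproducible
#'   from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 400L,
                       n_snps = 2000L,
                       n_transcripts = 300L,
                       chrom_length_bp = 5e7,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.5,
                       pattern_probs = default_pattern_probs(),
                       effect_mu = log(0.25),
                       effect_sigma = 0.6,
                       shared_boost = 1.5,
                       shared_distance_mean_bp = 1e5,
                       noise_sd = 1,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_snps = as.integer(n_snps),
    n_transcripts = as.integer(n_transcripts),
    chrom_length_bp = as.numeric(chrom_length_bp),
    maf_range = as.numeric(maf_range),
    ld_rho = as.numeric(ld_rho),
    pattern_probs = pattern_probs,
    effect_mu = as.numeric(effect_mu),
    effect_sigma = as.numeric(effect_sigma),
    shared_boost = as.numeric(shared_boost),
    shared_distance_mean_bp = as.numeric(shared_distance_mean_bp),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Default probabilities of the eight cis-architecture patterns
#'
#' @return Named numeric vector summing to 1.
#' @export
default_pattern_probs <- function() {
  c(none = 0.30, onlyA = 0.14, onlyB = 0.13, onlyC = 0.13,
    AB = 0.07, BC = 0.04, CA = 0.04, ABC = 0.15)
}

#' @keywords internal
pattern_levels <- function() {
  c("none", "onlyA", "onlyB", "onlyC", "AB", "BC", "CA", "ABC")
}

#' Tissues covered by each architecture pattern
#' @keywords internal
pattern_tissues <- function(pattern) {
  switch(pattern,
    none = character(0),
    onlyA = "A", onlyB = "B", onlyC = "C",
    AB = c("A", "B"), BC = c("B", "C"), CA = c("C", "A"),
    ABC = c("A", "B", "C"),
    stop("unknown pattern: ", pattern)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(cfg$n_individuals, cfg$n_snps, cfg$n_transcripts)
  if (any(!is.finite(counts)) || any(counts <= 0L))
    stop("all counts (individuals, SNPs, transcripts) must be positive")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("maf_range must be within (0, 0.5] with low <= high")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1)
    stop("ld_rho must lie in [0, 1)")
  pp <- cfg$pattern_probs
  if (is.null(names(pp)) || !setequal(names(pp), pattern_levels()))
    stop("pattern_probs must be named with exactly: ",
         paste(pattern_levels(), collapse = ", "))
  if (any(pp < 0) || abs(sum(pp) - 1) > 1e-9)
    stop("pattern_probs must be non-negative and sum to 1 (within 1e-9)")
  if (cfg$shared_boost < 1)
    stop("shared_boost must be >= 1")
  if (cfg$noise_sd < 0)
    stop("noise_sd must be non-negative")
  if (cfg$n_snps > cfg$chrom_length_bp)
    stop("position collision: n_snps exceeds chrom_length_bp, ",
         "cannot place SNPs at distinct positions")
  cfg
}

#' Write / read a simulation configuration as flat key-value text
#'
#' The on-disk format is YAML-style `key: value` lines, one per field;
#' `pattern_probs` and `maf_range` are comma-separated `name=value` /
#' value lists.
#'
#' @param cfg A `sim_config`.
#' @param path File path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  pp <- cfg$pattern_probs[pattern_levels()]
  lines <- c(
    sprintf("n_individuals: %d", cfg$n_individuals),
    sprintf("n_snps: %d", cfg$n_snps),
    sprintf("n_transcripts: %d", cfg$n_transcripts),
    sprintf("chrom_length_bp: %.15g", cfg$chrom_length_bp),
    sprintf("maf_range: %.15g, %.15g", cfg$maf_range[1], cfg$maf_range[2]),
    sprintf("ld_rho: %.15g", cfg$ld_rho),
    sprintf("pattern_probs: %s",
            paste(sprintf("%s=%.15g", names(pp), pp), collapse = ", ")),
    sprintf("effect_mu: %.15g", cfg$effect_mu),
    sprintf("effect_sigma: %.15g", cfg$effect_sigma),
    sprintf("shared_boost: %.15g", cfg$shared_boost),
    sprintf("shared_distance_mean_bp: %.15g", cfg$shared_distance_mean_bp),
    sprintf("noise_sd: %.15g", cfg$noise_sd),
    sprintf("seed: %d", cfg$seed)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L)) stop("malformed config line in ", path)
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("config field missing: ", k)
    vals[i]
  }
  pp_parts <- strsplit(get("pattern_probs"), ",")[[1]]
  pp_kv <- do.call(rbind, strsplit(trimws(pp_parts), "="))
  pp <- stats::setNames(as.numeric(pp_kv[, 2]), trimws(pp_kv[, 1]))
  mr <- as.numeric(trimws(strsplit(get("maf_range"), ",")[[1]]))
  sim_config(
    n_individuals = as.integer(get("n_individuals")),
    n_snps = as.integer(get("n_snps")),
    n_transcripts = as.integer(get("n_transcripts")),
    chrom_length_bp = as.numeric(get("chrom_length_bp")),
    maf_range = mr,
    ld_rho = as.numeric(get("ld_rho")),
    pattern_probs = pp,
    effect_mu = as.numeric(get("effect_mu")),
    effect_sigma = as.numeric(get("effect_sigma")),
    shared_boost = as.numeric(get("shared_boost")),
    shared_distance_mean_bp = as.numeric(get("shared_distance_mean_bp")),
    noise_sd = as.numeric(get("noise_sd")),
    seed = as.integer(get("seed"))
  )
}
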