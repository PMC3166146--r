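#' Simulate diploid genotypes on one synthetic chromosome
#'
#' Draws SNP positions uniformly (without replacement, sorted) along the
#' chromosome, a population allele frequency per SNP uniformly from
#' `maf_range`, and two haplotypes per individual. Linkage disequilibrium
#' is modelled by a first-order allele-copy process: moving left to right,
#' each haplotype copies the previous SNP's allele with probability
#' `ld_rho` and otherwise draws a fresh Bernoulli(f) allele. Genotypes are
#' the haplotype sums, coded 0/1/2 copies of the alternate allele.
#'
#' @param config A [sim_config()].
#' @return A list with `genotypes` (integer matrix, individuals x SNPs,
#'   dimnames sample/SNP ids) and `snps` (data.frame: id, chrom, pos, af
#'   where af is the population alternate-allele frequency used).
#' @export
simulate_genotypes <- function(config) {
  config <- validate_sim_config(config)
  n <- config$n_individuals
  p <- config$n_snps
  pos <- as.numeric(sort(sample.int(config$chrom_length_bp, p, replace = FALSE)))
  af <- stats::runif(p, config$maf_range[1], config$maf_range[2])

  # two haplotype matrices, n x p, filled SNP by SNP (first-order copy chain)
  h1 <- matrix(0L, n, p)
  h2 <- matrix(0L, n, p)
  rho <- config$ld_rho
  h1[, 1] <- stats::rbinom(n, 1L, af[1])
  h2[, 1] <- stats::rbinom(n, 1L, af[1])
  if (p > 1L) {
    for (j in 2:p) {
      fresh1 <- stats::rbinom(n, 1L, af[j])
      fresh2 <- stats::rbinom(n, 1L, af[j])
      if (rho > 0) {
        copy1 <- stats::runif(n) < rho
        copy2 <- stats::runif(n) < rho
        h1[, j] <- ifelse(copy1, h1[, j - 1L], fresh1)
        h2[, j] <- ifelse(copy2, h2[, j - 1L], fresh2)
      } else {
        h1[, j] <- fresh1
        h2[, j] <- fresh2
      }
    }
  }
  G <- h1 + h2
  storage.mode(G) <- "integer"
  sample_ids <- sprintf("ind%03d", seq_len(n))
  snp_ids <- sprintf("snp%05d", seq_len(p))
  dimnames(G) <- list(sample_ids, snp_ids)
  snps <- data.frame(id = snp_ids, chrom = "chr1", pos = pos, af = af,
                     stringsAsFactors = FALSE)
  list(genotypes = G, snps = snps)
}

#' Place transcription start sites along the synthetic chromosome
#'
#' TSS positions are uniform over the chromosome; with the default SNP
#' density every +/-1 Mb cis window contains many SNPs.
#'
#' @param config A [sim_config()].
#' @return data.frame: id, chrom, tss (1-based bp), sorted by position.
#' @export
simulate_transcripts <- function(config) {
  config <- validate_sim_config(config)
  tss <- as.numeric(sort(sample.int(config$chrom_length_bp, config$n_transcripts,
                                    replace = FALSE)))
  data.frame(id = sprintf("tx%04d", seq_len(config$n_transcripts)),
             chrom = "chr1", tss = tss, stringsAsFactors = FALSE)
}

#' Assign a cis architecture to each transcript
#'
#' Each transcript draws one of the eight patterns (`none`, three
#' single-tissue, three pairwise, `ABC`) from `pattern_probs`. For
#' patterns covering two or more tissues the causal SNP is the in-window
#' SNP whose TSS distance is nearest an Exponential(shared_distance_mean_bp)
#' draw, and the effect magnitude is multiplied by `shared_boost`; for
#' single-tissue patterns the target distance is uniform over the whole
#' window. `|b|` is log-normal and the (shared) sign is a fair coin. This
#' builds in the two contrasts the detection analysis is meant to see:
#' shared eQTLs are stronger and closer to the TSS than tissue-specific
#' ones.
#'
#' @param config A [sim_config()].
#' @param transcripts data.frame with columns id, tss (see
#'   [simulate_transcripts()]).
#' @param snps data.frame with columns id, pos.
#' @param window_bp Half-width of the cis window (default 1 Mb).
#' @return data.frame (class `cis_architecture`): transcript_id, pattern,
#'   causal_snp (NA for `none`), b_A, b_B, b_C (0 outside the pattern).
#' @export
assign_architecture <- function(config, transcripts, snps,
                                window_bp = 1e6) {
  config <- validate_sim_config(config)
  pp <- config$pattern_probs[pattern_levels()]
  nt <- nrow(transcripts)
  patterns <- sample(pattern_levels(), nt, replace = TRUE, prob = pp)
  causal <- rep(NA_character_, nt)
  b <- matrix(0, nt, 3, dimnames = list(NULL, c("A", "B", "C")))
  pos <- snps$pos
  for (i in seq_len(nt)) {
    pat <- patterns[i]
    if (pat == "none") next
    tss <- transcripts$tss[i]
    in_win <- which(pos >= tss - window_bp & pos <= tss + window_bp)
    if (length(in_win) == 0L)
      stop("transcript ", transcripts$id[i],
           " has no SNP in its cis window; increase SNP density")
    tissues <- pattern_tissues(pat)
    shared <- length(tissues) >= 2L
    if (shared) {
      target <- stats::rexp(1, rate = 1 / config$shared_distance_mean_bp)
      j <- in_win[which.min(abs(abs(pos[in_win] - tss) - target))]
    } else {
      target_pos <- stats::runif(1, tss - window_bp, tss + window_bp)
      j <- in_win[which.min(abs(pos[in_win] - target_pos))]
    }
    causal[i] <- snps$id[j]
    mag <- stats::rlnorm(1, config$effect_mu, config$effect_sigma)
    if (shared) mag <- mag * config$shared_boost
    eff <- mag * sample(c(-1, 1), 1)
    b[i, tissues] <- eff
  }
  arch <- data.frame(transcript_id = transcripts$id, pattern = patterns,
                     causal_snp = causal,
                     b_A = b[, "A"], b_B = b[, "B"], b_C = b[, "C"],
                     stringsAsFactors = FALSE)
  class(arch) <- c("cis_architecture", "data.frame")
  arch
}

#' Simulate per-tissue expression from genotypes and a cis architecture
#'
#' Additive model: `y_it = b_t * g_i,causal + e`, with independent
#' Gaussian noise of standard deviation `noise_sd` across tissues,
#' transcripts, and individuals. Transcripts with pattern `none` are pure
#' noise.
#'
#' @param genotypes Integer matrix, individuals x SNPs (dimnames required).
#' @param architecture A `cis_architecture` (see [assign_architecture()]).
#' @param config A [sim_config()].
#' @return Named list of three numeric matrices (tissues A, B, C), each
#'   transcripts x individuals.
#' @export
simulate_expression <- function(genotypes, architecture, config) {
  config <- validate_sim_config(config)
  n <- nrow(genotypes)
  nt <- nrow(architecture)
  tissues <- c("A", "B", "C")
  out <- vector("list", 3)
  names(out) <- tissues
  causal_idx <- match(architecture$causal_snp, colnames(genotypes))
  for (t in tissues) {
    bcol <- architecture[[paste0("b_", t)]]
    y <- matrix(stats::rnorm(nt * n, 0, config$noise_sd), nt, n)
    hit <- which(bcol != 0)
    for (i in hit) {
      j <- causal_idx[i]
      if (is.na(j)) stop("causal SNP not found in genotype matrix for ",
                         architecture$transcript_id[i])
      y[i, ] <- y[i, ] + bcol[i] * genotypes[, j]
    }
    dimnames(y) <- list(architecture$transcript_id, rownames(genotypes))
    out[[t]] <- y
  }
  out
}

#' Simulate a complete three-tissue cohort
#'
#' Runs the full generator (genotypes, TSS placement, architecture,
#' expression) under the configuration's seed. With a fixed seed every
#' component is bit-identical across runs.
#'
#' @param config A [sim_config()].
#' @return An object of class `eqtl_cohort`: list with `genotypes`, `snps`,
#'   `transcripts`, `architecture`, `expression` (list of 3 matrices),
#'   `sample_ids`, and the `config` used.
#' @export
simulate_cohort <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  gt <- simulate_genotypes(config)
  tx <- simulate_transcripts(config)
  arch <- assign_architecture(config, tx, gt$snps)
  expr <- simulate_expression(gt$genotypes, arch, config)
  cohort <- list(genotypes = gt$genotypes, snps = gt$snps, transcripts = tx,
                 architecture = arch, expression = expr,
                 sample_ids = rownames(gt$genotypes), config = config)
  class(cohort) <- "eqtl_cohort"
  cohort
}

#' @export
print.eqtl_cohort <- function(x, ...) {
  cat(sprintf(
    "eqtl_cohort: %d individuals, %d SNPs, %d transcripts, %d tissues\n",
    length(x$sample_ids), nrow(x$snps), nrow(x$transcripts),
    length(x$expression)))
  if (!is.null(x$architecture)) {
    tab <- table(factor(x$architecture$pattern, levels = pattern_levels()))
    cat("architecture patterns:\n")
    print(tab)
  }
  invisible(x)
}

#' Write a cohort to disk in standard formats
#'
#' Emits an unphased diploid VCF 4.2 (`genotypes.vcf`), one expression TSV
#' per tissue (`expression_<tissue>.tsv`, first column `transcript_id`,
#' remaining columns sample ids), a BED4 TSS annotation (`tss.bed`,
#' 0-based half-open), the ground-truth architecture TSV
#' (`architecture.tsv`, when present), and the generator configuration
#' (`config.txt`, when present). [read_cohort()] on the output reproduces
#' the numeric content exactly.
#'
#' @param cohort An `eqtl_cohort` (or compatible list).
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (length(cohort$expression) == 0L)
    stop("cohort has no expression matrices (empty tissue list)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  write_genotypes_vcf(cohort$genotypes, cohort$snps,
                      file.path(out_dir, "genotypes.vcf"))
  for (t in names(cohort$expression)) {
    write_expression_tsv(cohort$expression[[t]],
                         file.path(out_dir, sprintf("expression_%s.tsv", t)))
  }
  write_tss_bed(cohort$transcripts, file.path(out_dir, "tss.bed"))
  if (!is.null(cohort$architecture)) {
    utils::write.table(
      format(as.data.frame(cohort$architecture), digits = 17, trim = TRUE,
             scientific = FALSE),
      file.path(out_dir, "architecture.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$config))
    write_sim_config(cohort$config, file.path(out_dir, "config.txt"))
  invisible(out_dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `genotypes.vcf`, `expression_*.tsv`,
#'   `tss.bed`.
#' @return An `eqtl_cohort` (without ground truth unless
#'   `architecture.tsv` is present).
#' @export
read_cohort <- function(dir) {
  gt <- read_genotypes_vcf(file.path(dir, "genotypes.vcf"))
  expr_files <- list.files(dir, pattern = "^expression_.*\\.tsv$",
                           full.names = TRUE)
  if (length(expr_files) == 0L) stop("no expression TSVs found in ", dir)
  labels <- sub("^expression_(.*)\\.tsv$", "\\1", basename(expr_files))
  expr <- lapply(seq_along(expr_files), function(i)
    read_expression_tsv(expr_files[i], labels[i]))
  names(expr) <- labels
  tx <- read_tss_annotation(file.path(dir, "tss.bed"))
  arch_path <- file.path(dir, "architecture.tsv")
  arch <- NULL
  if (file.exists(arch_path)) {
    arch <- utils::read.delim(arch_path, stringsAsFactors = FALSE)
    class(arch) <- c("cis_architecture", "data.frame")
  }
  cfg_path <- file.path(dir, "config.txt")
  cfg <- if (file.exists(cfg_path)) read_sim_config(cfg_path) else NULL
  cohort <- list(genotypes = gt$genotypes, snps = gt$snps, transcripts = tx,
                 architecture = arch, expression = expr,
                 sample_ids = rownames(gt$genotypes), config = cfg)
  class(cohort) <- "eqtl_cohort"
  cohort
}
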