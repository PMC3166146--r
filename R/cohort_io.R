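#' Read genotypes from a VCF file
#'
#' Parses a plain-text VCF 4.2 with a GT FORMAT field into an allele-count
#' dosage matrix (0/1/2 alternate-allele copies). Phased (`0|1`) and
#' unphased (`0/1`) calls are treated alike; `./.` becomes `NA`.
#' Multi-allelic records are rejected. Only single-chromosome inputs are
#' expected; positions are 1-based as in the format.
#'
#' @param path Path to an uncompressed VCF.
#' @return List with `genotypes` (integer matrix, individuals x SNPs) and
#'   `snps` (data.frame: id, chrom, pos).
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  lines <- readLines(path)
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1L) stop("VCF header line #CHROM missing in ", path)
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L) stop("VCF has no sample columns: ", path)
  sample_ids <- hdr[-(1:9)]
  body_idx <- which(seq_along(lines) > hdr_i & nzchar(lines))
  n_snp <- length(body_idx)
  if (n_snp == 0L) stop("VCF has no variant records: ", path)
  G <- matrix(NA_integer_, length(sample_ids), n_snp)
  ids <- character(n_snp)
  chrom <- character(n_snp)
  pos <- numeric(n_snp)
  for (k in seq_len(n_snp)) {
    ln <- body_idx[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop("malformed VCF row at line ", ln, ": expected ", length(hdr),
           " fields, got ", length(f))
    if (grepl(",", f[5], fixed = TRUE))
      stop("multi-allelic record at line ", ln, " (ALT = ", f[5],
           "); split or remove it")
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) stop("GT missing from FORMAT at line ", ln)
    calls <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE),
                    function(x) x[gt_i], "")
    alleles <- strsplit(calls, "[/|]")
    dose <- vapply(alleles, function(a) {
      if (length(a) != 2L || any(a == ".")) return(NA_integer_)
      ai <- suppressWarnings(as.integer(a))
      if (any(is.na(ai)) || any(ai > 1L))
        stop("malformed or non-biallelic GT at line ", ln)
      sum(ai)
    }, NA_integer_)
    G[, k] <- dose
    chrom[k] <- f[1]
    pos[k] <- as.numeric(f[2])
    ids[k] <- if (f[3] == ".") sprintf("%s_%d", f[1], as.integer(pos[k])) else f[3]
  }
  if (anyDuplicated(ids)) stop("duplicate SNP ids in ", path)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in ", path)
  dimnames(G) <- list(sample_ids, ids)
  list(genotypes = G,
       snps = data.frame(id = ids, chrom = chrom, pos = pos,
                         stringsAsFactors = FALSE))
}

#' Write genotypes as VCF 4.2
#'
#' REF/ALT are fixed placeholder alleles (A/G); genotypes are emitted as
#' unphased diploid GT calls, `NA` as `./.`.
#'
#' @param genotypes Integer matrix, individuals x SNPs, values 0/1/2/NA.
#' @param snps data.frame with columns id, chrom, pos aligned to the
#'   genotype columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, snps, path) {
  stopifnot(ncol(genotypes) == nrow(snps))
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=eqtlsat",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t"))
  rows <- vapply(seq_len(nrow(snps)), function(k) {
    g <- genotypes[, k]
    calls <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(snps$chrom[k], format(snps$pos[k], scientific = FALSE),
            snps$id[k], "A", "G", ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a per-tissue expression matrix from TSV
#'
#' Expected layout: header row of sample ids following a `transcript_id`
#' column; numeric body.
#'
#' @param path TSV path.
#' @param tissue_label Label to attach (e.g. `"A"`).
#' @return Numeric matrix, transcripts x samples, with attribute `tissue`.
#' @export
read_expression_tsv <- function(path, tissue_label = NA_character_) {
  if (!file.exists(path)) stop("expression TSV not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs transcript_id + >=1 sample: ",
                          path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate transcript ids in ", path)
  body <- df[, -1, drop = FALSE]
  num_ok <- vapply(body, is.numeric, TRUE)
  if (!all(num_ok))
    stop("non-numeric expression values in ", path, " (column ",
         paste(colnames(body)[!num_ok], collapse = ", "), ")")
  m <- as.matrix(body)
  rownames(m) <- ids
  if (!all(is.finite(m))) stop("non-finite expression values in ", path)
  attr(m, "tissue") <- tissue_label
  m
}

#' Write an expression matrix as TSV
#'
#' Values are written with 17 significant digits so the binary doubles
#' survive a read/write round trip.
#'
#' @param expr Numeric matrix, transcripts x samples (dimnames required).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(!is.null(rownames(expr)), !is.null(colnames(expr)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("transcript_id", colnames(expr)), collapse = "\t"), con)
  body <- apply(expr, 1, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(rownames(expr), body, sep = "\t"), con)
  invisible(path)
}

#' Read a TSS annotation from BED4
#'
#' BED is 0-based half-open; the TSS is taken as `start + 1` (1-based).
#' Unsorted input is accepted and sorted by (chrom, tss).
#'
#' @param path BED4 path (chrom, start, end, name).
#' @return data.frame: id, chrom, tss.
#' @export
read_tss_annotation <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED4 requires 4 columns: ", path)
  names(df)[1:4] <- c("chrom", "start", "end", "name")
  if (any(df$end < df$start))
    stop("BED interval with end < start in ", path)
  if (any(df$start < 0)) stop("negative BED start in ", path)
  if (anyDuplicated(df$name)) stop("duplicate transcript ids in ", path)
  out <- data.frame(id = df$name, chrom = df$chrom, tss = df$start + 1,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$tss), , drop = FALSE]
}

#' Write a TSS annotation as BED4
#'
#' @param transcripts data.frame with columns id, chrom, tss (1-based).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(transcripts, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", transcripts$chrom,
                   as.integer(transcripts$tss - 1),
                   as.integer(transcripts$tss), transcripts$id)
  writeLines(lines, path)
  invisible(path)
}

#' Restrict genotypes and expression matrices to their common samples
#'
#' Keeps the intersection of sample ids across the genotype matrix and all
#' expression matrices, preserving the genotype matrix's original sample
#' order. Idempotent.
#'
#' @param genotypes Individuals x SNPs matrix with sample row names.
#' @param expression Named list of transcripts x samples matrices.
#' @return List `(genotypes, expression, sample_ids)` restricted to the
#'   common samples.
#' @export
align_samples <- function(genotypes, expression) {
  common <- rownames(genotypes)
  for (m in expression) common <- intersect(common, colnames(m))
  common <- rownames(genotypes)[rownames(genotypes) %in% common]
  if (length(common) < 2L)
    stop("fewer than 2 samples shared between genotypes and all tissues")
  list(genotypes = genotypes[common, , drop = FALSE],
       expression = lapply(expression, function(m) m[, common, drop = FALSE]),
       sample_ids = common)
}
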