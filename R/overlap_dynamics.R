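#' The seven tissue-overlap class labels
#' @return Character vector in a fixed order.
#' @export
overlap_classes <- function() {
  c("ONLY_A", "ONLY_B", "ONLY_C", "AB", "BC", "CA", "ABC")
}

#' Classify detected transcripts into the seven tissue-overlap classes
#'
#' A transcript detected in exactly one tissue is `ONLY_*`; in a pair,
#' `AB`/`BC`/`CA`; in all three, `ABC`. Transcripts detected nowhere do
#' not appear in the result.
#'
#' @param q_a,q_b,q_c Character vectors of transcript ids detected in
#'   tissues A, B, C.
#' @return Named character vector, transcript id -> class label.
#' @export
classify_overlap <- function(q_a, q_b, q_c) {
  all_t <- sort(unique(c(q_a, q_b, q_c)))
  if (length(all_t) == 0L)
    return(stats::setNames(character(0), character(0)))
  inA <- all_t %in% q_a
  inB <- all_t %in% q_b
  inC <- all_t %in% q_c
  code <- inA + 2L * inB + 4L * inC   # 1..7
  lab <- c("ONLY_A", "ONLY_B", "AB", "ONLY_C", "CA", "BC", "ABC")[code]
  stats::setNames(lab, all_t)
}

#' Fraction of one detection set recovered in another
#'
#' `consecutive_overlap_fraction` uses the earlier (smaller) step as the
#' denominator: the share of step-i detections still present at step i+1.
#' `reference_overlap` reports both directions against a reference set
#' (typically the largest subsample): `forward` = share of `q_i` present
#' in the reference, `backward` = share of the reference already present
#' in `q_i`.
#'
#' @param q_i,q_next,q_ref Character vectors of detected ids (transcripts
#'   for eQTLs, lead SNPs for eSNPs).
#' @return A fraction in `[0, 1]`; `NA` when the denominator set is empty.
#' @export
consecutive_overlap_fraction <- function(q_i, q_next) {
  if (length(q_i) == 0L) return(NA_real_)
  length(intersect(q_i, q_next)) / length(unique(q_i))
}

#' @rdname consecutive_overlap_fraction
#' @return `reference_overlap`: named numeric `c(forward=, backward=)`.
#' @export
reference_overlap <- function(q_i, q_ref) {
  inter <- length(intersect(q_i, q_ref))
  fw <- if (length(q_i) == 0L) NA_real_ else inter / length(unique(q_i))
  bw <- if (length(q_ref) == 0L) NA_real_ else inter / length(unique(q_ref))
  c(forward = fw, backward = bw)
}

#' Class-membership trajectory of a series replicate
#'
#' @param series A `series_result`.
#' @param replicate Replicate index.
#' @return Object of class `class_trajectory`: `membership` (list per
#'   step: named transcript -> class), `counts` (steps x 7 matrix),
#'   `sizes`.
#' @export
class_trajectory <- function(series, replicate = 1L) {
  k <- length(series$sizes)
  qa <- detected_sets(series, "A", replicate)
  qb <- detected_sets(series, "B", replicate)
  qc <- detected_sets(series, "C", replicate)
  membership <- lapply(seq_len(k), function(i)
    classify_overlap(qa[[i]], qb[[i]], qc[[i]]))
  counts <- t(vapply(membership, function(m)
    table(factor(m, levels = overlap_classes())),
    stats::setNames(integer(7), overlap_classes())))
  structure(list(membership = membership, counts = counts,
                 sizes = series$sizes, replicate = replicate),
            class = "class_trajectory")
}

#' Creation / deletion / move-in / move-out rates between two steps
#'
#' For each class X between consecutive steps i-1 and i:
#' * creation: transcripts in X at step i that were undetected in every
#'   tissue at step i-1;
#' * deletion: transcripts in X at step i-1 that are undetected everywhere
#'   at step i;
#' * move_out: in X at step i-1, detected at step i but in a different
#'   class;
#' * move_in: in X at step i, detected at step i-1 but in a different
#'   class.
#' Rates are the counts divided by the change in sample size.
#'
#' These satisfy the bookkeeping identity
#' `count_X(i) = count_X(i-1) + creation + move_in - deletion - move_out`.
#'
#' @param prev,curr Named transcript -> class vectors for steps i-1 and i
#'   (see [classify_overlap()]).
#' @param delta_n Change in sample size between the steps (> 0).
#' @return data.frame: class, creation, deletion, move_in, move_out (raw
#'   counts) and the four `*_rate` columns (counts / delta_n).
#' @export
transition_rates <- function(prev, curr, delta_n) {
  if (delta_n <= 0) stop("delta_n must be positive (consecutive steps)")
  classes <- overlap_classes()
  out <- data.frame(class = classes, creation = 0L, deletion = 0L,
                    move_in = 0L, move_out = 0L, stringsAsFactors = FALSE)
  for (ci in seq_along(classes)) {
    x <- classes[ci]
    in_x_curr <- names(curr)[curr == x]
    in_x_prev <- names(prev)[prev == x]
    out$creation[ci] <- sum(!(in_x_curr %in% names(prev)))
    out$deletion[ci] <- sum(!(in_x_prev %in% names(curr)))
    moved_from <- in_x_prev[in_x_prev %in% names(curr)]
    out$move_out[ci] <- sum(curr[moved_from] != x)
    moved_to <- in_x_curr[in_x_curr %in% names(prev)]
    out$move_in[ci] <- sum(prev[moved_to] != x)
  }
  for (col in c("creation", "deletion", "move_in", "move_out"))
    out[[paste0(col, "_rate")]] <- out[[col]] / delta_n
  out
}

#' Transition-rate series over a whole trajectory
#'
#' @param trajectory A `class_trajectory`.
#' @return data.frame: step_from, step_to, delta_n, class, the four raw
#'   counts and the four rates.
#' @export
rate_series <- function(trajectory) {
  k <- length(trajectory$membership)
  out <- list()
  for (i in 2:k) {
    tr <- transition_rates(trajectory$membership[[i - 1]],
                           trajectory$membership[[i]],
                           trajectory$sizes[i] - trajectory$sizes[i - 1])
    out[[i - 1]] <- cbind(step_from = i - 1L, step_to = i,
                          delta_n = trajectory$sizes[i] - trajectory$sizes[i - 1],
                          tr)
  }
  do.call(rbind, out)
}

#' Overlap-fraction curves for one replicate
#'
#' Consecutive-step overlap and forward/backward overlap against the
#' largest subsample, at both the eQTL (transcript) and eSNP (lead SNP)
#' level.
#'
#' @param series A `series_result`.
#' @param tissue Tissue label.
#' @param replicate Replicate index.
#' @return data.frame: level, kind
#'   (`consecutive`/`forward_ref`/`backward_ref`), step, value.
#' @export
overlap_curves <- function(series, tissue, replicate = 1L) {
  k <- length(series$sizes)
  out <- list()
  for (level in c("eqtl", "esnp")) {
    sets <- detected_sets(series, tissue, replicate, level)
    ref <- sets[[k]]
    cons <- vapply(seq_len(k - 1), function(i)
      consecutive_overlap_fraction(sets[[i]], sets[[i + 1]]), 0)
    refs <- t(vapply(seq_len(k), function(i)
      reference_overlap(sets[[i]], ref), c(forward = 0, backward = 0)))
    out[[length(out) + 1L]] <- data.frame(
      level = level, kind = "consecutive", step = seq_len(k - 1),
      value = cons, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      level = level, kind = "forward_ref", step = seq_len(k),
      value = refs[, "forward"], stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      level = level, kind = "backward_ref", step = seq_len(k),
      value = refs[, "backward"], stringsAsFactors = FALSE)
  }
  cbind(tissue = tissue, replicate = replicate, do.call(rbind, out))
}

#' Mean eSNP-TSS distance and association strength per overlap class
#'
#' For every class and tissue, the mean absolute lead-SNP distance to the
#' TSS (in Mb) and the mean `-log10 p` over the class members detected in
#' that tissue at the given step. Empty cells are `NA`, never zero.
#'
#' @param series A `series_result`.
#' @param trajectory Matching `class_trajectory`.
#' @param step Step index (default: last).
#' @param replicate Replicate index.
#' @return data.frame: class, tissue, n, mean_abs_delta_mb,
#'   mean_neglog10p.
#' @export
distance_strength_summary <- function(series, trajectory,
                                      step = length(series$sizes),
                                      replicate = 1L) {
  memb <- trajectory$membership[[step]]
  out <- list()
  for (t in series$tissues) {
    e <- series$scans[[replicate]][[step]][[t]]$eqtls
    cls <- memb[e$transcript_id]
    for (x in overlap_classes()) {
      sel <- which(cls == x)
      out[[length(out) + 1L]] <- data.frame(
        class = x, tissue = t, n = length(sel),
        mean_abs_delta_mb = if (length(sel)) mean(abs(e$distance_bp[sel])) / 1e6 else NA_real_,
        mean_neglog10p = if (length(sel)) mean(-log10(e$p[sel])) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Two-sided Mann-Whitney test between two distance (or strength) samples
#'
#' Exact when the combined sample size is at most 12, normal
#' approximation with tie correction otherwise. Because the test uses
#' ranks only, the p-value is invariant under any monotone transform of
#' the inputs (e.g. log10 of distances).
#'
#' @param x,y Numeric samples (each non-empty).
#' @return Two-sided p-value.
#' @export
compare_distance_distributions <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  exact <- (length(x) + length(y)) <= 12
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact)$p.value)
}

#' Tissue-specific and all-tissue shares of detections at one step
#'
#' For each tissue T: `specific` = |ONLY_T| / |detected in T| and
#' `shared_all` = |ABC| / |detected in T|, as percentages.
#'
#' @param trajectory A `class_trajectory`.
#' @param step Step index.
#' @return data.frame: tissue, n_detected, pct_specific, pct_shared_all
#'   (NA when a tissue has no detections).
#' @export
specificity_percentages <- function(trajectory, step) {
  memb <- trajectory$membership[[step]]
  tissue_classes <- list(
    A = c("ONLY_A", "AB", "CA", "ABC"),
    B = c("ONLY_B", "AB", "BC", "ABC"),
    C = c("ONLY_C", "BC", "CA", "ABC"))
  out <- lapply(names(tissue_classes), function(t) {
    det <- sum(memb %in% tissue_classes[[t]])
    only <- sum(memb == paste0("ONLY_", t))
    abc <- sum(memb == "ABC")
    data.frame(tissue = t, n_detected = det,
               pct_specific = if (det) 100 * only / det else NA_real_,
               pct_shared_all = if (det) 100 * abc / det else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
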