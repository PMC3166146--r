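#' Fit the eQTL-count scaling law
#'
#' Ordinary least squares of `sqrt(q)` on `ln(n)`: the square root of the
#' number of detected cis eQTLs is, empirically, linear in the log of the
#' sample size over the range studied, so
#' `q(n) = (alpha + beta * ln n)^2`. The fit is invariant to the order of
#' the points. A constant count series is reported as `beta = 0,
#' r_squared = 0`.
#'
#' @param n Sample sizes (>= 2 each).
#' @param q Detected eQTL counts (>= 0 each).
#' @return Object of class `scaling_fit`: `alpha`, `beta`, `r_squared`,
#'   `n_points`, `transform = "sqrt-count vs log-size"`.
#' @export
fit_scaling_law <- function(n, q) {
  stopifnot(length(n) == length(q))
  if (length(n) < 3L) stop("need at least 3 points to fit the scaling law")
  if (any(q < 0)) stop("counts must be non-negative")
  if (any(n < 2)) stop("sample sizes must be >= 2")
  x <- log(n)
  y <- sqrt(q)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= .Machine$double.eps * max(1, sum(y^2))) 0 else 1 - rss / tss
  structure(list(alpha = unname(co[1]), beta = unname(co[2]),
                 r_squared = r2, n_points = length(n),
                 transform = "sqrt-count vs log-size"),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("scaling_fit: sqrt(q) = %.3f + %.3f ln(n), R^2 = %.3f (%d points)\n",
              x$alpha, x$beta, x$r_squared, x$n_points))
  invisible(x)
}

#' Extrapolate the eQTL count to a sample size
#'
#' Evaluates `q_hat = (alpha + beta * ln n)^2`. The reported value is
#' rounded half-up to an integer count when `round = TRUE`. The linear
#' predictor must be non-negative: below `n = exp(-alpha/beta)` (for
#' `beta > 0`) the law has no meaning and an error is raised.
#'
#' @param fit A `scaling_fit`, or a numeric `c(alpha, beta)` pair.
#' @param n Sample size(s) to predict at.
#' @param round Round half-up to integer counts (default TRUE).
#' @return Predicted count(s).
#' @export
predict_count <- function(fit, n, round = TRUE) {
  if (inherits(fit, "scaling_fit")) {
    alpha <- fit$alpha; beta <- fit$beta
  } else {
    stopifnot(is.numeric(fit), length(fit) == 2L)
    alpha <- fit[1]; beta <- fit[2]
  }
  lp <- alpha + beta * log(n)
  if (any(lp < 0)) {
    n_min_valid <- if (beta > 0) exp(-alpha / beta) else NA_real_
    stop(sprintf(
      "negative linear predictor: the law is only valid for n >= %.1f",
      n_min_valid))
  }
  q <- lp^2
  if (round) floor(q + 0.5) else q
}

#' Sliding-window slopes of the scaling relation
#'
#' OLS slope of `sqrt(q)` on `ln(n)` within every window of `window`
#' consecutive steps. Rising slopes along the series signal accelerating
#' detection; falling slopes signal saturation of that count series.
#'
#' @param n Sample sizes in step order.
#' @param q Counts in step order.
#' @param window Window length in steps (>= 3; the reference choices are
#'   10 and 15).
#' @return data.frame: start, end, slope.
#' @export
sliding_window_slope <- function(n, q, window = 10L) {
  stopifnot(length(n) == length(q))
  window <- as.integer(window)
  if (window < 3L) stop("window must cover at least 3 points")
  if (window > length(n)) stop("window exceeds number of points")
  x <- log(n)
  y <- sqrt(q)
  starts <- seq_len(length(n) - window + 1L)
  slope <- vapply(starts, function(s) {
    xs <- x[s:(s + window - 1L)]
    ys <- y[s:(s + window - 1L)]
    sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  }, 0)
  data.frame(start = starts, end = starts + window - 1L, slope = slope)
}

#' Scaling-law fits for a whole series run
#'
#' Fits the law per tissue and replicate, plus a pooled per-tissue fit
#' over all replicates, and (optionally) extrapolates each fit to the
#' requested sample sizes.
#'
#' @param series A `series_result`.
#' @param predict_n Optional sample sizes to extrapolate to.
#' @return data.frame: tissue, replicate (`NA` = pooled), alpha, beta,
#'   r_squared, n_points, and one `pred_<n>` column per requested size.
#' @export
fit_series <- function(series, predict_n = NULL) {
  m <- series$manifest
  out <- list()
  add <- function(tissue, replicate, n, q) {
    f <- fit_scaling_law(n, q)
    row <- data.frame(tissue = tissue, replicate = replicate,
                      alpha = f$alpha, beta = f$beta,
                      r_squared = f$r_squared, n_points = f$n_points,
                      stringsAsFactors = FALSE)
    for (pn in predict_n)
      row[[sprintf("pred_%d", as.integer(pn))]] <-
        tryCatch(predict_count(f, pn), error = function(e) NA_real_)
    out[[length(out) + 1L]] <<- row
  }
  for (t in unique(m$tissue)) {
    for (r in unique(m$replicate)) {
      sub <- m[m$tissue == t & m$replicate == r, ]
      add(t, r, sub$n, sub$q)
    }
    sub <- m[m$tissue == t, ]
    if (length(unique(m$replicate)) > 1L) add(t, NA_integer_, sub$n, sub$q)
  }
  do.call(rbind, out)
}
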