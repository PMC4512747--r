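#' Default grid of discovery P-value inclusion thresholds
#' @export
default_threshold_grid <- function() c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)

check_threshold_grid <- function(thresholds) {
  if (length(thresholds) == 0 || any(thresholds <= 0) || any(thresholds > 1) ||
      is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing and in (0, 1]", call. = FALSE)
  }
  thresholds
}

#' Count effect-direction agreement at one inclusion threshold
#'
#' Among harmonized SNPs with discovery P at or below `threshold`, counts
#' how many have the same effect sign in discovery and target. SNPs with
#' an exactly zero effect in either trait carry no sign and are excluded
#' (their count is reported in the `n_zero` attribute).
#'
#' @param pair A `harmonized_pair`.
#' @param threshold Discovery P-value cutoff.
#' @return Named vector `c(n = , k = )`; `n` SNPs tested, `k` concordant.
#' @export
concordance_counts <- function(pair, threshold) {
  nz <- pair$beta_disc != 0 & pair$beta_targ != 0
  sub <- pair[nz & pair$p_disc <= threshold, , drop = FALSE]
  out <- c(n = nrow(sub),
           k = sum(sign(sub$beta_disc) == sign(sub$beta_targ)))
  attr(out, "n_zero") <- sum(!nz & pair$p_disc <= threshold)
  out
}

#' Exact two-sided binomial test
#'
#' Two-sided exact P value by the minimum-likelihood method: the sum of
#' Binomial(n, p0) point probabilities over all outcomes no more probable
#' than the observed `k`. For `p0 = 0.5` this equals the doubled smaller
#' tail, capped at 1.
#'
#' @param n Number of trials (>= 1).
#' @param k Number of successes, `0 <= k <= n`.
#' @param p0 Null success probability (default 0.5, chance agreement).
#' @return The two-sided P value.
#' @export
exact_binomial_two_sided <- function(n, k, p0 = 0.5) {
  if (length(n) != 1 || length(k) != 1 || is.na(n) || is.na(k) ||
      n < 1 || k < 0 || k > n || n != round(n) || k != round(k)) {
    stop("need integer counts with 0 <= k <= n, n >= 1", call. = FALSE)
  }
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)", call. = FALSE)
  d <- stats::dbinom(0:n, n, p0)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

#' Scan effect-direction concordance across inclusion thresholds
#'
#' Runs [concordance_counts()] and [exact_binomial_two_sided()] at each
#' threshold of the grid and labels each threshold `concordant` (excess
#' agreement), `discordant` (excess disagreement) or `none`, using
#' significance level `alpha`. Thresholds with no qualifying SNPs are
#' skipped with a warning and reported as `NA` rows.
#'
#' @param pair A `harmonized_pair`.
#' @param thresholds Strictly increasing thresholds in (0, 1].
#' @param alpha Significance level for the per-threshold label; by
#'   convention the study-wide corrected level from [corrected_alpha()].
#' @return A `concordance_scan` data frame: `threshold`, `n`, `k`,
#'   `proportion`, `p`, `label`.
#' @export
concordance_scan <- function(pair, thresholds = default_threshold_grid(),
                             alpha = 0.05) {
  check_threshold_grid(thresholds)
  if (nrow(pair) == 0) stop("empty harmonized pair", call. = FALSE)
  rows <- lapply(thresholds, function(thr) {
    ct <- concordance_counts(pair, thr)
    n <- ct[["n"]]; k <- ct[["k"]]
    if (n == 0) {
      warning("no SNPs at threshold ", thr, "; skipped", call. = FALSE)
      return(data.frame(threshold = thr, n = 0L, k = NA_integer_,
                        proportion = NA_real_, p = NA_real_,
                        label = "none", stringsAsFactors = FALSE))
    }
    p <- exact_binomial_two_sided(n, k)
    prop <- k / n
    label <- if (p <= alpha && prop > 0.5) "concordant"
             else if (p <= alpha && prop < 0.5) "discordant"
             else "none"
    data.frame(threshold = thr, n = n, k = k, proportion = prop, p = p,
               label = label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, alpha = alpha,
            class = c("concordance_scan", "data.frame"))
}

#' Plot a concordance scan as -log10(P) against inclusion threshold
#' @param x A `concordance_scan`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_concordance_scan <- function(x, ...) {
  ok <- !is.na(x$p)
  graphics::plot(x$threshold[ok], -log10(x$p[ok]), type = "b", pch = 19,
                 xlab = "discovery P inclusion threshold",
                 ylab = expression(-log[10] ~ P ~ "(exact binomial)"), ...)
  graphics::abline(h = -log10(attr(x, "alpha")), lty = 2)
  invisible(x)
}
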