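#' Nyholt effective number of independent tests
#'
#' Given a matrix of polygenic score profiles (individuals x traits),
#' estimates the effective number of independent traits from the
#' eigenvalues `lambda` of the trait correlation matrix:
#' `Meff = 1 + (T - 1) * (1 - Var(lambda) / T)`, with `Var` using
#' denominator `T - 1`. Mutually independent traits give `Meff = T`;
#' perfectly correlated traits give `Meff = 1`.
#'
#' @param profiles Numeric matrix, individuals in rows, one column per
#'   trait PRS.
#' @param floor_li_ji Apply a Li-and-Ji style floor, counting each
#'   eigenvalue at least as its fractional part (default `FALSE`; the
#'   plain eigenvalue-variance formula is used).
#' @return The estimated effective number of tests.
#' @export
nyholt_meff <- function(profiles, floor_li_ji = FALSE) {
  profiles <- as.matrix(profiles)
  T <- ncol(profiles)
  if (T < 2) stop("need at least 2 traits", call. = FALSE)
  sds <- apply(profiles, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(profiles)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant PRS column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lam <- eigen(stats::cor(profiles), symmetric = TRUE, only.values = TRUE)$values
  if (floor_li_ji) {
    return(sum(ifelse(lam >= 1, 1, 0) + (lam - floor(lam))))
  }
  1 + (T - 1) * (1 - stats::var(lam) / T)
}

#' Study-wide Bonferroni-corrected significance level
#'
#' Divides the raw level by the effective number of independent discovery
#' traits times the number of target subtypes analysed, e.g.
#' `0.05 / (13.4 * 4)` for 14 correlated discovery traits (Meff 13.4) and
#' 4 stroke subtypes.
#'
#' @param meff Effective number of independent discovery traits (>= 1).
#' @param n_subtypes Number of target subtypes (>= 1).
#' @param alpha_raw Raw level (default 0.05).
#' @export
corrected_alpha <- function(meff, n_subtypes, alpha_raw = 0.05) {
  if (meff < 1 || n_subtypes < 1 || alpha_raw <= 0) {
    stop("need meff >= 1, n_subtypes >= 1, alpha_raw > 0", call. = FALSE)
  }
  alpha_raw / (meff * n_subtypes)
}

#' Assemble a multiple-testing report
#'
#' @param profiles PRS score matrix passed to [nyholt_meff()].
#' @param n_subtypes Number of target subtypes.
#' @param alpha_raw Raw significance level.
#' @return List: `n_traits`, `meff`, `alpha_raw`, `n_subtypes`,
#'   `alpha_corrected`.
#' @export
meff_report <- function(profiles, n_subtypes = 1, alpha_raw = 0.05) {
  meff <- nyholt_meff(profiles)
  list(n_traits = ncol(as.matrix(profiles)), meff = meff,
       alpha_raw = alpha_raw, n_subtypes = n_subtypes,
       alpha_corrected = corrected_alpha(meff, n_subtypes, alpha_raw))
}
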