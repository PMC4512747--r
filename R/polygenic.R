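#' Joint effect of a SNP subset from summary statistics
#'
#' Precision-weighted mean estimator of the regression coefficient of the
#' target outcome on a discovery-weighted polygenic score, computed from
#' summary statistics alone. With discovery effects `b_i`, target effects
#' `w_i` and target standard errors `s_i` over SNPs passing the discovery
#' P threshold,
#' \deqn{\hat a = \frac{\sum_i b_i w_i / s_i^2}{\sum_i b_i^2 / s_i^2},
#'       \qquad se(\hat a) = \Big(\sum_i b_i^2 / s_i^2\Big)^{-1/2}.}
#' For a binary target, `a_hat` is on the log-odds scale per unit of
#' discovery-beta-weighted allele score. Covariate adjustment is inherited
#' from the contributing GWASs.
#'
#' @param pair A `harmonized_pair`.
#' @param threshold Discovery P-value inclusion threshold.
#' @return A one-row data frame: `threshold`, `n_snps`, `alpha_hat`, `se`,
#'   `z`, `p`.
#' @export
joint_effect <- function(pair, threshold) {
  sub <- pair[pair$p_disc <= threshold &
                is.finite(pair$beta_disc) & is.finite(pair$beta_targ) &
                is.finite(pair$se_targ) & pair$se_targ > 0, , drop = FALSE]
  if (nrow(sub) == 0) stop("no SNPs pass threshold ", threshold, call. = FALSE)
  w <- 1 / sub$se_targ^2
  den <- sum(sub$beta_disc^2 * w)
  if (den == 0) stop("degenerate input: all discovery effects zero", call. = FALSE)
  a <- sum(sub$beta_disc * sub$beta_targ * w) / den
  se <- 1 / sqrt(den)
  z <- a / se
  data.frame(threshold = threshold, n_snps = nrow(sub), alpha_hat = a,
             se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Joint-effect scan across inclusion thresholds
#'
#' Computes [joint_effect()] at each threshold and flags thresholds
#' significant at `alpha`. The attribute `best_threshold` records the most
#' significant threshold.
#'
#' @param pair A `harmonized_pair`.
#' @param thresholds Strictly increasing thresholds in (0, 1].
#' @param alpha Significance level for the per-threshold flag.
#' @return A `prs_scan` data frame: one [joint_effect()] row per
#'   threshold plus a logical `significant` column.
#' @export
prs_threshold_scan <- function(pair, thresholds = default_threshold_grid(),
                               alpha = 0.05) {
  check_threshold_grid(thresholds)
  if (nrow(pair) == 0) stop("empty harmonized pair", call. = FALSE)
  out <- do.call(rbind, lapply(thresholds, function(t) joint_effect(pair, t)))
  out$significant <- out$p <= alpha
  structure(out, alpha = alpha,
            best_threshold = out$threshold[which.min(out$p)],
            class = c("prs_scan", "data.frame"))
}

#' Score individuals with a discovery-weighted polygenic risk score
#'
#' Per-individual score: the sum over SNPs passing the discovery inclusion
#' threshold of the dosage of the (harmonized) discovery effect allele
#' times the discovery effect size. Panel dosages are assumed to count the
#' discovery effect allele. Missing dosages are mean-imputed per SNP.
#'
#' @param panel A `genotype_panel` of the individuals to score.
#' @param pair A `harmonized_pair` supplying weights.
#' @param threshold Discovery P-value inclusion threshold.
#' @return A `prs_profile` data frame (`individual_id`, `score`) with the
#'   number of SNPs used in attribute `n_snps`.
#' @export
score_individuals <- function(panel, pair, threshold) {
  sub <- pair[pair$p_disc <= threshold, , drop = FALSE]
  idx <- match(sub$snp_id, panel$map$snp_id)
  n_missing <- sum(is.na(idx))
  sub <- sub[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (nrow(sub) == 0) stop("no overlap between pair and panel SNPs", call. = FALSE)
  X <- panel$dosages[, idx, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu[nas[, 2]]
  }
  score <- as.numeric(X %*% sub$beta_disc)
  structure(data.frame(individual_id = panel$individual_ids, score = score,
                       stringsAsFactors = FALSE),
            n_snps = nrow(sub), n_absent = n_missing,
            class = c("prs_profile", "data.frame"))
}

#' Logistic regression of case status on a polygenic score
#'
#' Fits `status ~ score (+ covariates)` by logistic regression and reports
#' the score coefficient with its pseudo R-squared (Nagelkerke by default).
#' Complete separation is flagged rather than raised.
#'
#' @param profile A `prs_profile` (or data frame with a `score` column).
#' @param status 0/1 outcome per individual, in profile order.
#' @param covariates Optional numeric matrix of extra predictors.
#' @param pseudo_r2 `"nagelkerke"` or `"mcfadden"`.
#' @return List: `coefficient`, `se`, `p`, `pseudo_r2`, `separation`,
#'   `n`.
#' @export
fit_prs_model <- function(profile, status, covariates = NULL,
                          pseudo_r2 = c("nagelkerke", "mcfadden")) {
  pseudo_r2 <- match.arg(pseudo_r2)
  status <- as.integer(status)
  if (length(status) != nrow(profile)) {
    stop("status length does not match profile", call. = FALSE)
  }
  if (min(table(factor(status, levels = 0:1))) < 2) {
    stop("need at least 2 individuals per outcome class", call. = FALSE)
  }
  df <- data.frame(status = status, score = profile$score)
  form <- status ~ score
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    df <- cbind(df, covariates)
    form <- stats::as.formula(paste("status ~ score +",
                                    paste(colnames(covariates), collapse = "+")))
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (abs(stats::coef(fit)[["score"]]) > 1e3) separation <- TRUE
  n <- nrow(df)
  dev <- fit$deviance
  dev0 <- fit$null.deviance
  r2 <- if (pseudo_r2 == "mcfadden") {
    1 - dev / dev0
  } else {
    (1 - exp((dev - dev0) / n)) / (1 - exp(-dev0 / n))
  }
  sm <- summary(fit)$coefficients
  list(coefficient = sm["score", 1], se = sm["score", 2],
       p = sm["score", 4], pseudo_r2 = r2, separation = separation, n = n)
}

#' Bar plot of joint-effect variance explained by inclusion threshold
#' @param x A `prs_scan`.
#' @param r2 Optional vector of pseudo R-squared values per threshold; when
#'   absent, bars show the Wald chi-square of the joint effect.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_prs_scan <- function(x, r2 = NULL, ...) {
  height <- if (is.null(r2)) x$z^2 else r2
  ylab <- if (is.null(r2)) "joint-effect Wald chi-square" else "pseudo R-squared"
  graphics::barplot(height, names.arg = x$threshold,
                    xlab = "discovery P inclusion threshold", ylab = ylab, ...)
  invisible(x)
}
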