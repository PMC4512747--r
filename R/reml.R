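# Variance-component estimation on genomic relationship matrices by
# average-information REML with EM warm-start. The univariate fit works in
# the eigenbasis of the GRM, where the covariance matrix is diagonal and
# each iteration is O(n); the bivariate fit assembles the dense two-trait
# covariance matrix and pays one Cholesky per iteration.

# restricted log-likelihood and derived quantities in the GRM eigenbasis
.univ_eval <- function(lam, yt, Xt, sg, se) {
  n <- length(yt)
  p <- ncol(Xt)
  d <- sg * lam + se
  W <- Xt / d
  C <- crossprod(Xt, W)
  Cch <- chol(C)
  solveC <- function(B) backsolve(Cch, forwardsolve(t(Cch), B))
  Pof <- function(u) as.numeric(u / d - W %*% solveC(crossprod(W, u)))
  Py <- Pof(yt)
  ll <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(Cch))) + sum(yt * Py) +
                  (n - p) * log(2 * pi))
  trP <- function(g) {
    sum(g / d) - sum(diag(solveC(crossprod(W, g * W))))
  }
  yPVgPy <- sum(lam * Py^2)
  yPVePy <- sum(Py^2)
  score <- -0.5 * c(trP(lam) - yPVgPy, trP(rep(1, n)) - yPVePy)
  wg <- lam * Py
  we <- Py
  Pwg <- Pof(wg)
  Pwe <- Pof(we)
  AI <- 0.5 * matrix(c(sum(wg * Pwg), sum(we * Pwg),
                       sum(wg * Pwe), sum(we * Pwe)), 2, 2)
  list(ll = ll, score = score, AI = AI,
       yPVPy = c(yPVgPy, yPVePy), trPV = c(trP(lam), trP(rep(1, n))))
}

#' Univariate GREML: SNP heritability by AI-REML
#'
#' Fits `y = Xb + g + e` with `g ~ N(0, sigma2_g * A)` and
#' `e ~ N(0, sigma2_e * I)` by restricted maximum likelihood, using a few
#' EM warm-start iterations followed by average-information updates in the
#' eigenbasis of the GRM. Variance components are constrained to at least
#' `1e-6 * var(y)`; convergence is declared when the restricted
#' log-likelihood moves by less than `tol`.
#'
#' @param grm A `grm` (from [compute_grm()]).
#' @param phenotype Numeric phenotype, one per GRM individual (`NA`
#'   allowed; those individuals are excluded).
#' @param covariates Optional numeric matrix of fixed covariates.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-4).
#' @param max_iter Maximum iterations (default 100).
#' @param n_em EM warm-start iterations before AI updates (default 3).
#' @return A `reml_fit` list: `sigma2_g`, `sigma2_e`, `h2`, `se_h2`,
#'   `loglik`, `n_iter`, `converged`, `reliable`, `n`.
#' @export
reml_univariate <- function(grm, phenotype, covariates = NULL,
                            tol = 1e-4, max_iter = 100, n_em = 3) {
  ok <- !is.na(phenotype)
  y <- as.numeric(phenotype[ok])
  n <- length(y)
  if (stats::var(y) == 0) stop("phenotype has zero variance", call. = FALSE)
  A <- grm$values[ok, ok, drop = FALSE]
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates)[ok, , drop = FALSE])

  reliable <- TRUE
  offmax <- max(abs(A[upper.tri(A)]))
  if (offmax < 1e-10) {
    warning("GRM is (numerically) the identity; sigma2_g and sigma2_e are ",
            "not separately identifiable", call. = FALSE)
    reliable <- FALSE
  }

  E <- eigen(A, symmetric = TRUE)
  lam <- pmax(E$values, 0)
  yt <- as.numeric(crossprod(E$vectors, y))
  Xt <- crossprod(E$vectors, X)

  vy <- stats::var(y)
  lb <- 1e-6 * vy
  theta <- c(g = 0.5 * vy, e = 0.5 * vy)
  ev <- .univ_eval(lam, yt, Xt, theta[1], theta[2])
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    if (iter <= n_em) {
      theta_new <- theta + theta^2 / n * (ev$yPVPy - ev$trPV)
      theta_new <- pmax(theta_new, lb)
      ev_new <- .univ_eval(lam, yt, Xt, theta_new[1], theta_new[2])
    } else {
      delta <- tryCatch(solve(ev$AI, ev$score),
                        error = function(e) theta^2 / n * (ev$yPVPy - ev$trPV))
      step <- 1
      repeat {
        theta_new <- pmax(theta + step * delta, lb)
        ev_new <- .univ_eval(lam, yt, Xt, theta_new[1], theta_new[2])
        if (ev_new$ll >= ev$ll - 1e-8 || step < 1e-6) break
        step <- step / 2
      }
    }
    done <- abs(ev_new$ll - ev$ll) < tol && iter > n_em
    theta <- theta_new
    ev <- ev_new
    if (done) {
      converged <- TRUE
      break
    }
  }

  AIinv <- tryCatch(solve(ev$AI), error = function(e) matrix(NA_real_, 2, 2))
  g <- theta[[1]]; e <- theta[[2]]
  h2 <- g / (g + e)
  grad <- c(e, -g) / (g + e)^2
  se_h2 <- sqrt(max(0, drop(t(grad) %*% AIinv %*% grad)))
  structure(list(sigma2_g = g, sigma2_e = e, h2 = h2, se_h2 = se_h2,
                 loglik = ev$ll, n_iter = iter, converged = converged,
                 reliable = reliable, n = n),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit: h2 = %.3f (SE %.3f), sigma2_g = %.4f, sigma2_e = %.4f\n",
              x$h2, x$se_h2, x$sigma2_g, x$sigma2_e))
  cat(sprintf("  logLik %.3f after %d iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# --- bivariate machinery -----------------------------------------------

# parameter layout: g1, g2, [g12], e1, e2, [e12]
.biv_build_V <- function(theta, st) {
  V <- matrix(0, st$N, st$N)
  V[st$b1, st$b1] <- theta[["g1"]] * st$A11
  V[st$b2, st$b2] <- theta[["g2"]] * st$A22
  diag(V)[st$b1] <- diag(V)[st$b1] + theta[["e1"]]
  diag(V)[st$b2] <- diag(V)[st$b2] + theta[["e2"]]
  if ("g12" %in% names(theta)) {
    V[st$b1, st$b2] <- theta[["g12"]] * st$A12
    V[st$b2, st$b1] <- t(V[st$b1, st$b2, drop = FALSE])
  }
  if ("e12" %in% names(theta) && st$n_overlap > 0) {
    V[st$ov12] <- V[st$ov12] + theta[["e12"]]
    V[st$ov21] <- V[st$ov21] + theta[["e12"]]
  }
  V
}

# multiply the derivative matrix dV/dtheta_k into a vector or matrix
.biv_mulVk <- function(k, M, st) {
  M <- as.matrix(M)
  out <- matrix(0, st$N, ncol(M))
  if (k == "g1") out[st$b1, ] <- st$A11 %*% M[st$b1, , drop = FALSE]
  if (k == "g2") out[st$b2, ] <- st$A22 %*% M[st$b2, , drop = FALSE]
  if (k == "g12") {
    out[st$b1, ] <- st$A12 %*% M[st$b2, , drop = FALSE]
    out[st$b2, ] <- crossprod(st$A12, M[st$b1, , drop = FALSE])
  }
  if (k == "e1") out[st$b1, ] <- M[st$b1, , drop = FALSE]
  if (k == "e2") out[st$b2, ] <- M[st$b2, , drop = FALSE]
  if (k == "e12" && st$n_overlap > 0) {
    out[st$p1, ] <- M[st$p2, , drop = FALSE]
    out[st$p2, ] <- M[st$p1, , drop = FALSE]
  }
  out
}

.biv_trVinvVk <- function(k, Vinv, st) {
  switch(k,
         g1 = sum(Vinv[st$b1, st$b1] * st$A11),
         g2 = sum(Vinv[st$b2, st$b2] * st$A22),
         g12 = 2 * sum(Vinv[st$b1, st$b2] * st$A12),
         e1 = sum(diag(Vinv)[st$b1]),
         e2 = sum(diag(Vinv)[st$b2]),
         e12 = 2 * sum(Vinv[cbind(st$p1, st$p2)]))
}

.biv_eval <- function(theta, st) {
  V <- .biv_build_V(theta, st)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-6 * mean(diag(V))
    ch <- tryCatch(chol(V + diag(ridge, st$N)), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
  }
  Vinv <- chol2inv(ch)
  W <- Vinv %*% st$X
  C <- crossprod(st$X, W)
  Cch <- chol(C)
  solveC <- function(B) backsolve(Cch, forwardsolve(t(Cch), B))
  Pof <- function(M) Vinv %*% M - W %*% solveC(crossprod(W, M))
  Py <- as.numeric(Pof(st$y))
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(Cch))) +
                  sum(st$y * Py) + (st$N - ncol(st$X)) * log(2 * pi))
  ks <- names(theta)
  U <- vapply(ks, function(k) as.numeric(.biv_mulVk(k, Py, st)),
              numeric(st$N))
  yPVPy <- colSums(Py * U)
  trPV <- vapply(ks, function(k) {
    VkW <- .biv_mulVk(k, W, st)
    .biv_trVinvVk(k, Vinv, st) - sum(diag(solveC(crossprod(W, VkW))))
  }, numeric(1))
  score <- -0.5 * (trPV - yPVPy)
  PU <- Pof(U)
  AI <- 0.5 * crossprod(U, PU)
  dimnames(AI) <- list(ks, ks)
  list(ll = ll, score = score, AI = AI, yPVPy = yPVPy, trPV = trPV)
}

.biv_clamp <- function(theta, st) {
  theta[["g1"]] <- max(theta[["g1"]], st$lb1)
  theta[["e1"]] <- max(theta[["e1"]], st$lb1)
  theta[["g2"]] <- max(theta[["g2"]], st$lb2)
  theta[["e2"]] <- max(theta[["e2"]], st$lb2)
  if ("g12" %in% names(theta)) {
    cap <- 0.9999 * sqrt(theta[["g1"]] * theta[["g2"]])
    theta[["g12"]] <- max(min(theta[["g12"]], cap), -cap)
  }
  if ("e12" %in% names(theta)) {
    cap <- 0.9999 * sqrt(theta[["e1"]] * theta[["e2"]])
    theta[["e12"]] <- max(min(theta[["e12"]], cap), -cap)
  }
  theta
}

.biv_optimize <- function(theta, st, tol, max_iter, n_em) {
  ev <- .biv_eval(theta, st)
  if (is.null(ev)) stop("initial covariance matrix not positive definite",
                        call. = FALSE)
  em_n <- c(g1 = st$n1, g2 = st$n2, g12 = NA, e1 = st$n1, e2 = st$n2,
            e12 = NA)[names(theta)]
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    if (iter <= n_em) {
      theta_new <- theta
      for (k in names(theta)) {
        if (is.na(em_n[[k]])) next  # covariance terms held during warm start
        theta_new[[k]] <- theta[[k]] + theta[[k]]^2 / em_n[[k]] *
          (ev$yPVPy[[k]] - ev$trPV[[k]])
      }
      theta_new <- .biv_clamp(theta_new, st)
      ev_new <- .biv_eval(theta_new, st)
      if (is.null(ev_new)) { theta_new <- theta; ev_new <- ev }
    } else {
      delta <- tryCatch(solve(ev$AI, ev$score), error = function(e) ev$score)
      step <- 1
      repeat {
        theta_new <- .biv_clamp(theta + step * delta, st)
        ev_new <- .biv_eval(theta_new, st)
        if (!is.null(ev_new) && (ev_new$ll >= ev$ll - 1e-8 || step < 1e-6)) break
        if (step < 1e-6) { theta_new <- theta; ev_new <- ev; break }
        step <- step / 2
      }
    }
    done <- abs(ev_new$ll - ev$ll) < tol && iter > n_em
    theta <- theta_new
    ev <- ev_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, ev = ev, converged = converged, n_iter = iter)
}

#' Bivariate GREML: genetic covariance and correlation by AI-REML
#'
#' Fits the two-trait linear mixed model over the union of individuals
#' with either trait observed, with genetic (co)variance structured by the
#' GRM. The genetic covariance `sigma_g12` links the traits even when they
#' are measured on disjoint individuals (the two-cohort design); the
#' residual covariance is estimable only on individuals carrying both
#' traits and is fixed at zero when fewer than `min_overlap` such
#' individuals exist. Reports the genetic correlation
#' `rG = sigma_g12 / sqrt(sigma2_g1 * sigma2_g2)` (clamped to \[-1, 1\]
#' with a boundary flag), its delta-method standard error from the inverse
#' average-information matrix, and the likelihood-ratio test of
#' `sigma_g12 = 0`.
#'
#' @param grm A `grm` over the union of individuals.
#' @param trait1,trait2 Numeric phenotypes, one entry per GRM individual,
#'   `NA` where unobserved.
#' @param covariates1,covariates2 Optional per-trait fixed covariates
#'   (rows = GRM individuals).
#' @param residual_cov `"auto"` (estimate when overlap allows), `"zero"`,
#'   or `"estimate"`.
#' @param min_overlap Minimum number of doubly phenotyped individuals for
#'   the residual covariance to be estimated under `"auto"` (default 10).
#' @param fit_null Also fit the `sigma_g12 = 0` model for the LRT
#'   (default `TRUE`).
#' @param tol,max_iter,n_em As in [reml_univariate()].
#' @return A `bivar_reml_fit` list with the variance/covariance
#'   components, per-trait `h2`, `rG`, `se_rG`, log-likelihoods of the
#'   full and constrained models, and `p_lrt`.
#' @export
reml_bivariate <- function(grm, trait1, trait2,
                           covariates1 = NULL, covariates2 = NULL,
                           residual_cov = c("auto", "zero", "estimate"),
                           min_overlap = 10, fit_null = TRUE,
                           tol = 1e-4, max_iter = 100, n_em = 3) {
  residual_cov <- match.arg(residual_cov)
  obs1 <- which(!is.na(trait1))
  obs2 <- which(!is.na(trait2))
  n1 <- length(obs1)
  n2 <- length(obs2)
  if (n1 < 10 || n2 < 10) stop("too few observations per trait", call. = FALSE)
  if (n1 < 100 || n2 < 100) {
    warning("fewer than 100 observations for a trait; estimates will be noisy",
            call. = FALSE)
  }
  y1 <- trait1[obs1]
  y2 <- trait2[obs2]
  if (stats::var(y1) == 0 || stats::var(y2) == 0) {
    stop("constant trait", call. = FALSE)
  }
  overlap <- intersect(obs1, obs2)
  est_e12 <- switch(residual_cov,
                    zero = FALSE,
                    estimate = TRUE,
                    auto = length(overlap) >= min_overlap)

  A <- grm$values
  st <- list(
    N = n1 + n2, n1 = n1, n2 = n2,
    b1 = seq_len(n1), b2 = n1 + seq_len(n2),
    A11 = A[obs1, obs1, drop = FALSE],
    A22 = A[obs2, obs2, drop = FALSE],
    A12 = A[obs1, obs2, drop = FALSE],
    n_overlap = length(overlap),
    p1 = match(overlap, obs1),
    p2 = n1 + match(overlap, obs2),
    y = c(y1, y2),
    lb1 = 1e-6 * stats::var(y1),
    lb2 = 1e-6 * stats::var(y2)
  )
  X <- matrix(0, st$N, 2)
  X[st$b1, 1] <- 1
  X[st$b2, 2] <- 1
  if (!is.null(covariates1)) {
    C1 <- matrix(0, st$N, ncol(as.matrix(covariates1)))
    C1[st$b1, ] <- as.matrix(covariates1)[obs1, , drop = FALSE]
    X <- cbind(X, C1)
  }
  if (!is.null(covariates2)) {
    C2 <- matrix(0, st$N, ncol(as.matrix(covariates2)))
    C2[st$b2, ] <- as.matrix(covariates2)[obs2, , drop = FALSE]
    X <- cbind(X, C2)
  }
  st$X <- X

  v1 <- stats::var(y1)
  v2 <- stats::var(y2)
  theta <- c(g1 = 0.5 * v1, g2 = 0.5 * v2, g12 = 0,
             e1 = 0.5 * v1, e2 = 0.5 * v2)
  if (est_e12) theta <- c(theta, e12 = 0)

  full <- .biv_optimize(theta, st, tol, max_iter, n_em)

  loglik_rg0 <- NA_real_
  null_fit <- NULL
  if (fit_null) {
    theta0 <- full$theta[setdiff(names(full$theta), "g12")]
    null_fit <- .biv_optimize(theta0, st, tol, max_iter, n_em = 0)
    loglik_rg0 <- null_fit$ev$ll
    if (loglik_rg0 > full$ev$ll - 1e-8) {
      # the constrained fit found a better stationary region for the
      # variance components; resume the full fit from there (same
      # likelihood at g12 = 0, so it can only improve)
      resume <- c(null_fit$theta, g12 = 0)
      resume <- resume[intersect(c("g1", "g2", "g12", "e1", "e2", "e12"),
                                 names(resume))]
      full2 <- .biv_optimize(resume, st, tol, max_iter, n_em = 0)
      if (full2$ev$ll > full$ev$ll) full <- full2
    }
  }
  th <- full$theta

  g1 <- th[["g1"]]; g2 <- th[["g2"]]; g12 <- th[["g12"]]
  e1 <- th[["e1"]]; e2 <- th[["e2"]]
  rg_raw <- g12 / sqrt(g1 * g2)
  rg_clamped <- abs(rg_raw) > 1
  rG <- max(min(rg_raw, 1), -1)

  AIinv <- tryCatch(solve(full$ev$AI),
                    error = function(e) matrix(NA_real_, length(th), length(th),
                                               dimnames = list(names(th), names(th))))
  gidx <- c("g1", "g2", "g12")
  grad <- c(-rg_raw / (2 * g1), -rg_raw / (2 * g2), 1 / sqrt(g1 * g2))
  se_rG <- sqrt(max(0, drop(t(grad) %*% AIinv[gidx, gidx] %*% grad)))
  h2_se <- function(g, e, keys) {
    grad <- c(e, -g) / (g + e)^2
    sqrt(max(0, drop(t(grad) %*% AIinv[keys, keys] %*% grad)))
  }

  fit <- structure(list(
    sigma2_g1 = g1, sigma2_g2 = g2, sigma_g12 = g12,
    sigma2_e1 = e1, sigma2_e2 = e2,
    sigma_e12 = if (est_e12) th[["e12"]] else NA_real_,
    h2_1 = g1 / (g1 + e1), h2_2 = g2 / (g2 + e2),
    se_h2_1 = h2_se(g1, e1, c("g1", "e1")),
    se_h2_2 = h2_se(g2, e2, c("g2", "e2")),
    rG = rG, se_rG = se_rG, rG_clamped = rg_clamped,
    loglik_full = full$ev$ll, loglik_rg0 = loglik_rg0, p_lrt = NA_real_,
    converged = full$converged &&
      (is.null(null_fit) || null_fit$converged),
    n_iter = full$n_iter, n1 = n1, n2 = n2,
    n_overlap = length(overlap), residual_cov_estimated = est_e12
  ), class = "bivar_reml_fit")
  if (fit_null) fit$p_lrt <- lrt_rg_zero(fit)
  fit
}

#' @export
print.bivar_reml_fit <- function(x, ...) {
  cat(sprintf("bivar_reml_fit: rG = %.3f (SE %.3f)%s\n", x$rG, x$se_rG,
              if (x$rG_clamped) " [boundary]" else ""))
  cat(sprintf("  h2 trait1 = %.3f (SE %.3f), h2 trait2 = %.3f (SE %.3f)\n",
              x$h2_1, x$se_h2_1, x$h2_2, x$se_h2_2))
  if (!is.na(x$p_lrt)) {
    cat(sprintf("  LRT sigma_g12 = 0: P = %.3g\n", x$p_lrt))
  }
  invisible(x)
}

#' Likelihood-ratio test of zero genetic correlation
#'
#' Compares the full bivariate fit against the `sigma_g12 = 0` fit:
#' `P = upper tail of chi-square(1) at 2 * (loglik_full - loglik_rg0)`,
#' with the statistic floored at zero.
#'
#' @param fit A `bivar_reml_fit` with both log-likelihoods available.
#' @return The LRT P value.
#' @export
lrt_rg_zero <- function(fit) {
  if (is.na(fit$loglik_full) || is.na(fit$loglik_rg0)) {
    stop("both log-likelihoods required", call. = FALSE)
  }
  stat <- 2 * (fit$loglik_full - fit$loglik_rg0)
  if (stat < -1e-6) {
    stop("constrained likelihood exceeds full likelihood: optimization failure",
         call. = FALSE)
  }
  stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
}

#' Convert an observed-scale case-control h2 to the liability scale
#'
#' Transformation for an ascertained case-control study of a disease with
#' population prevalence `K` analysed on the observed 0/1 scale:
#' \deqn{h^2_{liab} = h^2_{obs} \frac{K^2(1-K)^2}{P(1-P)\,\phi(t)^2}}
#' where `P` is the sample case fraction and `phi(t)` the standard normal
#' density at the liability threshold `t = qnorm(1 - K)`. Off by default in
#' the pipeline, which reports the observed scale.
#'
#' @param h2_obs Observed-scale estimate (an SE may be converted with the
#'   same multiplier).
#' @param prevalence Population prevalence `K` in (0, 1).
#' @param case_fraction Sample case proportion `P`; defaults to `K`
#'   (unascertained).
#' @return The liability-scale estimate.
#' @export
h2_liability <- function(h2_obs, prevalence, case_fraction = prevalence) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence in (0,1)", call. = FALSE)
  K <- prevalence
  P <- case_fraction
  t <- stats::qnorm(1 - K)
  h2_obs * K^2 * (1 - K)^2 / (P * (1 - P) * stats::dnorm(t)^2)
}
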