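small_univ_problem <- function(n = 120, m = 200, h2 = 0.4, seed = 33) {
  set.seed(seed)
  cfg <- sim_config(n_snps = m, block_size = 1, within_block_r = 0,
                    seed = seed)
  panel <- simulate_genotypes(cfg, n, simulate_map(cfg))
  g <- compute_grm(panel, maf_min = 0.01)
  gv <- as.numeric(scale(panel$dosages) %*% rnorm(m))
  gv <- gv * sqrt(h2 / var(gv))
  y <- gv + rnorm(n, sd = sqrt(1 - h2))
  list(grm = g, y = y)
}

test_that("univariate REML maximizes the restricted likelihood (grid oracle)", {
  for (seed in c(33, 34)) {
    pr <- small_univ_problem(seed = seed)
    fit <- reml_univariate(pr$grm, pr$y)
    expect_true(fit$converged)
    # the package likelihood equals an independent dense evaluation
    expect_equal(fit$loglik,
                 oracle_reml_ll(pr$grm$values, pr$y, fit$sigma2_g,
                                fit$sigma2_e),
                 tolerance = 1e-6)
    vy <- var(pr$y)
    grid <- expand.grid(sg = seq(0.02, 1.8, length.out = 25) * vy,
                        se = seq(0.02, 1.8, length.out = 25) * vy)
    lls <- mapply(function(a, b) oracle_reml_ll(pr$grm$values, pr$y, a, b),
                  grid$sg, grid$se)
    expect_gte(fit$loglik, max(lls) - 1e-6)
    step <- diff(seq(0.02, 1.8, length.out = 25))[1] * vy
    best <- grid[which.max(lls), ]
    expect_lt(abs(fit$sigma2_g - best$sg), 1.5 * step)
    expect_lt(abs(fit$sigma2_e - best$se), 1.5 * step)
  }
})

test_that("h2 is invariant to affine phenotype transforms, components scale", {
  pr <- small_univ_problem(seed = 35)
  fit <- reml_univariate(pr$grm, pr$y)
  fit2 <- reml_univariate(pr$grm, 2 * pr$y + 7)
  expect_equal(fit2$h2, fit$h2, tolerance = 1e-4)
  expect_equal(fit2$sigma2_g, 4 * fit$sigma2_g, tolerance = 1e-3)
  expect_equal(fit2$sigma2_e, 4 * fit$sigma2_e, tolerance = 1e-3)
})

test_that("identity GRM triggers a non-identifiability warning", {
  g <- list(values = diag(100), individual_ids = sprintf("i%03d", 1:100),
            n_snps_used = 1)
  class(g) <- "grm"
  expect_warning(fit <- reml_univariate(g, rnorm(100)),
                 "not separately identifiable")
  expect_false(fit$reliable)
})

test_that("a trait paired with itself gives genetic correlation 1", {
  set.seed(36)
  pr <- small_univ_problem(n = 150, m = 250, h2 = 0.6, seed = 36)
  n <- length(pr$y)
  # duplicate every individual so the two traits live on "different"
  # rows of the union GRM but share genetics exactly
  A <- pr$grm$values
  big <- rbind(cbind(A, A), cbind(A, A))
  g2 <- list(values = big,
             individual_ids = c(paste0("a", 1:n), paste0("b", 1:n)),
             n_snps_used = pr$grm$n_snps_used)
  class(g2) <- "grm"
  t1 <- c(pr$y, rep(NA, n))
  t2 <- c(rep(NA, n), pr$y)
  fit <- suppressWarnings(reml_bivariate(g2, t1, t2, residual_cov = "zero"))
  expect_gt(fit$rG, 0.98)
})

test_that("bivariate fit with zero covariance reproduces the univariate fits", {
  sim <- simulate_disjoint_greml(n = 150, m = 250, h2_1 = 0.5, h2_2 = 0.3,
                                 rg = 0, seed = 37)
  n <- 150
  ids <- sim$grm$individual_ids
  g1 <- list(values = sim$grm$values[1:n, 1:n], individual_ids = ids[1:n],
             n_snps_used = sim$grm$n_snps_used)
  g2 <- list(values = sim$grm$values[n + 1:n, n + 1:n],
             individual_ids = ids[n + 1:n],
             n_snps_used = sim$grm$n_snps_used)
  class(g1) <- class(g2) <- "grm"
  u1 <- reml_univariate(g1, sim$trait1[1:n])
  u2 <- reml_univariate(g2, sim$trait2[n + 1:n])
  bf <- suppressWarnings(
    reml_bivariate(sim$grm, sim$trait1, sim$trait2, fit_null = TRUE))
  # the constrained (sigma_g12 = 0) likelihood factorizes over cohorts
  expect_equal(bf$loglik_rg0, u1$loglik + u2$loglik, tolerance = 1e-3)
})

test_that("LRT P values follow the chi-square(1) closed forms", {
  base <- list(loglik_full = -100, loglik_rg0 = -100)
  expect_equal(lrt_rg_zero(base), 1.0)
  expect_equal(lrt_rg_zero(list(loglik_full = -100,
                                loglik_rg0 = -100 - 3.841459 / 2)),
               0.05, tolerance = 1e-4)
  expect_equal(lrt_rg_zero(list(loglik_full = -100,
                                loglik_rg0 = -100 - 6.634897 / 2)),
               0.01, tolerance = 1e-4)
  expect_error(lrt_rg_zero(list(loglik_full = -101, loglik_rg0 = -100)),
               "optimization failure")
})

test_that("small-sample fits can pair large Wald SEs with small LRT P", {
  # the Wald z and the LRT need not agree at small n; look for at least
  # one replicate with |rG|/se < 2 but LRT P < 0.05
  found <- 0
  for (seed in 1:10) {
    sim <- simulate_disjoint_greml(n = 120, m = 200, h2_1 = 0.4, h2_2 = 0.4,
                                   rg = -0.9, seed = 700 + seed)
    fit <- suppressWarnings(reml_bivariate(sim$grm, sim$trait1, sim$trait2))
    if (fit$p_lrt < 0.05 && abs(fit$rG / fit$se_rG) < 2) found <- found + 1
  }
  expect_gte(found, 1)
})

test_that("liability-scale conversion has the textbook limiting behaviour", {
  # unascertained at prevalence 0.5: K(1-K)/phi(0)^2 = 0.25 / (1/(2*pi))
  expect_equal(h2_liability(0.3, 0.5), 0.3 * 0.25 / dnorm(0)^2)
  # ascertainment (P > K) shrinks the multiplier
  expect_lt(h2_liability(0.3, 0.1, case_fraction = 0.5),
            h2_liability(0.3, 0.1))
  expect_error(h2_liability(0.3, 0), "prevalence")
})
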