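test_that("genotype simulation is deterministic and respects HWE margins", {
  cfg <- sim_config(n_snps = 50, seed = 77)
  set.seed(1); p1 <- simulate_genotypes(cfg, 100, simulate_map(cfg))
  set.seed(1); p2 <- simulate_genotypes(cfg, 100, simulate_map(cfg))
  expect_identical(p1$dosages, p2$dosages)

  # genotype frequencies at MAF 0.3 within exact binomial 99% bands of
  # HWE (0.49, 0.42, 0.09)
  cfg2 <- sim_config(n_snps = 1, block_size = 1, maf_range = c(0.3, 0.3),
                     within_block_r = 0, seed = 78)
  set.seed(78)
  p <- simulate_genotypes(cfg2, 5000, simulate_map(cfg2))
  counts <- table(factor(p$dosages[, 1], levels = 0:2))
  hwe <- c(0.49, 0.42, 0.09)
  for (i in 1:3) {
    band <- qbinom(c(0.005, 0.995), 5000, hwe[i])
    expect_gte(counts[[i]], band[1])
    expect_lte(counts[[i]], band[2])
  }
})

test_that("block structure controls LD: none at r = 0, strong within blocks", {
  cfg <- sim_config(n_snps = 100, block_size = 5, within_block_r = 0,
                    seed = 79)
  set.seed(79)
  p <- simulate_genotypes(cfg, 2000, simulate_map(cfg))
  C <- cor(p$dosages)
  off <- abs(C[upper.tri(C)])
  expect_lt(mean(off), 0.05)

  cfg2 <- sim_config(n_snps = 100, block_size = 5, within_block_r = 0.7,
                     seed = 80)
  set.seed(80)
  map2 <- simulate_map(cfg2)
  p2 <- simulate_genotypes(cfg2, 2000, map2)
  C2 <- cor(p2$dosages)
  within <- outer(map2$block, map2$block, "==") & upper.tri(C2)
  between <- !outer(map2$block, map2$block, "==") & upper.tri(C2)
  expect_gt(mean(C2[within]), 0.4)
  expect_lt(mean(abs(C2[between])), 0.05)
})

test_that("effect pairs achieve the requested correlation and exact h2", {
  cfg <- sim_config(n_snps = 1200, n_causal = 1000, h2_disc = 0.13,
                    h2_targ = 0.45, rG_true = 1, seed = 81)
  set.seed(81)
  map <- simulate_map(cfg)
  pd <- simulate_genotypes(cfg, 300, map, "d")
  pt <- simulate_genotypes(cfg, 300, map, "t")
  tr <- simulate_effect_pairs(cfg, pd, pt)
  expect_gte(tr$realized_rG, 0.99)
  expect_equal(tr$realized_h2_disc, 0.13, tolerance = 1e-3)
  expect_equal(tr$realized_h2_targ, 0.45, tolerance = 1e-3)

  hits <- 0
  for (s in 1:10) {
    cfg0 <- sim_config(n_snps = 1200, n_causal = 1000, rG_true = 0,
                       seed = 82 + s)
    set.seed(82 + s)
    tr0 <- simulate_effect_pairs(cfg0, pd, pt)
    hits <- hits + (abs(tr0$realized_rG) < 0.1)
  }
  expect_gte(hits, 9)
})

test_that("liability thresholding yields the requested prevalence", {
  expect_equal(qnorm(1 - 0.5), 0)  # prevalence 1/2 puts the threshold at 0
  cfg <- sim_config(n_snps = 60, n_cases = 100, n_controls = 100,
                    prevalence = 0.02, n_pool = 20000, h2_targ = 0.3,
                    seed = 83)
  set.seed(83)
  map <- simulate_map(cfg)
  pd <- simulate_genotypes(cfg, 50, map, "d")
  pt <- simulate_genotypes(cfg, 20000, map, "t")
  tr <- simulate_effect_pairs(cfg, pd, pt)
  coh <- simulate_cohorts(tr, cfg)
  n_case <- sum(coh$liability > coh$threshold)
  band <- qbinom(c(0.005, 0.995), 20000, 0.02)
  expect_gte(n_case, band[1])
  expect_lte(n_case, band[2])

  # with h2 = 0 the genetic value is uninformative about status
  cfg0 <- sim_config(n_snps = 60, n_cases = 300, n_controls = 300,
                     h2_targ = 0, prevalence = 0.3, seed = 84)
  cors <- numeric(20)
  set.seed(84)
  pt2 <- simulate_genotypes(cfg0, cfg0$n_pool, map, "t")
  for (r in 1:20) {
    tr0 <- simulate_effect_pairs(cfg0, pd, pt2)
    coh0 <- simulate_cohorts(tr0, cfg0)
    gv <- as.numeric(scale(pt2$dosages[coh0$targ_idx, tr0$causal_idx,
                                       drop = FALSE]) %*% tr0$u_targ)
    cors[r] <- suppressWarnings(cor(gv, coh0$status))
    if (is.na(cors[r])) cors[r] <- 0
  }
  expect_lt(max(abs(cors)), 3.5 / sqrt(600))

  # asking for more cases than the pool can deliver errors clearly
  cfg_bad <- sim_config(n_snps = 60, n_cases = 5000, n_controls = 10,
                        prevalence = 0.02, n_pool = 6000, seed = 85)
  set.seed(85)
  pt3 <- simulate_genotypes(cfg_bad, 6000, map, "t")
  tr3 <- simulate_effect_pairs(cfg_bad, pd, pt3)
  expect_error(simulate_cohorts(tr3, cfg_bad), "n_pool")
})

test_that("single-SNP GWAS is calibrated and recovers planted effects", {
  cfg <- sim_config(n_snps = 400, block_size = 1, within_block_r = 0,
                    seed = 86)
  set.seed(86)
  panel <- simulate_genotypes(cfg, 1000, simulate_map(cfg))

  # perfect predictor: beta = 1, p essentially 0
  y <- panel$dosages[, 7]
  ss <- run_gwas(panel, y, "quantitative")
  expect_equal(ss$beta[ss$snp_id == "rs000007"], 1, tolerance = 1e-10)
  expect_lt(ss$p[ss$snp_id == "rs000007"], 1e-100)

  # permuted phenotype: uniform P, about 5% below 0.05
  set.seed(87)
  yperm <- sample(rnorm(1000))
  ss0 <- run_gwas(panel, yperm, "quantitative")
  frac <- mean(ss0$p < 0.05)
  band <- qbinom(c(0.025, 0.975), nrow(ss0), 0.05) / nrow(ss0)
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])

  # known single causal SNP, quantitative: estimate within 3 SE
  set.seed(88)
  y1 <- 0.5 * panel$dosages[, 11] + rnorm(1000)
  ss1 <- run_gwas(panel, y1, "quantitative")
  row <- ss1[ss1$snp_id == "rs000011", ]
  expect_lt(abs(row$beta - 0.5), 3 * row$se)

  # binary GWAS agrees with stats::glm per SNP
  set.seed(89)
  status <- rbinom(1000, 1, plogis(-0.5 + 0.4 * panel$dosages[, 3]))
  ssb <- run_gwas(panel, status, "binary")
  for (j in c(3, 10, 50)) {
    ref <- glm(status ~ panel$dosages[, j], family = binomial())
    row <- ssb[ssb$snp_id == panel$map$snp_id[j], ]
    expect_equal(row$beta, unname(coef(ref)[2]), tolerance = 1e-5)
    expect_equal(row$se, unname(summary(ref)$coefficients[2, 2]),
                 tolerance = 1e-4)
  }
})

test_that("orientation scrambling is undone exactly by harmonization", {
  cfg <- sim_config(n_disc = 300, n_cases = 100, n_controls = 150,
                    n_snps = 80, orient_scramble = 0.5, seed = 90)
  st <- simulate_study(cfg)
  pair <- harmonize(st$sumstats_disc, st$sumstats_targ)
  scrambled <- attr(st$sumstats_targ, "scrambled")
  expect_gt(length(scrambled), 0)
  expect_setequal(pair$snp_id[pair$flipped],
                  intersect(scrambled, pair$snp_id))

  # identical seeds give identical studies end to end
  st2 <- simulate_study(cfg)
  expect_identical(st$sumstats_disc$beta, st2$sumstats_disc$beta)
  expect_identical(st$panel_targ$dosages, st2$panel_targ$dosages)
})
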