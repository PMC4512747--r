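test_that("LD r2 matches hand-computed Pearson correlation", {
  panel <- make_panel(cbind(c(0, 1, 2, 0, 1, 2), c(0, 0, 1, 1, 2, 2)))
  # hand arithmetic: cov = 0.4, var = 0.8 each, r = 0.5
  expect_equal(ld_r2(panel, "rs0001", "rs0002"), 0.25)
  # identical and reflected columns are in complete LD
  panel2 <- make_panel(cbind(c(0, 1, 2, 1), c(0, 1, 2, 1), 2 - c(0, 1, 2, 1)))
  expect_equal(ld_r2(panel2, "rs0001", "rs0002"), 1.0)
  expect_equal(ld_r2(panel2, "rs0001", "rs0003"), 1.0)
  # monomorphic SNP has undefined LD
  panel3 <- make_panel(cbind(c(1, 1, 1, 1), c(0, 1, 2, 1)))
  expect_error(ld_r2(panel3, "rs0001", "rs0002"), "monomorphic")
})

test_that("clumping keeps the most significant SNP of a full-LD group", {
  x <- c(0, 1, 2, 0, 1, 2, 0, 2)
  panel <- make_panel(cbind(x, x, x), pos = c(1000, 5000, 9000))
  ss <- sumstat_table(data.frame(
    snp_id = panel$map$snp_id, chrom = "1", pos = panel$map$pos,
    ea = "A", oa = "G", eaf = 0.5,
    beta = 0.1, se = 0.1, p = c(1e-5, 1e-3, 0.1), n = 100))
  res <- clump(ss, panel, compute_effective = FALSE)
  expect_equal(res$index_snps, "rs0001")
  expect_setequal(res$members[["rs0001"]], c("rs0002", "rs0003"))

  # distance rule: strong LD beyond the window leaves both as indices
  panel2 <- make_panel(cbind(x, x), pos = c(1000, 501000))
  ss2 <- sumstat_table(data.frame(
    snp_id = panel2$map$snp_id, chrom = "1", pos = panel2$map$pos,
    ea = "A", oa = "G", eaf = 0.5, beta = 0.1, se = 0.1,
    p = c(1e-4, 1e-2), n = 100))
  res2 <- clump(ss2, panel2, compute_effective = FALSE)
  expect_setequal(res2$index_snps, panel2$map$snp_id)
})

random_clump_instance <- function(seed, m = 60, n = 50) {
  set.seed(seed)
  cfg <- sim_config(n_snps = m, block_size = 4, within_block_r = 0.8,
                    seed = seed)
  map <- simulate_map(cfg)
  panel <- simulate_genotypes(cfg, n, map)
  ss <- sumstat_table(data.frame(
    snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
    ea = map$ea, oa = map$oa, eaf = 0.5,
    beta = rnorm(m), se = 0.1, p = runif(m), n = n))
  list(panel = panel, ss = ss, map = map)
}

test_that("clumping matches the brute-force greedy oracle", {
  for (seed in 1:25) {
    inst <- random_clump_instance(seed)
    res <- clump(inst$ss, inst$panel, compute_effective = FALSE)
    cols <- match(inst$ss$snp_id, inst$panel$map$snp_id)
    r2mat <- suppressWarnings(cor(inst$panel$dosages[, cols]))^2
    expected <- oracle_clump(inst$ss$snp_id, inst$ss$chrom, inst$ss$pos,
                             inst$ss$p, r2mat, 0.25, 300)
    expect_equal(res$index_snps, expected)
  }
})

test_that("clump output is invariant to input row order and to absorbed SNPs", {
  inst <- random_clump_instance(101)
  res <- clump(inst$ss, inst$panel, compute_effective = FALSE)
  set.seed(1)
  shuffled <- as.data.frame(inst$ss)[sample.int(nrow(inst$ss)), ]
  res_sh <- clump(sumstat_table(shuffled), inst$panel,
                  compute_effective = FALSE)
  expect_equal(res_sh$index_snps, res$index_snps)

  absorbed <- setdiff(inst$ss$snp_id, res$index_snps)[1]
  ss_minus <- sumstat_table(as.data.frame(inst$ss)[inst$ss$snp_id != absorbed, ])
  res_minus <- clump(ss_minus, inst$panel, compute_effective = FALSE)
  expect_equal(res_minus$index_snps, res$index_snps)

  # disabling the LD rule makes every SNP an index
  res_all <- clump(inst$ss, inst$panel, r2_threshold = 1 + 1e-9,
                   compute_effective = FALSE)
  expect_setequal(res_all$index_snps, inst$ss$snp_id)
})

test_that("index SNPs pairwise satisfy the r2-or-distance condition", {
  inst <- random_clump_instance(202, m = 80)
  res <- clump(inst$ss, inst$panel, compute_effective = FALSE)
  idx <- match(res$index_snps, inst$panel$map$snp_id)
  r2 <- suppressWarnings(cor(inst$panel$dosages[, idx]))^2
  map <- inst$panel$map[idx, ]
  for (i in seq_along(idx)) {
    for (j in seq_len(i - 1)) {
      same_chr <- map$chrom[i] == map$chrom[j]
      near <- same_chr && abs(map$pos[i] - map$pos[j]) <= 300000
      expect_true(!near || r2[i, j] <= 0.25)
    }
  }
  # every SNP is an index or absorbed by exactly one index
  all_members <- unlist(res$members, use.names = FALSE)
  expect_equal(sort(c(res$index_snps, all_members)), sort(inst$ss$snp_id))
  expect_equal(anyDuplicated(all_members), 0)
})

test_that("effective number follows the eigenvalue closed forms", {
  # 5 mutually orthogonal dosage columns (Hadamard design on 8 individuals
  # mapped to 0/2): identity correlation, Meff = 5
  H2 <- matrix(c(1, 1, 1, -1), 2, 2)
  H8 <- H2 %x% H2 %x% H2
  Xo <- (H8[, 2:6] + 1)  # entries in {0, 2}, columns orthogonal after centering
  panel5 <- make_panel(Xo)
  expect_equal(effective_number(panel5, panel5$map$snp_id), 5)

  # all pairwise correlation 1: eigenvalues (M, 0, ..., 0), Meff = 1
  d1 <- Xo[, 1]
  panel_dup <- make_panel(cbind(d1, d1, d1, d1))
  expect_equal(effective_number(panel_dup, panel_dup$map$snp_id), 1)

  # two SNPs with correlation r: Meff = 2 - r^2 (eigenvalues 1 +/- r)
  panel_r <- make_panel(cbind(c(0, 1, 2, 0, 1, 2), c(0, 0, 1, 1, 2, 2)))
  expect_equal(effective_number(panel_r, panel_r$map$snp_id), 2 - 0.25)
})

test_that("Meff lies in [1, M] on random panels and errors on monomorphic SNPs", {
  for (seed in 1:20) {
    set.seed(seed)
    cfg <- sim_config(n_snps = 12, block_size = 3,
                      within_block_r = runif(1, 0, 0.9), seed = seed)
    panel <- simulate_genotypes(cfg, 60, simulate_map(cfg))
    meff <- effective_number(panel, panel$map$snp_id)
    expect_gte(meff, 1)
    expect_lte(meff, 12 + 1e-9)
  }
  mono <- make_panel(cbind(c(1, 1, 1, 1), c(0, 1, 2, 1)))
  expect_error(effective_number(mono, mono$map$snp_id), "rs0001")
})
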