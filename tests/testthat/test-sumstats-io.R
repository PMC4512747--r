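test_that("reading converts odds ratios, drops invalid rows and sorts", {
  df <- make_sumstat_df(5, seed = 11)
  df$or <- exp(df$beta)
  df$beta <- NULL
  df$or[1] <- 1.0
  df$se[1] <- 0.1
  path <- write_sumstat_file(df)
  tab <- read_sumstats(path, column_map = c(or = "or"), trait_kind = "binary")
  expect_s3_class(tab, "sumstat_table")
  expect_equal(tab$beta[tab$snp_id == df$snp[1]], 0)

  # a zero-SE row is dropped and counted
  df2 <- make_sumstat_df(5, seed = 12)
  df2$se[3] <- 0
  tab2 <- read_sumstats(write_sumstat_file(df2))
  expect_equal(nrow(tab2), 4)
  expect_equal(unname(attr(tab2, "drop_report")[["bad_se"]]), 1L)

  # rows come back sorted by (chrom, pos)
  df3 <- make_sumstat_df(7, seed = 13)
  tab3 <- read_sumstats(write_sumstat_file(df3))
  hand <- df3[order(df3$chr, df3$pos), ]
  expect_equal(tab3$snp_id, hand$snp)
  expect_false(is.unsorted(order(tab3$chrom, tab3$pos)))
})

test_that("missing mandatory columns and empty tables raise errors", {
  df <- make_sumstat_df(3)
  df$se <- NULL
  expect_error(read_sumstats(write_sumstat_file(df)), "mandatory column 'se'")
  df2 <- make_sumstat_df(2)
  df2$p <- c(0, 2)  # both invalid
  expect_error(read_sumstats(write_sumstat_file(df2)), "no valid")
})

test_that("MAF filtering is on the minor frequency with inclusive boundary", {
  df <- make_sumstat_df(3)
  df$eaf <- c(0.95, 0.96, 0.5)
  tab <- read_sumstats(write_sumstat_file(df))
  kept <- maf_filter(tab, 0.05)
  expect_setequal(kept$snp_id, df$snp[c(1, 3)])

  set.seed(20)
  df2 <- make_sumstat_df(100, seed = 20)
  df2$eaf <- runif(100)
  tab2 <- read_sumstats(write_sumstat_file(df2))
  kept2 <- maf_filter(tab2, 0.05)
  brute <- sum(pmin(tab2$eaf, 1 - tab2$eaf) >= 0.05)
  expect_equal(nrow(kept2), brute)

  tab2$eaf[4] <- NA
  expect_error(maf_filter(tab2), tab2$snp_id[4])
})

make_two_tables <- function(t_ea, t_oa, d_ea = "A", d_oa = "G",
                            beta_t = 0.3) {
  d <- make_sumstat_df(1)
  d$ea <- d_ea; d$oa <- d_oa; d$beta <- 0.2
  t <- d
  t$ea <- t_ea; t$oa <- t_oa; t$beta <- beta_t
  list(d = sumstat_table(setNames(d, c("snp_id", "chrom", "pos", "ea", "oa",
                                       "eaf", "beta", "se", "p", "n"))),
       t = sumstat_table(setNames(t, c("snp_id", "chrom", "pos", "ea", "oa",
                                       "eaf", "beta", "se", "p", "n"))))
}

test_that("harmonization resolves all allele orientations", {
  # hand table over the orientation cases for a discovery A/G SNP:
  # target alleles -> (retained, flipped)
  cases <- list(
    list(ea = "A", oa = "G", flip = FALSE),  # identical
    list(ea = "G", oa = "A", flip = TRUE),   # swapped
    list(ea = "T", oa = "C", flip = FALSE),  # strand complement
    list(ea = "C", oa = "T", flip = TRUE)    # complement + swap
  )
  for (cs in cases) {
    tabs <- make_two_tables(cs$ea, cs$oa)
    pair <- harmonize(tabs$d, tabs$t)
    expect_equal(nrow(pair), 1)
    expect_equal(pair$flipped, cs$flip)
    expect_equal(pair$beta_targ, if (cs$flip) -0.3 else 0.3)
  }
  # incompatible alleles dropped with a reason
  tabs <- make_two_tables("C", "G")
  pair <- harmonize(tabs$d, tabs$t)
  expect_equal(nrow(pair), 0)
  expect_equal(attr(pair, "dropped")$reason, "allele_mismatch")
  # strand-ambiguous discovery SNP dropped by default, kept on request
  tabs <- make_two_tables("A", "T", d_ea = "A", d_oa = "T")
  pair <- harmonize(tabs$d, tabs$t)
  expect_equal(attr(pair, "dropped")$reason, "strand_ambiguous")
  pair2 <- harmonize(tabs$d, tabs$t, drop_ambiguous = FALSE)
  expect_equal(nrow(pair2), 1)
})

test_that("harmonization errors on duplicate snp ids before joining", {
  d <- make_sumstat_df(3)
  names(d) <- c("snp_id", "chrom", "pos", "ea", "oa", "eaf", "beta",
                "se", "p", "n")
  dup <- rbind(d, d[1, ])
  tab <- structure(dup, class = c("sumstat_table", "data.frame"))
  good <- sumstat_table(d)
  expect_error(harmonize(tab, good), "duplicate")
  expect_error(harmonize(good, tab), "duplicate")
})

test_that("harmonization properties: idempotence, sign coherence, join symmetry", {
  set.seed(31)
  m <- 60
  df <- make_sumstat_df(m, seed = 31)
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  al <- pairs[sample.int(4, m, replace = TRUE), ]
  df$ea <- al[, 1]; df$oa <- al[, 2]
  names(df) <- c("snp_id", "chrom", "pos", "ea", "oa", "eaf", "beta",
                 "se", "p", "n")
  disc <- sumstat_table(df)
  targ_df <- df
  targ_df$beta <- rnorm(m, 0, 0.2)
  targ <- sumstat_table(targ_df)

  # already aligned: no sign changes
  pair <- harmonize(disc, targ)
  expect_false(any(pair$flipped))
  expect_equal(pair$beta_targ, targ$beta[match(pair$snp_id, targ$snp_id)])

  # negate every target beta and swap its allele columns: identical result
  sw <- targ_df
  sw$beta <- -sw$beta
  tmp <- sw$ea; sw$ea <- sw$oa; sw$oa <- tmp
  sw$eaf <- 1 - sw$eaf
  pair_sw <- harmonize(disc, sumstat_table(sw))
  expect_equal(pair_sw$beta_targ, pair$beta_targ)
  expect_equal(pair_sw$snp_id, pair$snp_id)

  # retained set does not depend on which table supplies position metadata
  scr <- targ_df
  scr$pos <- sample.int(1e6, m)
  scr$chrom <- sample(1:5, m, replace = TRUE)
  pair_scr <- harmonize(disc, sumstat_table(scr))
  expect_setequal(pair_scr$snp_id, pair$snp_id)
})
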