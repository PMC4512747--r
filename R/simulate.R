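#' Configuration for a paired synthetic GWAS study
#'
#' Encodes the statistical structure the three analysis arms assume: a
#' quantitative discovery trait and a liability-threshold case-control
#' target trait, both polygenic over a shared panel of LD-blocked SNPs,
#' with controllable SNP heritabilities and a known genetic correlation
#' between the per-SNP effect vectors.
#'
#' Defaults encode the reference study design: a discovery cohort of
#' 2000, a target study of 887 cases and 1493 controls (a 4x scale-down
#' of 3548/5972 for desk-scale runs), discovery heritability 0.13 and
#' target liability heritability 0.34 with genetic correlation -0.8.
#'
#' @param n_disc Discovery cohort size.
#' @param n_cases,n_controls Target study composition.
#' @param n_snps Number of SNPs on the panel.
#' @param block_size SNPs per LD block.
#' @param within_block_r Latent correlation between SNP liabilities within
#'   a block (dosage correlation is slightly attenuated by discretization).
#' @param maf_range Range minor allele frequencies are drawn from.
#' @param h2_disc,h2_targ SNP heritability of the discovery trait and of
#'   the target liability.
#' @param rG_true Genetic correlation between the per-SNP effect vectors.
#' @param n_causal Number of causal SNPs (shared between traits).
#' @param prevalence Population proportion above the liability threshold.
#' @param n_pool Size of the target population pool cases/controls are
#'   drawn from; defaults to enough for the requested cases with margin.
#' @param orient_scramble Fraction of target summary records emitted with
#'   swapped allele orientation (and negated effect), exercising
#'   harmonization (default 0.25).
#' @param seed Integer seed; every downstream draw is a deterministic
#'   function of it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_disc = 2000, n_cases = 887, n_controls = 1493,
                       n_snps = 1500, block_size = 3, within_block_r = 0.7,
                       maf_range = c(0.05, 0.5), h2_disc = 0.13,
                       h2_targ = 0.34, rG_true = -0.8, n_causal = NULL,
                       prevalence = 0.2, n_pool = NULL,
                       orient_scramble = 0.25, seed = 1L) {
  if (is.null(n_causal)) {
    # a dense polygenic architecture: 30% of the panel causal, so each
    # causal SNP contributes a small effect relative to GWAS noise (the
    # regime the summary-statistic joint-effect estimator assumes)
    n_causal <- min(n_snps, max(2, round(0.3 * n_snps)))
  }
  if (is.null(n_pool)) {
    n_pool <- max(ceiling(1.3 * n_cases / prevalence),
                  ceiling(1.3 * (n_cases + n_controls)))
  }
  cfg <- list(n_disc = n_disc, n_cases = n_cases, n_controls = n_controls,
              n_snps = n_snps, block_size = block_size,
              within_block_r = within_block_r, maf_range = maf_range,
              h2_disc = h2_disc, h2_targ = h2_targ, rG_true = rG_true,
              n_causal = n_causal, prevalence = prevalence, n_pool = n_pool,
              orient_scramble = orient_scramble, seed = as.integer(seed))
  stopifnot(cfg$n_disc > 1, cfg$n_cases > 0, cfg$n_controls > 0,
            cfg$n_snps >= 1, cfg$block_size >= 1,
            cfg$within_block_r >= 0, cfg$within_block_r < 1,
            length(cfg$maf_range) == 2, cfg$maf_range[1] > 0,
            cfg$maf_range[2] <= 0.5, cfg$maf_range[1] <= cfg$maf_range[2],
            cfg$h2_disc >= 0, cfg$h2_disc <= 1,
            cfg$h2_targ >= 0, cfg$h2_targ <= 1,
            abs(cfg$rG_true) <= 1, cfg$n_causal <= cfg$n_snps,
            cfg$prevalence > 0, cfg$prevalence < 1,
            cfg$orient_scramble >= 0, cfg$orient_scramble <= 1)
  structure(cfg, class = "sim_config")
}

# non-strand-ambiguous effect/other allele pairs
NONAMBIGUOUS_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))

#' Simulate the SNP map shared by all cohorts
#'
#' Assigns each LD block to a chromosome (round-robin over 22), spaces
#' SNPs 5 kb apart within a block and separates blocks on the same
#' chromosome by 1 Mb (well outside a 300 kb clumping window), and draws
#' a MAF and a non-ambiguous allele pair per SNP.
#'
#' @param config A `sim_config`.
#' @return Data frame `snp_id, chrom, pos, ea, oa, maf, block`.
#' @export
simulate_map <- function(config) {
  m <- config$n_snps
  block <- ceiling(seq_len(m) / config$block_size)
  n_block <- max(block)
  chrom_of_block <- ((seq_len(n_block) - 1) %% 22) + 1
  block_on_chrom <- stats::ave(seq_len(n_block), chrom_of_block,
                               FUN = seq_along)
  within <- stats::ave(seq_len(m), block, FUN = seq_along)
  pos <- (block_on_chrom[block] - 1) * 1e6 + (within - 1) * 5000 + 1
  alleles <- NONAMBIGUOUS_PAIRS[sample.int(nrow(NONAMBIGUOUS_PAIRS), m,
                                           replace = TRUE), , drop = FALSE]
  data.frame(
    snp_id = sprintf("rs%06d", seq_len(m)),
    chrom = as.character(chrom_of_block[block]),
    pos = as.integer(pos),
    ea = alleles[, 1], oa = alleles[, 2],
    maf = stats::runif(m, config$maf_range[1], config$maf_range[2]),
    block = block,
    stringsAsFactors = FALSE
  )
}

#' Simulate a genotype panel under block LD and Hardy-Weinberg margins
#'
#' Gaussian-copula model: each individual carries one latent standard
#' normal per block; each SNP's liability mixes it with SNP-specific
#' noise at weight `sqrt(within_block_r)`, giving latent correlation
#' `within_block_r` within a block and independence across blocks. The
#' liability is cut at the Hardy-Weinberg genotype frequencies of the
#' SNP's MAF to produce dosages in {0, 1, 2} counting the effect allele.
#'
#' @param config A `sim_config`.
#' @param n Number of individuals.
#' @param map SNP map from [simulate_map()]; generated if `NULL` (note
#'   that paired cohorts must share one map).
#' @param id_prefix Prefix for individual ids.
#' @return A `genotype_panel`.
#' @export
simulate_genotypes <- function(config, n, map = NULL, id_prefix = "ind") {
  if (is.null(map)) map <- simulate_map(config)
  m <- nrow(map)
  r <- config$within_block_r
  blocks <- map$block
  Z <- matrix(stats::rnorm(n * max(blocks)), n, max(blocks))
  L <- sqrt(r) * Z[, blocks, drop = FALSE] +
    sqrt(1 - r) * matrix(stats::rnorm(n * m), n, m)
  p <- map$maf  # frequency of the counted (effect) allele
  t0 <- stats::qnorm((1 - p)^2)
  t1 <- stats::qnorm(1 - p^2)
  G <- sweep(L, 2, t0, ">") + sweep(L, 2, t1, ">")
  storage.mode(G) <- "double"
  genotype_panel(G, map[c("snp_id", "chrom", "pos", "ea", "oa")],
                 sprintf("%s%05d", id_prefix, seq_len(n)))
}

#' Draw correlated per-SNP effect pairs with exact heritability scaling
#'
#' Causal SNPs are drawn uniformly; each receives a bivariate-normal
#' effect pair with correlation `rG_true` on the standardized-genotype
#' scale. Each trait's effect vector is then rescaled so the realized
#' genetic variance in its cohort panel equals the target heritability
#' exactly (phenotypes are built with residual variance `1 - h2`).
#'
#' @param config A `sim_config`.
#' @param panel_disc,panel_targ Cohort panels sharing the same SNP map.
#' @return A `synthetic_truth` list: `causal_ids`, dosage-scale effects
#'   `beta_disc`/`beta_targ`, standardized-scale effects `u_disc`/`u_targ`,
#'   genetic values `gv_disc`/`gv_targ`, `realized_h2_disc/_targ`,
#'   `realized_rG`.
#' @export
simulate_effect_pairs <- function(config, panel_disc, panel_targ) {
  if (config$n_causal < 2) stop("need n_causal >= 2", call. = FALSE)
  m <- nrow(panel_disc$map)
  causal <- sort(sample.int(m, config$n_causal))
  rG <- config$rG_true
  u1 <- stats::rnorm(config$n_causal)
  u2 <- rG * u1 + sqrt(max(0, 1 - rG^2)) * stats::rnorm(config$n_causal)

  scale_to <- function(panel, u, h2) {
    X <- panel$dosages[, causal, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) sds[sds == 0] <- 1  # monomorphic in-sample: no signal
    W <- sweep(sweep(X, 2, colMeans(X), "-"), 2, sds, "/")
    g <- as.numeric(W %*% u)
    vg <- stats::var(g)
    s <- if (h2 == 0 || vg == 0) 0 else sqrt(h2 / vg)
    list(u = u * s, beta = u * s / sds, gv = g * s)
  }
  d <- scale_to(panel_disc, u1, config$h2_disc)
  t <- scale_to(panel_targ, u2, config$h2_targ)
  structure(list(
    causal_ids = panel_disc$map$snp_id[causal],
    causal_idx = causal,
    u_disc = d$u, u_targ = t$u,
    beta_disc = d$beta, beta_targ = t$beta,
    gv_disc = d$gv, gv_targ = t$gv,
    realized_h2_disc = stats::var(d$gv),
    realized_h2_targ = stats::var(t$gv),
    realized_rG = stats::cor(u1, u2)
  ), class = "synthetic_truth")
}

#' Simulate cohort phenotypes from genetic values
#'
#' Discovery phenotype: genetic value plus normal noise with variance
#' `1 - h2_disc`. Target: a liability built the same way from `h2_targ`
#' is thresholded at `qnorm(1 - prevalence)`; the requested numbers of
#' cases and controls are sampled from the pool.
#'
#' @param truth A `synthetic_truth` whose genetic values index the
#'   discovery panel and the target pool panel respectively.
#' @param config A `sim_config`.
#' @return List: `pheno_disc` (numeric), `status` (0/1 for the selected
#'   target individuals), `targ_idx` (pool row indices selected),
#'   `liability` (full pool liability).
#' @export
simulate_cohorts <- function(truth, config) {
  pheno_disc <- truth$gv_disc +
    stats::rnorm(length(truth$gv_disc), sd = sqrt(1 - config$h2_disc))
  liab <- truth$gv_targ +
    stats::rnorm(length(truth$gv_targ), sd = sqrt(1 - config$h2_targ))
  thr <- stats::qnorm(1 - config$prevalence)
  is_case <- liab > thr
  if (sum(is_case) < config$n_cases) {
    stop("only ", sum(is_case), " cases realized; increase n_pool",
         call. = FALSE)
  }
  if (sum(!is_case) < config$n_controls) {
    stop("too few controls realized; increase n_pool", call. = FALSE)
  }
  cases <- sample(which(is_case), config$n_cases)
  controls <- sample(which(!is_case), config$n_controls)
  targ_idx <- c(cases, controls)
  list(pheno_disc = pheno_disc,
       status = rep(c(1L, 0L), c(config$n_cases, config$n_controls)),
       targ_idx = targ_idx, liability = liab, threshold = thr)
}

#' Single-SNP GWAS over a panel
#'
#' Per SNP, a simple linear regression (quantitative trait) or logistic
#' regression (binary trait, Newton-scoring vectorized across SNPs) of
#' the phenotype on the dosage. Monomorphic SNPs are skipped and counted
#' in the `n_skipped` attribute.
#'
#' @param panel A `genotype_panel`.
#' @param phenotype One value per panel individual.
#' @param kind `"quantitative"` or `"binary"`.
#' @param trait_name Label for the resulting table.
#' @return A `sumstat_table` with per-SNP `beta` (log-odds for binary),
#'   `se`, `p`, `eaf`, `n`.
#' @export
run_gwas <- function(panel, phenotype, kind = c("quantitative", "binary"),
                     trait_name = "trait") {
  kind <- match.arg(kind)
  X <- panel$dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu[nas[, 2]]
  }
  y <- as.numeric(phenotype)
  if (length(y) != nrow(X)) stop("phenotype length mismatch", call. = FALSE)
  n <- nrow(X)
  vx <- apply(X, 2, stats::var)
  poly <- vx > 0
  n_skipped <- sum(!poly)

  if (kind == "quantitative") {
    xc <- sweep(X, 2, colMeans(X), "-")
    beta <- as.numeric(crossprod(xc, y - mean(y))) / ((n - 1) * vx)
    # residual variance of y on each single SNP
    rss <- (stats::var(y) - beta^2 * vx) * (n - 1)
    sigma2 <- pmax(rss / (n - 2), 1e-12)
    se <- sqrt(sigma2 / ((n - 1) * vx))
    tval <- beta / se
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  } else {
    y <- as.integer(y)
    a <- rep(stats::qlogis(mean(y)), ncol(X))
    b <- rep(0, ncol(X))
    for (it in 1:25) {
      eta <- sweep(X * rep(b, each = n), 2, a, "+")
      mu <- stats::plogis(eta)
      w <- mu * (1 - mu)
      r <- y - mu
      g1 <- colSums(r)
      g2 <- colSums(r * X)
      h11 <- colSums(w)
      h12 <- colSums(w * X)
      h22 <- colSums(w * X^2)
      det <- h11 * h22 - h12^2
      det[det <= 0] <- NA
      da <- (h22 * g1 - h12 * g2) / det
      db <- (h11 * g2 - h12 * g1) / det
      da[is.na(da)] <- 0
      db[is.na(db)] <- 0
      # damp very large steps to keep separation-ish SNPs finite
      da <- pmax(pmin(da, 5), -5)
      db <- pmax(pmin(db, 5), -5)
      a <- a + da
      b <- b + db
      if (max(abs(da), abs(db)) < 1e-8) break
    }
    eta <- sweep(X * rep(b, each = n), 2, a, "+")
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    h11 <- colSums(w)
    h12 <- colSums(w * X)
    h22 <- colSums(w * X^2)
    det <- h11 * h22 - h12^2
    beta <- b
    se <- sqrt(h11 / det)
    zval <- beta / se
    p <- 2 * stats::pnorm(-abs(zval))
  }

  df <- data.frame(
    snp_id = panel$map$snp_id, chrom = panel$map$chrom, pos = panel$map$pos,
    ea = panel$map$ea, oa = panel$map$oa,
    eaf = colMeans(X) / 2, beta = beta, se = se, p = pmax(p, 1e-300),
    n = n, stringsAsFactors = FALSE
  )
  df <- df[poly & is.finite(df$se) & df$se > 0, , drop = FALSE]
  out <- sumstat_table(df, trait_name = trait_name,
                       trait_kind = if (kind == "binary") "binary" else "quantitative")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Swap the reported allele orientation of a fraction of records
#'
#' Pure representation change used by the simulator: swaps effect/other
#' alleles, negates the effect and complements the frequency for a random
#' subset of records. Harmonization must undo it exactly.
#'
#' @param table A `sumstat_table`.
#' @param fraction Fraction of records to scramble.
#' @export
scramble_orientation <- function(table, fraction = 0.25) {
  if (fraction <= 0) return(table)
  flip <- stats::runif(nrow(table)) < fraction
  df <- as.data.frame(table)
  tmp <- df$ea[flip]
  df$ea[flip] <- df$oa[flip]
  df$oa[flip] <- tmp
  df$beta[flip] <- -df$beta[flip]
  df$eaf[flip] <- 1 - df$eaf[flip]
  out <- sumstat_table(df, attr(table, "trait_name"), attr(table, "trait_kind"))
  attr(out, "scrambled") <- df$snp_id[flip]
  out
}

#' Simulate a complete paired GWAS study
#'
#' End-to-end generator: shared SNP map, discovery panel and target pool,
#' correlated effect pairs scaled to the target heritabilities,
#' liability-threshold case-control sampling, single-SNP GWAS in each
#' cohort, and orientation scrambling of the target table. Deterministic
#' given `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A `synthetic_study` list: `config`, `map`, `truth`,
#'   `panel_disc`, `panel_targ` (selected target individuals),
#'   `pheno_disc`, `status_targ`, `sumstats_disc`, `sumstats_targ`.
#' @export
simulate_study <- function(config) {
  set.seed(config$seed)
  map <- simulate_map(config)
  panel_disc <- simulate_genotypes(config, config$n_disc, map, "disc")
  panel_pool <- simulate_genotypes(config, config$n_pool, map, "targ")
  truth <- simulate_effect_pairs(config, panel_disc, panel_pool)
  coh <- simulate_cohorts(truth, config)
  panel_targ <- subset_panel(panel_pool, individuals = coh$targ_idx)
  sumstats_disc <- run_gwas(panel_disc, coh$pheno_disc, "quantitative",
                            trait_name = "discovery")
  sumstats_targ <- run_gwas(panel_targ, coh$status, "binary",
                            trait_name = "target")
  sumstats_targ <- scramble_orientation(sumstats_targ, config$orient_scramble)
  structure(list(config = config, map = map, truth = truth,
                 panel_disc = panel_disc, panel_targ = panel_targ,
                 pheno_disc = coh$pheno_disc, status_targ = coh$status,
                 sumstats_disc = sumstats_disc, sumstats_targ = sumstats_targ),
            class = "synthetic_study")
}
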