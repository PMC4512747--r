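# Independent oracles and fixture builders shared across the test files.
# The oracles deliberately avoid the package's own code paths.

# full-enumeration two-sided binomial P: point probabilities from first
# principles (choose), summing outcomes no more likely than the observed k
oracle_binom_p <- function(n, k, p0 = 0.5) {
  probs <- vapply(0:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j),
                  numeric(1))
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# brute-force greedy clumping over a precomputed r^2 matrix
oracle_clump <- function(snp_id, chrom, pos, p, r2mat, r2_threshold,
                         window_kb) {
  m <- length(snp_id)
  remaining <- rep(TRUE, m)
  ord <- order(p, chrom, pos, snp_id)
  indices <- character(0)
  for (i in ord) {
    if (!remaining[i]) next
    remaining[i] <- FALSE
    indices <- c(indices, snp_id[i])
    for (j in seq_len(m)) {
      r2 <- r2mat[i, j]
      if (remaining[j] && chrom[j] == chrom[i] &&
          abs(pos[j] - pos[i]) <= window_kb * 1000 &&
          !is.na(r2) && r2 > r2_threshold) {
        remaining[j] <- FALSE
      }
    }
  }
  indices
}

# dense-arithmetic restricted log-likelihood for y ~ N(Xb, sg*A + se*I)
oracle_reml_ll <- function(A, y, sg, se, X = matrix(1, length(y), 1)) {
  n <- length(y)
  V <- sg * A + diag(se, n)
  Vi <- solve(V)
  XVX <- crossprod(X, Vi %*% X)
  b <- solve(XVX, crossprod(X, Vi %*% y))
  r <- y - X %*% b
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XVX)$modulus +
                       crossprod(r, Vi %*% r) + (n - ncol(X)) * log(2 * pi)))
}

# build a harmonized_pair directly from vectors
make_pair <- function(beta_disc, beta_targ, se_targ = 0.1,
                      p_disc = 0.5, p_targ = 0.5,
                      chrom = "1", pos = NULL) {
  m <- length(beta_disc)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  structure(data.frame(
    snp_id = sprintf("rs%04d", seq_len(m)),
    chrom = rep_len(chrom, m), pos = pos,
    beta_disc = beta_disc, beta_targ = beta_targ,
    se_targ = rep_len(se_targ, m),
    p_disc = rep_len(p_disc, m), p_targ = rep_len(p_targ, m),
    flipped = FALSE, stringsAsFactors = FALSE),
    class = c("harmonized_pair", "data.frame"))
}

# small dosage panel from an explicit matrix
make_panel <- function(dosages, chrom = "1", pos = NULL) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  genotype_panel(dosages,
                 data.frame(snp_id = sprintf("rs%04d", seq_len(m)),
                            chrom = rep_len(chrom, m), pos = pos,
                            ea = "A", oa = "G",
                            stringsAsFactors = FALSE))
}

# sumstat data frame with sensible defaults, for file round-trips
make_sumstat_df <- function(m = 5, seed = 1) {
  set.seed(seed)
  data.frame(
    snp = sprintf("rs%04d", seq_len(m)),
    chr = sample(1:3, m, replace = TRUE),
    pos = sample.int(1e6, m),
    ea = "A", oa = "G",
    eaf = runif(m, 0.05, 0.95),
    beta = rnorm(m, 0, 0.1),
    se = runif(m, 0.05, 0.2),
    p = runif(m),
    n = 1000L,
    stringsAsFactors = FALSE
  )
}

write_sumstat_file <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# disjoint-cohort bivariate GREML simulation used by several tests:
# two panels over one map, correlated standardized effects, quantitative
# phenotypes, union GRM
simulate_disjoint_greml <- function(n, m, h2_1, h2_2, rg, seed) {
  set.seed(seed)
  cfg <- sim_config(n_snps = m, block_size = 1, within_block_r = 0,
                    seed = seed)
  map <- simulate_map(cfg)
  pa <- simulate_genotypes(cfg, n, map, "a")
  pb <- simulate_genotypes(cfg, n, map, "b")
  u1 <- rnorm(m)
  u2 <- rg * u1 + sqrt(1 - rg^2) * rnorm(m)
  gva <- as.numeric(scale(pa$dosages) %*% u1)
  gva <- gva * sqrt(h2_1 / var(gva))
  gvb <- as.numeric(scale(pb$dosages) %*% u2)
  gvb <- gvb * sqrt(h2_2 / var(gvb))
  y1 <- gva + rnorm(n, sd = sqrt(1 - h2_1))
  y2 <- gvb + rnorm(n, sd = sqrt(1 - h2_2))
  union_panel <- genotype_panel(
    rbind(pa$dosages, pb$dosages),
    pa$map,
    c(paste0("a", seq_len(n)), paste0("b", seq_len(n))))
  grm <- compute_grm(union_panel, maf_min = 0.01)
  list(grm = grm,
       trait1 = c(y1, rep(NA_real_, n)),
       trait2 = c(rep(NA_real_, n), y2),
       panels = list(pa, pb))
}
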