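#' Squared LD correlation between two panel SNPs
#'
#' Composite (phase-free) linkage disequilibrium: the squared Pearson
#' correlation of the two dosage vectors over individuals non-missing at
#' both SNPs.
#'
#' @param panel A `genotype_panel`.
#' @param snp_a,snp_b SNP identifiers.
#' @export
ld_r2 <- function(panel, snp_a, snp_b) {
  ia <- match(snp_a, panel$map$snp_id)
  ib <- match(snp_b, panel$map$snp_id)
  if (is.na(ia) || is.na(ib)) stop("SNP not in panel", call. = FALSE)
  x <- panel$dosages[, ia]
  y <- panel$dosages[, ib]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("LD undefined: monomorphic dosage vector for ",
         if (stats::var(x) == 0) snp_a else snp_b, call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' Greedy P-value-ranked LD clumping
#'
#' Repeatedly takes the unabsorbed SNP with the smallest discovery P value
#' as an index SNP and absorbs every unabsorbed SNP on the same chromosome
#' within `window_kb` kilobases whose dosage r-squared with the index
#' exceeds `r2_threshold`. Ties on P are broken by (chromosome, position,
#' snp_id). SNPs absent from the reference panel are dropped and counted.
#'
#' @param sumstats A `harmonized_pair` (ranked on `p_disc`) or a
#'   `sumstat_table` (ranked on `p`).
#' @param panel LD reference `genotype_panel`.
#' @param r2_threshold SNPs with r^2 above this are absorbed (default
#'   0.25, so retained index SNPs satisfy r^2 <= 0.25 pairwise within the
#'   window).
#' @param window_kb Half-window in kb around the index position (default
#'   300).
#' @param p_threshold Only SNPs with discovery P at or below this enter
#'   the clumping at all (default 1, i.e. everything).
#' @param compute_effective Also estimate the effective number of
#'   independent SNPs among the indices (default `TRUE`).
#' @return A `clump_result` list: `index_snps` (ordered by ascending P),
#'   `members` (named list mapping each index to the snp_ids it absorbed),
#'   `n_input`, `n_absent`, `effective_number`, `effective_ratio`.
#' @export
clump <- function(sumstats, panel, r2_threshold = 0.25, window_kb = 300,
                  p_threshold = 1.0, compute_effective = TRUE) {
  if (r2_threshold <= 0) stop("r2_threshold must be positive", call. = FALSE)
  if (window_kb <= 0) stop("window_kb must be positive", call. = FALSE)
  pcol <- if (inherits(sumstats, "harmonized_pair")) "p_disc" else "p"
  df <- data.frame(snp_id = sumstats$snp_id, chrom = as.character(sumstats$chrom),
                   pos = sumstats$pos, p = sumstats[[pcol]],
                   stringsAsFactors = FALSE)
  df <- df[df$p <= p_threshold, , drop = FALSE]
  n_input <- nrow(df)
  col <- match(df$snp_id, panel$map$snp_id)
  n_absent <- sum(is.na(col))
  df <- df[!is.na(col), , drop = FALSE]
  col <- col[!is.na(col)]
  if (nrow(df) == 0) stop("no SNPs left after panel intersection", call. = FALSE)

  ord <- order(df$p, df$chrom, df$pos, df$snp_id)
  df <- df[ord, , drop = FALSE]
  col <- col[ord]
  m <- nrow(df)
  absorbed <- rep(FALSE, m)
  index_snps <- character(0)
  members <- list()
  window_bp <- window_kb * 1000
  X <- panel$dosages

  for (i in seq_len(m)) {
    if (absorbed[i]) next
    absorbed[i] <- TRUE
    idx_id <- df$snp_id[i]
    cand <- which(!absorbed & df$chrom == df$chrom[i] &
                    abs(df$pos - df$pos[i]) <= window_bp)
    mem <- character(0)
    if (length(cand) > 0) {
      xi <- X[, col[i]]
      r <- suppressWarnings(
        stats::cor(xi, X[, col[cand], drop = FALSE],
                   use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      hit <- !is.na(r2) & r2 > r2_threshold
      if (any(hit)) {
        mem <- df$snp_id[cand[hit]]
        absorbed[cand[hit]] <- TRUE
      }
    }
    index_snps <- c(index_snps, idx_id)
    members[[idx_id]] <- mem
  }

  eff <- NA_real_
  ratio <- NA_real_
  if (compute_effective && length(index_snps) >= 2) {
    eff <- effective_number(panel, index_snps)
    ratio <- eff / length(index_snps)
  }
  structure(list(index_snps = index_snps, members = members,
                 n_input = n_input, n_absent = n_absent,
                 effective_number = eff, effective_ratio = ratio),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat("clump_result:", length(x$index_snps), "index SNPs from",
      x$n_input, "input SNPs")
  if (!is.na(x$effective_ratio)) {
    cat(sprintf(" (Meff = %.1f, effective ratio = %.3f)",
                x$effective_number, x$effective_ratio))
  }
  cat("\n")
  invisible(x)
}

#' Write a clump table
#' @param result A `clump_result`.
#' @param path Output path.
#' @param sumstats Optional table supplying the P value column.
#' @export
write_clumps <- function(result, path, sumstats = NULL) {
  members <- vapply(result$members[result$index_snps],
                    function(m) paste(m, collapse = ","), character(1))
  df <- data.frame(index_snp = result$index_snps,
                   n_members = lengths(result$members[result$index_snps]),
                   members = members, stringsAsFactors = FALSE)
  if (!is.null(sumstats)) {
    pcol <- if (inherits(sumstats, "harmonized_pair")) "p_disc" else "p"
    df$p <- sumstats[[pcol]][match(df$index_snp, sumstats$snp_id)]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Effective number of independent SNPs
#'
#' Eigenvalue-variance estimator of the number of independent tests among
#' a set of SNPs, computed per chromosome block and summed. For a block of
#' M SNPs with dosage correlation-matrix eigenvalues lambda,
#' `Meff = 1 + (M - 1) * (1 - Var(lambda) / M)` with `Var` using
#' denominator `M - 1`. Uncorrelated SNPs give Meff = M; perfectly
#' correlated SNPs give Meff = 1.
#'
#' @param panel A `genotype_panel`.
#' @param snp_ids SNPs to include (at least 2 overall).
#' @param block_cap Chromosome blocks larger than this are split into
#'   consecutive chunks to bound the eigendecomposition (default 2000).
#' @return The summed Meff across blocks.
#' @export
effective_number <- function(panel, snp_ids, block_cap = 2000) {
  idx <- match(snp_ids, panel$map$snp_id)
  if (anyNA(idx)) {
    stop("SNP(s) not in panel: ",
         paste(snp_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (length(idx) < 2) stop("need at least 2 SNPs", call. = FALSE)
  chrom <- panel$map$chrom[idx]
  pos <- panel$map$pos[idx]
  total <- 0
  for (ch in unique(chrom)) {
    sel <- idx[chrom == ch][order(pos[chrom == ch])]
    chunks <- split(sel, ceiling(seq_along(sel) / block_cap))
    for (block in chunks) {
      M <- length(block)
      if (M == 1) {
        total <- total + 1
        next
      }
      Xb <- panel$dosages[, block, drop = FALSE]
      sds <- apply(Xb, 2, stats::sd, na.rm = TRUE)
      if (any(sds == 0)) {
        stop("monomorphic SNP in block: ",
             paste(panel$map$snp_id[block[sds == 0]], collapse = ", "),
             call. = FALSE)
      }
      C <- suppressWarnings(stats::cor(Xb, use = "pairwise.complete.obs"))
      lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
      total <- total + 1 + (M - 1) * (1 - stats::var(lam) / M)
    }
  }
  total
}
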