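#' Genomic relationship matrix from a dosage panel
#'
#' Allele-frequency standardized GRM:
#' \deqn{A_{jk} = \frac{1}{m}\sum_i
#'   \frac{(x_{ij} - 2\hat p_i)(x_{ik} - 2\hat p_i)}{2\hat p_i(1-\hat p_i)}}
#' with \eqn{\hat p_i} the sample frequency of the counted allele at SNP
#' i. Missing dosages are mean-imputed before centering (so they
#' contribute zero). SNPs below `maf_min` or monomorphic are excluded.
#' Under Hardy-Weinberg sampling the diagonal averages 1.
#'
#' @param panel A `genotype_panel`.
#' @param maf_min Minimum minor allele frequency for a SNP to contribute
#'   (default 0.01).
#' @return A `grm` list: `values` (symmetric n x n), `individual_ids`,
#'   `n_snps_used`.
#' @export
compute_grm <- function(panel, maf_min = 0.01) {
  X <- panel$dosages
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min & maf > 0
  if (!any(keep)) stop("no polymorphic SNPs pass the MAF filter", call. = FALSE)
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  if (anyNA(X)) {
    mu <- 2 * p
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu[nas[, 2]]
  }
  W <- sweep(X, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(W) / ncol(W)
  structure(list(values = A, individual_ids = panel$individual_ids,
                 n_snps_used = ncol(W)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$individual_ids), "individuals,",
      x$n_snps_used, "SNPs; mean diagonal",
      sprintf("%.3f", mean(diag(x$values))), "\n")
  invisible(x)
}

#' Write a GRM as a lower-triangle delimited file with an id sidecar
#' @param grm A `grm`.
#' @param prefix Output prefix; writes `<prefix>.grm.tsv` (i, j, value
#'   over the lower triangle including the diagonal) and `<prefix>.ids.tsv`.
#' @export
write_grm <- function(grm, prefix) {
  n <- length(grm$individual_ids)
  ij <- which(lower.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(i = ij[, 1], j = ij[, 2],
                   value = grm$values[ij])
  utils::write.table(df, paste0(prefix, ".grm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(individual_id = grm$individual_ids),
                     paste0(prefix, ".ids.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Prune related individuals from a GRM
#'
#' Greedy removal: while any off-diagonal relatedness exceeds `cutoff`,
#' drop the individual involved in the most offending pairs (ties broken
#' by lexicographically smallest id). All retained pairs end at or below
#' the cutoff.
#'
#' @param grm A `grm`.
#' @param cutoff Maximum allowed pairwise relatedness (default 0.10,
#'   which removes up to first-cousin-level pairs; 0.025 is the stricter
#'   conventional default).
#' @return Character vector of retained individual ids.
#' @export
prune_related <- function(grm, cutoff = 0.10) {
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  A <- grm$values
  ids <- grm$individual_ids
  alive <- rep(TRUE, length(ids))
  off <- A
  diag(off) <- 0
  repeat {
    viol <- off > cutoff & outer(alive, alive)
    counts <- rowSums(viol)
    if (max(counts) == 0) break
    worst <- which(counts == max(counts))
    drop <- worst[order(ids[worst])][1]
    alive[drop] <- FALSE
    off[drop, ] <- 0
    off[, drop] <- 0
  }
  ids[alive]
}
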