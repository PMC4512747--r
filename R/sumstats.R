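#' @keywords internal
"_PACKAGE"

VALID_ALLELES <- c("A", "C", "G", "T")

allele_complement <- function(x) {
  chartr("ACGT", "TGCA", x)
}

is_strand_ambiguous <- function(ea, oa) {
  ea == allele_complement(oa)
}

#' Construct a validated summary-statistic table
#'
#' Wraps a data frame of per-SNP GWAS association records into a
#' `sumstat_table`. Records must carry a SNP identifier, chromosome,
#' 1-based base-pair position, effect and other allele, effect-allele
#' frequency, effect size (log-odds for binary traits), standard error,
#' P value and sample size. Rows are sorted by (chromosome, position).
#'
#' @param records Data frame with columns `snp_id`, `chrom`, `pos`, `ea`,
#'   `oa`, `eaf`, `beta`, `se`, `p`, `n`.
#' @param trait_name Label for the trait.
#' @param trait_kind `"quantitative"` or `"binary"`.
#' @return A `sumstat_table` (a data frame with attributes `trait_name`,
#'   `trait_kind`).
#' @export
sumstat_table <- function(records, trait_name = "trait",
                          trait_kind = c("quantitative", "binary")) {
  trait_kind <- match.arg(trait_kind)
  needed <- c("snp_id", "chrom", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("summary-statistic records lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[needed]
  if (anyDuplicated(records$snp_id)) {
    stop("duplicate snp_id in summary-statistic table", call. = FALSE)
  }
  records <- records[order(records$chrom, records$pos, records$snp_id), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(records,
            trait_name = trait_name,
            trait_kind = trait_kind,
            class = c("sumstat_table", "data.frame"))
}

#' Read a GWAS summary-statistic file
#'
#' Reads a headered, whitespace- or tab-delimited association table,
#' renames columns through `column_map`, validates every record and drops
#' (with a structured report) rows violating the record invariants:
#' alleles in A/C/G/T and distinct, `se > 0`, `p` in (0, 1], `n > 0`,
#' finite effect, `eaf` in \[0, 1\] or missing. Odds ratios are converted
#' to the log scale when the effect column is mapped as `or`.
#'
#' @param path File path.
#' @param column_map Named character vector mapping canonical names
#'   (`snp`, `chr`, `pos`, `ea`, `oa`, `eaf`, `beta` or `or`, `se`, `p`,
#'   `n`) to the file's column names. Defaults to the canonical names.
#' @param trait_kind `"quantitative"` or `"binary"`.
#' @param trait_name Label stored on the table; defaults to the file name.
#' @return A `sumstat_table`; attribute `drop_report` holds per-reason drop
#'   counts.
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_kind = c("quantitative", "binary"),
                          trait_name = NULL) {
  trait_kind <- match.arg(trait_kind)
  if (is.null(trait_name)) trait_name <- basename(path)
  canonical <- c(snp = "snp", chr = "chr", pos = "pos", ea = "ea", oa = "oa",
                 eaf = "eaf", beta = "beta", se = "se", p = "p", n = "n")
  effect_is_or <- FALSE
  if (is.null(column_map)) {
    column_map <- canonical
  } else {
    if ("or" %in% names(column_map)) {
      effect_is_or <- TRUE
      names(column_map)[names(column_map) == "or"] <- "beta"
    }
    column_map <- c(column_map, canonical[setdiff(names(canonical), names(column_map))])
  }
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  mandatory <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")
  for (key in mandatory) {
    if (!column_map[[key]] %in% names(raw)) {
      stop("mandatory column '", column_map[[key]], "' (", key,
           ") missing from ", path, call. = FALSE)
    }
  }
  df <- data.frame(
    snp_id = as.character(raw[[column_map[["snp"]]]]),
    chrom = as.character(raw[[column_map[["chr"]]]]),
    pos = as.integer(raw[[column_map[["pos"]]]]),
    ea = toupper(as.character(raw[[column_map[["ea"]]]])),
    oa = toupper(as.character(raw[[column_map[["oa"]]]])),
    eaf = as.numeric(raw[[column_map[["eaf"]]]]),
    beta = as.numeric(raw[[column_map[["beta"]]]]),
    se = as.numeric(raw[[column_map[["se"]]]]),
    p = as.numeric(raw[[column_map[["p"]]]]),
    n = as.numeric(raw[[column_map[["n"]]]]),
    stringsAsFactors = FALSE
  )
  if (effect_is_or) {
    bad_or <- !is.finite(df$beta) | df$beta <= 0
    df$beta[!bad_or] <- log(df$beta[!bad_or])
    df$beta[bad_or] <- NA_real_
  }

  drop <- c(bad_allele = 0L, bad_se = 0L, bad_p = 0L, bad_n = 0L,
            bad_beta = 0L, bad_eaf = 0L, bad_pos = 0L, duplicate_snp = 0L)
  keep <- rep(TRUE, nrow(df))
  flag <- function(bad, reason) {
    bad <- bad & keep
    drop[[reason]] <<- drop[[reason]] + sum(bad)
    keep <<- keep & !bad
  }
  flag(!(df$ea %in% VALID_ALLELES) | !(df$oa %in% VALID_ALLELES) |
         df$ea == df$oa, "bad_allele")
  flag(!is.finite(df$se) | df$se <= 0, "bad_se")
  flag(!is.finite(df$p) | df$p <= 0 | df$p > 1, "bad_p")
  flag(!is.finite(df$n) | df$n <= 0, "bad_n")
  flag(!is.finite(df$beta), "bad_beta")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "bad_eaf")
  flag(is.na(df$pos) | df$pos < 1, "bad_pos")
  flag(duplicated(df$snp_id), "duplicate_snp")

  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("no valid summary-statistic rows in ", path, call. = FALSE)
  }
  out <- sumstat_table(df, trait_name = trait_name, trait_kind = trait_kind)
  attr(out, "drop_report") <- drop
  out
}

#' Write a summary-statistic table to a tab-delimited file
#' @param table A `sumstat_table`.
#' @param path Output path.
#' @export
write_sumstats <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a summary table on minor allele frequency
#'
#' Retains records whose minor allele frequency, `min(eaf, 1 - eaf)`, is at
#' least `min_maf`. The boundary is inclusive, so `eaf = 0.95` survives
#' `min_maf = 0.05`.
#'
#' @param table A `sumstat_table`.
#' @param min_maf Minimum minor allele frequency (default 0.05, the usual
#'   common-variant cutoff).
#' @export
maf_filter <- function(table, min_maf = 0.05) {
  if (anyNA(table$eaf)) {
    stop("eaf missing for snp(s): ",
         paste(table$snp_id[is.na(table$eaf)], collapse = ", "),
         call. = FALSE)
  }
  keep <- pmin(table$eaf, 1 - table$eaf) >= min_maf
  sumstat_table(as.data.frame(table)[keep, , drop = FALSE],
                trait_name = attr(table, "trait_name"),
                trait_kind = attr(table, "trait_kind"))
}

#' Allele-harmonize a discovery/target pair of summary tables
#'
#' Joins two summary tables on `snp_id` and aligns the target effect to the
#' discovery effect allele. Four orientations are recognised: identical
#' alleles (kept), swapped alleles (target effect negated), strand
#' complement (kept) and strand complement plus swap (negated). Strand
#' ambiguous SNPs (A/T or C/G pairs), whose complement is indistinguishable
#' from a swap, are dropped by default. Allele pairs incompatible under all
#' four rules are dropped with reason `"allele_mismatch"`.
#'
#' @param discovery,target `sumstat_table`s. Positions and chromosome come
#'   from the discovery table; the retained SNP set does not depend on that
#'   choice.
#' @param drop_ambiguous Drop strand-ambiguous SNPs (default `TRUE`).
#' @return A `harmonized_pair` data frame with columns `snp_id`, `chrom`,
#'   `pos`, `beta_disc`, `beta_targ`, `se_targ`, `p_disc`, `p_targ`,
#'   `flipped`; attribute `dropped` records snp_id and reason for exclusions.
#' @export
harmonize <- function(discovery, target, drop_ambiguous = TRUE) {
  for (tab in list(discovery, target)) {
    if (anyDuplicated(tab$snp_id)) {
      stop("duplicate snp_id present before join", call. = FALSE)
    }
  }
  idx <- match(discovery$snp_id, target$snp_id)
  shared <- !is.na(idx)
  d <- as.data.frame(discovery)[shared, , drop = FALSE]
  t <- as.data.frame(target)[idx[shared], , drop = FALSE]

  same <- t$ea == d$ea & t$oa == d$oa
  swap <- t$ea == d$oa & t$oa == d$ea
  comp_same <- allele_complement(t$ea) == d$ea & allele_complement(t$oa) == d$oa
  comp_swap <- allele_complement(t$ea) == d$oa & allele_complement(t$oa) == d$ea
  ambiguous <- is_strand_ambiguous(d$ea, d$oa)

  reason <- rep(NA_character_, nrow(d))
  if (drop_ambiguous) reason[ambiguous] <- "strand_ambiguous"
  compatible <- same | swap | comp_same | comp_swap
  reason[is.na(reason) & !compatible] <- "allele_mismatch"

  keep <- is.na(reason)
  # for ambiguous SNPs kept on request, the same/comp and swap/comp-swap
  # branches coincide; direct match takes precedence
  flipped <- keep & !same & (swap | comp_swap)

  pair <- data.frame(
    snp_id = d$snp_id[keep],
    chrom = d$chrom[keep],
    pos = d$pos[keep],
    beta_disc = d$beta[keep],
    beta_targ = ifelse(flipped[keep], -t$beta[keep], t$beta[keep]),
    se_targ = t$se[keep],
    p_disc = d$p[keep],
    p_targ = t$p[keep],
    flipped = flipped[keep],
    stringsAsFactors = FALSE
  )
  pair <- pair[order(pair$chrom, pair$pos, pair$snp_id), , drop = FALSE]
  rownames(pair) <- NULL
  structure(pair,
            dropped = data.frame(snp_id = d$snp_id[!keep],
                                 reason = reason[!keep],
                                 stringsAsFactors = FALSE),
            class = c("harmonized_pair", "data.frame"))
}

#' Write a harmonized pair to a tab-delimited file
#' @param pair A `harmonized_pair`.
#' @param path Output path.
#' @export
write_harmonized <- function(pair, path) {
  utils::write.table(as.data.frame(pair), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
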