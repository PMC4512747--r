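#' Construct a reference genotype panel
#'
#' A genotype panel holds a dosage matrix (individuals in rows, SNPs in
#' columns, values in \[0, 2\], `NA` for missing) together with SNP
#' metadata. It serves as the LD reference for clumping, the genotype
#' source for individual-level polygenic scores, and the input to the
#' genomic relationship matrix.
#'
#' @param dosages Numeric matrix, individuals x SNPs.
#' @param map Data frame with one row per SNP: `snp_id`, `chrom`, `pos`
#'   and optionally `ea`, `oa` (the counted and alternate allele).
#' @param individual_ids Character vector of row identifiers.
#' @return A `genotype_panel` list with elements `dosages`, `map`,
#'   `individual_ids`.
#' @export
genotype_panel <- function(dosages, map, individual_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(individual_ids)) {
    individual_ids <- rownames(dosages)
    if (is.null(individual_ids)) {
      individual_ids <- sprintf("ind%04d", seq_len(nrow(dosages)))
    }
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "chrom", "pos") %in% names(map))) {
    stop("panel map needs columns snp_id, chrom, pos", call. = FALSE)
  }
  if (ncol(dosages) != nrow(map)) {
    stop("dosage columns (", ncol(dosages), ") and map rows (", nrow(map),
         ") disagree", call. = FALSE)
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  nonmiss <- colSums(!is.na(dosages))
  if (any(nonmiss < 2)) {
    stop("SNP(s) with fewer than 2 non-missing dosages: ",
         paste(map$snp_id[nonmiss < 2], collapse = ", "), call. = FALSE)
  }
  dimnames(dosages) <- list(individual_ids, map$snp_id)
  structure(list(dosages = dosages, map = map,
                 individual_ids = individual_ids),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$individual_ids), "individuals x",
      nrow(x$map), "SNPs\n")
  invisible(x)
}

#' Subset a genotype panel by individuals and/or SNPs
#' @param panel A `genotype_panel`.
#' @param individuals Indices or ids of individuals to keep.
#' @param snps Indices or ids of SNPs to keep.
#' @export
subset_panel <- function(panel, individuals = NULL, snps = NULL) {
  di <- panel$dosages
  ids <- panel$individual_ids
  map <- panel$map
  if (!is.null(individuals)) {
    if (is.character(individuals)) individuals <- match(individuals, ids)
    di <- di[individuals, , drop = FALSE]
    ids <- ids[individuals]
  }
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, map$snp_id)
    di <- di[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
  }
  genotype_panel(di, map, ids)
}

#' Write a genotype panel as delimited text
#'
#' Produces `<prefix>.dosages.tsv` (individuals x SNPs, first column the
#' individual id) and `<prefix>.snps.tsv` (the SNP metadata sidecar).
#' @param panel A `genotype_panel`.
#' @param prefix Output path prefix.
#' @export
write_panel <- function(panel, prefix) {
  dos <- data.frame(individual_id = panel$individual_ids,
                    panel$dosages, check.names = FALSE)
  utils::write.table(dos, paste0(prefix, ".dosages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$map, paste0(prefix, ".snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a genotype panel written by [write_panel()]
#' @param prefix Path prefix used at write time.
#' @export
read_panel <- function(prefix) {
  dos <- utils::read.table(paste0(prefix, ".dosages.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE)
  map <- utils::read.table(paste0(prefix, ".snps.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  genotype_panel(as.matrix(dos[, -1, drop = FALSE]), map,
                 as.character(dos[[1]]))
}
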