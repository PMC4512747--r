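# Arm 1: effect-direction concordance. Among the clumped index SNPs, count
# how often the discovery and target effects share a sign at each discovery
# P inclusion threshold and test against 50% with the exact two-sided
# binomial test.

source("analysis/00_config.R")

pair <- read.table(file.path(TABLE_DIR, "harmonized.tsv"), header = TRUE,
                   sep = "\t", colClasses = c(chrom = "character"))
idx <- read.table(file.path(TABLE_DIR, "clumps.tsv"), header = TRUE,
                  sep = "\t")$index_snp
pair <- pair[pair$snp_id %in% idx, ]

scan <- concordance_scan(pair, alpha = ALPHA_CORR)
write.table(scan, file.path(TABLE_DIR, "concordance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

png(file.path(FIG_DIR, "concordance_scan.png"), 720, 480)
plot_concordance_scan(scan, main = "effect-direction concordance")
dev.off()

best <- which.min(scan$p)
cat(sprintf("concordance by threshold: proportions %s\n",
            paste(sprintf("%.2f", scan$proportion), collapse = ", ")))
cat(sprintf("strongest signal at P<=%.2g: %d/%d concordant (P = %.3g, %s)\n",
            scan$threshold[best], scan$k[best], scan$n[best], scan$p[best],
            scan$label[best]))
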