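# Read the two summary tables back from disk, MAF-filter at 0.05, align the
# target effects to the discovery effect alleles, and LD-clump the shared
# SNPs on discovery P against the discovery genotype panel (r2 <= 0.25
# within 300 kb), reporting the effective number of independent index SNPs.

source("analysis/00_config.R")

disc <- read_sumstats(file.path(TABLE_DIR, "sumstats_discovery.tsv"),
                      column_map = c(snp = "snp_id", chr = "chrom"),
                      trait_kind = "quantitative")
targ <- read_sumstats(file.path(TABLE_DIR, "sumstats_target.tsv"),
                      column_map = c(snp = "snp_id", chr = "chrom"),
                      trait_kind = "binary")

pair <- harmonize(maf_filter(disc, 0.05), maf_filter(targ, 0.05))
cat(sprintf("harmonized %d shared SNPs (%d flipped to the discovery allele, %d dropped)\n",
            nrow(pair), sum(pair$flipped), nrow(attr(pair, "dropped"))))
write_harmonized(pair, file.path(TABLE_DIR, "harmonized.tsv"))

# the LD reference is the discovery panel, regenerated from the seed
study <- simulate_study(study_config())
cl <- clump(pair, study$panel_disc)
cat(sprintf("clumping kept %d of %d SNPs as indices; Meff = %.1f, effective ratio = %.3f\n",
            length(cl$index_snps), cl$n_input, cl$effective_number,
            cl$effective_ratio))
write_clumps(cl, file.path(TABLE_DIR, "clumps.tsv"), pair)
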