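# Simulate the paired GWAS study: a quantitative coagulation-factor-like
# discovery trait (n = 2000) and a liability-threshold case-control stroke-
# like target (887 cases / 1493 controls), polygenic over a shared panel of
# 1500 SNPs in LD blocks, with SNP heritabilities 0.13 / 0.34 and a planted
# genetic correlation of -0.8 between the per-SNP effect vectors.

source("analysis/00_config.R")

cfg <- study_config()
study <- simulate_study(cfg)

write_sumstats(study$sumstats_disc, file.path(TABLE_DIR, "sumstats_discovery.tsv"))
write_sumstats(study$sumstats_targ, file.path(TABLE_DIR, "sumstats_target.tsv"))

truth <- data.frame(
  n_snps = cfg$n_snps,
  n_causal = cfg$n_causal,
  realized_h2_disc = study$truth$realized_h2_disc,
  realized_h2_targ = study$truth$realized_h2_targ,
  realized_rG = study$truth$realized_rG,
  n_disc = length(study$pheno_disc),
  n_cases = sum(study$status_targ == 1),
  n_controls = sum(study$status_targ == 0)
)
write.table(truth, file.path(TABLE_DIR, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf(
  "simulated study: %d discovery individuals, %d cases / %d controls,\n",
  truth$n_disc, truth$n_cases, truth$n_controls))
cat(sprintf(
  "  %d SNPs (%d causal), realized h2 = %.3f / %.3f, realized rG = %.3f\n",
  truth$n_snps, truth$n_causal, truth$realized_h2_disc,
  truth$realized_h2_targ, truth$realized_rG))
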