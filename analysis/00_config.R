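# Shared configuration for the analysis scripts. Every script regenerates
# the synthetic study deterministically from this seed, so stages can be
# run independently while operating on identical data.

library(pleioscan)

ANALYSIS_SEED <- 20260929L
TABLE_DIR <- "results/tables"
FIG_DIR <- "results/figures"
dir.create(TABLE_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(FIG_DIR, showWarnings = FALSE, recursive = TRUE)

study_config <- function() sim_config(seed = ANALYSIS_SEED)

# corrected alpha for a single discovery trait and a single target subtype
ALPHA_CORR <- corrected_alpha(meff = 1, n_subtypes = 1)
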