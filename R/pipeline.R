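#' Default pipeline configuration
#'
#' Returns the configuration list [run_pipeline()] consumes, populated
#' with the synthetic study defaults. Fields under `sim` are passed to
#' [sim_config()]; `clump` holds `r2_threshold`, `window_kb`,
#' `p_threshold`; `analysis` holds `min_maf`, `thresholds`, `alpha_raw`,
#' `n_subtypes`, `relatedness_cutoff`, `n_greml` (per-cohort GREML
#' subsample size; `0` disables the genotype arm).
#'
#' @param seed Seed stored into the simulation config.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    sim = list(seed = as.integer(seed)),
    clump = list(r2_threshold = 0.25, window_kb = 300, p_threshold = 1.0),
    analysis = list(min_maf = 0.05,
                    thresholds = default_threshold_grid(),
                    alpha_raw = 0.05, n_subtypes = 1,
                    relatedness_cutoff = 0.25,
                    n_greml = 450)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  for (sec in names(base)) {
    if (!is.null(config[[sec]])) {
      base[[sec]][names(config[[sec]])] <- config[[sec]]
    }
  }
  base
}

write_stage_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the three-arm cross-trait analysis end to end
#'
#' Orchestrates one discovery/target trait pair: simulate (or load) the
#' paired study, MAF-filter and allele-harmonize the summary tables,
#' LD-clump on discovery P, then run the concordance scan and the
#' joint-effect scan across inclusion thresholds, and — when genotypes are
#' available — the GREML arm (GRM on a per-cohort subsample mirroring a
#' genotyped validation subset, relatedness pruning, bivariate AI-REML
#' with an LRT for zero genetic correlation). Stage tables, a summary
#' report and a run manifest are written under `out_dir`; reruns with the
#' same configuration are byte-identical.
#'
#' Arm-level significance in the summary applies Bonferroni factors for
#' the three arms and, for the threshold-scan arms, the grid size, on top
#' of the Nyholt/subtype-corrected level; per-threshold labels inside the
#' scans use the corrected level itself.
#'
#' @param config A configuration list (see [default_pipeline_config()]),
#'   or the path of a YAML file holding one.
#' @param out_dir Output directory (created if needed).
#' @param study Optionally a pre-built `synthetic_study`; when `NULL` one
#'   is simulated from `config$sim`.
#' @return Invisibly, a list with all stage objects and the manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = "pipeline_out", study = NULL) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }

  if (is.null(study)) {
    sim <- do.call(sim_config, cfg$sim)
    study <- simulate_study(sim)
  } else {
    sim <- study$config
  }
  log_stage("simulate", "discovery n=", length(study$pheno_disc),
            ", target n=", length(study$status_targ),
            ", snps=", nrow(study$map))
  paths <- list()
  paths$sumstats_disc <- write_stage_table(study$sumstats_disc, out_dir,
                                           "sumstats_discovery.tsv")
  paths$sumstats_targ <- write_stage_table(study$sumstats_targ, out_dir,
                                           "sumstats_target.tsv")

  disc <- maf_filter(study$sumstats_disc, cfg$analysis$min_maf)
  targ <- maf_filter(study$sumstats_targ, cfg$analysis$min_maf)
  pair <- harmonize(disc, targ)
  log_stage("harmonize", nrow(pair), " shared SNPs (",
            nrow(attr(pair, "dropped")), " dropped)")
  paths$harmonized <- write_stage_table(pair, out_dir, "harmonized.tsv")

  cl <- clump(pair, study$panel_disc,
              r2_threshold = cfg$clump$r2_threshold,
              window_kb = cfg$clump$window_kb,
              p_threshold = cfg$clump$p_threshold)
  pair_cl <- pair[pair$snp_id %in% cl$index_snps, , drop = FALSE]
  class(pair_cl) <- class(pair)
  log_stage("clump", length(cl$index_snps), " index SNPs, effective ratio ",
            sprintf("%.3f", cl$effective_ratio))
  paths$clumps <- write_clumps(cl, file.path(out_dir, "clumps.tsv"), pair)

  # single discovery trait and single subtype: Meff = 1 by construction
  meff <- 1
  alpha_corr <- corrected_alpha(meff, cfg$analysis$n_subtypes,
                                cfg$analysis$alpha_raw)
  n_thr <- length(cfg$analysis$thresholds)
  n_arms <- if (cfg$analysis$n_greml > 0) 3 else 2
  alpha_scan_flag <- alpha_corr / (n_arms * n_thr)
  alpha_greml_flag <- alpha_corr / n_arms

  conc <- concordance_scan(pair_cl, cfg$analysis$thresholds,
                           alpha = alpha_corr)
  paths$concordance <- write_stage_table(conc, out_dir, "concordance.tsv")
  prs <- prs_threshold_scan(pair_cl, cfg$analysis$thresholds,
                            alpha = alpha_corr)
  paths$prs <- write_stage_table(prs, out_dir, "prs_scan.tsv")
  log_stage("scan", "concordance min P = ",
            format(min(conc$p, na.rm = TRUE), digits = 3),
            "; joint-effect min P = ", format(min(prs$p), digits = 3))

  greml_fit <- NULL
  if (cfg$analysis$n_greml > 0) {
    ng <- min(cfg$analysis$n_greml, length(study$pheno_disc),
              length(study$status_targ))
    sub_d <- subset_panel(study$panel_disc, individuals = seq_len(ng))
    # target individuals are ordered cases-then-controls; evenly spaced
    # indices keep the subsample stratified by status
    t_idx <- unique(round(seq(1, length(study$status_targ), length.out = ng)))
    sub_t <- subset_panel(study$panel_targ, individuals = t_idx)
    union_panel <- genotype_panel(
      rbind(sub_d$dosages, sub_t$dosages), sub_d$map,
      c(sub_d$individual_ids, sub_t$individual_ids))
    grm <- compute_grm(union_panel, maf_min = cfg$analysis$min_maf)
    n_before <- length(grm$individual_ids)
    kept <- prune_related(grm, cfg$analysis$relatedness_cutoff)
    ki <- match(kept, grm$individual_ids)
    grm$values <- grm$values[ki, ki, drop = FALSE]
    grm$individual_ids <- kept
    pheno_sub <- study$pheno_disc[seq_len(ng)]
    status_sub <- study$status_targ[t_idx]
    t1 <- rep(NA_real_, length(kept))
    t2 <- rep(NA_real_, length(kept))
    in_d <- kept %in% sub_d$individual_ids
    t1[in_d] <- pheno_sub[match(kept[in_d], sub_d$individual_ids)]
    t2[!in_d] <- status_sub[match(kept[!in_d], sub_t$individual_ids)]
    greml_fit <- reml_bivariate(grm, t1, t2)
    log_stage("greml", "rG = ", sprintf("%.3f", greml_fit$rG),
              ", LRT P = ", format(greml_fit$p_lrt, digits = 3),
              " (n = ", length(kept), ")")
    greml_df <- data.frame(
      n_used = length(kept), n_pruned = n_before - length(kept),
      h2_disc = greml_fit$h2_1, se_h2_disc = greml_fit$se_h2_1,
      h2_targ = greml_fit$h2_2, se_h2_targ = greml_fit$se_h2_2,
      rG = greml_fit$rG, se_rG = greml_fit$se_rG, p_lrt = greml_fit$p_lrt,
      converged = greml_fit$converged)
    paths$greml <- write_stage_table(greml_df, out_dir, "greml.tsv")
  }

  conc_ok <- !is.na(conc$p)
  conc_min <- min(conc$p[conc_ok])
  conc_dir <- conc$proportion[conc_ok][which.min(conc$p[conc_ok])]
  arms <- data.frame(
    arm = c("concordance", "joint_effect",
            if (!is.null(greml_fit)) "greml"),
    statistic = c(conc_min, min(prs$p),
                  if (!is.null(greml_fit)) greml_fit$p_lrt),
    direction = c(if (conc_dir < 0.5) "discordant" else "concordant",
                  if (prs$alpha_hat[which.min(prs$p)] < 0) "negative" else "positive",
                  if (!is.null(greml_fit)) {
                    if (greml_fit$rG < 0) "negative" else "positive"
                  }),
    flagged = c(conc_min <= alpha_scan_flag,
                min(prs$p) <= alpha_scan_flag,
                if (!is.null(greml_fit)) greml_fit$p_lrt <= alpha_greml_flag),
    stringsAsFactors = FALSE
  )
  paths$summary <- write_stage_table(arms, out_dir, "summary.tsv")

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = cfg$sim$seed,
    software_version = as.character(utils::packageVersion("pleioscan")),
    alpha_corrected = alpha_corr,
    stages = lapply(paths, function(p) {
      list(path = basename(p),
           n_records = length(readLines(p)) - 1L)
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage("done", "elapsed ",
            sprintf("%.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs"))))

  invisible(list(config = cfg, study = study, pair = pair, clumps = cl,
                 pair_clumped = pair_cl, concordance = conc, prs = prs,
                 greml = greml_fit, summary = arms,
                 alpha_corrected = alpha_corr, manifest = manifest,
                 out_dir = out_dir))
}
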