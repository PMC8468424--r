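#' Pipeline run configuration
#'
#' Everything that affects numbers lives here: input mode (`simulate` with a
#' [simulation_spec()], or `data` with file paths), the missing-dosage
#' policy, the PRS stratification (default quartiles with the 2nd quartile
#' as reference) and predicted-risk stratification (default deciles with the
#' 5th decile as reference), the classification threshold, the seed and the
#' output directory.
#'
#' @param mode `"simulate"` or `"data"`.
#' @param sim A [simulation_spec()] (simulate mode); default built from
#'   `seed`.
#' @param genotype_path,cohort_path,dialect Input files (data mode).
#' @param panel_path Optional panel override; default packaged panel.
#' @param missing_policy Passed to [compute_prs()].
#' @param prs_bins,prs_ref_bin PRS quantile stratification (defaults 4, 2).
#' @param risk_bins,risk_ref_bin Predicted-risk stratification (defaults
#'   10, 5).
#' @param threshold Classification threshold (default 0.5).
#' @param seed Integer seed (default 1).
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "data"), sim = NULL,
                       genotype_path = NULL, cohort_path = NULL,
                       dialect = "csv", panel_path = NULL,
                       missing_policy = "expected_dosage",
                       prs_bins = 4, prs_ref_bin = 2,
                       risk_bins = 10, risk_ref_bin = 5,
                       threshold = 0.5, seed = 1L, out_dir = tempfile("run_")) {
  mode <- match.arg(mode)
  stopifnot(prs_ref_bin <= prs_bins, risk_ref_bin <= risk_bins)
  if (mode == "data") {
    for (p in c(genotype_path, cohort_path)) {
      if (is.null(p) || !file.exists(p)) stop("input file missing: ", p)
    }
  }
  if (mode == "simulate" && is.null(sim)) {
    sim <- simulation_spec(seed = seed)
  }
  structure(list(mode = mode, sim = sim, genotype_path = genotype_path,
                 cohort_path = cohort_path, dialect = dialect,
                 panel_path = panel_path, missing_policy = missing_policy,
                 prs_bins = prs_bins, prs_ref_bin = prs_ref_bin,
                 risk_bins = risk_bins, risk_ref_bin = risk_ref_bin,
                 threshold = threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full PRS / integrated-risk pipeline
#'
#' Panel -> genotypes -> complete-case filter -> PRS -> per-SNP association
#' -> PRS quartile OR table -> integrated model with decile table,
#' calibration, discrimination and classification metrics. All numeric
#' outputs land in `config$out_dir`: `panel_echo.tsv`, `prs_scores.csv`,
#' `per_snp_association.tsv`, `prs_quantile_or.tsv`, `decile_table.tsv`,
#' `roc_coordinates.csv`, `metrics.json` and `run_manifest.json` (seed,
#' package version, row counts at every filter). Runs are deterministic
#' under a fixed seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`panel`, `cohort`,
#'   `filter_report`, `prs`, `prs_summary`, `prs_fit`, `prs_strata`,
#'   `per_snp`, `model`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- load_panel(config$panel_path)
  weights <- prs_weights(panel)

  if (config$mode == "simulate") {
    sim <- simulate_cohort(config$sim)
    cohort <- sim$cohort
    genotypes <- sim$genotypes
  } else {
    genotypes <- read_genotypes(config$genotype_path, config$dialect, panel)
    cohort <- read_cohort(config$cohort_path)
  }
  n_initial <- nrow(cohort)

  filtered <- complete_case_filter(cohort, genotypes)
  cohort <- filtered$cohort
  genotypes <- filtered$genotypes

  prs <- compute_prs(genotypes, weights, config$missing_policy,
                     status = cohort$status, panel = panel)
  prs_summary <- summarize_prs(prs, cohort$status)
  scaled <- scale_prs_by_controls(prs, cohort$status)
  fit_raw <- fit_logistic(cbind(intercept = 1, prs = prs$score),
                          cohort$status)
  fit_sd <- fit_logistic(cbind(intercept = 1, prs_sd = scaled),
                         cohort$status)
  prs_bins <- control_quantile_bins(prs$score, cohort$status,
                                    config$prs_bins)
  prs_strata <- stratified_or_table(prs_bins, cohort$status,
                                    config$prs_ref_bin)
  per_snp <- per_snp_association(genotypes, cohort$status)
  model <- integrated_model(cohort, prs, config$risk_bins,
                            config$risk_ref_bin, config$threshold)

  paths <- list(
    panel = file.path(config$out_dir, "panel_echo.tsv"),
    scores = file.path(config$out_dir, "prs_scores.csv"),
    per_snp = file.path(config$out_dir, "per_snp_association.tsv"),
    prs_strata = file.path(config$out_dir, "prs_quantile_or.tsv"),
    deciles = file.path(config$out_dir, "decile_table.tsv"),
    roc = file.path(config$out_dir, "roc_coordinates.csv"),
    metrics = file.path(config$out_dir, "metrics.json"),
    manifest = file.path(config$out_dir, "run_manifest.json")
  )
  write.table(panel, paths$panel, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.csv(data.frame(prs[, c("individual_id", "score", "n_imputed")],
                       bin = prs_bins),
            paths$scores, row.names = FALSE, quote = FALSE)
  write.table(per_snp, paths$per_snp, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(as.data.frame(prs_strata), paths$prs_strata, sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(as.data.frame(model$strata), paths$deciles, sep = "\t",
              row.names = FALSE, quote = FALSE)
  thr <- sort(unique(model$p_hat))
  roc <- t(vapply(thr, function(t0) sens_spec(model$p_hat, cohort$status,
                                              min(max(t0, 1e-9), 1 - 1e-9)),
                  numeric(2)))
  write.csv(data.frame(threshold = thr, roc), paths$roc,
            row.names = FALSE, quote = FALSE)

  metrics <- list(
    prs_or_raw = as.list(wald_or(fit_raw, "prs")),
    prs_or_per_control_sd = as.list(wald_or(fit_sd, "prs_sd")),
    prs_mean_cases = prs_summary$mean[prs_summary$group == "cases"],
    prs_mean_controls = prs_summary$mean[prs_summary$group == "controls"],
    auc = model$discrimination$auc,
    auc_ci = c(model$discrimination$ci_low, model$discrimination$ci_high),
    hl_chi2 = model$calibration$chi2,
    hl_df = model$calibration$df,
    hl_p = model$calibration$p,
    sensitivity = model$classification[["sensitivity"]],
    specificity = model$classification[["specificity"]]
  )
  jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    seed = config$seed,
    mode = config$mode,
    package_version = as.character(utils::packageVersion("polyrisk")),
    n_initial = n_initial,
    n_complete_case = nrow(cohort),
    removed_by_field = as.list(filtered$report$removed_by_field),
    removed_by_status = as.list(filtered$report$removed_by_status),
    genotype_flips = attr(genotypes, "flipped") %||% character(0)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(panel = panel, cohort = cohort,
                 filter_report = filtered$report, prs = prs,
                 prs_summary = prs_summary, prs_fit = fit_raw,
                 prs_fit_per_sd = fit_sd, prs_strata = prs_strata,
                 per_snp = per_snp, model = model, paths = paths))
}
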