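#' Design matrix for the integrated risk model
#'
#' Intercept, PRS, and the ten classical risk factors: binary factors as
#' 0/1 indicators, age at menarche, height and BMI linear, and the FFTP age
#' category as indicator contrasts for bands 1-4 with the nulliparous code
#' folded into the reference band 0. Breastfeeding enters as 0 for
#' nulliparous women (it is defined only among parous women).
#'
#' @param cohort A complete-case `cohort_table`.
#' @param prs Numeric PRS per individual, aligned with the cohort rows (or
#'   the data frame from [compute_prs()], matched by `individual_id`).
#' @return Numeric design matrix with named columns.
#' @export
integrated_design <- function(cohort, prs) {
  if (is.data.frame(prs)) {
    idx <- match(cohort$individual_id, prs$individual_id)
    if (anyNA(idx)) stop("cohort ids absent from the PRS table")
    prs <- prs$score[idx]
  }
  stopifnot(length(prs) == nrow(cohort))
  fftp <- cohort$age_fftp_cat
  fftp[fftp == nulliparous_code()] <- 0L
  bf <- cohort$breastfed
  bf[is.na(bf) & cohort$parous == 0L] <- 0L
  design <- cbind(
    intercept = 1,
    prs = prs,
    menopausal = cohort$menopausal,
    age_menarche = cohort$age_menarche,
    parous = cohort$parous,
    fftp_cat1 = as.numeric(fftp == 1L),
    fftp_cat2 = as.numeric(fftp == 2L),
    fftp_cat3 = as.numeric(fftp == 3L),
    fftp_cat4 = as.numeric(fftp == 4L),
    breastfed = bf,
    height_cm = cohort$height_cm,
    bmi = cohort$bmi,
    hrt = cohort$hrt,
    smoker = cohort$smoker,
    family_history = cohort$family_history
  )
  if (anyNA(design)) {
    stop("integrated model needs complete-case inputs; run ",
         "complete_case_filter() first")
  }
  # drop constant non-intercept columns (e.g. an FFTP band absent from a
  # small sample), as factor-level dropping would in a formula interface
  constant <- apply(design[, -1, drop = FALSE], 2,
                    function(col) length(unique(col)) == 1)
  if (any(constant)) {
    dropped <- colnames(design)[-1][constant]
    design <- design[, c(TRUE, !constant), drop = FALSE]
    attr(design, "dropped") <- dropped
  }
  design
}

#' Fit and evaluate the integrated risk model
#'
#' Fits the multivariable logistic model of case/control status on the PRS
#' and the ten classical risk factors, then evaluates its full surface:
#' predicted-probability deciles of the pooled analysis sample with per-bin
#' odds ratios against a reference decile, Hosmer-Lemeshow calibration,
#' AUC with DeLong interval, and sensitivity/specificity at a probability
#' threshold. Decile cut-points use the pooled (cases + controls)
#' distribution, unlike the control-anchored PRS quantiles.
#'
#' @param cohort A complete-case `cohort_table`.
#' @param prs PRS per individual (vector or [compute_prs()] output).
#' @param n_bins Number of predicted-risk bins (default 10).
#' @param ref_bin Reference bin (default 5).
#' @param threshold Classification threshold for sensitivity/specificity
#'   (default 0.5).
#' @param hl_groups Hosmer-Lemeshow groups (default 10).
#' @return List of class `integrated_model`: `fit` (a `logistic_fit`),
#'   `p_hat`, `bins`, `strata` (a `stratum_table`), `calibration`
#'   (`hl_test`), `discrimination` (`auc_result`), `classification`
#'   (sensitivity/specificity), `n`.
#' @export
integrated_model <- function(cohort, prs, n_bins = 10, ref_bin = 5,
                             threshold = 0.5, hl_groups = 10) {
  design <- integrated_design(cohort, prs)
  y <- cohort$status
  fit <- fit_logistic(design, y)
  p_hat <- fit$fitted
  bins <- quantile_bins(p_hat, p_hat, n_bins)
  strata <- stratified_or_table(bins, y, ref_bin)
  structure(list(
    fit = fit,
    p_hat = p_hat,
    bins = bins,
    strata = strata,
    calibration = hosmer_lemeshow(p_hat, y, hl_groups),
    discrimination = auc_delong(p_hat, y),
    classification = sens_spec(p_hat, y, threshold),
    n = length(y)
  ), class = "integrated_model")
}

#' @export
print.integrated_model <- function(x, ...) {
  cat("Integrated risk model,", x$n, "individuals\n")
  print(x$discrimination)
  print(x$calibration)
  cat(sprintf("sensitivity %.3f, specificity %.3f\n",
              x$classification[["sensitivity"]],
              x$classification[["specificity"]]))
  invisible(x)
}
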