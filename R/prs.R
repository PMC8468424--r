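#' Compute polygenic risk scores
#'
#' Per-individual score `sum_k beta_k * x_k`, where `x_k` is the minor-allele
#' dosage at SNP k and `beta_k` the log of the published per-allele OR.
#' Missing dosages are handled by policy:
#'
#' * `expected_dosage` (default): fill with `2 * control minor-allele
#'   frequency`, computed from the supplied cohort's controls when `status`
#'   is given, otherwise from the panel's published frequencies (unbiased
#'   under Hardy-Weinberg; keeps the sample size).
#' * `zero`: missing dosages contribute nothing.
#' * `drop_individual`: individuals with any missing dosage are removed.
#'
#' @param genotypes Dosage matrix with rsID column names.
#' @param weights Weight table from [prs_weights()].
#' @param missing_policy One of `"expected_dosage"`, `"zero"`,
#'   `"drop_individual"`.
#' @param status Optional 0/1 vector aligned with the genotype rows; used
#'   only to compute control allele frequencies for `expected_dosage`.
#' @param panel Optional `snp_panel` supplying published frequencies when no
#'   `status` is given.
#' @return A data frame with columns `individual_id`, `score`, `n_imputed`.
#' @export
compute_prs <- function(genotypes, weights,
                        missing_policy = c("expected_dosage", "zero",
                                           "drop_individual"),
                        status = NULL, panel = NULL) {
  missing_policy <- match.arg(missing_policy)
  absent <- setdiff(weights$rsid, colnames(genotypes))
  if (length(absent) > 0) {
    stop("weight(s) without matching genotype column: ",
         paste(absent, collapse = ", "))
  }
  geno <- genotypes[, weights$rsid, drop = FALSE]
  n_imputed <- rowSums(is.na(geno))
  ids <- rownames(geno) %||% as.character(seq_len(nrow(geno)))

  if (missing_policy == "drop_individual") {
    keep <- n_imputed == 0
    geno <- geno[keep, , drop = FALSE]
    ids <- ids[keep]
    n_imputed <- rep(0L, nrow(geno))
  } else if (any(n_imputed > 0)) {
    fill <- if (missing_policy == "zero") {
      rep(0, ncol(geno))
    } else if (!is.null(status)) {
      if (!any(status == 0)) stop("no controls available to impute from")
      # mean control dosage = 2 * control minor-allele frequency
      colMeans(geno[status == 0, , drop = FALSE], na.rm = TRUE)
    } else if (!is.null(panel)) {
      2 * panel$eaf_published[match(colnames(geno), panel$rsid)]
    } else {
      stop("expected_dosage policy needs either status (for control ",
           "frequencies) or a panel (for published frequencies)")
    }
    for (j in seq_len(ncol(geno))) {
      miss <- is.na(geno[, j])
      if (any(miss)) geno[miss, j] <- fill[j]
    }
  }
  score <- as.numeric(geno %*% weights$beta)
  data.frame(individual_id = ids, score = score,
             n_imputed = as.integer(n_imputed), stringsAsFactors = FALSE)
}

#' Summarize PRS by case/control status
#'
#' @param scores Numeric scores or the data frame from [compute_prs()].
#' @param status 0/1 vector aligned with the scores.
#' @return Data frame with rows `controls`, `cases`, `overall` and columns
#'   `n`, `mean`, `sd`.
#' @export
summarize_prs <- function(scores, status) {
  if (is.data.frame(scores)) scores <- scores$score
  stopifnot(length(scores) == length(status))
  if (!any(status == 0) || !any(status == 1)) {
    stop("both cases and controls are required")
  }
  grp <- list(controls = scores[status == 0], cases = scores[status == 1],
              overall = scores)
  data.frame(group = names(grp),
             n = vapply(grp, length, integer(1)),
             mean = vapply(grp, mean, numeric(1)),
             sd = vapply(grp, sd, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scale scores by the control-group standard deviation
#'
#' Emits the auxiliary per-control-SD score, so associations can be reported
#' per standard deviation of the control distribution as well as per raw
#' score unit.
#'
#' @param scores Numeric scores.
#' @param status 0/1 vector aligned with the scores.
#' @return Scores divided by the control SD.
#' @export
scale_prs_by_controls <- function(scores, status) {
  if (is.data.frame(scores)) scores <- scores$score
  s <- sd(scores[status == 0])
  if (!is.finite(s) || s == 0) stop("control scores are degenerate")
  scores / s
}

# shared binning rule: type-7 quantile cut-points of the anchor values,
# half-open intervals [lower, upper), last bin closed above
quantile_bins <- function(values, anchor, n_bins) {
  stopifnot(n_bins >= 2)
  if (length(unique(anchor)) < n_bins) {
    stop("anchor distribution is degenerate: fewer than n_bins distinct ",
         "values")
  }
  cuts <- quantile(anchor, probs = seq_len(n_bins - 1) / n_bins,
                   type = 7, names = FALSE)
  as.integer(findInterval(values, cuts) + 1L)
}

#' Assign individuals to control-anchored quantile bins
#'
#' Cut-points are the 1/n, ..., (n-1)/n quantiles (type 7, linear
#' interpolation) of the CONTROL score distribution; every individual, case
#' or control, falls in the bin whose half-open interval \[lower, upper)
#' contains its score, with the last bin closed above. With `n_bins = 4`
#' this is the quartile stratification of the PRS "standardized by the
#' controls".
#'
#' @param scores Numeric scores or the data frame from [compute_prs()].
#' @param status 0/1 vector aligned with the scores.
#' @param n_bins Number of bins (default 4).
#' @return Integer bin index per individual, 1-based.
#' @export
control_quantile_bins <- function(scores, status, n_bins = 4) {
  if (is.data.frame(scores)) scores <- scores$score
  stopifnot(length(scores) == length(status))
  if (!any(status == 0)) stop("no controls to anchor the quantiles")
  quantile_bins(scores, scores[status == 0], n_bins)
}
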