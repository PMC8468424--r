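#' Closed-form odds ratio for a 2x2 table
#'
#' Point estimate `(cases_exposed * controls_ref) / (controls_exposed *
#' cases_ref)` with the Wald interval on the log scale,
#' `se = sqrt(sum(1/count))`, and a two-sided normal p-value. Zero cells are
#' rejected (no continuity correction): use the logistic route or add a
#' correction upstream.
#'
#' @param cases_exposed,controls_exposed Counts in the exposed (index)
#'   group.
#' @param cases_ref,controls_ref Counts in the reference group.
#' @param level Confidence level (default 0.95).
#' @return Named vector `or`, `ci_low`, `ci_high`, `p`.
#' @export
or_2x2 <- function(cases_exposed, controls_exposed, cases_ref, controls_ref,
                   level = 0.95) {
  counts <- c(cases_exposed, controls_exposed, cases_ref, controls_ref)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts == 0)) {
    stop("zero cell in 2x2 table; use the logistic route or a continuity ",
         "correction")
  }
  log_or <- log(cases_exposed) + log(controls_ref) -
    log(controls_exposed) - log(cases_ref)
  se <- sqrt(sum(1 / counts))
  z <- qnorm(1 - (1 - level) / 2)
  c(or = exp(log_or), ci_low = exp(log_or - z * se),
    ci_high = exp(log_or + z * se), p = 2 * pnorm(-abs(log_or / se)))
}

#' Per-SNP univariable association
#'
#' For each SNP, a univariable logistic regression of case/control status on
#' the minor-allele dosage, plus the control effect-allele frequency (mean
#' control dosage / 2). Monomorphic SNPs are flagged and carry no estimate.
#'
#' @param genotypes Dosage matrix (individuals x SNPs), no missing entries.
#' @param y Binary status vector aligned with the rows.
#' @return Data frame with one row per SNP: `rsid`, `eaf_controls`, `or`,
#'   `ci_low`, `ci_high`, `p`, `monomorphic`.
#' @export
per_snp_association <- function(genotypes, y) {
  stopifnot(nrow(genotypes) == length(y))
  res <- lapply(seq_len(ncol(genotypes)), function(j) {
    x <- genotypes[, j]
    eaf <- mean(x[y == 0], na.rm = TRUE) / 2
    if (length(unique(x[!is.na(x)])) < 2) {
      return(data.frame(rsid = colnames(genotypes)[j], eaf_controls = eaf,
                        or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        monomorphic = TRUE))
    }
    ok <- !is.na(x)
    fit <- fit_logistic(cbind(intercept = 1, dosage = x[ok]), y[ok])
    w <- wald_or(fit, "dosage")
    data.frame(rsid = colnames(genotypes)[j], eaf_controls = eaf,
               or = w[["or"]], ci_low = w[["ci_low"]],
               ci_high = w[["ci_high"]], p = w[["p"]], monomorphic = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Spearman rho with mid-rank ties and the two-sided t approximation
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(c(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  if (sd(rx) == 0 || sd(ry) == 0) return(c(rho = NA_real_, p = NA_real_,
                                           n = n))
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) / ((n - 1) * sd(rx) * sd(ry))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  c(rho = rho, p = p, n = n)
}

#' Pairwise Spearman correlation screen
#'
#' Rank correlations (mid-rank ties, pairwise-complete observations,
#' two-sided p by the t approximation) between every pair of the supplied
#' columns -- typically the PRS and the ten classical risk factors,
#' restricted to the control group, as a screen for dependence between the
#' score and the factors. Constant columns are flagged with an undefined
#' correlation.
#'
#' @param data Data frame of numeric columns to correlate (e.g. risk
#'   factors plus a `prs` column).
#' @param status Optional 0/1 vector; with `restrict_to` it selects the
#'   analysis subgroup.
#' @param restrict_to Status value to keep (default 0 = controls) when
#'   `status` is supplied.
#' @return Data frame with columns `var1`, `var2`, `rho`, `p`, `n`.
#' @export
spearman_screen <- function(data, status = NULL, restrict_to = 0L) {
  if (!is.null(status)) {
    data <- data[status == restrict_to, , drop = FALSE]
  }
  vars <- names(data)
  if (length(vars) < 2) stop("need at least two columns to correlate")
  pairs <- utils::combn(vars, 2)
  res <- apply(pairs, 2, function(pr) {
    spearman_rho(as.numeric(data[[pr[1]]]), as.numeric(data[[pr[2]]]))
  })
  data.frame(var1 = pairs[1, ], var2 = pairs[2, ],
             rho = res["rho", ], p = res["p", ], n = as.integer(res["n", ]),
             stringsAsFactors = FALSE)
}
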