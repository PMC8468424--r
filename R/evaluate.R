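#' Per-bin odds-ratio table against a reference bin
#'
#' One row per quantile bin: case/control counts, percentages of each status
#' group's total, and the odds ratio of each bin against the reference bin
#' with Wald CI and two-sided p. Bins empty of one status are flagged and
#' carry no estimate. The reference row carries OR 1 and no interval.
#'
#' @param bins Integer bin assignment per individual (1-based).
#' @param y Binary status vector aligned with `bins`.
#' @param ref_bin Reference bin index; must contain both statuses.
#' @return Data frame of class `stratum_table` with columns `bin`,
#'   `n_controls`, `n_cases`, `pct_controls`, `pct_cases`, `or`, `ci_low`,
#'   `ci_high`, `p`, `is_reference`, `estimable`.
#' @export
stratified_or_table <- function(bins, y, ref_bin) {
  stopifnot(length(bins) == length(y))
  levels_ <- sort(unique(bins))
  if (!ref_bin %in% levels_) stop("reference bin ", ref_bin, " is empty")
  n_cases <- vapply(levels_, function(b) sum(y == 1 & bins == b), numeric(1))
  n_controls <- vapply(levels_, function(b) sum(y == 0 & bins == b),
                       numeric(1))
  ref_idx <- match(ref_bin, levels_)
  if (n_cases[ref_idx] == 0 || n_controls[ref_idx] == 0) {
    stop("reference bin must contain both cases and controls")
  }
  out <- data.frame(
    bin = levels_,
    n_controls = as.integer(n_controls),
    n_cases = as.integer(n_cases),
    pct_controls = 100 * n_controls / sum(n_controls),
    pct_cases = 100 * n_cases / sum(n_cases),
    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
    is_reference = levels_ == ref_bin,
    estimable = TRUE
  )
  for (i in seq_along(levels_)) {
    if (i == ref_idx) {
      out$or[i] <- 1
      next
    }
    if (n_cases[i] == 0 || n_controls[i] == 0) {
      out$estimable[i] <- FALSE
      next
    }
    w <- or_2x2(n_cases[i], n_controls[i],
                n_cases[ref_idx], n_controls[ref_idx])
    out$or[i] <- w[["or"]]
    out$ci_low[i] <- w[["ci_low"]]
    out$ci_high[i] <- w[["ci_high"]]
    out$p[i] <- w[["p"]]
  }
  class(out) <- c("stratum_table", "data.frame")
  out
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Individuals are sorted by predicted probability and split into
#' `n_groups` near-equal groups; tied probabilities never straddle a group
#' boundary (the boundary shifts to the next distinct value). The statistic
#' sums `(O - E)^2 / E` over the event and non-event cells of every group
#' and is referred to a chi-square with `groups - 2` degrees of freedom.
#'
#' @param p_hat Predicted probabilities in (0, 1).
#' @param y Binary outcomes aligned with `p_hat`.
#' @param n_groups Number of risk groups (default 10).
#' @return List of class `hl_test`: `chi2`, `df`, `p`, and a per-group
#'   table of sizes, observed and expected events.
#' @export
hosmer_lemeshow <- function(p_hat, y, n_groups = 10) {
  stopifnot(length(p_hat) == length(y), n_groups >= 1)
  if (any(p_hat <= 0 | p_hat >= 1)) {
    stop("predicted probabilities must lie strictly in (0, 1)")
  }
  if (length(y) < n_groups) stop("fewer observations than groups")
  ord <- order(p_hat)
  p_s <- p_hat[ord]
  y_s <- y[ord]
  n <- length(y_s)
  # near-equal target boundaries, extended so ties stay together
  targets <- round(seq_len(n_groups) * n / n_groups)
  boundaries <- integer(0)
  for (tgt in targets[-n_groups]) {
    b <- tgt
    while (b < n && p_s[b + 1] == p_s[b]) b <- b + 1
    boundaries <- c(boundaries, b)
  }
  boundaries <- unique(c(boundaries[boundaries < n], n))
  start <- c(1L, head(boundaries, -1L) + 1L)
  groups <- data.frame(
    group = seq_along(boundaries),
    n = boundaries - start + 1L,
    observed = vapply(seq_along(boundaries), function(g)
      sum(y_s[start[g]:boundaries[g]]), numeric(1)),
    expected = vapply(seq_along(boundaries), function(g)
      sum(p_s[start[g]:boundaries[g]]), numeric(1))
  )
  if (any(groups$expected == 0 | groups$n - groups$expected == 0)) {
    stop("a group has zero expected events or non-events; use fewer groups")
  }
  chi2 <- sum((groups$observed - groups$expected)^2 / groups$expected +
              ((groups$n - groups$observed) - (groups$n - groups$expected))^2 /
                (groups$n - groups$expected))
  df <- nrow(groups) - 2L
  structure(list(chi2 = chi2, df = df,
                 p = if (df >= 1) pchisq(chi2, df, lower.tail = FALSE)
                     else NA_real_,
                 groups = groups),
            class = "hl_test")
}

#' @export
print.hl_test <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.4g on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' AUC with the DeLong confidence interval
#'
#' The AUC is the Mann-Whitney probability that a random case scores above
#' a random control, ties counted one half. Its standard error uses the
#' DeLong case/control placement values: `var = var(V10)/m + var(V01)/n`
#' for m cases and n controls, with a Wald interval clipped to \[0, 1\].
#'
#' @param scores Numeric risk scores or predicted probabilities.
#' @param y Binary status aligned with `scores`.
#' @param level Confidence level (default 0.95).
#' @return List of class `auc_result`: `auc`, `se`, `ci_low`, `ci_high`.
#' @export
auc_delong <- function(scores, y, level = 0.95) {
  stopifnot(length(scores) == length(y))
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  m <- length(cases)
  n <- length(controls)
  if (m == 0 || n == 0) stop("both cases and controls are required")
  # placement of each case among controls and vice versa
  r <- rank(c(cases, controls), ties.method = "average")
  v10 <- (r[seq_len(m)] - rank(cases, ties.method = "average")) / n
  v01 <- 1 - (r[m + seq_len(n)] - rank(controls, ties.method = "average")) / m
  auc <- mean(v10)
  se <- if (m > 1 && n > 1) sqrt(var(v10) / m + var(v01) / n) else NA_real_
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(auc = auc, se = se,
                 ci_low = max(0, auc - z * se),
                 ci_high = min(1, auc + z * se)),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%.0f%% DeLong CI %.4f-%.4f)\n", x$auc,
              95, x$ci_low, x$ci_high))
  invisible(x)
}

#' Sensitivity and specificity at a probability threshold
#'
#' Prediction is positive iff `p_hat >= threshold`. Sensitivity is the
#' fraction of cases predicted positive; specificity the fraction of
#' controls predicted negative.
#'
#' @param p_hat Predicted probabilities.
#' @param y Binary status aligned with `p_hat`.
#' @param threshold Classification threshold in (0, 1), default 0.5.
#' @return Named vector `sensitivity`, `specificity`.
#' @export
sens_spec <- function(p_hat, y, threshold = 0.5) {
  stopifnot(length(p_hat) == length(y))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (!any(y == 1) || !any(y == 0)) {
    stop("both cases and controls are required")
  }
  pos <- p_hat >= threshold
  c(sensitivity = mean(pos[y == 1]), specificity = mean(!pos[y == 0]))
}
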