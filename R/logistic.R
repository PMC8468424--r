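#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression fitted by IRLS on a design matrix
#' that already carries its intercept column. Convergence is declared when
#' the relative change in log-likelihood falls below `tol`. Rank deficiency
#' is a hard error naming the collinear columns. Complete or quasi-complete
#' separation (a coefficient diverging beyond 15 in absolute value) yields a
#' flagged, non-converged result rather than silent output.
#'
#' @param design Numeric matrix, n x p, including an intercept column;
#'   column names become coefficient names.
#' @param y Binary 0/1 response, not constant.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-10).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @return An object of class `logistic_fit`: `coefficients`,
#'   `standard_errors`, `covariance`, `log_likelihood`, `fitted` (per-row
#'   probabilities), `n_iterations`, `converged`, `separation`.
#' @export
fit_logistic <- function(design, y, tol = 1e-10, max_iter = 100L) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(design), all(y %in% c(0, 1)))
  if (all(y == y[1])) stop("response is constant; cannot fit")
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[-seq_len(qr_d$rank)]]
    stop("design is rank deficient; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }

  p <- ncol(design)
  beta <- numeric(p)
  eta <- drop(design %*% beta)
  mu <- plogis(eta)
  ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    fit <- qr(design * sw)
    beta_new <- qr.coef(fit, z * sw)
    eta <- drop(design %*% beta_new)
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ll_new <- sum(y * log(mu) + (1 - y) * log1p(-mu))
    beta <- beta_new
    if (any(abs(beta) > 15)) {
      separation <- TRUE
      ll <- ll_new
      break
    }
    if (abs(ll_new - ll) < tol * (abs(ll) + tol)) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(design * sqrt(w))
  covariance <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(covariance) <- list(colnames(design), colnames(design))
  se <- sqrt(diag(covariance))
  structure(list(
    term_names = colnames(design),
    coefficients = setNames(drop(beta), colnames(design)),
    standard_errors = se,
    covariance = covariance,
    log_likelihood = ll,
    fitted = mu,
    n_iterations = iter,
    converged = converged && !separation,
    separation = separation
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit (IRLS):", length(x$coefficients), "terms,",
      x$n_iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      if (x$separation) "(separation detected)" else "", "\n")
  print(data.frame(coef = x$coefficients, se = x$standard_errors))
  invisible(x)
}

#' Wald odds ratio for one model term
#'
#' `OR = exp(b)` with `CI = exp(b +/- z * se)` and a two-sided normal
#' p-value on `b / se`.
#'
#' @param fit A `logistic_fit`.
#' @param term Coefficient name.
#' @param level Confidence level (default 0.95).
#' @return Named vector `or`, `ci_low`, `ci_high`, `p`.
#' @export
wald_or <- function(fit, term, level = 0.95) {
  if (!term %in% fit$term_names) stop("unknown term: ", term)
  b <- fit$coefficients[[term]]
  se <- fit$standard_errors[[term]]
  z <- qnorm(1 - (1 - level) / 2)
  c(or = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se),
    p = 2 * pnorm(-abs(b / se)))
}
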