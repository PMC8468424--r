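#' Default covariate generating specification
#'
#' Marginal distributions and generating log odds ratios for the ten
#' classical risk factors used by the cohort simulator. These values are a
#' documented plausible set for a population of screening-age women (they do
#' not come from any published fit): binary factors carry a prevalence,
#' continuous factors a mean/SD and a per-unit log-OR (centred at the mean
#' when the linear predictor is formed, so the intercept keeps its
#' population-prevalence meaning), and the FFTP age category carries
#' category probabilities among parous women plus per-category log-ORs
#' relative to the youngest band. Breastfeeding is generated only for parous
#' women; nulliparous women receive the [nulliparous_code()] FFTP code and a
#' structural 0 for breastfeeding.
#'
#' @return A named list, one entry per risk factor.
#' @export
default_covariate_spec <- function() {
  list(
    menopausal     = list(type = "binary", prevalence = 0.65,
                          beta = log(1.3)),
    age_menarche   = list(type = "continuous", mean = 13, sd = 1.5,
                          beta = log(0.95)),
    parous         = list(type = "binary", prevalence = 0.85,
                          beta = log(0.8)),
    age_fftp_cat   = list(type = "ordinal",
                          probs = c(0.15, 0.35, 0.30, 0.15, 0.05),
                          betas = log(1.12) * 0:4),
    breastfed      = list(type = "binary", prevalence = 0.70,
                          beta = log(0.85)),
    height_cm      = list(type = "continuous", mean = 162, sd = 6,
                          beta = log(1.01)),
    bmi            = list(type = "continuous", mean = 27, sd = 4.5,
                          beta = log(1.02)),
    hrt            = list(type = "binary", prevalence = 0.25,
                          beta = log(1.2)),
    smoker         = list(type = "binary", prevalence = 0.30,
                          beta = log(1.1)),
    family_history = list(type = "binary", prevalence = 0.12,
                          beta = log(1.6))
  )
}

#' Build a cohort simulation specification
#'
#' Bundles everything the simulator needs: case/control quotas, the SNP
#' panel with generating per-SNP log-ORs, covariate marginals and effects,
#' the population disease prevalence (to which the logistic intercept is
#' calibrated) or a fixed intercept, per-field missingness rates and a seed.
#' Defaults reproduce the sampling frame of a retrospective breast-cancer
#' case-control study: 1109 cases and 1177 controls, Hardy-Weinberg
#' genotypes at the published panel frequencies, and disease assigned by a
#' logistic model with the published iCOGS effect sizes.
#'
#' @param n_cases,n_controls Sampling quotas (defaults 1109 / 1177).
#' @param panel A `snp_panel`; default the packaged 15-SNP panel.
#' @param snp_betas Generating per-SNP log-ORs for the minor-allele dosage,
#'   in panel order; default `log(panel$or_published)`.
#' @param covariate_spec As [default_covariate_spec()]; set a factor's
#'   `beta`(s) to 0 for a null covariate, or pass `NULL` to simulate
#'   genotype-only risk.
#' @param prevalence Target population disease prevalence in (0, 1) to which
#'   the intercept is calibrated; default 0.1. Ignored when `intercept` is
#'   given.
#' @param intercept Optional fixed logistic intercept.
#' @param missing_rates Named vector of per-field missingness probabilities
#'   (risk-factor columns only); default none.
#' @param seed Integer seed; default 1.
#' @param max_draws Cap on population draws before the quota search aborts.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_cases = 1109, n_controls = 1177,
                            panel = load_panel(),
                            snp_betas = log(panel$or_published),
                            covariate_spec = default_covariate_spec(),
                            prevalence = 0.1, intercept = NULL,
                            missing_rates = NULL, seed = 1L,
                            max_draws = 2e6) {
  stopifnot(n_cases >= 1, n_controls >= 1)
  validate_panel(panel)
  if (length(snp_betas) != nrow(panel)) {
    stop("snp_betas must have one value per panel SNP")
  }
  if (!all(is.finite(snp_betas))) stop("snp_betas must be finite")
  if (is.null(intercept)) {
    if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
      stop("prevalence must lie in (0, 1)")
    }
  }
  if (!is.null(missing_rates)) {
    if (is.null(names(missing_rates)) ||
        !all(names(missing_rates) %in% risk_factor_names())) {
      stop("missing_rates must be named after risk-factor columns")
    }
    if (any(missing_rates < 0 | missing_rates > 1)) {
      stop("missing rates must lie in [0, 1]")
    }
  }
  if (!is.null(covariate_spec)) validate_covariate_spec(covariate_spec)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 panel = panel, snp_betas = as.numeric(snp_betas),
                 covariate_spec = covariate_spec,
                 prevalence = if (is.null(intercept)) prevalence else NA_real_,
                 intercept = intercept,
                 missing_rates = missing_rates,
                 seed = as.integer(seed), max_draws = max_draws),
            class = "simulation_spec")
}

validate_covariate_spec <- function(covariate_spec) {
  for (nm in names(covariate_spec)) {
    cs <- covariate_spec[[nm]]
    if (cs$type == "binary") {
      stopifnot(cs$prevalence >= 0, cs$prevalence <= 1, is.finite(cs$beta))
    } else if (cs$type == "continuous") {
      stopifnot(cs$sd > 0, is.finite(cs$beta))
    } else if (cs$type == "ordinal") {
      stopifnot(abs(sum(cs$probs) - 1) < 1e-8, all(cs$probs >= 0),
                length(cs$betas) == length(cs$probs),
                all(is.finite(cs$betas)))
    } else stop("unknown covariate type: ", cs$type)
  }
  invisible(covariate_spec)
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each dosage is drawn independently as Binomial(2, maf), i.e. genotype
#' class probabilities (1-p)^2, 2p(1-p), p^2.
#'
#' @param n Number of individuals.
#' @param mafs Minor-allele frequencies in \[0, 0.5\]; names become column
#'   names.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return Integer dosage matrix, n x length(mafs).
#' @export
simulate_genotypes <- function(n, mafs, seed = NULL) {
  if (any(mafs < 0 | mafs > 0.5)) stop("each maf must lie in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  geno <- vapply(mafs, function(p) rbinom(n, 2L, p), integer(n))
  if (n == 1L) geno <- matrix(geno, nrow = 1L, dimnames = list(NULL, names(mafs)))
  geno
}

#' Simulate classical risk-factor covariates
#'
#' Draws each factor from its marginal in `covariate_spec`. Breastfeeding is
#' drawn only for parous women (structural 0 otherwise) and nulliparous
#' women receive the [nulliparous_code()] FFTP category.
#'
#' @param n Number of individuals.
#' @param covariate_spec As [default_covariate_spec()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A data frame with the ten risk-factor columns.
#' @export
simulate_covariates <- function(n, covariate_spec = default_covariate_spec(),
                                seed = NULL) {
  validate_covariate_spec(covariate_spec)
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(row.names = seq_len(n))
  draw <- function(cs, n) {
    switch(cs$type,
      binary = rbinom(n, 1L, cs$prevalence),
      continuous = rnorm(n, cs$mean, cs$sd),
      ordinal = sample.int(length(cs$probs), n, replace = TRUE,
                           prob = cs$probs) - 1L)
  }
  for (nm in setdiff(risk_factor_names(), c("age_fftp_cat", "breastfed"))) {
    out[[nm]] <- draw(covariate_spec[[nm]], n)
  }
  parous <- out$parous
  fftp <- rep(nulliparous_code(), n)
  fftp[parous == 1L] <- draw(covariate_spec$age_fftp_cat, sum(parous == 1L))
  out$age_fftp_cat <- as.integer(fftp)
  bf <- integer(n)
  bf[parous == 1L] <- draw(covariate_spec$breastfed, sum(parous == 1L))
  out$breastfed <- bf
  out[, risk_factor_names()]
}

# linear-predictor contribution of the covariates (continuous terms centred
# at their generating mean so the intercept retains its prevalence meaning)
covariate_linear_predictor <- function(covariates, covariate_spec) {
  eta <- numeric(nrow(covariates))
  if (is.null(covariate_spec)) return(eta)
  for (nm in names(covariate_spec)) {
    cs <- covariate_spec[[nm]]
    x <- covariates[[nm]]
    eta <- eta + switch(cs$type,
      binary = cs$beta * x,
      continuous = cs$beta * (x - cs$mean),
      ordinal = ifelse(x == nulliparous_code(), 0, cs$betas[x + 1L]))
  }
  eta
}

#' Simulate a retrospective case-control cohort
#'
#' Draws individuals from a prospective population model -- Hardy-Weinberg
#' genotypes at the panel frequencies, covariates from their marginals, case
#' status Bernoulli(plogis(intercept + sum(beta_snp * dosage) +
#' sum(beta_cov * covariate))) -- and retains them until both the case and
#' control quotas are met (rejection sampling of the retrospective design).
#' When a target prevalence is given instead of a fixed intercept, the
#' intercept is calibrated by root-finding on a large calibration sample so
#' the population case probability matches the target.
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `cohort` (a `cohort_table` of exactly
#'   `n_cases + n_controls` rows), `genotypes` (aligned dosage matrix) and
#'   `truth` (generating intercept, per-SNP and covariate log-ORs, seed and
#'   number of population draws used) for parameter-recovery checks.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  panel <- spec$panel
  mafs <- setNames(panel$eaf_published, panel$rsid)

  intercept <- spec$intercept
  if (is.null(intercept)) {
    n_cal <- 20000L
    g <- simulate_genotypes(n_cal, mafs)
    eta0 <- as.numeric(g %*% spec$snp_betas)
    if (!is.null(spec$covariate_spec)) {
      cv <- simulate_covariates(n_cal, spec$covariate_spec)
      eta0 <- eta0 + covariate_linear_predictor(cv, spec$covariate_spec)
    }
    f <- function(c0) mean(plogis(c0 + eta0)) - spec$prevalence
    if (f(-40) > 0 || f(40) < 0) {
      stop("prevalence calibration failed to bracket the intercept")
    }
    intercept <- uniroot(f, c(-40, 40), tol = 1e-8)$root
  }

  need_cases <- spec$n_cases
  need_controls <- spec$n_controls
  keep_geno <- vector("list", 0L)
  keep_cov <- vector("list", 0L)
  keep_status <- vector("list", 0L)
  draws <- 0L
  block <- 5000L
  while (need_cases > 0L || need_controls > 0L) {
    if (draws >= spec$max_draws) {
      stop("case/control quota unreachable within max_draws = ",
           spec$max_draws)
    }
    g <- simulate_genotypes(block, mafs)
    eta <- intercept + as.numeric(g %*% spec$snp_betas)
    cv <- simulate_covariates(block, spec$covariate_spec %||%
                                default_covariate_spec())
    if (is.null(spec$covariate_spec)) {
      # covariate-free risk: marginals still drawn so the table is complete
    } else {
      eta <- eta + covariate_linear_predictor(cv, spec$covariate_spec)
    }
    y <- rbinom(block, 1L, plogis(eta))
    draws <- draws + block
    take <- (y == 1L & cumsum(y == 1L) <= need_cases) |
            (y == 0L & cumsum(y == 0L) <= need_controls)
    if (any(take)) {
      keep_geno[[length(keep_geno) + 1L]] <- g[take, , drop = FALSE]
      keep_cov[[length(keep_cov) + 1L]] <- cv[take, , drop = FALSE]
      keep_status[[length(keep_status) + 1L]] <- y[take]
      need_cases <- need_cases - sum(y[take] == 1L)
      need_controls <- need_controls - sum(y[take] == 0L)
    }
  }
  genotypes <- do.call(rbind, keep_geno)
  covariates <- do.call(rbind, keep_cov)
  status <- unlist(keep_status)
  n <- length(status)
  ids <- sprintf("ind_%05d", seq_len(n))
  rownames(genotypes) <- ids
  cohort <- data.frame(individual_id = ids, status = as.integer(status),
                       covariates, stringsAsFactors = FALSE)
  rownames(cohort) <- NULL
  cohort <- as_cohort_table(cohort)
  if (!is.null(spec$missing_rates)) {
    cohort <- inject_missingness(cohort, spec$missing_rates)
  }
  cov_betas <- if (is.null(spec$covariate_spec)) NULL else
    lapply(spec$covariate_spec, function(cs)
      if (cs$type == "ordinal") cs$betas else cs$beta)
  truth <- list(intercept = intercept,
                snp_betas = setNames(spec$snp_betas, panel$rsid),
                covariate_betas = cov_betas,
                prevalence = spec$prevalence,
                seed = spec$seed, population_draws = draws)
  list(cohort = cohort, genotypes = genotypes, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inject missingness into a cohort table
#'
#' Sets each named field to missing independently with its rate; `status`
#' and `individual_id` are never touched. Breastfeeding missingness applies
#' only to parous women (the nulliparous structural 0 is retained).
#'
#' @param cohort A `cohort_table`.
#' @param missing_rates Named numeric vector of per-field rates in \[0, 1\].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return The cohort with missing values injected.
#' @export
inject_missingness <- function(cohort, missing_rates, seed = NULL) {
  if (any(missing_rates < 0 | missing_rates > 1)) {
    stop("missing rates must lie in [0, 1]")
  }
  bad <- setdiff(names(missing_rates), risk_factor_names())
  if (length(bad) > 0) {
    stop("cannot inject missingness into: ", paste(bad, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  for (nm in names(missing_rates)) {
    hit <- runif(n) < missing_rates[[nm]]
    if (nm == "breastfed") hit <- hit & !is.na(cohort$parous) &
        cohort$parous == 1L
    cohort[[nm]][hit] <- NA
  }
  cohort
}
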