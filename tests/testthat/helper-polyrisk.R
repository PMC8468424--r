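# shared test helpers: tiny file fixtures built in code, and independent
# brute-force oracles kept deliberately naive

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# brute-force AUC: enumerate every case-control pair, ties count one half
auc_bruteforce <- function(scores, y) {
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  total <- 0
  for (s1 in cases) {
    for (s0 in controls) {
      total <- total + (s1 > s0) + 0.5 * (s1 == s0)
    }
  }
  total / (length(cases) * length(controls))
}

# brute-force Spearman rho via the classical rank formula (no ties)
spearman_bruteforce_noties <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# expand a 2x2 table into individual-level exposure/status rows
expand_2x2 <- function(cases_exposed, controls_exposed, cases_ref,
                       controls_ref) {
  data.frame(
    exposed = rep(c(1, 1, 0, 0),
                  c(cases_exposed, controls_exposed, cases_ref,
                    controls_ref)),
    y = rep(c(1, 0, 1, 0),
            c(cases_exposed, controls_exposed, cases_ref, controls_ref))
  )
}

# small complete cohort + genotypes for structural tests
small_simulated <- function(n_cases = 60, n_controls = 70, seed = 11) {
  simulate_cohort(simulation_spec(n_cases = n_cases,
                                  n_controls = n_controls, seed = seed))
}
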