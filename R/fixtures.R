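# Decile/status counts from the published decile stratification of the
# motivating 15-SNP integrated-risk analysis (900 controls, 880 cases).
# Stored as counts, expanded on demand: they let the per-decile OR table be
# reproduced exactly from printed numbers alone.
published_decile_counts <- function() {
  data.frame(
    decile = 1:10,
    controls = c(139L, 135L, 108L, 98L, 94L, 92L, 89L, 62L, 45L, 38L),
    cases = c(39L, 51L, 64L, 91L, 74L, 86L, 102L, 122L, 114L, 137L)
  )
}

#' Build test fixtures
#'
#' Two kinds:
#' * `"tiny"`: a 30-individual toy cohort (genotype CSV + cohort CSV,
#'   simulated at a fixed seed) that parses cleanly through
#'   [read_genotypes()] / [read_cohort()]; written to `out_dir`.
#' * `"published_deciles"`: a 1780-row table carrying only `decile` and
#'   `status`, expanded from the published decile counts of the motivating
#'   integrated-risk analysis (900 controls, 880 cases), so the stratified
#'   OR table is exactly reproducible from printed numbers.
#'
#' @param kind `"tiny"` or `"published_deciles"`.
#' @param out_dir Output directory for `"tiny"` (created if needed); for
#'   `"published_deciles"` files are written only when `out_dir` is given.
#' @param seed Seed for the `"tiny"` simulation (default 42).
#' @return For `"tiny"`, a list of file paths; for `"published_deciles"`,
#'   the expanded data frame (invisibly also written as CSV when `out_dir`
#'   is given).
#' @export
make_fixture <- function(kind = c("tiny", "published_deciles"),
                         out_dir = NULL, seed = 42L) {
  kind <- match.arg(kind)
  if (kind == "tiny") {
    if (is.null(out_dir)) stop("tiny fixture needs an out_dir")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    spec <- simulation_spec(n_cases = 15, n_controls = 15, seed = seed)
    sim <- simulate_cohort(spec)
    geno_path <- file.path(out_dir, "tiny_genotypes.csv")
    cohort_path <- file.path(out_dir, "tiny_cohort.csv")
    write_genotypes(sim$genotypes, geno_path, "csv", spec$panel)
    write_cohort(sim$cohort, cohort_path)
    return(list(genotypes = geno_path, cohort = cohort_path))
  }
  counts <- published_decile_counts()
  out <- data.frame(
    decile = rep(rep(counts$decile, 2),
                 times = c(counts$controls, counts$cases)),
    status = rep(rep(c(0L, 1L), each = nrow(counts)),
                 times = c(counts$controls, counts$cases))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(out_dir, "published_deciles.csv"),
              row.names = FALSE, quote = FALSE)
  }
  out
}

#' Round half-up for display at printed precision
#'
#' Base R rounds half to even; published tables round half away from zero.
#' Used when comparing computed estimates to printed values.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
}
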