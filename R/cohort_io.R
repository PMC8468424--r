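#' Names of the classical risk-factor columns
#'
#' The ten classical breast-cancer risk factors carried by a cohort table:
#' menopausal status, age at menarche (years), parity, age at first
#' full-term pregnancy (FFTP) in 5-year bands, breastfeeding among parous
#' women, height (cm), BMI (kg/m^2), hormone-replacement therapy, smoking
#' status and first-degree family history.
#'
#' @return Character vector of column names.
#' @export
risk_factor_names <- function() {
  c("menopausal", "age_menarche", "parous", "age_fftp_cat", "breastfed",
    "height_cm", "bmi", "hrt", "smoker", "family_history")
}

#' Code marking nulliparous women in the FFTP category column
#'
#' Age at first full-term pregnancy is coded in 5-year bands 0-4; nulliparous
#' women carry the distinct code 5 and are folded into the reference band
#' when the category enters a model as indicator contrasts.
#'
#' @return The integer code.
#' @export
nulliparous_code <- function() 5L

cohort_columns <- function() {
  c("individual_id", "status", risk_factor_names())
}

#' Read a per-individual phenotype/risk-factor table
#'
#' Reads a CSV with one row per individual: `individual_id`, case/control
#' `status` (1/0) and the ten classical risk-factor columns of
#' [risk_factor_names()]. Status must code only 0 (control) and 1 (case).
#' Breastfeeding is defined only among parous women: rows with `parous = 0`
#' and `breastfed = 1` are repaired to missing and counted in the
#' `breastfed_repairs` attribute, with a warning.
#'
#' @param path File path.
#' @param missing_marker String marking missing values; default `"NA"`.
#' @return A `data.frame` of class `cohort_table`.
#' @export
read_cohort <- function(path, missing_marker = "NA") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  na.strings = missing_marker)
  if (nrow(tab) == 0) stop("empty cohort file: ", path)
  missing_cols <- setdiff(cohort_columns(), names(tab))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[, cohort_columns()]
  as_cohort_table(tab)
}

#' Coerce and validate a cohort table
#'
#' @param tab A data frame with the columns of a cohort table.
#' @return A validated `cohort_table`.
#' @export
as_cohort_table <- function(tab) {
  missing_cols <- setdiff(cohort_columns(), names(tab))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad_status <- !(tab$status %in% c(0, 1))
  if (any(bad_status)) {
    stop("unknown status code(s): ",
         paste(unique(tab$status[bad_status]), collapse = ", "),
         " (expected 0 = control, 1 = case)")
  }
  tab$status <- as.integer(tab$status)
  for (col in c("menopausal", "parous", "breastfed", "hrt", "smoker",
                "family_history")) {
    bad <- !is.na(tab[[col]]) & !(tab[[col]] %in% c(0, 1))
    if (any(bad)) stop("column ", col, " must be binary 0/1 or missing")
    tab[[col]] <- as.integer(tab[[col]])
  }
  repair <- !is.na(tab$parous) & tab$parous == 0L &
    !is.na(tab$breastfed) & tab$breastfed == 1L
  if (any(repair)) {
    tab$breastfed[repair] <- NA_integer_
    warning(sum(repair),
            " row(s) had breastfed = 1 with parous = 0; set to missing")
  }
  attr(tab, "breastfed_repairs") <- sum(repair)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Write a cohort table
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @param missing_marker Missing marker; default `"NA"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, missing_marker = "NA") {
  write.csv(as.data.frame(cohort)[, cohort_columns()], path,
            row.names = FALSE, na = missing_marker, quote = FALSE)
  invisible(path)
}

#' Restrict to individuals with complete observations
#'
#' Removes every individual with a missing value in any required field from
#' both the cohort and (when supplied) the genotype matrix, mirroring a
#' complete-case analysis. Breastfeeding counts as missing only for parous
#' women: among nulliparous women the factor is structurally absent and does
#' not exclude the row.
#'
#' @param cohort A `cohort_table`.
#' @param genotypes Optional dosage matrix with row names matching
#'   `cohort$individual_id`; rows are filtered in step. Set
#'   `require_genotypes = TRUE` to also drop individuals with any missing
#'   dosage.
#' @param required_fields Cohort columns that must be observed; default all
#'   ten risk factors.
#' @param require_genotypes Drop rows with missing dosages too? Default
#'   `FALSE`.
#' @return A list with elements `cohort`, `genotypes` and `report`; the
#'   report gives rows in/out and removal counts by field and by status.
#' @export
complete_case_filter <- function(cohort, genotypes = NULL,
                                 required_fields = risk_factor_names(),
                                 require_genotypes = FALSE) {
  unknown <- setdiff(required_fields, names(cohort))
  if (length(unknown) > 0) {
    stop("required field(s) not in cohort: ", paste(unknown, collapse = ", "))
  }
  miss <- sapply(required_fields, function(col) {
    m <- is.na(cohort[[col]])
    if (col == "breastfed") {
      m <- m & !is.na(cohort$parous) & cohort$parous == 1L
    }
    m
  })
  miss <- matrix(miss, nrow = nrow(cohort),
                 dimnames = list(NULL, required_fields))
  if (!is.null(genotypes)) {
    idx <- match(cohort$individual_id, rownames(genotypes))
    if (anyNA(idx)) stop("cohort ids absent from genotype matrix")
    genotypes <- genotypes[idx, , drop = FALSE]
    if (require_genotypes) {
      miss <- cbind(miss, genotype = rowSums(is.na(genotypes)) > 0)
    }
  }
  drop <- rowSums(miss) > 0
  report <- list(
    n_in = nrow(cohort),
    n_out = sum(!drop),
    n_removed = sum(drop),
    removed_by_field = colSums(miss[drop, , drop = FALSE]),
    removed_by_status = c(controls = sum(drop & cohort$status == 0L),
                          cases = sum(drop & cohort$status == 1L))
  )
  kept <- cohort[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- class(cohort)
  if (!is.null(genotypes)) genotypes <- genotypes[!drop, , drop = FALSE]
  list(cohort = kept, genotypes = genotypes, report = report)
}
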