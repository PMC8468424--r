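#' Read a genotype dosage table
#'
#' Reads per-individual minor-allele counts (0/1/2, possibly missing) in one
#' of two dialects and aligns the columns to a SNP panel.
#'
#' * `csv`: a header row with an id column (named `id` or the first column)
#'   plus one column per rsID holding integer dosages of the panel's minor
#'   allele; configurable missing marker.
#' * `plink_raw`: whitespace-separated PLINK `.raw` subset with columns
#'   `FID IID PAT MAT SEX PHENOTYPE` followed by `SNPID_ALLELE` tokens, where
#'   `ALLELE` is the counted allele and `NA` marks missing.
#'
#' Columns are subset and reordered to the panel's SNP order. In the
#' `plink_raw` dialect, any SNP whose counted allele differs from the panel's
#' minor allele is flipped (`dosage -> 2 - dosage`); flipped rsIDs are
#' recorded in the `flipped` attribute of the result.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"plink_raw"`.
#' @param panel A `snp_panel` giving SNP order and minor alleles.
#' @param missing_marker String marking missing dosages (`csv` dialect);
#'   default `"NA"`.
#' @return An integer matrix (individuals x SNPs) with individual ids as row
#'   names, panel rsIDs as column names, `NA` for missing, and attribute
#'   `flipped` listing rsIDs whose dosages were reoriented.
#' @export
read_genotypes <- function(path, dialect = c("csv", "plink_raw"), panel,
                           missing_marker = "NA") {
  dialect <- match.arg(dialect)
  validate_panel(panel)
  if (!file.exists(path)) stop("genotype file not found: ", path)

  if (dialect == "csv") {
    tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = missing_marker, colClasses = "character")
    if (nrow(tab) == 0) stop("empty genotype file: ", path)
    id_col <- if ("id" %in% names(tab)) "id" else names(tab)[1]
    ids <- tab[[id_col]]
    snp_cols <- setdiff(names(tab), id_col)
    missing_snps <- setdiff(panel$rsid, snp_cols)
    if (length(missing_snps) > 0) {
      stop("panel SNP(s) absent from genotype file: ",
           paste(missing_snps, collapse = ", "))
    }
    mat <- as.matrix(tab[, panel$rsid, drop = FALSE])
    mat[mat == missing_marker] <- NA
    geno <- suppressWarnings(
      matrix(as.integer(mat), nrow = nrow(mat), dimnames = dimnames(mat)))
    bad_parse <- !is.na(mat) & is.na(geno)
    flipped <- character(0)
  } else {
    tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, na.strings = "NA",
                      colClasses = "character")
    if (nrow(tab) == 0) stop("empty genotype file: ", path)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(tab))) {
      stop("plink_raw file must carry columns ", paste(meta, collapse = " "))
    }
    ids <- tab$IID
    snp_tokens <- setdiff(names(tab), meta)
    token_rsid <- sub("_[ACGT]$", "", snp_tokens)
    token_allele <- sub("^.*_", "", snp_tokens)
    missing_snps <- setdiff(panel$rsid, token_rsid)
    if (length(missing_snps) > 0) {
      stop("panel SNP(s) absent from genotype file: ",
           paste(missing_snps, collapse = ", "))
    }
    sel <- match(panel$rsid, token_rsid)
    mat <- as.matrix(tab[, snp_tokens[sel], drop = FALSE])
    geno <- suppressWarnings(
      matrix(as.integer(mat), nrow = nrow(mat)))
    bad_parse <- !is.na(mat) & is.na(geno)
    colnames(geno) <- panel$rsid
    to_flip <- token_allele[sel] != panel$effect_allele
    flipped <- panel$rsid[to_flip]
    if (any(to_flip)) {
      geno[, to_flip] <- 2L - geno[, to_flip, drop = FALSE]
    }
  }

  if (any(bad_parse)) {
    idx <- which(bad_parse, arr.ind = TRUE)[1, ]
    stop("non-integer dosage at row ", idx[1], ", SNP column ", idx[2])
  }
  out_of_range <- !is.na(geno) & (geno < 0L | geno > 2L)
  if (any(out_of_range)) {
    idx <- which(out_of_range, arr.ind = TRUE)[1, ]
    stop("dosage outside {0,1,2} at row ", idx[1],
         ", SNP ", colnames(geno)[idx[2]])
  }
  rownames(geno) <- ids
  attr(geno, "flipped") <- flipped
  geno
}

#' Write a genotype dosage table
#'
#' Inverse of [read_genotypes()] for both dialects; round-trips dosages and
#' missingness exactly.
#'
#' @param genotypes Integer dosage matrix with individual ids as row names
#'   and rsIDs as column names.
#' @param path Output file path.
#' @param dialect `"csv"` or `"plink_raw"`.
#' @param panel A `snp_panel` (needed for the counted-allele header tokens of
#'   the `plink_raw` dialect).
#' @param missing_marker Missing marker for the `csv` dialect.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, dialect = c("csv", "plink_raw"),
                            panel, missing_marker = "NA") {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    tab <- data.frame(id = rownames(genotypes), genotypes,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(tab, path, row.names = FALSE, na = missing_marker, quote = FALSE)
  } else {
    validate_panel(panel)
    alle <- panel$effect_allele[match(colnames(genotypes), panel$rsid)]
    if (anyNA(alle)) stop("genotype columns not all present in panel")
    tab <- data.frame(FID = rownames(genotypes), IID = rownames(genotypes),
                      PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
                      genotypes, check.names = FALSE, stringsAsFactors = FALSE)
    names(tab)[-(1:6)] <- paste0(colnames(genotypes), "_", alle)
    write.table(tab, path, row.names = FALSE, quote = FALSE, sep = " ",
                na = "NA")
  }
  invisible(path)
}

#' Flip dosage orientation at selected SNPs
#'
#' `dosage -> 2 - dosage` at the named columns; missing entries stay missing.
#' Flipping twice restores the original matrix.
#'
#' @param genotypes Integer dosage matrix.
#' @param rsids Column names to flip.
#' @return The matrix with flipped columns.
#' @export
flip_dosages <- function(genotypes, rsids) {
  missing_cols <- setdiff(rsids, colnames(genotypes))
  if (length(missing_cols) > 0) {
    stop("cannot flip absent SNP(s): ", paste(missing_cols, collapse = ", "))
  }
  genotypes[, rsids] <- 2L - genotypes[, rsids, drop = FALSE]
  genotypes
}
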