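#' Load a SNP susceptibility panel
#'
#' Reads a tab-delimited SNP panel and validates it. The packaged default is
#' a 15-SNP breast-cancer panel: GWAS-identified biallelic SNPs with, for
#' each, the build-37 coordinate, reference and effect allele, the published
#' effect-allele frequency in source-study controls and the published
#' per-allele odds ratio (iCOGS). The effect allele is always the published
#' minor allele, so `eaf_published` must lie in (0, 0.5]; this pins the
#' orientation of the PRS weights independently of any analysis cohort.
#'
#' @param path Path to a tab-delimited panel file with columns `chrom`,
#'   `rsid`, `pos_b37`, `ref_allele`, `effect_allele`, `eaf_published`,
#'   `or_published`, `p_published`. Defaults to the packaged 15-SNP panel.
#' @return A `data.frame` of class `snp_panel`, one row per SNP, ordered by
#'   (chromosome, position).
#' @examples
#' panel <- load_panel()
#' nrow(panel)                     # 15
#' panel[panel$rsid == "rs2981582", c("eaf_published", "or_published")]
#' @export
load_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "snp_panel_icogs.tsv", package = "polyrisk")
  }
  if (!file.exists(path)) {
    stop("panel file not found: ", path)
  }
  panel <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(chrom = "character"))
  required <- c("chrom", "rsid", "pos_b37", "ref_allele", "effect_allele",
                "eaf_published", "or_published", "p_published")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  panel <- panel[, required]
  validate_panel(panel)
  # order by chromosome (1-22 then X) and position
  chrom_num <- suppressWarnings(as.numeric(panel$chrom))
  chrom_num[panel$chrom == "X"] <- 23
  if (anyNA(chrom_num)) {
    stop("unrecognized chromosome label(s): ",
         paste(unique(panel$chrom[is.na(chrom_num)]), collapse = ", "))
  }
  panel <- panel[order(chrom_num, panel$pos_b37), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

validate_panel <- function(panel) {
  if (anyDuplicated(panel$rsid)) {
    stop("duplicate rsid in panel: ",
         paste(unique(panel$rsid[duplicated(panel$rsid)]), collapse = ", "))
  }
  alleles <- c("A", "C", "G", "T")
  bad_allele <- !(panel$ref_allele %in% alleles) |
    !(panel$effect_allele %in% alleles)
  if (any(bad_allele)) {
    stop("invalid allele code for: ",
         paste(panel$rsid[bad_allele], collapse = ", "))
  }
  same <- panel$ref_allele == panel$effect_allele
  if (any(same)) {
    stop("reference and effect allele identical for: ",
         paste(panel$rsid[same], collapse = ", "))
  }
  bad_eaf <- !is.finite(panel$eaf_published) |
    panel$eaf_published <= 0 | panel$eaf_published > 0.5
  if (any(bad_eaf)) {
    stop("published effect-allele frequency outside (0, 0.5] for: ",
         paste(panel$rsid[bad_eaf], collapse = ", "),
         " (the effect allele must be the published minor allele)")
  }
  if (any(!is.finite(panel$or_published) | panel$or_published <= 0)) {
    stop("published OR must be a positive real for every SNP")
  }
  if (any(!is.finite(panel$p_published) |
          panel$p_published <= 0 | panel$p_published > 1)) {
    stop("published p-value outside (0, 1]")
  }
  invisible(panel)
}

#' PRS weights from a panel
#'
#' One weight per panel SNP: the natural log of the published per-allele
#' odds ratio, attached to the published minor allele (= the panel's effect
#' allele). Betas are computed from the stored OR, never stored, so the
#' weights carry exactly the printed precision of the source table.
#'
#' @param panel A `snp_panel`, e.g. from [load_panel()].
#' @return A `data.frame` with columns `rsid`, `minor_allele`, `beta`.
#' @examples
#' w <- prs_weights(load_panel())
#' w$beta[w$rsid == "rs2981582"]   # log(1.26)
#' @export
prs_weights <- function(panel) {
  validate_panel(panel)
  data.frame(
    rsid = panel$rsid,
    minor_allele = panel$effect_allele,
    beta = log(panel$or_published),
    stringsAsFactors = FALSE
  )
}
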