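test_that("packaged panel loads with 15 validated SNPs in genomic order", {
  panel <- load_panel()
  expect_s3_class(panel, "snp_panel")
  expect_equal(nrow(panel), 15)
  r <- panel[panel$rsid == "rs2981582", ]
  expect_equal(r$or_published, 1.26)
  expect_equal(r$eaf_published, 0.38)
  expect_equal(r$effect_allele, "A")
  # ordered by (chromosome, position)
  chrom <- as.numeric(panel$chrom)
  expect_true(all(diff(chrom) >= 0))
  within_chr10 <- panel$pos_b37[panel$chrom == "10"]
  expect_true(all(diff(within_chr10) > 0))
  expect_true(all(panel$eaf_published > 0 & panel$eaf_published <= 0.5))
  expect_true(all(panel$ref_allele != panel$effect_allele))
})

test_that("panel validation rejects bad frequencies and duplicate rsids", {
  panel <- load_panel()
  bad <- panel
  bad$eaf_published[bad$rsid == "rs889312"] <- 0.6
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_panel(path), "rs889312")

  dup <- panel
  dup$rsid[2] <- dup$rsid[1]
  write.table(dup, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_panel(path), "duplicate")
})

test_that("weights are natural logs of the published ORs on the minor allele", {
  panel <- load_panel()
  w <- prs_weights(panel)
  expect_equal(nrow(w), 15)
  expect_equal(w$minor_allele, panel$effect_allele)
  expect_equal(w$beta[w$rsid == "rs13387042"], log(0.88), tolerance = 1e-12)
  expect_equal(w$beta[w$rsid == "rs2981582"], log(1.26), tolerance = 1e-12)
  expect_equal(w$beta, log(panel$or_published))
  expect_true(all(abs(w$beta) < 1))
  # hypothetical OR of exactly 1 gives beta 0
  p1 <- panel
  p1$or_published[1] <- 1
  expect_equal(prs_weights(p1)$beta[1], 0)
})

test_that("csv genotypes align to panel order and carry missingness through", {
  panel <- load_panel()
  rs_rev <- rev(panel$rsid)
  lines <- c(
    paste(c("id", rs_rev), collapse = ","),
    paste(c("a", rep("1", 15)), collapse = ","),
    paste(c("b", "NA", rep("0", 14)), collapse = ","),
    paste(c("c", rep("2", 15)), collapse = ",")
  )
  path <- write_temp_csv(lines)
  geno <- read_genotypes(path, "csv", panel)
  expect_equal(colnames(geno), panel$rsid)
  expect_equal(rownames(geno), c("a", "b", "c"))
  expect_equal(sum(is.na(geno)), 1)
  # the NA was attached to the FIRST file column = last panel SNP
  expect_true(is.na(geno["b", rs_rev[1]]))
  expect_equal(unname(geno["c", ]), rep(2L, 15))
})

test_that("csv reader rejects absent panel SNPs and out-of-range dosages", {
  panel <- load_panel()
  path <- write_temp_csv(c(
    paste(c("id", panel$rsid[-1]), collapse = ","),
    paste(c("a", rep("0", 14)), collapse = ",")))
  expect_error(read_genotypes(path, "csv", panel), panel$rsid[1])

  path2 <- write_temp_csv(c(
    paste(c("id", panel$rsid), collapse = ","),
    paste(c("a", "3", rep("0", 14)), collapse = ",")))
  expect_error(read_genotypes(path2, "csv", panel), "outside")
})

test_that("plink_raw reader flips dosages counted on the non-minor allele", {
  panel <- load_panel()
  # count the REFERENCE allele for rs2981582 (minor/effect allele is A)
  tokens <- paste0(panel$rsid, "_", panel$effect_allele)
  j <- which(panel$rsid == "rs2981582")
  tokens[j] <- paste0("rs2981582_", panel$ref_allele[j])
  header <- paste(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE", tokens),
                  collapse = " ")
  row1 <- paste(c("f1", "i1", "0", "0", "2", "1", rep("0", 15)),
                collapse = " ")
  row2 <- paste(c("f2", "i2", "0", "0", "2", "1", rep("1", 15)),
                collapse = " ")
  path <- write_temp_csv(c(header, row1, row2))
  geno <- read_genotypes(path, "plink_raw", panel)
  expect_equal(attr(geno, "flipped"), "rs2981582")
  expect_equal(unname(geno["i1", "rs2981582"]), 2L)  # 0 -> 2
  expect_equal(unname(geno["i1", "rs11249433"]), 0L)
  expect_equal(unname(geno["i2", "rs2981582"]), 1L)  # 1 stays 1
})

test_that("both genotype dialects round-trip dosages and missingness", {
  panel <- load_panel()
  set.seed(5)
  geno <- simulate_genotypes(20, setNames(panel$eaf_published, panel$rsid))
  geno[3, 4] <- NA
  geno[9, 1] <- NA
  rownames(geno) <- sprintf("id%02d", 1:20)
  for (dialect in c("csv", "plink_raw")) {
    path <- withr::local_tempfile()
    write_genotypes(geno, path, dialect, panel)
    back <- read_genotypes(path, dialect, panel)
    expect_equal(unname(back), unname(geno), ignore_attr = TRUE)
    expect_equal(rownames(back), rownames(geno))
  }
})

test_that("allele flip is an involution", {
  panel <- load_panel()
  set.seed(6)
  geno <- simulate_genotypes(12, setNames(panel$eaf_published, panel$rsid))
  geno[2, 5] <- NA
  twice <- flip_dosages(flip_dosages(geno, panel$rsid[c(1, 4)]),
                        panel$rsid[c(1, 4)])
  expect_identical(twice, geno)
})

test_that("cohort reader types columns and repairs the breastfed invariant", {
  lines <- c(
    paste(c("individual_id", "status", "menopausal", "age_menarche",
            "parous", "age_fftp_cat", "breastfed", "height_cm", "bmi",
            "hrt", "smoker", "family_history"), collapse = ","),
    "a,0,1,13,1,2,1,160,24,0,0,0",
    "b,0,0,12.5,0,5,1,158,28,1,1,0",   # parous=0, breastfed=1: repaired
    "c,1,1,14,1,0,0,171,22,0,0,1",
    "d,1,1,NA,0,5,0,165,30,0,1,0"
  )
  path <- write_temp_csv(lines)
  expect_warning(cohort <- read_cohort(path), "breastfed")
  expect_equal(sum(cohort$status == 0), 2)
  expect_equal(sum(cohort$status == 1), 2)
  expect_true(is.na(cohort$breastfed[cohort$individual_id == "b"]))
  expect_equal(attr(cohort, "breastfed_repairs"), 1L)
  expect_true(is.na(cohort$age_menarche[4]))
})

test_that("cohort reader rejects unknown status codes and empty files", {
  lines <- c(
    paste(cohort_cols <- c("individual_id", "status", "menopausal",
                           "age_menarche", "parous", "age_fftp_cat",
                           "breastfed", "height_cm", "bmi", "hrt", "smoker",
                           "family_history"), collapse = ","),
    "a,2,1,13,1,2,1,160,24,0,0,0")
  expect_error(read_cohort(write_temp_csv(lines)), "status")
  empty <- write_temp_csv(paste(cohort_cols, collapse = ","))
  expect_error(read_cohort(empty), "empty")
})

test_that("complete-case filter matches a brute-force count and leaves no missing", {
  sim <- simulate_cohort(simulation_spec(
    n_cases = 300, n_controls = 320, seed = 21,
    missing_rates = c(bmi = 0.08, hrt = 0.05, age_menarche = 0.04,
                      breastfed = 0.06)))
  cohort <- sim$cohort
  res <- complete_case_filter(cohort, sim$genotypes)
  # independent count: a row is complete if no required field is missing,
  # where breastfed only counts for parous women
  complete <- rep(TRUE, nrow(cohort))
  for (f in risk_factor_names()) {
    m <- is.na(cohort[[f]])
    if (f == "breastfed") m <- m & cohort$parous %in% 1L
    complete <- complete & !m
  }
  expect_equal(res$report$n_out, sum(complete))
  expect_equal(nrow(res$cohort), sum(complete))
  expect_equal(nrow(res$genotypes), sum(complete))
  expect_equal(res$report$n_removed + res$report$n_out, nrow(cohort))
  expect_equal(sum(res$report$removed_by_status), res$report$n_removed)
  for (f in risk_factor_names()) {
    m <- is.na(res$cohort[[f]])
    if (f == "breastfed") m <- m & res$cohort$parous %in% 1L
    expect_false(any(m))
  }
})

test_that("complete-case filter is the identity without missingness and empties fully-missing fields", {
  sim <- small_simulated()
  res <- complete_case_filter(sim$cohort, sim$genotypes)
  expect_equal(nrow(res$cohort), nrow(sim$cohort))
  expect_equal(res$report$n_removed, 0)

  all_miss <- sim$cohort
  all_miss$bmi <- NA_real_
  res2 <- complete_case_filter(all_miss, sim$genotypes)
  expect_equal(res2$report$n_out, 0)
  expect_equal(unname(res2$report$removed_by_field["bmi"]),
               nrow(sim$cohort))
})
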