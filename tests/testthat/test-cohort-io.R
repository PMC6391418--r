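test_that("cohort tables round-trip through TSV", {
  cfg <- sim_config(n_cases = 10, n_controls = 10, seed = 5)
  coh <- simulate_cohort(cfg)
  coh$waist[3] <- NA_real_ # exercise the missing-value sentinel
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-12)
  expect_identical(snp_cols(back), snp_cols(coh))
})

test_that("schema violations are rejected with named diagnostics", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tbl <- tibble::tibble(subject_id = c("a", "b"), status = c("case", "control"),
                        bmi = c(28, 27), rs1 = c(3, 1))
  readr::write_tsv(tbl, path)
  expect_error(read_cohort(path), "rs1.*row 1",
               class = "t2dvar_domain_error")

  tbl$rs1 <- c("AZ", "AA")
  readr::write_tsv(tbl, path)
  expect_error(read_cohort(path), "two-letter", class = "t2dvar_domain_error")

  tbl$rs1 <- c(1, 2)
  tbl$bmi <- c("fat", "28")
  readr::write_tsv(tbl, path)
  expect_error(read_cohort(path), "`bmi` must be numeric",
               class = "t2dvar_domain_error")
})

test_that("controls carrying an age at diagnosis are nulled with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tbl <- tibble::tibble(subject_id = c("a", "b"), status = c("case", "control"),
                        age_dx = c(45, 50), years_with_disease = c(5, 2))
  readr::write_tsv(tbl, path)
  expect_warning(back <- read_cohort(path), "control")
  expect_true(is.na(back$age_dx[2]))
  expect_true(is.na(back$years_with_disease[2]))
  expect_equal(back$age_dx[1], 45)
})

test_that("expand_counts reproduces counts exactly and matches 2x2 fits", {
  counts <- dplyr::filter(ph_reference_counts("main"), factor == "both_parents")
  tab <- expand_counts(counts)
  expect_equal(nrow(tab), 2043)
  retab <- table(tab$both_parents, tab$status)
  expect_equal(unname(retab[, "control"]), counts$controls)
  expect_equal(unname(retab[, "case"]), counts$cases)

  # empty counts give an empty table
  zero <- tibble::tibble(level = c("0", "1"), controls = c(0L, 0L),
                         cases = c(0L, 0L))
  expect_equal(nrow(expand_counts(zero)), 0)
  expect_error(expand_counts(dplyr::mutate(zero, cases = c(-1L, 0L))),
               class = "t2dvar_domain_error")

  # equivalence oracle: ULR on expanded father counts = 2x2 cross-product
  father <- dplyr::filter(ph_reference_counts("main"), factor == "father")
  fit <- fit_logistic(expand_ph("main", "father"), "father")
  cross <- with(as.list(setNames(
    c(father$controls, father$cases), c("c0", "c1", "k0", "k1"))),
    (k1 * c0) / (c1 * k0))
  expect_equal(exp(fit$coefficients[2]), cross, tolerance = 1e-10)
})

test_that("derived variable coding is correct and idempotent", {
  tbl <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    status = c("case", "case", "control"),
    age_dx = c(38, 55, NA),
    years_with_disease = c(4, 1, NA),
    bmi = c(25.0, 30.0, 30.01),
    waist = c(93.4, 90, 80),
    hip = c(101.7, 0, 100),
    father_t2d = c(1L, 0L, 1L),
    mother_t2d = c(1L, 1L, 0L)
  )
  expect_warning(coded <- derive_coded_variables(tbl), "hip")
  expect_equal(coded$ph_count, c(2L, 1L, 1L))
  expect_equal(coded$whr[1], 93.4 / 101.7, tolerance = 1e-12)
  expect_equal(round(coded$whr[1], 2), 0.92)
  expect_true(is.na(coded$whr[2]))
  # boundary rule: both 25 and 30 belong to the middle class
  expect_equal(as.character(coded$bmi_cat), c("25-30", "25-30", ">30"))
  expect_identical(suppressWarnings(derive_coded_variables(coded)), coded)
})

test_that("age-at-diagnosis grouping honours fixed and empirical cuts", {
  tbl <- tibble::tibble(
    subject_id = as.character(1:6), status = rep("case", 6),
    age_dx = c(35, 39, 40, 46, 53, 60)
  )
  coded <- derive_coded_variables(tbl, agedx_cuts = c(39, 45, 53))
  expect_equal(as.character(coded$agedx_quartile),
               c("<=39", "<=39", "39-45", "45-53", "45-53", ">=53"))
  expect_equal(as.character(coded$agedx_split),
               c("<=45", "<=45", "<=45", ">45", ">45", ">45"))
  emp <- derive_coded_variables(tbl)
  expect_equal(length(levels(emp$agedx_quartile)), 4)
})

test_that("two-letter genotypes resolve against declared risk alleles", {
  tbl <- tibble::tibble(
    subject_id = c("a", "b", "c"), status = c("case", "control", "case"),
    rs1 = c("AA", "AG", "GG")
  )
  attr(tbl, "snp_cols") <- "rs1"
  info <- tibble::tibble(snp_id = "rs1", risk_allele = "A", other_allele = "G")
  coded <- derive_coded_variables(tbl, snp_info = info)
  expect_equal(coded$rs1, c(2L, 1L, 0L))

  bad <- tbl
  bad$rs1 <- c("AA", "CT", "GG") # neither declared allele
  attr(bad, "snp_cols") <- "rs1"
  expect_error(derive_coded_variables(bad, snp_info = info),
               class = "t2dvar_domain_error")
  expect_error(derive_coded_variables(tbl), "snp_info",
               class = "t2dvar_domain_error")
})
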