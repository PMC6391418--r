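test_that("genotype draws follow Hardy-Weinberg probabilities", {
  expect_identical(simulate_genotypes(0, 100, seed = 1), rep(0L, 100))
  expect_identical(simulate_genotypes(1, 50, seed = 1), rep(2L, 50))
  expect_error(simulate_genotypes(1.2, 10), class = "t2dvar_domain_error")

  # brute-force HWE expansion at raf 0.30: (0.49, 0.42, 0.09)
  n <- 1e5
  g <- simulate_genotypes(0.30, n, seed = 7)
  probs <- c((1 - 0.3)^2, 2 * 0.3 * 0.7, 0.3^2)
  obs <- vapply(0:2, function(k) mean(g == k), numeric(1))
  tol <- 3 * sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(obs - probs) < tol))

  expect_identical(simulate_genotypes(0.3, 1000, seed = 5),
                   simulate_genotypes(0.3, 1000, seed = 5))
})

test_that("parental-history draws converge to the requested margins", {
  expect_identical(simulate_parental_history(c(1, 0, 0), 200, seed = 1),
                   rep(0L, 200))
  expect_error(simulate_parental_history(c(0.5, 0.3, 0.1), 10),
               class = "t2dvar_domain_error")
  expect_error(simulate_parental_history(c(-0.1, 0.6, 0.5), 10),
               class = "t2dvar_domain_error")

  margins <- c(0.703, 0.252, 0.045)
  n <- 1e5
  ph <- simulate_parental_history(margins, n, seed = 11)
  obs <- vapply(0:2, function(k) mean(ph == k), numeric(1))
  tol <- 3 * sqrt(margins * (1 - margins) / n)
  expect_true(all(abs(obs - margins) < tol))
})

test_that("case anthropometry declines with duration at the configured slope", {
  cfg <- sim_config(seed = 3)
  n <- 20000
  yrs <- runif(n, 0, 20)
  a <- simulate_anthropometry(cfg, rep("case", n), yrs, seed = 3)
  expect_true(all(a$bmi >= 15) && all(a$hip > 0) && all(a$waist > 0))
  expect_error(simulate_anthropometry(cfg, "case", -1),
               class = "t2dvar_domain_error")

  # least-squares oracle on duration-bin medians recovers -decay_slope
  df <- tibble::tibble(status = "case", years_with_disease = yrs, bmi = a$bmi)
  tr <- duration_trend(df, breaks = c(0, 3, 5, 7, 9, 11, 13, 15, 17, 20.01))
  fit <- lm(median ~ midpoint, data = tibble::as_tibble(tr))
  ci <- confint(fit)["midpoint", ]
  expect_true(ci[1] < -cfg$bmi_decay_slope && -cfg$bmi_decay_slope < ci[2])
  expect_lt(attr(tr, "r"), -0.9)

  # zero slope: stationary medians across duration bins
  cfg0 <- sim_config(bmi_decay_slope = 0, bmi_noise_sd = 0, seed = 4)
  a0 <- simulate_anthropometry(cfg0, rep("case", n), yrs, seed = 4)
  df0 <- tibble::tibble(status = "case", years_with_disease = yrs, bmi = a0$bmi)
  tr0 <- tibble::as_tibble(duration_trend(df0))
  slope0 <- coef(lm(median ~ midpoint, data = tr0))[2]
  expect_lt(abs(slope0), 0.05)
})

test_that("simulated cohorts are reproducible and respect requested counts", {
  cfg <- sim_config(n_cases = 150, n_controls = 120, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(sum(a$status == "case"), 150)
  expect_equal(sum(a$status == "control"), 120)
  expect_false(any(duplicated(a$subject_id)))
  # case bookkeeping: enrolment age = diagnosis age + duration
  cases <- dplyr::filter(a, status == "case")
  expect_equal(cases$age_enrol, cases$age_dx + cases$years_with_disease)
  expect_true(all(is.na(a$age_dx[a$status == "control"])))
})

test_that("null generating effects give null fitted odds ratios", {
  panel <- default_snp_panel()
  panel$log_or <- 0
  cfg <- sim_config(n_cases = 1500, n_controls = 1500, snp_panel = panel,
                    ph_log_ors = c(0, 0), bmi_per_unit_log_or = 0,
                    whr_sd_log_or = 0, seed = 21)
  coh <- derive_coded_variables(simulate_cohort(cfg))
  for (term in c("rs75493593", "ph_count", "bmi_onset")) {
    fit <- fit_logistic(coh, term)
    or <- wald_or_ci(fit)
    expect_true(all(or$conf.low < 1 & 1 < or$conf.high),
                label = sprintf("null OR CI for %s covers 1", term))
  }
})

test_that("case-control sampling preserves a generating per-allele OR of 1.5", {
  panel <- tibble::tibble(snp_id = "rs_test", gene = "TEST", raf = 0.3,
                          log_or = log(1.5))
  cfg <- sim_config(n_cases = 2500, n_controls = 2500, snp_panel = panel,
                    female_gene_attenuation = 1, seed = 31)
  coh <- derive_coded_variables(simulate_cohort(cfg))
  fit <- fit_logistic(coh, c("rs_test", "factor(ph_count)", "bmi_onset", "whr"))
  td <- tidy(fit)
  row <- td[td$term == "rs_test", ]
  expect_true(row$estimate - 1.96 * row$std.error < log(1.5) &&
                log(1.5) < row$estimate + 1.96 * row$std.error)
})

test_that("female gene-effect attenuation yields larger male genetic r2", {
  cfg <- sim_config(n_cases = 1000, n_controls = 1000,
                    female_gene_attenuation = 0.5, seed = 51)
  coh <- derive_coded_variables(simulate_cohort(cfg))
  terms <- snp_cols(coh)
  r2 <- vapply(c("male", "female"), function(s) {
    nagelkerke_r2(fit_logistic(dplyr::filter(coh, sex == s), terms))
  }, numeric(1))
  expect_gt(r2[["male"]], r2[["female"]])
})

test_that("parental history couples to the genetic score only when asked", {
  cfg1 <- sim_config(n_cases = 800, n_controls = 800, ph_gene_cor = 0.5,
                     seed = 61)
  coh1 <- derive_coded_variables(simulate_cohort(cfg1))
  score <- as.matrix(coh1[, snp_cols(coh1)]) %*% cfg1$snp_panel$log_or
  expect_gt(cor(score, coh1$ph_count), 0.1)

  cfg0 <- sim_config(n_cases = 800, n_controls = 800, ph_gene_cor = 0,
                     seed = 61)
  coh0 <- derive_coded_variables(simulate_cohort(cfg0))
  score0 <- as.matrix(coh0[, snp_cols(coh0)]) %*% cfg0$snp_panel$log_or
  expect_lt(abs(cor(score0, coh0$ph_count)), 0.08)
})

test_that("unsatisfiable configurations fail after bounded retries", {
  cfg <- sim_config(n_cases = 500, n_controls = 0, base_prevalence = 0.01,
                    seed = 1)
  expect_error(simulate_cohort(cfg, max_rounds = 1L),
               class = "t2dvar_generation_error")
})
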