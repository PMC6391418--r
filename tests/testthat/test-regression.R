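test_that("2x2 logistic ORs equal the cross-product ratio to 6 significant digits", {
  for (study in c("main", "replica")) {
    for (fac in c("father", "mother")) {
      counts <- dplyr::filter(ph_reference_counts(study), factor == fac)
      fit <- fit_logistic(expand_ph(study, fac), fac)
      cross <- (counts$cases[2] * counts$controls[1]) /
        (counts$controls[2] * counts$cases[1])
      expect_equal(exp(fit$coefficients[2]) / cross, 1, tolerance = 1e-7,
                   label = sprintf("%s %s OR vs cross-product", study, fac))
    }
  }
})

test_that("Wald intervals reproduce the published maternal-history CI", {
  fit <- fit_logistic(expand_ph("main", "mother"), "mother")
  or <- wald_or_ci(fit)
  expect_equal(round(or$or, 1), 3.2)
  expect_equal(round(or$conf.low, 2), 2.63)
  expect_equal(round(or$conf.high, 1), 3.9)
  expect_equal(or$stars, "e")
})

test_that("a null coefficient gives OR 1 with p 1", {
  set.seed(1)
  df <- tibble::tibble(status = rep(c("case", "control"), each = 500),
                       x = rep(c(0, 1), 500))
  fit <- fit_logistic(df, "x")
  or <- wald_or_ci(fit)
  expect_equal(or$or, 1, tolerance = 1e-8)
  expect_equal(or$p.value, 1, tolerance = 1e-6)
})

test_that("Nagelkerke r2 matches published values and its invariances", {
  fit_f <- fit_logistic(expand_ph("main", "father"), "father")
  fit_m <- fit_logistic(expand_ph("main", "mother"), "mother")
  expect_equal(round(nagelkerke_r2(fit_f), 3), 0.052)
  expect_equal(round(nagelkerke_r2(fit_m), 2), 0.09)

  # LL = LL0 => r2 = 0
  expect_equal(nagelkerke_r2(list(ll = -100, ll0 = -100, n = 50)), 0)

  # swapping case/control labels (sign of beta flips) leaves r2 unchanged
  tab <- expand_ph("main", "both_parents")
  swapped <- dplyr::mutate(tab,
                           status = ifelse(status == "case", "control", "case"))
  expect_equal(nagelkerke_r2(fit_logistic(swapped, "both_parents")),
               nagelkerke_r2(fit_logistic(tab, "both_parents")),
               tolerance = 1e-9)
})

test_that("saturated categorical log-likelihood equals the closed-form cell likelihood", {
  counts <- dplyr::filter(ph_reference_counts("main"), factor == "both_parents")
  fit <- fit_logistic(expand_ph("main", "both_parents"), "both_parents")
  expect_equal(fit$ll, saturated_ll(counts$controls, counts$cases),
               tolerance = 1e-8)
  expect_equal(fit$ll0, null_ll(counts$controls, counts$cases),
               tolerance = 1e-10)
})

test_that("omnibus test matches the closed-form likelihood-ratio oracle", {
  counts <- dplyr::filter(ph_reference_counts("main"), factor == "father")
  fit <- fit_logistic(expand_ph("main", "father"), "father")
  om <- omnibus_test(NULL, fit)
  oracle <- 2 * (saturated_ll(counts$controls, counts$cases) -
                   null_ll(counts$controls, counts$cases))
  expect_equal(om$statistic, oracle, tolerance = 1e-6)
  expect_equal(om$df, 1L)
  expect_lt(om$p.value, 1e-15)

  # identical models: statistic 0, p 1
  self <- omnibus_test(fit, fit)
  expect_equal(self$statistic, 0, tolerance = 1e-10)
  expect_equal(self$p.value, 1)

  # invariance to predictor rescaling
  coh <- test_cohort()
  f1 <- fit_logistic(coh, "bmi_onset")
  coh$bmi_x10 <- coh$bmi_onset * 10
  f2 <- fit_logistic(coh, "bmi_x10")
  expect_equal(omnibus_test(NULL, f1)$statistic,
               omnibus_test(NULL, f2)$statistic, tolerance = 1e-8)

  # different rows is a hard error
  f3 <- fit_logistic(coh[-1, ], "bmi_onset")
  expect_error(omnibus_test(f3, f1), class = "t2dvar_domain_error")
})

test_that("perfect separation is flagged rather than reported as converged", {
  df <- tibble::tibble(status = rep(c("case", "control"), each = 20),
                       x = rep(c(1, 0), each = 20))
  fit <- suppressWarnings(fit_logistic(df, "x"))
  expect_false(fit$converged)
  expect_true(fit$separated)
  expect_error(wald_or_ci(fit), class = "t2dvar_fit_error")
})

test_that("hierarchical decomposition is monotone and matches single fits", {
  coh <- test_cohort()
  blocks <- list(PH = "factor(ph_count)", BMI = "bmi_onset", WHR = "whr")
  dec <- hierarchical_decomposition(coh, blocks)
  expect_true(all(diff(dec$minus2ll) <= 1e-8))
  expect_true(all(diff(dec$r2) >= -1e-10))
  expect_equal(sum(dec$delta_r2), dec$r2[nrow(dec)], tolerance = 1e-12)

  # one block reduces to a single multivariate fit
  one <- hierarchical_decomposition(coh, blocks["PH"])
  solo <- fit_logistic(coh[complete.cases(coh[, c("ph_count", "bmi_onset",
                                                  "whr")]), ],
                       "factor(ph_count)")
  expect_equal(one$r2, nagelkerke_r2(solo), tolerance = 1e-9)
  expect_equal(one$p_block, one$p_model)

  expect_error(hierarchical_decomposition(coh, list(a = character(0))),
               class = "t2dvar_domain_error")
  expect_error(hierarchical_decomposition(coh, list(a = "whr", b = "whr")),
               class = "t2dvar_domain_error")
})

test_that("independent factors contribute near-orthogonal r2 increments", {
  set.seed(17)
  n <- 4000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 * x1 + 0.5 * x2))
  df <- tibble::tibble(status = y, x1 = x1, x2 = x2)
  dec <- hierarchical_decomposition(df, list(first = "x1", second = "x2"))
  solo2 <- nagelkerke_r2(fit_logistic(df, "x2"))
  expect_lt(abs(dec$delta_r2[2] - solo2), 0.02)
})

test_that("noise blocks contribute nothing", {
  set.seed(23)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * x))
  df <- tibble::tibble(status = y, x = x, z1 = rnorm(n), z2 = rnorm(n))
  dec <- hierarchical_decomposition(df, list(signal = "x", noise = c("z1", "z2")))
  expect_lt(dec$delta_r2[2], 0.01)
  expect_gt(dec$p_block[2], 0.001)
})

test_that("confounder screen keeps planted confounders and drops noise", {
  set.seed(31)
  n <- 3000
  z <- rnorm(n)                       # confounder: drives exposure and outcome
  x <- rbinom(n, 1, plogis(1.2 * z))
  w <- rnorm(n)                       # pure noise
  y <- rbinom(n, 1, plogis(0.5 * x + 1.0 * z))
  df <- tibble::tibble(status = y, x = x, z = z, w = w)
  scr <- confounder_screen(df, "status", "x", c("z", "w"))
  expect_true("z" %in% scr$selected)
  expect_true(scr$report$confounder[scr$report$candidate == "z"])
  expect_false("w" %in% scr$selected)

  # a candidate failing the univariate filter never enters
  expect_false(scr$report$entered[scr$report$candidate == "w"] &&
                 scr$report$p_univariate[scr$report$candidate == "w"] > 0.2)
  expect_error(confounder_screen(df, "status", "x", c("x", "z")),
               class = "t2dvar_domain_error")
})

test_that("post-hoc power behaves as a power function should", {
  expect_equal(posthoc_power(1, 0.3, 500), 0.05, tolerance = 1e-12)
  p <- vapply(c(100, 200, 400, 800, 1600),
              function(n) posthoc_power(1.5, 0.3, n, p_exposed = 0.25),
              numeric(1))
  expect_true(all(diff(p) > 0))
  expect_gt(posthoc_power(1.5, 0.3, 400, r2_other = 0),
            posthoc_power(1.5, 0.3, 400, r2_other = 0.3))
  expect_error(posthoc_power(1.5, 0.3, 400, r2_other = 1),
               class = "t2dvar_domain_error")
  expect_error(posthoc_power(-1, 0.3, 400), class = "t2dvar_domain_error")
})
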