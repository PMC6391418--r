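#' Descriptive comparison of cases and controls
#'
#' Continuous variables are summarised as mean +/- SD and compared by
#' Welch's t-test, or (when listed in `median_vars`) as median (IQR) and
#' compared by the Mann-Whitney U-test; categorical variables as % (n)
#' with a chi-square test. P-values carry the star coding of
#' [p_stars()]. All-missing columns are dropped with a warning; a group
#' with fewer than 2 observations has no SD and is flagged.
#'
#' @param table Cohort tibble.
#' @param vars Columns to summarise.
#' @param group Binary grouping column (default `"status"`).
#' @param median_vars Subset of `vars` to summarise by median/IQR.
#' @param strata Optional column (e.g. `"sex"`); summaries are then
#'   produced per stratum plus the pooled sample.
#' @return Tibble with one row per variable (and level, for categorical
#'   variables): group summaries, test used, statistic, p-value, stars.
#' @export
descriptive_table <- function(table, vars, group = "status",
                              median_vars = NULL, strata = NULL) {
  g <- table[[group]]
  lev <- sort(unique(as.character(g[!is.na(g)])))
  if (length(lev) != 2) stop_domain("grouping variable must be binary")
  if (!is.null(strata)) {
    pieces <- c(split(table, table[[strata]]), list(all = table))
    return(purrr::imap_dfr(pieces, function(piece, nm) {
      dplyr::mutate(
        descriptive_table(piece, vars, group, median_vars, strata = NULL),
        stratum = nm, .before = 1)
    }))
  }
  one_var <- function(v) {
    x <- table[[v]]
    if (all(is.na(x))) {
      warn(sprintf("column `%s` all missing: dropped", v))
      return(NULL)
    }
    x1 <- x[g == lev[1] & !is.na(g)]
    x2 <- x[g == lev[2] & !is.na(g)]
    if (is.numeric(x)) {
      use_median <- v %in% median_vars
      flag <- sum(!is.na(x1)) < 2 || sum(!is.na(x2)) < 2
      if (use_median) {
        tst <- tryCatch(suppressWarnings(wilcox.test(x1, x2)),
                        error = function(e) NULL)
        s1 <- sprintf("%.1f (%.1f-%.1f)", median(x1, na.rm = TRUE),
                      quantile(x1, .25, na.rm = TRUE), quantile(x1, .75, na.rm = TRUE))
        s2 <- sprintf("%.1f (%.1f-%.1f)", median(x2, na.rm = TRUE),
                      quantile(x2, .25, na.rm = TRUE), quantile(x2, .75, na.rm = TRUE))
        test <- "mann-whitney"
      } else {
        tst <- if (flag) NULL else
          tryCatch(t.test(x1, x2), error = function(e) NULL)
        s1 <- sprintf("%.1f ± %.1f (%d)", mean(x1, na.rm = TRUE),
                      sd(x1, na.rm = TRUE), sum(!is.na(x1)))
        s2 <- sprintf("%.1f ± %.1f (%d)", mean(x2, na.rm = TRUE),
                      sd(x2, na.rm = TRUE), sum(!is.na(x2)))
        test <- "t"
      }
      tibble::tibble(
        variable = v, level = NA_character_,
        !!lev[1] := s1, !!lev[2] := s2,
        test = test,
        statistic = if (is.null(tst)) NA_real_ else unname(tst$statistic),
        p.value = if (is.null(tst)) NA_real_ else tst$p.value,
        flag = if (flag) "insufficient n for SD/test" else NA_character_
      )
    } else {
      tab <- table(factor(x), factor(as.character(g), levels = lev))
      tst <- tryCatch(suppressWarnings(chisq.test(tab)),
                      error = function(e) NULL)
      pct <- prop.table(tab, margin = 2) * 100
      purrr::map_dfr(rownames(tab), function(lv) {
        tibble::tibble(
          variable = v, level = lv,
          !!lev[1] := sprintf("%.1f (%d)", pct[lv, 1], tab[lv, 1]),
          !!lev[2] := sprintf("%.1f (%d)", pct[lv, 2], tab[lv, 2]),
          test = "chi-square",
          statistic = if (is.null(tst)) NA_real_ else unname(tst$statistic),
          p.value = if (is.null(tst)) NA_real_ else tst$p.value,
          flag = NA_character_
        )
      })
    }
  }
  out <- purrr::map_dfr(vars, one_var)
  out$stars <- p_stars(out$p.value)
  out
}

#' Univariate logistic-regression catalogue
#'
#' One univariate logistic regression per factor, each on that factor's
#' own complete cases, reporting per-level percentages and counts by
#' status, Wald ORs with 95% CIs against the factor's first level, the
#' model's Nagelkerke r2 and omnibus p-value. Factors with a single
#' observed level are skipped with a warning.
#'
#' @param table Coded cohort tibble.
#' @param factors Character vector of factor columns (converted to
#'   factors if needed; numeric 0/1/2 codings are treated as
#'   categorical).
#' @param outcome Outcome column.
#' @return Tibble mirroring a published univariate association table:
#'   one row per factor level.
#' @export
ulr_catalog <- function(table, factors, outcome = "status") {
  purrr::map_dfr(factors, function(fac) {
    x <- table[[fac]]
    keep <- !is.na(x) & !is.na(table[[outcome]])
    tbl <- table[keep, , drop = FALSE]
    x <- x[keep]
    if (!is.factor(x)) x <- factor(x)
    if (nlevels(droplevels(x)) < 2) {
      warn(sprintf("factor `%s` has one level: skipped", fac))
      return(NULL)
    }
    tbl$.fac <- droplevels(x)
    fit <- fit_logistic(tbl, ".fac", outcome)
    orci <- wald_or_ci(fit)
    r2 <- nagelkerke_r2(fit)
    p_om <- omnibus_test(NULL, fit)$p.value
    y <- status_to_binary(tbl[[outcome]])
    counts <- table(tbl$.fac, y)
    pct <- prop.table(counts, margin = 2) * 100
    lv <- levels(tbl$.fac)
    tibble::tibble(
      factor = fac,
      level = lv,
      control_pct = unname(pct[lv, "0"]),
      control_n = as.integer(counts[lv, "0"]),
      case_pct = unname(pct[lv, "1"]),
      case_n = as.integer(counts[lv, "1"]),
      or = c(1, orci$or),
      conf.low = c(NA, orci$conf.low),
      conf.high = c(NA, orci$conf.high),
      p.value = c(NA, orci$p.value),
      stars = c(NA, orci$stars),
      r2 = r2,
      p_omnibus = p_om,
      n = fit$n
    )
  })
}

# sample-size floors for stratified multivariate models
meets_floor <- function(n_cases, n_terms, min_cases_per_term = 15,
                        min_cases = 50) {
  n_cases >= min_cases && n_cases >= min_cases_per_term * n_terms
}

#' Stratified block-wise decompositions
#'
#' Runs [hierarchical_decomposition()] in strata defined by a case-level
#' stratifier (for example the early/late median split of age at
#' diagnosis) crossed with sex (each sex plus both together). Controls
#' carry no age at diagnosis, so for case-only stratifiers the full
#' control group (of the matching sex) is reused in every stratum. Cells
#' below the sample-size floor — fewer than `min_cases` cases or fewer
#' than `min_cases_per_term` cases per model term — are reported as
#' insufficient and not fitted.
#'
#' @param table Coded cohort tibble.
#' @param blocks Named list of term blocks (see
#'   [hierarchical_decomposition()]).
#' @param stratify_by Case-level stratifier column (e.g.
#'   `"agedx_split"`), or `NULL` for the whole sample; levels with
#'   missing values are dropped from the case side.
#' @param by_sex Cross the stratifier with sex (default TRUE).
#' @param min_cases_per_term,min_cases Sample-size floors.
#' @param outcome Outcome column.
#' @return Tibble with one row per stratum-by-sex cell: counts, fit
#'   status, total r2, and the full `decomposition_result` in the
#'   `result` list-column (NULL where refused).
#' @export
stratified_decomposition <- function(table, blocks, stratify_by = NULL,
                                     by_sex = TRUE,
                                     min_cases_per_term = 15, min_cases = 50,
                                     outcome = "status") {
  n_terms_total <- length(unlist(blocks))
  strata_levels <- if (is.null(stratify_by)) {
    "all"
  } else {
    c(levels(factor(table[[stratify_by]])), "all")
  }
  sex_levels <- if (by_sex) c("female", "male", "both") else "both"
  grid <- tidyr::expand_grid(stratum = strata_levels, sex = sex_levels)
  res <- purrr::pmap(grid, function(stratum, sex) {
    piece <- table
    if (sex != "both") piece <- dplyr::filter(piece, .data$sex == !!sex)
    if (stratum != "all") {
      is_case <- piece[[outcome]] == "case"
      in_stratum <- !is.na(piece[[stratify_by]]) &
        as.character(piece[[stratify_by]]) == stratum
      # controls (no stratifier value) are reused in every stratum
      piece <- piece[(!is_case) | in_stratum, , drop = FALSE]
    }
    n_cases <- sum(piece[[outcome]] == "case", na.rm = TRUE)
    n_controls <- sum(piece[[outcome]] == "control", na.rm = TRUE)
    if (!meets_floor(n_cases, n_terms_total, min_cases_per_term, min_cases)) {
      return(list(n_cases = n_cases, n_controls = n_controls,
                  fit_status = "insufficient n", result = list(NULL),
                  total_r2 = NA_real_))
    }
    dec <- hierarchical_decomposition(piece, blocks, outcome)
    list(n_cases = attr(dec, "n_cases"),
         n_controls = attr(dec, "n") - attr(dec, "n_cases"),
         fit_status = "ok", result = list(dec),
         total_r2 = dec$r2[nrow(dec)])
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(lapply(res, tibble::as_tibble)))
}

#' Age-matched female resampling
#'
#' Tests whether a sex difference in the genetic contribution to disease
#' variability is an artefact of unequal sample sizes or age structure:
#' repeatedly samples groups of women 1:1 matched to the men of the
#' cohort — cases matched on age at diagnosis, controls on enrolment age
#' (controls have no diagnosis age), exact year first, then a +/-
#' `age_tol`-year fallback — fits the SNP multivariate logistic model on
#' each matched female group, and summarises the per-replicate Nagelkerke
#' r2. Women are sampled without replacement within a replicate and
#' independently across replicates.
#'
#' @param table Coded cohort tibble with `sex`, `age_dx`, `age_enrol`.
#' @param terms Model terms for the per-replicate fit; default: every SNP
#'   column as an indicator-coded factor.
#' @param group_size Number of men to match (and women to draw) per
#'   replicate; must not exceed the available men or women.
#' @param n_groups Number of replicates.
#' @param age_tol Fallback matching tolerance in years.
#' @param seed Seed controlling all replicate draws.
#' @return An object of class `resampling_result`: list with
#'   `replicates` (per-replicate r2 and fallback counts), `median_r2`,
#'   `mean_r2`, `group_size`, `n_groups`, `seed`.
#' @export
matched_female_resampling <- function(table, terms = NULL, group_size = 950,
                                      n_groups = 100, age_tol = 1,
                                      seed = 1L) {
  if (is.null(terms)) {
    sc <- snp_cols(table)
    if (length(sc) == 0) stop_domain("no SNP columns and no terms given")
    terms <- sprintf("factor(%s)", sc)
  }
  men <- dplyr::filter(table, .data$sex == "male")
  women <- dplyr::filter(table, .data$sex == "female")
  if (group_size > nrow(men)) {
    stop_domain("group_size (%d) exceeds available men (%d)",
                group_size, nrow(men))
  }
  if (group_size > nrow(women)) {
    stop_domain("group_size (%d) exceeds available women (%d)",
                group_size, nrow(women))
  }
  match_age <- function(tbl) {
    ifelse(tbl$status == "case" & !is.na(tbl$age_dx),
           tbl$age_dx, tbl$age_enrol)
  }
  men$.age <- round(match_age(men))
  women$.age <- round(match_age(women))

  one_rep <- function(rep_i) {
    with_substream(seed, 100L + rep_i, {
      m <- men[sample.int(nrow(men), group_size), , drop = FALSE]
      avail <- women
      picked <- integer(0)
      fallback <- 0L
      for (i in seq_len(nrow(m))) {
        cand <- which(avail$status == m$status[i] & avail$.age == m$.age[i])
        if (length(cand) == 0) {
          cand <- which(avail$status == m$status[i] &
                          abs(avail$.age - m$.age[i]) <= age_tol)
          if (length(cand) == 0) {
            abort(sprintf(
              "no woman matches a %s aged %d within +/-%g years",
              m$status[i], m$.age[i], age_tol),
              class = "t2dvar_matching_error")
          }
          fallback <- fallback + 1L
        }
        j <- cand[sample.int(length(cand), 1)]
        picked <- c(picked, which(women$subject_id == avail$subject_id[j]))
        avail <- avail[-j, , drop = FALSE]
      }
      grp <- women[picked, , drop = FALSE]
      fit <- suppressWarnings(fit_logistic(grp, terms))
      tibble::tibble(replicate = rep_i, r2 = nagelkerke_r2(fit),
                     n = fit$n, n_fallback = fallback)
    })
  }
  reps <- purrr::map_dfr(seq_len(n_groups), one_rep)
  structure(
    list(replicates = reps,
         median_r2 = median(reps$r2),
         mean_r2 = mean(reps$r2),
         group_size = group_size,
         n_groups = n_groups,
         seed = seed),
    class = "resampling_result"
  )
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf(
    "<resampling_result> %d groups of %d age-matched women: median r2 = %.4f (mean %.4f)\n",
    x$n_groups, x$group_size, x$median_r2, x$mean_r2))
  invisible(x)
}

#' @export
#' @method tidy resampling_result
tidy.resampling_result <- function(x, ...) x$replicates

#' @export
#' @method glance resampling_result
glance.resampling_result <- function(x, ...) {
  tibble::tibble(n_groups = x$n_groups, group_size = x$group_size,
                 median_r2 = x$median_r2, mean_r2 = x$mean_r2,
                 sd_r2 = sd(x$replicates$r2))
}

#' Run the full variance-decomposition analysis
#'
#' End-to-end orchestration on a subject-level cohort: derive coded
#' variables; Hardy-Weinberg scan in controls; duration trends and
#' quantile-map adjustment of BMI, waist and hip; descriptive
#' comparison; univariate catalogue of parental history and BMI
#' category; the four-block decomposition (SNPs, PH, adjusted BMI, WHR)
#' overall and stratified by the age-at-diagnosis split crossed with
#' sex; optional age-matched female resampling; and post-hoc power
#' annotations for the final models. Every random step is seeded from
#' `seed`; two runs with identical inputs and seed produce identical
#' report JSON.
#'
#' @param table Cohort tibble (raw; coding is applied internally).
#' @param seed Integer seed.
#' @param snp_terms Terms for the SNP block; default indicator-coded
#'   factors of every SNP column.
#' @param resample Run the female resampling stage (slowest stage)?
#' @param resample_groups,resample_size Resampling replicates and group
#'   size; `resample_size = NULL` matches all available men.
#' @param agedx_cuts,split_age Passed to [derive_coded_variables()].
#' @return A list of class `t2d_report` with one element per stage.
#' @export
run_full_analysis <- function(table, seed = 1L, snp_terms = NULL,
                              resample = FALSE, resample_groups = 100,
                              resample_size = NULL,
                              agedx_cuts = NULL, split_age = 45) {
  coded <- derive_coded_variables(table, agedx_cuts = agedx_cuts,
                                  split_age = split_age)
  sc <- snp_cols(coded)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            class = "t2dvar_stage_error", parent = e)
    })
  }

  hwe <- stage("hwe", if (length(sc) > 0) hwe_scan(coded, "control") else NULL)

  trends <- stage("trends", purrr::map(
    setNames(c("bmi", "waist", "hip", "whr"), c("bmi", "waist", "hip", "whr")),
    function(m) if (m %in% names(coded)) duration_trend(coded, m) else NULL))

  adjusted <- coded
  models <- list()
  for (m in c("bmi", "waist", "hip")) {
    if (!m %in% names(coded)) next
    cases <- dplyr::filter(coded, .data$status == "case",
                           !is.na(.data$years_with_disease), !is.na(.data[[m]]))
    ref <- cases[[m]][cases$years_with_disease < 3]
    tar <- cases[[m]][cases$years_with_disease >= 3]
    models[[m]] <- stage(paste0("adjust_", m),
                         fit_adjustment_model(ref, tar, measure = m))
    adjusted <- apply_adjustment(adjusted, models[[m]])
  }

  desc <- stage("descriptive", descriptive_table(
    adjusted,
    vars = intersect(c("age_enrol", "bmi", "waist", "hip", "whr",
                       "age_dx", "years_with_disease", "ph_count"),
                     names(adjusted)),
    median_vars = "years_with_disease"))

  ulr <- stage("ulr", ulr_catalog(
    adjusted, intersect(c("ph_count", "bmi_cat"), names(adjusted))))

  if (is.null(snp_terms)) snp_terms <- sprintf("factor(%s)", sc)
  blocks <- list(SNPs = snp_terms,
                 PH = "factor(ph_count)",
                 BMI = "adj_bmi",
                 WHR = "whr")
  blocks <- blocks[c(length(snp_terms) > 0, TRUE,
                     "adj_bmi" %in% names(adjusted),
                     "whr" %in% names(adjusted))]
  strat <- stage("decomposition", stratified_decomposition(
    adjusted, blocks,
    stratify_by = if ("agedx_split" %in% names(adjusted)) "agedx_split" else NULL))

  resamp <- NULL
  if (resample) {
    size <- resample_size %||% sum(adjusted$sex == "male")
    resamp <- stage("resample", matched_female_resampling(
      adjusted, group_size = size, n_groups = resample_groups, seed = seed))
  }

  power <- stage("power", {
    overall <- strat[strat$stratum == "all" & strat$sex == "both", ]
    if (nrow(overall) == 1 && overall$fit_status == "ok") {
      dec <- overall$result[[1]]
      p0 <- attr(dec, "n_cases") / attr(dec, "n")
      tibble::tibble(
        model = "all/both",
        n = attr(dec, "n"),
        total_r2 = dec$r2[nrow(dec)],
        power_or_1.5 = posthoc_power(1.5, p0, attr(dec, "n"),
                                     r2_other = dec$r2[nrow(dec)])
      )
    } else NULL
  })

  structure(
    list(seed = seed, hwe = hwe, trends = trends,
         adjustment_models = models, descriptive = desc, ulr = ulr,
         decomposition = strat, resampling = resamp, power = power),
    class = "t2d_report"
  )
}

#' Serialise a report bundle to JSON
#'
#' Machine-readable mirror of every stage of [run_full_analysis()];
#' deterministic for a given report (digits capped only by the JSON
#' writer's default full precision).
#'
#' @param report A `t2d_report`.
#' @param path Optional file to write; omitted, the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to file.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "t2d_report"))
  strat <- report$decomposition
  strat_out <- purrr::pmap(strat, function(stratum, sex, n_cases, n_controls,
                                           fit_status, result, total_r2) {
    list(stratum = stratum, sex = sex, n_cases = n_cases,
         n_controls = n_controls, fit_status = fit_status,
         total_r2 = total_r2,
         blocks = if (!is.null(result)) tibble::as_tibble(result) else NULL)
  })
  payload <- list(
    seed = report$seed,
    hwe = report$hwe,
    trends = purrr::map(purrr::compact(report$trends), function(tr) {
      list(measure = attr(tr, "measure"), r = attr(tr, "r"),
           p.value = attr(tr, "p.value"), bins = tibble::as_tibble(tr))
    }),
    adjustment_models = purrr::map(report$adjustment_models, unclass),
    descriptive = report$descriptive,
    ulr = report$ulr,
    decomposition = strat_out,
    resampling = if (!is.null(report$resampling)) {
      r <- report$resampling
      list(median_r2 = r$median_r2, mean_r2 = r$mean_r2,
           group_size = r$group_size, n_groups = r$n_groups,
           replicates = r$replicates)
    } else NULL,
    power = report$power
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.t2d_report <- function(x, ...) {
  cat("<t2d_report>\n")
  overall <- x$decomposition[x$decomposition$stratum == "all" &
                               x$decomposition$sex == "both", ]
  if (nrow(overall) == 1 && overall$fit_status == "ok") {
    cat(sprintf("  total r2 (all, both sexes): %.3f\n", overall$total_r2))
  }
  cat("  stages:", paste(names(x)[!purrr::map_lgl(x, is.null)], collapse = ", "), "\n")
  invisible(x)
}
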