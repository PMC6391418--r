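#' Fit a logistic regression of case-control status
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, log-likelihood tolerance 1e-8, at most 100 iterations) of a
#' binary outcome on a set of terms, on the complete cases for those
#' terms. Categorical predictors expand to indicator terms against their
#' first (reference) level — the conventions used throughout this package
#' are BMI `<25`, 0 affected parents and 0 risk alleles as references.
#' Perfect separation is detected (diverging coefficients) and flagged on
#' the returned fit rather than failing.
#'
#' @param data A data frame.
#' @param terms Character vector of model terms; entries may be bare
#'   column names or formula expressions such as `"factor(rs7903146)"`.
#' @param outcome Outcome column (default `"status"`, coded
#'   case/control or 0/1).
#' @param min_cases_per_term Emit a warning when the number of cases is
#'   below this multiple of the number of estimated slope terms
#'   (default 15).
#' @return An object of class `logistic_fit` with coefficients, standard
#'   errors, log-likelihoods (fitted and intercept-only null on the same
#'   rows), effective `n`, and convergence/separation flags.
#' @export
#' @examples
#' tab <- expand_counts(dplyr::filter(ph_reference_counts("main"),
#'                                    factor == "father"))
#' fit <- fit_logistic(tab, "father")
#' tidy(fit)
fit_logistic <- function(data, terms, outcome = "status",
                         min_cases_per_term = 15) {
  if (length(terms) == 0) stop_domain("no model terms given")
  f <- as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  vars <- setdiff(all.vars(f), ".y")
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop_domain("term column(s) not in data: %s",
                paste(missing_cols, collapse = ", "))
  }
  y <- status_to_binary(data[[outcome]])
  keep <- !is.na(y) & complete.cases(data[, vars, drop = FALSE])
  df <- data[keep, vars, drop = FALSE]
  df$.y <- y[keep]
  n <- nrow(df)
  if (n == 0) stop_domain("no complete cases")
  if (length(unique(df$.y)) < 2) {
    stop_domain("outcome must have both classes present")
  }
  fit <- suppressWarnings(
    glm(f, family = binomial(), data = df,
        control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  beta <- coef(fit)
  separated <- !fit$converged || any(abs(beta[-1]) > 15, na.rm = TRUE) ||
    any(is.na(beta))
  n_slopes <- length(beta) - 1
  n_cases <- sum(df$.y)
  if (!separated && n_slopes > 0 && n_cases < min_cases_per_term * n_slopes) {
    warn(sprintf("only %d cases for %d terms (< %d per term)",
                 n_cases, n_slopes, min_cases_per_term))
  }
  ll <- as.numeric(logLik(fit))
  pbar <- mean(df$.y)
  ll0 <- n_cases * log(pbar) + (n - n_cases) * log(1 - pbar)
  se <- rep(NA_real_, length(beta))
  v <- sqrt(diag(vcov(fit)))
  se[match(names(v), names(beta))] <- v
  structure(
    list(
      terms = terms,
      term_names = names(beta),
      coefficients = unname(beta),
      se = se,
      n = n,
      n_cases = n_cases,
      ll = ll,
      m2ll = -2 * ll,
      ll0 = ll0,
      m2ll0 = -2 * ll0,
      converged = !separated,
      separated = separated,
      outcome = outcome,
      model = fit
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d (%d cases), -2logL = %.2f, Nagelkerke r2 = %.4f%s\n",
              x$n, x$n_cases, x$m2ll, nagelkerke_r2(x),
              if (x$separated) " [possible separation: not converged]" else ""))
  print(tidy(x))
  invisible(x)
}

#' @export
#' @method tidy logistic_fit
tidy.logistic_fit <- function(x, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  est <- x$coefficients
  stat <- est / x$se
  tibble::tibble(
    term = x$term_names,
    estimate = est,
    std.error = x$se,
    statistic = stat,
    p.value = 2 * pnorm(-abs(stat)),
    or = exp(est),
    or.conf.low = exp(est - z * x$se),
    or.conf.high = exp(est + z * x$se)
  )
}

#' @export
#' @method glance logistic_fit
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_cases = x$n_cases,
    logLik = x$ll,
    minus2ll = x$m2ll,
    null_minus2ll = x$m2ll0,
    r2_cox_snell = 1 - exp(2 * (x$ll0 - x$ll) / x$n),
    r2_nagelkerke = nagelkerke_r2(x),
    converged = x$converged
  )
}

#' Wald odds ratios and confidence intervals
#'
#' OR = e^beta with CI e^(beta +/- z se) and two-sided Wald p-values, for
#' every slope term of a converged fit.
#'
#' @param fit A [fit_logistic()] result.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `term`, `or`, `conf.low`, `conf.high`, `p.value`,
#'   `stars`.
#' @export
wald_or_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) {
    abort("fit did not converge (possible separation); Wald intervals are meaningless",
          class = "t2dvar_fit_error")
  }
  td <- tidy(fit, conf.level = level)
  td <- td[td$term != "(Intercept)", , drop = FALSE]
  tibble::tibble(
    term = td$term,
    or = td$or,
    conf.low = td$or.conf.low,
    conf.high = td$or.conf.high,
    p.value = td$p.value,
    stars = p_stars(td$p.value)
  )
}

#' Nagelkerke pseudo-r-squared
#'
#' Cox-Snell r2 = 1 - exp(2 (LL0 - LL)/n), rescaled by its maximum
#' 1 - exp(2 LL0 / n) so the result spans `[0, 1]`. Used throughout as
#' "percent of case-control variability explained".
#'
#' @param fit A [fit_logistic()] result (or any list with `ll`, `ll0`,
#'   `n`).
#' @return A number in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  if (is.null(fit$n) || fit$n == 0) stop_domain("n = 0")
  cs <- 1 - exp(2 * (fit$ll0 - fit$ll) / fit$n)
  max_cs <- 1 - exp(2 * fit$ll0 / fit$n)
  r2 <- cs / max_cs
  min(max(r2, 0), 1)
}

#' Omnibus likelihood-ratio test between nested fits
#'
#' Chi-square statistic (-2LL_reduced) - (-2LL_full) on df = number of
#' added coefficients, requiring both fits to use the same rows (equal
#' effective n); a mismatch signals a complete-case inconsistency and is
#' an error.
#'
#' @param reduced,full Nested [fit_logistic()] results (the null model
#'   may be represented by `NULL` for `reduced`, using `full`'s own
#'   intercept-only likelihood).
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @export
omnibus_test <- function(reduced, full) {
  stopifnot(inherits(full, "logistic_fit"))
  if (is.null(reduced)) {
    m2ll_red <- full$m2ll0
    df_red <- 1L
    n_red <- full$n
  } else {
    stopifnot(inherits(reduced, "logistic_fit"))
    m2ll_red <- reduced$m2ll
    df_red <- length(reduced$coefficients)
    n_red <- reduced$n
  }
  if (n_red != full$n) {
    stop_domain("fits use different rows (n = %d vs %d): fix complete cases first",
                n_red, full$n)
  }
  df <- length(full$coefficients) - df_red
  if (df < 0) stop_domain("`full` has fewer coefficients than `reduced`")
  stat <- max(m2ll_red - full$m2ll, 0)
  tibble::tibble(
    statistic = stat,
    df = df,
    p.value = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  )
}

#' Change-in-estimate confounder screen
#'
#' Candidates first pass a univariate filter (p < `p_enter` in a
#' univariate logistic regression on the outcome). The exposure model is
#' then fitted with all entering candidates and candidates are removed
#' backwards: at each step the candidate with the weakest Wald evidence
#' is dropped if it fails both criteria — its p-value exceeds `p_keep`
#' and removing it shifts the exposure coefficient(s) by no more than
#' `change_threshold` (relative). A candidate whose removal shifts the
#' exposure beta by more than the threshold is a confounder and is kept
#' regardless of its own p-value. When the crude exposure beta is zero
#' the relative change is undefined and an absolute-change fallback is
#' used (flagged in the report).
#'
#' @param data Data frame.
#' @param outcome Outcome column (case/control or 0/1).
#' @param exposure Exposure term (kept in every model).
#' @param candidates Character vector of candidate terms (disjoint from
#'   the exposure).
#' @param p_enter Univariate entry threshold (default 0.20).
#' @param p_keep Wald p-value above which a non-confounder is dropped
#'   (default 0.10).
#' @param change_threshold Relative change in the exposure beta defining
#'   confounding (default 0.10).
#' @return A list of class `confounder_screen`: `selected` (terms
#'   retained besides the exposure), `confounders`, `report` (per
#'   candidate), `trail` (step-by-step audit), `beta_crude`,
#'   `absolute_fallback`.
#' @export
confounder_screen <- function(data, outcome, exposure, candidates,
                              p_enter = 0.20, p_keep = 0.10,
                              change_threshold = 0.10) {
  if (exposure %in% candidates) {
    stop_domain("candidates must be disjoint from the exposure")
  }
  term_p <- function(fit, term) {
    td <- tidy(fit)
    rows <- grepl(term, td$term, fixed = TRUE) & td$term != "(Intercept)"
    if (!any(rows)) return(NA_real_)
    min(td$p.value[rows], na.rm = TRUE)
  }
  exposure_beta <- function(fit) {
    td <- tidy(fit)
    rows <- grepl(exposure, td$term, fixed = TRUE) & td$term != "(Intercept)"
    td$estimate[rows]
  }
  uni_p <- vapply(candidates, function(cand) {
    term_p(fit_logistic(data, cand, outcome), cand)
  }, numeric(1))
  entered <- candidates[!is.na(uni_p) & uni_p < p_enter]

  crude <- fit_logistic(data, exposure, outcome)
  beta_crude <- exposure_beta(crude)
  absolute_fallback <- all(beta_crude == 0)
  rel_change <- function(b_new, b_ref) {
    if (absolute_fallback) return(max(abs(b_new - b_ref)))
    max(abs(b_new - b_ref) / pmax(abs(b_ref), 1e-12))
  }

  current <- entered
  trail <- list()
  step <- 0L
  repeat {
    fit_cur <- fit_logistic(data, c(exposure, current), outcome)
    if (length(current) == 0) break
    ps <- vapply(current, function(cand) term_p(fit_cur, cand), numeric(1))
    ord <- order(ps, decreasing = TRUE)
    dropped <- FALSE
    for (i in ord) {
      cand <- current[i]
      if (is.na(ps[i]) || ps[i] <= p_keep) next
      fit_wo <- fit_logistic(data, c(exposure, setdiff(current, cand)), outcome)
      chg <- rel_change(exposure_beta(fit_wo), exposure_beta(fit_cur))
      step <- step + 1L
      if (chg <= change_threshold) {
        trail[[step]] <- tibble::tibble(step = step, action = "drop",
                                        candidate = cand, p.value = ps[i],
                                        beta_change = chg)
        current <- setdiff(current, cand)
        dropped <- TRUE
        break
      } else {
        trail[[step]] <- tibble::tibble(step = step, action = "keep (confounder)",
                                        candidate = cand, p.value = ps[i],
                                        beta_change = chg)
      }
    }
    if (!dropped) break
  }

  fit_final <- fit_logistic(data, c(exposure, current), outcome)
  beta_adj <- exposure_beta(fit_final)
  report <- tibble::tibble(
    candidate = candidates,
    p_univariate = uni_p,
    entered = candidates %in% entered,
    retained = candidates %in% current,
    p_final = vapply(candidates, function(cand) {
      if (cand %in% current) term_p(fit_final, cand) else NA_real_
    }, numeric(1)),
    beta_change_vs_crude = vapply(candidates, function(cand) {
      if (!cand %in% current) return(NA_real_)
      fit_wo <- fit_logistic(data, c(exposure, setdiff(current, cand)), outcome)
      rel_change(exposure_beta(fit_final), exposure_beta(fit_wo))
    }, numeric(1))
  )
  report$confounder <- report$retained &
    !is.na(report$beta_change_vs_crude) &
    report$beta_change_vs_crude > change_threshold
  structure(
    list(
      selected = current,
      confounders = report$candidate[report$confounder],
      report = report,
      trail = if (length(trail) > 0) dplyr::bind_rows(trail) else
        tibble::tibble(step = integer(), action = character(),
                       candidate = character(), p.value = numeric(),
                       beta_change = numeric()),
      beta_crude = beta_crude,
      beta_adjusted = beta_adj,
      absolute_fallback = absolute_fallback
    ),
    class = "confounder_screen"
  )
}

#' @export
print.confounder_screen <- function(x, ...) {
  cat("<confounder_screen> retained:",
      if (length(x$selected) > 0) paste(x$selected, collapse = ", ") else "(none)",
      "\n")
  print(x$report)
  invisible(x)
}

#' Post-hoc power of a logistic odds-ratio test
#'
#' Large-sample two-sided Wald approximation for a binary exposure:
#' with event probability `p0` among the unexposed and
#' `p1 = expit(logit(p0) + log(OR))` among the exposed, the variance of
#' the log-OR estimate is `1/(n (1-pe) p0 q0) + 1/(n pe p1 q1)`, inflated
#' by `1/(1 - r2_other)` when the exposure is embedded in a multivariate
#' model explaining `r2_other` of its variance. Power is
#' `P(|Z| > z_{1-a/2})` under the alternative. At OR = 1 this returns
#' exactly `alpha`, and power is strictly increasing in `n` otherwise.
#'
#' @param or Odds ratio under the alternative (> 0).
#' @param p0 Event (case) probability among the unexposed, in (0, 1).
#' @param n Total sample size.
#' @param p_exposed Exposure prevalence (default 0.5).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param r2_other Variance of the exposure explained by the other model
#'   terms, in `[0, 1)`.
#' @return Power in `[0, 1]`.
#' @export
posthoc_power <- function(or, p0, n, p_exposed = 0.5, alpha = 0.05,
                          r2_other = 0) {
  if (or <= 0) stop_domain("or must be > 0")
  if (p0 <= 0 || p0 >= 1) stop_domain("p0 must lie in (0, 1)")
  if (n <= 0) stop_domain("n must be > 0")
  if (p_exposed <= 0 || p_exposed >= 1) stop_domain("p_exposed must lie in (0, 1)")
  if (r2_other < 0 || r2_other >= 1) stop_domain("r2_other must lie in [0, 1)")
  beta <- log(or)
  p1 <- expit(logit(p0) + beta)
  v <- (1 / ((1 - p_exposed) * p0 * (1 - p0)) +
          1 / (p_exposed * p1 * (1 - p1))) / (n * (1 - r2_other))
  z <- qnorm(1 - alpha / 2)
  se <- sqrt(v)
  pnorm(abs(beta) / se - z) + pnorm(-abs(beta) / se - z)
}
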