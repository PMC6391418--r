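#' Fractional percentile ranks
#'
#' Plotting-position ranks rank/(n+1) on the (0, 1) scale, with ties
#' sharing their mean rank. A single distinct value maps to 0.5; the
#' minimum of n distinct values maps to 1/(n+1).
#'
#' @param values Numeric vector (at least one finite value).
#' @return Numeric vector of ranks in (0, 1); NA propagates.
#' @export
percentile_rank <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) == 0) stop_domain("percentile_rank() needs at least one finite value")
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  out[ok] <- rank(values[ok], ties.method = "average") / (sum(ok) + 1)
  out
}

#' Construct a quantile-mapping adjustment model from coefficients
#'
#' The adjustment rebases a measurement taken after years of disease onto
#' the scale of recently diagnosed patients in two steps:
#' percentile = `a_ln * ln(value) + b_ln` (fitted on the long-duration
#' *target* group) composed into
#' adjusted = `c_exp * exp(d_exp * percentile)` (fitted on the <=2-year
#' *reference* group). With `a_ln > 0` and `d_exp > 0` the composed map
#' `c_exp * exp(d_exp * b_ln) * value^(a_ln * d_exp)` is strictly
#' increasing, so within-group rank order is preserved.
#'
#' @param a_ln,b_ln Log-curve coefficients (target group).
#' @param c_exp,d_exp Exponential-curve coefficients (reference group).
#' @param measure Measurement name (`"bmi"`, `"waist"`, `"hip"`).
#' @param r_target,r_reference Fit correlations (optional diagnostics).
#' @return An object of class `adjustment_model`.
#' @export
adjustment_model <- function(a_ln, b_ln, c_exp, d_exp, measure = "bmi",
                             r_target = NA_real_, r_reference = NA_real_) {
  if (a_ln <= 0 || d_exp <= 0) {
    stop_domain("a_ln and d_exp must be > 0 (both curves strictly increasing)")
  }
  structure(
    list(a_ln = a_ln, b_ln = b_ln, c_exp = c_exp, d_exp = d_exp,
         measure = measure, r_target = r_target, r_reference = r_reference),
    class = "adjustment_model"
  )
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat(sprintf("<adjustment_model: %s>\n", x$measure))
  cat(sprintf("  target:    percentile = %.4f ln(x) %+.4f  (r = %.3f)\n",
              x$a_ln, x$b_ln, x$r_target))
  cat(sprintf("  reference: value = %.4f e^(%.4f p)  (r = %.3f)\n",
              x$c_exp, x$d_exp, x$r_reference))
  invisible(x)
}

#' @export
#' @method tidy adjustment_model
tidy.adjustment_model <- function(x, ...) {
  tibble::tibble(
    curve = c("target_log", "target_log", "reference_exp", "reference_exp"),
    term = c("a_ln", "b_ln", "c_exp", "d_exp"),
    estimate = c(x$a_ln, x$b_ln, x$c_exp, x$d_exp)
  )
}

#' @export
#' @method glance adjustment_model
glance.adjustment_model <- function(x, ...) {
  tibble::tibble(measure = x$measure, r_target = x$r_target,
                 r_reference = x$r_reference)
}

#' Fit the two-curve quantile-mapping adjustment
#'
#' Computes fractional percentile ranks within the reference (recently
#' diagnosed, <=2 years) and target (>=3 years) groups, then fits by
#' least squares: percentile = a ln(value) + b on the target group, and
#' value = c e^(d percentile) on the reference group (fitted as
#' log(value) ~ percentile and back-transformed). The composition maps a
#' target-group value to the reference-group value occupying the same
#' percentile.
#'
#' @param reference_values Measurements of the reference group (> 0,
#'   at least 10).
#' @param target_values Measurements of the target group (> 0, at least
#'   10).
#' @param measure Measurement name carried into the model.
#' @return An [adjustment_model()] with fit correlations.
#' @export
fit_adjustment_model <- function(reference_values, target_values,
                                 measure = "bmi") {
  ref <- reference_values[!is.na(reference_values)]
  tar <- target_values[!is.na(target_values)]
  if (length(ref) < 10 || length(tar) < 10) {
    stop_domain("need at least 10 values per group (got %d reference, %d target)",
                length(ref), length(tar))
  }
  if (any(ref <= 0) || any(tar <= 0)) stop_domain("values must be > 0")
  if (sd(ref) == 0 || sd(tar) == 0) {
    abort("degenerate (constant) group: adjustment curves are not identifiable",
          class = "t2dvar_fit_error")
  }
  p_tar <- percentile_rank(tar)
  fit_t <- lm(p_tar ~ log(tar))
  a_ln <- unname(coef(fit_t)[2])
  b_ln <- unname(coef(fit_t)[1])
  r_t <- abs(cor(p_tar, log(tar)))
  p_ref <- percentile_rank(ref)
  fit_r <- lm(log(ref) ~ p_ref)
  d_exp <- unname(coef(fit_r)[2])
  c_exp <- exp(unname(coef(fit_r)[1]))
  r_r <- abs(cor(log(ref), p_ref))
  adjustment_model(a_ln, b_ln, c_exp, d_exp, measure,
                   r_target = r_t, r_reference = r_r)
}

#' Evaluate the composed adjustment map
#'
#' @param model An [adjustment_model()].
#' @param values Raw measurements (> 0).
#' @return Adjusted values `c_exp * exp(d_exp * (a_ln * ln(x) + b_ln))`.
#' @export
adjust_value <- function(model, values) {
  stopifnot(inherits(model, "adjustment_model"))
  model$c_exp * exp(model$d_exp * (model$a_ln * log(values) + model$b_ln))
}

#' Apply a duration adjustment to a cohort table
#'
#' Adds an `adj_<measure>` column: cases with at least `years_threshold`
#' years of disease get the composed quantile-mapped value; recently
#' diagnosed cases and controls keep their raw measurement. Non-positive
#' raw values are skipped (left missing) with a warning.
#'
#' @param table Cohort tibble with the measure and `years_with_disease`
#'   columns.
#' @param model An [adjustment_model()].
#' @param years_threshold Minimum years with disease for adjustment
#'   (default 3, i.e. the >=3-year group).
#' @return The table with the adjusted column added.
#' @export
apply_adjustment <- function(table, model, years_threshold = 3) {
  stopifnot(inherits(model, "adjustment_model"))
  measure <- model$measure
  if (!measure %in% names(table)) {
    stop_domain("measure column `%s` not present", measure)
  }
  raw <- table[[measure]]
  is_target <- !is.na(table$status) & table$status == "case" &
    !is.na(table$years_with_disease) &
    table$years_with_disease >= years_threshold
  bad <- is_target & !is.na(raw) & raw <= 0
  if (any(bad)) {
    warn(sprintf("%d record(s) with non-positive %s skipped by adjustment",
                 sum(bad), measure))
  }
  adj <- raw
  do <- is_target & !is.na(raw) & raw > 0
  adj[do] <- adjust_value(model, raw[do])
  adj[bad] <- NA_real_
  table[[paste0("adj_", measure)]] <- adj
  table
}

#' Waist-to-hip ratio
#'
#' @param waist,hip Circumferences (cm); computed from the raw values, not
#'   the duration-adjusted ones.
#' @return `waist / hip` (dimensionless); missing where hip is missing or
#'   non-positive.
#' @export
waist_hip_ratio <- function(waist, hip) {
  ifelse(is.na(hip) | hip <= 0, NA_real_, waist / hip)
}

#' Trend of a measurement over years with disease
#'
#' Bins cases by disease duration (default 2-year bins, terminal bin
#' >= 17 years), summarises each bin by its median and interquartile
#' range, and correlates bin medians with mean duration in the bin
#' (Pearson). Empty bins are dropped with a warning; a constant measure
#' is reported as a zero-slope trend with `constant = TRUE`.
#'
#' @param cases Cohort tibble (controls, if present, are ignored).
#' @param measure Column to summarise (default `"bmi"`).
#' @param breaks Left-closed bin breaks on years with disease.
#' @return An object of class `duration_trend`: a tibble of bins with
#'   attributes `r`, `p.value`, `measure`, `constant`.
#' @export
duration_trend <- function(cases, measure = "bmi",
                           breaks = c(0, 3, 5, 7, 9, 11, 13, 15, 17, Inf)) {
  if (length(breaks) < 3) stop_domain("need at least 2 bins")
  tbl <- cases
  if ("status" %in% names(tbl)) tbl <- dplyr::filter(tbl, .data$status == "case")
  tbl <- dplyr::filter(tbl, !is.na(.data$years_with_disease),
                       !is.na(.data[[measure]]))
  lab <- function(lo, hi) {
    if (is.infinite(hi)) sprintf(">=%g", lo)
    else if (hi - lo == 1) sprintf("%g", lo)
    else sprintf("%g-%g", lo, hi - 1)
  }
  labels <- mapply(lab, head(breaks, -1) , breaks[-1])
  labels[1] <- sprintf("<=%g", breaks[2] - 1)
  idx <- findInterval(tbl$years_with_disease, breaks,
                      rightmost.closed = FALSE)
  tbl$bin <- factor(labels[idx], levels = labels)
  bins <- tbl |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      midpoint = mean(.data$years_with_disease),
      median = median(.data[[measure]]),
      q1 = unname(quantile(.data[[measure]], 0.25)),
      q3 = unname(quantile(.data[[measure]], 0.75)),
      .groups = "drop"
    )
  dropped <- setdiff(labels, as.character(bins$bin))
  if (length(dropped) > 0) {
    warn(sprintf("empty duration bin(s) dropped: %s",
                 paste(dropped, collapse = ", ")))
  }
  if (nrow(bins) < 2) stop_domain("fewer than 2 non-empty duration bins")
  constant <- sd(bins$median) == 0
  if (constant) {
    r <- 0; p <- NA_real_
  } else if (nrow(bins) < 3) {
    r <- unname(sign(diff(bins$median))); p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(bins$midpoint, bins$median))
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(bins, class = c("duration_trend", class(bins)),
            r = r, p.value = p, measure = measure, constant = constant)
}

#' @export
print.duration_trend <- function(x, ...) {
  cat(sprintf("<duration_trend: %s>  Pearson r = %.3f (p = %.3g)%s\n",
              attr(x, "measure"), attr(x, "r"), attr(x, "p.value"),
              if (attr(x, "constant")) " [constant measure]" else ""))
  NextMethod()
}
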