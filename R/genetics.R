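#' Hardy-Weinberg expected genotype counts
#'
#' From observed counts (n0, n1, n2) of subjects carrying 0/1/2 copies of
#' the risk allele, estimates the risk-allele frequency
#' a = (n1 + 2 n2) / (2n) and returns the counts expected under
#' Hardy-Weinberg equilibrium, n * (b^2, 2ab, a^2) with b = 1 - a.
#' Expected counts sum exactly to n.
#'
#' @param n0,n1,n2 Non-negative genotype counts. Alternatively `n0` may
#'   be a length-3 vector.
#' @return A list with `expected` (length-3 numeric), `a` (risk-allele
#'   frequency), `b`, and `n`.
#' @export
#' @examples
#' hwe_expected(49, 42, 9) # already in equilibrium at a = 0.3
hwe_expected <- function(n0, n1 = NULL, n2 = NULL) {
  if (length(n0) == 3 && is.null(n1)) {
    n2 <- n0[3]; n1 <- n0[2]; n0 <- n0[1]
  }
  counts <- c(n0, n1, n2)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_domain("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop_domain("no genotyped subjects (n = 0)")
  a <- (n1 + 2 * n2) / (2 * n)
  b <- 1 - a
  list(expected = n * c(b^2, 2 * a * b, a^2), a = a, b = b, n = n)
}

#' Hardy-Weinberg chi-squared test
#'
#' Pearson chi-square of observed genotype counts against the
#' equilibrium expectation of [hwe_expected()], on 1 degree of freedom
#' (3 classes - 1 - 1 estimated allele frequency), without continuity
#' correction. Invariant to swapping the risk/other allele labels.
#'
#' @inheritParams hwe_expected
#' @return A one-row tibble: `a` (risk-allele frequency), `statistic`,
#'   `df`, `p.value`, and `low_expected` (TRUE when any expected cell
#'   is below 1, flagging an unreliable chi-square approximation).
#' @export
hwe_test <- function(n0, n1 = NULL, n2 = NULL) {
  exp_ <- hwe_expected(n0, n1, n2)
  if (length(n0) == 3 && is.null(n1)) {
    n2 <- n0[3]; n1 <- n0[2]; n0 <- n0[1]
  }
  obs <- c(n0, n1, n2)
  e <- exp_$expected
  keep <- e > 0
  stat <- sum((obs[keep] - e[keep])^2 / e[keep])
  low <- any(e < 1)
  if (low) warn("expected genotype cell < 1: chi-square approximation unreliable")
  tibble::tibble(
    a = exp_$a,
    statistic = stat,
    df = 1L,
    p.value = pchisq(stat, df = 1, lower.tail = FALSE),
    low_expected = low
  )
}

#' Per-SNP Hardy-Weinberg scan of a cohort
#'
#' Tests every genotype column, by convention in the control group (the
#' group in which equilibrium is expected to hold; cases are enriched for
#' risk genotypes by design).
#'
#' @param table Coded cohort tibble.
#' @param group `"control"` (default), `"case"`, or `"all"`.
#' @return A tibble with one row per SNP: counts, risk-allele frequency,
#'   chi-square, p-value and star code.
#' @export
hwe_scan <- function(table, group = "control") {
  sc <- snp_cols(table)
  if (length(sc) == 0) stop_domain("no genotype columns in table")
  tbl <- if (group == "all") table else dplyr::filter(table, .data$status == group)
  purrr::map_dfr(sc, function(s) {
    g <- tbl[[s]]
    g <- g[!is.na(g)]
    counts <- vapply(0:2, function(k) sum(g == k), numeric(1))
    res <- hwe_test(counts)
    dplyr::bind_cols(tibble::tibble(snp_id = s, n0 = counts[1],
                                    n1 = counts[2], n2 = counts[3]),
                     res) |>
      dplyr::mutate(stars = p_stars(.data$p.value))
  })
}
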