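#' Reference parental-history contingency counts
#'
#' Published contingency counts of parental history (PH) of type 2 diabetes
#' from two Mexican case-control studies: a main hospital-based study
#' (972 controls / 1071 cases with PH data) and a clinical replica study
#' (415 controls / 2460-2466 cases, totals differing slightly per factor
#' because of per-factor missingness). Three factors are tabulated: paternal
#' history (negative/positive), maternal history (negative/positive), and
#' the number of affected parents (0/1/2).
#'
#' These aggregated counts are sufficient to reproduce the univariate
#' logistic-regression odds ratios and Nagelkerke r-squared values of the
#' corresponding association tables exactly (see [expand_counts()]).
#'
#' @param study `"main"` or `"replica"`.
#' @return A tibble with columns `factor`, `level`, `controls`, `cases`.
#' @export
#' @examples
#' ph_reference_counts("main")
ph_reference_counts <- function(study = c("main", "replica")) {
  study <- match.arg(study)
  if (study == "main") {
    tibble::tribble(
      ~factor,        ~level,     ~controls, ~cases,
      "father",       "negative", 837L,      747L,
      "father",       "positive", 135L,      324L,
      "mother",       "negative", 774L,      589L,
      "mother",       "positive", 198L,      482L,
      "both_parents", "0",        683L,      443L,
      "both_parents", "1",        245L,      450L,
      "both_parents", "2",        44L,       178L
    )
  } else {
    tibble::tribble(
      ~factor,        ~level,     ~controls, ~cases,
      "father",       "negative", 344L,      1667L,
      "father",       "positive", 71L,       799L,
      "mother",       "negative", 317L,      1306L,
      "mother",       "positive", 98L,       1170L,
      "both_parents", "0",        263L,      905L,
      "both_parents", "1",        135L,      1161L,
      "both_parents", "2",        17L,       394L
    )
  }
}
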