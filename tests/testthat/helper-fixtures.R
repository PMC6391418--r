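# Shared fixtures and independent oracles, built in code at test time.

# Expand one factor of the bundled reference contingency counts.
expand_ph <- function(study, fac) {
  expand_counts(dplyr::filter(ph_reference_counts(study), factor == fac))
}

# Closed-form log-likelihood of the saturated model for a categorical
# predictor: each level's fitted case probability is its observed case
# fraction. Independent of the glm/IRLS path.
saturated_ll <- function(controls, cases) {
  p <- cases / (cases + controls)
  sum(cases * log(p) + controls * log(1 - p))
}

# Closed-form intercept-only (null) log-likelihood.
null_ll <- function(controls, cases) {
  n1 <- sum(cases); n0 <- sum(controls); n <- n0 + n1
  n1 * log(n1 / n) + n0 * log(n0 / n)
}

# One default mid-size coded synthetic cohort, built once per test run.
test_cohort <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- sim_config(n_cases = 400, n_controls = 400, seed = 42)
      val <<- derive_coded_variables(simulate_cohort(cfg))
    }
    val
  }
})
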