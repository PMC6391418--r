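#' Default susceptibility-SNP panel
#'
#' Sixteen SNPs associated with type 2 diabetes in Mexican-mestizo cohorts
#' (SIGMA-era panel: SLC16A11, INS-IGF2, HNF1A, WFS1, SLC30A8, PPARG,
#' IGF2BP2, CDKAL1, ADCY5, JAZF1, HHEX, KCNJ11, KCNQ1, TCF7L2, FTO,
#' CDKN2B), with risk-allele frequencies and additive per-allele odds
#' ratios on the scale reported for that population. Effects are entered
#' additively on the logit; genes with reported effects concentrated in
#' one sex are still given a single per-allele effect here, with the
#' sex-differential handled globally by `female_gene_attenuation` in
#' [sim_config()].
#'
#' @return A tibble with columns `snp_id`, `gene`, `raf` (risk-allele
#'   frequency in the source population) and `log_or` (per-allele log
#'   odds ratio in males; females get `log_or * female_gene_attenuation`).
#' @export
default_snp_panel <- function() {
  tibble::tribble(
    ~snp_id,        ~gene,       ~raf, ~or,
    "rs75493593",   "SLC16A11",  0.30, 1.45,
    "rs149483638",  "INS-IGF2",  0.06, 1.76,
    "rs483353044",  "HNF1A",     0.02, 1.89,
    "rs4458523",    "WFS1",      0.30, 1.12,
    "rs3802177",    "SLC30A8",   0.25, 1.22,
    "rs1801282",    "PPARG",     0.10, 1.15,
    "rs4402960",    "IGF2BP2",   0.25, 1.22,
    "rs7754840",    "CDKAL1",    0.30, 1.12,
    "rs11717195",   "ADCY5",     0.75, 1.04,
    "rs864745",     "JAZF1",     0.70, 1.08,
    "rs1111875",    "HHEX",      0.55, 1.10,
    "rs5219",       "KCNJ11",    0.35, 1.08,
    "rs2237897",    "KCNQ1",     0.45, 1.53,
    "rs7903146",    "TCF7L2",    0.20, 1.47,
    "rs9939609",    "FTO",       0.15, 1.10,
    "rs10811661",   "CDKN2B",    0.80, 1.25
  ) |>
    dplyr::mutate(log_or = log(.data$or)) |>
    dplyr::select("snp_id", "gene", "raf", "log_or")
}

#' Configuration of the synthetic case-control cohort generator
#'
#' Bundles every generative parameter of the simulator with defaults
#' calibrated to the Mexican T2D case-control study structure this package
#' analyses: Hardy-Weinberg genotypes at the panel's risk-allele
#' frequencies with additive per-allele odds ratios, parental-history
#' margins of (70.3, 25.2, 4.5)% for 0/1/2 affected parents in the source
#' population with log-ORs log(2.83)/log(6.24), a population BMI of
#' 28.8 +/- 4.7 kg/m2 entering the logit at 0.145 per kg/m2 — under
#' case-control selection this places the control mean near 27.8, the
#' case onset-scale median near 30.4 and the onset-BMI univariate
#' Nagelkerke r2 near 0.095 — post-diagnosis linear BMI decline
#' of 0.17 kg/m2 per year (duration-bin medians falling from ~30.4 at
#' <=2 years with disease to ~26.8 in the terminal >=17-year bin), duration-stationary
#' waist/hip ratio (0.91 women / 0.94 men), age at diagnosis 46.6 +/- 10.9
#' years, 61.2% women, and female SNP effects attenuated by 0.5 (mirroring
#' the reported male vs female genetic r2 of 0.115 vs 0.039).
#'
#' @param n_cases,n_controls Number of cases/controls to return.
#' @param snp_panel Tibble with `snp_id`, `raf`, `log_or`
#'   (see [default_snp_panel()]).
#' @param ph_margins Probabilities of 0/1/2 affected parents in the source
#'   population; must sum to 1.
#' @param ph_log_ors Log odds ratios for 1 and 2 affected parents vs none.
#' @param bmi_mean,bmi_sd Population (onset-scale) BMI distribution, kg/m2.
#' @param bmi_per_unit_log_or Log-OR of disease per kg/m2 of onset BMI.
#' @param bmi_decay_slope Post-diagnosis BMI decline, kg/m2 per year.
#' @param bmi_noise_sd Within-subject measurement noise around the decayed
#'   BMI, kg/m2.
#' @param whr_mean_female,whr_mean_male,whr_sd Waist/hip ratio distribution.
#' @param whr_sd_log_or Log-OR of disease per SD of WHR.
#' @param hip_mean,hip_sd Hip circumference (cm); waist is WHR * hip, and
#'   hip declines at `hip_decay_slope` cm/year in cases so that WHR stays
#'   duration-stationary while both circumferences fall.
#' @param hip_decay_slope Hip decline in cases, cm per year with disease.
#' @param sex_ratio_female Proportion of women in the cohort.
#' @param age_dx_mean,age_dx_sd Age at diagnosis of cases, years.
#' @param years_mean,years_sd Years with disease at enrolment (truncated
#'   at 0).
#' @param control_age_min,control_age_mean,control_age_sd Control enrolment
#'   age (truncated below at `control_age_min`).
#' @param female_gene_attenuation Multiplier in `[0, 1]` applied to SNP
#'   log-ORs in women.
#' @param ph_gene_cor Gaussian-latent correlation coupling parental history
#'   to the standardized genetic score (0 = independent, the default).
#' @param base_prevalence Marginal disease prevalence targeted by the
#'   generator's intercept (case-control sampling then discards prevalence
#'   but preserves odds ratios).
#' @param ph_missing_rate,anthro_missing_rate Fractions of subjects whose
#'   parental-history / waist-hip fields are set missing.
#' @param seed Integer seed; the single source of randomness (per-stage
#'   substreams are derived from it deterministically).
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 200, n_controls = 200, seed = 1)
#' cohort <- simulate_cohort(cfg)
sim_config <- function(n_cases = 1250,
                       n_controls = 1250,
                       snp_panel = default_snp_panel(),
                       ph_margins = c(0.703, 0.252, 0.045),
                       ph_log_ors = log(c(2.83, 6.24)),
                       bmi_mean = 28.8,
                       bmi_sd = 4.7,
                       bmi_per_unit_log_or = 0.145,
                       bmi_decay_slope = 0.17,
                       bmi_noise_sd = 1,
                       whr_mean_female = 0.91,
                       whr_mean_male = 0.94,
                       whr_sd = 0.06,
                       whr_sd_log_or = 0.25,
                       hip_mean = 102,
                       hip_sd = 10,
                       hip_decay_slope = 0.4,
                       sex_ratio_female = 0.612,
                       age_dx_mean = 46.6,
                       age_dx_sd = 10.9,
                       years_mean = 9.1,
                       years_sd = 8.5,
                       control_age_min = 50,
                       control_age_mean = 57.7,
                       control_age_sd = 10.9,
                       female_gene_attenuation = 0.5,
                       ph_gene_cor = 0,
                       base_prevalence = 0.35,
                       ph_missing_rate = 0,
                       anthro_missing_rate = 0,
                       seed = 1L) {
  if (n_cases < 0 || n_controls < 0) stop_domain("n_cases and n_controls must be >= 0")
  stopifnot(is.data.frame(snp_panel),
            all(c("snp_id", "raf", "log_or") %in% names(snp_panel)))
  check_prob(snp_panel$raf, "snp_panel$raf")
  if (any(ph_margins < 0)) stop_domain("ph_margins must be non-negative")
  if (abs(sum(ph_margins) - 1) > 1e-8) stop_domain("ph_margins must sum to 1")
  if (length(ph_margins) != 3) stop_domain("ph_margins must have length 3 (0/1/2 parents)")
  check_prob(sex_ratio_female, "sex_ratio_female")
  check_prob(female_gene_attenuation, "female_gene_attenuation")
  check_prob(base_prevalence, "base_prevalence")
  if (abs(ph_gene_cor) > 0.99) stop_domain("ph_gene_cor must lie in (-0.99, 0.99)")
  for (nm in c("bmi_sd", "whr_sd", "hip_sd", "age_dx_sd", "years_sd", "control_age_sd")) {
    if (get(nm) <= 0) stop_domain("`%s` must be > 0", nm)
  }
  cfg <- as.list(environment())
  cfg$nm <- NULL
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_cases, "cases /", x$n_controls, "controls;",
      nrow(x$snp_panel), "SNPs; seed", x$seed, "\n")
  invisible(x)
}

#' Draw SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Risk-allele counts are sampled with genotype probabilities
#' ((1-raf)^2, 2 raf (1-raf), raf^2), i.e. Binomial(2, raf).
#'
#' @param raf Risk-allele frequency in `[0, 1]`.
#' @param n Number of subjects.
#' @param seed Optional seed (draws are made on a derived substream and
#'   the caller's RNG state is restored).
#' @return Integer vector of risk-allele counts in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(raf, n, seed = NULL) {
  check_prob(raf, "raf")
  if (n < 0) stop_domain("n must be >= 0")
  with_substream(seed, 1L, rbinom(n, 2L, raf))
}

#' Draw parental-history counts at given population margins
#'
#' @param margins Probabilities of 0, 1 and 2 affected parents; must sum
#'   to 1.
#' @param n Number of subjects.
#' @param seed Optional seed.
#' @return Integer vector in `{0, 1, 2}`.
#' @export
simulate_parental_history <- function(margins, n, seed = NULL) {
  if (any(margins < 0)) stop_domain("margins must be non-negative")
  if (abs(sum(margins) - 1) > 1e-8) stop_domain("margins must sum to 1")
  with_substream(seed, 2L, sample(0:2, n, replace = TRUE, prob = margins))
}

#' Simulate anthropometry given disease status and duration
#'
#' Cases receive an onset-scale BMI that declines linearly with years
#' since diagnosis (plus measurement noise, truncated at 15 kg/m2);
#' controls are duration-stationary. Waist is generated as WHR * hip so
#' the ratio does not drift with duration even though both circumferences
#' shrink in cases.
#'
#' @param config A [sim_config()].
#' @param status Character vector, `"case"`/`"control"`.
#' @param years_with_disease Years since diagnosis (cases; ignored with
#'   controls). Must be non-negative.
#' @param sex Optional `"male"`/`"female"` vector (defaults to sampling
#'   from `config$sex_ratio_female`).
#' @param seed Optional seed.
#' @return Tibble with `bmi_onset`, `bmi`, `waist`, `hip`.
#' @export
simulate_anthropometry <- function(config, status, years_with_disease,
                                   sex = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(status)
  yrs <- ifelse(status == "case", years_with_disease, 0)
  if (any(!is.na(yrs) & yrs < 0)) stop_domain("years_with_disease must be >= 0")
  with_substream(seed, 3L, {
    if (is.null(sex)) {
      sex <- ifelse(runif(n) < config$sex_ratio_female, "female", "male")
    }
    bmi_onset <- rnorm(n, config$bmi_mean, config$bmi_sd)
    bmi <- bmi_onset - config$bmi_decay_slope * yrs +
      rnorm(n, 0, config$bmi_noise_sd) * (status == "case")
    bmi <- pmax(bmi, 15)
    bmi_onset <- pmax(bmi_onset, 15)
    whr <- rnorm(n, ifelse(sex == "female", config$whr_mean_female,
                           config$whr_mean_male), config$whr_sd)
    hip <- pmax(rnorm(n, config$hip_mean, config$hip_sd) -
                  config$hip_decay_slope * yrs, 60)
    tibble::tibble(bmi_onset = bmi_onset, bmi = bmi,
                   waist = whr * hip, hip = hip)
  })
}

# PH counts optionally coupled to the standardized genetic score through a
# Gaussian latent; rho = 0 reduces to independent sampling at the margins.
ph_from_latent <- function(gscore, margins, rho) {
  n <- length(gscore)
  z <- if (rho == 0 || sd(gscore) == 0) {
    rnorm(n)
  } else {
    rho * as.numeric(scale(gscore)) + sqrt(1 - rho^2) * rnorm(n)
  }
  cuts <- qnorm(cumsum(margins)[1:2])
  as.integer(findInterval(z, cuts))
}

#' Simulate a full case-control cohort
#'
#' Generates a source population under the configured logistic disease
#' model (additive per-allele SNP effects, attenuated in women; indicator
#' effects for 1/2 affected parents; onset-scale BMI and WHR on the
#' logit), assigns disease by Bernoulli draws on the linked probability,
#' and then samples the requested numbers of cases and controls
#' (case-control sampling preserves odds ratios, not prevalence).
#' Case anthropometry is degraded by disease duration as in
#' [simulate_anthropometry()]. The latent onset-scale BMI is kept in the
#' output (`bmi_onset`) as generator ground truth for parameter-recovery
#' tests.
#'
#' @param config A [sim_config()].
#' @param max_rounds Bounded number of oversampling rounds before the
#'   generator gives up (guards against unsatisfiable configurations).
#' @return A cohort tibble (one row per subject) with attribute
#'   `snp_cols` naming the genotype columns; identical `config` (and seed)
#'   gives an identical table.
#' @export
simulate_cohort <- function(config, max_rounds = 20L) {
  stopifnot(inherits(config, "sim_config"))
  panel <- config$snp_panel
  need_cases <- config$n_cases
  need_controls <- config$n_controls
  chunk <- max(1000L, 4L * (need_cases + need_controls))
  cases <- list()
  controls <- list()
  got_cases <- 0L
  got_controls <- 0L

  for (round in seq_len(max_rounds)) {
    pool <- with_substream(config$seed, 10L + round, {
      n <- chunk
      sex <- ifelse(runif(n) < config$sex_ratio_female, "female", "male")
      geno <- vapply(seq_len(nrow(panel)),
                     function(j) rbinom(n, 2L, panel$raf[j]),
                     integer(n))
      colnames(geno) <- panel$snp_id
      gscore <- as.numeric(geno %*% panel$log_or)
      ph <- ph_from_latent(gscore, config$ph_margins, config$ph_gene_cor)
      bmi_onset <- pmax(rnorm(n, config$bmi_mean, config$bmi_sd), 15)
      whr <- rnorm(n, ifelse(sex == "female", config$whr_mean_female,
                             config$whr_mean_male), config$whr_sd)

      atten <- ifelse(sex == "female", config$female_gene_attenuation, 1)
      snp_lp <- gscore * atten
      # centre every contribution so the intercept pins marginal prevalence
      e_snp <- sum(2 * panel$raf * panel$log_or) *
        (config$sex_ratio_female * config$female_gene_attenuation +
           (1 - config$sex_ratio_female))
      ph_lor <- c(0, config$ph_log_ors)
      e_ph <- sum(config$ph_margins * ph_lor)
      e_whr <- config$sex_ratio_female * config$whr_mean_female +
        (1 - config$sex_ratio_female) * config$whr_mean_male
      lp <- logit(config$base_prevalence) +
        (snp_lp - e_snp) +
        (ph_lor[ph + 1L] - e_ph) +
        config$bmi_per_unit_log_or * (bmi_onset - config$bmi_mean) +
        config$whr_sd_log_or * (whr - e_whr) / config$whr_sd
      status <- ifelse(runif(n) < expit(lp), "case", "control")

      father <- integer(n)
      mother <- integer(n)
      one <- ph == 1L
      father[one] <- rbinom(sum(one), 1L, 0.5)
      mother[one] <- 1L - father[one]
      father[ph == 2L] <- 1L
      mother[ph == 2L] <- 1L

      yrs <- pmax(rnorm(n, config$years_mean, config$years_sd), 0)
      age_dx <- pmax(rnorm(n, config$age_dx_mean, config$age_dx_sd), 20)
      # control enrolment age: normal truncated below at control_age_min
      u <- runif(n)
      plo <- pnorm(config$control_age_min, config$control_age_mean,
                   config$control_age_sd)
      ctl_age <- qnorm(plo + u * (1 - plo), config$control_age_mean,
                       config$control_age_sd)

      is_case <- status == "case"
      bmi <- pmax(bmi_onset - config$bmi_decay_slope * yrs * is_case +
                    rnorm(n, 0, config$bmi_noise_sd) * is_case, 15)
      hip <- pmax(rnorm(n, config$hip_mean, config$hip_sd) -
                    config$hip_decay_slope * yrs * is_case, 60)
      out <- tibble::tibble(
        status = status,
        sex = sex,
        age_enrol = ifelse(is_case, age_dx + yrs, ctl_age),
        age_dx = ifelse(is_case, age_dx, NA_real_),
        years_with_disease = ifelse(is_case, yrs, NA_real_),
        bmi_onset = bmi_onset,
        bmi = bmi,
        waist = whr * hip,
        hip = hip,
        father_t2d = father,
        mother_t2d = mother
      )
      dplyr::bind_cols(out, tibble::as_tibble(geno))
    })

    new_cases <- dplyr::filter(pool, .data$status == "case")
    new_controls <- dplyr::filter(pool, .data$status == "control")
    cases[[round]] <- head(new_cases, need_cases - got_cases)
    controls[[round]] <- head(new_controls, need_controls - got_controls)
    got_cases <- got_cases + nrow(cases[[round]])
    got_controls <- got_controls + nrow(controls[[round]])
    if (got_cases >= need_cases && got_controls >= need_controls) break
    if (round == max_rounds) {
      abort(sprintf(
        "cohort generation failed: %d/%d cases and %d/%d controls after %d rounds",
        got_cases, need_cases, got_controls, need_controls, max_rounds),
        class = "t2dvar_generation_error")
    }
  }

  out <- dplyr::bind_rows(dplyr::bind_rows(cases), dplyr::bind_rows(controls))
  out <- dplyr::mutate(out,
                       subject_id = sprintf("S%05d", dplyr::row_number()),
                       .before = 1)
  if (config$ph_missing_rate > 0) {
    drop <- with_substream(config$seed, 901L,
                           runif(nrow(out)) < config$ph_missing_rate)
    out$father_t2d[drop] <- NA_integer_
    out$mother_t2d[drop] <- NA_integer_
  }
  if (config$anthro_missing_rate > 0) {
    drop <- with_substream(config$seed, 902L,
                           runif(nrow(out)) < config$anthro_missing_rate)
    out$waist[drop] <- NA_real_
    out$hip[drop] <- NA_real_
  }
  attr(out, "snp_cols") <- panel$snp_id
  out
}

#' Genotype columns of a cohort table
#'
#' @param table A cohort tibble.
#' @return Character vector of SNP column names (from the `snp_cols`
#'   attribute if present, otherwise every non-schema column).
#' @export
snp_cols <- function(table) {
  sc <- attr(table, "snp_cols")
  if (!is.null(sc)) return(intersect(sc, names(table)))
  setdiff(names(table), cohort_schema_cols())
}
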