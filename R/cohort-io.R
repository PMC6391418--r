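# Cohort table schema: fixed subject-level columns; every other column is a
# genotype column (risk-allele count 0/1/2, or a two-letter genotype to be
# resolved against SNP metadata by derive_coded_variables()).

cohort_schema_cols <- function() {
  c("subject_id", "status", "sex", "age_enrol", "age_dx",
    "years_with_disease", "bmi_onset", "bmi", "waist", "hip",
    "father_t2d", "mother_t2d",
    # derived columns added by derive_coded_variables()
    "ph_count", "bmi_cat", "whr", "agedx_quartile", "agedx_split")
}

#' Read / write a cohort table
#'
#' Tab-delimited, UTF-8, header row, `NA` as the missing-value sentinel.
#' `read_cohort()` validates the schema: `status` must be case/control,
#' anthropometry must be numeric, numeric genotype columns must be 0/1/2
#' or missing, and controls must not carry an age at diagnosis (if they
#' do, a warning is raised and the field is nulled). Writing then reading
#' a valid table is the identity.
#'
#' @param path File path.
#' @param snp_cols Optional character vector naming the genotype columns;
#'   by default every column outside the fixed schema is treated as one.
#' @return `read_cohort()` returns the cohort tibble (with the `snp_cols`
#'   attribute set); `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path, snp_cols = NULL) {
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  tbl <- readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                         progress = FALSE)
  required <- c("subject_id", "status")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop_domain("cohort file lacks required column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tbl$subject_id)) stop_domain("duplicated subject ids")
  status_to_binary(tbl$status) # validates labels
  if (is.null(snp_cols)) snp_cols <- setdiff(names(tbl), cohort_schema_cols())
  unknown <- setdiff(snp_cols, names(tbl))
  if (length(unknown) > 0) {
    stop_domain("declared genotype column(s) not in file: %s",
                paste(unknown, collapse = ", "))
  }
  for (col in intersect(c("age_enrol", "age_dx", "years_with_disease",
                          "bmi_onset", "bmi", "waist", "hip"), names(tbl))) {
    if (!is.numeric(tbl[[col]])) {
      stop_domain("column `%s` must be numeric", col)
    }
  }
  for (col in snp_cols) {
    g <- tbl[[col]]
    if (is.numeric(g)) {
      bad <- which(!is.na(g) & !g %in% c(0, 1, 2))
      if (length(bad) > 0) {
        stop_domain("genotype column `%s`, row %d: value %s outside {0,1,2,NA}",
                    col, bad[1], format(g[bad[1]]))
      }
    } else {
      bad <- which(!is.na(g) & !grepl("^[ACGT]{2}$", g))
      if (length(bad) > 0) {
        stop_domain("genotype column `%s`, row %d: '%s' is not a two-letter genotype",
                    col, bad[1], g[bad[1]])
      }
    }
  }
  if (all(c("age_dx", "status") %in% names(tbl))) {
    bad <- !is.na(tbl$age_dx) & tbl$status == "control"
    if (any(bad)) {
      warn(sprintf("%d control(s) carried an age at diagnosis; field nulled",
                   sum(bad)))
      tbl$age_dx[bad] <- NA_real_
      if ("years_with_disease" %in% names(tbl)) {
        tbl$years_with_disease[bad] <- NA_real_
      }
    }
  }
  attr(tbl, "snp_cols") <- snp_cols
  tbl
}

#' @rdname read_cohort
#' @param table Cohort tibble to write.
#' @export
write_cohort <- function(table, path) {
  readr::write_tsv(table, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Expand aggregated contingency counts to subject-level records
#'
#' Turns a per-level (controls, cases) count table — e.g. a published
#' association table — into one record per counted subject with only
#' `status` and the factor populated, so the exact published statistics
#' can be recomputed with the ordinary subject-level machinery.
#'
#' @param counts Tibble with columns `level`, `controls`, `cases`, and
#'   optionally `factor` (a single factor name).
#' @param factor_name Name for the expanded factor column; defaults to
#'   the `factor` column of `counts` (or `"level"`).
#' @return Tibble with columns `status` and the factor, with
#'   `sum(controls) + sum(cases)` rows; the factor is a factor whose
#'   level order follows the input rows (first row = reference).
#' @export
#' @examples
#' counts <- dplyr::filter(ph_reference_counts("main"), factor == "both_parents")
#' nrow(expand_counts(counts)) # 2043
expand_counts <- function(counts, factor_name = NULL) {
  stopifnot(all(c("level", "controls", "cases") %in% names(counts)))
  if ("factor" %in% names(counts)) {
    fac <- unique(counts$factor)
    if (length(fac) != 1) {
      stop_domain("expand_counts() expects a single factor (got %d); filter first",
                  length(fac))
    }
    factor_name <- factor_name %||% fac
  }
  factor_name <- factor_name %||% "level"
  if (any(counts$controls < 0 | counts$cases < 0)) {
    stop_domain("counts must be non-negative")
  }
  if (any(counts$controls != round(counts$controls) |
            counts$cases != round(counts$cases))) {
    stop_domain("counts must be integers")
  }
  lev <- as.character(counts$level)
  out <- tibble::tibble(
    status = rep(rep(c("control", "case"), nrow(counts)),
                 times = as.vector(rbind(counts$controls, counts$cases))),
    value = rep(rep(lev, each = 2),
                times = as.vector(rbind(counts$controls, counts$cases)))
  )
  out$value <- factor(out$value, levels = lev)
  names(out)[2] <- factor_name
  out
}

# Convert a two-letter genotype vector to a risk-allele count given the
# declared risk allele (and optionally the other allele for validation).
letters_to_count <- function(g, risk_allele, other_allele = NULL, col = "genotype") {
  out <- rep(NA_integer_, length(g))
  ok <- !is.na(g)
  chars <- strsplit(g[ok], "")
  allowed <- c(risk_allele, other_allele)
  counts <- vapply(chars, function(ch) {
    if (!is.null(other_allele) && !all(ch %in% allowed)) {
      return(NA_integer_)
    }
    if (is.null(other_allele) && !any(ch %in% risk_allele) &&
        !all(ch == ch[1])) {
      # heterozygote containing no copy of the declared risk allele:
      # cannot arise from this SNP's two alleles -> ambiguous strand
      return(-1L)
    }
    sum(ch == risk_allele)
  }, integer(1))
  if (anyNA(counts)) {
    stop_domain("column `%s`: genotype with allele outside {%s}",
                col, paste(allowed, collapse = ","))
  }
  if (any(counts < 0)) {
    stop_domain("column `%s`: ambiguous genotype (no declared risk allele in a heterozygote); declare both alleles",
                col)
  }
  out[ok] <- counts
  out
}

#' Derive coded analysis variables
#'
#' Adds, idempotently, the coded variables every downstream analysis
#' expects: `ph_count` (affected parents, 0/1/2), `whr` (waist/hip, NA
#' where hip is missing or non-positive), `bmi_cat` (WHO classes `<25`,
#' `25-30`, `>30`, with both boundaries assigned to the middle class),
#' risk-allele counts for any two-letter genotype columns (resolved
#' against `snp_info`), `agedx_quartile` and the `agedx_split` median
#' split of age at diagnosis.
#'
#' @param table Cohort tibble.
#' @param snp_info Optional tibble `snp_id`, `risk_allele`, and optionally
#'   `other_allele`, needed only when genotype columns hold two-letter
#'   genotypes. An ambiguous genotype (strand not resolvable against the
#'   declared alleles) is an error, not a guess.
#' @param agedx_cuts Either `NULL` (empirical quartiles of cases' age at
#'   diagnosis) or three inner cut points; the fixed cuts
#'   `c(39, 45, 53)` give the groups <=39 / 40-45 / 46-53 / >=54.
#' @param split_age Upper age of the early-diagnosis class of
#'   `agedx_split` (default 45: `<=45` vs `>=46`); `NULL` uses the
#'   empirical median.
#' @return The input tibble with the derived columns added/refreshed.
#' @export
derive_coded_variables <- function(table, snp_info = NULL, agedx_cuts = NULL,
                                   split_age = 45) {
  sc <- snp_cols(table)
  tbl <- table
  if (all(c("father_t2d", "mother_t2d") %in% names(tbl))) {
    tbl$ph_count <- as.integer(tbl$father_t2d + tbl$mother_t2d)
  }
  if (all(c("waist", "hip") %in% names(tbl))) {
    bad_hip <- !is.na(tbl$hip) & tbl$hip <= 0
    if (any(bad_hip)) {
      warn(sprintf("%d record(s) with hip <= 0: WHR set missing", sum(bad_hip)))
    }
    tbl$whr <- ifelse(is.na(tbl$hip) | tbl$hip <= 0, NA_real_,
                      tbl$waist / tbl$hip)
  }
  if ("bmi" %in% names(tbl)) {
    tbl$bmi_cat <- bmi_category(tbl$bmi)
  }
  for (col in sc) {
    if (!is.numeric(tbl[[col]])) {
      if (is.null(snp_info)) {
        stop_domain("two-letter genotypes in `%s` but no snp_info given", col)
      }
      row <- snp_info[snp_info$snp_id == col, , drop = FALSE]
      if (nrow(row) != 1) stop_domain("snp_info lacks risk allele for `%s`", col)
      other <- if ("other_allele" %in% names(row)) row$other_allele else NULL
      tbl[[col]] <- letters_to_count(tbl[[col]], row$risk_allele, other, col)
    }
  }
  if ("age_dx" %in% names(tbl)) {
    agedx <- tbl$age_dx
    obs <- agedx[!is.na(agedx)]
    if (length(obs) >= 4) {
      cuts <- agedx_cuts %||%
        unname(quantile(obs, c(0.25, 0.5, 0.75), type = 7))
      labs <- c(sprintf("<=%g", cuts[1]),
                sprintf("%g-%g", cuts[1], cuts[2]),
                sprintf("%g-%g", cuts[2], cuts[3]),
                sprintf(">=%g", cuts[3]))
      idx <- findInterval(agedx, cuts, left.open = TRUE) + 1L
      tbl$agedx_quartile <- factor(labs[idx], levels = labs)
      split <- split_age %||% median(obs)
      tbl$agedx_split <- factor(ifelse(is.na(agedx), NA,
                                       ifelse(agedx <= split,
                                              sprintf("<=%g", split),
                                              sprintf(">%g", split))),
                                levels = c(sprintf("<=%g", split),
                                           sprintf(">%g", split)))
    }
  }
  attr(tbl, "snp_cols") <- sc
  tbl
}

#' WHO BMI category
#'
#' Classes `<25`, `25-30`, `>30` kg/m2; both printed boundaries belong to
#' the middle class (25 <= BMI <= 30 is `25-30`).
#'
#' @param bmi Numeric vector, kg/m2.
#' @return Factor with levels `<25`, `25-30`, `>30` (reference first).
#' @export
bmi_category <- function(bmi) {
  out <- dplyr::case_when(
    is.na(bmi) ~ NA_character_,
    bmi < 25 ~ "<25",
    bmi <= 30 ~ "25-30",
    TRUE ~ ">30"
  )
  factor(out, levels = c("<25", "25-30", ">30"))
}
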