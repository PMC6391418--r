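# Internal helpers shared across modules.

expit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' Star-code a p-value
#'
#' Maps a p-value onto the significance scheme used in the report tables:
#' `a` (> 0.05), `b` (< 0.05), `c` (< 0.01), `d` (< 0.001), `e` (< 0.0001).
#' Raw p-values are always retained in machine-readable output; the letters
#' are a display convention only.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of codes (NA propagates).
#' @export
#' @examples
#' p_stars(c(0.2, 0.03, 0.004, 2e-6))
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "e",
    p < 1e-3 ~ "d",
    p < 1e-2 ~ "c",
    p < 0.05 ~ "b",
    TRUE ~ "a"
  )
}

# Deterministic substream seed derived from a single global seed.
# Keeps every derived seed a valid 32-bit integer.
substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483629L)
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so simulation helpers do not perturb outer streams.
with_substream <- function(seed, k, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream(seed, k))
  force(expr)
}

stop_domain <- function(msg, ...) abort(sprintf(msg, ...), class = "t2dvar_domain_error")

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_domain("`%s` must lie in [0, 1]", name)
  }
  invisible(x)
}

# status is stored as "control"/"case"; analyses need a 0/1 outcome.
status_to_binary <- function(status) {
  if (is.numeric(status)) {
    if (!all(status %in% c(0, 1, NA))) stop_domain("numeric status must be 0/1")
    return(as.numeric(status))
  }
  s <- as.character(status)
  bad <- setdiff(unique(s[!is.na(s)]), c("case", "control"))
  if (length(bad) > 0) {
    stop_domain("status must be 'case'/'control' (found: %s)", paste(bad, collapse = ", "))
  }
  as.numeric(s == "case")
}
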