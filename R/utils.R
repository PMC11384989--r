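# Internal helpers shared across modules.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Two-sided normal p-value; NA for se <= 0 or non-finite inputs.
# Floored at the smallest positive double so extreme z never underflows to 0.
normal_pval <- function(beta, se) {
  ifelse(is.finite(beta) & is.finite(se) & se > 0,
         pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin),
         NA_real_)
}

empty_skipped <- function() {
  data.frame(snp_id = character(), reason = character(),
             stringsAsFactors = FALSE)
}

empty_exclusions <- function() {
  data.frame(snp_id = character(), stage = character(), detail = character(),
             stringsAsFactors = FALSE)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

minor_af <- function(eaf) pmin(eaf, 1 - eaf)

# Construct an MrResult, deriving pval/OR fields from beta and se.
# se = 0 marks a degenerate fit: pval NA, CI collapsed, flag in extra.
new_mr_result <- function(method, k, beta, se, extra = list()) {
  if (!is.finite(se) || se < 0) se <- NA_real_
  degenerate <- is.na(se) || se == 0
  pval <- if (degenerate) NA_real_ else normal_pval(beta, se)
  if (degenerate && !("flag" %in% names(extra)))
    extra$flag <- "degenerate_fit"
  half <- if (degenerate) 0 else 1.96 * se
  new("MrResult", method = method, k = as.integer(k), beta = beta,
      se = if (is.na(se)) 0 else se, pval = pval,
      orPoint = exp(beta), orLow = exp(beta - half), orHigh = exp(beta + half),
      extra = extra)
}
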