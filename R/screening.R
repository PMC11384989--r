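#' Classify evidence tier from the five method p-values
#'
#' Evidence levels follow the consistency of the five estimators at
#' significance level \code{alphaSig}: if the primary (IVW) p-value is not
#' significant the tier is \code{"none"} regardless of the other methods;
#' otherwise, with \code{c} the count of significant methods (NA counts as
#' non-significant), the tier is \code{"inclusion"} when only IVW is
#' significant (\code{c = 1}), \code{"strong"} when 2-3 methods are, and
#' \code{"very_strong"} when 4 or more are.
#'
#' @param methodPvals numeric vector of exactly five p-values named
#'   \code{IVW}, \code{Egger}, \code{WeightedMedian}, \code{SimpleMode},
#'   \code{WeightedMode} (or unnamed in that order). NAs allowed.
#' @param alphaSig significance level (default 0.05).
#' @return one of \code{"none"}, \code{"inclusion"}, \code{"strong"},
#'   \code{"very_strong"}.
#' @export
classifyTier <- function(methodPvals, alphaSig = 0.05) {
  stopifnot(length(methodPvals) == 5)
  if (is.null(names(methodPvals)))
    names(methodPvals) <- c("IVW", "Egger", "WeightedMedian", "SimpleMode",
                            "WeightedMode")
  sig <- !is.na(methodPvals) & methodPvals < alphaSig
  if (!sig[["IVW"]]) return("none")
  c_ <- sum(sig)
  if (c_ >= 4) "very_strong" else if (c_ >= 2) "strong" else "inclusion"
}

# One exposure through the full pipeline; returns a list of row fields.
.screen_one <- function(exposure, outcome, ld, config, seed) {
  instr <- selectInstruments(
    exposure, ld, pvalThreshold = config$pvalThreshold,
    windowKb = config$windowKb, r2Max = config$r2Max, fMin = config$fMin)
  ids <- instrumentIds(instr)
  if (!length(ids)) stop("no instruments")
  H <- harmonize(exposure, outcome, ids,
                 palindromicMafMax = config$palindromicMafMax)
  if (!nrow(H@rows)) stop("no instruments")
  fits <- mrAllMethods(H, ivwModel = config$ivwModel, nBoot = config$nBoot,
                       seed = seed)
  k <- nrow(H@rows)
  pvals <- vapply(c("IVW", "Egger", "WeightedMedian", "SimpleMode",
                    "WeightedMode"),
                  function(m) if (is.null(fits[[m]])) NA_real_
                  else fits[[m]]@pval, numeric(1))
  q_p <- if (k >= 2) cochranQ(H)@pval else NA_real_
  eg_p <- if (k >= 3) eggerInterceptTest(H)$pval else NA_real_
  pr_p <- if (k >= 4)
    mrPresso(H, nSim = config$pressoNSim, sig = config$pressoSig,
             seed = seed + 7L)@globalPval else NA_real_
  row <- list(exposure_id = exposure@studyId, k = k,
              n_methods_significant = sum(!is.na(pvals) &
                                            pvals < config$alphaSig),
              tier = classifyTier(pvals, config$alphaSig),
              q_pval = q_p, egger_intercept_pval = eg_p,
              presso_global_pval = pr_p)
  for (m in names(fits)) {
    f <- fits[[m]]
    pre <- tolower(gsub("([a-z])([A-Z])", "\\1_\\2", m))
    row[[paste0(pre, "_beta")]] <- if (is.null(f)) NA_real_ else f@beta
    row[[paste0(pre, "_se")]] <- if (is.null(f)) NA_real_ else f@se
    row[[paste0(pre, "_pval")]] <- if (is.null(f)) NA_real_ else f@pval
    row[[paste0(pre, "_or")]] <- if (is.null(f)) NA_real_ else f@orPoint
    row[[paste0(pre, "_or_lo95")]] <- if (is.null(f)) NA_real_ else f@orLow
    row[[paste0(pre, "_or_hi95")]] <- if (is.null(f)) NA_real_ else f@orHigh
  }
  row
}

.failed_row <- function(exposure_id, reason) {
  list(exposure_id = exposure_id, k = 0L, n_methods_significant = 0L,
       tier = "none", q_pval = NA_real_, egger_intercept_pval = NA_real_,
       presso_global_pval = NA_real_, failure = reason)
}

#' Screen many exposures against one outcome
#'
#' For each exposure: instrument selection, harmonization, the
#' five-estimator battery, sensitivity diagnostics (Cochran's Q, Egger
#' intercept, PRESSO-style global test where enough instruments exist),
#' optional reverse MR, and evidence tiering. Per-exposure failures
#' (typically "no instruments") never abort the screen; the exposure gets a
#' tier-\code{none} row carrying the failure reason. Benjamini-Hochberg
#' q-values are computed across all exposures' IVW p-values. Rows are sorted
#' by IVW p-value, so the output is invariant to the input order of
#' exposures.
#'
#' @param exposures list of \code{\link{SummaryStudy}} objects.
#' @param outcome the outcome \code{\link{SummaryStudy}}.
#' @param ld correlation matrix covering all exposure panels.
#' @param config a \code{\link{mrConfig}} list.
#' @param seed integer seed; per-exposure bootstrap seeds are derived from
#'   it, so identical inputs and seed give byte-identical output.
#' @param reverse also run reverse MR (outcome as exposure) per row; adds a
#'   \code{reverse_mr_pval} column (NA when the outcome side has no
#'   instruments for that panel) and a \code{direction} label
#'   (\code{"unidirectional"} when the forward finding is significant and
#'   the reverse is not).
#' @return data.frame, one row per exposure, with per-method estimate
#'   columns, sensitivity p-values, \code{tier}, and \code{fdr_q}.
#' @export
mrScreen <- function(exposures, outcome, ld, config = mrConfig(), seed = 1,
                     reverse = FALSE) {
  if (!length(exposures)) stop("no exposures")
  rows <- vector("list", length(exposures))
  for (i in seq_along(exposures)) {
    ex <- exposures[[i]]
    # derive the per-exposure seed from the study id, not the list position,
    # so the screen is invariant to exposure input order
    key <- sum(utf8ToInt(ex@studyId) * seq_len(nchar(ex@studyId)))
    sub_seed <- as.integer((seed * 10007 + key * 13) %% .Machine$integer.max)
    rows[[i]] <- tryCatch(
      .screen_one(ex, outcome, ld, config, sub_seed),
      error = function(e) .failed_row(ex@studyId, conditionMessage(e)))
    if (reverse) {
      rev_fit <- tryCatch(
        reverseMr(outcome, ex, ld, config),
        error = function(e) NULL)
      rows[[i]]$reverse_mr_pval <- if (is.null(rev_fit)) NA_real_
      else rev_fit@pval
    }
  }
  all_names <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(all_names, names(r))] <- NA
    as.data.frame(r[all_names], stringsAsFactors = FALSE)
  }))
  if (!"failure" %in% names(df)) df$failure <- NA_character_
  df$fdr_q <- stats::p.adjust(df$ivw_pval, method = "BH")
  if (reverse) {
    sig_fwd <- !is.na(df$ivw_pval) & df$ivw_pval < config$alphaSig
    df$direction <- ifelse(
      sig_fwd & (is.na(df$reverse_mr_pval) |
                   df$reverse_mr_pval >= config$alphaSig),
      "unidirectional",
      ifelse(sig_fwd, "bidirectional", NA_character_))
  }
  df <- df[order(df$ivw_pval, df$exposure_id, na.last = TRUE), ]
  rownames(df) <- NULL
  df
}

#' Reverse-direction MR
#'
#' Runs the identical pipeline with the roles swapped: instruments are
#' selected in the (former) outcome study and their effects on the (former)
#' exposure estimated by IVW. A non-significant reverse estimate alongside a
#' significant forward one supports a unidirectional causal reading. When
#' the outcome study has no instruments at the configured threshold the
#' condition is reported as an error with message \code{"no instruments"}
#' (reverse-untestable, not a pipeline failure).
#'
#' @param outcomeAsExposure the outcome study, now playing the exposure
#'   role.
#' @param exposureAsOutcome the exposure study, now playing the outcome
#'   role.
#' @param ld correlation matrix covering the outcome study's SNPs.
#' @param config a \code{\link{mrConfig}} list.
#' @return an \code{\link{MrResult}} (IVW).
#' @export
reverseMr <- function(outcomeAsExposure, exposureAsOutcome, ld,
                      config = mrConfig()) {
  leg <- .mr_leg(outcomeAsExposure, exposureAsOutcome, ld, config)
  leg$fit
}

#' Write a screen table as TSV
#'
#' Fixed column order and full-precision numerics, so identical screens
#' produce byte-identical files.
#'
#' @param df result of \code{\link{mrScreen}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScreenTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- format(out[[j]], digits = 17)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
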