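#' @describeIn SummaryStudy-accessors study identifier
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))

#' @describeIn SummaryStudy-accessors trait name
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @describeIn SummaryStudy-accessors per-SNP association table
#' @export
setGeneric("snps", function(x) standardGeneric("snps"))

#' @describeIn SummaryStudy-accessors rows skipped on import
#' @export
setGeneric("skippedRows", function(x) standardGeneric("skippedRows"))

#' Accessors for SummaryStudy
#'
#' @param x a \code{SummaryStudy}.
#' @name SummaryStudy-accessors
#' @aliases studyId traitName snps skippedRows
NULL

setMethod("studyId", "SummaryStudy", function(x) x@studyId)
setMethod("traitName", "SummaryStudy", function(x) x@traitName)
setMethod("snps", "SummaryStudy", function(x) x@snps)
setMethod("skippedRows", "SummaryStudy", function(x) x@skipped)

#' Retained rows of a harmonized set
#' @param x a \code{HarmonizedSet}.
#' @return data.frame of aligned per-SNP effects.
#' @export
harmonizedRows <- function(x) {
  stopifnot(is(x, "HarmonizedSet"))
  x@rows
}

#' SNPs dropped during harmonization, with reasons
#' @param x a \code{HarmonizedSet}.
#' @export
droppedSnps <- function(x) {
  stopifnot(is(x, "HarmonizedSet"))
  x@dropped
}

#' Retained instrument snp_ids
#' @param x an \code{InstrumentSet}.
#' @export
instrumentIds <- function(x) {
  stopifnot(is(x, "InstrumentSet"))
  x@table$snp_id
}

#' Per-stage exclusion audit of an instrument selection
#' @param x an \code{InstrumentSet}.
#' @export
instrumentExclusions <- function(x) {
  stopifnot(is(x, "InstrumentSet"))
  x@exclusions
}

#' Flatten an MrResult to a one-row data.frame
#'
#' @param x an \code{MrResult}.
#' @return data.frame with columns method, k, beta, se, pval, or, or_lo95,
#'   or_hi95.
#' @export
mrResultRow <- function(x) {
  stopifnot(is(x, "MrResult"))
  data.frame(method = x@method, k = x@k, beta = x@beta, se = x@se,
             pval = x@pval, or = x@orPoint, or_lo95 = x@orLow,
             or_hi95 = x@orHigh, stringsAsFactors = FALSE)
}

setMethod("show", "SummaryStudy", function(object) {
  cat("SummaryStudy '", object@studyId, "' (", object@traitType, " trait '",
      object@traitName, "')\n", sep = "")
  cat("  ", nrow(object@snps), " SNPs; ", nrow(object@skipped),
      " rows skipped on import\n", sep = "")
})

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet ", object@exposureId, " -> ", object@outcomeId, "\n",
      sep = "")
  cat("  ", nrow(object@rows), " SNPs retained, ", nrow(object@dropped),
      " dropped\n", sep = "")
  if (nrow(object@dropped)) {
    tab <- table(object@dropped$reason)
    cat("  dropped:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet for ", object@exposureId, ": ", nrow(object@table),
      " instruments retained, ", nrow(object@exclusions), " excluded\n",
      sep = "")
})

setMethod("show", "MrResult", function(object) {
  cat(sprintf("MrResult [%s] k=%d beta=%.4f se=%.4f p=%s OR=%.4f (%.4f-%.4f)\n",
              object@method, object@k, object@beta, object@se,
              format(object@pval, digits = 4), object@orPoint,
              object@orLow, object@orHigh))
})

setMethod("show", "QResult", function(object) {
  cat(sprintf("Cochran's Q = %.4f on %d df, p = %s\n", object@Q, object@df,
              format(object@pval, digits = 4)))
})

setMethod("show", "PressoReport", function(object) {
  cat(sprintf("PRESSO-style report: RSS = %.4f, global p = %s\n",
              object@rssObs, format(object@globalPval, digits = 4)))
  cat("  outliers:", if (length(object@outliers))
    paste(object@outliers, collapse = ", ") else "none", "\n")
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf(
    "MediationResult: alpha=%.4f beta1=%.4f beta2=%.4f beta3=%.5f\n",
    object@alpha, object@beta1, object@beta2, object@beta3))
  cat(sprintf("  proportion mediated = %.4f; bootstrap 95%% CI (%.5f, %.5f), p = %s\n",
              object@proportion, object@bootCiLow, object@bootCiHigh,
              format(object@bootPval, digits = 4)))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "MrSimConfig", function(object) {
  cat(sprintf(
    "MrSimConfig: %d instruments + %d null SNPs, theta=%.3g, beta1=%.3g, beta2=%.3g\n",
    object@nInstruments, object@nNullSnps, object@theta, object@beta1,
    object@beta2))
  cat(sprintf("  pleiotropy=%s (sd=%.3g, mean=%.3g, outliers=%d); LD blocks of %d at r=%.2f; seed=%d\n",
              object@pleiotropyMode, object@pleiotropySd, object@pleiotropyMean,
              object@nOutliers, object@ldBlockSize, object@ldR, object@seed))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d SNPs, implied total effect %.4f, %d outliers\n",
              length(object@gamma), object@impliedTotal,
              length(object@outlierIds)))
})
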