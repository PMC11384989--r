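#' @import methods
NULL

VALID_BASES <- c("A", "C", "G", "T")

.snp_columns <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n", "pval_derived")

#' Per-study GWAS summary statistics
#'
#' A \code{SummaryStudy} holds one study's per-SNP association statistics:
#' identifier, position, alleles, effect-allele frequency, effect size (beta,
#' on the log-odds scale for binary traits), its standard error, p-value and
#' sample size. Rows skipped on import are kept in a separate audit table.
#'
#' @slot studyId character identifier of the study.
#' @slot traitName human-readable trait name.
#' @slot traitType \code{"quantitative"} or \code{"binary"}.
#' @slot snps data.frame with columns \code{snp_id}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{other_allele}, \code{eaf}, \code{beta},
#'   \code{se}, \code{pval}, \code{n}, \code{pval_derived}.
#' @slot skipped data.frame of rows dropped on import (\code{snp_id},
#'   \code{reason}).
#' @exportClass SummaryStudy
setClass("SummaryStudy",
  representation(
    studyId = "character",
    traitName = "character",
    traitType = "character",
    snps = "data.frame",
    skipped = "data.frame"
  ),
  prototype(
    traitType = "quantitative",
    skipped = data.frame(snp_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  )
)

setValidity("SummaryStudy", function(object) {
  msgs <- character()
  df <- object@snps
  missing_cols <- setdiff(.snp_columns, names(df))
  if (length(missing_cols))
    msgs <- c(msgs, paste0("snps lacks columns: ",
                           paste(missing_cols, collapse = ", ")))
  if (!length(msgs) && nrow(df)) {
    if (anyDuplicated(df$snp_id))
      msgs <- c(msgs, "snp_id must be unique within a study")
    if (any(!is.na(df$se) & df$se <= 0))
      msgs <- c(msgs, "se must be > 0")
    if (any(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)))
      msgs <- c(msgs, "eaf must lie in [0, 1]")
    if (any(!is.na(df$pval) & (df$pval <= 0 | df$pval > 1)))
      msgs <- c(msgs, "pval must lie in (0, 1]")
    same <- !is.na(df$effect_allele) & !is.na(df$other_allele) &
      df$effect_allele == df$other_allele
    if (any(same))
      msgs <- c(msgs, "effect_allele must differ from other_allele")
  }
  if (!object@traitType %in% c("quantitative", "binary"))
    msgs <- c(msgs, "traitType must be 'quantitative' or 'binary'")
  if (length(msgs)) msgs else TRUE
})

#' Exposure/outcome effects aligned to a shared effect allele
#'
#' Produced by \code{\link{harmonize}}. Retained rows carry both studies'
#' effects expressed for the exposure's effect allele; SNPs that could not be
#' aligned are listed in \code{dropped} with a reason, so that
#' \code{retained + dropped} always accounts for every requested SNP.
#'
#' @slot exposureId,outcomeId study identifiers.
#' @slot rows data.frame: \code{snp_id}, \code{beta_exp}, \code{se_exp},
#'   \code{beta_out}, \code{se_out}, \code{eaf_exp}.
#' @slot dropped data.frame: \code{snp_id}, \code{reason}.
#' @exportClass HarmonizedSet
setClass("HarmonizedSet",
  representation(
    exposureId = "character",
    outcomeId = "character",
    rows = "data.frame",
    dropped = "data.frame"
  )
)

setValidity("HarmonizedSet", function(object) {
  msgs <- character()
  need <- c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out", "eaf_exp")
  if (!all(need %in% names(object@rows)))
    msgs <- c(msgs, "rows lacks required columns")
  if (!all(c("snp_id", "reason") %in% names(object@dropped)))
    msgs <- c(msgs, "dropped lacks required columns")
  if (!length(msgs)) {
    overlap <- intersect(object@rows$snp_id, object@dropped$snp_id)
    if (length(overlap))
      msgs <- c(msgs, paste0("snp_id in both rows and dropped: ",
                             paste(overlap, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Selected genetic instruments with an exclusion audit trail
#'
#' @slot exposureId study the instruments were selected for.
#' @slot table data.frame of retained SNPs: \code{snp_id}, \code{pval},
#'   \code{r2_explained}, \code{f_stat}.
#' @slot exclusions data.frame of excluded SNPs: \code{snp_id}, \code{stage}
#'   (\code{"pval"}, \code{"clump"} or \code{"weak"}), \code{detail}.
#' @exportClass InstrumentSet
setClass("InstrumentSet",
  representation(
    exposureId = "character",
    table = "data.frame",
    exclusions = "data.frame"
  )
)

setValidity("InstrumentSet", function(object) {
  msgs <- character()
  if (!all(c("snp_id", "pval", "r2_explained", "f_stat") %in%
           names(object@table)))
    msgs <- c(msgs, "table lacks required columns")
  if (!all(c("snp_id", "stage", "detail") %in% names(object@exclusions)))
    msgs <- c(msgs, "exclusions lacks required columns")
  if (!length(msgs) && nrow(object@exclusions) &&
      !all(object@exclusions$stage %in% c("pval", "clump", "weak")))
    msgs <- c(msgs, "exclusion stage must be pval, clump or weak")
  if (length(msgs)) msgs else TRUE
})

#' One estimator's causal estimate
#'
#' Causal log-odds estimate from a single MR method, with its normal-theory
#' p-value and the odds-ratio scale derived as \code{exp(beta)} with a 95\%
#' Wald interval. Method-specific extras (Egger intercept, random-effects
#' scale factor, bootstrap settings) live in \code{extra}.
#'
#' @slot method one of \code{"IVW"}, \code{"Egger"}, \code{"WeightedMedian"},
#'   \code{"SimpleMode"}, \code{"WeightedMode"}, or \code{"WaldRatio"}.
#' @slot k number of SNPs used.
#' @slot beta,se point estimate and standard error (log-odds scale).
#' @slot pval two-sided normal p-value; \code{NA} when \code{se} is zero
#'   (degenerate fit).
#' @slot orPoint,orLow,orHigh odds ratio and 95\% CI.
#' @slot extra named list of method-specific fields.
#' @exportClass MrResult
setClass("MrResult",
  representation(
    method = "character",
    k = "integer",
    beta = "numeric",
    se = "numeric",
    pval = "numeric",
    orPoint = "numeric",
    orLow = "numeric",
    orHigh = "numeric",
    extra = "list"
  )
)

setValidity("MrResult", function(object) {
  msgs <- character()
  if (!isTRUE(all.equal(object@orPoint, exp(object@beta))))
    msgs <- c(msgs, "orPoint must equal exp(beta)")
  if (is.finite(object@se) && object@se > 0) {
    if (!(object@orLow < object@orPoint && object@orPoint < object@orHigh))
      msgs <- c(msgs, "CI must bracket the point estimate")
    expect_p <- 2 * stats::pnorm(-abs(object@beta / object@se))
    if (!is.na(object@pval) && !isTRUE(all.equal(object@pval, expect_p)))
      msgs <- c(msgs, "pval inconsistent with beta/se under the normal test")
  }
  if (length(msgs)) msgs else TRUE
})

#' Cochran's Q heterogeneity test
#'
#' @slot Q the heterogeneity statistic (weighted sum of squared deviations of
#'   Wald ratios from the fixed-effect IVW estimate).
#' @slot df degrees of freedom, \code{k - 1}.
#' @slot pval upper-tail chi-square p-value.
#' @slot contributions named numeric vector of per-SNP contributions summing
#'   to \code{Q}.
#' @exportClass QResult
setClass("QResult",
  representation(
    Q = "numeric",
    df = "integer",
    pval = "numeric",
    contributions = "numeric"
  )
)

setValidity("QResult", function(object) {
  msgs <- character()
  if (object@df < 0L) msgs <- c(msgs, "df must be >= 0")
  if (is.finite(object@Q) && object@Q < -1e-12) msgs <- c(msgs, "Q must be >= 0")
  if (is.finite(object@Q) &&
      !isTRUE(all.equal(object@Q, sum(object@contributions))))
    msgs <- c(msgs, "contributions must sum to Q")
  if (length(msgs)) msgs else TRUE
})

#' PRESSO-style global, outlier and distortion report
#'
#' Simulation-based pleiotropy residual-sum-and-outlier diagnostics: a global
#' heterogeneity test on the leave-one-out residual sum of squares, per-SNP
#' outlier p-values (Bonferroni-corrected), and a distortion test comparing
#' the estimate before and after removing flagged outliers. All simulated
#' tail probabilities use add-one smoothing and so never reach zero.
#'
#' @slot rssObs observed residual sum of squares.
#' @slot globalPval simulated global test p-value.
#' @slot outlierPvals named per-SNP corrected outlier p-values.
#' @slot outliers snp_ids flagged at the significance threshold.
#' @slot distortionPval simulated distortion-test p-value (\code{NA} when no
#'   outlier was flagged).
#' @slot betaBefore,betaAfter IVW estimate on all SNPs and on the complement
#'   of the outlier set (\code{NA} when nothing was removed or nothing left).
#' @slot nSim number of simulations used.
#' @exportClass PressoReport
setClass("PressoReport",
  representation(
    rssObs = "numeric",
    globalPval = "numeric",
    outlierPvals = "numeric",
    outliers = "character",
    distortionPval = "numeric",
    betaBefore = "numeric",
    betaAfter = "numeric",
    nSim = "integer"
  )
)

setValidity("PressoReport", function(object) {
  msgs <- character()
  if (!all(object@outliers %in% names(object@outlierPvals)))
    msgs <- c(msgs, "outliers must be a subset of the tested SNPs")
  floor_p <- 1 / (object@nSim + 1)
  sim_p <- c(object@globalPval, object@distortionPval)
  sim_p <- sim_p[!is.na(sim_p)]
  if (length(sim_p) && any(sim_p < floor_p - 1e-12 | sim_p > 1 + 1e-12))
    msgs <- c(msgs, "simulated p-values must lie in [1/(nSim+1), 1]")
  if (length(msgs)) msgs else TRUE
})

#' Two-step mediation MR result
#'
#' Total effect \code{alpha} (exposure to outcome), step effects \code{beta1}
#' (exposure to mediator) and \code{beta2} (mediator to outcome, after
#' removing mediator instruments associated with the exposure), the product
#' indirect effect \code{beta3 = beta1 * beta2}, the proportion mediated
#' \code{beta3 / alpha}, and a parametric-bootstrap percentile CI and p-value
#' for \code{beta3}.
#'
#' @slot alpha,beta1,beta2,beta3,proportion numeric effect estimates.
#' @slot bootCiLow,bootCiHigh,bootPval bootstrap inference for \code{beta3}.
#' @slot nBoot,seed bootstrap settings.
#' @slot flags character vector of warnings such as
#'   \code{"opposite_sign_proportion"}.
#' @slot detail list of per-leg \code{MrResult}s and instrument audits.
#' @exportClass MediationResult
setClass("MediationResult",
  representation(
    alpha = "numeric",
    beta1 = "numeric",
    beta2 = "numeric",
    beta3 = "numeric",
    proportion = "numeric",
    bootCiLow = "numeric",
    bootCiHigh = "numeric",
    bootPval = "numeric",
    nBoot = "integer",
    seed = "integer",
    flags = "character",
    detail = "list"
  )
)

setValidity("MediationResult", function(object) {
  msgs <- character()
  if (!isTRUE(all.equal(object@beta3, object@beta1 * object@beta2)))
    msgs <- c(msgs, "beta3 must equal beta1 * beta2 exactly")
  if (!is.na(object@proportion) && object@alpha != 0 &&
      !isTRUE(all.equal(object@proportion * object@alpha, object@beta3)))
    msgs <- c(msgs, "proportion * alpha must equal beta3")
  if (length(msgs)) msgs else TRUE
})

#' Configuration of the synthetic GWAS generator
#'
#' Encodes the simulated study design: counts of true instruments and null
#' SNPs, per-study sample sizes, the planted direct causal effect
#' \code{theta}, the mediation path \code{beta1 * beta2}, the pleiotropy
#' regime, gross-outlier SNPs, and the block LD structure. Identical configs
#' (including \code{seed}) always produce byte-identical studies.
#'
#' @seealso \code{\link{mrSimConfig}} for the user-facing constructor with
#'   documented defaults.
#' @exportClass MrSimConfig
setClass("MrSimConfig",
  representation(
    nInstruments = "integer",
    nMediatorInstruments = "integer",
    nNullSnps = "integer",
    nExposure = "integer",
    nOutcome = "integer",
    nMediator = "integer",
    theta = "numeric",
    beta1 = "numeric",
    beta2 = "numeric",
    gammaSd = "numeric",
    pleiotropyMode = "character",
    pleiotropySd = "numeric",
    pleiotropyMean = "numeric",
    nOutliers = "integer",
    outlierEffect = "numeric",
    eafRange = "numeric",
    ldBlockSize = "integer",
    ldR = "numeric",
    seed = "integer"
  )
)

setValidity("MrSimConfig", function(object) {
  msgs <- character()
  if (object@nInstruments < 0L || object@nNullSnps < 0L ||
      object@nMediatorInstruments < 0L)
    msgs <- c(msgs, "SNP counts must be >= 0")
  if (any(c(object@nExposure, object@nOutcome, object@nMediator) <= 2L))
    msgs <- c(msgs, "sample sizes must be > 2")
  if (!object@pleiotropyMode %in% c("none", "balanced", "directional"))
    msgs <- c(msgs, "pleiotropyMode must be none, balanced or directional")
  if (abs(object@ldR) >= 1) msgs <- c(msgs, "|ldR| must be < 1")
  if (object@ldBlockSize < 1L) msgs <- c(msgs, "ldBlockSize must be >= 1")
  if (object@nOutliers > object@nInstruments)
    msgs <- c(msgs, "nOutliers cannot exceed nInstruments")
  if (length(object@eafRange) != 2 || object@eafRange[1] <= 0 ||
      object@eafRange[2] >= 1 || object@eafRange[1] > object@eafRange[2])
    msgs <- c(msgs, "eafRange must be an increasing pair inside (0, 1)")
  if (object@gammaSd < 0 || object@pleiotropySd < 0)
    msgs <- c(msgs, "SDs must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Ground truth behind a synthetic simulation
#'
#' @slot config the \code{MrSimConfig} that produced the studies.
#' @slot gamma per-SNP true instrument effects on the exposure (zero for null
#'   SNPs), named by snp_id.
#' @slot delta per-SNP mediator-specific instrument effects (zero outside the
#'   mediator-instrument block).
#' @slot alphaDirect per-SNP direct (pleiotropic) effects on the outcome.
#' @slot outlierIds snp_ids of planted gross-pleiotropy SNPs.
#' @slot block per-SNP LD block index.
#' @slot chrom,pos simulated positions.
#' @slot impliedTotal \code{theta + beta1 * beta2}, the total causal effect a
#'   correctly working pipeline should recover.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(
    config = "MrSimConfig",
    gamma = "numeric",
    delta = "numeric",
    alphaDirect = "numeric",
    outlierIds = "character",
    block = "integer",
    chrom = "character",
    pos = "numeric",
    impliedTotal = "numeric"
  )
)

setValidity("SyntheticTruth", function(object) {
  m <- object@config@nInstruments + object@config@nMediatorInstruments +
    object@config@nNullSnps
  msgs <- character()
  if (length(object@gamma) != m || length(object@alphaDirect) != m ||
      length(object@delta) != m)
    msgs <- c(msgs, "gamma/delta/alphaDirect length must equal the SNP count")
  tot <- object@config@theta + object@config@beta1 * object@config@beta2
  if (!isTRUE(all.equal(object@impliedTotal, tot)))
    msgs <- c(msgs, "impliedTotal must equal theta + beta1 * beta2")
  if (length(msgs)) msgs else TRUE
})
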