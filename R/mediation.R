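#' Remove mediator instruments associated with the exposure
#'
#' For the mediator-to-outcome leg of a two-step mediation analysis, mediator
#' instruments that are themselves associated with the exposure (p-value
#' below \code{threshold} in the exposure study) are excluded, so that the
#' leg estimates the mediator's effect conditional on the exposure pathway.
#' Instruments absent from the exposure study cannot be checked and are
#' retained with a warning.
#'
#' @param instruments an \code{\link{InstrumentSet}} selected for the
#'   mediator.
#' @param exposure the exposure \code{\link{SummaryStudy}}.
#' @param threshold exposure-association p-value below which a mediator
#'   instrument is removed (default 1e-5).
#' @return the filtered \code{\link{InstrumentSet}} with audit rows added at
#'   stage \code{"pval"} detail \code{"associated_with_exposure"}.
#' @export
excludeExposureSnps <- function(instruments, exposure, threshold = 1e-5) {
  stopifnot(is(instruments, "InstrumentSet"), is(exposure, "SummaryStudy"))
  tab <- instruments@table
  idx <- match(tab$snp_id, exposure@snps$snp_id)
  p_exp <- exposure@snps$pval[idx]
  unchecked <- is.na(idx)
  if (any(unchecked))
    warning(sum(unchecked), " mediator instrument(s) absent from the ",
            "exposure study; retained unchecked")
  remove <- !unchecked & !is.na(p_exp) & p_exp < threshold
  excl <- instruments@exclusions
  if (any(remove))
    excl <- rbind(excl, data.frame(snp_id = tab$snp_id[remove],
                                   stage = "pval",
                                   detail = "associated_with_exposure",
                                   stringsAsFactors = FALSE))
  rownames(excl) <- NULL
  new("InstrumentSet", exposureId = instruments@exposureId,
      table = tab[!remove, , drop = FALSE], exclusions = excl)
}

# One IVW leg: select instruments in `from`, harmonize against `to`, fit.
.mr_leg <- function(from, to, ld, cfg, instruments = NULL) {
  if (is.null(instruments)) {
    instruments <- selectInstruments(
      from, ld, pvalThreshold = cfg$pvalThreshold, windowKb = cfg$windowKb,
      r2Max = cfg$r2Max, fMin = cfg$fMin)
  }
  ids <- instrumentIds(instruments)
  if (!length(ids)) stop("no instruments")
  H <- harmonize(from, to, ids, palindromicMafMax = cfg$palindromicMafMax)
  if (!nrow(H@rows)) stop("no instruments")
  list(instruments = instruments, H = H,
       fit = mrIvw(H, model = cfg$ivwModel))
}

#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' instrument p-value cutoff 1e-5 (strict), clumping window 10,000 kb and
#' r-squared cutoff 0.001, weak-instrument F minimum 10, palindromic-SNP
#' MAF ceiling 0.42, IVW multiplicative random-effects model, tiering and
#' sensitivity significance level 0.05, 1000 bootstrap and PRESSO
#' simulations.
#'
#' @param pvalThreshold,windowKb,r2Max,fMin instrument-selection settings.
#' @param palindromicMafMax harmonization palindrome ceiling.
#' @param ivwModel \code{"random_multiplicative"} or \code{"fixed"}.
#' @param alphaSig significance level for tiering and diagnostics.
#' @param nBoot bootstrap replicates for median/mode SEs and the mediation
#'   indirect effect.
#' @param pressoNSim,pressoSig PRESSO simulation count and threshold.
#' @param tierOn \code{"raw"} (default, mirroring common practice of tiering
#'   on unadjusted p-values) or \code{"fdr"} to tier on BH q-values.
#' @return named list.
#' @export
mrConfig <- function(pvalThreshold = 1e-5, windowKb = 10000, r2Max = 0.001,
                     fMin = 10, palindromicMafMax = 0.42,
                     ivwModel = "random_multiplicative", alphaSig = 0.05,
                     nBoot = 1000, pressoNSim = 1000, pressoSig = 0.05,
                     tierOn = c("raw", "fdr")) {
  list(pvalThreshold = pvalThreshold, windowKb = windowKb, r2Max = r2Max,
       fMin = fMin, palindromicMafMax = palindromicMafMax,
       ivwModel = ivwModel, alphaSig = alphaSig, nBoot = nBoot,
       pressoNSim = pressoNSim, pressoSig = pressoSig,
       tierOn = match.arg(tierOn))
}

#' Two-step mediation MR
#'
#' Estimates the total effect \code{alpha} (exposure to outcome, IVW), the
#' step effects \code{beta1} (exposure to mediator, IVW on the exposure's
#' instruments) and \code{beta2} (mediator to outcome, IVW on the mediator's
#' instruments after \code{\link{excludeExposureSnps}}), the product
#' indirect effect \code{beta3 = beta1 * beta2} and the proportion mediated
#' \code{beta3 / alpha}, with a parametric-bootstrap percentile CI and
#' p-value for \code{beta3} (\code{\link{bootstrapIndirect}}). When the
#' indirect effect and the total effect disagree in sign the proportion is
#' still reported but flagged \code{"opposite_sign_proportion"}.
#'
#' @param exposure,mediator,outcome \code{\link{SummaryStudy}} objects.
#' @param ld correlation matrix covering both instrument panels.
#' @param config a \code{\link{mrConfig}} list.
#' @param nBoot bootstrap replicates (default from config).
#' @param seed RNG seed for the bootstrap.
#' @return a \code{\link{MediationResult}}.
#' @export
twoStepMediation <- function(exposure, mediator, outcome, ld,
                             config = mrConfig(), nBoot = config$nBoot,
                             seed = 1) {
  legs <- .mediation_legs(exposure, mediator, outcome, ld, config)
  alpha <- legs$total$fit@beta
  beta1 <- legs$leg1$fit@beta
  beta2 <- legs$leg2$fit@beta
  beta3 <- beta1 * beta2
  proportion <- if (alpha != 0) beta3 / alpha else NA_real_
  flags <- character(0)
  if (!is.na(proportion) && sign(beta3) != 0 && sign(beta3) != sign(alpha))
    flags <- c(flags, "opposite_sign_proportion")
  boot <- .bootstrap_indirect_core(legs, nBoot, seed)
  new("MediationResult", alpha = alpha, beta1 = beta1, beta2 = beta2,
      beta3 = beta3, proportion = proportion, bootCiLow = boot$ci_low,
      bootCiHigh = boot$ci_high, bootPval = boot$pval,
      nBoot = as.integer(nBoot), seed = as.integer(seed), flags = flags,
      detail = list(total = legs$total$fit, leg1 = legs$leg1$fit,
                    leg2 = legs$leg2$fit,
                    mediator_instruments = legs$leg2$instruments))
}

.mediation_legs <- function(exposure, mediator, outcome, ld, config) {
  total <- tryCatch(.mr_leg(exposure, outcome, ld, config),
                    error = function(e)
                      stop("exposure->outcome leg: ", conditionMessage(e)))
  leg1 <- tryCatch(.mr_leg(exposure, mediator, ld, config,
                           instruments = total$instruments),
                   error = function(e)
                     stop("exposure->mediator leg: ", conditionMessage(e)))
  med_instr <- tryCatch(
    selectInstruments(mediator, ld, pvalThreshold = config$pvalThreshold,
                      windowKb = config$windowKb, r2Max = config$r2Max,
                      fMin = config$fMin),
    error = function(e)
      stop("mediator instrument selection: ", conditionMessage(e)))
  med_instr <- excludeExposureSnps(med_instr, exposure,
                                   threshold = config$pvalThreshold)
  leg2 <- tryCatch(.mr_leg(mediator, outcome, ld, config,
                           instruments = med_instr),
                   error = function(e)
                     stop("mediator->outcome leg: ", conditionMessage(e)))
  list(total = total, leg1 = leg1, leg2 = leg2)
}

# Parametric bootstrap of beta3 = beta1 * beta2: resample each leg's
# outcome-side betas from Normal(beta, se), refit the IVW slope.
.bootstrap_indirect_core <- function(legs, nBoot, seed) {
  H1 <- legs$leg1$H   # exposure -> mediator
  H2 <- legs$leg2$H   # mediator -> outcome
  ivw_resampled <- function(H) {
    r <- H@rows
    by <- stats::rnorm(nrow(r), r$beta_out, r$se_out)
    w <- r$beta_exp^2 / r$se_out^2
    sum(w * (by / r$beta_exp)) / sum(w)
  }
  reps <- with_seed(seed, {
    vapply(seq_len(nBoot), function(i)
      ivw_resampled(H1) * ivw_resampled(H2), numeric(1))
  })
  ci <- unname(stats::quantile(reps, c(0.025, 0.975), type = 7))
  p_le <- (sum(reps <= 0) + 1) / (nBoot + 1)
  p_ge <- (sum(reps >= 0) + 1) / (nBoot + 1)
  list(ci_low = ci[1], ci_high = ci[2], pval = min(1, 2 * min(p_le, p_ge)))
}

#' Bootstrap CI and p-value for the indirect effect
#'
#' Standalone parametric bootstrap of \code{beta3 = beta1 * beta2}: per
#' replicate, each leg's outcome-side per-SNP betas are resampled from
#' \code{Normal(beta, se)} (the only resampling available with summary
#' data), the IVW slopes refitted and their product recorded. The CI is the
#' 2.5/97.5 percentile of the replicates; the p-value is
#' \code{2 * min(P(beta3* <= 0), P(beta3* >= 0))} with add-one smoothing.
#'
#' @inheritParams twoStepMediation
#' @param nBoot bootstrap replicates; below 100 a warning about unstable
#'   percentile CIs is issued.
#' @return list: \code{ci_low}, \code{ci_high}, \code{pval}.
#' @export
bootstrapIndirect <- function(exposure, mediator, outcome, ld,
                              config = mrConfig(), nBoot = 1000, seed = 1) {
  if (nBoot < 100) warning("unstable percentile CI (nBoot < 100)")
  legs <- .mediation_legs(exposure, mediator, outcome, ld, config)
  .bootstrap_indirect_core(legs, nBoot, seed)
}

#' Serialize a MediationResult to JSON
#'
#' @param x a \code{\link{MediationResult}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMediationJson <- function(x, path) {
  stopifnot(is(x, "MediationResult"))
  out <- list(alpha = x@alpha, beta1 = x@beta1, beta2 = x@beta2,
              beta3 = x@beta3, proportion = x@proportion,
              boot_ci_low = x@bootCiLow, boot_ci_high = x@bootCiHigh,
              boot_pval = x@bootPval, n_boot = x@nBoot, seed = x@seed,
              flags = as.list(x@flags))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
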