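#' Cochran's Q heterogeneity test
#'
#' Per-SNP contributions \code{q_j = w_j (r_j - beta_IVW)^2} about the
#' fixed-effect IVW centre (the standard definition, regardless of which IVW
#' model the main analysis reports), with \code{Q = sum(q_j)} referred to the
#' upper tail of chi-square on \code{k - 1} degrees of freedom.
#'
#' @param H a \code{\link{HarmonizedSet}} with at least two SNPs.
#' @return a \code{\link{QResult}}.
#' @export
cochranQ <- function(H) {
  rr <- .ratios(H)
  k <- length(rr$ratio)
  if (k < 2) stop("insufficient instruments (k >= 2 required)")
  core <- .ivw_core(rr$ratio, rr$se)
  Q <- sum(core$q_contrib)
  new("QResult", Q = Q, df = k - 1L,
      pval = stats::pchisq(Q, df = k - 1, lower.tail = FALSE),
      contributions = stats::setNames(core$q_contrib, rr$snp_id))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-exports the intercept triple of \code{\link{mrEgger}}; a small p-value
#' indicates directional pleiotropy (a nonzero average direct effect across
#' instruments). On a degenerate perfect fit the SE is zero and the p-value
#' is NA with flag \code{"degenerate_fit"}.
#'
#' @param H a \code{\link{HarmonizedSet}} with at least three SNPs.
#' @return list: \code{intercept}, \code{se}, \code{pval}, \code{flag}
#'   (NA unless degenerate).
#' @export
eggerInterceptTest <- function(H) {
  fit <- mrEgger(H)
  list(intercept = fit@extra$intercept, se = fit@extra$intercept_se,
       pval = fit@extra$intercept_pval,
       flag = if (is.null(fit@extra$flag)) NA_character_ else fit@extra$flag)
}

#' Leave-one-out influence analysis
#'
#' Recomputes the IVW estimate \code{k} times, omitting one SNP each time,
#' plus the all-SNP row; a single influential or pleiotropic SNP shows up as
#' the one omission that moves the estimate.
#'
#' @param H a \code{\link{HarmonizedSet}} with at least two SNPs.
#' @param model IVW model used for every fit (same as the main analysis).
#' @return data.frame with \code{k + 1} rows: \code{snp_id} (the left-out
#'   SNP, or \code{"(all)"}), \code{beta_loo}, \code{se_loo},
#'   \code{pval_loo}.
#' @export
leaveOneOut <- function(H, model = "random_multiplicative") {
  rows <- H@rows
  k <- nrow(rows)
  if (k < 2) stop("insufficient instruments (k >= 2 required)")
  fit_on <- function(df) {
    sub <- H
    sub@rows <- df
    mrIvw(sub, model = model)
  }
  out <- lapply(seq_len(k), function(j) {
    f <- fit_on(rows[-j, , drop = FALSE])
    data.frame(snp_id = rows$snp_id[j], beta_loo = f@beta, se_loo = f@se,
               pval_loo = f@pval, stringsAsFactors = FALSE)
  })
  all_fit <- fit_on(rows)
  out <- c(out, list(data.frame(snp_id = "(all)", beta_loo = all_fit@beta,
                                se_loo = all_fit@se, pval_loo = all_fit@pval,
                                stringsAsFactors = FALSE)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Leave-one-out fixed-effect IVW betas for each SNP (vector of length k):
# the expected ratio for SNP j under the model fitted without it.
.loo_betas <- function(ratio, se) {
  w <- 1 / se^2
  sw <- sum(w); swr <- sum(w * ratio)
  (swr - w * ratio) / (sw - w)
}

#' PRESSO-style pleiotropy residual-sum and outlier test
#'
#' Simulation-based diagnostics inspired by the published
#' pleiotropy-residual-sum-and-outlier procedure, re-implemented from its
#' description and simplified to a single-parameter (intercept-free IVW)
#' search. The observed statistic is the weighted leave-one-out residual sum
#' of squares \code{RSS = sum_j w_j (r_j - beta_loo(j))^2}. Its null
#' distribution is built from \code{nSim} parametric simulations drawing
#' each ratio from \code{Normal(beta_loo(j), se_j)}; the global p-value is
#' the simulated upper-tail probability with add-one smoothing (never
#' exactly zero). Each SNP's residual contribution gets a simulated tail
#' probability, Bonferroni-corrected by \code{k}; SNPs below \code{sig} are
#' flagged as outliers. The distortion test compares the estimate shift
#' after removing the flagged outliers with the shift from removing equally
#' many SNPs at random.
#'
#' @param H a \code{\link{HarmonizedSet}} with at least four SNPs.
#' @param nSim parametric simulations (default 1000). Note the per-SNP
#'   corrected p-values cannot fall below \code{k / (nSim + 1)}; for outlier
#'   detection at level \code{sig}, \code{nSim} must exceed
#'   \code{k / sig}.
#' @param sig significance threshold for corrected outlier p-values and for
#'   reporting (default 0.05).
#' @param seed RNG seed; identical seeds give identical reports.
#' @return a \code{\link{PressoReport}}.
#' @export
mrPresso <- function(H, nSim = 1000, sig = 0.05, seed) {
  rr <- .ratios(H)
  k <- length(rr$ratio)
  if (k < 4) stop("insufficient instruments for PRESSO (k >= 4 required)")
  w <- 1 / rr$se^2
  loo <- .loo_betas(rr$ratio, rr$se)
  q_obs <- w * (rr$ratio - loo)^2
  rss_obs <- sum(q_obs)

  with_seed(seed, {
    exceed_global <- 0L
    exceed_snp <- integer(k)
    for (s in seq_len(nSim)) {
      r_star <- stats::rnorm(k, loo, rr$se)
      loo_star <- .loo_betas(r_star, rr$se)
      q_star <- w * (r_star - loo_star)^2
      if (sum(q_star) >= rss_obs) exceed_global <- exceed_global + 1L
      exceed_snp <- exceed_snp + (q_star >= q_obs)
    }
    global_p <- (exceed_global + 1) / (nSim + 1)
    p_snp <- pmin(1, k * (exceed_snp + 1) / (nSim + 1))
    names(p_snp) <- rr$snp_id
    outliers <- rr$snp_id[p_snp < sig]

    before <- .ivw_core(rr$ratio, rr$se)$beta
    after <- NA_real_
    distortion_p <- NA_real_
    if (length(outliers) && length(outliers) < k) {
      keep <- !(rr$snp_id %in% outliers)
      after <- .ivw_core(rr$ratio[keep], rr$se[keep])$beta
      d_obs <- after - before
      n_out <- sum(!keep)
      exceed_d <- 0L
      for (s in seq_len(nSim)) {
        drop_idx <- sample.int(k, n_out)
        d_star <- .ivw_core(rr$ratio[-drop_idx], rr$se[-drop_idx])$beta - before
        if (abs(d_star) >= abs(d_obs)) exceed_d <- exceed_d + 1L
      }
      distortion_p <- (exceed_d + 1) / (nSim + 1)
    }
    new("PressoReport", rssObs = rss_obs, globalPval = global_p,
        outlierPvals = p_snp, outliers = outliers,
        distortionPval = distortion_p, betaBefore = before,
        betaAfter = after, nSim = as.integer(nSim))
  })
}
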