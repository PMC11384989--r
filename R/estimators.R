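#' Per-SNP Wald ratio
#'
#' Ratio estimate \code{beta_out / beta_exp} with first-order delta-method
#' standard error \code{se_out / |beta_exp|} (ignoring the exposure SE, the
#' dominant convention). A second-order SE incorporating \code{se_exp} is
#' available via \code{secondOrder = TRUE}.
#'
#' @param betaExp,betaOut exposure and outcome effects (vectorized).
#' @param seOut outcome standard error.
#' @param seExp exposure standard error (needed for \code{secondOrder}).
#' @param secondOrder use the second-order delta approximation.
#' @return list with numeric vectors \code{ratio} and \code{se}.
#' @export
waldRatio <- function(betaExp, betaOut, seOut, seExp = NULL,
                      secondOrder = FALSE) {
  if (any(betaExp == 0)) stop("beta_exp must be nonzero for a Wald ratio")
  ratio <- betaOut / betaExp
  if (secondOrder) {
    if (is.null(seExp)) stop("seExp required for the second-order SE")
    se <- sqrt(seOut^2 / betaExp^2 + betaOut^2 * seExp^2 / betaExp^4)
  } else {
    se <- seOut / abs(betaExp)
  }
  list(ratio = ratio, se = se)
}

.ratios <- function(H, secondOrder = FALSE) {
  r <- H@rows
  if (!nrow(r)) stop("no instruments")
  wr <- waldRatio(r$beta_exp, r$beta_out, r$se_out, r$se_exp,
                  secondOrder = secondOrder)
  list(snp_id = r$snp_id, ratio = wr$ratio, se = wr$se)
}

# Fixed-effect IVW core on ratio vectors: beta, se, and Cochran's Q parts.
.ivw_core <- function(ratio, se) {
  w <- 1 / se^2
  beta <- sum(w * ratio) / sum(w)
  list(beta = beta, se = sqrt(1 / sum(w)), w = w,
       q_contrib = w * (ratio - beta)^2)
}

#' Inverse-variance weighted estimate
#'
#' Pools per-SNP Wald ratios with weights \code{1/se_j^2}; algebraically the
#' weighted least-squares slope of \code{beta_out} on \code{beta_exp}
#' through the origin with weights \code{1/se_out^2}. The default
#' \code{"random_multiplicative"} model inflates the fixed-effect SE by
#' \code{max(1, sqrt(Q/(k-1)))} (never deflates it); \code{"fixed"} reports
#' the fixed-effect SE. With a single SNP the estimate is that SNP's Wald
#' ratio.
#'
#' @param H a \code{\link{HarmonizedSet}} with at least one SNP.
#' @param model \code{"random_multiplicative"} (default) or \code{"fixed"}.
#' @return an \code{\link{MrResult}}; \code{extra$scale} holds the applied
#'   SE inflation factor.
#' @export
mrIvw <- function(H, model = c("random_multiplicative", "fixed")) {
  model <- match.arg(model)
  rr <- .ratios(H)
  k <- length(rr$ratio)
  core <- .ivw_core(rr$ratio, rr$se)
  scale <- 1
  if (model == "random_multiplicative" && k >= 2) {
    Q <- sum(core$q_contrib)
    scale <- max(1, sqrt(Q / (k - 1)))
  }
  new_mr_result("IVW", k, core$beta, core$se * scale,
                extra = list(model = model, scale = scale))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with a free
#' intercept (weights \code{1/se_out^2}). The slope estimates the causal
#' effect under the InSIDE assumption; the intercept and its test quantify
#' directional pleiotropy. Rows are first oriented so every exposure beta is
#' non-negative (flipping both betas of a row leaves the slope invariant and
#' makes the intercept interpretable). SEs use the multiplicative
#' random-effects convention: the regression SE is never deflated below the
#' weighted-least-squares value (residual scale floored at 1).
#'
#' @param H a \code{\link{HarmonizedSet}} with at least three SNPs.
#' @return an \code{\link{MrResult}} for the slope; \code{extra} carries
#'   \code{intercept}, \code{intercept_se}, \code{intercept_pval}, and a
#'   \code{flag} of \code{"degenerate_fit"} when the regression fits
#'   perfectly (zero residual variance, p-values reported NA).
#' @export
mrEgger <- function(H) {
  rows <- H@rows
  k <- nrow(rows)
  if (k < 3) stop("insufficient instruments for Egger (k >= 3 required)")
  flip <- rows$beta_exp < 0
  bx <- ifelse(flip, -rows$beta_exp, rows$beta_exp)
  by <- ifelse(flip, -rows$beta_out, rows$beta_out)
  w <- 1 / rows$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  # exact-line inputs trigger lm's perfect-fit warning; degenerate fits are
  # detected and flagged explicitly below
  sm <- suppressWarnings(summary(fit))
  sigma <- sm$sigma
  coefs <- sm$coefficients
  # unscale lm's SEs (proportional to sigma), then apply max(1, sigma):
  # multiplicative random effects, floored at the fixed-effect value
  se_raw <- coefs[, "Std. Error"]
  degenerate <- !is.finite(sigma) || sigma < 1e-10
  if (degenerate) {
    se_adj <- c(0, 0)
  } else {
    se_adj <- se_raw / sigma * max(1, sigma)
  }
  slope <- unname(coefs["bx", "Estimate"])
  icpt <- unname(coefs["(Intercept)", "Estimate"])
  extra <- list(
    intercept = icpt,
    intercept_se = unname(se_adj[1]),
    intercept_pval = if (degenerate) NA_real_ else
      normal_pval(icpt, unname(se_adj[1])),
    residual_scale = if (degenerate) 0 else max(1, sigma)
  )
  if (degenerate) extra$flag <- "degenerate_fit"
  new_mr_result("Egger", k, slope, unname(se_adj[2]), extra = extra)
}

# Weighted median of values x with weights w, centred cumulative-weight
# convention: p_j = (S_j - w_j/2) / S_k on the sorted values, linear
# interpolation at p = 0.5.
.weighted_median <- function(x, w) {
  # merge tied ratios (summing their weight) so the estimate depends only on
  # the weight attached to each distinct ratio value
  ux <- sort(unique(x))
  if (length(ux) < length(x)) {
    w <- vapply(ux, function(v) sum(w[x == v]), numeric(1))
    x <- ux
  } else {
    o <- order(x)
    x <- x[o]; w <- w[o]
  }
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(x[1])
  if (p[length(p)] <= 0.5) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' The Wald ratio at the point where the cumulative normalized
#' inverse-variance weight crosses one half (centred convention, linear
#' interpolation between bracketing ratios). Consistent when at least half
#' the total weight comes from valid instruments. The SE comes from a seeded
#' parametric bootstrap: each ratio is resampled from
#' \code{Normal(r_j, se_j)}, the weighted median recomputed, and the SD of
#' the replicates reported.
#'
#' @param H a \code{\link{HarmonizedSet}} with at least three SNPs.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return an \code{\link{MrResult}}.
#' @export
mrWeightedMedian <- function(H, nBoot = 1000, seed) {
  rr <- .ratios(H)
  k <- length(rr$ratio)
  if (k < 3) stop("insufficient instruments (k >= 3 required)")
  w <- 1 / rr$se^2
  beta <- .weighted_median(rr$ratio, w)
  se <- .boot_se(rr$ratio, rr$se, nBoot, seed,
                 function(r) .weighted_median(r, w))
  new_mr_result("WeightedMedian", k, beta, se,
                extra = list(n_boot = nBoot, seed = seed))
}

# SD over parametric-bootstrap replicates of statistic(r*).
.boot_se <- function(ratio, se, nBoot, seed, statistic) {
  with_seed(seed, {
    reps <- vapply(seq_len(nBoot), function(i) {
      statistic(stats::rnorm(length(ratio), ratio, se))
    }, numeric(1))
    stats::sd(reps)
  })
}

# Mode of a (weighted) Gaussian KDE over the ratios; bandwidth by the
# modified Silverman rule h = phi * 0.9 * min(sd, mad) * k^(-1/5).
.kde_mode <- function(x, w, phi) {
  if (length(unique(x)) == 1) return(x[1])
  s <- min(stats::sd(x), stats::mad(x))
  if (s == 0) s <- stats::sd(x)
  h <- phi * 0.9 * s * length(x)^(-1 / 5)
  d <- stats::density(x, weights = w / sum(w), bw = h, n = 1024,
                      from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

#' Mode-based estimates (simple and weighted)
#'
#' The mode of the Gaussian kernel density of the Wald ratios: unweighted
#' ("simple mode") or inverse-variance weighted ("weighted mode").
#' Bandwidth is \code{phi} times the modified Silverman rule
#' \code{0.9 * min(sd, mad) * k^(-1/5)} on the ratios. Consistent when the
#' largest group of instruments sharing a causal estimate is valid
#' (plurality validity). SE by seeded parametric bootstrap as in
#' \code{\link{mrWeightedMedian}}.
#'
#' @param H a \code{\link{HarmonizedSet}} with at least three SNPs.
#' @param weighted use inverse-variance weights (weighted mode) instead of
#'   equal weights (simple mode).
#' @param phi bandwidth multiplier (default 1).
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an \code{\link{MrResult}}.
#' @export
mrMode <- function(H, weighted = FALSE, phi = 1, nBoot = 1000, seed) {
  rr <- .ratios(H)
  k <- length(rr$ratio)
  if (k < 3) stop("insufficient instruments (k >= 3 required)")
  w <- if (weighted) 1 / rr$se^2 else rep(1, k)
  beta <- .kde_mode(rr$ratio, w, phi)
  se <- .boot_se(rr$ratio, rr$se, nBoot, seed,
                 function(r) .kde_mode(r, w, phi))
  new_mr_result(if (weighted) "WeightedMode" else "SimpleMode", k, beta, se,
                extra = list(phi = phi, n_boot = nBoot, seed = seed))
}

#' Convert a log-odds estimate to an odds ratio with 95\% CI
#'
#' \code{exp(beta)} with Wald limits \code{exp(beta -/+ 1.96 * se)}.
#'
#' @param beta log-odds estimate.
#' @param se standard error (>= 0).
#' @return named numeric vector \code{or}, \code{or_lo95}, \code{or_hi95}.
#' @export
betaToOr <- function(beta, se = 0) {
  stopifnot(all(se >= 0))
  c(or = exp(beta), or_lo95 = exp(beta - 1.96 * se),
    or_hi95 = exp(beta + 1.96 * se))
}

#' Run the five-estimator battery
#'
#' IVW (primary), MR-Egger, weighted median, simple mode and weighted mode
#' on one harmonized set. Estimators whose instrument-count preconditions
#' fail are reported as NA rows rather than errors.
#'
#' @param H a \code{\link{HarmonizedSet}}.
#' @param ivwModel IVW model (see \code{\link{mrIvw}}).
#' @param nBoot,seed bootstrap settings for the median and mode estimators.
#' @return named list of \code{\link{MrResult}} (entries NULL where a
#'   precondition failed).
#' @export
mrAllMethods <- function(H, ivwModel = "random_multiplicative", nBoot = 1000,
                         seed = 1) {
  res <- list(
    IVW = tryCatch(mrIvw(H, model = ivwModel), error = function(e) NULL),
    Egger = tryCatch(mrEgger(H), error = function(e) NULL),
    WeightedMedian = tryCatch(mrWeightedMedian(H, nBoot = nBoot, seed = seed),
                              error = function(e) NULL),
    SimpleMode = tryCatch(mrMode(H, weighted = FALSE, nBoot = nBoot,
                                 seed = seed + 1L), error = function(e) NULL),
    WeightedMode = tryCatch(mrMode(H, weighted = TRUE, nBoot = nBoot,
                                   seed = seed + 2L), error = function(e) NULL)
  )
  res
}
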