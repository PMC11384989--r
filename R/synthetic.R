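#' Configure a synthetic GWAS simulation
#'
#' Builds an \code{\link{MrSimConfig}} describing a three-study (exposure,
#' mediator, outcome) summary-statistics simulation with known ground truth.
#' True instruments receive exposure effects \code{gamma_j ~ N(0, gammaSd)};
#' observed betas add sampling noise with the standard per-SNP standard error
#' \code{1 / sqrt(2 * maf * (1 - maf) * n)}. Mediator betas are
#' \code{beta1 * gamma_j}, outcome betas are
#' \code{(theta + beta1 * beta2) * gamma_j + alpha_j}, where \code{alpha_j}
#' are direct (pleiotropic) effects drawn according to
#' \code{pleiotropyMode}. \code{nOutliers} instruments additionally receive a
#' gross direct effect \code{outlierEffect * sign(gamma_j)} (a fixed-direction
#' shift on the Wald-ratio scale). SNPs sit on one chromosome in LD blocks of
#' \code{ldBlockSize} with within-block correlation \code{ldR} and zero
#' correlation between blocks; sampling noise is correlated accordingly.
#'
#' @param nInstruments number of true exposure instruments (default 50).
#' @param nMediatorInstruments number of mediator-specific instruments
#'   (default 0): SNPs with effects \code{delta_j ~ N(0, gammaSd)} on the
#'   mediator, zero effect on the exposure, and \code{beta2 * delta_j} on
#'   the outcome. Needed for estimating the mediator-to-outcome leg of a
#'   two-step mediation analysis.
#' @param nNullSnps number of SNPs with zero true effects (default 450).
#' @param nExposure,nOutcome,nMediator per-study sample sizes (default 50000).
#' @param theta direct causal effect of exposure on outcome (log-odds scale).
#' @param beta1,beta2 mediation path effects (exposure to mediator, mediator
#'   to outcome).
#' @param gammaSd SD of true instrument effects (default 0.1, strong
#'   pQTL-scale instruments).
#' @param pleiotropyMode \code{"none"}, \code{"balanced"} or
#'   \code{"directional"}.
#' @param pleiotropySd,pleiotropyMean SD and (directional-mode) mean of the
#'   per-instrument direct effects.
#' @param nOutliers number of gross-pleiotropy SNPs planted among the
#'   instruments (the first \code{nOutliers} of them).
#' @param outlierEffect magnitude of the planted gross direct effect
#'   (default 0.1).
#' @param eafRange range of the uniform effect-allele-frequency draw.
#' @param ldBlockSize,ldR LD block size and within-block correlation.
#' @param seed integer RNG seed; identical configs give byte-identical
#'   studies.
#' @return an \code{\link{MrSimConfig}}.
#' @export
mrSimConfig <- function(nInstruments = 50, nMediatorInstruments = 0,
                        nNullSnps = 450,
                        nExposure = 50000, nOutcome = 50000,
                        nMediator = 50000, theta = 0, beta1 = 0, beta2 = 0,
                        gammaSd = 0.1, pleiotropyMode = "none",
                        pleiotropySd = 0, pleiotropyMean = 0, nOutliers = 0,
                        outlierEffect = 0.1, eafRange = c(0.05, 0.95),
                        ldBlockSize = 1, ldR = 0, seed = 1) {
  new("MrSimConfig", nInstruments = as.integer(nInstruments),
      nMediatorInstruments = as.integer(nMediatorInstruments),
      nNullSnps = as.integer(nNullSnps), nExposure = as.integer(nExposure),
      nOutcome = as.integer(nOutcome), nMediator = as.integer(nMediator),
      theta = theta, beta1 = beta1, beta2 = beta2, gammaSd = gammaSd,
      pleiotropyMode = pleiotropyMode, pleiotropySd = pleiotropySd,
      pleiotropyMean = pleiotropyMean, nOutliers = as.integer(nOutliers),
      outlierEffect = outlierEffect, eafRange = as.numeric(eafRange),
      ldBlockSize = as.integer(ldBlockSize), ldR = ldR,
      seed = as.integer(seed))
}

# Cholesky factor of an s x s equicorrelation matrix (unit diagonal, off r).
.equicorr_chol <- function(s, r) {
  if (s == 1) return(matrix(1, 1, 1))
  chol(matrix(r, s, s) + diag(1 - r, s))
}

# Draw m standard normals with block-equicorrelation structure.
.block_noise <- function(block, r) {
  m <- length(block)
  z <- stats::rnorm(m)
  if (r == 0) return(z)
  out <- numeric(m)
  for (b in unique(block)) {
    idx <- which(block == b)
    L <- .equicorr_chol(length(idx), r)
    out[idx] <- drop(crossprod(L, z[idx]))
  }
  out
}

#' Simulate exposure, outcome and mediator summary studies
#'
#' Generates three \code{\link{SummaryStudy}} objects sharing one SNP panel,
#' plus the \code{\link{SyntheticTruth}} needed to validate downstream
#' estimates. See \code{\link{mrSimConfig}} for the generative model.
#' LD blocks are laid out 25 Mb apart (so different blocks always fall
#' outside a 10,000 kb clumping window) with 5 kb spacing inside a block.
#'
#' @param config an \code{\link{MrSimConfig}}.
#' @return list with elements \code{exposure}, \code{outcome},
#'   \code{mediator} (SummaryStudy) and \code{truth} (SyntheticTruth).
#' @export
simulateMrStudy <- function(config) {
  stopifnot(is(config, "MrSimConfig"))
  validObject(config)
  c_ <- config
  m <- c_@nInstruments + c_@nMediatorInstruments + c_@nNullSnps
  if (m == 0) stop("no SNPs to simulate")
  with_seed(c_@seed, {
    snp_id <- sprintf("rs%05d", seq_len(m))
    block <- as.integer(ceiling(seq_len(m) / c_@ldBlockSize))
    within <- seq_len(m) - (block - 1L) * c_@ldBlockSize
    pos <- (block - 1) * 25e6 + (within - 1) * 5e3 + 1
    chrom <- rep("1", m)
    eaf <- stats::runif(m, c_@eafRange[1], c_@eafRange[2])

    gamma <- numeric(m)
    is_instr <- seq_len(m) <= c_@nInstruments
    gamma[is_instr] <- stats::rnorm(c_@nInstruments, 0, c_@gammaSd)
    delta <- numeric(m)
    is_med <- seq_len(m) > c_@nInstruments &
      seq_len(m) <= c_@nInstruments + c_@nMediatorInstruments
    if (c_@nMediatorInstruments > 0)
      delta[is_med] <- stats::rnorm(c_@nMediatorInstruments, 0, c_@gammaSd)

    alpha <- numeric(m)
    if (c_@pleiotropyMode == "balanced") {
      alpha[is_instr] <- stats::rnorm(c_@nInstruments, 0, c_@pleiotropySd)
    } else if (c_@pleiotropyMode == "directional") {
      # directional pleiotropy acts in the direction of the
      # exposure-increasing allele (sign(gamma)), so that orienting
      # instruments to positive exposure effects preserves its mean --
      # the regime the Egger intercept is designed to detect
      alpha[is_instr] <- ifelse(gamma[is_instr] >= 0, 1, -1) *
        stats::rnorm(c_@nInstruments, c_@pleiotropyMean, c_@pleiotropySd)
    }
    outlier_ids <- character(0)
    if (c_@nOutliers > 0) {
      out_idx <- seq_len(c_@nOutliers)
      alpha[out_idx] <- alpha[out_idx] +
        c_@outlierEffect * ifelse(gamma[out_idx] >= 0, 1, -1)
      outlier_ids <- snp_id[out_idx]
    }

    se_for <- function(n) 1 / sqrt(2 * eaf * (1 - eaf) * n)
    se_e <- se_for(c_@nExposure)
    se_m <- se_for(c_@nMediator)
    se_o <- se_for(c_@nOutcome)

    total <- c_@theta + c_@beta1 * c_@beta2
    beta_e <- gamma + se_e * .block_noise(block, c_@ldR)
    beta_m <- c_@beta1 * gamma + delta + se_m * .block_noise(block, c_@ldR)
    beta_o <- total * gamma + c_@beta2 * delta + alpha +
      se_o * .block_noise(block, c_@ldR)

    # alleles: fixed non-palindromic pair; harmonization is tested elsewhere
    ea <- rep("A", m); oa <- rep("G", m)

    mk <- function(beta, se, n, id, trait, type) {
      makeSummaryStudy(
        data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                   effect_allele = ea, other_allele = oa, eaf = eaf,
                   beta = beta, se = se, n = rep(n, m),
                   stringsAsFactors = FALSE),
        studyId = id, traitName = trait, traitType = type)
    }
    truth <- new("SyntheticTruth", config = c_,
                 gamma = stats::setNames(gamma, snp_id),
                 delta = stats::setNames(delta, snp_id),
                 alphaDirect = stats::setNames(alpha, snp_id),
                 outlierIds = outlier_ids, block = block, chrom = chrom,
                 pos = pos, impliedTotal = total)
    list(
      exposure = mk(beta_e, se_e, c_@nExposure, "sim_exposure",
                    "simulated exposure", "quantitative"),
      outcome = mk(beta_o, se_o, c_@nOutcome, "sim_outcome",
                   "simulated outcome", "binary"),
      mediator = mk(beta_m, se_m, c_@nMediator, "sim_mediator",
                    "simulated mediator", "quantitative"),
      truth = truth
    )
  })
}

#' True-instrument snp_ids of a simulation
#' @param truth a \code{\link{SyntheticTruth}}.
#' @export
trueInstruments <- function(truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  names(truth@gamma)[seq_len(truth@config@nInstruments)]
}

#' Mediator-specific instrument snp_ids of a simulation
#' @param truth a \code{\link{SyntheticTruth}}.
#' @export
trueMediatorInstruments <- function(truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  names(truth@gamma)[truth@config@nInstruments +
                       seq_len(truth@config@nMediatorInstruments)]
}

#' Block-diagonal LD correlation matrix of a simulation
#'
#' Symmetric with unit diagonal; within a block every off-diagonal entry is
#' the configured \code{ldR}, between blocks zero. For |ldR| < 1 each block
#' is positive definite (equicorrelation eigenvalues
#' \code{1 + (s-1) ldR} and \code{1 - ldR}).
#'
#' @param truth a \code{\link{SyntheticTruth}}.
#' @return square matrix with snp_id dimnames.
#' @export
ldMatrix <- function(truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  ids <- names(truth@gamma)
  m <- length(ids)
  R <- diag(1, m)
  r <- truth@config@ldR
  if (r != 0) {
    for (b in unique(truth@block)) {
      idx <- which(truth@block == b)
      R[idx, idx] <- r
    }
    # restore the diagonal clobbered by the block fill
    diag(R) <- 1
  }
  dimnames(R) <- list(ids, ids)
  R
}

#' Simulate a multi-exposure screening panel
#'
#' Builds \code{nExposures} independent exposure studies (disjoint SNP
#' panels, ids prefixed \code{e<k>_}) against one shared outcome study whose
#' rows concatenate all panels, plus the combined block-diagonal LD matrix.
#' Exposure \code{k} has planted causal effect \code{thetas[k]} on the
#' outcome.
#'
#' @param nExposures number of exposures.
#' @param thetas numeric vector (recycled) of per-exposure causal effects.
#' @param config base \code{\link{mrSimConfig}}; per-exposure seeds are
#'   derived from \code{config@seed}.
#' @return list: \code{exposures} (named list of SummaryStudy),
#'   \code{outcome} (SummaryStudy), \code{ld} (matrix), \code{truths}
#'   (list of SyntheticTruth).
#' @export
simulateScreenPanel <- function(nExposures, thetas = 0,
                                config = mrSimConfig()) {
  stopifnot(nExposures >= 1)
  thetas <- rep_len(thetas, nExposures)
  exposures <- vector("list", nExposures)
  truths <- vector("list", nExposures)
  out_rows <- vector("list", nExposures)
  ld_blocks <- vector("list", nExposures)
  for (k in seq_len(nExposures)) {
    ck <- config
    ck@theta <- thetas[k]
    ck@seed <- as.integer((config@seed * 1000L + k) %% .Machine$integer.max)
    sim <- simulateMrStudy(ck)
    prefix <- sprintf("e%02d_", k)
    relab <- function(study) {
      study@snps$snp_id <- paste0(prefix, study@snps$snp_id)
      study
    }
    ex <- relab(sim$exposure)
    ex@studyId <- sprintf("exposure_%02d", k)
    ex@traitName <- ex@studyId
    exposures[[k]] <- ex
    ot <- relab(sim$outcome)
    out_rows[[k]] <- ot@snps
    tr <- sim$truth
    names(tr@gamma) <- paste0(prefix, names(tr@gamma))
    names(tr@delta) <- paste0(prefix, names(tr@delta))
    names(tr@alphaDirect) <- paste0(prefix, names(tr@alphaDirect))
    if (length(tr@outlierIds)) tr@outlierIds <- paste0(prefix, tr@outlierIds)
    truths[[k]] <- tr
    ld_blocks[[k]] <- ldMatrix(tr)
  }
  names(exposures) <- vapply(exposures, studyId, "")
  names(truths) <- names(exposures)
  outcome_df <- do.call(rbind, out_rows)
  rownames(outcome_df) <- NULL
  outcome <- new("SummaryStudy", studyId = "sim_outcome",
                 traitName = "shared simulated outcome", traitType = "binary",
                 snps = outcome_df, skipped = empty_skipped())
  ids <- unlist(lapply(ld_blocks, rownames), use.names = FALSE)
  L <- diag(1, length(ids))
  dimnames(L) <- list(ids, ids)
  off <- 0L
  for (B in ld_blocks) {
    s <- nrow(B)
    L[off + seq_len(s), off + seq_len(s)] <- B
    off <- off + s
  }
  list(exposures = exposures, outcome = outcome, ld = L, truths = truths)
}

#' Write a simulated study set to disk
#'
#' Writes the three studies as GWAS-SSF TSVs, the LD matrix as a TSV and the
#' ground truth as JSON into \code{dir}.
#'
#' @param sim result of \code{\link{simulateMrStudy}}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeSummaryStudy(sim$exposure, file.path(dir, "exposure.tsv"))
  writeSummaryStudy(sim$outcome, file.path(dir, "outcome.tsv"))
  writeSummaryStudy(sim$mediator, file.path(dir, "mediator.tsv"))
  L <- ldMatrix(sim$truth)
  utils::write.table(data.frame(snp_id = rownames(L), L,
                                check.names = FALSE),
                     file.path(dir, "ld_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  truth_list <- list(
    theta = tr@config@theta, beta1 = tr@config@beta1,
    beta2 = tr@config@beta2, implied_total = tr@impliedTotal,
    gamma = as.list(tr@gamma), alpha_direct = as.list(tr@alphaDirect),
    outlier_ids = tr@outlierIds, seed = tr@config@seed)
  jsonlite::write_json(truth_list, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
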