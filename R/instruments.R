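#' Select SNPs by association p-value
#'
#' Returns snp_ids whose p-value is strictly below \code{threshold}, ordered
#' by ascending p-value with ties broken lexicographically by snp_id. The
#' conventional genome-wide cutoff is 5e-8; screens of molecular traits
#' commonly relax it to 1e-5 when too few SNPs reach genome-wide
#' significance.
#'
#' @param study a \code{\link{SummaryStudy}}.
#' @param threshold p-value cutoff in (0, 1); the comparison is strict.
#' @return character vector of snp_ids (possibly empty).
#' @export
selectByPvalue <- function(study, threshold = 1e-5) {
  stopifnot(is(study, "SummaryStudy"), threshold > 0, threshold < 1)
  df <- study@snps
  hit <- !is.na(df$pval) & df$pval < threshold
  df <- df[hit, ]
  df$snp_id[order(df$pval, df$snp_id)]
}

#' Greedy LD clumping
#'
#' Standard greedy clumping: repeatedly take the remaining candidate with the
#' smallest p-value as an index SNP and remove every remaining candidate on
#' the same chromosome within \code{windowKb} of it whose squared correlation
#' with it is at or above \code{r2Max}. Retained SNPs are the index SNPs in
#' selection order. The window is two-sided (plus/minus \code{windowKb} from
#' the index position); SNPs on different chromosomes are never pruned
#' against each other. Ties on p-value break lexicographically by snp_id, so
#' the output depends only on the statistics, never on input order.
#'
#' @param candidates snp_ids to clump; all must be in \code{study} and
#'   \code{ld}.
#' @param study a \code{\link{SummaryStudy}} supplying p-values and
#'   positions.
#' @param ld square correlation (not r-squared) matrix with snp_id dimnames.
#' @param windowKb physical window in kb (default 10000).
#' @param r2Max squared-correlation removal threshold (default 0.001; the
#'   comparison uses \code{>=} so this prunes essentially all correlated
#'   pairs).
#' @return character vector of retained snp_ids in selection order.
#' @export
ldClump <- function(candidates, study, ld, windowKb = 10000, r2Max = 0.001) {
  stopifnot(is(study, "SummaryStudy"))
  if (!length(candidates)) return(character(0))
  df <- study@snps
  missing_study <- setdiff(candidates, df$snp_id)
  if (length(missing_study))
    stop("candidates absent from study: ",
         paste(missing_study, collapse = ", "))
  missing_ld <- setdiff(candidates, rownames(ld))
  if (length(missing_ld))
    stop("candidates absent from LD matrix: ",
         paste(missing_ld, collapse = ", "))
  idx <- match(candidates, df$snp_id)
  tab <- data.frame(snp_id = candidates, pval = df$pval[idx],
                    chrom = df$chrom[idx], pos = df$pos[idx],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$pval, tab$snp_id), ]
  kept <- character(0)
  remaining <- tab
  win_bp <- windowKb * 1000
  while (nrow(remaining)) {
    index <- remaining[1, ]
    kept <- c(kept, index$snp_id)
    remaining <- remaining[-1, , drop = FALSE]
    if (!nrow(remaining)) break
    same_chr <- !is.na(remaining$chrom) & !is.na(index$chrom) &
      remaining$chrom == index$chrom
    near <- same_chr & abs(remaining$pos - index$pos) <= win_bp
    r2 <- ld[index$snp_id, remaining$snp_id]^2
    remaining <- remaining[!(near & r2 >= r2Max), , drop = FALSE]
  }
  kept
}

#' Variance in the exposure explained by one SNP
#'
#' \code{R^2 = 2 * (1 - MAF) * MAF * beta^2} with the minor-allele frequency
#' folded as \code{min(eaf, 1 - eaf)}; \code{beta} is assumed to be on the
#' standardized trait scale.
#'
#' @param eaf effect-allele frequency in [0, 1] (vectorized).
#' @param beta per-allele effect size (vectorized).
#' @return proportion of variance explained.
#' @export
r2FromMaf <- function(eaf, beta) {
  stopifnot(all(is.na(eaf) | (eaf >= 0 & eaf <= 1)))
  maf <- minor_af(eaf)
  2 * (1 - maf) * maf * beta^2
}

#' Instrument-strength F-statistic
#'
#' \code{F = R^2 * (N - 2) / (1 - R^2)}; F below 10 conventionally flags a
#' weak instrument.
#'
#' @param r2 variance explained, in [0, 1).
#' @param n exposure-study sample size, > 2.
#' @return F value (vectorized).
#' @export
fStatistic <- function(r2, n) {
  if (any(!is.na(r2) & (r2 < 0 | r2 >= 1)))
    stop("r2 must lie in [0, 1)")
  stopifnot(all(is.na(n) | n > 2))
  r2 * (n - 2) / (1 - r2)
}

#' Exclude weak instruments by F-statistic
#'
#' Computes each SNP's explained variance from its allele frequency and beta
#' (\code{\link{r2FromMaf}}) and its F-statistic (\code{\link{fStatistic}},
#' using the per-SNP sample size when present, else \code{nFallback}), and
#' retains SNPs with \code{F >= fMin}. SNPs with missing allele frequency or
#' sample size are excluded with an audit detail and a warning.
#'
#' @param snpIds candidate snp_ids.
#' @param study a \code{\link{SummaryStudy}}.
#' @param fMin minimum F (default 10; exclusion of \code{F < fMin} is
#'   strict, so F exactly 10 is retained).
#' @param nFallback study-level sample size used when a SNP's \code{n} is
#'   missing.
#' @param exclusions prior audit rows to prepend (used by
#'   \code{\link{selectInstruments}}).
#' @return an \code{\link{InstrumentSet}}.
#' @export
filterWeak <- function(snpIds, study, fMin = 10, nFallback = NA_real_,
                       exclusions = empty_exclusions()) {
  stopifnot(is(study, "SummaryStudy"))
  df <- study@snps
  idx <- match(snpIds, df$snp_id)
  stopifnot(!anyNA(idx))
  eaf <- df$eaf[idx]
  n <- df$n[idx]
  n[is.na(n)] <- nFallback
  r2 <- r2FromMaf(eaf, df$beta[idx])
  f <- rep(NA_real_, length(snpIds))
  ok_in <- !is.na(eaf) & !is.na(n)
  f[ok_in] <- fStatistic(r2[ok_in], n[ok_in])

  detail <- rep(NA_character_, length(snpIds))
  detail[is.na(eaf)] <- "no_eaf"
  detail[!is.na(eaf) & is.na(n)] <- "no_n"
  weak <- is.na(detail) & f < fMin
  detail[weak] <- sprintf("F=%.4g", f[weak])
  keep <- is.na(detail)
  if (any(is.na(eaf)))
    warning("excluding ", sum(is.na(eaf)), " SNP(s) with missing eaf")

  tab <- data.frame(snp_id = snpIds[keep], pval = df$pval[idx][keep],
                    r2_explained = r2[keep], f_stat = f[keep],
                    stringsAsFactors = FALSE)
  excl <- rbind(exclusions,
                data.frame(snp_id = snpIds[!keep],
                           stage = rep("weak", sum(!keep)),
                           detail = detail[!keep], stringsAsFactors = FALSE))
  rownames(tab) <- rownames(excl) <- NULL
  new("InstrumentSet", exposureId = study@studyId, table = tab,
      exclusions = excl)
}

#' Full instrument-selection pipeline
#'
#' p-value screen (\code{\link{selectByPvalue}}), greedy LD clumping
#' (\code{\link{ldClump}}), then weak-instrument exclusion
#' (\code{\link{filterWeak}}), with a complete exclusion audit: every SNP of
#' the study that entered consideration is either retained or recorded with
#' the stage at which it left.
#'
#' @param study exposure \code{\link{SummaryStudy}}.
#' @param ld correlation matrix covering the study's SNPs.
#' @param pvalThreshold instrument p-value cutoff (default 1e-5, strict).
#' @param windowKb,r2Max clumping parameters (defaults 10000 kb, 0.001).
#' @param fMin weak-instrument cutoff (default 10).
#' @param nFallback sample size used when a SNP lacks one.
#' @return an \code{\link{InstrumentSet}}.
#' @export
selectInstruments <- function(study, ld, pvalThreshold = 1e-5,
                              windowKb = 10000, r2Max = 0.001, fMin = 10,
                              nFallback = NA_real_) {
  df <- study@snps
  byp <- selectByPvalue(study, pvalThreshold)
  out_p <- setdiff(df$snp_id, byp)
  excl_p <- data.frame(snp_id = out_p, stage = rep("pval", length(out_p)),
                       detail = rep(sprintf("pval >= %.3g", pvalThreshold),
                                    length(out_p)),
                       stringsAsFactors = FALSE)
  clumped <- ldClump(byp, study, ld, windowKb = windowKb, r2Max = r2Max)
  out_c <- setdiff(byp, clumped)
  excl_c <- data.frame(snp_id = out_c, stage = rep("clump", length(out_c)),
                       detail = rep("pruned against a stronger index SNP",
                                    length(out_c)),
                       stringsAsFactors = FALSE)
  filterWeak(clumped, study, fMin = fMin, nFallback = nFallback,
             exclusions = rbind(excl_p, excl_c))
}
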