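#' Default column mapping (GWAS-SSF names)
#'
#' Maps the package's standard field names onto the column names used by the
#' GWAS-SSF summary-statistics format. Any entry can be overridden through
#' the \code{columnMap} argument of \code{\link{readSummaryStudy}}.
#'
#' @return named character vector: standard field -> file column.
#' @export
defaultColumnMap <- function() {
  c(snp_id = "rsid",
    chrom = "chromosome",
    pos = "base_pair_location",
    effect_allele = "effect_allele",
    other_allele = "other_allele",
    eaf = "effect_allele_frequency",
    beta = "beta",
    se = "standard_error",
    pval = "p_value",
    n = "n")
}

# Fields that must be present in the file; the rest may be absent (NA-filled,
# or derived in the case of pval).
.mandatory_fields <- c("snp_id", "effect_allele", "other_allele", "beta", "se")

.detect_sep <- function(header_line) {
  if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited table (auto-detected from the header line)
#' of per-SNP association statistics into a \code{\link{SummaryStudy}}.
#' Alleles are upper-cased. Rows with a missing or non-numeric beta or
#' standard error are skipped and recorded in the study's skipped-rows table.
#' When the file has no p-value column (and \code{columnMap} does not name
#' one), p-values are derived from the two-sided normal test
#' \code{2 * (1 - pnorm(|beta/se|))} and flagged in the \code{pval_derived}
#' column.
#'
#' @param path file path.
#' @param studyId,traitName,traitType study metadata; \code{traitType} is
#'   \code{"quantitative"} (default) or \code{"binary"}.
#' @param columnMap named character vector overriding
#'   \code{\link{defaultColumnMap}} entries.
#' @return a \code{\link{SummaryStudy}}.
#' @export
readSummaryStudy <- function(path, studyId = basename(path),
                             traitName = studyId,
                             traitType = c("quantitative", "binary"),
                             columnMap = character()) {
  traitType <- match.arg(traitType)
  cmap <- defaultColumnMap()
  if (length(columnMap)) cmap[names(columnMap)] <- columnMap
  header <- readLines(path, n = 1L)
  sep <- .detect_sep(header)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  for (f in .mandatory_fields) {
    if (!cmap[[f]] %in% names(raw))
      stop("missing mandatory column '", cmap[[f]], "' (field ", f, ")")
  }
  get_col <- function(field) {
    col <- cmap[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  blank <- function(x) is.na(x) | !nzchar(trimws(x))

  snp_id <- get_col("snp_id")
  beta_raw <- get_col("beta")
  se_raw <- get_col("se")
  beta <- num(beta_raw)
  se <- num(se_raw)

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(se) & !blank(se_raw)] <- "non_numeric_se"
  reason[is.na(beta) & !blank(beta_raw)] <- "non_numeric_beta"
  reason[blank(se_raw)] <- "missing se"
  reason[blank(beta_raw)] <- "missing beta"
  keep <- is.na(reason)

  skipped <- data.frame(snp_id = snp_id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)

  pval_col_present <- cmap[["pval"]] %in% names(raw)
  pval <- if (pval_col_present) num(get_col("pval")) else rep(NA_real_, nrow(raw))
  derived <- !pval_col_present | is.na(pval)
  pval[derived] <- normal_pval(beta[derived], se[derived])

  df <- data.frame(
    snp_id = snp_id,
    chrom = as.character(get_col("chrom")),
    pos = num(get_col("pos")),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    eaf = num(get_col("eaf")),
    beta = beta,
    se = se,
    pval = pval,
    n = num(get_col("n")),
    pval_derived = derived,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(df) <- NULL

  new("SummaryStudy", studyId = studyId, traitName = traitName,
      traitType = traitType, snps = df, skipped = skipped)
}

#' Write a GWAS summary-statistics table
#'
#' Writes the study in GWAS-SSF column order as a TSV, plus a sidecar
#' skipped-rows report (\code{<path>.skipped.tsv}) listing rows that were
#' dropped when the study was read. Numeric fields round-trip at full
#' precision.
#'
#' @param study a \code{\link{SummaryStudy}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSummaryStudy <- function(study, path) {
  stopifnot(is(study, "SummaryStudy"))
  cmap <- defaultColumnMap()
  df <- study@snps
  out <- df[, setdiff(.snp_columns, "pval_derived")]
  names(out) <- unname(cmap[names(out)])
  # full-precision numeric serialization
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- format(out[[j]], digits = 17)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study@skipped, paste0(path, ".skipped.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a SummaryStudy from a data.frame
#'
#' Constructor used by the synthetic-data generator and by tests; expects the
#' package's standard column names (see \code{\link{SummaryStudy}}).
#'
#' @param df data.frame with (a subset of) the standard columns; missing
#'   optional columns are NA-filled.
#' @param studyId,traitName,traitType study metadata.
#' @return a \code{\link{SummaryStudy}}.
#' @export
makeSummaryStudy <- function(df, studyId, traitName = studyId,
                             traitType = c("quantitative", "binary")) {
  traitType <- match.arg(traitType)
  full <- data.frame(snp_id = df$snp_id, stringsAsFactors = FALSE)
  full$chrom <- if ("chrom" %in% names(df)) as.character(df$chrom) else NA_character_
  full$pos <- if ("pos" %in% names(df)) df$pos else NA_real_
  full$effect_allele <- if ("effect_allele" %in% names(df))
    toupper(df$effect_allele) else NA_character_
  full$other_allele <- if ("other_allele" %in% names(df))
    toupper(df$other_allele) else NA_character_
  full$eaf <- if ("eaf" %in% names(df)) df$eaf else NA_real_
  full$beta <- df$beta
  full$se <- df$se
  if ("pval" %in% names(df)) {
    full$pval <- df$pval
    full$pval_derived <- is.na(df$pval)
  } else {
    full$pval <- NA_real_
    full$pval_derived <- rep(TRUE, nrow(full))
  }
  full$pval[full$pval_derived] <- normal_pval(full$beta[full$pval_derived],
                                              full$se[full$pval_derived])
  full$n <- if ("n" %in% names(df)) df$n else NA_real_
  full <- full[, .snp_columns]
  new("SummaryStudy", studyId = studyId, traitName = traitName,
      traitType = traitType, snps = full, skipped = empty_skipped())
}

#' Harmonize outcome effects onto the exposure's effect alleles
#'
#' For every requested SNP, expresses the outcome study's effect for the
#' exposure study's effect allele. Matching orientations are copied; swapped
#' orientations (effect and other allele exchanged) flip the sign of the
#' outcome beta and complement its allele frequency. Palindromic SNPs (A/T or
#' C/G) whose exposure minor-allele frequency is at or above
#' \code{palindromicMafMax} are dropped as strand-ambiguous; palindromic SNPs
#' below the threshold are aligned using allele frequency (outcome EAF on the
#' opposite side of 0.5 from the exposure EAF indicates a strand flip).
#' Allele pairs that match neither orientation are dropped. Every requested
#' SNP ends up either retained or dropped with a reason; nothing is lost
#' silently.
#'
#' @param exposure,outcome \code{\link{SummaryStudy}} objects.
#' @param snpIds SNPs to harmonize; all must be present in \code{exposure}.
#' @param palindromicMafMax drop palindromic SNPs with exposure MAF at or
#'   above this value (default 0.42).
#' @return a \code{\link{HarmonizedSet}}.
#' @export
harmonize <- function(exposure, outcome, snpIds, palindromicMafMax = 0.42) {
  stopifnot(is(exposure, "SummaryStudy"), is(outcome, "SummaryStudy"))
  if (length(snpIds) == 0) stop("no instruments")
  exp_df <- exposure@snps
  out_df <- outcome@snps
  missing_exp <- setdiff(snpIds, exp_df$snp_id)
  if (length(missing_exp))
    stop("snp_ids absent from exposure study: ",
         paste(missing_exp, collapse = ", "))

  e <- exp_df[match(snpIds, exp_df$snp_id), ]
  o_idx <- match(snpIds, out_df$snp_id)

  rows <- vector("list", length(snpIds))
  dropped <- vector("list", length(snpIds))
  for (i in seq_along(snpIds)) {
    id <- snpIds[i]
    if (is.na(o_idx[i])) {
      dropped[[i]] <- data.frame(snp_id = id, reason = "absent_in_outcome",
                                 stringsAsFactors = FALSE)
      next
    }
    o <- out_df[o_idx[i], ]
    ea <- e$effect_allele[i]; oa <- e$other_allele[i]
    pal <- is_palindromic(ea, oa)
    if (pal && !is.na(e$eaf[i]) && minor_af(e$eaf[i]) >= palindromicMafMax) {
      dropped[[i]] <- data.frame(snp_id = id, reason = "palindromic_ambiguous",
                                 stringsAsFactors = FALSE)
      next
    }
    beta_out <- NA_real_
    if (o$effect_allele == ea && o$other_allele == oa) {
      beta_out <- o$beta
      out_eaf <- o$eaf
    } else if (o$effect_allele == oa && o$other_allele == ea) {
      beta_out <- -o$beta
      out_eaf <- 1 - o$eaf
    } else {
      dropped[[i]] <- data.frame(snp_id = id, reason = "allele_mismatch",
                                 stringsAsFactors = FALSE)
      next
    }
    if (pal && !is.na(e$eaf[i]) && !is.na(out_eaf)) {
      # a palindromic match can still be reported on opposite strands; the
      # allele-frequency comparison disambiguates (MAF < threshold guaranteed)
      if ((e$eaf[i] < 0.5) != (out_eaf < 0.5)) beta_out <- -beta_out
    }
    rows[[i]] <- data.frame(snp_id = id, beta_exp = e$beta[i],
                            se_exp = e$se[i], beta_out = beta_out,
                            se_out = o$se, eaf_exp = e$eaf[i],
                            stringsAsFactors = FALSE)
  }
  rows_df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows_df))
    rows_df <- data.frame(snp_id = character(), beta_exp = numeric(),
                          se_exp = numeric(), beta_out = numeric(),
                          se_out = numeric(), eaf_exp = numeric(),
                          stringsAsFactors = FALSE)
  dropped_df <- do.call(rbind, dropped[!vapply(dropped, is.null, TRUE)])
  if (is.null(dropped_df)) dropped_df <- empty_skipped()
  rownames(rows_df) <- rownames(dropped_df) <- NULL
  new("HarmonizedSet", exposureId = exposure@studyId,
      outcomeId = outcome@studyId, rows = rows_df, dropped = dropped_df)
}

# Internal: build a HarmonizedSet straight from aligned vectors (tests,
# bootstrap resampling).
new_harmonized <- function(snp_id, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = NA_real_, exposureId = "exposure",
                           outcomeId = "outcome") {
  new("HarmonizedSet", exposureId = exposureId, outcomeId = outcomeId,
      rows = data.frame(snp_id = snp_id, beta_exp = beta_exp, se_exp = se_exp,
                        beta_out = beta_out, se_out = se_out,
                        eaf_exp = rep_len(eaf_exp, length(snp_id)),
                        stringsAsFactors = FALSE),
      dropped = empty_skipped())
}
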