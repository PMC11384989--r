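# Small in-code fixtures shared across test files.

# A minimal well-formed summary-statistics data.frame.
toy_snps <- function() {
  data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(1000, 2000, 3000),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    eaf = c(0.30, 0.10, 0.45),
    beta = c(0.10, -0.05, 0.02),
    se = c(0.01, 0.02, 0.015),
    pval = c(1e-23, 0.0124, 0.18),
    n = c(10000, 10000, 9000),
    stringsAsFactors = FALSE
  )
}

toy_study <- function(id = "toy", df = toy_snps()) {
  makeSummaryStudy(df, studyId = id, traitName = id)
}

# Write a study data.frame as a GWAS-SSF-named TSV and return the path.
write_ssf_tsv <- function(df, sep = "\t") {
  path <- tempfile(fileext = if (sep == "\t") ".tsv" else ".csv")
  names(df) <- c(snp_id = "rsid", chrom = "chromosome",
                 pos = "base_pair_location", effect_allele = "effect_allele",
                 other_allele = "other_allele",
                 eaf = "effect_allele_frequency", beta = "beta",
                 se = "standard_error", pval = "p_value",
                 n = "n")[names(df)]
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Harmonized set built directly from ratio-level inputs: beta_exp = 1 makes
# the Wald ratios equal beta_out.
ratio_hset <- function(ratios, ses, beta_exp = rep(1, length(ratios))) {
  medimr:::new_harmonized(
    snp_id = sprintf("rs%d", seq_along(ratios)),
    beta_exp = beta_exp, se_exp = rep(0.01, length(ratios)),
    beta_out = ratios * beta_exp, se_out = ses * abs(beta_exp),
    eaf_exp = 0.3)
}

# IVW oracle: weighted least squares of beta_out on beta_exp through the
# origin, weights 1/se_out^2, via stats::lm (independent of the package's
# ratio-pooling implementation).
ivw_wls_oracle <- function(H) {
  r <- harmonizedRows(H)
  fit <- lm(beta_out ~ beta_exp - 1, data = r, weights = 1 / r$se_out^2)
  unname(coef(fit)["beta_exp"])
}
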