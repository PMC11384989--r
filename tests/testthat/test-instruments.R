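test_that("p-value selection is strict and deterministically ordered", {
  df <- toy_snps()
  df$pval <- c(1e-6, 2e-5, 1e-8)
  st <- toy_study("s", df)
  expect_identical(selectByPvalue(st, 1e-5), c("rs3", "rs1"))
  # boundary: exactly the threshold is excluded
  df$pval <- c(1e-5, 2e-5, 1e-8)
  expect_identical(selectByPvalue(toy_study("s", df), 1e-5), "rs3")
  # p-value ties break lexicographically by snp_id
  df$pval <- c(1e-8, 1e-8, 1e-8)
  expect_identical(selectByPvalue(toy_study("s", df), 1e-5),
                   c("rs1", "rs2", "rs3"))
})

test_that("clumping keeps the dominant index SNP within a window", {
  df <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = c(1000, 2000),
                   effect_allele = "A", other_allele = "G", eaf = 0.3,
                   beta = 0.1, se = 0.01, pval = c(1e-8, 1e-6), n = 1e4)
  st <- toy_study("s", df)
  ld <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(ldClump(c("a", "b"), st, ld), "a")
  # same correlation on different chromosomes: both retained
  df2 <- df; df2$chrom <- c("1", "2")
  expect_identical(ldClump(c("a", "b"), toy_study("s", df2), ld), c("a", "b"))
  # outside the window on the same chromosome: both retained
  df3 <- df; df3$pos <- c(1000, 1000 + 10000 * 1000 + 1)
  expect_identical(ldClump(c("a", "b"), toy_study("s", df3), ld), c("a", "b"))
  # missing from the LD matrix is an error naming the SNP
  expect_error(ldClump(c("a", "b", "c"),
                       toy_study("s", rbind(df, within(df[1, ], {
                         snp_id <- "c"; pos <- 5000
                       }))), ld), "c")
})

test_that("block-structured candidates clump to one index per block, matching a brute-force oracle", {
  cfg <- mrSimConfig(nInstruments = 30, nNullSnps = 0, ldBlockSize = 3,
                     ldR = 0.9, seed = 12)
  sim <- simulateMrStudy(cfg)
  ld <- ldMatrix(sim$truth)
  cand <- snps(sim$exposure)$snp_id
  kept <- ldClump(cand, sim$exposure, ld)
  expect_length(kept, 10)

  # brute-force oracle: independent pairwise implementation of greedy
  # selection by ascending p-value over the (distance, r2) removal rule
  df <- snps(sim$exposure)
  df <- df[order(df$pval, df$snp_id), ]
  oracle <- character(0)
  alive <- df$snp_id
  while (length(alive)) {
    idx <- alive[1]
    oracle <- c(oracle, idx)
    drop <- vapply(alive, function(s) {
      same <- df$chrom[df$snp_id == s] == df$chrom[df$snp_id == idx]
      near <- abs(df$pos[df$snp_id == s] - df$pos[df$snp_id == idx]) <= 1e7
      s != idx && same && near && ld[idx, s]^2 >= 0.001
    }, logical(1))
    alive <- alive[!drop & alive != idx]
  }
  expect_identical(kept, oracle)
  # each retained SNP is the minimum-p member of its block
  blocks <- sim$truth@block
  for (s in kept) {
    b <- blocks[match(s, snps(sim$exposure)$snp_id)]
    members <- snps(sim$exposure)[blocks == b, ]
    expect_equal(s, members$snp_id[which.min(members$pval)])
  }
})

test_that("clump output is invariant to candidate input order", {
  cfg <- mrSimConfig(nInstruments = 12, nNullSnps = 0, ldBlockSize = 4,
                     ldR = 0.6, seed = 4)
  sim <- simulateMrStudy(cfg)
  ld <- ldMatrix(sim$truth)
  cand <- snps(sim$exposure)$snp_id
  k1 <- ldClump(cand, sim$exposure, ld)
  set.seed(1)
  k2 <- ldClump(sample(cand), sim$exposure, ld)
  expect_identical(k1, k2)
})

test_that("variance explained follows the folded-MAF formula", {
  expect_equal(r2FromMaf(0.5, 1), 0.5)
  expect_equal(r2FromMaf(0, 2), 0)
  expect_equal(r2FromMaf(1, 2), 0)
  expect_equal(r2FromMaf(0.9, 0.2), r2FromMaf(0.1, 0.2))
  # hand evaluation: 2 * 0.8 * 0.2 * 0.09
  expect_equal(r2FromMaf(0.2, 0.3), 2 * 0.8 * 0.2 * 0.09)
})

test_that("the F-statistic matches its closed form and is monotone in r2", {
  expect_equal(fStatistic(0.01, 1002), 0.01 * 1000 / 0.99)
  expect_equal(fStatistic(0, 100), 0)
  expect_gt(fStatistic(0.02, 500), fStatistic(0.01, 500))
  expect_error(fStatistic(1, 100), "r2")
})

test_that("weak-instrument filtering is strict below F = 10 and audited", {
  # construct SNPs with F straddling 10: F = r2 (n-2) / (1 - r2)
  # choose eaf = 0.5 so r2 = beta^2 / 2
  n <- 2002
  f_target <- c(9.5, 10.001, 80)
  r2 <- f_target / (n - 2 + f_target)
  beta <- sqrt(2 * r2)
  df <- toy_snps()
  df$eaf <- 0.5; df$beta <- beta; df$n <- n
  st <- toy_study("s", df)
  is <- filterWeak(df$snp_id, st, fMin = 10)
  expect_setequal(instrumentIds(is), c("rs2", "rs3"))
  expect_equal(instrumentExclusions(is)$snp_id, "rs1")
  expect_equal(is@table$f_stat, f_target[2:3], tolerance = 1e-9)
  # the exclusion rule is strict: F exactly at the cutoff is retained
  df10 <- df[1, ]; df10$beta <- 0.1; df10$n <- 1992  # r2 = 0.005, F = 10
  expect_identical(instrumentIds(filterWeak("rs1", toy_study("s", df10),
                                            fMin = 10)), "rs1")
  # missing eaf: excluded with detail and warning
  df$eaf[2] <- NA
  expect_warning(is2 <- filterWeak(df$snp_id, toy_study("s", df), fMin = 10),
                 "eaf")
  ex <- instrumentExclusions(is2)
  expect_equal(ex$detail[ex$snp_id == "rs2"], "no_eaf")
})

test_that("strong simulated instruments survive the full selection pipeline with a complete audit", {
  cfg <- mrSimConfig(nInstruments = 40, nNullSnps = 200, seed = 21)
  sim <- simulateMrStudy(cfg)
  ld <- ldMatrix(sim$truth)
  instr <- selectInstruments(sim$exposure, ld)
  ids <- instrumentIds(instr)
  # only planted instruments pass the genome-wide-relaxed threshold
  expect_true(all(ids %in% trueInstruments(sim$truth)))
  expect_gt(length(ids), 20)
  # audit completeness: every SNP is retained or excluded exactly once
  all_ids <- snps(sim$exposure)$snp_id
  expect_setequal(c(ids, instrumentExclusions(instr)$snp_id), all_ids)
  expect_equal(length(ids) + nrow(instrumentExclusions(instr)),
               length(all_ids))
  # selected instruments at this sample size are all strong
  expect_true(all(instr@table$f_stat >= 10))
})
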