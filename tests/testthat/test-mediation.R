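test_that("mediator instruments associated with the exposure are excluded", {
  df <- toy_snps()
  med <- toy_study("med", df)
  instr <- filterWeak(df$snp_id, med, fMin = 0)
  exp_df <- toy_snps()
  exp_df$pval <- c(1e-7, 0.5, 0.9)   # rs1 exposure-associated
  exposure <- toy_study("exp", exp_df)
  out <- excludeExposureSnps(instr, exposure, threshold = 1e-5)
  expect_setequal(instrumentIds(out), c("rs2", "rs3"))
  ex <- instrumentExclusions(out)
  expect_equal(ex$detail[ex$snp_id == "rs1"], "associated_with_exposure")
  # instruments absent from the exposure study are retained with a warning
  exp_small <- toy_study("exp", toy_snps()[1:2, ])
  expect_warning(kept <- excludeExposureSnps(instr, exp_small),
                 "retained unchecked")
  expect_true("rs3" %in% instrumentIds(kept))
})

test_that("exposure-independent mediator instruments are essentially never excluded", {
  sim <- simulateMrStudy(mrSimConfig(nInstruments = 20,
                                     nMediatorInstruments = 200,
                                     nNullSnps = 0, beta1 = 0, seed = 31))
  ld <- ldMatrix(sim$truth)
  med_instr <- selectInstruments(sim$mediator, ld)
  kept <- excludeExposureSnps(med_instr, sim$exposure, threshold = 1e-5)
  # null calibration: expected removals ~ threshold * k, i.e. ~0
  removed <- setdiff(instrumentIds(med_instr), instrumentIds(kept))
  expect_lte(length(removed), 2)
})

test_that("the worked effect-scale example composes alpha, beta1 and beta2", {
  # product and quotient of the published per-leg estimates
  beta1 <- -0.1394
  beta2 <- log(1.08)
  alpha <- -0.2454
  beta3 <- beta1 * beta2
  expect_equal(beta3, -0.010728369134376289, tolerance = 1e-12)
  expect_equal(beta3 / alpha, 0.043717885633155210, tolerance = 1e-12)
})

test_that("two-step mediation recovers planted mediation structure", {
  cfg <- mrSimConfig(nInstruments = 40, nMediatorInstruments = 40,
                     nNullSnps = 20, theta = -0.25, beta1 = -0.15,
                     beta2 = 0.08, seed = 19)
  sim <- simulateMrStudy(cfg)
  ld <- ldMatrix(sim$truth)
  med <- twoStepMediation(sim$exposure, sim$mediator, sim$outcome, ld,
                          nBoot = 300, seed = 7)
  expect_identical(med@beta3, med@beta1 * med@beta2)
  expect_equal(med@proportion * med@alpha, med@beta3)
  truth_prop <- (-0.15 * 0.08) / (-0.25 + (-0.15 * 0.08))
  expect_equal(med@proportion, truth_prop, tolerance = 0.35)
  # the total effect is recovered up to sampling noise and the mild
  # winner's-curse attenuation of selecting instruments from the same data
  expect_equal(med@alpha, sim$truth@impliedTotal, tolerance = 0.15)
  # bootstrap CI contains the point estimate
  expect_lte(med@bootCiLow, med@beta3)
  expect_gte(med@bootCiHigh, med@beta3)
  # identical seed reproduces the bootstrap exactly
  med2 <- twoStepMediation(sim$exposure, sim$mediator, sim$outcome, ld,
                           nBoot = 300, seed = 7)
  expect_identical(med@bootCiLow, med2@bootCiLow)
  expect_identical(med@bootPval, med2@bootPval)
})

test_that("a zero mediator-to-outcome path yields zero indirect effect", {
  cfg <- mrSimConfig(nInstruments = 30, nMediatorInstruments = 30,
                     nNullSnps = 10, theta = 0.2, beta1 = -0.15, beta2 = 0,
                     seed = 23)
  sim <- simulateMrStudy(cfg)
  ld <- ldMatrix(sim$truth)
  med <- twoStepMediation(sim$exposure, sim$mediator, sim$outcome, ld,
                          nBoot = 200, seed = 3)
  expect_lt(abs(med@beta3), 0.01)
  expect_identical(med@beta3, med@beta1 * med@beta2)
})

test_that("opposite-sign indirect effects are reported but flagged", {
  cfg <- mrSimConfig(nInstruments = 40, nMediatorInstruments = 40,
                     nNullSnps = 0, theta = 0.3, beta1 = 0.2, beta2 = -0.2,
                     seed = 29)
  sim <- simulateMrStudy(cfg)
  ld <- ldMatrix(sim$truth)
  med <- twoStepMediation(sim$exposure, sim$mediator, sim$outcome, ld,
                          nBoot = 200, seed = 3)
  # alpha = 0.3 - 0.04 > 0 while beta3 < 0
  expect_true("opposite_sign_proportion" %in% med@flags)
  expect_lt(med@proportion, 0)
})

test_that("bootstrap inference is seeded, bounded and degenerates sensibly", {
  cfg <- mrSimConfig(nInstruments = 30, nMediatorInstruments = 30,
                     nNullSnps = 0, theta = -0.2, beta1 = -0.15, beta2 = 0.1,
                     seed = 41)
  sim <- simulateMrStudy(cfg)
  ld <- ldMatrix(sim$truth)
  b1 <- bootstrapIndirect(sim$exposure, sim$mediator, sim$outcome, ld,
                          nBoot = 200, seed = 11)
  b2 <- bootstrapIndirect(sim$exposure, sim$mediator, sim$outcome, ld,
                          nBoot = 200, seed = 11)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$ci_high)
  expect_gte(b1$pval, 2 / 201)
  expect_warning(bootstrapIndirect(sim$exposure, sim$mediator, sim$outcome,
                                   ld, nBoot = 50, seed = 1), "unstable")
})

test_that("failures name the leg that lacked instruments", {
  sim <- simulateMrStudy(mrSimConfig(nInstruments = 20,
                                     nMediatorInstruments = 0,
                                     nNullSnps = 10, theta = 0.2,
                                     beta1 = 0, seed = 13))
  ld <- ldMatrix(sim$truth)
  expect_error(
    twoStepMediation(sim$exposure, sim$mediator, sim$outcome, ld,
                     nBoot = 100, seed = 1),
    "mediator")
})

test_that("mediation results serialize to JSON faithfully", {
  cfg <- mrSimConfig(nInstruments = 20, nMediatorInstruments = 20,
                     nNullSnps = 0, theta = 0.2, beta1 = 0.1, beta2 = 0.1,
                     seed = 47)
  sim <- simulateMrStudy(cfg)
  med <- twoStepMediation(sim$exposure, sim$mediator, sim$outcome,
                          ldMatrix(sim$truth), nBoot = 100, seed = 2)
  path <- tempfile(fileext = ".json")
  writeMediationJson(med, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$beta3, med@beta3)
  expect_equal(back$proportion, med@proportion)
})
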