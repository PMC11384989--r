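test_that("Wald ratios follow the delta-method arithmetic", {
  wr <- waldRatio(0.1, 0.02, 0.01)
  expect_equal(wr$ratio, 0.2)
  expect_equal(wr$se, 0.1)
  expect_equal(waldRatio(0.1, 0, 0.01)$ratio, 0)
  expect_equal(waldRatio(-0.1, 0.02, 0.01)$ratio, -0.2)
  expect_equal(waldRatio(-0.1, 0.02, 0.01)$se, 0.1)
  expect_error(waldRatio(0, 0.02, 0.01), "nonzero")
  # second-order option adds the exposure-noise term
  so <- waldRatio(0.1, 0.02, 0.01, seExp = 0.05, secondOrder = TRUE)
  expect_equal(so$se, sqrt(0.01^2 / 0.1^2 + 0.02^2 * 0.05^2 / 0.1^4))
})

test_that("IVW reproduces the three-SNP worked example and the WLS oracle", {
  H <- medimr:::new_harmonized(
    snp_id = c("a", "b", "c"),
    beta_exp = c(0.1, 0.2, 0.15), se_exp = 0.01,
    beta_out = c(0.02, 0.05, 0.03), se_out = 0.01)
  fit <- mrIvw(H, model = "fixed")
  expect_equal(fit@beta, 0.0165 / 0.0725)
  expect_equal(fit@beta, ivw_wls_oracle(H), tolerance = 1e-12)
  expect_equal(fit@se, sqrt(1 / 725))
  # k = 1 degenerates to the single Wald ratio
  H1 <- ratio_hset(0.31, 0.05)
  f1 <- mrIvw(H1)
  expect_equal(f1@beta, 0.31)
  expect_equal(f1@se, 0.05)
  # linearity: scaling all outcome betas scales the estimate
  H2 <- H; H2@rows$beta_out <- 3 * H2@rows$beta_out
  expect_equal(mrIvw(H2, model = "fixed")@beta, 3 * fit@beta)
})

test_that("the random-effects IVW SE is never below the fixed-effect SE", {
  for (seed in 1:20) {
    set.seed(seed)
    H <- ratio_hset(rnorm(8, 0.2, 0.3), runif(8, 0.02, 0.2))
    expect_gte(mrIvw(H, "random_multiplicative")@se, mrIvw(H, "fixed")@se)
  }
})

test_that("IVW is invariant to row order", {
  set.seed(3)
  H <- ratio_hset(rnorm(10, 0.1, 0.1), runif(10, 0.01, 0.1))
  Hr <- H; Hr@rows <- Hr@rows[10:1, ]
  expect_equal(mrIvw(H)@beta, mrIvw(Hr)@beta)
  expect_equal(mrIvw(H)@se, mrIvw(Hr)@se)
})

test_that("Egger recovers an exact affine relation to machine precision", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  H <- medimr:::new_harmonized(
    snp_id = letters[1:4], beta_exp = bx, se_exp = 0.01,
    beta_out = 0.03 + 0.5 * bx, se_out = c(0.01, 0.02, 0.01, 0.03))
  fit <- mrEgger(H)
  expect_equal(fit@beta, 0.5, tolerance = 1e-10)
  expect_equal(fit@extra$intercept, 0.03, tolerance = 1e-10)
  expect_equal(fit@extra$flag, "degenerate_fit")
  expect_true(is.na(fit@pval))
  expect_true(is.na(fit@extra$intercept_pval))
  expect_error(mrEgger(ratio_hset(c(0.1, 0.2), c(0.01, 0.01))), "Egger")
})

test_that("Egger orientation flip leaves the slope meaningful for mixed-sign exposures", {
  set.seed(10)
  bx <- c(-0.3, -0.1, 0.2, 0.4, 0.15)
  a <- 0.02; b <- 0.6
  by <- a + b * abs(bx) + rnorm(5, 0, 1e-4)
  by <- ifelse(bx < 0, -by, by)  # effects recorded for the negative allele
  H <- medimr:::new_harmonized(letters[1:5], bx, 0.01, by, 0.01)
  fit <- mrEgger(H)
  expect_equal(fit@beta, b, tolerance = 0.01)
  expect_equal(fit@extra$intercept, a, tolerance = 0.01)
})

test_that("the weighted median interpolates cumulative weight and renormalizes", {
  expect_equal(mrWeightedMedian(ratio_hset(c(0.1, 0.2, 0.3),
                                           c(0.05, 0.05, 0.05)),
                                nBoot = 50, seed = 1)@beta, 0.2)
  # duplicating every SNP leaves the estimate unchanged
  r <- c(0.05, 0.21, 0.33, 0.4); s <- c(0.03, 0.05, 0.02, 0.08)
  one <- mrWeightedMedian(ratio_hset(r, s), nBoot = 50, seed = 1)@beta
  two <- mrWeightedMedian(ratio_hset(c(r, r), c(s, s)), nBoot = 50,
                          seed = 1)@beta
  expect_equal(one, two)
  # row order does not matter (fixed bootstrap seed)
  H <- ratio_hset(r, s)
  Ho <- H; Ho@rows <- Ho@rows[4:1, ]
  expect_equal(mrWeightedMedian(H, nBoot = 200, seed = 9)@beta,
               mrWeightedMedian(Ho, nBoot = 200, seed = 9)@beta)
})

test_that("mode estimators find the plurality cluster, not the mean", {
  ratios <- c(rep(0.25, 7), rep(0.6, 3)) + c(seq(-3, 3) * 1e-3,
                                             seq(-1, 1) * 1e-3)
  ses <- rep(0.01, 10)
  sm <- mrMode(ratio_hset(ratios, ses), weighted = FALSE, nBoot = 50,
               seed = 2)
  wm <- mrMode(ratio_hset(ratios, ses), weighted = TRUE, nBoot = 50,
               seed = 2)
  expect_equal(sm@beta, 0.25, tolerance = 0.02)
  expect_equal(wm@beta, 0.25, tolerance = 0.02)
  # a point mass returns the common ratio exactly
  expect_equal(mrMode(ratio_hset(rep(0.4, 5), rep(0.02, 5)), nBoot = 10,
                      seed = 1)@beta, 0.4)
  # bandwidth scaling moves the estimate smoothly within the ratio range
  for (phi in c(0.5, 1, 2)) {
    est <- mrMode(ratio_hset(ratios, ses), phi = phi, nBoot = 10,
                  seed = 3)@beta
    expect_gte(est, min(ratios)); expect_lte(est, max(ratios))
  }
})

test_that("odds-ratio conversion matches the published effect-scale arithmetic", {
  expect_equal(unname(betaToOr(-0.2454)["or"]), 0.7824, tolerance = 5e-5)
  expect_equal(unname(betaToOr(-0.1394)["or"]), 0.87, tolerance = 5e-3)
  expect_equal(unname(betaToOr(0, 0.1)["or"]), 1)
  out <- betaToOr(0.5, 0.1)
  expect_equal(unname(out), c(exp(0.5), exp(0.5 - 0.196), exp(0.5 + 0.196)))
})

test_that("MrResult p-values and CIs are internally consistent", {
  set.seed(5)
  H <- ratio_hset(rnorm(6, 0.2, 0.1), runif(6, 0.02, 0.1))
  for (fit in list(mrIvw(H), mrWeightedMedian(H, nBoot = 100, seed = 2))) {
    expect_equal(fit@pval, 2 * pnorm(-abs(fit@beta / fit@se)))
    expect_equal(fit@orPoint, exp(fit@beta))
    expect_lt(fit@orLow, fit@orPoint)
    expect_gt(fit@orHigh, fit@orPoint)
  }
})

test_that("all five estimators recover a planted effect on clean truth instruments", {
  R <- 40
  est <- matrix(NA_real_, R, 5)
  for (i in seq_len(R)) {
    sim <- simulateMrStudy(mrSimConfig(nInstruments = 50, nNullSnps = 0,
                                       theta = 0.25, seed = 1000 + i))
    H <- harmonize(sim$exposure, sim$outcome, trueInstruments(sim$truth))
    fits <- mrAllMethods(H, nBoot = 100, seed = i)
    est[i, ] <- vapply(fits, function(f) f@beta, numeric(1))
  }
  for (j in 1:5) {
    expect_lt(abs(mean(est[, j]) - 0.25), 3 * sd(est[, j]),
              label = colnames(est)[j])
  }
})
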