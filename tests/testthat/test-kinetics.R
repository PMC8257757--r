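test_that("fraction product follows the band-intensity definition", {
  expect_equal(fractionProduct(50, 50), 0.5)
  expect_equal(fractionProduct(0, 100), 0)
  expect_equal(fractionProduct(80, 20), 0.8)
  expect_true(is.na(fractionProduct(0, 0)))
  expect_equal(fractionProduct(c(50, 80), c(50, 20)), c(0.5, 0.8))
  expect_error(fractionProduct(-1, 5), "non-negative")
})

test_that("simulation matches the one-phase association closed form", {
  tc <- simulateTimecourse(0.9, 0.1, noiseSd = 0)
  expect_equal(productFractions(tc), 0.9 * (1 - exp(-0.1 * assayTimes(tc))),
               tolerance = 1e-12)
  expect_equal(productFractions(tc)[assayTimes(tc) == 30],
               0.9 * (1 - exp(-3)), tolerance = 1e-12)
  expect_true(all(productFractions(simulateTimecourse(0.9, 0)) == 0))
  ## the standard grid starts at the 5-second quench point
  expect_equal(defaultTimeGrid()[1], 0.083)
  expect_length(defaultTimeGrid(), 13L)
  expect_error(simulateTimecourse(0.9, 0.1, times = c(2, 1, 3)),
               "strictly increasing")
})

test_that("noiseless fits recover the generating parameters exactly", {
  fit <- fitTimecourse(simulateTimecourse(0.85, 0.5, noiseSd = 0))
  expect_true(isConverged(fit))
  expect_equal(amplitude(fit), 0.85, tolerance = 1e-6)
  expect_equal(kObs(fit), 0.5, tolerance = 1e-6)

  ## simulate -> fit -> simulate reproduces the noiseless curve
  again <- simulateTimecourse(amplitude(fit), kObs(fit), noiseSd = 0)
  expect_equal(productFractions(again),
               productFractions(simulateTimecourse(0.85, 0.5, noiseSd = 0)),
               tolerance = 1e-6)

  z <- fitTimecourse(TimeCourse(c(1, 2, 5, 10), rep(0, 4)))
  expect_equal(kObs(z), 0)
  expect_equal(amplitude(z), 0)
  expect_true(isConverged(z))
})

test_that("fits are invariant to time-point permutation", {
  tc <- simulateTimecourse(0.8, 0.3, noiseSd = 0.02, seed = 5)
  df <- data.frame(time_min = assayTimes(tc),
                   fraction_product = productFractions(tc))
  set.seed(1); shuffled <- df[sample(nrow(df)), ]
  f1 <- fitTimecourse(df)
  f2 <- fitTimecourse(shuffled)
  expect_equal(kObs(f1), kObs(f2), tolerance = 1e-9)
  expect_equal(amplitude(f1), amplitude(f2), tolerance = 1e-9)
})

test_that("rate recovery stays within a few percent at assay-level noise", {
  errs <- vapply(1:60, function(i) {
    reps <- lapply(1:3, function(j)
      simulateTimecourse(0.85, 0.5, noiseSd = 0.02, seed = 1000 * i + j,
                         replicate = paste0("r", j)))
    abs(kObs(fitTimecourse(reps)) - 0.5) / 0.5
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("estimator bias shrinks as noise decreases", {
  medErr <- vapply(c(0.05, 0.02, 0.005), function(sd) {
    errs <- vapply(1:30, function(i) {
      tc <- simulateTimecourse(0.85, 0.5, noiseSd = sd,
                               seed = round(sd * 1e5) + i)
      abs(kObs(fitTimecourse(tc)) - 0.5) / 0.5
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(medErr) < 0))
  expect_lt(medErr[3], 0.01)
})

test_that("rate-ratio test covers the true ratio and inverts cleanly", {
  mkFits <- function(k, seedBase) lapply(1:3, function(j)
    fitTimecourse(simulateTimecourse(0.85, k, noiseSd = 0.02,
                                     seed = seedBase + j)))
  fa <- mkFits(0.8, 100); fb <- mkFits(0.2, 200)
  same <- kobsRatioTest(fa, fa)
  expect_equal(same$ratio, 1.0)
  expect_true(same$lower <= 1 && same$upper >= 1)
  ab <- kobsRatioTest(fa, fb); ba <- kobsRatioTest(fb, fa)
  expect_equal(ab$ratio * ba$ratio, 1, tolerance = 1e-12)

  ## coverage at true ratio 4 over seeded repeats
  hits <- vapply(1:100, function(i) {
    fa <- mkFits(0.8, 10000 + 10 * i)
    fb <- mkFits(0.2, 20000 + 10 * i)
    ci <- kobsRatioTest(fa, fb)
    ci$lower <= 4 && 4 <= ci$upper
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("slow substrates need the extended 72-hour window", {
  kSlow <- 1e-4  # min^-1, the mismatched-dT regime
  rel <- sapply(1:8, function(i) {
    mk <- function(grid) lapply(1:3, function(j)
      simulateTimecourse(0.9, kSlow, times = grid, noiseSd = 0.01,
                         seed = 100 * i + j))
    c(ext = abs(kObs(fitTimecourse(mk(defaultTimeGrid("extended")))) -
                  kSlow) / kSlow,
      std = abs(kObs(fitTimecourse(mk(defaultTimeGrid()))) -
                  kSlow) / kSlow)
  })
  expect_lt(median(rel["ext", ]), 0.25)
  ## inside 180 min the curve is indistinguishable from a straight line:
  ## A and k_obs are not separately identifiable there
  expect_gt(median(rel["std", ]), 1)
  expect_equal(max(defaultTimeGrid("extended")), 4320)  # 72 h
})

test_that("thermo and kinetics compose: fitted ratios track p_A ratios", {
  tab <- triageConsistencyCheck(1.0, c(0, 0), noiseSd = 0)
  expect_equal(tab$fittedRatio[2], 1, tolerance = 1e-9)

  tab2 <- triageConsistencyCheck(1.0, c(0, 1.0), noiseSd = 0)
  expect_equal(tab2$fittedRatio[2], activatedFraction(1) / 0.5,
               tolerance = 1e-6)
  expect_equal(1 / tab2$fittedRatio[2], 3.2034, tolerance = 1e-3)

  grid <- triageConsistencyCheck(1.0, c(-2, -1, 0, 1, 2), noiseSd = 0)
  expect_true(all(diff(grid$fittedKobs) < 0))
})
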