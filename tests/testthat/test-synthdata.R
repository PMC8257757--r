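test_that("generators are deterministic under a fixed seed", {
  s1 <- genConformationalEnsemble(ensembleSpec(n = 500, seed = 8))
  s2 <- genConformationalEnsemble(ensembleSpec(n = 500, seed = 8))
  expect_identical(s1, s2)
  s3 <- genConformationalEnsemble(ensembleSpec(n = 500, seed = 9))
  expect_false(identical(s1$d242, s3$d242))

  ## byte-identical CSV regeneration
  spec <- kineticsSpec(data.frame(variant = "K242", substrate = "DHU",
                                  kcat = 1, dGconf = 0, dGchem = 0),
                       seed = 4)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeTimecourseCSV(genTimecourseDataset(spec), f1)
  writeTimecourseCSV(genTimecourseDataset(spec), f2)
  expect_identical(readLines(f1), readLines(f2))

  ## byte-identical toy structure files
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  genToyStructure("apo", path = p1); genToyStructure("apo", path = p2)
  expect_identical(readLines(p1), readLines(p2))

  ## the generator leaves the caller's RNG stream untouched
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(genConformationalEnsemble(ensembleSpec(n = 10, seed = 1)))
  expect_identical(runif(1), before)
})

test_that("ensemble spec validates covariances and weights", {
  badCov <- matrix(c(1, 2, 0, 1), 2, 2)
  expect_error(ensembleSpec(covariances = badCov), "symmetric")
  notPD <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(ensembleSpec(covariances = notPD), "positive semi-definite")
  expect_error(ensembleSpec(weights = c(apo = 0.5, in242 = 0.2,
                                        in244 = 0.2)), "sum to 1")
  ## degenerate zero covariance collapses to the centroid
  e <- genConformationalEnsemble(
    ensembleSpec(covariances = matrix(0, 2, 2), n = 50, seed = 1))
  refs <- defaultStateReferences()
  for (i in 1:3) {
    sub <- e[e$label == refs$label[i], ]
    if (nrow(sub)) {
      expect_true(all(sub$d242 == refs$d242[i]))
      expect_true(all(sub$d244 == refs$d244[i]))
    }
  }
})

test_that("Boltzmann weights drive the generated state split", {
  ## equal free energies: 50/50 between the two competing states
  e <- genConformationalEnsemble(
    ensembleSpec(freeEnergies = c(apo = Inf, in242 = 0, in244 = 0),
                 n = 4000, seed = 12))
  n242 <- sum(e$label == "in242")
  expect_lt(abs(n242 - 2000), 3 * sqrt(4000 / 4))

  ## dG = 1 kcal/mol: activated fraction 0.156
  e2 <- genConformationalEnsemble(
    ensembleSpec(freeEnergies = c(apo = Inf, in242 = 1, in244 = 0),
                 n = 10000, seed = 13))
  p <- 1 / (1 + exp(1 / rtKcal()))
  expect_lt(abs(mean(e2$label == "in242") - p),
            3 * sqrt(p * (1 - p) / 10000))
})

test_that("truth labels agree with classification for separated basins", {
  e <- genConformationalEnsemble(ensembleSpec(n = 5000, seed = 21))
  cls <- classifyEnsemble(e[, c("d242", "d244")])
  expect_gte(mean(cls$label == e$label), 0.99)
})

test_that("end-to-end free-energy recovery through the full pipeline", {
  dgTrue <- 1.0
  e <- genConformationalEnsemble(
    ensembleSpec(freeEnergies = c(apo = 0, in242 = dgTrue, in244 = 0),
                 n = 10000, seed = 33))
  est <- ensembleDeltaG(statePopulations(e[, c("d242", "d244")]))
  expect_lt(abs(as.numeric(est) - dgTrue), 3 * attr(est, "se"))
})

test_that("kinetics datasets encode the auto-inhibition rate law", {
  params <- data.frame(variant = c("K242", "K242"),
                       substrate = c("DHU", "Tg"),
                       kcat = c(1, 1), dGconf = c(0, 1), dGchem = c(0, 0))
  spec <- kineticsSpec(params, noiseSd = 0, replicates = 1)
  ds <- genTimecourseDataset(spec)
  truth <- attr(ds, "truth")
  expect_equal(truth$kObs[1] / truth$kObs[2], 0.5 / activatedFraction(1),
               tolerance = 1e-12)
  expect_equal(truth$kObs[1] / truth$kObs[2], 3.2035, tolerance = 1e-3)
  ## noiseless curves equal the closed form at every grid point
  sub <- ds[ds$substrate == "DHU", ]
  expect_equal(sub$fraction_product,
               0.9 * (1 - exp(-truth$kObs[1] * sub$time_min)),
               tolerance = 1e-12)
  ## truth sidecar round-trips
  f <- tempfile(fileext = ".csv")
  writeTimecourseCSV(ds, f)
  back <- readTimecourseCSV(f)
  expect_equal(attr(back, "truth")$kObs, truth$kObs, tolerance = 1e-12)
})

test_that("toy structures honor requested geometry and reject infeasible ones", {
  m <- genToyStructure("in242", d242 = 2.5)
  expect_equal(as.numeric(computeD242(m, "A", toyBase(m))), 2.5,
               tolerance = 1e-9)
  m2 <- genToyStructure("in244", d244 = 4.2)
  expect_equal(as.numeric(computeD244(m2, "A", toyBase(m2))), 4.2,
               tolerance = 1e-9)
  expect_error(genToyStructure("in242", d242 = 0.2), "infeasible")
  expect_error(genToyStructure("apo", rotationDeg = 2), "infeasible")
})

test_that("solvation shells keep exact in-shell bookkeeping", {
  zero <- genSolvationShell(toyIn242, expectedInShell = 0, seed = 1)
  expect_equal(zero$nInShell, 0L)
  expect_equal(countShellWaters(zero$model, toyBase(zero$model), 5), 0L)

  for (s in 1:5) {
    sh <- genSolvationShell(toyIn242, expectedInShell = 12,
                            shell = c(2.5, 5), seed = 100 + s)
    expect_equal(countShellWaters(sh$model, toyBase(sh$model), 5),
                 sh$nInShell)
  }

  ## Poisson mean oracle over repeated draws
  ns <- vapply(1:200, function(s)
    genSolvationShell(toyIn242, expectedInShell = 10, nFarField = 0,
                      seed = 5000 + s)$nInShell, numeric(1))
  expect_lt(abs(mean(ns) - 10), 3 * sqrt(10 / 200))
})
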