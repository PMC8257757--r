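test_that("nearest-centroid classification matches exhaustive enumeration", {
  refs <- defaultStateReferences()
  set.seed(2024)
  pts <- cbind(runif(1000, 0, 15), runif(1000, 0, 15))
  got <- classifyEnsemble(data.frame(d242 = pts[, 1], d244 = pts[, 2]),
                          refs)
  cent <- as.matrix(refs[, c("d242", "d244")])
  oracle <- apply(pts, 1, function(p) {
    d <- sqrt(rowSums(sweep(cent, 2, p)^2))
    refs$label[which.min(d)]
  })
  expect_identical(got$label, oracle)
  expect_true(all(got$margin >= 0))
})

test_that("ties break deterministically by label order and centroid hits win", {
  refs <- defaultStateReferences()
  ## midpoint of the in242 and in244 centroids is exactly equidistant
  mid <- c(mean(refs$d242[2:3]), mean(refs$d244[2:3]))
  hit <- classifySnapshot(mid[1], mid[2], refs)
  expect_equal(hit$label, "in242")

  atCentroid <- classifySnapshot(refs$d242[3], refs$d244[3], refs)
  expect_equal(atCentroid$label, "in244")
  expect_equal(atCentroid$margin,
               sort(atCentroid$distances)[2], tolerance = 1e-12)

  expect_true(is.na(classifySnapshot(NA, 3)$label))
})

test_that("state populations tabulate labeled ensembles exactly", {
  df <- data.frame(
    d242 = 0, d244 = 0,
    label = rep(c("apo", "in242", "in244"), c(50, 30, 20)))
  s <- statePopulations(df)
  expect_equal(unname(stateFractions(s)), c(0.5, 0.3, 0.2))
  expect_equal(sum(stateFractions(s)), 1, tolerance = 1e-12)
  expect_equal(sum(stateCounts(s)), s@nTotal)

  ## permutation invariance
  s2 <- statePopulations(df[sample(nrow(df)), , drop = FALSE])
  expect_equal(stateFractions(s2), stateFractions(s))

  allApo <- statePopulations(data.frame(d242 = 12, d244 = 10,
                                        label = rep("apo", 10)))
  expect_equal(unname(stateFractions(allApo)), c(1, 0, 0))
  expect_true(is.nan(as.numeric(ensembleDeltaG(allApo))))
})

test_that("Boltzmann-generated populations match the two-state prediction", {
  ## dG = +1 kcal/mol between activated and quarantine at 298.15 K
  spec <- ensembleSpec(freeEnergies = c(apo = Inf, in242 = 1, in244 = 0),
                       n = 10000, seed = 31)
  e <- genConformationalEnsemble(spec)
  s <- statePopulations(e)
  p <- 1 / (1 + exp(1 / rtKcal()))   # 0.156
  seBin <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(stateFractions(s)[["in242"]] - p), 3 * seBin)
})

test_that("free energy from populations matches closed forms and markers", {
  expect_equal(deltaGFromPopulations(0.4, 0.4), 0)
  expect_equal(as.numeric(deltaGFromPopulations(0.25, 0.75)),
               rtKcal() * log(3), tolerance = 1e-12)
  expect_equal(as.numeric(deltaGFromPopulations(0.25, 0.75)), 0.65091,
               tolerance = 1e-4)
  expect_identical(as.numeric(deltaGFromPopulations(0, 0.5)), Inf)
  expect_identical(as.numeric(deltaGFromPopulations(0.5, 0)), -Inf)
  dg <- deltaGFromPopulations(0.2, 0.6, nActivated = 200, nQuarantine = 600)
  expect_equal(attr(dg, "se"), rtKcal() * sqrt(1 / 200 + 1 / 600),
               tolerance = 1e-12)
})

test_that("population-to-free-energy conversion inverts the activated fraction", {
  for (dg in seq(-5, 5, by = 0.25)) {
    p <- activatedFraction(dg)
    back <- as.numeric(deltaGFromPopulations(p, 1 - p))
    expect_equal(back, dg, tolerance = 1e-12)
  }
})

test_that("generated ensembles recover the generating free energy", {
  for (dgTrue in c(-1, 0.5)) {
    spec <- ensembleSpec(
      freeEnergies = c(apo = 0, in242 = dgTrue, in244 = 0),
      n = 10000, seed = 77 + round(10 * dgTrue))
    s <- statePopulations(genConformationalEnsemble(spec))
    est <- ensembleDeltaG(s)
    expect_lt(abs(as.numeric(est) - dgTrue), 3 * attr(est, "se"))
  }
})

test_that("zone detection finds the three generated basins", {
  e <- genConformationalEnsemble(ensembleSpec(n = 3000, seed = 3))
  z <- findMetastableZones(e)
  expect_equal(nrow(z), 3L)
  refs <- defaultStateReferences()
  for (i in seq_len(3)) {
    dx <- min(abs(z$modeD242 - refs$d242[i]))
    dy <- min(abs(z$modeD244 - refs$d244[i]))
    j <- which.min((z$modeD242 - refs$d242[i])^2 +
                     (z$modeD244 - refs$d244[i])^2)
    expect_lte(abs(z$modeD242[j] - refs$d242[i]), 0.5 + 1e-9)
    expect_lte(abs(z$modeD244[j] - refs$d244[i]), 0.5 + 1e-9)
  }
  expect_true(all(diff(z$population) <= 0))
})

test_that("zone detection degenerate and contract cases", {
  single <- findMetastableZones(data.frame(d242 = 3, d244 = 8))
  expect_equal(nrow(single), 1L)
  expect_equal(single$population, 1)

  set.seed(9)
  unif <- data.frame(d242 = runif(400, 0, 5), d244 = runif(400, 0, 5))
  z <- suppressWarnings(findMetastableZones(unif, minDensity = 0.9))
  expect_gte(nrow(z), 1L)
  expect_true(all(z$modeCount >= 0.9 * max(z$modeCount)))
  expect_error(findMetastableZones(data.frame(d242 = numeric(),
                                              d244 = numeric())),
               "empty")
})

test_that("reference configs load from YAML and validate", {
  f <- system.file("extdata", "state_references.yaml",
                   package = "NeilTriage")
  refs <- readStateReferences(f)
  expect_equal(refs$label, c("apo", "in242", "in244"))
  expect_equal(refs$d242[2], 3.0)
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("- label: apo", "  d242: 1", "  d244: 1",
               "- label: in242", "  d242: 1", "  d244: 1",
               "- label: in244", "  d242: 2", "  d244: 2"), bad)
  expect_error(readStateReferences(bad), "distinct")
})
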