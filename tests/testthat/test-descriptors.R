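test_that("d242 and d244 hit the constructed toy geometry exactly", {
  b2 <- toyBase(toyIn242)
  expect_equal(as.numeric(computeD242(toyIn242, "A", b2)), 3.0,
               tolerance = 1e-9)
  expect_equal(as.numeric(computeD244(toyIn242, "A", b2)), 8.0,
               tolerance = 1e-9)
  b4 <- toyBase(toyIn244)
  expect_equal(as.numeric(computeD244(toyIn244, "A", b4)), 3.6,
               tolerance = 1e-9)
  expect_gte(as.numeric(computeD242(toyIn244, "A", b4)), 7)
  ba <- toyBase(toyApo)
  expect_gte(as.numeric(computeD242(toyApo, "A", ba)), 9)
  expect_gte(as.numeric(computeD244(toyApo, "A", ba)), 9)
})

test_that("d242 equals the brute-force minimum over all atom pairs", {
  set.seed(101)
  for (rep in 1:40) {
    arg <- matrix(rnorm(5 * 3, sd = 4), 5, 3,
                  dimnames = list(c("CB", "CG", "NE", "NH1", "NH2"), NULL))
    base <- matrix(rnorm(8 * 3, sd = 4) + 10, 8, 3,
                   dimnames = list(c("N1", "C2", "N3", "C4", "C5", "C6",
                                     "O2", "O4"), NULL))
    m <- makePairModel(arg, base)
    got <- as.numeric(computeD242(m, "A", selectResidue(m, "B", 6)))
    ## oracle: exhaustive enumeration over Arg terminal N x base atoms
    oracle <- min(vapply(c("NE", "NH1", "NH2"), function(i)
      min(sqrt(rowSums(sweep(base, 2, arg[i, ])^2))), numeric(1)))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("truncated side chains yield not-available with a reason", {
  a <- toyIn242@atoms
  keep <- !(a$chain == "A" & a$resno == 242 &
              a$elety %in% c("CG", "CD", "CE", "NZ"))
  trunc <- NeilTriage:::.newStructureModel("trunc", a[keep, ])
  d <- computeD242(trunc, "A", toyBase(trunc))
  expect_true(is.na(d))
  expect_match(attr(d, "reason"), "truncated")
  hb <- detectTautomerHbond(trunc, "A", toyBase(trunc))
  expect_true(is.na(hb$hbond))
})

test_that("tautomer H-bond criterion is inclusive at the cutoff", {
  hb <- detectTautomerHbond(toyIn242, "A", toyBase(toyIn242))
  expect_true(hb$hbond)
  expect_equal(hb$distance, 3.0, tolerance = 1e-9)
  expect_equal(unname(hb$pair), c("NZ", "N3"))

  hbApo <- detectTautomerHbond(toyApo, "A", toyBase(toyApo))
  expect_false(hbApo$hbond)
  expect_gte(hbApo$distance, 9)

  ## boundary rule: a pair sitting exactly at the cutoff still counts
  mEdge <- genToyStructure("in242", d242 = 3.5)
  dEdge <- detectTautomerHbond(mEdge, "A", toyBase(mEdge))$distance
  expect_true(detectTautomerHbond(mEdge, "A", toyBase(mEdge),
                                  cutoff = dEdge)$hbond)
  expect_false(detectTautomerHbond(mEdge, "A", toyBase(mEdge),
                                   cutoff = dEdge - 1e-9)$hbond)
})

test_that("descriptors are invariant under rigid transforms of the model", {
  moved <- applyRigidModel(toyIn244, rotZ(77), c(12, -4, 9))
  b <- toyBase(moved)
  expect_equal(as.numeric(computeD242(moved, "A", b)), 8.0,
               tolerance = 1e-9)
  expect_equal(as.numeric(computeD244(moved, "A", b)), 3.6,
               tolerance = 1e-9)
  ## pure translation leaves d244 unchanged to 1e-9
  shifted <- applyRigidModel(toyIn244, diag(3), c(100, 50, -30))
  expect_equal(as.numeric(computeD244(shifted, "A", toyBase(shifted))),
               3.6, tolerance = 1e-9)
})

test_that("loop rotation angle recovers constructed rotations and is symmetric", {
  expect_equal(loopRotationAngle(toyIn242, toyIn242), 0, tolerance = 1e-9)
  expect_equal(loopRotationAngle(toyApo, toyIn242), 40, tolerance = 1e-6)
  expect_equal(loopRotationAngle(toyIn242, toyApo), 40, tolerance = 1e-6)
  m55 <- genToyStructure("apo", rotationDeg = 55)
  expect_equal(loopRotationAngle(m55, toyIn242), 55, tolerance = 1e-6)
  ## missing apex C-alpha -> not-available
  a <- toyIn242@atoms
  noApex <- NeilTriage:::.newStructureModel(
    "noapex", a[!(a$resno == 244 & a$elety == "CA"), ])
  expect_true(is.na(loopRotationAngle(noApex, toyIn242)))
})

test_that("shell water counting matches construction and is monotone in radius", {
  ## waters along +x beyond ring atom C6 at (1.39, 0, 0): min distance is
  ## the gap to C6 by construction
  din <- c(3, 3.3, 3.6, 3.9, 4.2, 4.5)
  dout <- c(7, 7.2, 7.4, 7.6)
  coords <- cbind(1.39 + c(din, dout), 0, 0)
  coords[, 2] <- seq_len(nrow(coords)) * 1e-4   # avoid duplicates
  m <- addWaters(toyIn242, coords)
  b <- toyBase(m)
  expect_equal(countShellWaters(m, b, radius = 5), 6L)
  expect_equal(countShellWaters(m, b, radius = 0), 0L)
  radii <- seq(0, 10, by = 0.5)
  counts <- vapply(radii, function(r) countShellWaters(m, b, r), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(max(counts), 10L)
})

test_that("delta-N-water reproduces constructed and Poisson differences", {
  edges <- seq(0, 10, by = 0.5)
  snapA <- replicate(20, c(3.0, 4.1, 6.2), simplify = FALSE)
  expect_true(all(deltaNWater(snapA, snapA, edges)$deltaN == 0))

  snapQ <- replicate(20, c(4.1, 6.2), simplify = FALSE)  # one fewer at 3 A
  d <- deltaNWater(snapA, snapQ, edges)
  expect_equal(d$deltaN[d$lower == 3.0], 1)
  expect_true(all(d$deltaN[d$lower != 3.0] == 0))

  ## Poisson oracle: hydrophilic (lambda 10) vs hydrophobic (lambda 6)
  set.seed(500)
  mk <- function(lam) replicate(500, runif(rpois(1, lam), 2.5, 5),
                                simplify = FALSE)
  dd <- deltaNWater(mk(10), mk(6), edges)
  shellSum <- sum(dd$deltaN[dd$lower >= 2.5 & dd$upper <= 5])
  se <- sqrt((10 + 6) / 500)
  expect_lt(abs(shellSum - 4), 3 * se)
  expect_error(deltaNWater(list(), mk(6), edges), "non-empty")
})

test_that("descriptor tables round-trip through CSV with empty-cell NAs", {
  rows <- rbind(
    computeLoopDescriptors(toyIn242, "A", "B", 6, reference = toyIn242),
    computeLoopDescriptors(toyApo, "A", "B", 6, reference = toyIn242))
  f <- tempfile(fileext = ".csv")
  writeDescriptorTable(rows, f)
  back <- readDescriptorTable(f)
  expect_equal(back$d242, rows$d242, tolerance = 1e-9)
  expect_equal(back$hbond, rows$hbond)
  expect_equal(back$rotationDeg, rows$rotationDeg, tolerance = 1e-6)
})
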