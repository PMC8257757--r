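## Synthetic-data generators with known ground truth for every pipeline
## stage: Boltzmann-weighted descriptor ensembles, one-phase-association
## time-course datasets, toy coordinate files realizing the three loop
## conformations, and solvation shells around a flipped base.
##
## The toy structures use idealized geometry (planar hexagonal rings,
## uniform bond lengths): they are descriptor fixtures with exactly known
## geometry, not chemically valid models.

## ---------------------------------------------------------------------------
## descriptor ensembles
## ---------------------------------------------------------------------------

#' Specify a synthetic conformational ensemble
#'
#' Three-component Gaussian mixture in the (d242, d244) plane with
#' Boltzmann-consistent component weights
#' \eqn{w_s \propto e^{-G_s/RT}}.
#'
#' @param centroids Data frame as [defaultStateReferences()] (label, d242,
#'   d244).
#' @param covariances List of 2 x 2 symmetric positive (semi-)definite
#'   matrices named by state label, or a single matrix recycled; an
#'   all-zero matrix is the allowed degenerate point-mass limit.  Default
#'   0.25 I (sd 0.5 A per axis), keeping the basins many sigma apart, as
#'   the well-separated crystallographic conformers are.
#' @param freeEnergies Named per-state free energies in kcal/mol (relative
#'   values only matter).  Use `-Inf`-free finite values; a state can be
#'   switched off by weight instead.
#' @param weights Optional explicit state weights (sum to 1); overrides
#'   `freeEnergies`.
#' @param temperature Kelvin.
#' @param n Number of snapshots (>= 1).
#' @param seed Optional integer seed.
#' @return A validated spec (list of class `ensemble_spec`).
#' @export
ensembleSpec <- function(centroids = defaultStateReferences(),
                         covariances = diag(0.25, 2),
                         freeEnergies = c(apo = 0, in242 = 0, in244 = 0),
                         weights = NULL, temperature = 298.15,
                         n = 3000L, seed = NULL) {
  centroids <- .validateReferences(centroids)
  labs <- centroids$label
  if (is.matrix(covariances)) {
    covariances <- setNames(rep(list(covariances), nrow(centroids)), labs)
  }
  for (s in labs) {
    cv <- covariances[[s]]
    if (is.null(cv) || !is.matrix(cv) || !all(dim(cv) == 2L) ||
        max(abs(cv - t(cv))) > 1e-12)
      stop("covariance for state ", s, " must be a symmetric 2x2 matrix",
           call. = FALSE)
    if (any(eigen(cv, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
      stop("covariance for state ", s, " is not positive semi-definite",
           call. = FALSE)
  }
  if (is.null(weights)) {
    g <- freeEnergies[labs]
    if (anyNA(g)) stop("freeEnergies must name every state", call. = FALSE)
    w <- exp(-(g - min(g)) / rtKcal(temperature))
    weights <- w / sum(w)
  } else {
    weights <- weights[labs]
    if (abs(sum(weights) - 1) > 1e-9)
      stop("weights must sum to 1", call. = FALSE)
  }
  stopifnot(n >= 1)
  structure(list(centroids = centroids, covariances = covariances,
                 weights = as.numeric(weights), temperature = temperature,
                 n = as.integer(n), seed = seed),
            class = "ensemble_spec")
}

#' Generate a Boltzmann-weighted descriptor ensemble
#'
#' Draws `n` snapshots: a state per snapshot by Boltzmann weight, then a
#' (d242, d244) pair from that state's Gaussian.  Truth labels are
#' retained so classification and free-energy recovery can be checked
#' against the generating parameters.
#'
#' @param spec An [ensembleSpec()].
#' @return Data frame with columns `d242`, `d244`, `label` (generating
#'   state); attribute `weights` carries the true state weights.
#' @examples
#' spec <- ensembleSpec(freeEnergies = c(apo = Inf, in242 = 0, in244 = 1),
#'                      n = 1000, seed = 1)
#' e <- genConformationalEnsemble(spec)
#' mean(e$label == "in242")  # ~ 1/(1 + exp(-1/RT)) = 0.844
#' @export
genConformationalEnsemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  labs <- spec$centroids$label
  withSeed(spec$seed, {
    lab <- sample(labs, spec$n, replace = TRUE, prob = spec$weights)
    xy <- matrix(NA_real_, spec$n, 2)
    for (s in labs) {
      idx <- which(lab == s)
      if (!length(idx)) next
      mu <- as.numeric(spec$centroids[spec$centroids$label == s,
                                      c("d242", "d244")])
      cv <- spec$covariances[[s]]
      xy[idx, ] <- if (max(abs(cv)) == 0) {
        matrix(mu, length(idx), 2, byrow = TRUE)
      } else {
        MASS::mvrnorm(length(idx), mu = mu, Sigma = cv)
      }
    }
    structure(data.frame(d242 = xy[, 1], d244 = xy[, 2], label = lab,
                         stringsAsFactors = FALSE),
              weights = setNames(spec$weights, labs))
  })
}

## ---------------------------------------------------------------------------
## kinetics datasets
## ---------------------------------------------------------------------------

#' Specify a synthetic single-turnover kinetics dataset
#'
#' One time-course per (parameter row x replicate); each row's observed
#' rate follows the auto-inhibition law,
#' \eqn{k_{obs} = k_{cat} / (1 + e^{(\Delta G_{conf} + \Delta
#' G_{chem})/RT})}.  Defaults mirror the single-turnover assay design:
#' the 13-point sampling schedule and three replicates.
#'
#' @param params Data frame with columns `variant`, `substrate`, `kcat`
#'   (min^-1), `dGconf`, `dGchem` (kcal/mol).
#' @param amplitude Reaction amplitude A in \[0, 1\] (default 0.9).
#' @param times Sampling grid in minutes.
#' @param noiseSd Additive Gaussian noise sd (default 0.02, a typical
#'   gel-densitometry scatter).
#' @param replicates Replicates per row (default 3).
#' @param temperature Kelvin.
#' @param seed Optional master seed; per-curve substreams are derived.
#' @return A validated spec (list of class `kinetics_spec`).
#' @export
kineticsSpec <- function(params, amplitude = 0.9,
                         times = defaultTimeGrid(), noiseSd = 0.02,
                         replicates = 3L, temperature = 298.15,
                         seed = NULL) {
  need <- c("variant", "substrate", "kcat", "dGconf", "dGchem")
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("params missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(diff(times) <= 0))
    stop("time grid must be strictly increasing", call. = FALSE)
  stopifnot(replicates >= 1, noiseSd >= 0,
            amplitude >= 0, amplitude <= 1)
  structure(list(params = params, amplitude = amplitude, times = times,
                 noiseSd = noiseSd, replicates = as.integer(replicates),
                 temperature = temperature, seed = seed),
            class = "kinetics_spec")
}

#' Generate a synthetic time-course dataset
#'
#' @param spec A [kineticsSpec()].
#' @return Long data frame with columns `variant`, `substrate`,
#'   `replicate`, `time_min`, `fraction_product`; attribute `truth` holds
#'   the generating per-row parameters (`kObs`, `A`).
#' @export
genTimecourseDataset <- function(spec) {
  stopifnot(inherits(spec, "kinetics_spec"))
  p <- spec$params
  dg <- p$dGconf + p$dGchem
  kObs <- p$kcat * activatedFraction(dg, spec$temperature)
  rows <- list(); ri <- 0L
  for (i in seq_len(nrow(p))) for (j in seq_len(spec$replicates)) {
    ri <- ri + 1L
    s <- if (is.null(spec$seed)) NULL else deriveSeed(spec$seed, ri)
    tc <- simulateTimecourse(spec$amplitude, kObs[i], times = spec$times,
                             noiseSd = spec$noiseSd, seed = s,
                             replicate = paste0("r", j))
    rows[[ri]] <- data.frame(
      variant = p$variant[i], substrate = p$substrate[i],
      replicate = paste0("r", j), time_min = assayTimes(tc),
      fraction_product = productFractions(tc), stringsAsFactors = FALSE)
  }
  truth <- data.frame(variant = p$variant, substrate = p$substrate,
                      kcat = p$kcat, dGconf = p$dGconf, dGchem = p$dGchem,
                      kObs = kObs, A = spec$amplitude,
                      stringsAsFactors = FALSE)
  structure(do.call(rbind, rows), truth = truth)
}

#' Write / read a time-course dataset as CSV with a truth sidecar
#'
#' @param x Data frame from [genTimecourseDataset()].
#' @param path CSV path; the truth sidecar goes to `truthPath`.
#' @param truthPath JSON sidecar path (default `path` + `.truth.json`).
#' @return Invisibly, `path`.  `readTimecourseCSV` returns the data frame
#'   (with the truth attribute re-attached when the sidecar exists).
#' @name timecourse-io
NULL

#' @rdname timecourse-io
#' @export
writeTimecourseCSV <- function(x, path,
                               truthPath = paste0(path, ".truth.json")) {
  utils::write.csv(x, path, row.names = FALSE)
  truth <- attr(x, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, truthPath, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname timecourse-io
#' @export
readTimecourseCSV <- function(path,
                              truthPath = paste0(path, ".truth.json")) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (file.exists(truthPath))
    attr(out, "truth") <- as.data.frame(jsonlite::fromJSON(truthPath))
  out
}

## ---------------------------------------------------------------------------
## toy coordinate fixtures
## ---------------------------------------------------------------------------

.hexRing <- function(center, radius = 1.39, normal = c(0, 0, 1),
                     names = .PYRIMIDINE_RING) {
  ## orthonormal frame perpendicular to `normal`
  n <- normal / sqrt(sum(normal^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n; u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  ang <- (seq_len(6) * 60) * pi / 180
  m <- t(vapply(ang, function(th)
    center + radius * (cos(th) * u + sin(th) * v), numeric(3)))
  rownames(m) <- names
  m
}

.atomRow <- function(chain, resno, resid, elety, xyz, type = "ATOM") {
  data.frame(chain = chain, resno = as.integer(resno), resid = resid,
             elety = elety, elesy = substr(gsub("[0-9]", "", elety), 1, 1),
             x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, alt = "",
             type = type, water = FALSE, stringsAsFactors = FALSE)
}

## rotate points about an axis (point p0, unit direction u) by theta (rad)
.rotateAboutAxis <- function(xyz, p0, u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  sweep(sweep(xyz, 2, p0) %*% t(R), 2, p0, "+")
}

#' Generate a toy structure realizing one loop conformation
#'
#' Builds a minimal coordinate model containing a flipped pyrimidine-like
#' base (hexagonal ring plus two exocyclic oxygens, chain B residue 6), the
#' recognition-loop backbone (C-alpha trace, residues 240-249 in chain A,
#' Lys at 242 and Tyr at 244 with explicit side chains), and a rigid
#' C-alpha core outside the loop for superposition.  Side chains are placed
#' so the computed descriptors equal the requested values exactly:
#'
#' * `"in242"` (activated): the Lys242 NZ sits `d242` (default 3.0 A, the
#'   crystallographic contact) from the nearest base ring nitrogen; Tyr244
#'   is swung out to `d244` (default 8 A).
#' * `"in244"` (quarantine): the Tyr244 ring stacks parallel over the base
#'   at `d244` (default 3.6 A); the Lys side chain is displaced to `d242`
#'   (default 8 A).
#' * `"apo"`: the whole loop of the in242 template is rotated by
#'   `rotationDeg` (default 40) about the Calpha240-Calpha249 hinge axis,
#'   leaving both contacts beyond 9 A.
#'
#' Construction is verified numerically; an infeasible parameter
#' combination is an error, never a silently wrong fixture.
#'
#' @param state `"in242"`, `"in244"` or `"apo"`.
#' @param d242,d244 Target descriptor values in Angstrom (state-dependent
#'   defaults as above).
#' @param rotationDeg Loop rotation for the apo state, degrees.
#' @param path Optional output PDB path; the model is also returned.
#' @return A [StructureModel-class] (invisibly when `path` is given).
#' @examples
#' m <- genToyStructure("in242")
#' computeD242(m, "A", selectResidue(m, "B", 6))  # exactly 3.0
#' @export
genToyStructure <- function(state = c("in242", "in244", "apo"),
                            d242 = NULL, d244 = NULL, rotationDeg = 40,
                            path = NULL) {
  state <- match.arg(state)
  d242 <- if (is.null(d242)) switch(state, in242 = 3.0, in244 = 8.0,
                                    apo = 3.0) else d242
  d244 <- if (is.null(d244)) switch(state, in242 = 8.0, in244 = 3.6,
                                    apo = 8.0) else d244
  if (d242 < 1 || d244 < 1)
    stop("infeasible distance combination: targets below contact range",
         call. = FALSE)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- .atomRow(...)

  ## flipped base, chain B residue 6: ring in the z = 0 plane centered at
  ## the origin, N3 pointing along -x toward the loop
  ringAng <- c(N1 = 60, C2 = 120, N3 = 180, C4 = 240, C5 = 300, C6 = 0)
  for (nm in names(ringAng)) {
    th <- ringAng[[nm]] * pi / 180
    add("B", 6, "DHU", nm, 1.39 * c(cos(th), sin(th), 0), type = "HETATM")
  }
  for (o in list(c("O2", 120), c("O4", 240))) {
    th <- as.numeric(o[2]) * pi / 180
    add("B", 6, "DHU", o[1], 2.62 * c(cos(th), sin(th), 0), type = "HETATM")
  }

  ## rigid core C-alpha scaffold outside the loop (non-collinear)
  corePos <- rbind(
    cbind(20 + 0:5, -12, c(0, 1, -1, 2, -2, 0.5)),
    cbind(20 + 0:5, -16, c(1, -1, 0, 2, 0.5, -2)))
  coreRes <- c(225:230, 252:257)
  for (i in seq_along(coreRes))
    add("A", coreRes[i], "GLY", "CA", corePos[i, ])

  ## loop C-alpha trace, hinge on the axis x = 14, y = 0 (along z)
  hingeA <- c(14, 0, -6); hingeB <- c(14, 0, 6)
  nzX <- -(1.39 + d242)
  caPos <- list(
    `240` = hingeA,
    `241` = c(8, 1, -4),
    `242` = c(nzX - 7.5, 0, 0),
    `243` = c(2, 5, -1),
    `244` = c(0, d244 + 1.5, 0),
    `245` = c(4, 6, 1),
    `246` = c(7, 5, 2),
    `247` = c(10, 4, 3),
    `248` = c(12, 2, 4.5),
    `249` = hingeB)
  resNames <- c(`242` = "LYS", `244` = "TYR")
  for (rn in names(caPos)) {
    add("A", as.integer(rn),
        if (rn %in% names(resNames)) resNames[[rn]] else "GLY",
        "CA", caPos[[rn]])
  }
  ## Lys242 side chain strung along -x, NZ closest to the base
  scX <- c(CB = -6, CG = -4.5, CD = -3, CE = -1.5, NZ = 0)
  for (nm in names(scX)) add("A", 242, "LYS", nm, c(nzX + scX[[nm]], 0, 0))
  ## Tyr244 ring
  tyrCenter <- if (state == "in244") c(0, 0, d244) else c(0, d244, 0)
  tyrNormal <- if (state == "in244") c(0, 0, 1) else c(0, 1, 0)
  ring <- .hexRing(tyrCenter, normal = tyrNormal, names = .TYR_RING)
  for (nm in rownames(ring)) add("A", 244, "TYR", nm, ring[nm, ])
  add("A", 244, "TYR", "CB", tyrCenter + 2.5 * tyrNormal)

  atoms <- do.call(rbind, rows)
  if (state == "in244") {
    ## in244 apex follows the stacked ring
    atoms[atoms$resno == 244 & atoms$elety == "CA", c("x", "y", "z")] <-
      tyrCenter + c(0, 1.5, 1.5)
  }
  if (state == "apo") {
    sel <- atoms$chain == "A" & atoms$resno >= 240 & atoms$resno <= 249
    xyz <- as.matrix(atoms[sel, c("x", "y", "z")])
    atoms[sel, c("x", "y", "z")] <-
      .rotateAboutAxis(xyz, hingeA, hingeB - hingeA,
                       -rotationDeg * pi / 180)
  }
  model <- .newStructureModel(paste0("toy_", state), atoms)

  ## verify construction against the requested geometry
  base <- selectResidue(model, "B", 6)
  got242 <- as.numeric(computeD242(model, "A", base))
  got244 <- as.numeric(computeD244(model, "A", base))
  if (state %in% c("in242", "in244")) {
    if (abs(got242 - d242) > 1e-9 || abs(got244 - d244) > 1e-9)
      stop(sprintf(
        "infeasible distance combination: realized (%.3f, %.3f) != requested (%.3f, %.3f)",
        got242, got244, d242, d244), call. = FALSE)
  } else {
    if (got242 < 9 || got244 < 9)
      stop(sprintf(
        "infeasible apo construction: contacts (%.2f, %.2f) not beyond 9 A after %g deg rotation",
        got242, got244, rotationDeg), call. = FALSE)
  }
  if (!is.null(path)) {
    writeStructurePDB(model, path)
    return(invisible(model))
  }
  model
}

## ---------------------------------------------------------------------------
## solvation shells
## ---------------------------------------------------------------------------

#' Add a synthetic solvation shell around the flipped base
#'
#' Draws a Poisson(`expectedInShell`) number of water oxygens whose minimum
#' distance to the base heavy atoms falls inside `shell`, plus a fixed
#' far-field set well outside it, so the in-shell count of the generated
#' model is known exactly.
#'
#' @param model A [StructureModel-class] containing the base (default: the
#'   activated toy conformer).
#' @param expectedInShell Poisson mean of the in-shell water count.
#' @param shell Length-2 vector (rMin, rMax) in Angstrom; default
#'   c(2.5, 5), the 5-A shell examined around damaged bases.
#' @param nFarField Number of waters placed beyond the shell (default 4).
#' @param baseChain,baseResno Location of the base residue.
#' @param seed Optional integer seed.
#' @param path Optional PDB output path; a JSON sidecar `path.truth.json`
#'   records the in-shell bookkeeping.
#' @return A list with `model` (waters appended) and `nInShell` (the
#'   generator's in-shell count).
#' @export
genSolvationShell <- function(model = genToyStructure("in242"),
                              expectedInShell = 10, shell = c(2.5, 5.0),
                              nFarField = 4L, baseChain = "B",
                              baseResno = 6, seed = NULL, path = NULL) {
  stopifnot(expectedInShell >= 0, length(shell) == 2L, shell[1] < shell[2],
            shell[1] >= 0)
  base <- selectResidue(model, baseChain, baseResno)
  B <- .baseHeavyCoords(base)
  minDist <- function(p) {
    sqrt(min(rowSums(sweep(B, 2, p)^2)))
  }
  randDir <- function() {
    repeat {
      v <- stats::rnorm(3)
      nv <- sqrt(sum(v^2))
      if (nv > 1e-12) return(v / nv)
    }
  }
  out <- withSeed(seed, {
    nIn <- stats::rpois(1, expectedInShell)
    pts <- list()
    while (length(pts) < nIn) {
      anchor <- B[sample(nrow(B), 1), ]
      r <- (stats::runif(1) * (shell[2]^3 - shell[1]^3) + shell[1]^3)^(1 / 3)
      p <- anchor + r * randDir()
      md <- minDist(p)
      if (md >= shell[1] && md <= shell[2])
        pts[[length(pts) + 1L]] <- p
    }
    far <- list()
    ctr <- colMeans(B)
    while (length(far) < nFarField) {
      p <- ctr + (shell[2] + 5) * randDir()
      if (minDist(p) > shell[2] + 2) far[[length(far) + 1L]] <- p
    }
    list(nIn = nIn, pts = pts, far = far)
  })
  wrows <- lapply(seq_along(c(out$pts, out$far)), function(i) {
    p <- c(out$pts, out$far)[[i]]
    r <- .atomRow("W", 1000L + i, "HOH", "O", p, type = "HETATM")
    r$water <- TRUE
    r
  })
  atoms <- rbind(model@atoms, do.call(rbind, wrows))
  solvated <- .newStructureModel(paste0(model@identifier, "_solv"), atoms)
  if (!is.null(path)) {
    writeStructurePDB(solvated, path)
    jsonlite::write_json(list(nInShell = out$nIn, shell = shell),
                         paste0(path, ".truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(model = solvated, nInShell = out$nIn)
}
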