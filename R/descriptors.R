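## Geometric descriptors operationalizing the three lesion-recognition-loop
## conformations: d242 (residue-242 terminal N to flipped-base heavy atoms),
## d244 (residue-244 ring centroid to base ring centroid), the
## tautomerization-dependent H-bond flag, the hinge rotation angle about
## Gly240-Gly249, and solvation-shell water counts.

## Terminal side-chain nitrogens by residue type at position 242.  The wild
## type carries Lys (unedited) or Arg (RNA-edited); His covers the R242H
## mutant studied biochemically.
.TERMINAL_N <- list(
  LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2"))

.BACKBONE <- c("N", "CA", "C", "O", "OXT")

## Heterocyclic ring atom names per nucleotide/lesion residue name.  Lesions
## preserving the pyrimidine ring (dihydro, glycol, 5-hydroxy) keep the
## canonical names; ring-rearranged hydantoins (Sp/Gh) have no canonical ring
## and fall back to all base heavy atoms, flagged.
.PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")
.PURINE_RING <- c(.PYRIMIDINE_RING, "N7", "C8", "N9")
.BASE_RING <- c(
  setNames(rep(list(.PYRIMIDINE_RING), 14),
           c("DT", "T", "THY", "DU", "U", "URA", "DC", "C", "CYT",
             "DHU", "DHT", "5OU", "OHU", "TG")),
  setNames(rep(list(.PURINE_RING), 6),
           c("DA", "A", "ADE", "DG", "G", "GUA")))

.TYR_RING <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

## sugar/phosphate atoms are not part of the flipped base
.isBaseAtom <- function(elety) {
  !grepl("'", elety, fixed = TRUE) &
    !(elety %in% c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P"))
}

.baseHeavyCoords <- function(base) {
  a <- base@atoms
  a <- a[.isBaseAtom(a$elety) & a$elesy != "H", , drop = FALSE]
  if (nrow(a) == 0L)
    stop("base residue ", base@resid, base@resno, " has no base heavy atoms",
         call. = FALSE)
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$elety
  m
}

.sideChainCoords <- function(view) {
  a <- view@atoms
  a <- a[!(a$elety %in% .BACKBONE), , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z"), drop = FALSE])
  rownames(m) <- a$elety
  m
}

.minPairDist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  list(dist = sqrt(d2[ij[1], ij[2]]),
       pair = c(rownames(A)[ij[1]], rownames(B)[ij[2]]))
}

.naWithReason <- function(reason) {
  structure(NA_real_, reason = reason)
}

## coordinates of the terminal side-chain N atoms of the interrogation
## residue; NULL with reason attribute when the side chain is unusable
.terminalNCoords <- function(view) {
  sc <- .sideChainCoords(view)
  if (nrow(sc) == 0L || all(rownames(sc) %in% "CB"))
    return(structure(list(), reason = paste0(
      "side chain of ", view@resid, view@resno,
      " truncated; terminal atoms unavailable")))
  want <- .TERMINAL_N[[view@resid]]
  if (!is.null(want)) {
    hit <- intersect(want, rownames(sc))
    if (length(hit) == 0L)
      return(structure(list(), reason = paste0(
        "terminal N atom(s) ", paste(want, collapse = "/"),
        " missing from ", view@resid, view@resno)))
    return(sc[hit, , drop = FALSE])
  }
  ns <- sc[grepl("^N", rownames(sc)), , drop = FALSE]
  if (nrow(ns) > 0L) ns else sc
}

#' Distance from the residue-242 terminal nitrogen(s) to the flipped base
#'
#' Minimum heavy-atom distance between the terminal side-chain nitrogen
#' atoms of the loop interrogation residue (Lys: NZ; Arg: NE/NH1/NH2; His:
#' ND1/NE2; other types fall back to side-chain nitrogens, then to all
#' side-chain heavy atoms) and the heavy atoms of the flipped base.  In the
#' activated (242-in) crystal conformation this contact sits at ~3.0 A; in
#' the apo conformation the side chain is displaced beyond 9 A.
#'
#' @param model A [StructureModel-class].
#' @param loopChain Chain holding the recognition loop.
#' @param base A [ResidueView-class] over the flipped-base nucleotide.
#' @param resno Residue number of the interrogation residue (default 242,
#'   full-length numbering).
#' @return Distance in Angstrom, or `NA` with a `"reason"` attribute when the
#'   side chain is truncated.
#' @examples
#' m <- genToyStructure("in242")
#' computeD242(m, "A", selectResidue(m, "B", 6))  # 3.0
#' @export
computeD242 <- function(model, loopChain, base, resno = 242) {
  stopifnot(is(base, "ResidueView"))
  view <- selectResidue(model, loopChain, resno)
  tn <- .terminalNCoords(view)
  if (is.list(tn) && length(tn) == 0L)
    return(.naWithReason(attr(tn, "reason")))
  hit <- .minPairDist(tn, .baseHeavyCoords(base))
  structure(hit$dist, pair = hit$pair)
}

#' Ring-centroid distance between residue 244 and the flipped base
#'
#' Distance between the mean position of the residue-244 aromatic ring atoms
#' (Tyr: CG/CD1/CD2/CE1/CE2/CZ) and the centroid of the base heterocyclic
#' ring.  In the quarantine (244-in) conformation Tyr244 stacks on the base
#' at van der Waals contact (~3.6 A); in the activated conformation it is
#' swung away.  A non-aromatic residue at 244 falls back to its side-chain
#' centroid, flagged with attribute `fallback`; a base with no canonical
#' ring-name set falls back to all base heavy atoms, flagged likewise.
#'
#' @inheritParams computeD242
#' @param resno Residue number of the stacking residue (default 244).
#' @return Distance in Angstrom (possibly with a `fallback` attribute), or
#'   `NA` with a `"reason"` attribute.
#' @export
computeD244 <- function(model, loopChain, base, resno = 244) {
  stopifnot(is(base, "ResidueView"))
  view <- selectResidue(model, loopChain, resno)
  sc <- .sideChainCoords(view)
  fallback <- FALSE
  ringNames <- intersect(.TYR_RING, rownames(sc))
  if (length(ringNames) == length(.TYR_RING)) {
    resRing <- sc[ringNames, , drop = FALSE]
  } else {
    if (nrow(sc) == 0L)
      return(.naWithReason(paste0("no side-chain atoms in ",
                                  view@resid, view@resno)))
    resRing <- sc
    fallback <- TRUE
  }
  bh <- .baseHeavyCoords(base)
  ring <- .BASE_RING[[base@resid]]
  if (!is.null(ring) && all(ring %in% rownames(bh))) {
    baseRing <- bh[ring, , drop = FALSE]
  } else {
    baseRing <- bh
    fallback <- TRUE
  }
  d <- sqrt(sum((colMeans(resRing) - colMeans(baseRing))^2))
  if (fallback) structure(d, fallback = TRUE) else d
}

#' Detect the tautomerization-dependent hydrogen bond
#'
#' Geometry-only criterion for the key hydrogen bond between the terminal
#' nitrogen of residue 242 and a ring-position N/O atom of the flipped base:
#' flag = (minimum donor-acceptor heavy-atom distance <= cutoff, inclusive).
#' No angle term is applied because X-ray models carry no hydrogens; the
#' contact observed crystallographically sits at ~3.0 A.
#'
#' @inheritParams computeD242
#' @param cutoff Donor-acceptor heavy-atom cutoff in Angstrom (default 3.5).
#' @return A list with `hbond` (logical), `distance` (Angstrom) and `pair`
#'   (the minimizing atom names).  When the side chain is truncated,
#'   `hbond = NA` and `reason` is set.
#' @export
detectTautomerHbond <- function(model, loopChain, base, cutoff = 3.5,
                                resno = 242) {
  stopifnot(is(base, "ResidueView"))
  view <- selectResidue(model, loopChain, resno)
  tn <- .terminalNCoords(view)
  if (is.list(tn) && length(tn) == 0L)
    return(list(hbond = NA, distance = NA_real_, pair = NULL,
                reason = attr(tn, "reason")))
  bh <- .baseHeavyCoords(base)
  ring <- .BASE_RING[[base@resid]]
  acceptorNames <- if (!is.null(ring) && all(ring %in% rownames(bh))) {
    ring[grepl("^[NO]", ring)]
  } else {
    rownames(bh)[grepl("^[NO]", rownames(bh))]
  }
  if (length(acceptorNames) == 0L)
    return(list(hbond = NA, distance = NA_real_, pair = NULL,
                reason = "base has no N/O acceptor atoms"))
  hit <- .minPairDist(tn, bh[acceptorNames, , drop = FALSE])
  list(hbond = hit$dist <= cutoff, distance = hit$dist, pair = hit$pair)
}

#' Loop rotation angle about the Gly240-Gly249 hinge
#'
#' Measures how far the lesion-recognition loop has swung between two
#' structures.  Both models are first superposed on the protein core (all
#' shared C-alpha atoms outside the hinge residue range); the loop plane is
#' then taken through the C-alpha atoms of the two hinge residues and the
#' apex residue 244, and the angle between the two planes is measured about
#' the hinge C-alpha axis.  The apo loop sits ~40 degrees away from the
#' DNA-bound conformations by this measure.
#'
#' This plane-through-apex construction is one explicit operationalization
#' of the loop swing among several possible; it is exact for rigid rotations
#' of the loop about the hinge axis.
#'
#' @param model,reference [StructureModel-class] objects to compare.
#' @param hinge Length-2 residue numbers of the hinge glycines (default
#'   c(240, 249)).
#' @param apex Residue number defining the loop plane (default 244).
#' @param chain,refChain Chains holding the loop in `model` / `reference`;
#'   `NULL` auto-detects the chain containing C-alpha atoms at the hinge and
#'   apex positions.
#' @return Angle in degrees in \[0, 180\], or `NA` with a `"reason"` attribute
#'   when required C-alpha atoms are missing.
#' @export
loopRotationAngle <- function(model, reference, hinge = c(240, 249),
                              apex = 244, chain = NULL, refChain = NULL) {
  stopifnot(length(hinge) == 2L)
  findChain <- function(m) {
    a <- m@atoms
    ca <- a[a$elety == "CA" & a$resno %in% c(hinge, apex), ]
    for (ch in unique(ca$chain))
      if (all(c(hinge, apex) %in% ca$resno[ca$chain == ch])) return(ch)
    NULL
  }
  if (is.null(chain)) chain <- findChain(model)
  if (is.null(refChain)) refChain <- findChain(reference)
  if (is.null(chain) || is.null(refChain))
    return(.naWithReason("hinge/apex C-alpha atoms not found in one model"))
  caOf <- function(m, ch, resno) {
    a <- m@atoms
    sel <- a$chain == ch & a$resno == resno & a$elety == "CA"
    if (!any(sel)) return(NULL)
    as.numeric(a[which(sel)[1], c("x", "y", "z")])
  }
  loopRange <- seq(min(hinge), max(hinge))
  am <- model@atoms; ar <- reference@atoms
  coreM <- am[am$elety == "CA" & !(am$resno %in% loopRange) &
                am$chain == chain, c("chain", "resno")]
  coreR <- ar[ar$elety == "CA" & !(ar$resno %in% loopRange) &
                ar$chain == refChain, c("resno")]
  shared <- intersect(coreM$resno, coreR)
  if (length(shared) < 3L)
    return(.naWithReason("fewer than 3 shared core C-alpha atoms"))
  selM <- data.frame(chain = chain, resno = shared, elety = "CA",
                     stringsAsFactors = FALSE)
  fitted <- if (identical(chain, refChain)) {
    superposeStructures(model, reference, selM)$model
  } else {
    ## align across differing chain ids by renaming the mobile loop chain
    tmp <- model@atoms
    tmp$chain[tmp$chain == chain] <- refChain
    m2 <- .newStructureModel(model@identifier, tmp)
    selM$chain <- refChain
    superposeStructures(m2, reference, selM)$model
  }
  fitChain <- if (identical(chain, refChain)) chain else refChain
  h1 <- caOf(reference, refChain, hinge[1])
  h2 <- caOf(reference, refChain, hinge[2])
  apR <- caOf(reference, refChain, apex)
  apM <- caOf(fitted, fitChain, apex)
  h1m <- caOf(fitted, fitChain, hinge[1])
  if (is.null(h1) || is.null(h2) || is.null(apR) || is.null(apM))
    return(.naWithReason("missing hinge or apex C-alpha"))
  u <- (h2 - h1) / sqrt(sum((h2 - h1)^2))
  proj <- function(v) v - sum(v * u) * u
  vR <- proj(apR - h1)
  vM <- proj(apM - h1m)
  nR <- sqrt(sum(vR^2)); nM <- sqrt(sum(vM^2))
  if (nR < 1e-9 || nM < 1e-9)
    return(.naWithReason("apex lies on the hinge axis; angle undefined"))
  cosang <- sum(vR * vM) / (nR * nM)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Count waters in the solvation shell of the flipped base
#'
#' Number of water oxygen atoms whose minimum distance to any base heavy
#' atom is at most `radius` (default 5 A, the shell examined around damaged
#' bases in the crystal structures).
#'
#' @inheritParams computeD242
#' @param radius Shell radius in Angstrom (default 5.0).
#' @return Integer count (0 is a valid result).
#' @export
countShellWaters <- function(model, base, radius = 5.0) {
  stopifnot(is(model, "StructureModel"), is(base, "ResidueView"),
            radius >= 0)
  w <- solventRecords(model)
  w <- w[grepl("^O", w$elety), , drop = FALSE]
  if (nrow(w) == 0L) return(0L)
  W <- as.matrix(w[, c("x", "y", "z")])
  B <- .baseHeavyCoords(base)
  d2 <- outer(rowSums(W^2), rowSums(B^2), "+") - 2 * W %*% t(B)
  d2[d2 < 0] <- 0
  sum(sqrt(apply(d2, 1, min)) <= radius)
}

#' Mean per-bin difference in water counts between two ensembles
#'
#' For the desolvation analysis: given per-snapshot vectors of
#' water-to-base distances for an activated-state (242-in) ensemble and a
#' quarantine-state (244-in) ensemble, computes per distance bin
#' \eqn{\Delta N_{water}} = mean count (activated) - mean count
#' (quarantine).  Positive values mean waters are stripped from the base on
#' entering the quarantine state.
#'
#' @param ensembleA,ensembleQ Lists of numeric vectors (one vector of water
#'   distances in Angstrom per snapshot) for the 242-in and 244-in
#'   ensembles.
#' @param binEdges Strictly increasing bin edges in Angstrom.
#' @return Data frame with columns `lower`, `upper`, `deltaN`.
#' @export
deltaNWater <- function(ensembleA, ensembleQ,
                        binEdges = seq(0, 10, by = 0.5)) {
  if (length(ensembleA) == 0L || length(ensembleQ) == 0L)
    stop("both ensembles must be non-empty", call. = FALSE)
  if (any(diff(binEdges) <= 0))
    stop("binEdges must be strictly increasing", call. = FALSE)
  ## left-closed bins [lower, upper); the final edge is included
  countsOf <- function(v)
    hist(v[v >= binEdges[1] & v <= binEdges[length(binEdges)]],
         breaks = binEdges, plot = FALSE, right = FALSE,
         include.lowest = TRUE)$counts
  mA <- rowMeans(vapply(ensembleA, countsOf,
                        numeric(length(binEdges) - 1L)))
  mQ <- rowMeans(vapply(ensembleQ, countsOf,
                        numeric(length(binEdges) - 1L)))
  data.frame(lower = binEdges[-length(binEdges)], upper = binEdges[-1],
             deltaN = mA - mQ)
}

#' Compute the full loop/lesion descriptor row for one structure
#'
#' Convenience wrapper assembling d242, d244, the H-bond call, the loop
#' rotation angle versus an optional reference model, and the shell water
#' count into a one-row data frame matching the descriptor-table schema.
#'
#' @inheritParams computeD242
#' @param baseChain,baseResno Location of the flipped-base nucleotide.
#' @param reference Optional [StructureModel-class] for the rotation angle.
#' @param hbondCutoff H-bond heavy-atom cutoff in Angstrom.
#' @param shellRadius Water-shell radius in Angstrom.
#' @return One-row data frame: source, d242, d244, hbond, hbondDist,
#'   rotationDeg, nWatersShell.  Unavailable values are `NA`.
#' @export
computeLoopDescriptors <- function(model, loopChain, baseChain, baseResno,
                                   reference = NULL, hbondCutoff = 3.5,
                                   shellRadius = 5.0) {
  base <- selectResidue(model, baseChain, baseResno)
  hb <- detectTautomerHbond(model, loopChain, base, cutoff = hbondCutoff)
  rot <- if (is.null(reference)) NA_real_
         else as.numeric(loopRotationAngle(model, reference))
  data.frame(
    source = structureId(model),
    d242 = as.numeric(computeD242(model, loopChain, base)),
    d244 = as.numeric(computeD244(model, loopChain, base)),
    hbond = hb$hbond,
    hbondDist = hb$distance,
    rotationDeg = rot,
    nWatersShell = countShellWaters(model, base, radius = shellRadius),
    stringsAsFactors = FALSE)
}

#' Read/write descriptor tables
#'
#' Descriptor tables are CSV files with one row per structure or snapshot
#' and columns matching the descriptor schema; unavailable values are empty
#' cells.
#'
#' @param x Data frame of descriptors.
#' @param path CSV file path.
#' @return `readDescriptorTable` returns a data frame;
#'   `writeDescriptorTable` invisibly returns `path`.
#' @name descriptor-io
NULL

#' @rdname descriptor-io
#' @export
writeDescriptorTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname descriptor-io
#' @export
readDescriptorTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
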