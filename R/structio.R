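## Coordinate-file input/output, residue selection and rigid-body
## superposition.  Reading goes through bio3d (PDB and mmCIF); the minimal
## fixed-width PDB writer used for fixtures is local.

.WATER_NAMES <- c("HOH", "WAT", "H2O")

.newStructureModel <- function(identifier, atoms) {
  rownames(atoms) <- NULL
  new("StructureModel", identifier = identifier, atoms = atoms)
}

## Resolve alternate locations: keep the highest-occupancy conformer per
## atom, ties broken by altloc letter order.  Deterministic by construction.
.resolveAltloc <- function(atoms) {
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  atoms$alt <- alt
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  key <- key[ord]
  atoms[!duplicated(key), , drop = FALSE]
}

#' Read a macromolecular structure
#'
#' Parses a PDB or mmCIF file into a [StructureModel-class].  Hydrogens are
#' dropped (crystallographic models rarely contain them and all package
#' geometry is heavy-atom based), alternate locations are resolved to the
#' highest-occupancy conformer (ties by altloc letter), and residues named
#' HOH/WAT/H2O are flagged as solvent.
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (default; decided by file
#'   extension, `.cif`/`.mmcif` meaning mmCIF).
#' @return A [StructureModel-class].
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' genToyStructure("in242", path = f)
#' m <- readStructure(f)
#' m
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("coordinate file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e)
      stop(sprintf("failed to parse '%s' as %s: %s",
                   path, format, conditionMessage(e)), call. = FALSE))
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0L)
    stop("empty model: no atom records in ", path, call. = FALSE)
  elesy <- a$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(a))
  miss <- is.na(elesy) | elesy == ""
  elesy[miss] <- substr(gsub("[^A-Za-z].*$", "", a$elety[miss]), 1, 1)
  chain <- a$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(
    chain = as.character(chain),
    resno = as.integer(a$resno),
    resid = as.character(a$resid),
    elety = as.character(a$elety),
    elesy = toupper(as.character(elesy)),
    x = as.numeric(a$x), y = as.numeric(a$y), z = as.numeric(a$z),
    occ = ifelse(is.na(a$o), 1, as.numeric(a$o)),
    alt = as.character(a$alt),
    type = as.character(a$type),
    stringsAsFactors = FALSE)
  atoms <- atoms[atoms$elesy != "H" & atoms$elesy != "D", , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("empty model after hydrogen removal: ", path, call. = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path, call. = FALSE)
  atoms <- .resolveAltloc(atoms)
  atoms$water <- atoms$resid %in% .WATER_NAMES
  id <- sub("\\.[^.]*$", "", basename(path))
  .newStructureModel(id, atoms)
}

#' Write a StructureModel as a minimal PDB file
#'
#' Emits plain ATOM/HETATM records with 3-decimal coordinates — sufficient
#' for fixture round-trips and external viewers; no header, symmetry or
#' connectivity records.
#'
#' @param model A [StructureModel-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeStructurePDB <- function(model, path) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  name4 <- ifelse(nchar(a$elety) < 4L, sprintf(" %-3s", a$elety),
                  sprintf("%-4s", a$elety))
  rec <- sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 ifelse(a$type == "HETATM", "HETATM", "ATOM"),
                 seq_len(nrow(a)), name4, "", a$resid, a$chain, a$resno,
                 a$x, a$y, a$z, a$occ, 0, a$elesy)
  writeLines(c(rec, "END"), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## accessors
## ---------------------------------------------------------------------------

#' StructureModel accessors
#'
#' `atomRecords()` returns the non-solvent atom table, `solventRecords()`
#' the water records, and `structureId()` the model label.
#'
#' @param x A [StructureModel-class].
#' @return A data frame of atom records, or a character label.
#' @name StructureModel-accessors
#' @aliases atomRecords solventRecords structureId
NULL

#' @rdname StructureModel-accessors
setMethod("atomRecords", "StructureModel",
          function(x) x@atoms[!x@atoms$water, , drop = FALSE])

#' @rdname StructureModel-accessors
setMethod("solventRecords", "StructureModel",
          function(x) x@atoms[x@atoms$water, , drop = FALSE])

#' @rdname StructureModel-accessors
setMethod("structureId", "StructureModel", function(x) x@identifier)

## ---------------------------------------------------------------------------
## residue selection
## ---------------------------------------------------------------------------

#' Select one residue as a read-only view
#'
#' @param model A [StructureModel-class].
#' @param chain Chain identifier.
#' @param resno Author residue number (full-length hNEIL1 numbering for the
#'   recognition-loop residues: 240, 242, 244, 249).
#' @return A [ResidueView-class].
#' @examples
#' m <- genToyStructure("in242")
#' selectResidue(m, "A", 242)
#' @export
selectResidue <- function(model, chain, resno) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  sel <- a$chain == chain & a$resno == resno
  if (!any(sel)) {
    avail <- sort(unique(a$resno[a$chain == chain]))
    stop(sprintf(
      "residue %s not found in chain '%s'; available residue numbers: %s",
      resno, chain,
      if (length(avail)) paste(avail, collapse = ", ") else "<none>"),
      call. = FALSE)
  }
  sub <- a[sel, , drop = FALSE]
  new("ResidueView", chain = as.character(chain), resno = as.integer(resno),
      resid = sub$resid[1], atoms = sub)
}

#' Coordinates of named atoms in a residue view
#'
#' @param view A [ResidueView-class].
#' @param names Atom names to extract; `NULL` returns all atoms.  A missing
#'   atom is an explicit error.
#' @return Numeric matrix with one row per atom and columns x, y, z.
#' @export
atomCoords <- function(view, names = NULL) {
  stopifnot(is(view, "ResidueView"))
  a <- view@atoms
  if (is.null(names)) {
    m <- as.matrix(a[, c("x", "y", "z")])
    rownames(m) <- a$elety
    return(m)
  }
  idx <- match(names, a$elety)
  if (anyNA(idx))
    stop(sprintf("atom(s) %s not present in %s %d (chain %s); has: %s",
                 paste(names[is.na(idx)], collapse = ", "),
                 view@resid, view@resno, view@chain,
                 paste(a$elety, collapse = ", ")), call. = FALSE)
  m <- as.matrix(a[idx, c("x", "y", "z"), drop = FALSE])
  rownames(m) <- names
  m
}

## ---------------------------------------------------------------------------
## superposition
## ---------------------------------------------------------------------------

#' Plain coordinate RMSD (no fitting)
#'
#' Root-mean-square deviation between two already-aligned coordinate sets.
#'
#' @param a,b Numeric n x 3 matrices with matched rows.
#' @return RMSD in Angstrom.
#' @export
coordRmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3L, identical(dim(a), dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

## Kabsch: rotation + translation mapping P (mobile) onto Q (reference),
## both n x 3.  Returns list(rotation, translation).
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (svd(Qc)$d[2] < 1e-8 || svd(Pc)$d[2] < 1e-8)
    stop("superposition selection is (near-)collinear; ",
         ">= 3 non-collinear paired atoms required", call. = FALSE)
  s <- svd(t(Pc) %*% Qc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, translation = as.numeric(cq - R %*% cp))
}

#' Least-squares rigid-body superposition
#'
#' Superposes `mobile` onto `reference` over a set of paired atoms
#' (Kabsch algorithm) and applies the fitted transform to the whole mobile
#' model.
#'
#' @param mobile,reference [StructureModel-class] objects.
#' @param selection Data frame with columns `chain`, `resno`, `elety` naming
#'   the atoms to pair (must exist in both models), or `NULL` (default) to
#'   pair all C-alpha atoms shared by chain and residue number.
#' @return A list with elements `rotation` (3 x 3 matrix), `translation`
#'   (length-3 vector), `rmsd` (Angstrom, over the selection after fitting)
#'   and `model` (the transformed mobile [StructureModel-class]).
#' @examples
#' m <- genToyStructure("in242")
#' superposeStructures(m, m)$rmsd  # 0
#' @export
superposeStructures <- function(mobile, reference, selection = NULL) {
  stopifnot(is(mobile, "StructureModel"), is(reference, "StructureModel"))
  am <- mobile@atoms; ar <- reference@atoms
  if (is.null(selection)) {
    cam <- am[am$elety == "CA", c("chain", "resno")]
    car <- ar[ar$elety == "CA", c("chain", "resno")]
    shared <- merge(cam, car)
    selection <- data.frame(chain = shared$chain, resno = shared$resno,
                            elety = "CA", stringsAsFactors = FALSE)
  }
  if (nrow(selection) < 3L)
    stop("superposition needs >= 3 paired atoms; got ", nrow(selection),
         call. = FALSE)
  keyOf <- function(a) paste(a$chain, a$resno, a$elety, sep = "\r")
  km <- keyOf(am); kr <- keyOf(ar); ks <- keyOf(selection)
  im <- match(ks, km); ir <- match(ks, kr)
  if (anyNA(im) || anyNA(ir))
    stop("selection atoms missing from ",
         if (anyNA(im)) "mobile" else "reference", " model", call. = FALSE)
  P <- as.matrix(am[im, c("x", "y", "z")])
  Q <- as.matrix(ar[ir, c("x", "y", "z")])
  tr <- .kabsch(P, Q)
  Pfit <- sweep(P %*% t(tr$rotation), 2, tr$translation, "+")
  allxyz <- as.matrix(am[, c("x", "y", "z")])
  allfit <- sweep(allxyz %*% t(tr$rotation), 2, tr$translation, "+")
  out <- am
  out$x <- allfit[, 1]; out$y <- allfit[, 2]; out$z <- allfit[, 3]
  list(rotation = tr$rotation, translation = tr$translation,
       rmsd = coordRmsd(Pfit, Q),
       model = .newStructureModel(mobile@identifier, out))
}

#' Rotation angle of a 3 x 3 rotation matrix
#'
#' @param rotation A proper rotation matrix.
#' @return The rotation angle in degrees, in \[0, 180\].
#' @export
rotationAngleDeg <- function(rotation) {
  tr <- sum(diag(rotation))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}
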