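#' @import methods
NULL

## ---------------------------------------------------------------------------
## StructureModel: a parsed macromolecular coordinate set
## ---------------------------------------------------------------------------

#' StructureModel: a parsed macromolecular coordinate set
#'
#' Holds one coordinate model with author chain/residue numbering preserved,
#' alternate locations already resolved to a single conformer per atom, and
#' solvent records flagged.  Atoms live in a plain data frame with columns
#' `chain`, `resno`, `resid`, `elety` (atom name), `elesy` (element), `x`,
#' `y`, `z` (Angstrom), `occ`, `alt`, `type` (ATOM/HETATM) and the logical
#' `water`.
#'
#' Author numbering is authoritative: residues 242/244 and the Gly240/Gly249
#' hinge of the hNEIL1 lesion-recognition loop are addressed by their
#' full-length residue numbers exactly as deposited.
#'
#' @slot identifier Character, a label for the model (file stem or synthetic
#'   fixture tag).
#' @slot atoms A data frame of atom records (see Details).
#' @name StructureModel-class
#' @aliases StructureModel-class
#' @exportClass StructureModel
setClass("StructureModel",
  representation(identifier = "character", atoms = "data.frame"),
  validity = function(object) {
    a <- object@atoms
    need <- c("chain", "resno", "resid", "elety", "elesy",
              "x", "y", "z", "occ", "alt", "type", "water")
    if (!all(need %in% names(a)))
      return(paste("atom table missing columns:",
                   paste(setdiff(need, names(a)), collapse = ", ")))
    if (nrow(a) == 0L) return("empty model: no atom records")
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite atom coordinates")
    key <- paste(a$chain, a$resno, a$resid, a$elety)
    if (anyDuplicated(key))
      return("duplicate atom records after alternate-location resolution")
    TRUE
  })

#' ResidueView: read-only view over a single residue
#'
#' Lightweight handle over one residue of a [StructureModel-class].
#' Requesting an atom that the residue does not contain is an explicit error,
#' never a silent default.
#'
#' @slot chain Chain identifier.
#' @slot resno Author residue number.
#' @slot resid Residue name (three-letter / nucleotide code).
#' @slot atoms Data frame of the residue's atom records.
#' @name ResidueView-class
#' @aliases ResidueView-class
#' @exportClass ResidueView
setClass("ResidueView",
  representation(chain = "character", resno = "integer",
                 resid = "character", atoms = "data.frame"),
  validity = function(object) {
    if (nrow(object@atoms) == 0L) return("view over an empty residue")
    TRUE
  })

## ---------------------------------------------------------------------------
## TwoStateModel: auto-inhibition rate-law parameters
## ---------------------------------------------------------------------------

#' TwoStateModel: parameters of the auto-inhibition rate law
#'
#' Bundles the intrinsic glycosylase rate constant k_cat with the free-energy
#' difference between the activated (242-in) and quarantine (244-in) states,
#' decomposed into a loop-conformation term and a tautomerization
#' ("chemical-check") term:
#'
#' \deqn{\Delta G = \Delta G_{conf} + \Delta G_{chem}}
#' \deqn{\tilde k_{cat} = k_{cat} / (1 + e^{\Delta G / RT})}
#'
#' Positive \eqn{\Delta G} means the quarantine state dominates and catalysis
#' is auto-inhibited.  Infinite \eqn{\Delta G} components are legal markers
#' for fully quarantined (+Inf) or fully activated (-Inf) limits.
#'
#' @slot kcat Intrinsic rate constant, min^-1, strictly positive.
#' @slot dGconf Conformational free-energy term, kcal/mol.
#' @slot dGchem Chemical-check (tautomerization) free-energy term, kcal/mol.
#' @slot temperature Absolute temperature, K.
#' @seealso [TwoStateModel()], [apparentKcat()], [activatedFraction()]
#' @name TwoStateModel-class
#' @aliases TwoStateModel-class
#' @exportClass TwoStateModel
setClass("TwoStateModel",
  representation(kcat = "numeric", dGconf = "numeric",
                 dGchem = "numeric", temperature = "numeric"),
  validity = function(object) {
    if (length(object@kcat) != 1L || is.na(object@kcat) ||
        !is.finite(object@kcat) || object@kcat <= 0)
      return("kcat must be a single finite value > 0")
    if (length(object@temperature) != 1L || !is.finite(object@temperature) ||
        object@temperature <= 0)
      return("temperature must be a single finite value > 0 (Kelvin)")
    for (s in c("dGconf", "dGchem")) {
      v <- slot(object, s)
      if (length(v) != 1L || is.na(v))
        return(sprintf("%s must be a single numeric (Inf/-Inf allowed)", s))
    }
    TRUE
  })

## ---------------------------------------------------------------------------
## EnsembleSummary: state populations and the derived free energy
## ---------------------------------------------------------------------------

#' EnsembleSummary: state populations and the derived free energy
#'
#' Result of [statePopulations()]: per-state snapshot counts and fractions,
#' and the free-energy difference of the activated over the quarantine state,
#' \eqn{\Delta G = RT \ln(p_{244in} / p_{242in})}, with a binomial-propagation
#' standard error.
#'
#' @slot counts Named integer vector (apo, in242, in244).
#' @slot fractions Named numeric vector summing to 1 over classified
#'   snapshots.
#' @slot nTotal Number of classified snapshots.
#' @slot nUnclassified Snapshots excluded for missing descriptors.
#' @slot deltaG kcal/mol; +Inf / -Inf markers when a state is unobserved.
#' @slot deltaGse Standard error of deltaG (NA when not estimable).
#' @slot temperature Kelvin.
#' @name EnsembleSummary-class
#' @aliases EnsembleSummary-class
#' @exportClass EnsembleSummary
setClass("EnsembleSummary",
  representation(counts = "integer", fractions = "numeric",
                 nTotal = "integer", nUnclassified = "integer",
                 deltaG = "numeric", deltaGse = "numeric",
                 temperature = "numeric"),
  validity = function(object) {
    if (!identical(names(object@counts), c("apo", "in242", "in244")))
      return("counts must be named apo, in242, in244")
    if (sum(object@counts) != object@nTotal)
      return("counts must sum to nTotal")
    if (object@nTotal > 0L &&
        abs(sum(object@fractions) - 1) > 1e-12)
      return("fractions must sum to 1")
    TRUE
  })

## ---------------------------------------------------------------------------
## TimeCourse / FitResult: single-turnover kinetics
## ---------------------------------------------------------------------------

#' TimeCourse: a single-turnover cleavage time-course
#'
#' Fraction-product observations on a strictly increasing time grid
#' (minutes).  Noisy simulated values are clipped to \[0, 1\]; the number of
#' clipped points is recorded so downstream fits can flag censoring.
#'
#' @slot times Sampling times in minutes, strictly increasing.
#' @slot fractionProduct Observed fraction product, same length as `times`.
#' @slot replicate Replicate identifier.
#' @slot metadata Named list (enzyme variant, substrate, temperature label).
#' @slot clipped Number of values clipped into \[0, 1\].
#' @name TimeCourse-class
#' @aliases TimeCourse-class
#' @exportClass TimeCourse
setClass("TimeCourse",
  representation(times = "numeric", fractionProduct = "numeric",
                 replicate = "character", metadata = "list",
                 clipped = "integer"),
  validity = function(object) {
    if (length(object@times) != length(object@fractionProduct))
      return("times and fractionProduct must have equal length")
    if (length(object@times) == 0L) return("empty time-course")
    if (any(!is.finite(object@times)) || any(diff(object@times) <= 0))
      return("times must be finite and strictly increasing")
    if (any(!is.finite(object@fractionProduct)))
      return("fractionProduct must be finite")
    TRUE
  })

#' FitResult: one-phase-association fit
#'
#' Estimates of the amplitude A and observed rate constant k_obs from the
#' model fraction product = A (1 - exp(-k_obs t)), with curvature-based
#' standard errors.  A is constrained to \[0, 1.2\] (tolerating noise overshoot
#' while rejecting degenerate fits) and k_obs to \[0, Inf).  A fit that failed
#' to converge from every start is returned flagged, not thrown.
#'
#' @slot A Amplitude estimate (dimensionless fraction).
#' @slot kObs Rate constant estimate, min^-1.
#' @slot seA,seKObs Standard errors (NA when unavailable).
#' @slot rss Residual sum of squares.
#' @slot converged Logical convergence flag.
#' @slot nPoints Number of fitted observations.
#' @name FitResult-class
#' @aliases FitResult-class
#' @exportClass FitResult
setClass("FitResult",
  representation(A = "numeric", kObs = "numeric", seA = "numeric",
                 seKObs = "numeric", rss = "numeric",
                 converged = "logical", nPoints = "integer"),
  validity = function(object) {
    if (!is.na(object@kObs) && object@kObs < 0) return("kObs must be >= 0")
    if (!is.na(object@A) && (object@A < 0 || object@A > 1.2))
      return("A must lie in [0, 1.2]")
    TRUE
  })

## ---------------------------------------------------------------------------
## TriageReport
## ---------------------------------------------------------------------------

#' TriageReport: per-variant/substrate triage summary
#'
#' A table of free energies, activated fractions and apparent rate constants
#' for each (enzyme variant, substrate) pair, plus the matrix of pairwise
#' discrimination ratios (quotients of apparent k_cat values).
#'
#' @slot table Data frame with columns variant, substrate, kcat, dGconf,
#'   dGchem, temperature, deltaG, activatedFraction, apparentKcat.
#' @slot ratios Square matrix of apparent-k_cat quotients (row over column).
#' @name TriageReport-class
#' @aliases TriageReport-class
#' @exportClass TriageReport
setClass("TriageReport",
  representation(table = "data.frame", ratios = "matrix"),
  validity = function(object) {
    k <- object@table$apparentKcat
    n <- length(k)
    if (!all(dim(object@ratios) == c(n, n)))
      return("ratio matrix dimensions must match the table")
    expect <- outer(k, k, function(a, b) ifelse(b == 0, Inf, a / b))
    got <- object@ratios
    fin <- is.finite(expect) & expect != 0
    if (any(abs(got[fin] / expect[fin] - 1) > 1e-12))
      return("ratios must equal quotients of tabulated apparent kcat values")
    TRUE
  })

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  nw <- sum(a$water)
  cat("StructureModel '", object@identifier, "': ",
      nrow(a), " atoms, ",
      length(unique(paste(a$chain[!a$water], a$resno[!a$water]))),
      " non-solvent residues, ", nw, " water atoms\n", sep = "")
  invisible(NULL)
})

setMethod("show", "ResidueView", function(object) {
  cat("ResidueView ", object@resid, object@resno, " (chain ",
      object@chain, "): ", nrow(object@atoms), " atoms\n", sep = "")
  invisible(NULL)
})

setMethod("show", "TwoStateModel", function(object) {
  dg <- object@dGconf + object@dGchem
  cat("TwoStateModel: kcat =", object@kcat, "min^-1, dG =",
      format(dg, digits = 4), "kcal/mol (conf",
      format(object@dGconf, digits = 4), "+ chem",
      format(object@dGchem, digits = 4), ") at",
      object@temperature, "K\n")
  invisible(NULL)
})

setMethod("show", "EnsembleSummary", function(object) {
  cat("EnsembleSummary:", object@nTotal, "classified snapshots (",
      object@nUnclassified, "unclassifiable )\n")
  print(rbind(count = object@counts,
              fraction = round(object@fractions, 4)))
  cat("deltaG (activated vs quarantine):",
      format(object@deltaG, digits = 4), "+/-",
      format(object@deltaGse, digits = 3), "kcal/mol at",
      object@temperature, "K\n")
  invisible(NULL)
})

setMethod("show", "TimeCourse", function(object) {
  cat("TimeCourse (", object@replicate, "): ", length(object@times),
      " points, t = ", min(object@times), "..", max(object@times),
      " min", if (object@clipped > 0L)
        paste0(", ", object@clipped, " clipped"), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult: A =", format(object@A, digits = 4), "+/-",
      format(object@seA, digits = 3), "; k_obs =",
      format(object@kObs, digits = 4), "+/-",
      format(object@seKObs, digits = 3), "min^-1;",
      object@nPoints, "points;",
      if (object@converged) "converged" else "NOT CONVERGED", "\n")
  invisible(NULL)
})

setMethod("show", "TriageReport", function(object) {
  cat("TriageReport over", nrow(object@table), "variant/substrate pairs\n")
  print(object@table, digits = 4)
  invisible(NULL)
})
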