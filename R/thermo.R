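## The auto-inhibition rate law and its free-energy decomposition.
## Only the ES complexes in the activated (242-in) state proceed to
## catalysis; the quarantine (244-in) state competes thermodynamically:
##
##   r = kcat \[ES\]_A = kcat / (1 + exp(dG/RT)) \[ES\] = kcat~ \[ES\]
##   dG = dGconf + dGchem
##
## The Michaelis binding step is treated as pre-equilibrated, so no K_M
## machinery appears here; dGconf and dGchem enter as inputs (from enhanced
## sampling / electronic-structure work upstream, or from ensemble
## populations via statePopulations()).

#' Construct a TwoStateModel
#'
#' @param kcat Intrinsic glycosylase rate constant, min^-1 (> 0).
#' @param dGconf Loop-conformation ("structural check") free-energy term,
#'   kcal/mol; +Inf/-Inf are legal limiting markers.
#' @param dGchem Tautomerization ("chemical check") free-energy term,
#'   kcal/mol.
#' @param temperature Kelvin (default 298.15).
#' @return A [TwoStateModel-class].
#' @examples
#' m <- TwoStateModel(kcat = 1.5, dGconf = 0.7, dGchem = 0.3)
#' apparentKcat(m)  # 0.234 min^-1
#' @export
TwoStateModel <- function(kcat, dGconf = 0, dGchem = 0,
                          temperature = 298.15) {
  new("TwoStateModel", kcat = as.numeric(kcat),
      dGconf = as.numeric(dGconf), dGchem = as.numeric(dGchem),
      temperature = as.numeric(temperature))
}

#' Rate-law operations on the two-state model
#'
#' `totalDeltaG()` returns \eqn{\Delta G = \Delta G_{conf} + \Delta
#' G_{chem}} (opposing infinities are an undefined-free-energy error).
#' `activatedFraction()` maps a free energy (or a model) to the activated
#' population \eqn{p_A = 1/(1 + e^{\Delta G/RT})}, strictly decreasing in
#' \eqn{\Delta G}, with \eqn{\pm\infty} mapping exactly to 0/1.
#' `apparentKcat()` returns \eqn{\tilde k_{cat} = k_{cat} \, p_A}, and
#' `overallRate()` the rate \eqn{r = \tilde k_{cat} \[ES\]} for a total
#' pre-equilibrated complex concentration.
#'
#' @param object A [TwoStateModel-class], or for `activatedFraction` a
#'   numeric free energy in kcal/mol.
#' @param temperature Kelvin (numeric method only; the model method uses
#'   the model's own temperature).
#' @param esTotal Total ES-complex concentration (>= 0; any concentration
#'   unit — the rate inherits it per minute).
#' @return Free energy in kcal/mol, a fraction in \[0, 1\], a rate constant
#'   in min^-1, or a rate in concentration units per minute.
#' @examples
#' activatedFraction(0)            # 0.5
#' activatedFraction(1.0)          # 0.156
#' m <- TwoStateModel(2)
#' overallRate(m, 20)              # 20 (units of esTotal per minute)
#' @name thermo-ops
NULL

#' @rdname thermo-ops
setMethod("totalDeltaG", "TwoStateModel", function(object) {
  a <- object@dGconf; b <- object@dGchem
  if (is.infinite(a) && is.infinite(b) && sign(a) != sign(b))
    stop("undefined total free energy: opposing infinite components",
         call. = FALSE)
  a + b
})

#' @rdname thermo-ops
setMethod("activatedFraction", "numeric",
  function(object, temperature = 298.15) {
    stats::plogis(-object / rtKcal(temperature))
  })

#' @rdname thermo-ops
setMethod("activatedFraction", "TwoStateModel",
  function(object, temperature = 298.15) {
    if (!missing(temperature))
      warning("temperature argument ignored; the model's own temperature ",
              "slot is used", call. = FALSE)
    activatedFraction(totalDeltaG(object), object@temperature)
  })

#' @rdname thermo-ops
setMethod("apparentKcat", "TwoStateModel", function(object) {
  object@kcat * activatedFraction(object)
})

#' @rdname thermo-ops
setMethod("overallRate", "TwoStateModel", function(object, esTotal) {
  if (!is.numeric(esTotal) || any(esTotal < 0))
    stop("esTotal must be a non-negative concentration", call. = FALSE)
  apparentKcat(object) * esTotal
})

#' Discrimination ratio between two substrates or variants
#'
#' Quotient of apparent rate constants, \eqn{\tilde k_{cat}(damage) /
#' \tilde k_{cat}(normal)} — how much faster the enzyme processes one
#' substrate than another once the two-state competition is accounted for.
#'
#' @param mDamage,mNormal [TwoStateModel-class] objects (a warning is
#'   issued if their temperatures differ).
#' @return Dimensionless ratio; `Inf` when the denominator is zero.
#' @examples
#' discriminationRatio(TwoStateModel(1, 0, 0), TwoStateModel(1, 2, 0))
#' # ~15.1: a 2 kcal/mol quarantine penalty slows the competitor 15-fold
#' @export
discriminationRatio <- function(mDamage, mNormal) {
  stopifnot(is(mDamage, "TwoStateModel"), is(mNormal, "TwoStateModel"))
  if (abs(mDamage@temperature - mNormal@temperature) > 1e-9)
    warning("models are at different temperatures; ratio mixes ensembles",
            call. = FALSE)
  num <- apparentKcat(mDamage); den <- apparentKcat(mNormal)
  if (den == 0) Inf else num / den
}

#' Build a triage report over a parameter table
#'
#' For each (variant, substrate) row with columns `kcat`, `dGconf`,
#' `dGchem` (and optionally `temperature`), tabulates the total free
#' energy, activated fraction and apparent k_cat, plus the full matrix of
#' pairwise discrimination ratios.
#'
#' @param params Data frame with columns `variant`, `substrate`, `kcat`,
#'   `dGconf`, `dGchem` and optional `temperature` (default 298.15 K).
#' @return A [TriageReport-class].
#' @export
buildTriageReport <- function(params) {
  need <- c("variant", "substrate", "kcat", "dGconf", "dGchem")
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("parameter table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"temperature" %in% names(params)) params$temperature <- 298.15
  models <- lapply(seq_len(nrow(params)), function(i)
    TwoStateModel(params$kcat[i], params$dGconf[i], params$dGchem[i],
                  params$temperature[i]))
  tab <- params[, c("variant", "substrate", "kcat", "dGconf", "dGchem",
                    "temperature")]
  tab$deltaG <- vapply(models, totalDeltaG, numeric(1))
  tab$activatedFraction <- vapply(models, activatedFraction, numeric(1))
  tab$apparentKcat <- vapply(models, apparentKcat, numeric(1))
  k <- tab$apparentKcat
  ratios <- outer(k, k, function(a, b) ifelse(b == 0, Inf, a / b))
  lab <- paste(tab$variant, tab$substrate, sep = ":")
  dimnames(ratios) <- list(lab, lab)
  new("TriageReport", table = tab, ratios = ratios)
}

#' TriageReport accessors
#'
#' @param x A [TriageReport-class].
#' @return The per-pair summary table or the pairwise apparent-kcat ratio
#'   matrix.
#' @name TriageReport-accessors
NULL

#' @rdname TriageReport-accessors
#' @export
triageTable <- function(x) { stopifnot(is(x, "TriageReport")); x@table }

#' @rdname TriageReport-accessors
#' @export
triageRatios <- function(x) { stopifnot(is(x, "TriageReport")); x@ratios }

#' Read a model parameter table from CSV or JSON
#'
#' Columns: `variant`, `substrate`, `kcat`, `dGconf`, `dGchem`, optional
#' `temperature`.
#'
#' @param path File path (`.csv` or `.json`).
#' @return Data frame suitable for [buildTriageReport()].
#' @export
readModelTable <- function(path) {
  if (!file.exists(path)) stop("parameter table not found: ", path,
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::fromJSON(path))
  else utils::read.csv(path, stringsAsFactors = FALSE)
}
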