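## Metastable-state classification of loop-conformation snapshots in the
## (d242, d244) descriptor plane, density-based zone detection, and the
## conversion of state populations into free-energy differences.

.STATE_LABELS <- c("apo", "in242", "in244")

#' Default metastable-state reference centroids
#'
#' Operational centroids in the (d242, d244) plane for the three loop
#' conformations seen crystallographically: apo (loop displaced, both
#' distances large), 242-in (activated; short 242-base contact) and 244-in
#' (quarantine; Tyr244 stacked on the base).  No numerical centroid
#' coordinates are published for the conformational zones, so these are
#' package defaults chosen to be consistent with the structural
#' observations (~3.0 A activated contact, ~3.6 A stacking, >9 A apo
#' displacement); override them freely or load a config file with
#' [readStateReferences()].
#'
#' @return Data frame with columns `label`, `d242`, `d244` in the fixed
#'   tie-break order apo, in242, in244.
#' @export
defaultStateReferences <- function() {
  data.frame(label = .STATE_LABELS,
             d242 = c(12, 3, 8),
             d244 = c(10, 8, 3.5),
             stringsAsFactors = FALSE)
}

#' Read state reference centroids from a YAML or JSON config
#'
#' The file must define a list/array of records with fields `label`, `d242`
#' and `d244`; all three state labels must be present exactly once.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Data frame as [defaultStateReferences()], reordered to the
#'   canonical tie-break order.
#' @export
readStateReferences <- function(path) {
  if (!file.exists(path)) stop("reference config not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  df <- if (is.data.frame(raw)) raw else do.call(rbind.data.frame, raw)
  .validateReferences(df)
}

.validateReferences <- function(refs) {
  need <- c("label", "d242", "d244")
  if (!all(need %in% names(refs)))
    stop("state references need columns label, d242, d244", call. = FALSE)
  if (!setequal(refs$label, .STATE_LABELS) || nrow(refs) != 3L)
    stop("state references must contain exactly the labels apo, in242, in244",
         call. = FALSE)
  refs <- refs[match(.STATE_LABELS, refs$label), , drop = FALSE]
  pts <- as.matrix(refs[, c("d242", "d244")])
  if (min(stats::dist(pts)) < 1e-9)
    stop("reference centroids must be pairwise distinct", call. = FALSE)
  rownames(refs) <- NULL
  refs
}

.refDistances <- function(d242, d244, refs, scale = NULL) {
  refs <- .validateReferences(refs)
  sx <- if (is.null(scale)) c(1, 1) else {
    stopifnot(length(scale) == 2L, all(scale > 0))
    as.numeric(scale)
  }
  dx <- outer(d242, refs$d242, "-") / sx[1]
  dy <- outer(d244, refs$d244, "-") / sx[2]
  d <- sqrt(dx^2 + dy^2)
  colnames(d) <- refs$label
  d
}

#' Classify one descriptor snapshot by nearest reference centroid
#'
#' Euclidean nearest-centroid assignment in the (d242, d244) plane (both
#' axes in Angstrom; optional per-axis scaling).  Ties are broken
#' deterministically by label order apo < in242 < in244.
#'
#' @param d242,d244 Descriptor values in Angstrom.
#' @param refs Reference centroids (see [defaultStateReferences()]).
#' @param scale Optional length-2 positive scale dividing the (d242, d244)
#'   axes before distance computation.
#' @return A list with `label`, `distances` (named, to each centroid) and
#'   `margin` (runner-up minus winner distance, >= 0).  Missing descriptors
#'   give `label = NA` (unclassifiable marker).
#' @examples
#' classifySnapshot(3.1, 7.9)$label  # "in242"
#' @export
classifySnapshot <- function(d242, d244, refs = defaultStateReferences(),
                             scale = NULL) {
  if (is.na(d242) || is.na(d244))
    return(list(label = NA_character_, distances = NULL, margin = NA_real_))
  d <- .refDistances(d242, d244, refs, scale)[1, ]
  w <- which.min(d)  # first minimum = tie-break by label order
  list(label = names(d)[w], distances = d,
       margin = sort(d)[2] - d[[w]])
}

#' Classify a whole descriptor ensemble
#'
#' Vectorized nearest-centroid classification; returns the input with
#' `label`, per-centroid distances and `margin` columns appended.  Rows
#' with missing descriptors get `label = NA`.
#'
#' @param ensemble Data frame with numeric columns `d242` and `d244`.
#' @inheritParams classifySnapshot
#' @return The annotated data frame.
#' @export
classifyEnsemble <- function(ensemble, refs = defaultStateReferences(),
                             scale = NULL) {
  stopifnot(all(c("d242", "d244") %in% names(ensemble)))
  if (nrow(ensemble) == 0L) stop("empty ensemble", call. = FALSE)
  ok <- !(is.na(ensemble$d242) | is.na(ensemble$d244))
  lab <- rep(NA_character_, nrow(ensemble))
  dist3 <- matrix(NA_real_, nrow(ensemble), 3,
                  dimnames = list(NULL, paste0("dist_", .STATE_LABELS)))
  margin <- rep(NA_real_, nrow(ensemble))
  if (any(ok)) {
    d <- .refDistances(ensemble$d242[ok], ensemble$d244[ok], refs, scale)
    w <- apply(d, 1, which.min)
    lab[ok] <- .STATE_LABELS[w]
    dist3[ok, ] <- d
    srt <- t(apply(d, 1, sort))
    margin[ok] <- srt[, 2] - srt[, 1]
  }
  cbind(ensemble, label = lab, as.data.frame(dist3), margin = margin)
}

#' Detect metastable zones as density maxima in descriptor space
#'
#' Builds a 2D histogram of the ensemble over (d242, d244), thresholds
#' cells at `minDensity` times the modal cell density, and reports the
#' connected components (4-neighbour) of supra-threshold cells as zones.
#' With well-separated conformational basins this recovers the three
#' enriched zones corresponding to the apo, 242-in and 244-in states.
#'
#' @param ensemble Data frame with numeric columns `d242`, `d244`.
#' @param binWidth Histogram bin width in Angstrom (default 0.5).
#' @param minDensity Zone threshold as a fraction of the modal cell count
#'   (default 0.2).
#' @return Data frame sorted by decreasing population, one row per zone:
#'   `zone`, `population` (member snapshots), `nCells`, `modeD242`,
#'   `modeD244` (center of the zone's modal cell), `modeCount`.
#' @export
findMetastableZones <- function(ensemble, binWidth = 0.5,
                                minDensity = 0.2) {
  stopifnot(all(c("d242", "d244") %in% names(ensemble)))
  x <- ensemble$d242; y <- ensemble$d244
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0L) stop("empty ensemble", call. = FALSE)
  bx <- floor(x / binWidth); by <- floor(y / binWidth)
  x0 <- min(bx) * binWidth; y0 <- min(by) * binWidth
  bx <- bx - min(bx); by <- by - min(by)
  nx <- max(bx) + 1L; ny <- max(by) + 1L
  if (length(x) < nx * ny)
    warning("ensemble smaller than the histogram cell count; ",
            "zone detection may be noisy", call. = FALSE)
  counts <- matrix(0L, nx, ny)
  for (i in seq_along(bx))
    counts[bx[i] + 1L, by[i] + 1L] <- counts[bx[i] + 1L, by[i] + 1L] + 1L
  thr <- minDensity * max(counts)
  above <- counts >= thr & counts > 0L
  ## connected components over supra-threshold cells (4-neighbour BFS)
  comp <- matrix(0L, nx, ny)
  nzone <- 0L
  for (ci in seq_len(nx)) for (cj in seq_len(ny)) {
    if (!above[ci, cj] || comp[ci, cj] != 0L) next
    nzone <- nzone + 1L
    queue <- list(c(ci, cj)); comp[ci, cj] <- nzone
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (st in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ni <- cur[1] + st[1]; nj <- cur[2] + st[2]
        if (ni >= 1 && ni <= nx && nj >= 1 && nj <= ny &&
            above[ni, nj] && comp[ni, nj] == 0L) {
          comp[ni, nj] <- nzone
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  zones <- lapply(seq_len(nzone), function(z) {
    cells <- which(comp == z, arr.ind = TRUE)
    cnts <- counts[comp == z]
    mode_idx <- cells[which.max(cnts), , drop = TRUE]
    data.frame(zone = z,
               population = sum(cnts),
               nCells = nrow(cells),
               modeD242 = x0 + (mode_idx[1] - 0.5) * binWidth,
               modeD244 = y0 + (mode_idx[2] - 0.5) * binWidth,
               modeCount = max(cnts))
  })
  out <- do.call(rbind, zones)
  out <- out[order(-out$population), , drop = FALSE]
  out$zone <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' State populations and free-energy summary of an ensemble
#'
#' Classifies every snapshot against the reference centroids, tabulates
#' per-state counts and fractions (unclassifiable snapshots are excluded
#' and reported), and converts the activated/quarantine populations into
#' the free-energy difference
#' \eqn{\Delta G = RT \ln(p_{in244} / p_{in242})} with a binomial
#' error-propagation standard error \eqn{RT \sqrt{1/n_{242} + 1/n_{244}}}.
#'
#' @param ensemble Data frame with `d242`, `d244` columns, or an already
#'   classified data frame carrying a `label` column.
#' @inheritParams classifySnapshot
#' @param temperature Kelvin (default 298.15).
#' @return An [EnsembleSummary-class].
#' @export
statePopulations <- function(ensemble, refs = defaultStateReferences(),
                             scale = NULL, temperature = 298.15) {
  lab <- if ("label" %in% names(ensemble) &&
             all(ensemble$label %in% c(.STATE_LABELS, NA))) {
    ensemble$label
  } else {
    classifyEnsemble(ensemble, refs, scale)$label
  }
  n_un <- sum(is.na(lab))
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0L)
    stop("no classifiable snapshots in the ensemble", call. = FALSE)
  counts <- vapply(.STATE_LABELS, function(s) sum(lab == s), integer(1))
  fr <- counts / sum(counts)
  dg <- if (counts[["in242"]] == 0L && counts[["in244"]] == 0L) {
    NaN  # neither competing state observed: relative stability undefined
  } else {
    deltaGFromPopulations(fr[["in242"]], fr[["in244"]],
                          temperature = temperature,
                          nActivated = counts[["in242"]],
                          nQuarantine = counts[["in244"]])
  }
  new("EnsembleSummary",
      counts = counts, fractions = fr,
      nTotal = sum(counts), nUnclassified = as.integer(n_un),
      deltaG = as.numeric(dg),
      deltaGse = if (is.null(attr(dg, "se"))) NA_real_ else attr(dg, "se"),
      temperature = temperature)
}

#' EnsembleSummary accessors
#'
#' @param x An [EnsembleSummary-class].
#' @return Named counts/fractions, or the free-energy estimate in kcal/mol
#'   (with attribute `se`).
#' @name EnsembleSummary-accessors
NULL

#' @rdname EnsembleSummary-accessors
#' @export
stateCounts <- function(x) { stopifnot(is(x, "EnsembleSummary")); x@counts }

#' @rdname EnsembleSummary-accessors
#' @export
stateFractions <- function(x) {
  stopifnot(is(x, "EnsembleSummary")); x@fractions
}

#' @rdname EnsembleSummary-accessors
#' @export
ensembleDeltaG <- function(x) {
  stopifnot(is(x, "EnsembleSummary"))
  structure(x@deltaG, se = x@deltaGse)
}

#' Free-energy difference from state populations
#'
#' \eqn{\Delta G = RT \ln(p_{quarantine} / p_{activated})}: positive when
#' the quarantine (244-in) state dominates and catalysis is auto-inhibited.
#' A zero fraction yields an infinite-free-energy marker (+Inf when the
#' activated state is unobserved, -Inf when the quarantine state is), not
#' an error.  When counts are supplied, the binomial-propagation standard
#' error \eqn{RT\sqrt{1/n_A + 1/n_Q}} is attached as attribute `se`.
#'
#' @param pActivated,pQuarantine State fractions (need not sum to 1; the
#'   apo state may hold the remainder).
#' @param temperature Kelvin (default 298.15).
#' @param nActivated,nQuarantine Optional snapshot counts for the standard
#'   error.
#' @return Free energy in kcal/mol (attribute `se` when counts are given).
#' @examples
#' deltaGFromPopulations(0.25, 0.75)  # RT ln 3 = 0.651 kcal/mol
#' @export
deltaGFromPopulations <- function(pActivated, pQuarantine,
                                  temperature = 298.15,
                                  nActivated = NULL, nQuarantine = NULL) {
  stopifnot(pActivated >= 0, pQuarantine >= 0,
            pActivated + pQuarantine > 0)
  rt <- rtKcal(temperature)
  dg <- if (pActivated == 0) Inf
        else if (pQuarantine == 0) -Inf
        else rt * log(pQuarantine / pActivated)
  if (!is.null(nActivated) && !is.null(nQuarantine) &&
      nActivated > 0 && nQuarantine > 0 && is.finite(dg)) {
    attr(dg, "se") <- rt * sqrt(1 / nActivated + 1 / nQuarantine)
  }
  dg
}
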