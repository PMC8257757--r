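## Pipeline layer tying the stages together: a resolved run configuration,
## four stage drivers (structure analysis, ensemble classification,
## kinetics fitting, triage reporting) and a machine-readable run log.
## Input/usage problems signal conditions of class "triageUsageError" so
## callers can distinguish them from internal failures.

.usageStop <- function(...) {
  stop(structure(class = c("triageUsageError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Build a resolved run configuration
#'
#' Collects every tunable the pipeline stages consume, with the package
#' defaults made explicit so they can be recorded in the run log.
#'
#' @param hbondCutoff H-bond heavy-atom cutoff, Angstrom (default 3.5).
#' @param shellRadius Water-shell radius, Angstrom (default 5).
#' @param temperature Kelvin (default 298.15).
#' @param binWidth Zone-detection histogram bin width, Angstrom (0.5).
#' @param minDensity Zone threshold as fraction of modal density (0.2).
#' @param timeGrid `"standard"` (13-point, 180 min) or `"extended"` (72 h).
#' @param seed Optional master seed for stochastic stages.
#' @param outputDir Optional directory; when set, stages write their
#'   tables/JSON and a run log there.
#' @param verbose Emit progress messages.
#' @return A list of class `triage_config`.
#' @export
triageConfig <- function(hbondCutoff = 3.5, shellRadius = 5.0,
                         temperature = 298.15, binWidth = 0.5,
                         minDensity = 0.2,
                         timeGrid = c("standard", "extended"),
                         seed = NULL, outputDir = NULL, verbose = FALSE) {
  timeGrid <- match.arg(timeGrid)
  if (!is.null(outputDir)) {
    if (!dir.exists(outputDir))
      dir.create(outputDir, recursive = TRUE)
    outputDir <- normalizePath(outputDir)
  }
  structure(list(hbondCutoff = hbondCutoff, shellRadius = shellRadius,
                 temperature = temperature, binWidth = binWidth,
                 minDensity = minDensity, timeGrid = timeGrid,
                 seed = seed, outputDir = outputDir, verbose = verbose),
            class = "triage_config")
}

.logMsg <- function(config, ...) {
  if (isTRUE(config$verbose)) message(...)
}

#' Write the machine-readable run log
#'
#' Records the command name, resolved configuration, package version and
#' produced outputs as JSON.  Deliberately timestamp-free so identical
#' configurations reproduce identical logs.
#'
#' @param config A [triageConfig()].
#' @param command Stage name.
#' @param outputs Character vector of files written.
#' @return Invisibly, the log path (or `NULL` without an output
#'   directory).
#' @export
writeRunLog <- function(config, command, outputs = character()) {
  if (is.null(config$outputDir)) return(invisible(NULL))
  path <- file.path(config$outputDir, paste0(command, ".runlog.json"))
  cfg <- config[!vapply(config, is.null, logical(1))]
  jsonlite::write_json(
    list(command = command,
         package = "NeilTriage",
         version = as.character(utils::packageVersion("NeilTriage")),
         config = cfg,
         outputs = as.character(outputs)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Analyze structures into a descriptor/state table
#'
#' Reads each coordinate file, computes the loop/lesion descriptors (d242,
#' d244, H-bond call, rotation versus an optional reference, shell water
#' count) and the nearest-centroid state call, one row per structure.
#' Unreadable files are skipped with a warning; if every file fails the
#' stage raises a usage error.
#'
#' @param paths Character vector of PDB/mmCIF files.
#' @param loopChain Chain holding the recognition loop (default "A").
#' @param baseChain,baseResno Location of the flipped-base nucleotide
#'   (defaults match the toy fixtures: chain "B", residue 6).
#' @param reference Optional [StructureModel-class] (or path) used as the
#'   rotation-angle reference.
#' @param refs State reference centroids.
#' @param config A [triageConfig()].
#' @return Data frame with descriptor columns plus `label` and `margin`.
#' @export
analyzeStructures <- function(paths, loopChain = "A", baseChain = "B",
                              baseResno = 6, reference = NULL,
                              refs = defaultStateReferences(),
                              config = triageConfig()) {
  if (length(paths) == 0L) .usageStop("no structure files given")
  if (is.character(reference)) reference <- readStructure(reference)
  rows <- list()
  for (p in paths) {
    row <- tryCatch({
      m <- readStructure(p)
      computeLoopDescriptors(m, loopChain, baseChain, baseResno,
                             reference = reference,
                             hbondCutoff = config$hbondCutoff,
                             shellRadius = config$shellRadius)
    }, error = function(e) {
      warning("skipping '", p, "': ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L)
    .usageStop("all structure files failed to analyze")
  out <- do.call(rbind, rows)
  cls <- classifyEnsemble(out, refs)
  out$label <- cls$label
  out$margin <- cls$margin
  if (!is.null(config$outputDir)) {
    csv <- file.path(config$outputDir, "descriptors.csv")
    writeDescriptorTable(out, csv)
    writeRunLog(config, "analyze-structure", csv)
  }
  .logMsg(config, "analyzed ", nrow(out), " structure(s)")
  out
}

#' Summarize a descriptor ensemble: populations, free energy, zones
#'
#' @param x Descriptor data frame (columns `d242`, `d244`) or a CSV path.
#' @param refs State reference centroids.
#' @param config A [triageConfig()].
#' @param zones Also run density-based zone detection (default TRUE).
#' @return List with `summary` (an [EnsembleSummary-class]) and `zones`
#'   (data frame or NULL).
#' @export
summarizeEnsemble <- function(x, refs = defaultStateReferences(),
                              config = triageConfig(), zones = TRUE) {
  if (is.character(x)) {
    if (!file.exists(x)) .usageStop("ensemble file not found: ", x)
    x <- readDescriptorTable(x)
  }
  if (!is.data.frame(x) || nrow(x) == 0L)
    .usageStop("ensemble input is empty")
  if (!all(c("d242", "d244") %in% names(x)))
    .usageStop("ensemble input must have d242 and d244 columns")
  summ <- statePopulations(x, refs, temperature = config$temperature)
  zn <- if (isTRUE(zones))
    findMetastableZones(x, binWidth = config$binWidth,
                        minDensity = config$minDensity) else NULL
  if (!is.null(config$outputDir)) {
    out <- file.path(config$outputDir, "ensemble_summary.json")
    jsonlite::write_json(
      list(counts = as.list(stateCounts(summ)),
           fractions = as.list(stateFractions(summ)),
           nUnclassified = summ@nUnclassified,
           deltaG = summ@deltaG, deltaGse = summ@deltaGse,
           temperature = summ@temperature,
           zones = zn),
      out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeRunLog(config, "classify-ensemble", out)
  }
  list(summary = summ, zones = zn)
}

#' Fit single-turnover kinetics for every variant/substrate group
#'
#' Pools replicates within each (variant, substrate) group and fits the
#' one-phase association model.
#'
#' @param x Long time-course data frame (columns `variant`, `substrate`,
#'   `replicate`, `time_min`, `fraction_product`) or a CSV path.
#' @param config A [triageConfig()].
#' @return Data frame: variant, substrate, A, kObs, seA, seKObs, rss,
#'   converged, nPoints.
#' @export
fitKineticsTable <- function(x, config = triageConfig()) {
  if (is.character(x)) {
    if (!file.exists(x)) .usageStop("time-course file not found: ", x)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  need <- c("variant", "substrate", "replicate", "time_min",
            "fraction_product")
  miss <- setdiff(need, names(x))
  if (length(miss))
    .usageStop("time-course table missing column(s): ",
               paste(miss, collapse = ", "))
  if (nrow(x) == 0L) .usageStop("time-course table is empty")
  groups <- unique(x[, c("variant", "substrate")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- x[x$variant == groups$variant[i] &
             x$substrate == groups$substrate[i], ]
    f <- fitTimecourse(g[order(g$replicate, g$time_min),
                         c("time_min", "fraction_product")])
    data.frame(variant = groups$variant[i],
               substrate = groups$substrate[i],
               A = f@A, kObs = f@kObs, seA = f@seA, seKObs = f@seKObs,
               rss = f@rss, converged = f@converged,
               nPoints = f@nPoints, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(config$outputDir)) {
    csv <- file.path(config$outputDir, "kinetics_fits.csv")
    utils::write.csv(out, csv, row.names = FALSE)
    writeRunLog(config, "fit-kinetics", csv)
  }
  out
}

#' Run the triage report stage
#'
#' Reads a (variant, substrate, kcat, dGconf, dGchem) parameter table,
#' builds the [TriageReport-class] and optionally writes it out.
#'
#' @param x Parameter data frame or CSV/JSON path (see
#'   [readModelTable()]).
#' @param config A [triageConfig()].
#' @return A [TriageReport-class].
#' @export
runTriageReport <- function(x, config = triageConfig()) {
  if (is.character(x)) {
    if (!file.exists(x)) .usageStop("parameter table not found: ", x)
    x <- readModelTable(x)
  }
  if (!is.data.frame(x) || nrow(x) == 0L)
    .usageStop("parameter table is empty")
  rep <- tryCatch(buildTriageReport(x),
                  error = function(e) .usageStop(conditionMessage(e)))
  if (!is.null(config$outputDir)) {
    csv <- file.path(config$outputDir, "triage_report.csv")
    utils::write.csv(triageTable(rep), csv, row.names = FALSE)
    js <- file.path(config$outputDir, "triage_report.json")
    jsonlite::write_json(
      list(table = triageTable(rep), ratios = triageRatios(rep)),
      js, digits = NA, pretty = TRUE)
    writeRunLog(config, "triage-report", c(csv, js))
  }
  rep
}
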