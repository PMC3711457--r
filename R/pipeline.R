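# Orchestration: one-call analyses that mirror the command-line interface
# (inst/scripts/groovedna.R). Every numeric result equals the underlying
# module call; the file outputs are CSV/JSON with a provenance header
# echoing the configuration.

.writeCSVWithHeader <- function(df, file, config) {
  hdr <- c("# grooveDNA output",
           paste0("# ", names(config), ": ",
                  vapply(config, function(v) paste(format(v), collapse = " "),
                         "")))
  writeLines(hdr, file)
  suppressWarnings(utils::write.table(df, file, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))
  invisible(file)
}

.asDuplex <- function(input, aliases = baseAliases()) {
  if (is(input, "Duplex")) return(input)
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    r <- readDuplexPDB(input, aliases)
    if (!length(r$duplexes)) stop("no duplex found in ", input)
    return(r$duplexes[[1L]])
  }
  stop("input must be a Duplex or a PDB file path")
}

#' Analyse one structure: helical parameters and groove profile
#'
#' @param input A [Duplex-class] or PDB file path (first duplex used).
#' @param outDir Optional output directory for `parameters_intra.csv`,
#'   `parameters_step.csv`, `groove_profile.csv` and `summary.json`.
#' @param convention A [GrooveConvention-class].
#' @param window Central position window for summaries (default -2..+2).
#' @param origin Pair index given position 0 (default: center).
#' @return List: `parameters` (see [parameterTable()]), `profile`
#'   (a [GrooveProfile-class]), `window` ([windowStats()] plus
#'   [windowMeans()]).
#' @export
analyzeStructure <- function(input, outDir = NULL,
                             convention = grooveConvention(),
                             window = c(-2, 2), origin = NULL) {
  d <- .asDuplex(input)
  params <- parameterTable(d, origin)
  profile <- grooveProfile(d, convention, origin)
  winG <- windowStats(profile, window)
  winP <- windowMeans(params, window)
  res <- list(parameters = params, profile = profile,
              window = c(winG, winP))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    config <- list(input = if (is.character(input)) input else "<Duplex>",
                   vdwSubtraction = convention@vdwSubtraction,
                   minorOffsets = convention@minorOffsets,
                   majorOffsets = convention@majorOffsets,
                   window = window)
    .writeCSVWithHeader(params$intra,
                        file.path(outDir, "parameters_intra.csv"), config)
    .writeCSVWithHeader(params$step,
                        file.path(outDir, "parameters_step.csv"), config)
    .writeCSVWithHeader(as.data.frame(profile),
                        file.path(outDir, "groove_profile.csv"), config)
    jsonlite::write_json(list(config = config, window = as.list(res$window)),
                         file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' Compare groove statistics of two structures
#'
#' @param inputA,inputB [Duplex-class] objects or PDB file paths.
#' @param outFile Optional JSON output path.
#' @inheritParams analyzeStructure
#' @return List with each structure's [windowStats()] and their
#'   difference (A minus B).
#' @export
compareStructures <- function(inputA, inputB, outFile = NULL,
                              convention = grooveConvention(),
                              window = c(-2, 2), origin = NULL) {
  pa <- grooveProfile(.asDuplex(inputA), convention, origin)
  pb <- grooveProfile(.asDuplex(inputB), convention, origin)
  res <- list(A = windowStats(pa, window), B = windowStats(pb, window),
              delta = profileDelta(pa, pb, window))
  if (!is.null(outFile))
    jsonlite::write_json(lapply(res, as.list), outFile, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  res
}

#' Rebuild a duplex model and optionally write it as PDB
#'
#' Builds either a mean-parameter model of a sequence, or a partial
#' reconstruction of a reference structure keeping a subset of its step
#' parameters.
#'
#' @param sequence Base string (mean-parameter build), or `NULL`.
#' @param reference [Duplex-class]/PDB path for partial reconstruction.
#' @param keep,fill Passed to [reconstructPartial()].
#' @param outFile Optional PDB output path.
#' @return The built [Duplex-class].
#' @export
rebuildModel <- function(sequence = NULL, reference = NULL,
                         keep = c("twist", "roll", "slide"), fill = "mean",
                         outFile = NULL) {
  d <- if (!is.null(reference))
    reconstructPartial(.asDuplex(reference), keep, fill)
  else if (!is.null(sequence)) buildMeanDuplex(sequence)
  else stop("give a sequence or a reference")
  if (!is.null(outFile)) writeDuplexPDB(d, outFile)
  d
}

#' Trajectory statistics: most-probable groove profile and normality
#'
#' @param trajectory A [DuplexTrajectory-class], or a multi-model PDB path
#'   (then `topology` is required).
#' @param topology [Duplex-class] topology when reading from file.
#' @param outDir Optional output directory for `most_probable.csv` and
#'   `trajstats.json`.
#' @inheritParams mostProbableProfile
#' @return The [mostProbableProfile()] result.
#' @export
trajectoryStats <- function(trajectory, topology = NULL, outDir = NULL,
                            convention = grooveConvention(), burnIn = 0.2,
                            origin = NULL, range = c(-2, 2), alpha = 0.01) {
  if (is.character(trajectory)) {
    if (is.null(topology)) stop("topology required when reading from file")
    trajectory <- readTrajectoryPDB(trajectory, topology)
  }
  res <- mostProbableProfile(trajectory, convention, burnIn, origin, range,
                             alpha)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    config <- list(burnIn = burnIn, alpha = alpha, range = range,
                   vdwSubtraction = convention@vdwSubtraction)
    .writeCSVWithHeader(res$profile, file.path(outDir, "most_probable.csv"),
                        config)
    jsonlite::write_json(list(config = config, window = as.list(res$window)),
                         file.path(outDir, "trajstats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' Clash scan of a model
#'
#' @param input A [Duplex-class] or PDB file path.
#' @param outFile Optional CSV output path.
#' @inheritParams findClashes
#' @return The [findClashes()] report.
#' @export
clashScan <- function(input, outFile = NULL, vdw = vdwRadii(),
                      tolerance = 0.4) {
  rep <- findClashes(.asDuplex(input), vdw, tolerance)
  if (!is.null(outFile))
    .writeCSVWithHeader(rep, outFile, list(tolerance = tolerance))
  rep
}
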