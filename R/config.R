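# Run configuration and the function-level command layer wrapped by the
# inst/cli/voxnorm.R script.

#' Workflow run configuration
#'
#' Collects the tunable constants of the workflow with their standard
#' defaults: z threshold 2.5 SD, 8-mm smoothing FWHM, template ages 18-75
#' with a +/- 2-year window, SD floor 1e-6, GM-mask mean threshold 0.1 and
#' QC cutoff 0.95.
#'
#' @param templatePath template library directory (or `NULL`).
#' @param zCut,fwhm,ageMin,ageMax,halfWidth,sdFloor,maskMeanThreshold,qcCutoff
#'   workflow constants, see above.
#' @param outDir output directory.
#' @param seed integer seed for any stochastic step.
#' @return A list with class `"voxnormConfig"`.
#' @export
runConfig <- function(templatePath = NULL, zCut = 2.5, fwhm = 8,
                      ageMin = 18, ageMax = 75, halfWidth = 2,
                      sdFloor = 1e-6, maskMeanThreshold = 0.1,
                      qcCutoff = 0.95, outDir = ".", seed = 1L) {
  if (zCut < 0 || fwhm < 0 || halfWidth < 0 || sdFloor < 0)
    configError("negative workflow constant")
  if (ageMin > ageMax) configError("ageMin must not exceed ageMax")
  if (qcCutoff < 0 || qcCutoff > 1) configError("qcCutoff must be in [0, 1]")
  structure(list(templatePath = templatePath, zCut = zCut, fwhm = fwhm,
                 ageMin = ageMin, ageMax = ageMax, halfWidth = halfWidth,
                 sdFloor = sdFloor, maskMeanThreshold = maskMeanThreshold,
                 qcCutoff = qcCutoff, outDir = outDir,
                 seed = as.integer(seed)),
            class = "voxnormConfig")
}

#' @noRd
saveConfigSnapshot <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @noRd
logStage <- function(fmt, ..., quiet = FALSE) {
  if (!quiet) message(sprintf("[voxnorm] %s", sprintf(fmt, ...)))
}

#' Command layer: build a template library from a cohort manifest
#'
#' Reads a cohort CSV (`subject_id,age,sex,gm_map`), builds the normative
#' library and writes it (with a resolved config snapshot) to `outDir`.
#' Per-window subject counts are logged.
#'
#' @param cohortCsv cohort manifest path.
#' @param outDir output directory.
#' @param config a [runConfig()] list.
#' @param quiet suppress progress messages.
#' @return The [TemplateSet-class], invisibly.
#' @export
cliBuildTemplates <- function(cohortCsv, outDir, config = runConfig(),
                              quiet = FALSE) {
  cohort <- readCohortTable(cohortCsv)
  logStage("cohort: %d subjects, ages %g-%g", nrow(cohort),
           min(cohort$age), max(cohort$age), quiet = quiet)
  ts <- buildTemplates(cohort, ageMin = config$ageMin, ageMax = config$ageMax,
                       halfWidth = config$halfWidth,
                       maskMeanThreshold = config$maskMeanThreshold,
                       sdFloor = config$sdFloor, fwhm = config$fwhm)
  logStage("built %d template pairs; window sizes %d-%d", length(ts@mu),
           min(ts@nSubjects), max(ts@nSubjects), quiet = quiet)
  saveTemplates(ts, outDir)
  saveConfigSnapshot(config, outDir)
  logStage("library written to %s", outDir, quiet = quiet)
  invisible(ts)
}

#' Command layer: map one subject
#'
#' Loads the template library and the subject T1, runs [mapSubject()] and
#' writes the artifacts ([writeAtrophyMap()]) plus the config snapshot. A
#' QC failure is reported in `qc.json`, not raised as an error.
#'
#' @param t1Path subject T1 NIfTI.
#' @param age,sex subject demographics.
#' @param templatesDir template library directory.
#' @param outDir output directory.
#' @param config a [runConfig()] list.
#' @param gmPath optional preprocessed template-space GM map (bypass).
#' @param referencePath optional registration reference NIfTI; default: the
#'   library's grand-mean GM map.
#' @param quiet suppress progress messages.
#' @return The [AtrophyMap-class], invisibly.
#' @export
cliMap <- function(t1Path, age, sex, templatesDir, outDir,
                   config = runConfig(), gmPath = NULL, referencePath = NULL,
                   quiet = FALSE) {
  ts <- loadTemplates(templatesDir)
  t1 <- readVolume(t1Path)
  gm <- if (!is.null(gmPath)) {
    v <- readVolume(gmPath)
    new("GMMap", volume = v, space = "template", modulated = TRUE,
        smoothedFWHM = NA_real_)
  }
  reference <- if (!is.null(referencePath)) readVolume(referencePath)
  else if (is.null(gm)) {
    keys <- names(ts@mu)
    brainVolume(Reduce(`+`, ts@mu) / length(keys), ts@affine)
  }
  am <- mapSubject(t1, ts, age, sex, reference = reference, gm = gm,
                   zCut = config$zCut, qcCutoff = config$qcCutoff,
                   seed = config$seed)
  writeAtrophyMap(am, outDir)
  saveConfigSnapshot(config, outDir)
  logStage("z range [%.2f, %.2f], QC %.3f (%s)", min(am@zSubject@data),
           max(am@zSubject@data), am@qcFraction,
           if (am@qcPassed) "pass" else "FLAGGED", quiet = quiet)
  invisible(am)
}

#' Command layer: simulate a phantom cohort
#'
#' @param outDir output directory for maps + `cohort.csv`.
#' @param specJson optional JSON file overriding [phantomSpec()] fields.
#' @param ages,nPerCell,seed cohort layout, see [generateCohort()].
#' @param smoothFWHM smoothing applied to the written maps (mm; `NA` none).
#' @param quiet suppress progress messages.
#' @return The cohort data.frame, invisibly.
#' @export
cliSimulate <- function(outDir, specJson = NULL, ages = 16:77, nPerCell = 6,
                        seed = 1L, smoothFWHM = NA_real_, quiet = FALSE) {
  spec <- if (is.null(specJson)) phantomSpec() else {
    args <- jsonlite::read_json(specJson, simplifyVector = TRUE)
    do.call(phantomSpec, args)
  }
  res <- generateCohort(spec, ages = ages, nPerCell = nPerCell, seed = seed,
                        outDir = outDir, smoothFWHM = smoothFWHM)
  logStage("wrote %d phantoms to %s", nrow(res$cohort), outDir, quiet = quiet)
  invisible(res$cohort)
}

#' Command layer: evaluate a reader study
#'
#' @param readingsCsv CSV of reading records
#'   (`subject_id,diagnosis,hemisphere,map_reading,mta_score`); `NULL`
#'   evaluates the bundled fourfold tables ([readerStudyTables()]).
#' @param outDir output directory for `report.md` + `report.json`.
#' @param quiet suppress progress messages.
#' @return The report data.frame, invisibly.
#' @export
cliEvaluate <- function(readingsCsv = NULL, outDir, quiet = FALSE) {
  x <- if (is.null(readingsCsv)) readerStudyTables()
  else {
    if (!file.exists(readingsCsv)) dataError("no such file: %s", readingsCsv)
    read.csv(readingsCsv, stringsAsFactors = FALSE)
  }
  report <- evaluateStudy(x)
  writeStudyReport(report, outDir)
  logStage("report for %d strata written to %s", nrow(report), outDir,
           quiet = quiet)
  invisible(report)
}
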