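# Normative template library: sliding-window per-(age, sex) mean/SD maps.

#' Read and validate a cohort metadata table
#'
#' CSV with header `subject_id,age,sex,gm_map` (the last column a path to a
#' template-space GM NIfTI, resolved relative to the CSV's directory when
#' not absolute).
#'
#' @param path CSV file.
#' @return A `data.frame` with validated columns.
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) dataError("no such cohort table: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validateCohort(df)
  if ("gm_map" %in% names(df)) {
    rel <- !grepl("^(/|[A-Za-z]:)", df$gm_map)
    df$gm_map[rel] <- file.path(dirname(path), df$gm_map[rel])
  }
  df
}

#' @noRd
validateCohort <- function(cohort) {
  need <- c("subject_id", "age", "sex")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    dataError("cohort table is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(cohort) == 0) dataError("cohort table is empty")
  if (anyDuplicated(cohort$subject_id))
    dataError("duplicate subject_id: %s",
              paste(unique(cohort$subject_id[duplicated(cohort$subject_id)]),
                    collapse = ", "))
  if (any(!is.finite(cohort$age))) dataError("non-finite ages in cohort table")
  invisible(cohort)
}

#' Select the subjects feeding one (age, sex) template
#'
#' All cohort subjects of the matching sex whose (floored) age lies within
#' `age - halfWidth` to `age + halfWidth`, both bounds inclusive.
#'
#' @param cohort cohort `data.frame` (see [readCohortTable()]).
#' @param age template age in years.
#' @param sex sex category.
#' @param halfWidth window half-width in years (default 2).
#' @return The matching rows of `cohort`.
#' @export
selectWindow <- function(cohort, age, sex, halfWidth = 2) {
  validateCohort(cohort)
  a <- floor(cohort$age)
  sel <- cohort$sex == sex & a >= age - halfWidth & a <= age + halfWidth
  if (!any(sel))
    voxnormStop("voxnorm_window_empty",
                "no cohort subjects for age %s, sex %s (window +/- %s years)",
                age, sex, halfWidth)
  cohort[sel, , drop = FALSE]
}

# load cohort GM maps into a voxels x subjects matrix (double), checking
# that all maps share one grid
#' @noRd
loadCohortMaps <- function(cohort, maps = NULL) {
  getMap <- function(i) {
    if (!is.null(maps)) {
      m <- maps[[cohort$subject_id[i]]]
      if (is.null(m)) dataError("no map supplied for subject %s",
                                cohort$subject_id[i])
    } else {
      if (is.null(cohort$gm_map))
        dataError("cohort table is missing column(s): gm_map")
      m <- readVolume(cohort$gm_map[i])
    }
    if (is(m, "GMMap")) m@volume else m
  }
  first <- getMap(1)
  d <- gridDim(first)
  V <- matrix(0, prod(d), nrow(cohort))
  V[, 1] <- first@data
  offenders <- character(0)
  for (i in seq_len(nrow(cohort))[-1]) {
    m <- getMap(i)
    if (!sameGrid(m, first)) offenders <- c(offenders, cohort$subject_id[i])
    else V[, i] <- m@data
  }
  if (length(offenders))
    geometryError("GM maps not on the common grid: %s",
                  paste(offenders, collapse = ", "))
  list(V = V, dim = d, affine = first@affine)
}

#' Build the normative template library
#'
#' For every sex and every integer age from `ageMin` to `ageMax`, computes
#' the voxel-wise sample mean and sample SD (denominator n - 1) across the
#' smoothed GM maps of all cohort subjects within `halfWidth` years of that
#' age (inclusive both ends; subject ages floored to integer years), and
#' derives the binary GM mask from the grand-mean map and pooled SD.
#'
#' @param cohort cohort `data.frame` with columns `subject_id`, `age`,
#'   `sex`, and `gm_map` (paths) unless `maps` is given.
#' @param maps optional named list (by `subject_id`) of [GMMap-class] /
#'   [BrainVolume-class] objects, used instead of reading `gm_map` paths.
#' @param ageMin,ageMax template age range (defaults 18 and 75).
#' @param halfWidth window half-width in years (default 2).
#' @param minN hard minimum window size (default 2; SD is undefined below).
#' @param warnN windows smaller than this draw a warning (default 20).
#' @param onSmallWindow `"error"` or `"warn"` for windows below `minN`.
#' @param maskMeanThreshold,sdFloor GM-mask construction parameters, see
#'   [gmMaskFromTemplates()].
#' @param fwhm smoothing FWHM recorded in provenance (the maps are assumed
#'   already smoothed; use [asPreprocessedGM()] or [preprocessSubject()]).
#' @return A [TemplateSet-class].
#' @export
buildTemplates <- function(cohort, maps = NULL, ageMin = 18, ageMax = 75,
                           halfWidth = 2, minN = 2, warnN = 20,
                           onSmallWindow = c("error", "warn"),
                           maskMeanThreshold = 0.1, sdFloor = 1e-6,
                           fwhm = NA_real_) {
  onSmallWindow <- match.arg(onSmallWindow)
  validateCohort(cohort)
  loaded <- loadCohortMaps(cohort, maps)
  V <- loaded$V
  ages <- as.integer(ageMin:ageMax)
  sexes <- sort(unique(cohort$sex))
  aInt <- floor(cohort$age)

  mu <- list(); sigma <- list()
  nSub <- integer(0)
  small <- character(0)
  for (s in sexes) for (a in ages) {
    sel <- which(cohort$sex == s & aInt >= a - halfWidth & aInt <= a + halfWidth)
    n <- length(sel)
    key <- paste(a, s, sep = "_")
    if (n < minN) {
      msg <- sprintf("window (age %d, sex %s) has %d subject(s), below minimum %d",
                     a, s, n, minN)
      if (onSmallWindow == "error") dataError("%s", msg)
      warning(msg)
    }
    if (n < warnN) small <- c(small, sprintf("%s (n=%d)", key, n))
    Vs <- V[, sel, drop = FALSE]
    m <- rowMeans(Vs)
    sdv <- if (n >= 2) sqrt(rowSums((Vs - m)^2) / (n - 1)) else rep(0, length(m))
    mu[[key]] <- array(m, loaded$dim)
    sigma[[key]] <- array(sdv, loaded$dim)
    nSub[key] <- n
  }
  if (length(small))
    warning(sprintf("%d template window(s) below %d subjects: %s",
                    length(small), warnN,
                    paste(head(small, 8), collapse = ", ")))

  ts <- new("TemplateSet", mu = mu, sigma = sigma, nSubjects = nSub,
            mask = array(1, loaded$dim), affine = loaded$affine,
            ages = ages, sexes = sexes,
            provenance = list(halfWidth = halfWidth, fwhm = fwhm,
                              dim = loaded$dim,
                              voxelSize = sqrt(colSums(loaded$affine[1:3, 1:3]^2)),
                              minN = minN,
                              maskMeanThreshold = maskMeanThreshold,
                              sdFloor = sdFloor, version = 1L))
  ts@mask <- gmMaskFromTemplates(ts, maskMeanThreshold, sdFloor)@data
  ts
}

#' Derive the binary GM mask from a template library
#'
#' Voxels where the grand mean of all (age, sex) mean maps exceeds
#' `meanThreshold` *and* the pooled SD (root-mean-square of the SD maps)
#' exceeds `sdFloor` — the standard absolute-threshold VBM mask plus a
#' division-safety floor for the z-map.
#'
#' @param ts a [TemplateSet-class].
#' @param meanThreshold GM probability/volume threshold (default 0.1).
#' @param sdFloor minimum pooled SD (default 1e-6).
#' @return A binary [BrainVolume-class].
#' @export
gmMaskFromTemplates <- function(ts, meanThreshold = 0.1, sdFloor = 1e-6) {
  keys <- names(ts@mu)
  grand <- Reduce(`+`, ts@mu) / length(keys)
  pooled <- sqrt(Reduce(`+`, lapply(ts@sigma, function(s) s^2)) / length(keys))
  m <- (grand > meanThreshold) & (pooled > sdFloor)
  if (!any(m))
    configError("GM mask is empty (meanThreshold %g too high?)", meanThreshold)
  brainVolume(m * 1, ts@affine)
}

#' Look up one template
#'
#' @param ts a [TemplateSet-class].
#' @param age integer template age.
#' @param sex sex category.
#' @rdname template-accessors
#' @return `templateMean`/`templateSD`: a [BrainVolume-class];
#'   `templateMask`: the binary mask volume; `nTemplateSubjects`: the
#'   window size.
#' @export
templateMean <- function(ts, age, sex) {
  brainVolume(ts@mu[[templateKey(ts, age, sex)]], ts@affine)
}

#' @rdname template-accessors
#' @export
templateSD <- function(ts, age, sex) {
  brainVolume(ts@sigma[[templateKey(ts, age, sex)]], ts@affine)
}

#' @rdname template-accessors
#' @export
templateMask <- function(ts) brainVolume(ts@mask, ts@affine)

#' @rdname template-accessors
#' @export
nTemplateSubjects <- function(ts, age, sex)
  unname(ts@nSubjects[templateKey(ts, age, sex)])

#' @rdname template-accessors
#' @export
templateAges <- function(ts) ts@ages

#' @rdname template-accessors
#' @export
templateSexes <- function(ts) ts@sexes

#' @noRd
templateKey <- function(ts, age, sex) {
  age <- as.integer(floor(age))
  if (!age %in% ts@ages)
    voxnormStop("voxnorm_unsupported_age",
                "age %d outside the template range %d-%d", age,
                min(ts@ages), max(ts@ages))
  if (!sex %in% ts@sexes)
    argumentError("sex '%s' not in template categories (%s)", sex,
                  paste(ts@sexes, collapse = ", "))
  paste(age, sex, sep = "_")
}

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet  ages %d-%d, sexes %s: %d (mean, SD) template pairs\n",
              min(object@ages), max(object@ages),
              paste(object@sexes, collapse = "/"),
              length(object@mu)))
  cat(sprintf("  grid %s, window +/- %g y, smoothing %s, mask %d voxels\n",
              paste(object@provenance$dim, collapse = "x"),
              object@provenance$halfWidth,
              if (is.na(object@provenance$fwhm)) "unspecified"
              else sprintf("%g mm FWHM", object@provenance$fwhm),
              sum(object@mask > 0)))
  cat(sprintf("  window sizes %d-%d subjects\n", min(object@nSubjects),
              max(object@nSubjects)))
})

#' Persist and reload a template library
#'
#' `saveTemplates` writes one directory holding `manifest.json` plus
#' uncompressed float64 NIfTI files `mean_<age>_<sex>.nii`,
#' `sd_<age>_<sex>.nii` and `gm_mask.nii`; reruns on identical inputs are
#' byte-identical. `loadTemplates` restores the [TemplateSet-class]
#' bit-for-bit, erroring descriptively on a missing map or a manifest
#' version mismatch.
#'
#' @param ts a [TemplateSet-class].
#' @param path directory to write / read.
#' @return `saveTemplates`: `path` invisibly; `loadTemplates`: the
#'   [TemplateSet-class].
#' @export
saveTemplates <- function(ts, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (k in names(ts@mu)) {
    writeVolume(brainVolume(ts@mu[[k]], ts@affine),
                file.path(path, sprintf("mean_%s.nii", k)), datatype = "double")
    writeVolume(brainVolume(ts@sigma[[k]], ts@affine),
                file.path(path, sprintf("sd_%s.nii", k)), datatype = "double")
  }
  writeVolume(templateMask(ts), file.path(path, "gm_mask.nii"),
              datatype = "double")
  manifest <- list(version = ts@provenance$version %||% 1L,
                   ages = ts@ages, sexes = ts@sexes,
                   nSubjects = as.list(ts@nSubjects),
                   affine = as.vector(ts@affine),
                   provenance = ts@provenance[setdiff(names(ts@provenance),
                                                      "version")])
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveTemplates
#' @export
loadTemplates <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) dataError("no manifest.json under %s", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$version), 1L))
    dataError("unsupported template library version: %s", manifest$version)
  ages <- as.integer(manifest$ages)
  sexes <- as.character(manifest$sexes)
  affine <- matrix(as.numeric(manifest$affine), 4, 4)
  mu <- list(); sigma <- list()
  for (s in sexes) for (a in ages) {
    k <- paste(a, s, sep = "_")
    fm <- file.path(path, sprintf("mean_%s.nii", k))
    fs <- file.path(path, sprintf("sd_%s.nii", k))
    if (!file.exists(fm) || !file.exists(fs))
      dataError("template library is missing maps for (age %d, sex %s)", a, s)
    mu[[k]] <- readVolume(fm)@data
    sigma[[k]] <- readVolume(fs)@data
  }
  mask <- readVolume(file.path(path, "gm_mask.nii"))@data
  prov <- manifest$provenance
  prov$dim <- as.integer(prov$dim)
  prov$version <- 1L
  nSub <- unlist(manifest$nSubjects)
  nSub <- structure(as.integer(nSub), names = names(manifest$nSubjects))
  new("TemplateSet", mu = mu, sigma = sigma, nSubjects = nSub, mask = mask,
      affine = affine, ages = ages, sexes = sexes, provenance = prov)
}
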