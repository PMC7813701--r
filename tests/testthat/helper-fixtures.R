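# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

# small random volume on an anisotropic grid
randomVolume <- function(d = c(6, 6, 6), vs = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  A <- diag(c(vs, 1))
  A[1:3, 4] <- -vs * (d - 1) / 2
  brainVolume(array(rnorm(prod(d)), d), A)
}

# nonnegative variant for GM-map fixtures (template maps must be >= 0)
randomGMVolume <- function(d = c(4, 4, 4), seed = 1) {
  v <- randomVolume(d, seed = seed)
  brainVolume(abs(volData(v)), volAffine(v))
}

# the reference study conditions: default phantom spec
studySpec <- function() phantomSpec()

# normative library under the default study conditions (ages 16-77, both
# sexes, 6 per cell, 8-mm smoothing), built once
studyTemplates <- function() {
  if (is.null(.fixtures$ts)) {
    co <- generateCohort(studySpec(), ages = 16:77, nPerCell = 6, seed = 20,
                         smoothFWHM = 8)
    .fixtures$ts <- suppressWarnings(
      buildTemplates(co$cohort, maps = co$maps, fwhm = 8))
  }
  .fixtures$ts
}

# a tiny cohort on an 8^3 grid for template-math checks
tinyCohort <- function(nPerCell = 3, ages = 16:77) {
  key <- paste0("tiny_", nPerCell, "_", length(ages))
  if (is.null(.fixtures[[key]])) {
    spec <- phantomSpec(dim = c(8L, 8L, 8L), voxelSize = c(16, 16, 16))
    .fixtures[[key]] <- generateCohort(spec, ages = ages,
                                       nPerCell = nPerCell, seed = 7)
  }
  .fixtures[[key]]
}

expect_volumes_equal <- function(x, y, tol = 1e-12) {
  expect_true(sameGrid(x, y))
  expect_lt(max(abs(volData(x) - volData(y))), tol)
}
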