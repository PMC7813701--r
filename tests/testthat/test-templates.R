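# Normative template construction: windows, mean/SD math, mask, persistence.

test_that("window selection is inclusive at both bounds", {
  cohort <- data.frame(subject_id = sprintf("s%02d", 1:62), age = 16:77,
                       sex = "F", stringsAsFactors = FALSE)
  expect_setequal(selectWindow(cohort, 18, "F")$age, 16:20)
  expect_setequal(selectWindow(cohort, 75, "F")$age, 73:77)
  expect_setequal(selectWindow(cohort, 40, "F", halfWidth = 0)$age, 40)
  expect_error(selectWindow(cohort, 40, "M"), class = "voxnorm_window_empty")
  # fractional ages are floored before windowing
  cohort$age <- cohort$age + 0.9
  expect_setequal(floor(selectWindow(cohort, 18, "F")$age), 16:20)
})

test_that("a window of identical maps gives mu = map and sigma = 0", {
  M <- randomGMVolume(c(4, 4, 4), seed = 1)
  cohort <- data.frame(subject_id = c("a", "b", "c"), age = c(39, 40, 41),
                       sex = "F", stringsAsFactors = FALSE)
  maps <- list(a = M, b = M, c = M)
  ts <- suppressWarnings(buildTemplates(
    cohort, maps = maps, ageMin = 40, ageMax = 40, minN = 2,
    maskMeanThreshold = -Inf, sdFloor = -1))
  expect_volumes_equal(templateMean(ts, 40, "F"), M)
  expect_equal(max(abs(volData(templateSD(ts, 40, "F")))), 0)
})

test_that("template mean and SD match a brute-force per-voxel loop (n - 1 denominator)", {
  set.seed(42)
  maps <- lapply(1:5, function(i) randomGMVolume(c(4, 4, 4), seed = 100 + i))
  names(maps) <- sprintf("s%d", 1:5)
  cohort <- data.frame(subject_id = names(maps), age = c(38, 39, 40, 41, 42),
                       sex = "M", stringsAsFactors = FALSE)
  ts <- suppressWarnings(buildTemplates(cohort, maps = maps, ageMin = 40,
                                        ageMax = 40, maskMeanThreshold = -Inf,
                                        sdFloor = -1))
  mu <- volData(templateMean(ts, 40, "M"))
  sg <- volData(templateSD(ts, 40, "M"))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    xs <- vapply(maps, function(m) volData(m)[i, j, k], 0)
    expect_equal(mu[i, j, k], mean(xs), tolerance = 1e-12)
    expect_equal(sg[i, j, k], sd(xs), tolerance = 1e-12)  # stats::sd uses n-1
  }
  # hand-computed 3-subject check of the n-1 convention
  h <- c(0.2, 0.5, 0.8)
  expect_equal(sd(h), sqrt(sum((h - 0.5)^2) / 2))
})

test_that("the full library holds one template pair per age and sex (ages 18-75)", {
  co <- tinyCohort()
  ts <- suppressWarnings(buildTemplates(co$cohort, maps = co$maps, fwhm = 8))
  expect_equal(length(ts@mu), 116L)   # 58 ages x 2 sexes
  expect_equal(length(ts@sigma), 116L)
  expect_setequal(templateAges(ts), 18:75)
  expect_setequal(templateSexes(ts), c("F", "M"))
  # each window counted the exact inclusive subject set
  aInt <- floor(co$cohort$age)
  for (a in c(18, 40, 75)) {
    expected <- sum(co$cohort$sex == "F" & aInt >= a - 2 & aInt <= a + 2)
    expect_equal(nTemplateSubjects(ts, a, "F"), expected)
  }
})

test_that("windows below the minimum are errors; sparse windows warn", {
  cohort <- data.frame(subject_id = c("a", "b"), age = c(40, 40), sex = "F",
                       stringsAsFactors = FALSE)
  maps <- list(a = randomGMVolume(c(3, 3, 3), seed = 1),
               b = randomGMVolume(c(3, 3, 3), seed = 2))
  expect_error(suppressWarnings(
    buildTemplates(cohort, maps = maps, ageMin = 50, ageMax = 50)),
    class = "voxnorm_data_error")
  expect_warning(
    buildTemplates(cohort, maps = maps, ageMin = 40, ageMax = 40,
                   maskMeanThreshold = -Inf, sdFloor = -1),
    regexp = "below")
})

test_that("grid mismatches name the offending subjects", {
  cohort <- data.frame(subject_id = c("a", "b", "c"), age = c(40, 40, 40),
                       sex = "F", stringsAsFactors = FALSE)
  maps <- list(a = randomGMVolume(c(4, 4, 4), seed = 1),
               b = randomGMVolume(c(5, 5, 5), seed = 2),
               c = randomGMVolume(c(4, 4, 4), seed = 3))
  err <- tryCatch(buildTemplates(cohort, maps = maps, ageMin = 40, ageMax = 40),
                  error = identity)
  expect_s3_class(err, "voxnorm_geometry_error")
  expect_match(conditionMessage(err), "b")
})

test_that("the GM mask excludes low-mean and zero-variance voxels", {
  ts <- studyTemplates()
  mask <- volData(templateMask(ts))
  grand <- Reduce(`+`, ts@mu) / length(ts@mu)
  pooled <- sqrt(Reduce(`+`, lapply(ts@sigma, function(s) s^2)) / length(ts@sigma))
  expect_true(all(grand[mask > 0] > 0.1))
  expect_true(all(pooled[mask > 0] > 1e-6))
  expect_true(all(mask[grand <= 0.1] == 0))
  # the mask stays within the smoothed true GM ribbon support
  support <- volData(gaussianSmooth(phantomBaseline(studySpec()), 8)) > 0.01
  expect_true(all(support[mask > 0]))
})

test_that("template libraries round trip losslessly and fail loudly when incomplete", {
  co <- tinyCohort()
  sub <- co$cohort[floor(co$cohort$age) >= 38 & floor(co$cohort$age) <= 46, ]
  ts <- suppressWarnings(buildTemplates(sub, maps = co$maps, ageMin = 40,
                                        ageMax = 44, fwhm = 8))
  dir <- tempfile("tpl")
  saveTemplates(ts, dir)
  back <- loadTemplates(dir)
  expect_identical(back@mu, ts@mu)         # bit-for-bit arrays
  expect_identical(back@sigma, ts@sigma)
  expect_identical(back@nSubjects, ts@nSubjects)
  expect_equal(back@provenance$halfWidth, ts@provenance$halfWidth)
  expect_equal(back@provenance$fwhm, 8)
  expect_lt(max(abs(back@affine - ts@affine)), 1e-5)

  file.remove(file.path(dir, "mean_42_F.nii"))
  err <- tryCatch(loadTemplates(dir), error = identity)
  expect_s3_class(err, "voxnorm_data_error")
  expect_match(conditionMessage(err), "42")
})

test_that("template means recover the programmed aging slope within 10%", {
  spec <- phantomSpec(dim = c(12L, 12L, 12L), voxelSize = c(10, 10, 10))
  co <- generateCohort(spec, ages = 16:77, nPerCell = 6, seed = 31)
  ts <- suppressWarnings(buildTemplates(co$cohort, maps = co$maps))
  g0 <- volData(phantomBaseline(spec))
  vox <- which(g0 > 0.7)[1:5]
  ages <- templateAges(ts)
  for (v in vox) {
    muA <- vapply(ages, function(a) volData(templateMean(ts, a, "F"))[v], 0)
    slope <- unname(coef(lm(muA ~ ages))[2])
    target <- -spec@ageSlope * g0[v]
    expect_lt(abs(slope - target), 0.1 * abs(target))
  }
})
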