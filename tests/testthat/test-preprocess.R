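# Segmentation, registration, modulation and the composed chain.

test_that("EM segmentation recovers well-separated tissue plateaus", {
  spec <- phantomSpec(gmPeak = 1, edgeWidth = 0, noiseSD = 0, t1NoiseSD = 0.005)
  ph <- generatePhantom(spec, 18, "F", seed = 41)
  frac <- generatePhantom(phantomSpec(gmPeak = 1, edgeWidth = 0, noiseSD = 0,
                                      t1NoiseSD = 0), 18, "F", seed = 1)
  headMask <- brainVolume((volData(frac$t1) > 0.1) * 1, volAffine(ph$t1))
  gm <- segmentGM(ph$t1, headMask)
  # closed-form Gaussian posterior at the generating parameters is ~1 for
  # intensities this far apart; the fit should agree on true-GM voxels
  expect_gt(min(volData(gm)[frac$gmLabel]), 0.99)
  m <- attr(gm, "model")
  expect_s4_class(m, "SegmentationModel")
  expect_equal(sum(m@weights), 1, tolerance = 1e-9)
  expect_equal(m@means, sort(m@means))
})

test_that("segmentation rejects degenerate inputs", {
  flat <- brainVolume(array(1, c(6, 6, 6)))
  mask <- brainVolume(array(1, c(6, 6, 6)))
  expect_error(segmentGM(flat, mask), class = "voxnorm_degenerate_fit")
})

test_that("segmentation of the reference phantom overlaps the true GM ribbon (Dice > 0.95)", {
  ph <- generatePhantom(studySpec(), 30, "F", seed = 7)
  gm <- suppressWarnings(segmentGM(ph$t1))
  post <- volData(gm) > 0.5
  dice <- 2 * sum(post & ph$gmLabel) / (sum(post) + sum(ph$gmLabel))
  expect_gt(dice, 0.95)
})

test_that("registration recovers identity, translation and scale", {
  ref <- generatePhantom(studySpec(), 30, "F", seed = 1)$t1

  idXfm <- registerAffine(ref, ref)
  expect_lt(max(abs(xfmMatrix(idXfm) - diag(4))), 1e-6)
  expect_identical(idXfm@direction, "subject2template")

  mov <- resampleVolume(ref, translationTransform(c(-3, 2, -1)))
  xfm <- registerAffine(mov, ref)
  # recovered translation within 0.5 voxel (2 mm at 4-mm voxels)
  expect_lt(max(abs(xfmMatrix(xfm)[1:3, 4] - c(3, -2, 1))), 2)

  mov2 <- resampleVolume(ref, scalingTransform(1 / 1.10))
  xfm2 <- registerAffine(mov2, ref)
  expect_equal(det(xfmMatrix(xfm2)[1:3, 1:3])^(1 / 3), 1.10, tolerance = 0.02)

  flat <- brainVolume(array(0, c(8, 8, 8)))
  expect_error(registerAffine(flat, ref), class = "voxnorm_registration_error")
})

test_that("modulation preserves total GM volume and respects the Jacobian", {
  spec <- phantomSpec(noiseSD = 0)
  gmv <- gmVolume(generatePhantom(spec, 30, "F", seed = 3)$gm)
  asTemplate <- function(v) new("GMMap", volume = v, space = "template",
                                modulated = FALSE, smoothedFWHM = NA_real_)

  # identity: unchanged
  gmT <- asTemplate(gmv)
  expect_volumes_equal(gmVolume(modulateGM(gmT, identityTransform())), gmv)

  # isotropic subject->template expansion s: every voxel scaled by 1/s^3,
  # total template-space volume matches subject space within 1%
  for (s in c(1.1, 0.9)) {
    tr <- scalingTransform(s, direction = "subject2template")
    warped <- asTemplate(resampleVolume(gmv, tr))
    mod <- modulateGM(warped, tr)
    expect_equal(volData(mod), volData(warped@volume) / s^3, tolerance = 1e-12)
    expect_equal(totalGMVolume(mod) / totalGMVolume(gmv), 1, tolerance = 0.01)
  }

  # unit-determinant shear: values unchanged
  sh <- diag(4); sh[1, 2] <- 0.3
  expect_volumes_equal(gmVolume(modulateGM(gmT, affineTransform(sh))), gmv)

  expect_error(modulateGM(modulateGM(gmT, identityTransform()),
                          identityTransform()),
               class = "voxnorm_state_error")
})

test_that("the composed chain on an aligned, noise-free plateau phantom equals smoothing the truth", {
  spec <- phantomSpec(gmPeak = 1, edgeWidth = 0, noiseSD = 0, t1NoiseSD = 0)
  ph <- generatePhantom(spec, 18, "F", seed = 1)
  headMask <- brainVolume((volData(ph$t1) > 0.1) * 1, volAffine(ph$t1))
  res <- preprocessSubject(ph$t1, ph$t1, fwhm = 8, mask = headMask)
  oracle <- gaussianSmooth(phantomBaseline(spec), 8)
  expect_lt(max(abs(volData(res$gm) - volData(oracle))), 1e-6)
  expect_lt(max(abs(xfmMatrix(res$transform) - diag(4))), 1e-12)
  expect_true(res$gm@modulated)
  expect_equal(res$gm@smoothedFWHM, 8)

  # determinism: same input twice -> bit-identical output
  res2 <- preprocessSubject(ph$t1, ph$t1, fwhm = 8, mask = headMask)
  expect_identical(volData(res$gm), volData(res2$gm))
})

test_that("stage errors are labeled and degenerate inputs fail in segmentation", {
  zero <- brainVolume(array(0, c(8, 8, 8)))
  ref <- generatePhantom(studySpec(), 30, "F", seed = 1)$t1
  full <- brainVolume(array(1, c(8, 8, 8)))
  err <- tryCatch(preprocessSubject(zero, ref, mask = full), error = identity)
  expect_s3_class(err, "voxnorm_degenerate_fit")
  expect_match(conditionMessage(err), "segmentation")
  # without an explicit mask the flat image already fails at brain masking
  err2 <- tryCatch(preprocessSubject(zero, ref), error = identity)
  expect_match(conditionMessage(err2), "stage")
})

test_that("bypass ingest smooths unsmoothed maps and is idempotent", {
  ph <- generatePhantom(studySpec(), 40, "M", seed = 9)
  sm <- asPreprocessedGM(ph$gm, 8)
  expect_equal(sm@smoothedFWHM, 8)
  expect_identical(asPreprocessedGM(sm, 8), sm)   # untouched
  expect_identical(asPreprocessedGM(sm, 12), sm)  # still untouched
  subjMap <- new("GMMap", volume = gmVolume(ph$gm), space = "subject",
                 modulated = FALSE, smoothedFWHM = NA_real_)
  expect_error(asPreprocessedGM(subjMap), class = "voxnorm_state_error")
})

test_that("end-to-end template-space GM volume tracks the phantom truth within 5%", {
  spec <- studySpec()
  ref <- generatePhantom(spec, 40, "F", seed = 1)$t1
  # tissue-label truth: the GM ribbon volume (baseline pattern / its peak)
  truthVol <- totalGMVolume(phantomBaseline(spec)) / spec@gmPeak
  for (s in seq_len(2)) {
    ph <- generatePhantom(spec, 25 + 20 * s, "F", seed = 100 + s)
    res <- suppressWarnings(preprocessSubject(ph$t1, ref, fwhm = 8))
    expect_equal(totalGMVolume(res$gm) / truthVol, 1, tolerance = 0.05)
  }
})
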