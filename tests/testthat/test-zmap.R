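# z-map computation, thresholding, back-transformation, fusion and QC.

# small consistent (g, mu, sigma, mask) fixture
zFixture <- function(d = c(6, 6, 6), seed = 21) {
  set.seed(seed)
  A <- diag(4)
  g <- brainVolume(array(abs(rnorm(prod(d), 0.5, 0.2)), d), A)
  mu <- brainVolume(array(abs(rnorm(prod(d), 0.5, 0.2)), d), A)
  sigma <- brainVolume(array(runif(prod(d), 0.02, 0.1), d), A)
  mask <- brainVolume(array(1, d), A)
  list(g = g, mu = mu, sigma = sigma, mask = mask)
}

test_that("z-map equals (g - mu) / sigma inside the mask and matches a scalar loop", {
  f <- zFixture()
  z <- computeZMap(f$g, f$mu, f$sigma, f$mask)
  d <- gridDim(f$g)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    expect_equal(volData(z)[i, j, k],
                 (volData(f$g)[i, j, k] - volData(f$mu)[i, j, k]) /
                   volData(f$sigma)[i, j, k],
                 tolerance = 1e-12)
  }
  # subject equal to the template mean -> z identically 0
  z0 <- computeZMap(f$mu, f$mu, f$sigma, f$mask)
  expect_equal(max(abs(volData(z0))), 0)
  # a voxel exactly 2.5 SD above the mean -> z = 2.5
  g2 <- volData(f$mu); g2[2, 3, 4] <- g2[2, 3, 4] + 2.5 * volData(f$sigma)[2, 3, 4]
  z2 <- computeZMap(brainVolume(g2, volAffine(f$mu)), f$mu, f$sigma, f$mask)
  expect_equal(volData(z2)[2, 3, 4], 2.5)
})

test_that("z-map respects the mask, the SD floor, and rejects grid mismatches", {
  f <- zFixture()
  m <- volData(f$mask); m[1, , ] <- 0
  s <- volData(f$sigma); s[6, 6, 6] <- 0
  z <- computeZMap(f$g, f$mu, brainVolume(s, volAffine(f$sigma)),
                   brainVolume(m, volAffine(f$mask)))
  expect_true(all(volData(z)[1, , ] == 0))
  expect_equal(volData(z)[6, 6, 6], 0)
  other <- randomVolume(c(5, 5, 5))
  expect_error(computeZMap(f$g, other, f$sigma, f$mask),
               class = "voxnorm_geometry_error")
})

test_that("thresholding keeps |z| strictly above the cut", {
  z <- brainVolume(array(c(2.5, -2.5, 2.5000001, -3, 0, 1.2, 7, -2.49),
                         c(2, 2, 2)))
  thr <- thresholdZMap(z, 2.5)
  expect_equal(as.vector(volData(thr)),
               c(0, 0, 2.5000001, -3, 0, 0, 7, 0))
  zero <- brainVolume(array(0, c(2, 2, 2)))
  expect_equal(max(abs(volData(thresholdZMap(zero)))), 0)
  expect_error(thresholdZMap(z, -1), class = "voxnorm_argument_error")
})

test_that("z linearity and symmetry hold exactly", {
  f <- zFixture(seed = 31)
  z <- computeZMap(f$g, f$mu, f$sigma, f$mask)
  # adding c * sigma(v) raises z(v) by exactly c
  for (cc in c(1, -2.5, 4)) {
    g2 <- volData(f$g); g2[3, 3, 3] <- g2[3, 3, 3] + cc * volData(f$sigma)[3, 3, 3]
    z2 <- computeZMap(brainVolume(g2, volAffine(f$g)), f$mu, f$sigma, f$mask)
    expect_equal(volData(z2)[3, 3, 3] - volData(z)[3, 3, 3], cc,
                 tolerance = 1e-10)
  }
  # negating the deviation negates z
  gneg <- brainVolume(2 * volData(f$mu) - volData(f$g), volAffine(f$g))
  zneg <- computeZMap(gneg, f$mu, f$sigma, f$mask)
  expect_equal(volData(zneg), -volData(z), tolerance = 1e-12)
})

test_that("back-transformation moves findings by the inverse transform", {
  # blob on a 16^3 grid, 2-mm voxels
  d <- c(16L, 16L, 16L)
  A <- diag(c(2, 2, 2, 1)); A[1:3, 4] <- -(d - 1)
  z <- array(0, d); z[8:9, 8:9, 8:9] <- 5
  zv <- gaussianSmooth(brainVolume(z, A), 3)

  expect_identical(zToSubjectSpace(zv, identityTransform(), d, A), zv)

  tr <- translationTransform(c(4, 0, -2), "subject2template")
  back <- zToSubjectSpace(zv, tr, d, A)
  cent <- function(v) {
    w <- volData(v) * (volData(v) > 2.5)
    idx <- which(w > 0, arr.ind = TRUE)
    colSums(idx * w[w > 0]) / sum(w[w > 0])
  }
  shiftVox <- cent(back) - cent(zv)
  expect_lt(max(abs(shiftVox - c(-2, 0, 1))), 0.5)  # -(4,0,-2) mm / 2 mm voxels

  # round trip template -> subject -> template preserves interior z
  fwd <- resampleVolume(back, tr, d, A)
  i <- 5:12
  expect_lt(max(abs(volData(fwd)[i, i, i] - volData(zv)[i, i, i])), 0.15)
  expect_error(zToSubjectSpace(zv, NULL, d, A), class = "voxnorm_state_error")
})

test_that("color fusion renders loss blue, gain red, and grayscale elsewhere", {
  set.seed(5)
  d <- c(8, 8, 8)
  t1 <- brainVolume(array(runif(prod(d)), d))
  z0 <- brainVolume(array(0, d))
  ov <- colorizeAndFuse(t1, z0)
  gray <- (volData(t1) - quantile(volData(t1), 0.01)) /
    diff(quantile(volData(t1), c(0.01, 0.99)))
  gray <- pmin(1, pmax(0, gray))
  for (ch in 1:3) expect_equal(ov[, , , ch], gray, tolerance = 1e-12,
                               ignore_attr = TRUE)

  z <- array(0, d); z[2, 2, 2] <- -5; z[6, 6, 6] <- 5
  ov2 <- colorizeAndFuse(t1, brainVolume(z, volAffine(t1)))
  expect_gt(ov2[2, 2, 2, 3], ov2[2, 2, 2, 1])  # blue > red at z = -5
  expect_gt(ov2[6, 6, 6, 1], ov2[6, 6, 6, 3])  # red > blue at z = +5
  expect_error(colorizeAndFuse(t1, z0, zCut = 3, zMax = 2),
               class = "voxnorm_argument_error")
})

test_that("overlay alignment QC counts colored voxels inside the brain mask", {
  d <- c(4, 4, 4)
  mask <- array(0, d); mask[1:2, , ] <- 1
  allIn <- array(0, d); allIn[1, , ] <- 1
  expect_equal(qcOverlayAlignment(allIn, mask)$fraction, 1)
  half <- array(0, d); half[2:3, 1, 1] <- 1
  expect_equal(qcOverlayAlignment(half, mask)$fraction, 0.5)
  none <- array(0, d)
  qc <- qcOverlayAlignment(none, mask)
  expect_equal(qc$fraction, 1)
  expect_true(qc$noFindings)
})

test_that("mapSubject enforces the supported age range and sex categories", {
  ts <- studyTemplates()
  t1 <- generatePhantom(studySpec(), 40, "F", seed = 3)$t1
  expect_error(mapSubject(t1, ts, 80, "F"), class = "voxnorm_unsupported_age")
  expect_error(mapSubject(t1, ts, 17, "F"), class = "voxnorm_unsupported_age")
  expect_error(mapSubject(t1, ts, 40, "X"), class = "voxnorm_argument_error")
})

test_that("a null phantom maps with few suprathreshold voxels and passes QC", {
  ts <- studyTemplates()
  spec <- studySpec()
  ph <- generatePhantom(spec, 45, "M", seed = 77)
  am <- mapSubject(ph$t1, ts, 45, "M", gm = ph$gm)
  frac <- sum(volData(am@zThresholded) != 0) / sum(volData(templateMask(ts)) > 0)
  expect_lt(frac, 0.05)
  expect_true(am@qcPassed)
  expect_s4_class(am, "AtrophyMap")
  expect_equal(dim(am@overlay), c(gridDim(ph$t1), 3))
})

test_that("an injected -4 SD lesion is recovered as negative suprathreshold z", {
  ts <- studyTemplates()
  spec <- studySpec()
  ph <- generatePhantom(spec, 50, "F", seed = 88)
  sig <- templateSD(ts, 50, "F")
  les <- injectAtrophy(asPreprocessedGM(ph$gm, 8), c(40, 0, 0), 12, -4, sig)
  am <- mapSubject(ph$t1, ts, 50, "F", gm = les)
  lm_ <- attr(les, "lesionMask") & (volData(templateMask(ts)) > 0)
  zl <- volData(am@zTemplate)[lm_]
  expect_lt(mean(zl), -2.5)
  expect_equal(mean(zl), -4, tolerance = 0.5)
  expect_true(all(volData(am@zThresholded)[volData(am@zThresholded) != 0 &
                                             lm_] < 0))
})
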