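test_that("foreground segmentation separates the intensity classes", {
  m <- matrix(0, 64, 64); m[20:40, 10:30] <- 1
  msk <- segmentForeground(m)
  expect_equal(msk, m == 1, ignore_attr = TRUE)
  expect_equal(attr(msk, "provenance")$method, "otsu")
  expect_error(segmentForeground(matrix(0.5, 16, 16)), "degenerate")
  fx <- segmentForeground(m, "fixed", level = 0.5)
  expect_equal(fx, m > 0.5, ignore_attr = TRUE)
  expect_error(segmentForeground(m, "fixed"), "level")
  ## all-background after thresholding is allowed
  m2 <- matrix(0, 32, 32); m2[1, 1] <- 1
  expect_equal(sum(segmentForeground(m2, "fixed", 2)), 0)
  ## segmenting at half the isolated-disc peak recovers the realized
  ## GFP+ fraction of a synthetic image to within the PSF-induced bias
  img <- generateRandomImage(ImageSpec("random", 512,
                                       backgroundFraction = 0.08, seed = 3))
  sf <- mean(segmentForeground(img, "fixed", 0.43))
  expect_lt(abs(sf / imageTruth(img)$realizedFraction - 1), 0.12)
})

test_that("radial profiles average annuli and conserve mass", {
  m <- matrix(0.4, 101, 101)
  pr <- radialProfile(m, dr = 2, pitch = 1)
  expect_equal(pr@values[pr@npix > 0],
               rep(0.4, sum(pr@npix > 0)))
  ## mass conservation over the covered disc
  img <- generateRandomImage(ImageSpec("random", 128, seed = 2))
  pr2 <- radialProfile(img, dr = 5)
  m2 <- intensity(img)
  expect_equal(sum(pr2@values * pr2@npix, na.rm = TRUE), sum(m2),
               tolerance = 1e-12)
  ## a single bright annulus produces a unique maximum at its radius
  co <- 0:100
  r <- sqrt(outer((co - 50)^2, (co - 50)^2, "+"))
  ann <- matrix(0, 101, 101); ann[abs(r - 30) < 2] <- 1
  pra <- radialProfile(ann, center = c(50, 50), dr = 1, pitch = 1)
  expect_lt(abs(pra@radii[which.max(pra@values)] - 30), 2)
  ## errors and conventions
  expect_error(radialProfile(m, dr = 0.5, pitch = 1), "pitch")
  expect_error(radialProfile(m, center = c(500, 0), dr = 1, pitch = 1),
               "inside")
  ## empty annuli are NA, not zero
  small <- matrix(1, 11, 11)
  prs <- radialProfile(small, center = c(0, 0), dr = 1, pitch = 1, rmax = 20)
  expect_true(anyNA(prs@values) || all(prs@npix > 0))
})

test_that("peak detection honours prominence and alternation", {
  mono <- profileFromValues(seq(0, 1, length.out = 50))
  expect_equal(nrow(detectPeaks(mono)@peaks), 0)
  ## triangle wave with 4 teeth
  tooth <- c(seq(0, 1, by = 0.2), seq(0.8, 0.2, by = -0.2))
  tri <- profileFromValues(c(rep(tooth, 4), 0))
  ps <- detectPeaks(tri, prominence = 0.5)
  expect_equal(nrow(ps@peaks), 4)
  expect_equal(ps@peaks$height, rep(1, 4))
  expect_equal(nrow(ps@valleys), 3)
  ## valleys interleave peaks
  expect_true(all(ps@valleys$index > head(ps@peaks$index, -1) &
                  ps@valleys$index < tail(ps@peaks$index, -1)))
  ## small bumps are rejected at high prominence
  bump <- profileFromValues(c(0, 0.1, 0, rep(c(0, 1, 0), 2)))
  expect_equal(nrow(detectPeaks(bump, prominence = 0.5)@peaks), 2)
  expect_error(detectPeaks(profileFromValues(c(1, 2, 1))), "5")
})

test_that("valley-to-peak ratio is the mean depth over flanking heights", {
  v <- c(0, 1, 0.2, 1, 0)
  ps <- detectPeaks(profileFromValues(c(0, v, 0)), prominence = 0.3)
  expect_equal(valleyToPeakRatio(ps), 0.2)
  ## zero valleys give ratio 0
  ps0 <- detectPeaks(profileFromValues(c(0, 0, 1, 0, 1, 0, 0)),
                     prominence = 0.3)
  expect_equal(valleyToPeakRatio(ps0), 0)
  ## filling the valleys monotonically raises the ratio
  ratios <- vapply(c(0, 0.25, 0.5, 0.75), function(fill) {
    vv <- c(0, 1, fill, 1, fill, 1, 0)
    valleyToPeakRatio(detectPeaks(profileFromValues(c(0, vv, 0)),
                                  prominence = 0.2))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  ## undefined with fewer than 2 peaks
  one <- detectPeaks(profileFromValues(c(0, 0, 1, 0, 0)), prominence = 0.3)
  expect_warning(r1 <- valleyToPeakRatio(one), "undefined")
  expect_true(is.na(r1))
})

test_that("FWHM matches rectangular and Gaussian references", {
  ## rectangular peak of width 20 samples (dr = 1 um)
  v <- rep(0, 100); v[41:60] <- 1
  pr <- profileFromValues(v)
  ps <- detectPeaks(pr, prominence = 0.3)
  fw <- ringFWHM(pr, ps, 1)
  expect_lt(abs(fw - 20), 1.01)
  ## Gaussian ridge: FWHM = 2.3548 sigma
  x <- 0:199; sig <- 12
  g <- profileFromValues(exp(-(x - 100)^2 / (2 * sig^2)))
  psg <- detectPeaks(g, prominence = 0.3)
  fwg <- ringFWHM(g, psg, 1)
  expect_lt(abs(fwg - 2.3548 * sig) / (2.3548 * sig), 0.05)
  ## half-max crossing centre is reported for ROI placement
  expect_lt(abs(attr(fwg, "center") - 100.5), 1)
  ## censored on one side
  vc <- c(seq(0, 1, length.out = 30), rep(1, 5))
  pc <- profileFromValues(vc)
  psc <- new("PeakSet", peaks = data.frame(position = 34, height = 1,
                                           index = 34L),
             valleys = data.frame(position = numeric(0), depth = numeric(0),
                                  index = integer(0)),
             prominence = 0.1)
  expect_warning(fwc <- ringFWHM(pc, psc, 1), "censored")
  expect_true(is.na(fwc))
})

test_that("ROI enhancement reproduces constructed density contrasts", {
  ## deterministic fixture: 50% fill on-pattern, 10% in the control
  n <- 400
  onMask <- matrix(rep(c(TRUE, FALSE), length.out = n), n, n)   # 50%
  ctrlMask <- matrix(rep(c(TRUE, rep(FALSE, 9)), length.out = n), n, n) # 10%
  lay <- roiLayout(center = c(200, 200), ringRadius = 120, lineWidth = 40)
  res <- roiDensityEnhancement(onMask, lay, ctrlMask, pitch = 1)
  expect_equal(res$byLocation$mean[res$byLocation$location == "on_pattern"],
               0.5, tolerance = 0.01)
  expect_equal(res$byLocation$mean[res$byLocation$location == "random"],
               0.1, tolerance = 0.05)
  expect_equal(res$enhancementPct, 400, tolerance = 25)
  expect_equal(nrow(res$roi), 12)   # 3 ROIs x 4 locations
  ## identical masks give 0% exactly (same ROIs on both)
  same <- roiDensityEnhancement(onMask, lay, onMask, pitch = 1)
  expect_equal(same$enhancementPct, 0)
  ## zero control is flagged
  expect_warning(
    z <- roiDensityEnhancement(onMask, lay, matrix(FALSE, n, n), pitch = 1),
    "undefined")
  expect_true(is.na(z$enhancementPct))
  ## out-of-image ROI errors
  layBad <- roiLayout(center = c(10, 10), ringRadius = 120, lineWidth = 40)
  expect_error(roiDensityEnhancement(onMask, layBad, ctrlMask, pitch = 1),
               "outside")
  ## layout geometry: 3 per location, distal/proximal offset 1.5 linewidths
  pos <- lay@positions
  expect_equal(as.integer(table(pos$location)), rep(3L, 4))
  don <- pos[pos$location == "on_pattern", ]
  ddi <- pos[pos$location == "distal", ]
  expect_equal(sqrt((ddi$cx_um - 200)^2 + (ddi$cy_um - 200)^2),
               rep(120 + 60, 3))
  expect_equal(sqrt((don$cx_um - 200)^2 + (don$cy_um - 200)^2), rep(120, 3))
})

test_that("profile smoothing preserves plateau FWHM", {
  v <- rep(0.1, 200); v[81:120] <- 1
  pr <- profileFromValues(v)
  sm <- smoothProfile(pr, 15)
  ps <- detectPeaks(sm, prominence = 0.5)
  fw <- ringFWHM(sm, ps, 1)
  expect_lt(abs(fw - 40), 2)
  expect_error(smoothProfile(pr, 4), "odd")
})
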