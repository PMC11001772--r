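test_that("generators are pure functions of spec and seed", {
  fld <- ringField128()
  sp <- ImageSpec("rings", imageSize = 256, enhancementPct = 200,
                  backgroundFraction = 0.1, seed = 11)
  a <- generatePatternImage(sp, fld)
  b <- generatePatternImage(sp, fld)
  expect_identical(intensity(a), intensity(b))
  expect_identical(imageTruth(a)$cellMask, imageTruth(b)$cellMask)
  r1 <- generateRandomImage(ImageSpec("random", 256, seed = 5))
  r2 <- generateRandomImage(ImageSpec("random", 256, seed = 5))
  expect_identical(intensity(r1), intensity(r2))
  n1 <- generateNetworkImage(NetworkSpec(day = 3, ribbonCount = 5,
                                         imageSize = 256, seed = 9))
  n2 <- generateNetworkImage(NetworkSpec(day = 3, ribbonCount = 5,
                                         imageSize = 256, seed = 9))
  expect_identical(intensity(n1), intensity(n2))
  ## the callers' RNG stream is untouched
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(generateRandomImage(ImageSpec("random", 64, seed = 2)))
  expect_identical(rnorm(1), before)
})

test_that("realized area fractions match the programmed ground truth", {
  fld <- ringField128()
  sp <- ImageSpec("rings", imageSize = 1024, pixelPitch = 2.5,
                  backgroundFraction = 0.05, enhancementPct = 438, seed = 1)
  img <- generatePatternImage(sp, fld)
  tr <- imageTruth(img)
  expect_equal(tr$programmedOnFraction, 0.05 * 5.38)
  expect_lt(abs(tr$realizedOnFraction / tr$programmedOnFraction - 1), 0.02)
  expect_lt(abs(tr$realizedOffFraction / tr$programmedOffFraction - 1), 0.02)
  ## no enhancement: on/off ratio is 1
  sp0 <- ImageSpec("rings", imageSize = 1024, backgroundFraction = 0.05,
                   enhancementPct = 0, seed = 2)
  tr0 <- imageTruth(generatePatternImage(sp0, fld))
  expect_equal(tr0$realizedOnFraction / tr0$realizedOffFraction, 1,
               tolerance = 0.02)
  ## honeycomb geometry fills the same contract
  sq <- squareModeField(ModeSpec("square", 5, 1, 15, 128))
  trh <- imageTruth(generatePatternImage(
    ImageSpec("honeycomb", imageSize = 1024, backgroundFraction = 0.05,
              enhancementPct = 200, seed = 3), sq))
  expect_lt(abs(trh$realizedOnFraction / trh$programmedOnFraction - 1), 0.02)
  expect_lt(abs(trh$realizedOffFraction / trh$programmedOffFraction - 1), 0.02)
  ## saturating programmed fraction is rejected
  expect_error(ImageSpec("rings", backgroundFraction = 0.3,
                         enhancementPct = 250))
})

test_that("random control is a homogeneous Poisson disc process", {
  ## the 2% realized-fraction contract holds at 1024^2 and above
  fr <- vapply(1:3, function(s) {
    imageTruth(generateRandomImage(
      ImageSpec("random", 1024, backgroundFraction = 0.05,
                seed = s)))$realizedFraction
  }, numeric(1))
  expect_true(all(abs(fr / 0.05 - 1) < 0.02))
  ## quadrat-count dispersion (16 quadrats) consistent with Poisson:
  ## the index of dispersion averages to 1 across seeds
  disp <- vapply(1:20, function(s) {
    tr <- imageTruth(generateRandomImage(
      ImageSpec("random", 256, backgroundFraction = 0.05, seed = 100 + s)))
    ci <- (tr$centers - 1) %% 256; cj <- (tr$centers - 1) %/% 256
    q <- table(factor(pmin(ci %/% 64, 3) + 4 * pmin(cj %/% 64, 3),
                      levels = 0:15))
    var(as.numeric(q)) / mean(q)
  }, numeric(1))
  expect_lt(abs(mean(disp) - 1), 0.2)
})

test_that("ribbon networks record their centerlines and widths", {
  sp <- networkSpecForDay(5, "random", ribbonCount = 8, imageSize = 512,
                          pixelPitch = 1.25, seed = 4)
  expect_equal(sp@ribbonWidthMean, 4.5)
  expect_equal(sp@ribbonWidthSd, 8.8)
  expect_equal(networkSpecForDay(5, "patterned")@ribbonWidthMean, 4.1)
  expect_equal(networkSpecForDay(5, "patterned")@ribbonWidthSd, 9.5)
  img <- generateNetworkImage(sp)
  tr <- imageTruth(img)
  expect_length(tr$widthsUm, 8)
  expect_length(tr$centerlines, 8)
  expect_true(all(tr$widthsUm >= 1.25))      # truncated at one pixel
  ## day presets carry the published width statistics
  expect_equal(networkSpecForDay(1, "patterned")@ribbonWidthMean, 13.1)
  expect_equal(networkSpecForDay(3, "patterned")@ribbonWidthSd, 18.9)
  expect_equal(networkSpecForDay(3, "random")@ribbonWidthMean, 9.3)
  ## zero ribbons -> empty image
  e <- generateNetworkImage(NetworkSpec(day = 1, ribbonCount = 0,
                                        imageSize = 128, seed = 1))
  expect_equal(sum(intensity(e)), 0)
})

test_that("network thickness recovers the area-weighted programmed widths", {
  sp <- NetworkSpec(day = 5, ribbonWidthMean = 10, ribbonWidthSd = 3,
                    ribbonCount = 15, imageSize = 512, pixelPitch = 1.25,
                    seed = 6)
  img <- generateNetworkImage(sp)
  tr <- imageTruth(img)
  st <- thicknessStats(localThickness(tr$cellMask, 1.25))
  ## map mean ~ area-weighted mean of the sampled widths (wide ribbons
  ## carry proportionally more pixels); rasterisation adds ~1 px
  predicted <- sum(tr$widthsUm^2) / sum(tr$widthsUm)
  expect_lt(abs(st$mean - predicted) / predicted, 0.2)
})

test_that("pattern images put intensity ridges on the simulated nodal radii", {
  fld <- ringField128()
  sp <- ImageSpec("rings", imageSize = 1024, pixelPitch = 2.5,
                  backgroundFraction = 0.05, enhancementPct = 438, seed = 3)
  img <- generatePatternImage(sp, fld)
  radii <- imageTruth(img)$nodalRadiiUm
  prof <- smoothProfile(radialProfile(img, dr = 2.5,
                                      rmax = 1023 * 2.5 / 2), 15)
  pks <- detectPeaks(prof, 0.5)
  expect_equal(nrow(pks@peaks), 4)
  for (k in 1:4) {
    fw <- ringFWHM(prof, pks, k)
    expect_lt(abs(attr(fw, "center") - radii[k]), 2 * 2.5)
  }
  ## the same ridges appear in a symmetry-line profile across the centre
  ctr <- 1023 * 2.5 / 2
  pr <- symmetryLineProfile(img, c(0, ctr), c(2 * ctr, ctr), 1024)
  expect_equal(nrow(pr), 1024)
  expect_true(all(is.finite(pr$value)))
})
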