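#' Synthetic patterned cell image
#'
#' Renders GFP+ cells as opaque discs under a Boolean (Poisson disc) model
#' whose intensity differs on and off the pattern lines, then applies a
#' Gaussian point-spread blur (sigma = `cellRadius / 2`). The on-pattern
#' region is the nodal-line band of width `lineWidth` of the supplied
#' standing-wave mode, re-evaluated with the chamber scaled to the image
#' field of view (a desk-scale stand-in for the full chamber scan). The
#' placement intensity in each region is calibrated (Poisson top-up rounds)
#' so that the realized binarized area fractions match the programmed
#' `backgroundFraction` and `backgroundFraction * (1 + enhancementPct/100)`;
#' the realized values are recorded in the ground truth.
#'
#' The off-pattern fraction is measured away from the band (beyond
#' `lineWidth/2 + 2 * cellRadius` from the nodal set) so that disc spill-over
#' at the band edge does not contaminate it.
#'
#' @param spec an [ImageSpec] with `geometry` `"rings"` or `"honeycomb"`.
#' @param field a [WaveField] from [roundModeField] (rings) or
#'   [squareModeField] (honeycomb) providing the mode indices.
#' @return A [SyntheticImage]; `imageTruth()` carries `mask` (pattern band),
#'   `cellMask`, programmed/realized fractions, nodal ring radii (um, rings
#'   only), the seed and the spec.
#' @examples
#' fld <- roundModeField(ModeSpec("round", 0, 4, 21, 128))
#' img <- generatePatternImage(ImageSpec("rings", imageSize = 256,
#'   enhancementPct = 100, seed = 1), fld)
#' @export
generatePatternImage <- function(spec, field) {
  stopifnot(is(spec, "ImageSpec"), is(field, "WaveField"))
  if (!spec@geometry %in% c("rings", "honeycomb"))
    stop("geometry must be 'rings' or 'honeycomb' (use generateRandomImage for controls)")
  if ((spec@geometry == "rings") != (field@spec@shape == "round"))
    stop("field shape does not match the requested geometry")
  withSeed(spec@seed, {
    n <- spec@imageSize
    pitch <- spec@pixelPitch
    Wum <- n * pitch
    ## re-evaluate the mode with the chamber scaled into the image frame;
    ## round chambers are inscribed at 94% of the field so the boundary
    ## nodal circle (where cells also condense) is fully visible
    mspec <- field@spec
    if (mspec@shape == "round") {
      spec2 <- ModeSpec("round", mspec@m, mspec@n, 0.94 * Wum / 2000, 64L)
      co <- ((seq_len(n) - 1L) * pitch - (Wum - pitch) / 2) / 1000
    } else {
      spec2 <- ModeSpec("square", mspec@m, mspec@n, Wum / 1000, 64L)
      co <- (seq_len(n) - 1L) * pitch / 1000
    }
    X <- matrix(co, n, n)
    Y <- matrix(co, n, n, byrow = TRUE)
    if (mspec@shape == "round" && mspec@m == 0L) {
      ## exact distance to the concentric nodal circles
      alpha <- besselZero(0, seq_len(mspec@n))
      rk <- spec2@chamberDim * alpha / alpha[mspec@n]
      r <- sqrt(X^2 + Y^2)
      dmm <- abs(r - rk[1])
      for (k in rk[-1]) dmm <- pmin(dmm, abs(r - k))
      dUm <- dmm * 1000
    } else {
      ## first-order distance |zeta| / |grad zeta| to the nodal set
      Z <- .evalMode(spec2, X, Y, mask = FALSE)
      dUm <- .nodalDistance(Z, pitch / 1000) * 1000
    }
    band <- dUm <= spec@lineWidth / 2

    fOn <- spec@backgroundFraction * (1 + spec@enhancementPct / 100)
    fOff <- spec@backgroundFraction
    rpx <- spec@cellRadius / pitch
    M <- matrix(FALSE, n, n)
    offMeasure <- which(dUm > spec@lineWidth / 2 + 2 * spec@cellRadius)
    ## off region first: the band top-up then accounts for discs spilling
    ## across the band edge
    M <- .fillRegion(M, which(!band), offMeasure, fOff, rpx)$mask
    M <- .fillRegion(M, which(band), which(band), fOn, rpx)$mask

    truth <- list(
      mask = band,
      cellMask = M,
      programmedOnFraction = fOn, programmedOffFraction = fOff,
      realizedOnFraction = mean(M[band]),
      realizedOffFraction = mean(M[offMeasure]),
      seed = spec@seed, spec = spec, modeSpec = spec2)
    if (mspec@shape == "round" && mspec@m == 0L) {
      alpha <- besselZero(0, seq_len(mspec@n))
      truth$nodalRadiiUm <- spec2@chamberDim * 1000 * alpha / alpha[mspec@n]
    }
    new("SyntheticImage",
        intensity = .gblur(M * 1, (spec@cellRadius / 2) / pitch),
        pixelPitch = pitch, truth = truth)
  })
}

## Boolean-model rendering of one region with top-up calibration:
## centers drawn uniformly over `region`, realized coverage measured over
## `measure`, topped up until within 0.5% relative of `target`
.fillRegion <- function(M, region, measure, target, rpx, maxRounds = 12L) {
  if (!length(region) || target <= 0) return(list(mask = M,
                                                  centers = integer(0)))
  a <- nrow(.discOffsets(rpx))          # exact rasterized disc area, px
  ## Poisson count for 85% of the deficit (relative to coverage already
  ## present, e.g. disc spill from a neighbouring region), then calibrated
  ## top-up rounds; the margin keeps count fluctuations below the target
  realized0 <- mean(M[measure])
  if (realized0 >= target) return(list(mask = M, centers = integer(0)))
  lam0 <- log((1 - realized0) / (1 - target)) / a
  nAdd <- rpois(1, 0.85 * lam0 * length(region))
  centers <- sample(region, nAdd, replace = TRUE)
  M <- .stampDiscs(M, centers, rpx)
  for (i in seq_len(maxRounds)) {
    realized <- mean(M[measure])
    if (realized >= target * 0.995) break
    ## deterministic top-up count (placement stays uniform): calibrates the
    ## realized fraction without last-round Poisson overshoot
    lamAdd <- log((1 - realized) / (1 - target)) / a
    nAdd <- max(1L, round(lamAdd * length(region)))
    more <- sample(region, nAdd, replace = TRUE)
    centers <- c(centers, more)
    M <- .stampDiscs(M, more, rpx)
  }
  list(mask = M, centers = centers)
}

#' Synthetic stationary-control image
#'
#' Spatially homogeneous Poisson placement of cell discs at the programmed
#' `backgroundFraction`, emulating cells seeded without sound application.
#' The truth carries the realized fraction and the sampled disc centres
#' (linear indices, for point-pattern diagnostics); there is no pattern
#' mask.
#'
#' @param spec an [ImageSpec] with `geometry = "random"`.
#' @return A [SyntheticImage].
#' @export
generateRandomImage <- function(spec) {
  stopifnot(is(spec, "ImageSpec"))
  if (spec@geometry != "random") stop("geometry must be 'random'")
  withSeed(spec@seed, {
    n <- spec@imageSize
    rpx <- spec@cellRadius / spec@pixelPitch
    M <- matrix(FALSE, n, n)
    all <- seq_len(n * n)
    fill <- .fillRegion(M, all, all, spec@backgroundFraction, rpx)
    M <- fill$mask
    new("SyntheticImage",
        intensity = .gblur(M * 1, (spec@cellRadius / 2) / spec@pixelPitch),
        pixelPitch = spec@pixelPitch,
        truth = list(cellMask = M, centers = fill$centers,
                     programmedFraction = spec@backgroundFraction,
                     realizedFraction = mean(M),
                     seed = spec@seed, spec = spec))
  })
}

#' Add detector noise to a synthetic image
#'
#' Additive Gaussian intensity noise with SD equal to `sdFraction` of the
#' image dynamic range, clipped back to `[0, 1]`. The truth annotations are
#' kept; the noise parameters are appended to them.
#'
#' @param img a [SyntheticImage].
#' @param sdFraction noise SD as a fraction of the dynamic range.
#' @param seed RNG seed.
#' @return A [SyntheticImage].
#' @export
addIntensityNoise <- function(img, sdFraction = 0.1, seed = 1L) {
  stopifnot(is(img, "SyntheticImage"))
  withSeed(seed, {
    m <- img@intensity
    s <- sdFraction * diff(range(m))
    m <- pmin(pmax(m + rnorm(length(m), 0, s), 0), 1)
    tr <- img@truth
    tr$noise <- list(sdFraction = sdFraction, seed = seed)
    initialize(img, intensity = matrix(m, nrow(img@intensity)), truth = tr)
  })
}

#' Day presets for synthetic capillary networks
#'
#' Named width-distribution profiles for patterned and random (stationary)
#' capillary networks at culture days 1, 3 and 5. Means/SDs (um):
#' patterned 13.1/24.7, 10.6/18.9, 4.1/9.5; random 6.6/7.8, 9.3/12.5,
#' 4.5/8.8. Widths are drawn from these normals truncated at one pixel, so
#' the realized width distribution is right-shifted for the strongly
#' overdispersed presets; the sampled widths are recorded in the truth.
#'
#' @param day 1, 3 or 5.
#' @param condition `"patterned"` (ribbons follow nodal curves) or
#'   `"random"` (isotropic placement).
#' @param ... further arguments passed to [NetworkSpec()].
#' @return A [NetworkSpec].
#' @export
networkSpecForDay <- function(day, condition = c("patterned", "random"), ...) {
  condition <- match.arg(condition)
  day <- as.integer(day)
  tab <- list(patterned = rbind(`1` = c(13.1, 24.7), `3` = c(10.6, 18.9),
                                `5` = c(4.1, 9.5)),
              random = rbind(`1` = c(6.6, 7.8), `3` = c(9.3, 12.5),
                             `5` = c(4.5, 8.8)))[[condition]]
  p <- tab[as.character(day), ]
  NetworkSpec(day = day, ribbonWidthMean = p[1], ribbonWidthSd = p[2],
              alongPattern = condition == "patterned", ...)
}

#' Synthetic capillary ribbon-network image
#'
#' Renders capillary-like structures as smoothed ribbons: random smooth-walk
#' centerlines (or sub-segments of the nodal curves of `field` when
#' `alongPattern`) dilated to a per-ribbon width drawn from the spec's
#' truncated normal. The truth records every centerline and width.
#'
#' @param spec a [NetworkSpec].
#' @param field optional [WaveField]; required when `spec@alongPattern`.
#' @return A [SyntheticImage].
#' @export
generateNetworkImage <- function(spec, field = NULL) {
  stopifnot(is(spec, "NetworkSpec"))
  if (spec@alongPattern && is.null(field))
    stop("alongPattern networks need a wave field")
  withSeed(spec@seed, {
    n <- spec@imageSize
    pitch <- spec@pixelPitch
    Wum <- n * pitch
    M <- matrix(FALSE, n, n)
    nh <- spec@ribbonCount
    widths <- if (nh) pmax(rnorm(nh, spec@ribbonWidthMean,
                                 spec@ribbonWidthSd), pitch) else numeric(0)
    lines <- vector("list", nh)
    patternCurves <- NULL
    if (spec@alongPattern && nh) {
      patternCurves <- .imageFrameNodalCurves(field, n, pitch)
      if (!length(patternCurves)) stop("field has no nodal curves")
    }
    for (k in seq_len(nh)) {
      cl <- if (!is.null(patternCurves))
        .curveSegment(patternCurves[[sample.int(length(patternCurves), 1)]],
                      Wum)
      else .smoothWalk(Wum)
      lines[[k]] <- cl
      M <- .stampRibbon(M, cl, widths[k], pitch)
    }
    new("SyntheticImage",
        intensity = .gblur(M * 1, 1),
        pixelPitch = pitch,
        truth = list(cellMask = M, centerlines = lines, widthsUm = widths,
                     day = spec@day, seed = spec@seed, spec = spec))
  })
}

## nodal curves of the mode scaled into the image frame, um corner origin
.imageFrameNodalCurves <- function(field, n, pitch) {
  Wum <- n * pitch
  ns <- extractNodalSet(field)
  scale <- if (field@spec@shape == "round") {
    0.94 * Wum / 2 / field@spec@chamberDim   # match generatePatternImage
  } else Wum / field@spec@chamberDim
  shift <- if (field@spec@shape == "round") Wum / 2 else 0
  lapply(nodalCurves(ns), function(cc)
    cbind(x = cc$x_mm * scale + shift, y = cc$y_mm * scale + shift))
}

## random sub-segment of a polyline, resampled to ~2 um steps
.curveSegment <- function(cl, Wum) {
  np <- nrow(cl)
  if (np < 3) return(cl)
  i0 <- sample.int(max(np - 2L, 1L), 1)
  i1 <- min(np, i0 + sample.int(np, 1))
  seg <- cl[i0:i1, , drop = FALSE]
  seg[seg[, 1] >= 0 & seg[, 1] <= Wum & seg[, 2] >= 0 & seg[, 2] <= Wum, ,
      drop = FALSE]
}

## smooth random-walk centerline across the field of view (um)
.smoothWalk <- function(Wum) {
  len <- runif(1, 0.4, 0.9) * Wum
  step <- Wum / 400
  nstep <- max(ceiling(len / step), 2)
  th <- runif(1, 0, 2 * pi) + cumsum(rnorm(nstep, 0, 0.08))
  x <- runif(1, 0.1, 0.9) * Wum + c(0, cumsum(cos(th) * step))
  y <- runif(1, 0.1, 0.9) * Wum + c(0, cumsum(sin(th) * step))
  keep <- x >= 0 & x <= Wum & y >= 0 & y <= Wum
  cbind(x = x[keep], y = y[keep])
}

## dilate a centerline (um coords) to a ribbon of width w (um)
.stampRibbon <- function(M, cl, w, pitch) {
  if (is.null(cl) || nrow(cl) < 2) return(M)
  n <- nrow(M)
  rpx <- (w / 2) / pitch
  ## resample to steps fine enough for a smooth edge
  dists <- sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2)
  s <- c(0, cumsum(dists))
  stepUm <- max(pitch / 2, w / 5)
  ss <- seq(0, s[length(s)], by = stepUm)
  px <- approx(s, cl[, 1], ss)$y / pitch + 1
  py <- approx(s, cl[, 2], ss)$y / pitch + 1
  centers <- (round(py) - 1L) * n + round(px)
  centers <- centers[round(px) >= 1 & round(px) <= n &
                     round(py) >= 1 & round(py) <= n]
  .stampDiscs(M, unique(centers), rpx)
}
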