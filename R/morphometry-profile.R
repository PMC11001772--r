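.asIntensity <- function(image) {
  if (is(image, "SyntheticImage")) image@intensity else as.matrix(image)
}

#' Segment the GFP+ foreground of a fluorescence image
#'
#' Global thresholding of a single-channel image: Otsu's method (via
#' [EBImage::otsu]) or a fixed level. The mask is `TRUE` for GFP+ pixels;
#' the method and level are recorded in the `provenance` attribute.
#'
#' @param image a [SyntheticImage] or numeric matrix in `[0, 1]`.
#' @param method `"otsu"` or `"fixed"`.
#' @param level threshold for `method = "fixed"`.
#' @return Logical matrix with attribute `provenance`.
#' @export
segmentForeground <- function(image, method = c("otsu", "fixed"),
                              level = NULL) {
  method <- match.arg(method)
  m <- .asIntensity(image)
  if (method == "otsu") {
    if (diff(range(m)) == 0)
      stop("degenerate threshold: image is constant")
    level <- EBImage::otsu(EBImage::Image(m), range = range(m))
  } else if (is.null(level)) stop("'level' is required for method = 'fixed'")
  mask <- m > level
  attr(mask, "provenance") <- list(method = method, level = level)
  mask
}

#' Radial intensity profile
#'
#' Mean intensity over concentric annuli `[k dr, (k+1) dr)` around a centre.
#' Empty annuli are carried as `NA`, never zero-filled. The profile conserves
#' mass: `sum(values * npix)` equals the total intensity over the covered
#' disc.
#'
#' @param image a [SyntheticImage] or numeric matrix.
#' @param center centre in um (corner-origin pixel-centre coordinates);
#'   default the image centre.
#' @param dr annulus width, um; must be at least one pixel pitch.
#' @param pitch um per pixel (taken from a [SyntheticImage] automatically).
#' @param rmax optional largest radius to keep, um (e.g. half the image
#'   width, to drop the sparsely covered corner annuli).
#' @return A [RadialProfile].
#' @export
radialProfile <- function(image, center = NULL, dr = NULL, pitch = NULL,
                          rmax = Inf) {
  if (is(image, "SyntheticImage")) pitch <- image@pixelPitch
  if (is.null(pitch)) stop("'pitch' is required for matrix input")
  if (is.null(dr)) dr <- pitch
  if (dr < pitch) stop("'dr' must be at least the pixel pitch")
  m <- .asIntensity(image)
  n <- nrow(m)
  co <- (seq_len(n) - 1L) * pitch
  if (is.null(center)) center <- c(co[n] / 2, co[ncol(m)] / 2)
  if (center[1] < 0 || center[1] > co[n] || center[2] < 0 ||
      center[2] > (ncol(m) - 1) * pitch)
    stop("centre must lie inside the image")
  r <- sqrt(outer((co - center[1])^2, ((seq_len(ncol(m)) - 1) * pitch -
                                        center[2])^2, "+"))
  bin <- floor(r / dr)
  bin[r > rmax] <- NA
  K <- max(bin, na.rm = TRUE) + 1L
  keep <- !is.na(bin)
  sums <- rowsum(as.vector(m)[keep], as.vector(bin)[keep])
  cnts <- rowsum(rep(1L, sum(keep)), as.vector(bin)[keep])
  values <- rep(NA_real_, K)
  npix <- integer(K)
  at <- as.integer(rownames(sums)) + 1L
  values[at] <- sums / cnts
  npix[at] <- cnts
  new("RadialProfile", radii = (seq_len(K) - 1L) * dr, values = values,
      npix = npix, center = as.numeric(center), dr = dr)
}

#' Smooth a radial profile
#'
#' Centred moving average over `window` samples (odd; `NA` samples bridged
#' by linear interpolation first, edges extended). By default the average
#' is weighted by the annulus pixel counts, which suppresses the shot noise
#' of the small inner annuli (a single cell disc near the centre can
#' otherwise dominate the profile's dynamic range). Box smoothing preserves
#' the FWHM of plateau-like ring peaks; use before [detectPeaks] /
#' [ringFWHM] on raw profiles of disc images.
#'
#' @param profile a [RadialProfile].
#' @param window window size in samples (odd integer).
#' @param weightByCount weight samples by annulus pixel counts.
#' @return A smoothed [RadialProfile].
#' @export
smoothProfile <- function(profile, window = 15L, weightByCount = TRUE) {
  stopifnot(is(profile, "RadialProfile"))
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("'window' must be odd")
  if (window <= 1L) return(profile)
  v <- profile@values
  ok <- !is.na(v)
  if (sum(ok) >= 2)
    v[!ok] <- approx(which(ok), v[ok], xout = which(!ok), rule = 2)$y
  w <- if (weightByCount) pmax(as.numeric(profile@npix), 0) else
       rep(1, length(v))
  w[w == 0] <- min(w[w > 0], 1)    # bridged annuli get minimal weight
  h <- window %/% 2L
  pad <- function(x) c(rep(x[1], h), x, rep(x[length(x)], h))
  kern <- rep(1, window)
  num <- as.numeric(stats::filter(pad(v * w), kern, sides = 2))
  den <- as.numeric(stats::filter(pad(w), kern, sides = 2))
  sm <- (num / den)[(h + 1):(h + length(v))]
  initialize(profile, values = sm)
}

## local maxima of v with relative prominence >= promAbs; ties toward
## smaller index. Returns indices.
.prominentMaxima <- function(v, promAbs) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  ## plateau handling: keep the first index of equal-valued runs
  keep <- logical(length(cand))
  for (ii in seq_along(cand)) {
    i <- cand[ii]
    h <- v[i]
    ## walk left/right to the first point higher than h; the prominence is
    ## h minus the highest of the two intervening minima
    lmin <- h; j <- i
    while (j > 1 && v[j - 1] <= h) { j <- j - 1; lmin <- min(lmin, v[j]) }
    lbase <- if (j == 1) min(v[1:i]) else lmin
    rmin <- h; j <- i
    while (j < n && v[j + 1] <= h) { j <- j + 1; rmin <- min(rmin, v[j]) }
    rbase <- if (j == n) min(v[i:n]) else rmin
    keep[ii] <- (h - max(lbase, rbase)) >= promAbs
  }
  cand[keep]
}

#' Detect peaks and valleys in a radial profile
#'
#' Local maxima whose relative prominence is at least `prominence` times the
#' profile's dynamic range; the valleys are the minima between consecutive
#' retained peaks. Internal `NA` annuli are bridged by linear interpolation
#' before detection. A profile with no qualifying maxima yields an empty
#' [PeakSet] (no error).
#'
#' @param profile a [RadialProfile] with at least 5 samples.
#' @param prominence prominence as a fraction of the dynamic range.
#' @return A [PeakSet].
#' @export
detectPeaks <- function(profile, prominence = 0.1) {
  stopifnot(is(profile, "RadialProfile"))
  v <- profile@values
  if (length(v) < 5) stop("need at least 5 profile samples")
  ok <- !is.na(v)
  if (sum(ok) >= 2)
    v[!ok] <- approx(which(ok), v[ok], xout = which(!ok), rule = 2)$y
  rng <- diff(range(v))
  idx <- if (rng == 0) integer(0) else .prominentMaxima(v, prominence * rng)
  ## positions at annulus midpoints: [r, r+dr) carries mean radius r + dr/2
  peaks <- data.frame(position = profile@radii[idx] + profile@dr / 2,
                      height = v[idx], index = idx)
  valleys <- data.frame(position = numeric(0), depth = numeric(0),
                        index = integer(0))
  if (length(idx) >= 2) {
    vi <- vapply(seq_len(length(idx) - 1L), function(k) {
      seg <- idx[k]:idx[k + 1]
      seg[which.min(v[seg])]
    }, integer(1))
    valleys <- data.frame(position = profile@radii[vi] + profile@dr / 2,
                          depth = v[vi], index = vi)
  }
  new("PeakSet", peaks = peaks, valleys = valleys, prominence = prominence)
}

#' Valley-to-peak ratio of a radial profile
#'
#' Mean, over the valleys, of the valley depth divided by the mean height of
#' its two flanking peaks. Rises towards 1 as capillaries grow between the
#' patterned rings. Requires at least two peaks; otherwise returns `NA` with
#' a warning (undefined-ratio signal).
#'
#' @param peaks a [PeakSet].
#' @return A scalar in `[0, 1]` for nonnegative profiles.
#' @export
valleyToPeakRatio <- function(peaks) {
  stopifnot(is(peaks, "PeakSet"))
  if (nrow(peaks@peaks) < 2) {
    warning("valley-to-peak ratio undefined with fewer than 2 peaks")
    return(NA_real_)
  }
  h <- peaks@peaks$height
  mean(peaks@valleys$depth / ((h[-length(h)] + h[-1]) / 2))
}

#' Ring thickness from the FWHM of a profile peak
#'
#' Full width at half maximum of one detected peak, with the baseline taken
#' as the mean of the flanking valley depths (profile edge minima for
#' terminal peaks) and half-maximum crossings located by linear
#' interpolation between profile samples. If the profile never crosses the
#' half maximum on one side the width is censored: `NA` with a warning.
#'
#' @param profile a [RadialProfile].
#' @param peaks a [PeakSet] from [detectPeaks].
#' @param which index of the peak to measure (1 = innermost).
#' @return Width in um, with attributes `crossings` (the two half-maximum
#'   radii) and `center` (their midpoint — a plateau-robust estimate of the
#'   ring radius, used for ROI placement).
#' @export
ringFWHM <- function(profile, peaks, which = 1L) {
  stopifnot(is(profile, "RadialProfile"), is(peaks, "PeakSet"))
  if (nrow(peaks@peaks) < which) stop("no such peak")
  v <- profile@values
  ok <- !is.na(v)
  if (sum(ok) >= 2)
    v[!ok] <- approx(base::which(ok), v[ok], xout = base::which(!ok),
                     rule = 2)$y
  i <- peaks@peaks$index[which]
  h <- v[i]
  vl <- peaks@valleys
  left <- vl$depth[vl$index < i]
  right <- vl$depth[vl$index > i]
  baseline <- mean(c(if (length(left)) left[length(left)] else min(v[1:i]),
                     if (length(right)) right[1] else min(v[i:length(v)])))
  half <- baseline + (h - baseline) / 2
  r <- profile@radii + profile@dr / 2   # annulus midpoints
  cross <- function(side) {
    js <- if (side < 0) rev(seq_len(i - 1L)) else (i + 1L):length(v)
    if (i + side < 1 || i + side > length(v)) return(NA_real_)
    for (j in js) {
      if (v[j] <= half) {
        j2 <- j - side
        return(r[j] + (r[j2] - r[j]) * (half - v[j]) / (v[j2] - v[j]))
      }
    }
    NA_real_
  }
  lo <- cross(-1L); hi <- cross(1L)
  if (is.na(lo) || is.na(hi)) {
    warning("censored width: half maximum not crossed on one side")
    return(NA_real_)
  }
  structure(hi - lo, crossings = c(lo, hi), center = (lo + hi) / 2)
}

#' Automated ROI layout around a patterned ring
#'
#' Places three square ROIs per location at angles 0, 120 and 240 degrees:
#' `on_pattern` ROIs centred on the detected ring radius, `distal` /
#' `proximal` ROIs offset radially outwards/inwards by 1.5 times the line
#' width, and `random` ROIs at the on-pattern positions (to be evaluated in
#' the stationary-control image). The ROI side equals the pattern line
#' width.
#'
#' @param center pattern centre, um.
#' @param ringRadius detected ring radius, um.
#' @param lineWidth pattern line width (= ROI side), um.
#' @param angles ROI angles, degrees.
#' @return An [ROILayout].
#' @export
roiLayout <- function(center, ringRadius, lineWidth,
                      angles = c(0, 120, 240)) {
  th <- angles * pi / 180
  mk <- function(loc, rad)
    data.frame(location = loc, cx_um = center[1] + rad * cos(th),
               cy_um = center[2] + rad * sin(th))
  pos <- rbind(mk("on_pattern", ringRadius),
               mk("distal", ringRadius + 1.5 * lineWidth),
               mk("proximal", ringRadius - 1.5 * lineWidth),
               mk("random", ringRadius))
  new("ROILayout", positions = pos, side = lineWidth)
}

.roiFraction <- function(mask, cx, cy, side, pitch) {
  n <- nrow(mask)
  half <- side / 2
  i0 <- round(cx / pitch - half / pitch) + 1L
  i1 <- round(cx / pitch + half / pitch)
  j0 <- round(cy / pitch - half / pitch) + 1L
  j1 <- round(cy / pitch + half / pitch)
  if (i0 < 1 || j0 < 1 || i1 > n || j1 > ncol(mask))
    stop("ROI falls outside the image")
  mean(mask[i0:i1, j0:j1])
}

#' ROI-based cell density enhancement
#'
#' GFP+ area fraction of each ROI (GFP+ pixels / ROI pixels), the
#' per-location mean and SD, and the enhancement
#' `(mean_on_pattern / mean_random - 1) * 100` relative to the stationary
#' control. `on_pattern`, `distal` and `proximal` ROIs are evaluated in the
#' patterned mask; `random` ROIs in the control mask.
#'
#' @param mask binary mask of the patterned image.
#' @param layout an [ROILayout].
#' @param controlMask binary mask of the stationary-control image.
#' @param pitch um per pixel.
#' @return List with `roi` (per-ROI fractions), `byLocation`
#'   (mean/SD per location) and `enhancementPct` (`NA` with a warning when
#'   the control mean is zero).
#' @export
roiDensityEnhancement <- function(mask, layout, controlMask, pitch) {
  stopifnot(is(layout, "ROILayout"))
  pos <- layout@positions
  frac <- vapply(seq_len(nrow(pos)), function(k) {
    src <- if (pos$location[k] == "random") controlMask else mask
    .roiFraction(src, pos$cx_um[k], pos$cy_um[k], layout@side, pitch)
  }, numeric(1))
  roi <- cbind(pos, fraction = frac)
  agg <- aggregate(fraction ~ location, roi,
                   function(x) c(mean = mean(x), sd = sd(x)))
  byLoc <- data.frame(location = agg$location,
                      mean = agg$fraction[, "mean"], sd = agg$fraction[, "sd"])
  mOn <- byLoc$mean[byLoc$location == "on_pattern"]
  mRnd <- byLoc$mean[byLoc$location == "random"]
  enh <- if (mRnd == 0) {
    warning("undefined enhancement: control mean is zero")
    NA_real_
  } else (mOn / mRnd - 1) * 100
  list(roi = roi, byLocation = byLoc, enhancementPct = enh,
       provenance = list(side = layout@side, pitch = pitch))
}
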