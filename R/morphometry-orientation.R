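#' High-pass filter an image in the Fourier domain
#'
#' Zeroes every spectrum amplitude inside the centred low-frequency disc of
#' radius `cutoff` (cycles per image width) and returns the real part of the
#' inverse transform. The DC component is always removed, so a constant
#' image maps to zero.
#'
#' @param image a [SyntheticImage] or square numeric matrix.
#' @param cutoff disc radius in cycles/image; must be below Nyquist (n/2).
#' @return Filtered matrix.
#' @export
fftHighpass <- function(image, cutoff = 10) {
  m <- .asIntensity(image)
  if (nrow(m) != ncol(m)) stop("image must be square")
  n <- nrow(m)
  if (cutoff >= n / 2) stop("'cutoff' must be below the Nyquist frequency")
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))   # fft frequency order
  kr <- sqrt(outer(k^2, k^2, "+"))
  F <- stats::fft(m)
  F[kr < cutoff] <- 0
  F[1, 1] <- 0
  Re(stats::fft(F, inverse = TRUE)) / (n * n)
}

## derivative of the interpolating cubic spline at the nodes, along the
## first dimension, natural end conditions; tridiagonal (Thomas) solve
## vectorized over columns:  d[i-1] + 4 d[i] + d[i+1] = 3 (f[i+1] - f[i-1])
.splineDeriv <- function(f) {
  n <- nrow(f)
  rhs <- matrix(0, n, ncol(f))
  rhs[1, ] <- 3 * (f[2, ] - f[1, ])
  rhs[n, ] <- 3 * (f[n, ] - f[n - 1, ])
  rhs[2:(n - 1), ] <- 3 * (f[3:n, ] - f[1:(n - 2), ])
  ## diagonals: b = c(2, 4, 4, ..., 4, 2), off-diagonals 1
  cp <- numeric(n); b <- c(2, rep(4, n - 2), 2)
  cp[1] <- 1 / b[1]
  rhs[1, ] <- rhs[1, ] / b[1]
  for (i in 2:n) {
    mlt <- 1 / (b[i] - cp[i - 1])
    cp[i] <- mlt
    rhs[i, ] <- (rhs[i, ] - rhs[i - 1, ]) * mlt
  }
  for (i in (n - 1):1) rhs[i, ] <- rhs[i, ] - cp[i] * rhs[i + 1, ]
  rhs
}

#' Structure-tensor orientation distribution
#'
#' Orientation analysis of elongated structures: image gradients are taken
#' as cubic-spline derivatives, the structure tensor components (fx^2, fy^2,
#' fx fy) are averaged under a Gaussian window of width `sigmaPx`, and the
#' per-pixel orientation is `0.5 * atan2(2 <fx fy>, <fy^2> - <fx^2>)`
#' (image-row convention, reported with y pointing up so that a structure
#' along +45 degrees reads +45). Pixels whose tensor energy (trace) falls
#' below `energyThreshold` times the maximum energy are excluded. The
#' histogram over `[-90, 90)` degrees is smoothed with a periodic moving
#' average (window `smoothWindow` bins) and normalized to sum 1.
#'
#' If no pixel passes the energy threshold (e.g. a constant image) the
#' histogram is empty: all weights 0, with a warning.
#'
#' @param image a [SyntheticImage] or numeric matrix.
#' @param sigmaPx Gaussian window SD, pixels.
#' @param energyThreshold minimum energy as a fraction of the maximum.
#' @param nBins histogram bins over `[-90, 90)`.
#' @param smoothWindow moving-average window, bins.
#' @return An [OrientationHist].
#' @export
orientationDistribution <- function(image, sigmaPx = 4,
                                    energyThreshold = 0.30, nBins = 180L,
                                    smoothWindow = 5L) {
  m <- .asIntensity(image)
  fx <- .splineDeriv(m)
  fy <- t(.splineDeriv(t(m)))
  Jxx <- .gaussSmooth(fx * fx, sigmaPx)
  Jyy <- .gaussSmooth(fy * fy, sigmaPx)
  Jxy <- .gaussSmooth(fx * fy, sigmaPx)
  energy <- Jxx + Jyy
  emax <- max(energy)
  keep <- energy >= energyThreshold * emax & energy > 0
  if (emax <= 0 || !any(keep)) {
    warning("empty histogram: no pixel above the energy threshold")
    return(new("OrientationHist",
               angles = -90 + (seq_len(nBins) - 0.5) * 180 / nBins,
               weights = rep(0, nBins),
               params = list(sigmaPx = sigmaPx,
                             energyThreshold = energyThreshold,
                             smoothWindow = smoothWindow, nBins = nBins)))
  }
  ## 0.5 atan2(2<fx fy>, <fy^2>-<fx^2>) with fy in image-row (y-down)
  ## convention; our fy is y-up, so the cross term changes sign
  theta <- 0.5 * atan2(-2 * Jxy[keep], Jyy[keep] - Jxx[keep]) * 180 / pi
  theta[theta >= 90] <- theta[theta >= 90] - 180
  theta[theta < -90] <- theta[theta < -90] + 180
  bw <- 180 / nBins
  bin <- pmin(floor((theta + 90) / bw) + 1L, nBins)
  counts <- tabulate(bin, nBins)
  sm <- .periodicMA(counts, smoothWindow)
  new("OrientationHist",
      angles = -90 + (seq_len(nBins) - 0.5) * bw,
      weights = sm / sum(sm),
      params = list(sigmaPx = sigmaPx, energyThreshold = energyThreshold,
                    smoothWindow = smoothWindow, nBins = nBins))
}

#' Dominant angle of an orientation histogram
#'
#' Weight-averaged circular mean on the doubled-angle circle (orientations
#' are pi-periodic), robust to the flat plateau that bin smoothing puts
#' around a sharp mode. Meaningful for unimodal distributions; returns `NA`
#' for an empty histogram.
#'
#' @param hist an [OrientationHist].
#' @return Angle in degrees in `[-90, 90)`.
#' @export
dominantAngle <- function(hist) {
  stopifnot(is(hist, "OrientationHist"))
  w <- hist@weights
  if (sum(w) == 0) return(NA_real_)
  a2 <- 2 * hist@angles * pi / 180
  ang <- atan2(sum(w * sin(a2)), sum(w * cos(a2))) / 2 * 180 / pi
  if (ang >= 90) ang <- ang - 180
  if (ang < -90) ang <- ang + 180
  ang
}

.periodicMA <- function(x, w) {
  if (w <= 1) return(x)
  h <- w %/% 2
  xx <- c(tail(x, h), x, head(x, h))
  as.numeric(stats::filter(xx, rep(1 / w, w), sides = 2))[(h + 1):(h + length(x))]
}

.gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}
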