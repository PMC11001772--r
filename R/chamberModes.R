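#' Positive zeros of Bessel functions of the first kind
#'
#' Returns the k-th positive zero \eqn{\alpha_{m,k}} of \eqn{J_m}, found by
#' sign-change bracketing of `besselJ` followed by `uniroot` refinement.
#' These zeros set the nodal-circle radii of round-chamber modes:
#' ring k of an (m = 0, n) mode sits at \eqn{R\,\alpha_{0,k}/\alpha_{0,n}}.
#'
#' @param m Bessel order (integer `>= 0`).
#' @param k zero index (integer `>= 1`); may be a vector.
#' @return The zero(s), accurate to about 1e-12 (`|Jm(alpha)| < 1e-10`).
#' @examples
#' besselZero(0, 1)           # 2.404826
#' besselZero(0, 4)           # 11.791534
#' @export
besselZero <- function(m, k) {
  if (length(m) != 1L || m < 0 || m != floor(m))
    stop("'m' must be a single non-negative integer")
  if (any(k < 1) || any(k != floor(k)))
    stop("'k' must be positive integer(s)")
  kmax <- max(k)
  zeros <- numeric(0)
  ## scan for sign changes; J_m zeros are separated by more than pi/2
  x <- max(m / 2, 0.5)
  fx <- besselJ(x, m)
  step <- 0.5
  while (length(zeros) < kmax) {
    x2 <- x + step
    f2 <- besselJ(x2, m)
    if (fx == 0) zeros <- c(zeros, x)
    else if (fx * f2 < 0)
      zeros <- c(zeros,
                 uniroot(function(t) besselJ(t, m), c(x, x2),
                         tol = 1e-13)$root)
    x <- x2
    fx <- f2
  }
  zeros[k]
}

## evaluate a mode on arbitrary physical coordinates (round: centre origin,
## NA outside r > R; square: corner origin on [0, L]^2)
.evalMode <- function(spec, X, Y, mask = TRUE) {
  if (spec@shape == "round") {
    R <- spec@chamberDim
    r <- sqrt(X^2 + Y^2)
    alpha <- besselZero(spec@m, spec@n)
    z <- besselJ(alpha * r / R, spec@m)
    if (spec@m > 0) z <- z * cos(spec@m * atan2(Y, X))
    if (mask) z[r > R] <- NA_real_
    z
  } else {
    L <- spec@chamberDim
    m <- spec@m; n <- spec@n
    cos(n * pi * X / L) * cos(m * pi * Y / L) -
      cos(m * pi * X / L) * cos(n * pi * Y / L)
  }
}

.fieldCoords <- function(field) {
  nr <- nrow(field@zeta)
  if (field@frame == "center") {
    R <- field@spec@chamberDim
    seq(-R, R, length.out = nr)
  } else seq(0, field@spec@chamberDim, length.out = nr)
}

#' Round-chamber standing-wave field
#'
#' Evaluates \eqn{\zeta(r,\theta) = J_m(\alpha_{mn} r/R)\cos(m\theta)} on a
#' square grid spanning the chamber (centre origin), `NA` outside `r > R`.
#' For m = 0 the field is rotationally symmetric; its n nodal circles
#' (boundary included, since \eqn{J_0(\alpha_{0n}) = 0}) are the loci where
#' suspended cells condense.
#'
#' @param spec a [ModeSpec] with `shape = "round"`.
#' @return A [WaveField].
#' @examples
#' fld <- roundModeField(ModeSpec("round", 0, 4, 21, 256))
#' @export
roundModeField <- function(spec) {
  stopifnot(is(spec, "ModeSpec"))
  if (spec@shape != "round") stop("spec@shape must be 'round'")
  R <- spec@chamberDim
  co <- seq(-R, R, length.out = spec@gridResolution)
  z <- .evalMode(spec, matrix(co, spec@gridResolution, spec@gridResolution),
                 matrix(co, spec@gridResolution, spec@gridResolution,
                        byrow = TRUE))
  new("WaveField", zeta = z, pitch = co[2] - co[1], frame = "center",
      spec = spec)
}

#' Square-chamber standing-wave field
#'
#' Evaluates the antisymmetric two-mode superposition
#' \eqn{\zeta(x,y) = \cos(n\pi x/l)\cos(m\pi y/l) -
#' \cos(m\pi x/l)\cos(n\pi y/l)} on `[0, l]^2` (corner origin). The main
#' diagonal `x = y` is always nodal; for (m, n) = (5, 1) the nodal set is the
#' honeycomb-like pattern observed in square chambers.
#'
#' @param spec a [ModeSpec] with `shape = "square"`.
#' @return A [WaveField].
#' @examples
#' fld <- squareModeField(ModeSpec("square", 5, 1, 15, 256))
#' @export
squareModeField <- function(spec) {
  stopifnot(is(spec, "ModeSpec"))
  if (spec@shape != "square") stop("spec@shape must be 'square'")
  co <- seq(0, spec@chamberDim, length.out = spec@gridResolution)
  z <- .evalMode(spec, matrix(co, spec@gridResolution, spec@gridResolution),
                 matrix(co, spec@gridResolution, spec@gridResolution,
                        byrow = TRUE))
  new("WaveField", zeta = z, pitch = co[2] - co[1], frame = "corner",
      spec = spec)
}

#' Extract the nodal set of a wave field
#'
#' Builds the near-zero mask `|zeta| < tol * max|zeta|`, traces zero-level
#' contour polylines (marching squares via [grDevices::contourLines] with
#' sub-cell linear interpolation), and, for rotationally symmetric round
#' modes (m = 0), reduces closed circular contours to their radii. The
#' boundary circle `r = R` is counted as nodal whenever `zeta(R) = 0`, which
#' holds for every round mode because \eqn{\alpha_{mn}} is a zero of
#' \eqn{J_m}.
#'
#' @param field a [WaveField].
#' @param tol tolerance as a fraction of `max|zeta|`, in (0, 0.5).
#' @return A [NodalSet].
#' @examples
#' ns <- extractNodalSet(roundModeField(ModeSpec("round", 0, 4, 21, 256)))
#' nodalRadii(ns) / 21   # alpha_{0,k} / alpha_{0,4}
#' @export
extractNodalSet <- function(field, tol = 0.02) {
  stopifnot(is(field, "WaveField"))
  if (!(tol > 0 && tol < 0.5)) stop("'tol' must be in (0, 0.5)")
  z <- field@zeta
  zmax <- max(abs(z), na.rm = TRUE)
  if (!is.finite(zmax) || zmax == 0)
    stop("degenerate field: zeta is identically zero")
  mask <- abs(z) < tol * zmax
  mask[is.na(mask)] <- FALSE

  co <- .fieldCoords(field)
  ## a constant field legitimately has no zero contour; contourLines warns
  cl <- suppressWarnings(grDevices::contourLines(co, co, z, levels = 0))
  curves <- lapply(cl, function(cc) data.frame(x_mm = cc$x, y_mm = cc$y))

  radii <- numeric(0)
  spec <- field@spec
  if (spec@shape == "round" && spec@m == 0L) {
    R <- spec@chamberDim
    rad <- vapply(curves, function(cc) mean(sqrt(cc$x_mm^2 + cc$y_mm^2)),
                  numeric(1))
    ## keep only closed, genuinely circular contours
    circ <- vapply(curves, function(cc) {
      rr <- sqrt(cc$x_mm^2 + cc$y_mm^2)
      (max(rr) - min(rr)) < 2 * field@pitch
    }, logical(1))
    radii <- rad[circ]
    ## boundary circle r = R: not traced by contourLines (outside is NA);
    ## counted when the field itself vanishes along the boundary
    rg <- sqrt(outer(co^2, co^2, "+"))
    bsel <- !is.na(z) & rg >= R - field@pitch / 2 & rg <= R
    if (any(bsel) && max(abs(z[bsel])) < tol * zmax) {
      radii <- c(radii, R)
      th <- seq(0, 2 * pi, length.out = 361L)
      curves <- c(curves, list(data.frame(x_mm = R * cos(th),
                                          y_mm = R * sin(th))))
    }
    ## merge duplicates within one grid pitch
    radii <- sort(radii)
    if (length(radii) > 1)
      radii <- radii[c(TRUE, diff(radii) > field@pitch)]
  }
  new("NodalSet", mask = mask, curves = curves, radii = radii, tol = tol)
}

## bilinear interpolation of matrix z (grid coords xco/yco) at points (px,py)
.bilinear <- function(z, xco, yco, px, py) {
  dx <- xco[2] - xco[1]; dy <- yco[2] - yco[1]
  fi <- (px - xco[1]) / dx
  fj <- (py - yco[1]) / dy
  i0 <- pmin(pmax(floor(fi), 0), length(xco) - 2)
  j0 <- pmin(pmax(floor(fj), 0), length(yco) - 2)
  wx <- fi - i0; wy <- fj - j0
  n <- nrow(z)
  idx <- function(i, j) z[cbind(i + 1L, j + 1L)]
  (1 - wx) * (1 - wy) * idx(i0, j0) + wx * (1 - wy) * idx(i0 + 1L, j0) +
    (1 - wx) * wy * idx(i0, j0 + 1L) + wx * wy * idx(i0 + 1L, j0 + 1L)
}

.lineProfile <- function(z, xco, yco, from, to, samples) {
  rngx <- range(xco); rngy <- range(yco)
  pts <- rbind(from, to)
  if (any(pts[, 1] < rngx[1] | pts[, 1] > rngx[2] |
          pts[, 2] < rngy[1] | pts[, 2] > rngy[2]))
    stop("line endpoints fall outside the grid")
  tt <- seq(0, 1, length.out = samples)
  px <- from[1] + tt * (to[1] - from[1])
  py <- from[2] + tt * (to[2] - from[2])
  data.frame(s = tt * sqrt(sum((to - from)^2)),
             value = .bilinear(z, xco, yco, px, py))
}

#' @rdname symmetryLineProfile
#' @export
setMethod("symmetryLineProfile", "WaveField",
  function(x, from, to, samples = 512L, ...) {
    co <- .fieldCoords(x)
    .lineProfile(x@zeta, co, co, as.numeric(from), as.numeric(to),
                 as.integer(samples))
  })

#' @rdname symmetryLineProfile
#' @export
setMethod("symmetryLineProfile", "SyntheticImage",
  function(x, from, to, samples = 512L, ...) {
    co <- (seq_len(nrow(x@intensity)) - 1L) * x@pixelPitch
    .lineProfile(x@intensity, co, co, as.numeric(from), as.numeric(to),
                 as.integer(samples))
  })

#' Cell-accumulation density predicted from a wave field
#'
#' Converts a standing-wave field into a normalized accumulation density:
#' \eqn{\rho \propto \exp(-(d/s)^2)} where `d = |zeta| / |grad zeta|` is the
#' first-order distance to the nodal set and `s` is set so the density ridge
#' across a nodal line has full width at half maximum `width`. The density is
#' maximal exactly on the nodal set and integrates to 1 over the chamber.
#'
#' @param field a [WaveField].
#' @param width ridge FWHM, mm; must be smaller than the chamber.
#' @return A matrix of densities (per mm^2) on the field grid, with
#'   attributes `pitch` (mm) and `frame`; `NA` cells outside a round chamber
#'   carry density 0.
#' @export
accumulationMap <- function(field, width) {
  stopifnot(is(field, "WaveField"))
  if (!(width > 0)) stop("'width' must be > 0")
  if (width > field@spec@chamberDim)
    stop("'width' exceeds the chamber dimension")
  z <- field@zeta
  d <- .nodalDistance(z, field@pitch)
  s <- (width / 2) / sqrt(log(2))
  dens <- exp(-(d / s)^2)
  dens[is.na(dens)] <- 0
  dens / (sum(dens) * field@pitch^2)
}

## first-order distance |zeta|/|grad zeta| to the zero-level set
.nodalDistance <- function(z, pitch) {
  n <- nrow(z); m <- ncol(z)
  gx <- z; gy <- z
  gx[2:(n - 1), ] <- (z[3:n, ] - z[1:(n - 2), ]) / (2 * pitch)
  gx[1, ] <- (z[2, ] - z[1, ]) / pitch
  gx[n, ] <- (z[n, ] - z[n - 1, ]) / pitch
  gy[, 2:(m - 1)] <- (z[, 3:m] - z[, 1:(m - 2)]) / (2 * pitch)
  gy[, 1] <- (z[, 2] - z[, 1]) / pitch
  gy[, m] <- (z[, m] - z[, m - 1]) / pitch
  g <- sqrt(gx^2 + gy^2)
  zmax <- max(abs(z), na.rm = TRUE)
  g[!is.na(g) & g < 1e-9 * zmax] <- 1e-9 * zmax
  abs(z) / g
}
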