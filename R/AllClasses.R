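#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Matrix convention used throughout the package: for a field or image matrix
## `z`, `z[i, j]` is the value at x-index i and y-index j (the convention of
## graphics::image and grDevices::contourLines), with y increasing with j.
## Wave fields live on physical mm coordinates, images on micrometre (um)
## coordinates with the origin at the corner pixel centre.

#' Standing-wave mode specification
#'
#' Describes one stationary Faraday-wave surface mode of a patterning chamber:
#' the chamber geometry, the mode indices and the simulation grid.
#'
#' For a round chamber the mode is \eqn{\zeta(r,\theta) =
#' J_m(\alpha_{mn} r / R)\cos(m\theta)} where \eqn{\alpha_{mn}} is the n-th
#' positive zero of the Bessel function \eqn{J_m} and \eqn{R} is the domain
#' radius (`chamberDim`, mm). For a square chamber the surface displacement is
#' the antisymmetric superposition of two (m, n) cosine modes on an
#' \eqn{l \times l} domain (`chamberDim` = side length, mm).
#'
#' @slot shape `"round"` or `"square"`.
#' @slot m,n integer mode indices (`m >= 0`, `n >= 1`, both `<= 10`).
#' @slot chamberDim domain radius (round) or side length (square), mm.
#' @slot gridResolution grid points per axis (`>= 64`).
#' @export
setClass("ModeSpec",
  representation(shape = "character", m = "integer", n = "integer",
                 chamberDim = "numeric", gridResolution = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!(length(object@shape) == 1L && object@shape %in% c("round", "square")))
      msg <- c(msg, "shape must be 'round' or 'square'")
    if (object@m < 0L || object@m > 10L) msg <- c(msg, "m must be in 0..10")
    if (object@n < 1L || object@n > 10L) msg <- c(msg, "n must be in 1..10")
    if (!(object@chamberDim > 0)) msg <- c(msg, "chamberDim must be > 0")
    if (object@gridResolution < 64L) msg <- c(msg, "gridResolution must be >= 64")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname ModeSpec-class
#' @param shape,m,n,chamberDim,gridResolution see slots.
#' @return A `ModeSpec` object.
#' @examples
#' ModeSpec("round", m = 0, n = 4, chamberDim = 21)
#' @export
ModeSpec <- function(shape = c("round", "square"), m, n, chamberDim,
                     gridResolution = 512L) {
  shape <- match.arg(shape)
  new("ModeSpec", shape = shape, m = as.integer(m), n = as.integer(n),
      chamberDim = as.numeric(chamberDim),
      gridResolution = as.integer(gridResolution))
}

#' Standing-wave surface displacement field
#'
#' A dimensionless surface displacement \eqn{\zeta} sampled on a square grid
#' with physical pitch in mm. Round-chamber fields are centred on the chamber
#' axis (origin at the centre, `frame = "center"`) and are `NA` outside the
#' chamber; square-chamber fields use a corner origin (`frame = "corner"`).
#'
#' @slot zeta numeric matrix, `zeta[i, j]` at x-index i / y-index j.
#' @slot pitch mm per grid cell.
#' @slot frame `"center"` or `"corner"`.
#' @slot spec the [ModeSpec] that produced the field.
#' @export
setClass("WaveField",
  representation(zeta = "matrix", pitch = "numeric", frame = "character",
                 spec = "ModeSpec"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@zeta) != ncol(object@zeta)) msg <- c(msg, "grid must be square")
    if (!(object@pitch > 0)) msg <- c(msg, "pitch must be > 0")
    if (!object@frame %in% c("center", "corner"))
      msg <- c(msg, "frame must be 'center' or 'corner'")
    if (is.null(msg)) TRUE else msg
  })

#' Nodal set of a wave field
#'
#' Zero-displacement loci of a standing-wave field: a near-zero binary mask,
#' traced zero-level contour polylines (physical mm coordinates), and — for
#' rotationally symmetric round modes (m = 0) — the radii of the concentric
#' nodal circles. Suspended cells condense onto these loci during sound
#' patterning.
#'
#' @slot mask logical matrix, `TRUE` where `|zeta| < tol * max|zeta|`.
#' @slot curves list of data.frames with columns `x_mm`, `y_mm`.
#' @slot radii nodal circle radii (mm, ascending), round m = 0 fields only.
#' @slot tol the tolerance fraction used.
#' @export
setClass("NodalSet",
  representation(mask = "matrix", curves = "list", radii = "numeric",
                 tol = "numeric"),
  validity = function(object) {
    if (is.unsorted(object@radii)) "radii must be sorted ascending" else TRUE
  })

#' Synthetic cell-pattern image specification
#'
#' Parameters of the synthetic fluorescence image generators. The programmed
#' ground truth is the off-pattern GFP+ area fraction (`backgroundFraction`)
#' and the relative on-pattern enhancement (`enhancementPct`): the programmed
#' on-pattern fraction is `backgroundFraction * (1 + enhancementPct/100)`.
#'
#' @slot geometry `"rings"`, `"honeycomb"` or `"random"`.
#' @slot imageSize pixels per axis.
#' @slot pixelPitch um per pixel.
#' @slot cellRadius cell disc radius, um.
#' @slot lineWidth pattern line width, um.
#' @slot backgroundFraction off-pattern GFP+ area fraction in [0, 1).
#' @slot enhancementPct programmed percent increase of the on-pattern fraction.
#' @slot seed RNG seed.
#' @export
setClass("ImageSpec",
  representation(geometry = "character", imageSize = "integer",
                 pixelPitch = "numeric", cellRadius = "numeric",
                 lineWidth = "numeric", backgroundFraction = "numeric",
                 enhancementPct = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@geometry %in% c("rings", "honeycomb", "random"))
      msg <- c(msg, "geometry must be rings, honeycomb or random")
    if (!(object@pixelPitch > 0)) msg <- c(msg, "pixelPitch must be > 0")
    if (object@cellRadius < object@pixelPitch)
      msg <- c(msg, "cellRadius must be at least one pixel")
    f <- object@backgroundFraction
    if (!(f >= 0 && f < 1)) msg <- c(msg, "backgroundFraction must be in [0,1)")
    if (f * (1 + object@enhancementPct / 100) >= 0.9)
      msg <- c(msg, "programmed on-pattern fraction must stay below 0.9 (saturation)")
    if (object@imageSize < 64L) msg <- c(msg, "imageSize must be >= 64")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname ImageSpec-class
#' @param geometry,imageSize,pixelPitch,cellRadius,lineWidth see slots.
#' @param backgroundFraction,enhancementPct,seed see slots.
#' @return An `ImageSpec`.
#' @examples
#' ImageSpec("rings", imageSize = 512, enhancementPct = 438, seed = 1)
#' @export
ImageSpec <- function(geometry = c("rings", "honeycomb", "random"),
                      imageSize = 2048L, pixelPitch = 2.5, cellRadius = 7.5,
                      lineWidth = 100, backgroundFraction = 0.05,
                      enhancementPct = 0, seed = 1L) {
  geometry <- match.arg(geometry)
  new("ImageSpec", geometry = geometry, imageSize = as.integer(imageSize),
      pixelPitch = pixelPitch, cellRadius = cellRadius, lineWidth = lineWidth,
      backgroundFraction = backgroundFraction, enhancementPct = enhancementPct,
      seed = as.integer(seed))
}

#' Synthetic capillary ribbon-network specification
#'
#' Geometric stand-in for a maturing capillary-like network: smoothed ribbon
#' centerlines with per-ribbon widths drawn from a normal distribution
#' truncated at one pixel. Day presets (see [networkSpecForDay]) carry the
#' width statistics of patterned/random networks at culture days 1, 3 and 5.
#'
#' @slot day culture day, one of 1, 3, 5.
#' @slot ribbonWidthMean,ribbonWidthSd width distribution parameters, um.
#' @slot ribbonCount number of ribbons.
#' @slot alongPattern if `TRUE`, centerlines follow supplied nodal curves.
#' @slot imageSize pixels per axis.
#' @slot pixelPitch um per pixel.
#' @slot seed RNG seed.
#' @export
setClass("NetworkSpec",
  representation(day = "integer", ribbonWidthMean = "numeric",
                 ribbonWidthSd = "numeric", ribbonCount = "integer",
                 alongPattern = "logical", imageSize = "integer",
                 pixelPitch = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@day %in% c(1L, 3L, 5L)) msg <- c(msg, "day must be 1, 3 or 5")
    if (!(object@ribbonWidthMean > 0)) msg <- c(msg, "ribbonWidthMean must be > 0")
    if (!(object@ribbonWidthSd >= 0)) msg <- c(msg, "ribbonWidthSd must be >= 0")
    if (object@ribbonCount < 0L) msg <- c(msg, "ribbonCount must be >= 0")
    if (!(object@pixelPitch > 0)) msg <- c(msg, "pixelPitch must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname NetworkSpec-class
#' @param day,ribbonWidthMean,ribbonWidthSd,ribbonCount,alongPattern see slots.
#' @param imageSize,pixelPitch,seed see slots.
#' @return A `NetworkSpec`.
#' @export
NetworkSpec <- function(day = 1L, ribbonWidthMean = 13.1, ribbonWidthSd = 24.7,
                        ribbonCount = 30L, alongPattern = FALSE,
                        imageSize = 1024L, pixelPitch = 1.25, seed = 1L) {
  new("NetworkSpec", day = as.integer(day), ribbonWidthMean = ribbonWidthMean,
      ribbonWidthSd = ribbonWidthSd, ribbonCount = as.integer(ribbonCount),
      alongPattern = alongPattern, imageSize = as.integer(imageSize),
      pixelPitch = pixelPitch, seed = as.integer(seed))
}

#' Synthetic two-group proteome specification
#'
#' Log-normal abundance model for a patterned-vs-random label-free proteomics
#' comparison: per-protein log2 baselines, a programmed log2 shift for the
#' regulated subsets in the patterned group, and i.i.d. per-sample residual
#' noise on the log2 scale.
#'
#' @slot nProteins total number of proteins.
#' @slot nPerGroup samples per group (default 3).
#' @slot nUp,nDown sizes of the up-/down-regulated subsets.
#' @slot effectMean,effectSd absolute log2 effect distribution for regulated
#'   proteins (up positive, down negative).
#' @slot residualSd per-sample residual SD, log2 units.
#' @slot baselineMean,baselineSd per-protein baseline distribution, log2 units.
#' @slot seed RNG seed.
#' @export
setClass("ProteomeSpec",
  representation(nProteins = "integer", nPerGroup = "integer", nUp = "integer",
                 nDown = "integer", effectMean = "numeric", effectSd = "numeric",
                 residualSd = "numeric", baselineMean = "numeric",
                 baselineSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nUp + object@nDown > object@nProteins)
      msg <- c(msg, "nUp + nDown must not exceed nProteins")
    if (!(object@residualSd > 0)) msg <- c(msg, "residualSd must be > 0")
    if (!(object@effectMean >= 0)) msg <- c(msg, "effectMean is an absolute effect")
    if (object@nPerGroup < 2L) msg <- c(msg, "need >= 2 samples per group")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname ProteomeSpec-class
#' @param nProteins,nPerGroup,nUp,nDown,effectMean,effectSd see slots.
#' @param residualSd,baselineMean,baselineSd,seed see slots.
#' @return A `ProteomeSpec`.
#' @examples
#' ProteomeSpec(nUp = 643, nDown = 261, seed = 1)
#' @export
ProteomeSpec <- function(nProteins = 4000L, nPerGroup = 3L, nUp = 0L,
                         nDown = 0L, effectMean = 2, effectSd = 0.3,
                         residualSd = 0.25, baselineMean = 20, baselineSd = 2,
                         seed = 1L) {
  new("ProteomeSpec", nProteins = as.integer(nProteins),
      nPerGroup = as.integer(nPerGroup), nUp = as.integer(nUp),
      nDown = as.integer(nDown), effectMean = effectMean, effectSd = effectSd,
      residualSd = residualSd, baselineMean = baselineMean,
      baselineSd = baselineSd, seed = as.integer(seed))
}

#' Synthetic fluorescence image with ground truth
#'
#' An intensity image in `[0, 1]` together with the generator's ground-truth
#' annotations (`truth`): the pattern-line mask, programmed and realized GFP+
#' area fractions, ribbon centerlines/widths for network images, the seed and
#' an echo of the generating spec.
#'
#' @slot intensity numeric matrix in `[0, 1]`, `[i, j]` = (x, y).
#' @slot pixelPitch um per pixel.
#' @slot truth named list of ground-truth annotations.
#' @export
setClass("SyntheticImage",
  representation(intensity = "matrix", pixelPitch = "numeric", truth = "list"),
  validity = function(object) {
    rng <- range(object@intensity, finite = TRUE)
    msg <- NULL
    if (length(object@intensity) && (rng[1] < 0 || rng[2] > 1))
      msg <- c(msg, "intensity must lie in [0, 1]")
    if (!(object@pixelPitch > 0)) msg <- c(msg, "pixelPitch must be > 0")
    if (!is.null(object@truth$mask) &&
        !identical(dim(object@truth$mask), dim(object@intensity)))
      msg <- c(msg, "truth mask must match the intensity grid")
    if (is.null(msg)) TRUE else msg
  })

#' Radial intensity profile
#'
#' Mean image intensity per annulus around a centre, on half-open annuli
#' `[r, r + dr)`. Empty annuli carry `NA`, never zero.
#'
#' @slot radii annulus left edges, um (uniform step `dr`).
#' @slot values mean intensity per annulus (`NA` when empty).
#' @slot npix pixel count per annulus.
#' @slot center centre used, um (x, y).
#' @slot dr annulus width, um.
#' @export
setClass("RadialProfile",
  representation(radii = "numeric", values = "numeric", npix = "integer",
                 center = "numeric", dr = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@radii) != length(object@values))
      msg <- c(msg, "radii/values length mismatch")
    if (length(object@radii) > 1 && any(diff(object@radii) <= 0))
      msg <- c(msg, "radii must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' Detected peaks and valleys of a radial profile
#'
#' Local maxima with a minimum relative prominence, and the minima (valleys)
#' between consecutive peaks; valley k lies between peaks k and k+1.
#'
#' @slot peaks data.frame with `position` (um), `height`, `index`.
#' @slot valleys data.frame with `position` (um), `depth`, `index`.
#' @slot prominence prominence fraction used.
#' @export
setClass("PeakSet",
  representation(peaks = "data.frame", valleys = "data.frame",
                 prominence = "numeric"),
  validity = function(object) {
    if (nrow(object@valleys) &&
        nrow(object@valleys) != nrow(object@peaks) - 1L)
      "valleys must interleave peaks (one fewer than peaks)" else TRUE
  })

#' Square-ROI layout for density quantification
#'
#' Square regions of interest with side length equal to the pattern line
#' width, three per location: on the patterned line (`on_pattern`), adjacent
#' towards the periphery (`distal`), adjacent towards the centre
#' (`proximal`), and matched positions for the stationary control
#' (`random`).
#'
#' @slot positions data.frame with `location`, `cx_um`, `cy_um`.
#' @slot side ROI side length, um.
#' @export
setClass("ROILayout",
  representation(positions = "data.frame", side = "numeric"),
  validity = function(object) {
    locs <- table(object@positions$location)
    if (length(locs) && any(locs != 3L)) "exactly 3 ROIs per location" else TRUE
  })

#' Local thickness map
#'
#' Per-pixel diameter (um) of the largest disc fully inscribed in the
#' foreground that contains the pixel; 0 on background.
#'
#' @slot values numeric matrix of diameters, um.
#' @slot pixelPitch um per pixel.
#' @slot provenance list of parameters used.
#' @export
setClass("ThicknessMap",
  representation(values = "matrix", pixelPitch = "numeric",
                 provenance = "list"))

#' Orientation distribution histogram
#'
#' Structure-tensor orientation histogram over `[-90, 90)` degrees,
#' periodically smoothed and normalized to sum 1.
#'
#' @slot angles bin centres, degrees.
#' @slot weights normalized bin weights (sum 1, or all 0 when no pixel
#'   passes the energy threshold).
#' @slot params list: `sigmaPx`, `energyThreshold`, `smoothWindow`, `nBins`.
#' @export
setClass("OrientationHist",
  representation(angles = "numeric", weights = "numeric", params = "list"),
  validity = function(object) {
    s <- sum(object@weights)
    if (length(object@weights) && !(abs(s - 1) < 1e-8 || s == 0))
      "weights must sum to 1 (or all be 0 for an empty histogram)" else TRUE
  })

#' Two-group protein abundance experiment
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding a strictly positive `abundance` assay (proteins x samples) with a
#' two-level `group` factor (`patterned`, `random`) in `colData` and, for
#' synthetic tables, a `truth` label (`up`/`down`/`null`) in `rowData`.
#'
#' @export
setClass("AbundanceExperiment", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "an 'abundance' assay is required")
    else if (any(SummarizedExperiment::assay(object, "abundance") <= 0))
      msg <- c(msg, "abundances must be strictly positive")
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicate protein identifiers")
    g <- SummarizedExperiment::colData(object)$group
    if (is.null(g) || nlevels(factor(g)) != 2L || any(table(g) < 2L))
      msg <- c(msg, "colData$group must have two levels with >= 2 samples each")
    if (is.null(msg)) TRUE else msg
  })

#' Differential-expression result table
#'
#' A [S4Vectors::DataFrame] subclass with one row per protein and columns
#' `log2FC` (patterned minus random, log2), `t`, `p`, `q` (BH-adjusted) and
#' `direction` (`up`/`down`/`ns`). The testing parameters are stored in
#' `metadata()`.
#'
#' @export
setClass("DEResult", contains = "DFrame")

#' PCA sample scores
#'
#' Scores of the samples on the leading principal components, with the
#' explained-variance fractions. The sign convention fixes the
#' largest-magnitude loading of each component to be positive.
#'
#' @slot scores samples x components matrix.
#' @slot explained explained-variance fractions (non-increasing).
#' @export
setClass("PCAScores",
  representation(scores = "matrix", explained = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@explained) > 1 && any(diff(object@explained) > 1e-12))
      msg <- c(msg, "explained variance must be non-increasing")
    if (max(abs(colMeans(object@scores))) > 1e-6)
      msg <- c(msg, "scores must be column-centred")
    if (is.null(msg)) TRUE else msg
  })
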