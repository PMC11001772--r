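#' Write / read a synthetic image as 16-bit TIFF
#'
#' The intensity grid is written as a 16-bit grayscale TIFF (row-major, top
#' row = maximal y, matching standard viewers) together with a JSON sidecar
#' `<path>.json` carrying the pixel pitch, seed and programmed/realized
#' fractions (the pixel-level truth masks are not serialized).
#'
#' @param img a [SyntheticImage].
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
writeImageTiff <- function(img, path) {
  stopifnot(is(img, "SyntheticImage"))
  ## matrix is [x, y] with y up; TIFF rows run top-down
  m <- t(img@intensity)[rev(seq_len(ncol(img@intensity))), , drop = FALSE]
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  tr <- img@truth
  side <- list(pixelPitchUm = img@pixelPitch, seed = tr$seed,
               programmedOnFraction = tr$programmedOnFraction,
               programmedOffFraction = tr$programmedOffFraction,
               programmedFraction = tr$programmedFraction,
               realizedOnFraction = tr$realizedOnFraction,
               realizedOffFraction = tr$realizedOffFraction,
               realizedFraction = tr$realizedFraction,
               nodalRadiiUm = tr$nodalRadiiUm,
               widthsUm = tr$widthsUm, day = tr$day)
  side <- side[!vapply(side, is.null, logical(1))]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeImageTiff
#' @param path TIFF path; the JSON sidecar is read when present.
#' @export
readImageTiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  side <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list(pixelPitchUm = 1)
  new("SyntheticImage", intensity = m,
      pixelPitch = as.numeric(side$pixelPitchUm),
      truth = side[setdiff(names(side), "pixelPitchUm")])
}

#' Export nodal curves as CSV polylines
#'
#' One row per vertex: `curve_id`, `x_mm`, `y_mm`.
#'
#' @param nodal a [NodalSet].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeNodalCurves <- function(nodal, path) {
  stopifnot(is(nodal, "NodalSet"))
  curves <- nodalCurves(nodal)
  df <- do.call(rbind, lapply(seq_along(curves), function(k)
    cbind(curve_id = k, curves[[k]])))
  if (is.null(df)) df <- data.frame(curve_id = integer(0), x_mm = numeric(0),
                                    y_mm = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
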