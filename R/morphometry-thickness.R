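#' Local thickness transform
#'
#' Assigns to every foreground pixel the diameter (um) of the largest disc
#' fully contained in the foreground that covers the pixel — the standard
#' local-thickness definition (distance transform, then inscription of the
#' maximal discs). The image boundary is treated as background. Concretely:
#' each foreground pixel q carries the exact Euclidean distance r(q) to its
#' nearest background pixel; every pixel p with |p - q| < r(q) lies inside
#' q's inscribed disc and receives at least 2 r(q) * pitch; the map is the
#' pixelwise maximum over all q. The disc-inscription step is computed here
#' directly; only the Euclidean distance transform is delegated to
#' [EBImage::distmap].
#'
#' @param mask logical/binary matrix (foreground `TRUE`/`1`).
#' @param pixelPitch um per pixel.
#' @return A [ThicknessMap] (0 on background). An empty mask yields an empty
#'   map with a warning.
#' @examples
#' m <- matrix(FALSE, 32, 32); m[8:24, 14:18] <- TRUE   # 5 px wide ribbon
#' tm <- localThickness(m, 2)
#' @export
localThickness <- function(mask, pixelPitch = 1) {
  mask <- mask > 0
  if (!any(mask)) {
    warning("empty mask: thickness map is empty")
    return(new("ThicknessMap", values = matrix(0, nrow(mask), ncol(mask)),
               pixelPitch = pixelPitch,
               provenance = list(empty = TRUE)))
  }
  ## pad with one background ring so the border counts as background
  n1 <- nrow(mask) + 2L; n2 <- ncol(mask) + 2L
  pm <- matrix(FALSE, n1, n2)
  pm[2:(n1 - 1L), 2:(n2 - 1L)] <- mask
  ## exact squared Euclidean distance to background
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(pm * 1)))
  r2 <- round(d^2)   # squared distances are integers for exact EDT
  out <- matrix(0, n1, n2)
  fg <- which(pm)
  ## paint each pixel's inscribed disc, largest radii first
  byr2 <- split(fg, r2[fg])
  for (key in as.character(sort(as.numeric(names(byr2)), decreasing = TRUE))) {
    rr2 <- as.numeric(key)
    centers <- byr2[[key]]
    q <- ceiling(sqrt(rr2))
    g <- expand.grid(dx = -q:q, dy = -q:q)
    g <- g[g$dx^2 + g$dy^2 < rr2, , drop = FALSE]   # strict: |p-q| < r
    ci <- (centers - 1L) %% n1 + 1L
    cj <- (centers - 1L) %/% n1 + 1L
    i <- rep(ci, each = nrow(g)) + g$dx
    j <- rep(cj, each = nrow(g)) + g$dy
    idx <- cbind(i, j)
    val <- 2 * sqrt(rr2)
    upd <- out[idx] < val
    out[idx[upd, , drop = FALSE]] <- val
    ## the centre pixel itself (g excludes nothing at rr2 > 0; for rr2 = 1
    ## only the centre is strictly inside)
  }
  out <- out[2:(n1 - 1L), 2:(n2 - 1L)] * pixelPitch
  out[!mask] <- 0
  new("ThicknessMap", values = out, pixelPitch = pixelPitch,
      provenance = list(boundary = "background", strict = TRUE))
}

#' Summary statistics of a thickness map
#'
#' Mean, SD and a 1-um-bin histogram of the local thickness values, over the
#' foreground pixels only (default) or over all pixels including the zero
#' background (`includeZero = TRUE`; the convention is recorded in the
#' provenance). An empty foreground yields `NA` statistics with a warning.
#'
#' @param tmap a [ThicknessMap].
#' @param includeZero include background zeros in the statistics.
#' @return List with `mean`, `sd`, `histogram` (data.frame `mid`, `count`)
#'   and `provenance`.
#' @export
thicknessStats <- function(tmap, includeZero = FALSE) {
  stopifnot(is(tmap, "ThicknessMap"))
  v <- as.vector(tmap@values)
  fg <- v[v > 0]
  if (!length(fg)) {
    warning("undefined statistics: empty foreground")
    return(list(mean = NA_real_, sd = NA_real_, histogram = NULL,
                provenance = list(includeZero = includeZero)))
  }
  use <- if (includeZero) v else fg
  breaks <- seq(0, ceiling(max(fg)) + 1, by = 1)
  h <- hist(fg, breaks = breaks, plot = FALSE)
  list(mean = mean(use), sd = sd(use),
       histogram = data.frame(mid = h$mids, count = h$counts),
       provenance = list(includeZero = includeZero, binWidthUm = 1))
}
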