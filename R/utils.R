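## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

## evaluate expr with a local RNG state; the caller's stream is untouched
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## integer offsets of a filled disc of radius r (px), dx^2 + dy^2 <= r^2
.discOffsets <- function(r) {
  r <- max(r, 0)
  q <- floor(r)
  g <- expand.grid(dx = -q:q, dy = -q:q)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

## stamp filled discs of radius rpx at linear indices `centers` of an
## n x n logical matrix
.stampDiscs <- function(M, centers, rpx) {
  if (!length(centers)) return(M)
  n <- nrow(M)
  off <- .discOffsets(rpx)
  ci <- (centers - 1L) %% n + 1L
  cj <- (centers - 1L) %/% n + 1L
  i <- rep(ci, each = nrow(off)) + off$dx
  j <- rep(cj, each = nrow(off)) + off$dy
  ok <- i >= 1L & i <= n & j >= 1L & j <= n
  M[cbind(i[ok], j[ok])] <- TRUE
  M
}

## Gaussian blur on a plain matrix (EBImage backend)
.gblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  out <- EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
  pmin(pmax(out, 0), 1)
}
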