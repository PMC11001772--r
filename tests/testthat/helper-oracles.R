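## Independent oracles, deliberately implemented without the package's own
## code paths (and without besselJ): power-series Bessel evaluation with
## bisection root finding, and a brute-force inscribed-disc local-thickness
## reference.

## J_m(x): power series for small x (ratio-recursed terms); Hankel
## asymptotic expansion beyond x = 12, where series cancellation erodes
## double precision
jmSeries <- function(x, m, tol = 1e-16) {
  if (x > 12) return(jmAsymptotic(x, m))
  term <- (x / 2)^m / factorial(m)
  total <- term
  k <- 0
  repeat {
    k <- k + 1
    term <- -term * (x / 2)^2 / (k * (k + m))
    total <- total + term
    if (abs(term) < tol * max(abs(total), 1) || k > 200) break
  }
  total
}

jmAsymptotic <- function(x, m, nTerms = 10) {
  mu <- 4 * m^2
  a <- 1
  P <- 1; Q <- 0
  best <- Inf
  for (k in seq_len(nTerms)) {
    a <- a * (mu - (2 * k - 1)^2) / (k * 8 * x)
    term <- a
    if (abs(term) > best) break        # truncate at the smallest term
    best <- abs(term)
    if (k %% 2L == 1L) Q <- Q + term * (-1)^((k - 1) / 2)
    else P <- P + term * (-1)^(k / 2)
  }
  om <- x - (m / 2 + 0.25) * pi
  sqrt(2 / (pi * x)) * (P * cos(om) - Q * sin(om))
}

## k-th positive zero of J_m by scanning + bisection on the series
besselZeroOracle <- function(m, k, step = 0.2, tol = 1e-10) {
  x <- max(m / 2, step)
  f <- jmSeries(x, m)
  found <- 0
  repeat {
    x2 <- x + step
    f2 <- jmSeries(x2, m)
    if (f * f2 < 0) {
      found <- found + 1
      if (found == k) {
        lo <- x; hi <- x2
        while (hi - lo > tol) {
          mid <- (lo + hi) / 2
          if (jmSeries(lo, m) * jmSeries(mid, m) <= 0) hi <- mid else lo <- mid
        }
        return((lo + hi) / 2)
      }
    }
    x <- x2; f <- f2
    if (x > 60) stop("oracle scan exhausted")
  }
}

## brute-force local thickness: enumerate every foreground pixel's maximal
## inscribed disc (radius = min distance to a background pixel, boundary
## counting as background) and take the pixelwise maximum of the diameters
bruteThickness <- function(mask, pitch = 1) {
  n1 <- nrow(mask) + 2L; n2 <- ncol(mask) + 2L
  pm <- matrix(FALSE, n1, n2)
  pm[2:(n1 - 1L), 2:(n2 - 1L)] <- mask
  fg <- which(pm); bg <- which(!pm)
  fi <- (fg - 1L) %% n1 + 1L; fj <- (fg - 1L) %/% n1 + 1L
  bi <- (bg - 1L) %% n1 + 1L; bj <- (bg - 1L) %/% n1 + 1L
  out <- matrix(0, n1, n2)
  for (k in seq_along(fg)) {
    d2 <- min((bi - fi[k])^2 + (bj - fj[k])^2)
    cover <- (fi - fi[k])^2 + (fj - fj[k])^2 < d2
    val <- 2 * sqrt(d2)
    sel <- fg[cover]
    out[sel] <- pmax(out[sel], val)
  }
  out[2:(n1 - 1L), 2:(n2 - 1L)] * pitch
}

## random blobby binary mask (union of discs) for thickness property tests
randomBlobMask <- function(n, seed, nBlobs = 6, rMax = n / 5) {
  set.seed(seed)
  co <- seq_len(n)
  m <- matrix(FALSE, n, n)
  for (b in seq_len(nBlobs)) {
    cx <- runif(1, 1, n); cy <- runif(1, 1, n); r <- runif(1, 1.5, rMax)
    m <- m | outer((co - cx)^2, (co - cy)^2, "+") <= r^2
  }
  m
}

## RadialProfile built directly from a value vector (dr = 1 um)
profileFromValues <- function(v, dr = 1) {
  new("RadialProfile", radii = (seq_along(v) - 1) * dr, values = v,
      npix = rep(1L, length(v)), center = c(0, 0), dr = dr)
}

ringField128 <- function() roundModeField(ModeSpec("round", 0, 4, 21, 128))

## FWHM of a single-peak curve by outward scanning with linear interpolation
fwhmOfCurve <- function(x, y, baseline = 0) {
  pk <- which.max(y)
  half <- baseline + (y[pk] - baseline) / 2
  lo <- NA_real_; hi <- NA_real_
  for (j in rev(seq_len(pk - 1))) if (y[j] <= half) {
    lo <- x[j] + (x[j + 1] - x[j]) * (half - y[j]) / (y[j + 1] - y[j]); break
  }
  for (j in (pk + 1):length(y)) if (y[j] <= half) {
    hi <- x[j] + (x[j - 1] - x[j]) * (half - y[j]) / (y[j - 1] - y[j]); break
  }
  hi - lo
}
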