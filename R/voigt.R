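# Voigt lineshape via the Faddeeva function w(z), evaluated with Weideman's
# rational approximation (N = 64 terms; relative error far below the fitting
# tolerances used anywhere in the package).  Valid on the closed upper half
# plane, which is all a lineshape needs (gamma >= 0).

.faddeevaCoef <- local({
  N <- 64L
  M <- 2L * N
  M2 <- 2L * M
  k <- seq(-M + 1, M - 1)
  L <- sqrt(N / sqrt(2))
  theta <- k * pi / M
  tk <- L * tan(theta / 2)
  f <- exp(-tk^2) * (L^2 + tk^2)
  f <- c(0, f)
  fs <- c(f[(M + 1):M2], f[1:M])
  a <- Re(stats::fft(fs)) / M2
  list(a = rev(a[2:(N + 1)]), L = L)
})

.faddeeva <- function(z) {
  a <- .faddeevaCoef$a
  L <- .faddeevaCoef$L
  iz <- 1i * z
  Z <- (L + iz) / (L - iz)
  p <- rep(0 + 0i, length(z))
  for (ck in a) p <- p * Z + ck
  2 * p / (L - iz)^2 + (1 / sqrt(pi)) / (L - iz)
}

#' Voigt peak parameter set
#'
#' A Voigt profile is the convolution of a Gaussian (standard deviation
#' \code{sigma}) and a Lorentzian (half-width at half-maximum \code{gamma});
#' either component may vanish but not both.  \code{area} is the integral of
#' the profile over the whole real line.
#'
#' @param center centre chemical shift (ppm).
#' @param sigma Gaussian standard deviation (ppm, >= 0).
#' @param gamma Lorentzian half-width (ppm, >= 0); \code{sigma + gamma} must
#'   be positive.
#' @param area integrated intensity (>= 0).
#' @return a list with class \code{"voigtPeak"}.
#' @examples
#' voigtPeak(5.24, sigma = 0.002, gamma = 0.001, area = 1)
#' @export
voigtPeak <- function(center, sigma, gamma, area = 1) {
  if (!is.finite(center) || !is.finite(sigma) || !is.finite(gamma) ||
      !is.finite(area))
    stop("invalid-input: voigtPeak parameters must be finite")
  if (sigma < 0 || gamma < 0)
    stop("invalid-input: sigma and gamma must be non-negative")
  if (sigma + gamma <= 0)
    stop("degenerate-lineshape: sigma and gamma cannot both be zero")
  if (area < 0) stop("invalid-input: area must be non-negative")
  structure(list(center = center, sigma = sigma, gamma = gamma, area = area),
            class = "voigtPeak")
}

#' Evaluate a Voigt profile on a ppm grid
#'
#' Reduces exactly to a Gaussian when \code{gamma = 0} and to a Lorentzian
#' when \code{sigma = 0}.  The returned trace is non-negative and integrates
#' (over infinite support) to \code{peak$area}.
#'
#' @param peak a \code{\link{voigtPeak}}.
#' @param grid strictly ascending numeric ppm axis.
#' @return numeric intensity trace, same length as \code{grid}.
#' @examples
#' g <- seq(5.0, 5.5, by = 1e-4)
#' v <- voigtProfile(voigtPeak(5.24, 0.002, 0.001), g)
#' @export
voigtProfile <- function(peak, grid) {
  if (!inherits(peak, "voigtPeak"))
    peak <- do.call(voigtPeak, as.list(peak))
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stop("invalid-input: grid must be strictly ascending")
  x <- grid - peak$center
  if (peak$sigma == 0) {
    v <- peak$area * peak$gamma / (pi * (x^2 + peak$gamma^2))
  } else if (peak$gamma == 0) {
    v <- peak$area * stats::dnorm(x, sd = peak$sigma)
  } else {
    s2 <- peak$sigma * sqrt(2)
    z <- complex(real = x / s2, imaginary = rep(peak$gamma / s2, length(x)))
    v <- peak$area * Re(.faddeeva(z)) / (peak$sigma * sqrt(2 * pi))
  }
  pmax(v, 0)
}

#' Render a multiplet as a sum of Voigt components
#'
#' Components are spaced by \code{J / spectrometerFrequency} ppm around the
#' multiplet centre with binomial relative amplitudes (1:1 doublet, 1:2:1
#' triplet, 1:3:3:1 quartet); all components share one pair of linewidths.
#' The rendered trace integrates to \code{totalArea}.
#'
#' @param m a \code{\link{multiplet}}.
#' @param totalArea total integrated intensity (>= 0).
#' @param sigma,gamma shared Voigt linewidths (ppm).
#' @param grid strictly ascending ppm axis.
#' @return numeric intensity trace.
#' @examples
#' g <- seq(1.2, 1.45, by = 1e-4)
#' tr <- renderMultiplet(multiplet("doublet", 1.33, J = 6.9), 1, 8e-4, 8e-4, g)
#' @export
renderMultiplet <- function(m, totalArea, sigma, gamma, grid) {
  if (!inherits(m, "multiplet"))
    stop("invalid-input: m must be a multiplet()")
  if (totalArea < 0) stop("invalid-input: totalArea must be non-negative")
  amps <- multipletAmplitudes(m$pattern)
  n <- length(amps)
  spacing <- m$J / m$spectrometerFrequency
  centers <- m$center + (seq_len(n) - (n + 1) / 2) * spacing
  v <- numeric(length(grid))
  for (i in seq_len(n)) {
    if (amps[i] * totalArea == 0 && totalArea == 0) next
    v <- v + voigtProfile(
      voigtPeak(centers[i], sigma, gamma, amps[i] * totalArea), grid)
  }
  v
}

# Render one library signal (all its multiplets, weight-shared area) on grid.
# Internal; used by the generator and by the fit model.
.renderSignal <- function(def, area, sigma, gamma, grid,
                          centerShift = 0) {
  w <- vapply(def@multiplets, function(m) m$weight, numeric(1))
  w <- w / sum(w)
  v <- numeric(length(grid))
  for (i in seq_along(def@multiplets)) {
    m <- def@multiplets[[i]]
    m$center <- m$center + centerShift
    v <- v + renderMultiplet(m, area * w[i], sigma, gamma, grid)
  }
  v
}

#' Trapezoidal integral of a trace over (part of) its grid
#'
#' @param x ascending grid.
#' @param y trace.
#' @param region optional numeric(2) [low, high] restricting the integral.
#' @return the trapezoid-rule integral.
#' @export
trapezoidIntegral <- function(x, y, region = NULL) {
  if (!is.null(region)) {
    keep <- x >= region[1] & x <= region[2]
    if (sum(keep) < 2L)
      stop("invalid-region: fewer than 2 grid points inside region")
    x <- x[keep]
    y <- y[keep]
  }
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
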