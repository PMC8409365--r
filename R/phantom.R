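#' @include morphometry.R
NULL

#' Periodic groove surface emulating a roughness calibration plate
#'
#' Vertical-milled roughness standards carry a periodic groove profile; this
#' generator reproduces one as a height grid with an exactly known Ra. For a
#' symmetric triangle wave of amplitude \code{A} the mean absolute deviation
#' is \code{A/2}, so \code{A = 2 * targetRa}; for a sine it is
#' \code{2A/pi}, so \code{A = (pi/2) * targetRa}. Grooves run along y
#' (constant over the slow axis) with the stated pitch along x.
#'
#' @param pattern \code{"triangle"} or \code{"sine"}.
#' @param targetRa nominal Ra in um (> 0).
#' @param groovePitchUm groove period in um; must span at least 4 lateral
#'   pixels or the profile is under-sampled (error).
#' @param gridDim integer \code{c(nX, nY)}.
#' @param lateralPitch lateral pixel pitch in um.
#' @return numeric nX x nY height matrix (um), zero mean over a period.
#' @export
#' @examples
#' h <- makePlateSurface("triangle", 1.6, 180, c(64, 64), 9)
#' mean(abs(h - mean(h)))   # ~1.6
makePlateSurface <- function(pattern = c("triangle", "sine"), targetRa,
                             groovePitchUm, gridDim, lateralPitch) {
  pattern <- match.arg(pattern)
  stopifnot(targetRa > 0)
  if (groovePitchUm < 4 * lateralPitch)
    stop("groove pitch is under-sampled: need >= 4 lateral pixels per period")
  nX <- as.integer(gridDim[1]); nY <- as.integer(gridDim[2])
  x <- (seq_len(nX) - 1) * lateralPitch
  t <- (x / groovePitchUm) %% 1
  profile <- switch(pattern,
    triangle = 2 * targetRa * (4 * abs(t - 0.5) - 1),
    sine     = (pi / 2) * targetRa * sin(2 * pi * t))
  matrix(profile, nX, nY)
}

#' Random skin-like surface with controlled Ra, skewness and tilt
#'
#' A seeded Gaussian random field (white noise smoothed by circular FFT
#' convolution with a Gaussian kernel of the requested correlation length)
#' emulating the scattered, dot-like protrusions of a cultured skin
#' surface. Positive skewness -- peak-dominated texture, as keratinising
#' samples show -- is injected by the exponential warp
#' \code{(exp(s z) - 1)/s} of the standardised field. The field is centred
#' and rescaled so its Ra equals \code{targetRa} exactly before the tilt
#' plane \code{a x + b y} is added (so Ra after tilt removal recovers the
#' target). Bit-reproducible given \code{seed}.
#'
#' @param seed integer RNG seed.
#' @param correlationLengthUm Gaussian correlation length in um (>= 2
#'   lateral pixels).
#' @param targetRa target Ra in um.
#' @param skewStrength >= 0; 0 keeps the field symmetric.
#' @param baseTilt numeric \code{c(a, b)}, um of height per um of x and y.
#' @param gridDim integer \code{c(nX, nY)}.
#' @param lateralPitch lateral pixel pitch in um.
#' @return numeric nX x nY height matrix (um).
#' @export
makeSkinSurface <- function(seed, correlationLengthUm, targetRa,
                            skewStrength = 0, baseTilt = c(0, 0),
                            gridDim, lateralPitch) {
  nX <- as.integer(gridDim[1]); nY <- as.integer(gridDim[2])
  sigmaPx <- correlationLengthUm / lateralPitch
  if (sigmaPx < 2)
    stop("correlation length must be at least 2 lateral pixels")
  stopifnot(targetRa > 0, skewStrength >= 0)

  f <- withSeed(seed, {
    noise <- matrix(rnorm(nX * nY), nX, nY)
    # circular Gaussian smoothing in the Fourier domain
    kx <- c(0:(nX %/% 2), -((ceiling(nX / 2) - 1):1))
    ky <- c(0:(nY %/% 2), -((ceiling(nY / 2) - 1):1))
    gx <- exp(-kx^2 / (2 * sigmaPx^2))
    gy <- exp(-ky^2 / (2 * sigmaPx^2))
    kern <- outer(gx, gy)
    Re(fft(fft(noise) * fft(kern / sum(kern)), inverse = TRUE)) / (nX * nY)
  })
  f <- (f - mean(f)) / sd(f)
  if (skewStrength > 0)
    f <- (exp(skewStrength * f) - 1) / skewStrength
  f <- f - mean(f)
  ra <- mean(abs(f))
  f <- f * targetRa / ra
  x <- (seq_len(nX) - 1) * lateralPitch
  y <- (seq_len(nY) - 1) * lateralPitch
  f + outer(baseTilt[1] * x, rep(1, nY)) + outer(rep(1, nX), baseTilt[2] * y)
}

#' Render a synthetic OCT volume from two surfaces
#'
#' Builds one A-scan per lateral cell: a clipped Gaussian noise floor plus
#' Gaussian axial point-spread peaks at the two interface depths, and
#' optionally (per the \linkS4class{SignalModel}) a spurious speckle-like
#' peak at a random depth, stratum-corneum spikes at reduced amplitude just
#' below the upper interface, and a basement-membrane echo below the lower
#' interface. Surfaces are given as depth grids in um below the volume top
#' (in-air scale, z = 1 at the top); they are quantised to axial pixels for
#' rendering and the placed indices are recorded in the returned
#' \linkS4class{PhantomTruth}. Cells outside \code{discRadiusUm} (if
#' finite) receive pure noise, emulating the signal drop at the sample
#' edge. Intensities are rounded to integers (16-bit-like storage) unless
#' \code{quantize = FALSE}. Deterministic given \code{model@seed}.
#'
#' @param upper,lower depth grids in um (matrices, nX x nY); \code{lower}
#'   must be strictly deeper everywhere.
#' @param geometry an \linkS4class{AcquisitionGeometry} matching the grids.
#' @param model a \linkS4class{SignalModel}.
#' @param discRadiusUm sample disc radius in um measured from the lateral
#'   field centre; \code{Inf} (default) fills the whole field.
#' @param nominalRa nominal Ra of the upper surface recorded in the truth
#'   object (um; \code{NA} when not applicable).
#' @param quantize round intensities to integers (default TRUE).
#' @return list with elements \code{volume} (an \linkS4class{OCTVolume})
#'   and \code{truth} (a \linkS4class{PhantomTruth}).
#' @export
renderVolume <- function(upper, lower, geometry, model,
                         discRadiusUm = Inf, nominalRa = NA_real_,
                         quantize = TRUE) {
  g <- geometry
  nX <- g@nX; nY <- g@nY; nZ <- g@nZ
  stopifnot(identical(dim(upper), c(nX, nY)), identical(dim(lower), c(nX, nY)))
  if (any(lower <= upper))
    stop("the lower surface must be strictly deeper than the upper everywhere")
  delta <- g@axialPitch
  zu <- round(upper / delta) + 1L
  zl <- round(lower / delta) + 1L
  margin <- 3 * model@psfSigma
  if (any(zu < 1 + margin) || any(zl > nZ - margin))
    stop("surfaces fall outside the axial window (need a margin of 3 psf sigma)")

  if (is.finite(discRadiusUm)) {
    ctr <- c((nX + 1) / 2, (nY + 1) / 2)
    rpx <- discRadiusUm / g@lateralPitchX
    inDisc <- circleMask(nX, nY, ctr, rpx)
  } else {
    inDisc <- matrix(TRUE, nX, nY)
  }

  zAxis <- seq_len(nZ)
  s2 <- 2 * model@psfSigma^2
  arr <- withSeed(model@seed, {
    a <- array(0, dim = c(nZ, nX, nY))   # z-fastest for cache-friendly fill
    for (iy in seq_len(nY)) for (ix in seq_len(nX)) {
      sig <- rnorm(nZ, 0, model@noiseSigma)
      if (inDisc[ix, iy]) {
        cu <- zu[ix, iy]; cl <- zl[ix, iy]
        sig <- sig + model@peakAmpUpper * exp(-(zAxis - cu)^2 / s2) +
                     model@peakAmpLower * exp(-(zAxis - cl)^2 / s2)
        if (model@corneumSpikeCount > 0L) {
          # distinct spike depths spaced >= 3 psf sigma so spikes never merge
          # into a summed peak brighter than the surface itself
          lo <- cu + max(2L, ceiling(3 * model@psfSigma))
          hi <- cu + (cl - cu) %/% 2L - 1L
          slots <- if (hi >= lo)
            seq.int(lo, hi, by = max(1L, ceiling(3 * model@psfSigma)))
          else integer()
          if (length(slots)) {
            n <- min(model@corneumSpikeCount, length(slots))
            at <- slots[sample.int(length(slots), n)]
            amp <- model@corneumSpikeFrac * model@peakAmpUpper
            for (c0 in at) sig <- sig + amp * exp(-(zAxis - c0)^2 / s2)
          }
        }
        if (model@membraneAmpFrac > 0) {
          c0 <- cl + model@membraneOffset
          sig <- sig + model@membraneAmpFrac * model@peakAmpLower *
            exp(-(zAxis - c0)^2 / s2)
        }
      }
      if (model@spuriousProb > 0 && runif(1) < model@spuriousProb) {
        c0 <- sample.int(nZ, 1L)
        sig <- sig + model@spuriousAmp * exp(-(zAxis - c0)^2 / s2)
      }
      a[, ix, iy] <- sig
    }
    a
  })
  arr <- aperm(arr, c(2L, 3L, 1L))
  arr <- pmax(arr, 0)
  if (quantize) arr <- round(arr)

  truth <- new("PhantomTruth",
               upperDepthUm = upper, lowerDepthUm = lower,
               upperIndex = matrix(zu, nX, nY), lowerIndex = matrix(zl, nX, nY),
               nominalRa = as.numeric(nominalRa),
               lateralExtent = discRadiusUm, model = model)
  list(volume = OCTVolume(arr, g), truth = truth)
}
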