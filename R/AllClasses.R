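#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# AcquisitionGeometry
# ---------------------------------------------------------------------------

#' Acquisition geometry of an OCT volume
#'
#' Holds the physical sampling of a volume: lateral pixel pitches, the axial
#' pixel pitch in air (\eqn{\delta}), the group refractive index of the sample
#' (\eqn{\gamma}), and the pixel counts along x, y, z. The in-tissue axial
#' pitch is \eqn{\delta / \gamma}: an optical path of one axial pixel
#' corresponds to a shorter physical depth inside the medium.
#'
#' @slot lateralPitchX,lateralPitchY lateral pixel pitch, micrometres/pixel.
#' @slot axialPitch axial pixel pitch in air (\eqn{\delta}), micrometres/pixel.
#' @slot refractiveIndex sample group refractive index (\eqn{\gamma \ge 1}).
#' @slot nX,nY,nZ pixel counts along the x (fast lateral), y (slow lateral)
#'   and z (depth) axes.
#'
#' @examples
#' g <- AcquisitionGeometry(nX = 64, nY = 64, nZ = 256)
#' axialPitch(g) / refractiveIndex(g)   # in-tissue axial resolution, um
#' @export
setClass("AcquisitionGeometry",
  representation(
    lateralPitchX   = "numeric",
    lateralPitchY   = "numeric",
    axialPitch      = "numeric",
    refractiveIndex = "numeric",
    nX = "integer", nY = "integer", nZ = "integer"
  )
)

setValidity("AcquisitionGeometry", function(object) {
  msg <- character()
  for (s in c("lateralPitchX", "lateralPitchY", "axialPitch")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  }
  g <- object@refractiveIndex
  if (length(g) != 1L || !is.finite(g) || g < 1)
    msg <- c(msg, "'refractiveIndex' must be a single number >= 1")
  for (s in c("nX", "nY", "nZ")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 1L)
      msg <- c(msg, sprintf("'%s' must be a positive integer", s))
  }
  if (length(msg)) msg else TRUE
})

#' @param lateralPitchX,lateralPitchY,axialPitch,refractiveIndex,nX,nY,nZ see
#'   the corresponding slots. Defaults mirror a 9 mm x 9 mm x 3.59 mm field
#'   sampled as 1000 x 1000 x 1024 voxels with a skin-like refractive index.
#' @rdname AcquisitionGeometry-class
#' @export
AcquisitionGeometry <- function(lateralPitchX = 9, lateralPitchY = 9,
                                axialPitch = 3590 / 1024,
                                refractiveIndex = 1.38,
                                nX = 1000L, nY = 1000L, nZ = 1024L) {
  new("AcquisitionGeometry",
      lateralPitchX = as.numeric(lateralPitchX),
      lateralPitchY = as.numeric(lateralPitchY),
      axialPitch = as.numeric(axialPitch),
      refractiveIndex = as.numeric(refractiveIndex),
      nX = as.integer(nX), nY = as.integer(nY), nZ = as.integer(nZ))
}

#' @rdname AcquisitionGeometry-class
#' @param x an \code{AcquisitionGeometry}.
#' @export
setMethod("axialPitch", "AcquisitionGeometry", function(x) x@axialPitch)

#' @rdname AcquisitionGeometry-class
#' @export
setMethod("lateralPitch", "AcquisitionGeometry",
          function(x) c(x = x@lateralPitchX, y = x@lateralPitchY))

#' @rdname AcquisitionGeometry-class
#' @export
setMethod("refractiveIndex", "AcquisitionGeometry", function(x) x@refractiveIndex)

#' @rdname AcquisitionGeometry-class
#' @export
setMethod("dim", "AcquisitionGeometry", function(x) c(x@nX, x@nY, x@nZ))

setMethod("show", "AcquisitionGeometry", function(object) {
  cat(sprintf(
    "AcquisitionGeometry: %d x %d x %d voxels\n  lateral pitch %.4g x %.4g um, axial pitch %.4g um (air), n = %.3g\n",
    object@nX, object@nY, object@nZ,
    object@lateralPitchX, object@lateralPitchY,
    object@axialPitch, object@refractiveIndex))
})

# ---------------------------------------------------------------------------
# OCTVolume
# ---------------------------------------------------------------------------

#' A 3D OCT intensity volume with acquisition geometry
#'
#' An intensity volume indexed \code{[x, y, z]} (z = 1 at the top, increasing
#' with depth) together with its \linkS4class{AcquisitionGeometry}. All
#' intensities must be finite and non-negative.
#'
#' @slot intensity 3D numeric array, dimensions matching the geometry.
#' @slot geometry an \linkS4class{AcquisitionGeometry}.
#' @export
setClass("OCTVolume",
  representation(intensity = "array", geometry = "AcquisitionGeometry"))

setValidity("OCTVolume", function(object) {
  d <- dim(object@intensity)
  if (length(d) != 3L)
    return("'intensity' must be a 3D array")
  if (!identical(as.integer(d), as.integer(dim(object@geometry))))
    return(sprintf("intensity dimensions (%s) do not match geometry (%s)",
                   paste(d, collapse = "x"),
                   paste(dim(object@geometry), collapse = "x")))
  if (anyNA(object@intensity) || any(!is.finite(object@intensity)))
    return("'intensity' must be finite")
  if (any(object@intensity < 0))
    return("'intensity' must be non-negative")
  TRUE
})

#' @param intensity,geometry see slots.
#' @rdname OCTVolume-class
#' @export
OCTVolume <- function(intensity, geometry) {
  new("OCTVolume", intensity = intensity, geometry = geometry)
}

#' @rdname OCTVolume-class
#' @param x an \code{OCTVolume}.
#' @export
setMethod("intensity", "OCTVolume", function(x) x@intensity)

#' @rdname OCTVolume-class
#' @export
setMethod("geometry", "OCTVolume", function(x) x@geometry)

#' @rdname OCTVolume-class
#' @export
setMethod("dim", "OCTVolume", function(x) dim(x@intensity))

setMethod("show", "OCTVolume", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("OCTVolume: %d x %d x %d, intensity range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(object@intensity), max(object@intensity)))
  show(object@geometry)
})

# ---------------------------------------------------------------------------
# ROISpec
# ---------------------------------------------------------------------------

#' Region-of-interest specification
#'
#' The calibrated axial window \code{[rbU, rbB]} known from the fixed focus
#' position, the detected lateral margins \code{[rbLx, rbRx]} /
#' \code{[rbLy, rbRy]} bounding the sample, and the circular quantification
#' region (centre, radius, pixels). All bounds are 1-based and inclusive.
#' Circle membership is strict: a cell \code{(ix, iy)} belongs to the circle
#' iff \code{(ix - cx)^2 + (iy - cy)^2 < r^2}.
#'
#' @slot rbU,rbB axial window bounds (pixels, inclusive), \code{rbU < rbB}.
#' @slot rbLx,rbRx,rbLy,rbRy lateral margins per axis (pixels, inclusive).
#' @slot center circle centre \code{c(x, y)} in pixels (may be fractional).
#' @slot radius circle radius in pixels.
#' @export
setClass("ROISpec",
  representation(rbU = "integer", rbB = "integer",
                 rbLx = "integer", rbRx = "integer",
                 rbLy = "integer", rbRy = "integer",
                 center = "numeric", radius = "numeric"))

setValidity("ROISpec", function(object) {
  msg <- character()
  if (object@rbU < 1L || object@rbU >= object@rbB)
    msg <- c(msg, "axial bounds must satisfy 1 <= rbU < rbB")
  if (object@rbLx < 1L || object@rbLx >= object@rbRx)
    msg <- c(msg, "lateral x margins must satisfy 1 <= rbLx < rbRx")
  if (object@rbLy < 1L || object@rbLy >= object@rbRy)
    msg <- c(msg, "lateral y margins must satisfy 1 <= rbLy < rbRy")
  if (length(object@center) != 2L || anyNA(object@center))
    msg <- c(msg, "'center' must be c(x, y)")
  if (length(object@radius) != 1L || is.na(object@radius) || object@radius <= 0)
    msg <- c(msg, "'radius' must be a single positive number")
  if (!length(msg)) {
    r <- object@radius
    if (object@center[1] - r < object@rbLx - 0.5 ||
        object@center[1] + r > object@rbRx + 0.5 ||
        object@center[2] - r < object@rbLy - 0.5 ||
        object@center[2] + r > object@rbRy + 0.5)
      msg <- c(msg, "circle must lie within the lateral margins")
  }
  if (length(msg)) msg else TRUE
})

#' @param rbU,rbB,rbLx,rbRx,rbLy,rbRy,center,radius see slots.
#' @rdname ROISpec-class
#' @export
ROISpec <- function(rbU, rbB, rbLx, rbRx, rbLy, rbRy, center, radius) {
  new("ROISpec", rbU = as.integer(rbU), rbB = as.integer(rbB),
      rbLx = as.integer(rbLx), rbRx = as.integer(rbRx),
      rbLy = as.integer(rbLy), rbRy = as.integer(rbRy),
      center = as.numeric(center), radius = as.numeric(radius))
}

setMethod("show", "ROISpec", function(object) {
  cat(sprintf(
    "ROISpec: axial [%d, %d], lateral x [%d, %d], y [%d, %d]\n  circle centre (%.1f, %.1f), radius %.1f px\n",
    object@rbU, object@rbB, object@rbLx, object@rbRx, object@rbLy,
    object@rbRy, object@center[1], object@center[2], object@radius))
})

# ---------------------------------------------------------------------------
# DetectionParams
# ---------------------------------------------------------------------------

#' Parameters of the two-stage interface detection
#'
#' \code{t1} is the minimum admissible axial separation (pixels) between the
#' two interface peaks in the coarse stage; it encodes the minimum plausible
#' sample thickness and rejects split peaks from a single interface. The
#' coarse stage on early-culture skin uses 10 px (about 25 um of tissue at a
#' 3.5 um axial pitch); thicker, more keratinised samples use 15-20 px.
#' \code{t2Fraction} is the fine-stage intensity tolerance: a local maximum
#' shallower than the coarse peak replaces it when its intensity is at least
#' \code{(1 - t2Fraction)} times the coarse peak's intensity.
#' \code{edgeDropFraction} is the lateral-boundary threshold used by
#' \code{\link{determineROI}}.
#'
#' @slot t1 integer, pixels, >= 1.
#' @slot t2Fraction numeric in (0, 1), default 0.2.
#' @slot edgeDropFraction numeric in (0, 1), default 0.5.
#' @export
setClass("DetectionParams",
  representation(t1 = "integer", t2Fraction = "numeric",
                 edgeDropFraction = "numeric"))

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (length(object@t1) != 1L || is.na(object@t1) || object@t1 < 1L)
    msg <- c(msg, "'t1' must be an integer >= 1")
  if (length(object@t2Fraction) != 1L || is.na(object@t2Fraction) ||
      object@t2Fraction <= 0 || object@t2Fraction >= 1)
    msg <- c(msg, "'t2Fraction' must lie in (0, 1)")
  if (length(object@edgeDropFraction) != 1L || is.na(object@edgeDropFraction) ||
      object@edgeDropFraction <= 0 || object@edgeDropFraction >= 1)
    msg <- c(msg, "'edgeDropFraction' must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param t1,t2Fraction,edgeDropFraction see slots.
#' @rdname DetectionParams-class
#' @export
DetectionParams <- function(t1 = 10L, t2Fraction = 0.2, edgeDropFraction = 0.5) {
  new("DetectionParams", t1 = as.integer(t1),
      t2Fraction = as.numeric(t2Fraction),
      edgeDropFraction = as.numeric(edgeDropFraction))
}

setMethod("show", "DetectionParams", function(object) {
  cat(sprintf("DetectionParams: t1 = %d px, t2 = %.2f, edge drop = %.2f\n",
              object@t1, object@t2Fraction, object@edgeDropFraction))
})

# ---------------------------------------------------------------------------
# InterfaceMap
# ---------------------------------------------------------------------------

#' Per-A-scan upper/lower interface positions
#'
#' Axial pixel indices of the upper (\code{Pu}) and lower (\code{Pb})
#' interface for every lateral position \code{(x, y)}, with a validity mask.
#' Cells outside the circular ROI or where detection failed are invalid and
#' carry \code{NA}. Wherever valid, \code{rbU <= Pu < Pb <= rbB} and
#' \code{Pb - Pu >= t1} hold by construction.
#'
#' @slot puGrid,pbGrid numeric matrices (x by y) of axial indices, \code{NA}
#'   where invalid.
#' @slot validMask logical matrix of the same shape.
#' @export
setClass("InterfaceMap",
  representation(puGrid = "matrix", pbGrid = "matrix", validMask = "matrix"))

setValidity("InterfaceMap", function(object) {
  if (!identical(dim(object@puGrid), dim(object@pbGrid)) ||
      !identical(dim(object@puGrid), dim(object@validMask)))
    return("puGrid, pbGrid and validMask must share a lateral shape")
  if (!is.logical(object@validMask))
    return("'validMask' must be logical")
  v <- object@validMask
  if (any(v & (is.na(object@puGrid) | is.na(object@pbGrid))))
    return("valid cells must carry non-NA Pu and Pb")
  if (any(object@pbGrid[v] <= object@puGrid[v]))
    return("Pu < Pb must hold at every valid cell")
  TRUE
})

#' @param puGrid,pbGrid,validMask see slots.
#' @rdname InterfaceMap-class
#' @export
InterfaceMap <- function(puGrid, pbGrid, validMask) {
  new("InterfaceMap", puGrid = puGrid, pbGrid = pbGrid, validMask = validMask)
}

#' @rdname InterfaceMap-class
#' @param x an \code{InterfaceMap}.
#' @export
setMethod("upperIndex", "InterfaceMap", function(x) x@puGrid)

#' @rdname InterfaceMap-class
#' @export
setMethod("lowerIndex", "InterfaceMap", function(x) x@pbGrid)

#' @rdname InterfaceMap-class
#' @export
setMethod("validMask", "InterfaceMap", function(x) x@validMask)

#' @rdname InterfaceMap-class
#' @export
setMethod("dim", "InterfaceMap", function(x) dim(x@puGrid))

setMethod("show", "InterfaceMap", function(object) {
  d <- dim(object@puGrid)
  nv <- sum(object@validMask)
  cat(sprintf("InterfaceMap: %d x %d cells, %d valid (%.1f%%)\n",
              d[1], d[2], nv, 100 * nv / prod(d)))
})

# ---------------------------------------------------------------------------
# ThicknessMap
# ---------------------------------------------------------------------------

#' Physical thickness field
#'
#' Per-cell physical thickness Th = delta * N / gamma (um), where N = Pb - Pu
#' is the axial pixel gap, delta the in-air axial pitch and gamma the sample
#' refractive index (the optical path between the peaks is converted to
#' physical depth). Mean and SD are over valid cells only.
#'
#' @slot thGrid numeric matrix of thickness in um, \code{NA} where invalid.
#' @slot validMask logical matrix.
#' @slot meanTh,sdTh summary statistics over valid cells (um).
#' @export
setClass("ThicknessMap",
  representation(thGrid = "matrix", validMask = "matrix",
                 meanTh = "numeric", sdTh = "numeric"))

setValidity("ThicknessMap", function(object) {
  if (!identical(dim(object@thGrid), dim(object@validMask)))
    return("thGrid and validMask must share a shape")
  if (any(object@thGrid[object@validMask] < 0))
    return("thickness must be non-negative at valid cells")
  TRUE
})

#' @rdname ThicknessMap-class
#' @param x a \code{ThicknessMap}.
#' @export
setMethod("thicknessGrid", "ThicknessMap", function(x) x@thGrid)

#' @rdname ThicknessMap-class
#' @export
setMethod("validMask", "ThicknessMap", function(x) x@validMask)

#' @rdname ThicknessMap-class
#' @export
setMethod("meanThickness", "ThicknessMap", function(x) x@meanTh)

#' @rdname ThicknessMap-class
#' @export
setMethod("sdThickness", "ThicknessMap", function(x) x@sdTh)

setMethod("show", "ThicknessMap", function(object) {
  cat(sprintf("ThicknessMap: %d valid cells, mean Th = %.2f um (sd %.2f)\n",
              sum(object@validMask), object@meanTh, object@sdTh))
})

# ---------------------------------------------------------------------------
# SurfaceHeights
# ---------------------------------------------------------------------------

#' Upper-surface height field and (optional) cubic reference fit
#'
#' Heights in um derived from the upper-interface indices, up-positive
#' (\code{Z = -(Pu - 1) * delta}; the air-side axial pitch applies with no
#' refractive correction, since the upper interface is an air--sample
#' boundary measured in air). After \code{\link{fitReferenceSurface}} the
#' object also carries the 10 coefficients of the total-degree-3 bivariate
#' polynomial (on internally centred/scaled coordinates, see
#' \code{coordCenter}/\code{coordScale}) and the residual grid.
#'
#' @slot zGrid heights (um), \code{NA} where invalid.
#' @slot xCoords,yCoords lateral physical coordinates (um) of grid lines.
#' @slot validMask logical matrix.
#' @slot fitCoeffs named numeric, length 0 before fitting.
#' @slot coordCenter,coordScale centring/scaling applied to (x, y) before
#'   building the cubic design matrix (conditioning).
#' @slot residuals numeric matrix (um), empty before fitting.
#' @slot zBar mean height (raw) or mean residual (after fitting) over valid
#'   cells, um.
#' @slot pn number of valid cells.
#' @export
setClass("SurfaceHeights",
  representation(zGrid = "matrix", xCoords = "numeric", yCoords = "numeric",
                 validMask = "matrix", fitCoeffs = "numeric",
                 coordCenter = "numeric", coordScale = "numeric",
                 residuals = "matrix", zBar = "numeric", pn = "integer"))

setValidity("SurfaceHeights", function(object) {
  msg <- character()
  d <- dim(object@zGrid)
  if (!identical(d, dim(object@validMask)))
    msg <- c(msg, "zGrid and validMask must share a shape")
  if (length(object@xCoords) != d[1] || length(object@yCoords) != d[2])
    msg <- c(msg, "coordinate vectors must match the grid shape")
  if (object@pn != sum(object@validMask))
    msg <- c(msg, "'pn' must equal the number of valid cells")
  if (length(object@residuals) && !identical(dim(object@residuals), d))
    msg <- c(msg, "residual grid must match the height grid shape")
  if (length(object@residuals) && object@pn > 0L) {
    if (abs(mean(object@residuals[object@validMask])) > 1e-9)
      msg <- c(msg, "mean residual over valid cells must vanish (<= 1e-9 um)")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SurfaceHeights-class
#' @param x a \code{SurfaceHeights}.
#' @export
setMethod("heights", "SurfaceHeights", function(x) x@zGrid)

#' @rdname SurfaceHeights-class
#' @export
setMethod("validMask", "SurfaceHeights", function(x) x@validMask)

#' @rdname SurfaceHeights-class
#' @export
setMethod("fitCoeffs", "SurfaceHeights", function(x) x@fitCoeffs)

#' @rdname SurfaceHeights-class
#' @param object a \code{SurfaceHeights} (for \code{residuals}).
#' @param ... unused.
#' @export
setMethod("residuals", "SurfaceHeights", function(object, ...) object@residuals)

setMethod("show", "SurfaceHeights", function(object) {
  cat(sprintf("SurfaceHeights: %d x %d grid, %d valid cells%s\n",
              nrow(object@zGrid), ncol(object@zGrid), object@pn,
              if (length(object@fitCoeffs)) ", cubic reference fitted" else ""))
})

# ---------------------------------------------------------------------------
# RoughnessResult
# ---------------------------------------------------------------------------

#' Areal roughness parameters over the circular ROI
#'
#' \code{Ra} is the arithmetic mean absolute deviation of heights from their
#' ROI mean, \code{Rq} the root-mean-square deviation, and \code{Rsk} the
#' height-distribution skewness normalised by \code{Rq^3} (dimensionless;
#' positive for peak-dominated surfaces). \code{Rsk} is undefined when
#' \code{Rq = 0} and is then reported as \code{NA} with
#' \code{rskDefined = FALSE}.
#'
#' @slot ra,rq roughness in um.
#' @slot rsk dimensionless skewness, \code{NA} when undefined.
#' @slot rskDefined logical.
#' @slot pn number of contributing sample points.
#' @export
setClass("RoughnessResult",
  representation(ra = "numeric", rq = "numeric", rsk = "numeric",
                 rskDefined = "logical", pn = "integer"))

setValidity("RoughnessResult", function(object) {
  msg <- character()
  if (object@ra < 0) msg <- c(msg, "'ra' must be >= 0")
  if (object@rq < object@ra - 1e-12 * max(1, object@rq))
    msg <- c(msg, "'rq' must be >= 'ra' (power-mean inequality)")
  if (object@rskDefined && !is.finite(object@rsk))
    msg <- c(msg, "defined 'rsk' must be finite")
  if (object@pn < 1L) msg <- c(msg, "'pn' must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname RoughnessResult-class
#' @param x a \code{RoughnessResult}.
#' @export
setMethod("Ra", "RoughnessResult", function(x) x@ra)

#' @rdname RoughnessResult-class
#' @export
setMethod("Rq", "RoughnessResult", function(x) x@rq)

#' @rdname RoughnessResult-class
#' @export
setMethod("Rsk", "RoughnessResult", function(x) x@rsk)

setMethod("show", "RoughnessResult", function(object) {
  cat(sprintf("RoughnessResult: Ra = %.4g um, Rq = %.4g um, Rsk = %s (PN = %d)\n",
              object@ra, object@rq,
              if (object@rskDefined) sprintf("%.4g", object@rsk) else "undefined",
              object@pn))
})

# ---------------------------------------------------------------------------
# SignalModel
# ---------------------------------------------------------------------------

#' A-scan signal model for the synthetic phantom
#'
#' Phenomenological model of one OCT A-scan of a two-interface sample: a
#' noise floor, Gaussian axial point-spread peaks at the two interfaces,
#' optional spurious (speckle-like) peaks at random depths, stratum-corneum
#' multi-spikes just below the upper interface at reduced amplitude, and a
#' basement-membrane echo below the lower interface. Speckle is approximated
#' as additive Gaussian intensity noise plus the discrete spurious peaks
#' (not fully developed multiplicative speckle); this is sufficient to
#' exercise the detector's failure modes and is exactly seedable.
#'
#' @slot peakAmpUpper,peakAmpLower interface peak amplitudes (intensity).
#' @slot psfSigma axial Gaussian point-spread sigma, pixels (>= 0.5).
#' @slot noiseSigma noise-floor standard deviation (intensity).
#' @slot spuriousProb per-A-scan probability of one spurious peak.
#' @slot spuriousAmp spurious peak amplitude.
#' @slot corneumSpikeCount number of sub-surface corneum spikes per A-scan.
#' @slot corneumSpikeFrac corneum spike amplitude as a fraction of the upper
#'   peak amplitude (default 0.85).
#' @slot membraneOffset basement-membrane echo depth below Pb, pixels.
#' @slot membraneAmpFrac membrane amplitude as a fraction of the lower peak
#'   amplitude (0 disables the echo).
#' @slot seed integer RNG seed; rendering is bit-reproducible given the seed.
#' @export
setClass("SignalModel",
  representation(peakAmpUpper = "numeric", peakAmpLower = "numeric",
                 psfSigma = "numeric", noiseSigma = "numeric",
                 spuriousProb = "numeric", spuriousAmp = "numeric",
                 corneumSpikeCount = "integer", corneumSpikeFrac = "numeric",
                 membraneOffset = "integer", membraneAmpFrac = "numeric",
                 seed = "integer"))

setValidity("SignalModel", function(object) {
  msg <- character()
  if (object@peakAmpUpper <= object@noiseSigma ||
      object@peakAmpLower <= object@noiseSigma)
    msg <- c(msg, "interface amplitudes must exceed the noise-floor sigma")
  if (object@psfSigma < 0.5)
    msg <- c(msg, "'psfSigma' must be >= 0.5 px")
  if (object@spuriousProb < 0 || object@spuriousProb > 1)
    msg <- c(msg, "'spuriousProb' must lie in [0, 1]")
  if (object@corneumSpikeCount < 0L)
    msg <- c(msg, "'corneumSpikeCount' must be >= 0")
  if (object@membraneAmpFrac < 0)
    msg <- c(msg, "'membraneAmpFrac' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param peakAmpUpper,peakAmpLower,psfSigma,noiseSigma,spuriousProb,spuriousAmp,corneumSpikeCount,corneumSpikeFrac,membraneOffset,membraneAmpFrac,seed
#'   see slots.
#' @rdname SignalModel-class
#' @export
SignalModel <- function(peakAmpUpper = 10000, peakAmpLower = 8000,
                        psfSigma = 1.5, noiseSigma = 1e-3,
                        spuriousProb = 0, spuriousAmp = 5000,
                        corneumSpikeCount = 0L, corneumSpikeFrac = 0.85,
                        membraneOffset = 12L, membraneAmpFrac = 0,
                        seed = 1L) {
  new("SignalModel", peakAmpUpper = as.numeric(peakAmpUpper),
      peakAmpLower = as.numeric(peakAmpLower), psfSigma = as.numeric(psfSigma),
      noiseSigma = as.numeric(noiseSigma),
      spuriousProb = as.numeric(spuriousProb),
      spuriousAmp = as.numeric(spuriousAmp),
      corneumSpikeCount = as.integer(corneumSpikeCount),
      corneumSpikeFrac = as.numeric(corneumSpikeFrac),
      membraneOffset = as.integer(membraneOffset),
      membraneAmpFrac = as.numeric(membraneAmpFrac), seed = as.integer(seed))
}

setMethod("show", "SignalModel", function(object) {
  cat(sprintf(
    "SignalModel: peaks %.3g/%.3g, psf sigma %.2g px, noise %.3g, spurious p = %.2g\n",
    object@peakAmpUpper, object@peakAmpLower, object@psfSigma,
    object@noiseSigma, object@spuriousProb))
})

# ---------------------------------------------------------------------------
# PhantomTruth
# ---------------------------------------------------------------------------

#' Ground truth of a rendered phantom volume
#'
#' Records the surfaces actually placed into a rendered volume: the
#' continuous input depth grids (um below the volume top, in-air scale) and
#' the quantised axial pixel indices at which the interface peaks were
#' rendered, together with the generator parameters. Used to score surface
#' recovery exactly.
#'
#' @slot upperDepthUm,lowerDepthUm continuous depth grids, um.
#' @slot upperIndex,lowerIndex rendered axial pixel indices (1-based).
#' @slot nominalRa nominal Ra of the upper surface, um (\code{NA} if not
#'   applicable).
#' @slot lateralExtent disc radius of the sample in um, \code{Inf} for a
#'   full-field sample.
#' @slot model the \linkS4class{SignalModel} used.
#' @export
setClass("PhantomTruth",
  representation(upperDepthUm = "matrix", lowerDepthUm = "matrix",
                 upperIndex = "matrix", lowerIndex = "matrix",
                 nominalRa = "numeric", lateralExtent = "numeric",
                 model = "SignalModel"))

setValidity("PhantomTruth", function(object) {
  if (!identical(dim(object@upperDepthUm), dim(object@lowerDepthUm)))
    return("surface grids must share a shape")
  if (any(object@lowerIndex <= object@upperIndex))
    return("the lower surface must lie strictly deeper than the upper")
  TRUE
})

#' @rdname PhantomTruth-class
#' @param x a \code{PhantomTruth}.
#' @export
setMethod("upperIndex", "PhantomTruth", function(x) x@upperIndex)

#' @rdname PhantomTruth-class
#' @export
setMethod("lowerIndex", "PhantomTruth", function(x) x@lowerIndex)

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: %d x %d surfaces, upper depth %.1f-%.1f um, nominal Ra %s\n",
    nrow(object@upperDepthUm), ncol(object@upperDepthUm),
    min(object@upperDepthUm), max(object@upperDepthUm),
    if (is.na(object@nominalRa)) "n/a" else sprintf("%.3g um", object@nominalRa)))
})
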