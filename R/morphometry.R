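#' @include detect.R
NULL

#' Physical thickness from an interface map
#'
#' Per valid cell the axial pixel gap is \code{N = Pb - Pu} and the physical
#' thickness is \code{Th = delta * N / gamma} um: the gap measures optical
#' path at the in-air pitch \code{delta}, and dividing by the refractive
#' index \code{gamma} converts it to geometric depth inside the sample
#' (e.g. a 3.5 um in-air pitch corresponds to 3.5/1.38 = 2.54 um of tissue).
#'
#' @param interfaces an \linkS4class{InterfaceMap}.
#' @param geometry an \linkS4class{AcquisitionGeometry}.
#' @param ... unused.
#' @return a \linkS4class{ThicknessMap}.
#' @export
setMethod("thicknessMap", signature(interfaces = "InterfaceMap",
                                    geometry = "AcquisitionGeometry"),
  function(interfaces, geometry, ...) {
    v <- validMask(interfaces)
    if (!any(v))
      stop("no valid cells: cannot compute a thickness map")
    nGrid <- lowerIndex(interfaces) - upperIndex(interfaces)
    th <- geometry@axialPitch * nGrid / geometry@refractiveIndex
    th[!v] <- NA_real_
    new("ThicknessMap", thGrid = th, validMask = v,
        meanTh = mean(th[v]), sdTh = if (sum(v) > 1L) sd(th[v]) else 0)
  })

#' Upper-surface heights from an interface map
#'
#' Converts the upper-interface indices to physical heights in um,
#' up-positive: \code{Z = -(Pu - 1) * delta}. The air-side axial pitch is
#' used with no refractive correction -- the upper interface is an
#' air--sample boundary and its topography is measured in air (as are bare
#' calibration plates). Lateral grid coordinates are physical
#' (\code{(i - 1) * pitch} um).
#'
#' @param interfaces an \linkS4class{InterfaceMap}.
#' @param geometry an \linkS4class{AcquisitionGeometry}.
#' @param ... unused.
#' @return a \linkS4class{SurfaceHeights} (no reference fit yet).
#' @export
setMethod("surfaceHeights", signature(interfaces = "InterfaceMap",
                                      geometry = "AcquisitionGeometry"),
  function(interfaces, geometry, ...) {
    v <- validMask(interfaces)
    if (!any(v))
      stop("no valid cells: cannot compute surface heights")
    z <- -(upperIndex(interfaces) - 1) * geometry@axialPitch
    z[!v] <- NA_real_
    d <- dim(v)
    new("SurfaceHeights", zGrid = z,
        xCoords = (seq_len(d[1]) - 1) * geometry@lateralPitchX,
        yCoords = (seq_len(d[2]) - 1) * geometry@lateralPitchY,
        validMask = v, fitCoeffs = numeric(),
        coordCenter = c(0, 0), coordScale = c(1, 1),
        residuals = matrix(numeric(), 0, 0),
        zBar = mean(z[v]), pn = as.integer(sum(v)))
  })

# the ten monomials of a total-degree-<=3 bivariate polynomial
.cubicTerms <- c("1", "x", "y", "x2", "xy", "y2", "x3", "x2y", "xy2", "y3")

.cubicDesign <- function(x, y) {
  cbind(`1` = 1, x = x, y = y, x2 = x^2, xy = x * y, y2 = y^2,
        x3 = x^3, x2y = x^2 * y, xy2 = x * y^2, y3 = y^3)
}

#' Fit the bivariate cubic reference surface
#'
#' Ordinary least squares of the heights on the ten monomials of a
#' total-degree-3 bivariate polynomial in the lateral coordinates, over the
#' valid cells. Subtracting the fit flattens the surface: tilt (from sample
#' placement) and bow (from growth) are removed before roughness is
#' measured. Coordinates are internally centred and scaled to unit
#' half-range for conditioning; \code{fitCoeffs} are reported on that basis
#' and the centring/scale stored alongside. Because the constant term is
#' included, the residuals average to zero over the valid cells exactly.
#' A rank-deficient design (e.g. all points collinear) degrades to the
#' maximal identifiable subset of terms with a warning.
#'
#' @param heights a \linkS4class{SurfaceHeights} with \code{pn >= 10}.
#' @param ... unused.
#' @return the input with \code{fitCoeffs}, \code{residuals} and
#'   \code{zBar} (now the mean residual, ~0) populated.
#' @export
setMethod("fitReferenceSurface", "SurfaceHeights", function(heights, ...) {
  v <- heights@validMask
  if (heights@pn < 10L)
    stop("need at least 10 valid points to fit the 10-coefficient cubic surface")
  idx <- which(v, arr.ind = TRUE)
  xs <- heights@xCoords[idx[, 1L]]
  ys <- heights@yCoords[idx[, 2L]]
  ctr <- c(mean(range(xs)), mean(range(ys)))
  scl <- c(max(diff(range(xs)) / 2, 1), max(diff(range(ys)) / 2, 1))
  X <- .cubicDesign((xs - ctr[1]) / scl[1], (ys - ctr[2]) / scl[2])
  z <- heights@zGrid[v]

  fit <- lm.fit(X, z)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    dropped <- names(beta)[is.na(beta)]
    warning(sprintf("rank-deficient cubic design; dropped term(s): %s",
                    paste(dropped, collapse = ", ")))
    beta[is.na(beta)] <- 0
  }
  res <- z - as.numeric(X %*% beta)
  resGrid <- matrix(NA_real_, nrow(v), ncol(v))
  resGrid[v] <- res

  out <- heights
  out@fitCoeffs <- setNames(as.numeric(beta), .cubicTerms)
  out@coordCenter <- ctr
  out@coordScale <- scl
  out@residuals <- resGrid
  out@zBar <- mean(res)
  validObject(out)
  out
})

#' Areal roughness over the circular ROI
#'
#' With \eqn{Z_n} the heights (residuals after flattening when
#' \code{flatten = TRUE}, raw heights otherwise) at the \eqn{PN} valid cells
#' strictly inside the ROI circle, and \eqn{\bar Z} their mean:
#' \deqn{Ra = \frac{1}{PN} \sum_n |Z_n - \bar Z|, \quad
#'       Rq = \sqrt{\frac{1}{PN} \sum_n (Z_n - \bar Z)^2}, \quad
#'       Rsk = \frac{1}{Rq^3} \frac{1}{PN} \sum_n (Z_n - \bar Z)^3.}
#' \eqn{\bar Z} is recomputed on whichever height set is used. When
#' \eqn{Rq = 0} (a perfectly flat field) the skewness is undefined and
#' reported as \code{NA} with \code{rskDefined = FALSE}.
#'
#' @param heights a \linkS4class{SurfaceHeights}; must carry residuals if
#'   \code{flatten = TRUE}.
#' @param roi a \linkS4class{ROISpec} (only the circle is used here).
#' @param flatten use the cubic-fit residuals (default) or the raw heights.
#' @param ... unused.
#' @return a \linkS4class{RoughnessResult}.
#' @export
setMethod("roughness", signature(heights = "SurfaceHeights", roi = "ROISpec"),
  function(heights, roi, flatten = TRUE, ...) {
    if (flatten) {
      if (!length(heights@residuals))
        stop("flatten = TRUE but no reference fit present; run fitReferenceSurface() first")
      z <- heights@residuals
    } else {
      z <- heights@zGrid
    }
    d <- dim(z)
    mask <- heights@validMask & circleMask(d[1], d[2], roi@center, roi@radius)
    pn <- sum(mask)
    if (pn == 0L)
      stop("no valid cells inside the ROI circle")
    zz <- z[mask]
    zbar <- mean(zz)
    dev <- zz - zbar
    ra <- mean(abs(dev))
    rq <- sqrt(mean(dev^2))
    if (rq > 0) {
      rsk <- mean(dev^3) / rq^3
      defined <- TRUE
    } else {
      rsk <- NA_real_
      defined <- FALSE
    }
    new("RoughnessResult", ra = ra, rq = rq, rsk = rsk,
        rskDefined = defined, pn = as.integer(pn))
  })

#' Verification statistics against nominal roughness standards
#'
#' Given nominal Ra values of calibration plates and the measured values,
#' reports the maximum absolute deviation, the relative error at the plate
#' where that maximum occurs (percent of its nominal value), and the
#' ordinary-least-squares slope (with intercept) of measured on nominal --
#' the sensitivity of the measurement (1 = ideal).
#'
#' @param nominal,measured equal-length numeric vectors (um), length >= 2.
#' @return list with \code{maxDeviation} (um), \code{relativeErrorAtMax}
#'   (percent) and \code{olsSlope}.
#' @export
#' @examples
#' verificationStats(c(1, 1.6, 3.2, 5.8), c(1.35, 1.92, 3.14, 5.16))
verificationStats <- function(nominal, measured) {
  if (length(nominal) != length(measured))
    stop("'nominal' and 'measured' must have equal length")
  if (length(nominal) < 2L)
    stop("need at least two plates")
  dev <- abs(measured - nominal)
  i <- which.max(dev)
  list(maxDeviation = dev[i],
       relativeErrorAtMax = 100 * dev[i] / nominal[i],
       olsSlope = unname(coef(lm(measured ~ nominal))[2L]))
}
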