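#' @include utils.R
NULL

#' Determine the region of interest from the lateral signal drop
#'
#' The axial window \code{[rbU, rbB]} is a calibrated input (the focus and
#' optical path difference are fixed on the instrument, so the sample always
#' falls in a known depth range). The lateral margins are found from the
#' drop of the interface peak at the sample edge: for each lateral index the
#' within-window maximum intensity is taken (over the other lateral axis and
#' depth), and the margins are the outermost indices whose maximum exceeds
#' \code{edgeDropFraction} times the median maximum over the central 10% of
#' columns. The circular quantification region is centred at the midpoint of
#' the margins with the requested physical radius converted to pixels via
#' the lateral pitch.
#'
#' @param volume an \linkS4class{OCTVolume}.
#' @param axialRange integer \code{c(rbU, rbB)}, inclusive 1-based bounds of
#'   the calibrated depth window.
#' @param circleRadiusMm radius of the circular ROI in millimetres
#'   (default 2.5).
#' @param edgeDropFraction lateral-boundary threshold in (0, 1), default 0.5.
#' @return a \linkS4class{ROISpec}.
#' @export
#' @examples
#' v <- renderVolume(matrix(50, 24, 24), matrix(150, 24, 24),
#'                   AcquisitionGeometry(nX = 24, nY = 24, nZ = 64),
#'                   SignalModel())
#' determineROI(v$volume, c(1, 64), circleRadiusMm = 0.05)
determineROI <- function(volume, axialRange, circleRadiusMm = 2.5,
                         edgeDropFraction = 0.5) {
  stopifnot(is(volume, "OCTVolume"), length(axialRange) == 2L)
  g <- geometry(volume)
  rbU <- as.integer(axialRange[1]); rbB <- as.integer(axialRange[2])
  if (rbU < 1L || rbB > g@nZ || rbU >= rbB)
    stop("axial range must satisfy 1 <= rbU < rbB <= nZ")
  w <- intensity(volume)[, , rbU:rbB, drop = FALSE]

  marginsAlong <- function(profile) {
    n <- length(profile)
    cw <- max(1L, round(0.1 * n))
    lo <- floor((n - cw) / 2) + 1L
    central <- profile[lo:(lo + cw - 1L)]
    thr <- edgeDropFraction * median(central)
    hit <- which(profile > thr)
    if (!length(hit))
      stop("no sample found: no lateral position exceeds the edge-drop threshold")
    c(min(hit), max(hit))
  }

  sx <- apply(w, 1L, max)
  sy <- apply(w, 2L, max)
  mx <- marginsAlong(sx)
  my <- marginsAlong(sy)

  radiusPx <- round(circleRadiusMm * 1000 / g@lateralPitchX)
  ROISpec(rbU = rbU, rbB = rbB,
          rbLx = mx[1], rbRx = mx[2], rbLy = my[1], rbRy = my[2],
          center = c(mean(mx), mean(my)), radius = radiusPx)
}

#' Coarse interface-pair detection in one A-scan
#'
#' Candidate peaks are the strict local maxima of the A-scan restricted to
#' the axial window. The highest peak anchors the pair; the remaining peaks
#' are visited in order of decreasing intensity (ties broken towards the
#' smaller depth) and the first whose axial separation from the anchor is at
#' least \code{t1} completes it. \code{t1} encodes the minimum plausible
#' sample thickness, so near-coincident peaks split off one interface by
#' noise can never form a pair. \code{Pu} is the shallower and \code{Pb} the
#' deeper member. If no qualifying pair exists (including flat or all-zero
#' signals, which have no strict local maxima) the result is invalid rather
#' than an error.
#'
#' @param ascan numeric vector, one depth profile.
#' @param roiAxial integer \code{c(rbU, rbB)}, inclusive.
#' @param t1 minimum peak separation in pixels (>= 1).
#' @return list with elements \code{pu}, \code{pb} (axial indices, \code{NA}
#'   if invalid) and \code{valid}.
#' @export
#' @examples
#' a <- numeric(200); a[100] <- 1000; a[140] <- 800
#' coarseDetect(a, c(1, 200), t1 = 10)
coarseDetect <- function(ascan, roiAxial, t1) {
  t1 <- as.integer(t1)
  stopifnot(t1 >= 1L)
  rbU <- as.integer(roiAxial[1]); rbB <- as.integer(roiAxial[2])
  seg <- ascan[rbU:rbB]
  peaks <- findPeaks(seg) + rbU - 1L
  invalid <- list(pu = NA_integer_, pb = NA_integer_, valid = FALSE)
  if (length(peaks) < 2L) return(invalid)
  ord <- order(-ascan[peaks], peaks)
  peaks <- peaks[ord]
  anchor <- peaks[1L]
  for (p in peaks[-1L]) {
    if (abs(p - anchor) >= t1)
      return(list(pu = min(anchor, p), pb = max(anchor, p), valid = TRUE))
  }
  invalid
}

#' Fine interface refinement in one A-scan
#'
#' The coarse pair can land on a bright sub-surface structure: keratinised
#' stratum corneum produces multiple spikes just below the physical upper
#' surface, and the basement membrane echoes below the lower interface. The
#' fine stage therefore searches the upper half-range
#' \code{[rbU, mid - 1]} (with \code{mid = floor((Pu + Pb) / 2)}) for strict
#' local maxima whose intensity is at least
#' \code{(1 - t2Fraction) * intensity(Pu)} and moves \code{Pu} to the
#' shallowest such point ("the point above the physical position");
#' symmetrically \code{Pb} moves to the shallowest qualifying maximum in
#' \code{[mid, rbB]} relative to \code{intensity(Pb)}. Neither index can
#' move deeper. The pair invariants (\code{rbU <= Pu < Pb <= rbB},
#' \code{Pb - Pu >= t1}) are re-checked; violation invalidates the pair.
#'
#' @param ascan numeric vector, one depth profile.
#' @param pair a list as returned by \code{\link{coarseDetect}}.
#' @param roiAxial integer \code{c(rbU, rbB)}, inclusive.
#' @param t2Fraction intensity tolerance in (0, 1), default 0.2.
#' @param t1 minimum separation re-checked after refinement (default 1).
#' @return a refined pair list (\code{pu}, \code{pb}, \code{valid}).
#' @export
fineRefine <- function(ascan, pair, roiAxial, t2Fraction = 0.2, t1 = 1L) {
  if (!isTRUE(pair$valid)) return(pair)
  rbU <- as.integer(roiAxial[1]); rbB <- as.integer(roiAxial[2])
  pu <- pair$pu; pb <- pair$pb
  mid <- (pu + pb) %/% 2L

  seg <- ascan[rbU:rbB]
  peaks <- findPeaks(seg) + rbU - 1L

  refineOne <- function(incumbent, inRange) {
    cand <- unique(c(incumbent, peaks[inRange(peaks)]))
    keep <- ascan[cand] >= (1 - t2Fraction) * ascan[incumbent]
    min(cand[keep])
  }
  if (mid - 1L >= rbU)
    pu <- refineOne(pu, function(p) p >= rbU & p <= mid - 1L)
  if (mid <= rbB)
    pb <- refineOne(pb, function(p) p >= mid & p <= rbB)

  valid <- pu >= rbU && pu < pb && pb <= rbB && (pb - pu) >= as.integer(t1)
  if (valid) list(pu = pu, pb = pb, valid = TRUE)
  else list(pu = NA_integer_, pb = NA_integer_, valid = FALSE)
}

#' Extract the interface map of a volume
#'
#' Applies \code{\link{coarseDetect}} then \code{\link{fineRefine}} to every
#' A-scan whose lateral position lies strictly inside the circular ROI.
#' Cells outside the circle, or where no qualifying pair exists, are
#' invalid. A summary of valid/invalid counts is emitted as a message; if
#' fewer than half of the in-circle cells are valid a warning is raised (the
#' map is still returned).
#'
#' @param volume an \linkS4class{OCTVolume}.
#' @param roi a \linkS4class{ROISpec}.
#' @param params a \linkS4class{DetectionParams}.
#' @param ... unused.
#' @return an \linkS4class{InterfaceMap}.
#' @export
setMethod("extractSurfaces", signature(volume = "OCTVolume", roi = "ROISpec",
                                       params = "DetectionParams"),
  function(volume, roi, params, ...) {
    g <- geometry(volume)
    if (roi@rbB > g@nZ || roi@rbRx > g@nX || roi@rbRy > g@nY)
      stop("ROI exceeds the volume bounds")
    arr <- intensity(volume)
    axial <- c(roi@rbU, roi@rbB)
    inCircle <- circleMask(g@nX, g@nY, roi@center, roi@radius)

    pu <- matrix(NA_real_, g@nX, g@nY)
    pb <- matrix(NA_real_, g@nX, g@nY)
    valid <- matrix(FALSE, g@nX, g@nY)

    cells <- which(inCircle, arr.ind = TRUE)
    for (k in seq_len(nrow(cells))) {
      ix <- cells[k, 1L]; iy <- cells[k, 2L]
      a <- arr[ix, iy, ]
      pr <- coarseDetect(a, axial, params@t1)
      pr <- fineRefine(a, pr, axial, params@t2Fraction, params@t1)
      if (pr$valid) {
        pu[ix, iy] <- pr$pu
        pb[ix, iy] <- pr$pb
        valid[ix, iy] <- TRUE
      }
    }
    nIn <- sum(inCircle); nOk <- sum(valid)
    message(sprintf("extractSurfaces: %d/%d A-scans valid inside the ROI circle",
                    nOk, nIn))
    if (nIn > 0L && nOk < 0.5 * nIn)
      warning(sprintf("fewer than half of the ROI A-scans yielded a valid pair (%d/%d)",
                      nOk, nIn))
    InterfaceMap(puGrid = pu, pbGrid = pb, validMask = valid)
  })
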