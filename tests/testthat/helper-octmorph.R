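# shared fixtures and independent oracles; everything is generated in code

# production-like geometry on a small grid (default axial pitch 3.506 um)
smallGeom <- function(nX = 64L, nY = 64L, nZ = 256L)
  AcquisitionGeometry(nX = nX, nY = nY, nZ = nZ)

# axially super-sampled geometry for micrometre-scale Ra recovery
fineGeom <- function(nX = 64L, nY = 64L, nZ = 256L, axialPitch = 0.25)
  AcquisitionGeometry(nX = nX, nY = nY, nZ = nZ, axialPitch = axialPitch)

fullFieldROI <- function(g, radius = (min(g@nX, g@nY) - 1) / 2 - 3)
  ROISpec(1, g@nZ, 1, g@nX, 1, g@nY,
          center = c((g@nX + 1) / 2, (g@nY + 1) / 2), radius = radius)

detectMap <- function(volume, roi, params)
  suppressMessages(suppressWarnings(extractSurfaces(volume, roi, params)))

# render a two-layer phantom with a plate or skin upper surface; the lower
# surface is the upper shifted by `gapPx` axial pixels
renderTwoLayer <- function(upper, g, gapPx = 60L, meanDepthFrac = 0.35,
                           model = SignalModel(), ...) {
  depth <- meanDepthFrac * g@nZ * g@axialPitch - (upper - mean(upper))
  renderVolume(depth, depth + gapPx * g@axialPitch, g, model, ...)
}

# render a groove plate at the given nominal Ra, detect the surface and
# measure Ra over the ROI circle (raw heights: plates are already level)
recoverPlateRa <- function(target, snr = Inf, seed = 37L, roiR = 28) {
  g <- fineGeom()
  up <- makePlateSurface("triangle", target, 180, c(64, 64), 9)
  m <- SignalModel(noiseSigma = if (is.finite(snr)) 10000 / snr else 1e-3,
                   spuriousProb = if (is.finite(snr)) 0.05 else 0,
                   seed = seed)
  ph <- renderTwoLayer(up, g, gapPx = 60L, model = m)
  roi <- fullFieldROI(g, radius = roiR)
  ifm <- detectMap(ph$volume, roi, DetectionParams(t1 = 10))
  sh <- surfaceHeights(ifm, g)
  Ra(roughness(sh, roi, flatten = FALSE))
}

# independent coarse-stage oracle: keep the peak set explicitly, remove the
# current best candidate one at a time, stop at the first admissible partner
bruteCoarse <- function(ascan, roiAxial, t1) {
  rbU <- roiAxial[1]; rbB <- roiAxial[2]
  pk <- integer(); i <- rbU + 1L
  while (i <= rbB) {
    if (ascan[i] > ascan[i - 1L]) {
      j <- i
      while (j < rbB && ascan[j + 1L] == ascan[i]) j <- j + 1L
      if (j < rbB && ascan[j + 1L] < ascan[i]) pk <- c(pk, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(pk) < 2L) return(list(pu = NA, pb = NA, valid = FALSE))
  best <- function(set) {
    top <- set[ascan[set] == max(ascan[set])]
    min(top)
  }
  anchor <- best(pk)
  rest <- setdiff(pk, anchor)
  while (length(rest)) {
    p <- best(rest)
    if (abs(p - anchor) >= t1)
      return(list(pu = min(anchor, p), pb = max(anchor, p), valid = TRUE))
    rest <- setdiff(rest, p)
  }
  list(pu = NA, pb = NA, valid = FALSE)
}

# naive point-wise roughness oracle (explicit loops, no shared code)
directRoughness <- function(z, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(z)
  vals <- numeric(sum(mask)); k <- 0L
  for (i in seq_len(nrow(z))) for (j in seq_len(ncol(z)))
    if (mask[i, j]) { k <- k + 1L; vals[k] <- z[i, j] }
  zbar <- sum(vals) / length(vals)
  sAbs <- 0; sSq <- 0; sCu <- 0
  for (v in vals) {
    d <- v - zbar
    sAbs <- sAbs + abs(d); sSq <- sSq + d^2; sCu <- sCu + d^3
  }
  pn <- length(vals)
  rq <- sqrt(sSq / pn)
  list(ra = sAbs / pn, rq = rq,
       rsk = if (rq > 0) (sCu / pn) / rq^3 else NA_real_, pn = pn)
}

# wrap a height grid in a SurfaceHeights via a synthetic InterfaceMap
heightsFromGrid <- function(z, g, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(z), ncol(z))
  pu <- 1 - z / g@axialPitch   # invert Z = -(Pu - 1) * delta
  ifm <- InterfaceMap(puGrid = pu, pbGrid = pu + 40, validMask = valid)
  surfaceHeights(ifm, g)
}
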