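#' @include volume-io.R phantom.R stats.R
NULL

#' Run the full detection + quantification pipeline
#'
#' Reads a volume, determines the ROI, extracts the interface map, computes
#' thickness, flattens the upper surface (unless disabled) and computes
#' roughness; writes the maps, a machine-readable \code{results.json} and a
#' human-readable \code{report.txt} under \code{config$outDir}. The
#' effective configuration is echoed into the results for provenance. Any
#' stage failure aborts with the stage name in the error.
#'
#' @param config a list (or path to a JSON file holding one) with entries:
#'   \code{input}, \code{meta} (paths), \code{rbu}, \code{rbb} (axial
#'   window), \code{t1} (default 10), \code{t2} (default 0.2),
#'   \code{edgeDrop} (default 0.5), \code{roiRadiusMm} (default 2.5),
#'   \code{flatten} (default TRUE), \code{outDir}.
#' @return invisibly, the results list.
#' @export
runPipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(t1 = 10L, t2 = 0.2, edgeDrop = 0.5, roiRadiusMm = 2.5,
                   flatten = TRUE)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  for (k in c("input", "meta", "rbu", "rbb", "outDir"))
    if (is.null(config[[k]])) stop("config is missing required entry '", k, "'")
  for (k in c("input", "meta"))
    if (!file.exists(config[[k]]))
      stop("stage read: input path does not exist: ", config[[k]])

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  vol <- stage("read", readVolume(config$input, config$meta))
  roi <- stage("roi", determineROI(vol, c(config$rbu, config$rbb),
                                   circleRadiusMm = config$roiRadiusMm,
                                   edgeDropFraction = config$edgeDrop))
  params <- DetectionParams(t1 = config$t1, t2Fraction = config$t2,
                            edgeDropFraction = config$edgeDrop)
  ifm <- stage("detect", extractSurfaces(vol, roi, params))
  th <- stage("thickness", thicknessMap(ifm, geometry(vol)))
  sh <- stage("heights", surfaceHeights(ifm, geometry(vol)))
  if (isTRUE(config$flatten))
    sh <- stage("flatten", fitReferenceSurface(sh))
  rr <- stage("roughness", roughness(sh, roi, flatten = isTRUE(config$flatten)))

  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stage("write", writeMaps(ifm, th, config$outDir))

  results <- list(
    mean_Th = meanThickness(th), sd_Th = sdThickness(th),
    Ra = Ra(rr), Rq = Rq(rr), Rsk = Rsk(rr), PN = rr@pn,
    valid_fraction = sum(validMask(ifm)) /
      sum(circleMask(dim(ifm)[1], dim(ifm)[2], roi@center, roi@radius)),
    fit_coeffs = if (length(fitCoeffs(sh))) as.list(fitCoeffs(sh)) else NULL,
    config = config[c("input", "meta", "rbu", "rbb", "t1", "t2", "edgeDrop",
                      "roiRadiusMm", "flatten", "outDir")])
  jsonlite::write_json(results, file.path(config$outDir, "results.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  writeLines(c(
    "octmorph pipeline report",
    sprintf("input: %s", config$input),
    sprintf("valid A-scans in ROI: %.1f%%", 100 * results$valid_fraction),
    sprintf("mean thickness: %.2f um (sd %.2f)", results$mean_Th, results$sd_Th),
    sprintf("Ra = %.4g um, Rq = %.4g um, Rsk = %s",
            results$Ra, results$Rq,
            if (rr@rskDefined) sprintf("%.4g", results$Rsk) else "undefined"),
    sprintf("PN = %d, flattened: %s", results$PN, isTRUE(config$flatten))),
    file.path(config$outDir, "report.txt"))
  invisible(results)
}

#' Simulate a phantom data set on disk
#'
#' Convenience wrapper used by the command line: generates a plate-like or
#' skin-like phantom, renders it, and writes the volume, metadata sidecar
#' and ground-truth JSON under \code{outDir}.
#'
#' @param preset \code{"plate"}, \code{"skin"} or \code{"abnormal"} (a
#'   rough, strongly skewed skin surface emulating a failed culture).
#' @param targetRa nominal Ra in um.
#' @param seed RNG seed.
#' @param snr peak signal-to-noise ratio (upper peak amplitude over the
#'   noise-floor sigma); \code{Inf} renders noise-free.
#' @param outDir output directory.
#' @param gridDim,nZ phantom grid (defaults 64 x 64 x 256).
#' @return invisibly, a list with the written paths and the truth object.
#' @export
simulatePhantom <- function(preset = c("plate", "skin", "abnormal"),
                            targetRa = 1.6, seed = 1L, snr = Inf,
                            outDir, gridDim = c(64L, 64L), nZ = 256L) {
  preset <- match.arg(preset)
  # plate scans super-sample the axial axis (calibration-style acquisition)
  # so that micrometre-scale Ra is not dominated by height quantisation;
  # skin presets keep the production pitch
  axialPitch <- if (preset == "plate") 0.25 else 3590 / 1024
  g <- AcquisitionGeometry(nX = gridDim[1], nY = gridDim[2], nZ = nZ,
                           axialPitch = axialPitch)
  upper <- switch(preset,
    plate = makePlateSurface("triangle", targetRa, groovePitchUm = 20 * g@lateralPitchX,
                             gridDim = gridDim, lateralPitch = g@lateralPitchX),
    skin = makeSkinSurface(seed, correlationLengthUm = 4 * g@lateralPitchX,
                           targetRa = targetRa, skewStrength = 0.8,
                           gridDim = gridDim, lateralPitch = g@lateralPitchX),
    abnormal = makeSkinSurface(seed, correlationLengthUm = 8 * g@lateralPitchX,
                               targetRa = max(targetRa, 8), skewStrength = 1.5,
                               gridDim = gridDim, lateralPitch = g@lateralPitchX))
  depthMid <- 0.35 * nZ * g@axialPitch
  upperDepth <- depthMid - (upper - mean(upper))
  lowerDepth <- upperDepth + 40 * g@axialPitch
  noiseSigma <- if (is.finite(snr)) 10000 / snr else 1e-3
  model <- SignalModel(noiseSigma = noiseSigma, seed = seed)
  ph <- renderVolume(upperDepth, lowerDepth, g, model, nominalRa = targetRa)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  volPath <- file.path(outDir, "volume.raw")
  writeVolume(ph$volume, volPath)
  truthPath <- file.path(outDir, "truth.json")
  jsonlite::write_json(
    list(preset = preset, nominal_Ra = targetRa, seed = seed, snr = snr,
         upper_index = ph$truth@upperIndex, lower_index = ph$truth@lowerIndex,
         upper_depth_um = ph$truth@upperDepthUm,
         lower_depth_um = ph$truth@lowerDepthUm),
    truthPath, digits = NA)
  invisible(list(volume = volPath,
                 meta = file.path(outDir, "volume.json"),
                 truth = truthPath, phantom = ph))
}

#' Command-line entry point
#'
#' Dispatches the subcommands \code{simulate}, \code{detect},
#' \code{quantify}, \code{verify}, \code{compare} and \code{run}; see
#' \code{inst/scripts/octmorph} for the launcher. Each subcommand is a thin
#' wrapper over the exported functions.
#'
#' @param args character vector, defaults to \code{commandArgs(TRUE)}.
#' @return exit status (0 on success), invisibly.
#' @export
octmorphCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: octmorph <simulate|detect|quantify|verify|compare|run> [options]",
    "  simulate --preset P --target-ra X --seed N --snr X --out-dir D",
    "  detect   --input F --meta F --rbu N --rbb N [--t1 N --t2 X",
    "           --edge-drop X --roi-radius-mm X] --out-dir D",
    "  quantify --maps D --meta F [--no-flatten --roi-radius-mm X] --out F",
    "  verify   --nominal a,b,... --measured a,b,... --out F",
    "  compare  --table F.csv --factor time|batch --parameter P --out F",
    "  run      --config F.json", sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1L]
  opts <- .parseArgs(args[-1L])
  get <- function(k, default = NULL) {
    v <- opts[[k]]
    if (is.null(v)) default else v
  }
  num <- function(k, default = NULL) {
    v <- get(k); if (is.null(v)) default else as.numeric(v)
  }

  status <- tryCatch({
    switch(cmd,
      simulate = {
        simulatePhantom(preset = get("preset", "plate"),
                        targetRa = num("target-ra", 1.6),
                        seed = as.integer(num("seed", 1)),
                        snr = num("snr", Inf),
                        outDir = get("out-dir", "."))
      },
      detect = {
        vol <- readVolume(get("input"), get("meta"))
        roi <- determineROI(vol, c(num("rbu"), num("rbb")),
                            circleRadiusMm = num("roi-radius-mm", 2.5),
                            edgeDropFraction = num("edge-drop", 0.5))
        params <- DetectionParams(t1 = as.integer(num("t1", 10)),
                                  t2Fraction = num("t2", 0.2),
                                  edgeDropFraction = num("edge-drop", 0.5))
        ifm <- extractSurfaces(vol, roi, params)
        th <- thicknessMap(ifm, geometry(vol))
        outDir <- get("out-dir", ".")
        writeMaps(ifm, th, outDir)
        jsonlite::write_json(
          list(valid = sum(validMask(ifm)), cells = prod(dim(ifm)),
               roi = list(rbU = roi@rbU, rbB = roi@rbB,
                          rbLx = roi@rbLx, rbRx = roi@rbRx,
                          rbLy = roi@rbLy, rbRy = roi@rbRy,
                          center = roi@center, radius = roi@radius)),
          file.path(outDir, "detection.json"), auto_unbox = TRUE, digits = NA)
      },
      quantify = {
        maps <- readMaps(get("maps"))
        meta <- jsonlite::read_json(get("meta"), simplifyVector = TRUE)
        g <- .geomFromList(meta)
        flatten <- is.null(opts[["no-flatten"]])
        sh <- surfaceHeights(maps$interfaces, g)
        if (flatten) sh <- fitReferenceSurface(sh)
        d <- dim(validMask(maps$interfaces))
        rpx <- round(num("roi-radius-mm", 2.5) * 1000 / g@lateralPitchX)
        roi <- ROISpec(1, g@nZ, 1, d[1], 1, d[2],
                       center = (d + 1) / 2, radius = min(rpx, (min(d) - 1) / 2))
        rr <- roughness(sh, roi, flatten = flatten)
        th <- thicknessMap(maps$interfaces, g)
        jsonlite::write_json(
          list(mean_Th = meanThickness(th), sd_Th = sdThickness(th),
               Ra = Ra(rr), Rq = Rq(rr), Rsk = Rsk(rr), PN = rr@pn,
               fit_coeffs = as.list(fitCoeffs(sh))),
          get("out", "results.json"), auto_unbox = TRUE, digits = NA)
      },
      verify = {
        vs <- verificationStats(
          as.numeric(strsplit(get("nominal"), ",")[[1L]]),
          as.numeric(strsplit(get("measured"), ",")[[1L]]))
        jsonlite::write_json(vs, get("out", "verify.json"),
                             auto_unbox = TRUE, digits = NA)
      },
      compare = {
        tab <- read.csv(get("table"))
        res <- anovaF(tab, get("factor", "time"), get("parameter"))
        jsonlite::write_json(res, get("out", "anova.json"),
                             auto_unbox = TRUE, digits = NA)
      },
      run = {
        runPipeline(get("config"))
      },
      { cat(usage, "\n"); return(invisible(1L)) })
    0L
  }, error = function(e) {
    message("octmorph ", cmd, " failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

# --key value and --flag parsing
.parseArgs <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      out[[key]] <- args[i + 1L]; i <- i + 2L
    } else {
      out[[key]] <- TRUE; i <- i + 1L
    }
  }
  out
}
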