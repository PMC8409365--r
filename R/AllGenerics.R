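#' @include octmorph-package.R
NULL

#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @export
setGeneric("axialPitch", function(x) standardGeneric("axialPitch"))

#' @export
setGeneric("lateralPitch", function(x) standardGeneric("lateralPitch"))

#' @export
setGeneric("refractiveIndex", function(x) standardGeneric("refractiveIndex"))

#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @export
setGeneric("upperIndex", function(x) standardGeneric("upperIndex"))

#' @export
setGeneric("lowerIndex", function(x) standardGeneric("lowerIndex"))

#' @export
setGeneric("thicknessGrid", function(x) standardGeneric("thicknessGrid"))

#' @export
setGeneric("meanThickness", function(x) standardGeneric("meanThickness"))

#' @export
setGeneric("sdThickness", function(x) standardGeneric("sdThickness"))

#' @export
setGeneric("heights", function(x) standardGeneric("heights"))

#' @export
setGeneric("fitCoeffs", function(x) standardGeneric("fitCoeffs"))

#' @export
setGeneric("Ra", function(x) standardGeneric("Ra"))

#' @export
setGeneric("Rq", function(x) standardGeneric("Rq"))

#' @export
setGeneric("Rsk", function(x) standardGeneric("Rsk"))

#' @export
setGeneric("extractSurfaces",
           function(volume, roi, params, ...) standardGeneric("extractSurfaces"))

#' @export
setGeneric("thicknessMap",
           function(interfaces, geometry, ...) standardGeneric("thicknessMap"))

#' @export
setGeneric("surfaceHeights",
           function(interfaces, geometry, ...) standardGeneric("surfaceHeights"))

#' @export
setGeneric("fitReferenceSurface",
           function(heights, ...) standardGeneric("fitReferenceSurface"))

#' @export
setGeneric("roughness",
           function(heights, roi, flatten = TRUE, ...) standardGeneric("roughness"))
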