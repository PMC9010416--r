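## Accessor generics and show methods.

#' Pixel values of a raster object
#' @param x a \linkS4class{ScalarImage} or \linkS4class{BinaryMask}.
#' @return numeric matrix (ny x nx).
#' @export
setGeneric("pixelValues", function(x) standardGeneric("pixelValues"))

#' @rdname pixelValues
#' @export
setMethod("pixelValues", "ScalarImage", function(x) x@values)

#' Pixel / node spacing in micrometres
#' @param x an object carrying a \linkS4class{Grid2D}.
#' @return numeric scalar, micrometres per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "Grid2D", function(x) x@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ScalarImage", function(x) x@grid@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "VectorField2D", function(x) x@grid@pixelSize)

#' Grid geometry of a raster or field
#' @param x an object carrying a \linkS4class{Grid2D}.
#' @return the \linkS4class{Grid2D}.
#' @export
setGeneric("gridGeometry", function(x) standardGeneric("gridGeometry"))

#' @rdname gridGeometry
#' @export
setMethod("gridGeometry", "ScalarImage", function(x) x@grid)
#' @rdname gridGeometry
#' @export
setMethod("gridGeometry", "VectorField2D", function(x) x@grid)

#' Field components
#'
#' \code{compX}/\code{compY} return the x/y component matrices of a
#' \linkS4class{VectorField2D}; \code{fieldUnits} its units;
#' \code{fieldMagnitude} the per-node Euclidean norm.
#'
#' @param x a \linkS4class{VectorField2D}.
#' @return matrix (components, magnitude) or character (units).
#' @export
setGeneric("compX", function(x) standardGeneric("compX"))
#' @rdname compX
#' @export
setGeneric("compY", function(x) standardGeneric("compY"))
#' @rdname compX
#' @export
setGeneric("fieldUnits", function(x) standardGeneric("fieldUnits"))
#' @rdname compX
#' @export
setGeneric("fieldMagnitude", function(x) standardGeneric("fieldMagnitude"))

#' @rdname compX
#' @export
setMethod("compX", "VectorField2D", function(x) x@compX)
#' @rdname compX
#' @export
setMethod("compY", "VectorField2D", function(x) x@compY)
#' @rdname compX
#' @export
setMethod("fieldUnits", "VectorField2D", function(x) x@units)
#' @rdname compX
#' @export
setMethod("fieldMagnitude", "VectorField2D",
          function(x) sqrt(x@compX^2 + x@compY^2))

setMethod("show", "Grid2D", function(object) {
  cat(sprintf("Grid2D: %d x %d px, %.4g um/px\n",
              object@nx, object@ny, object@pixelSize))
})

setMethod("show", "ScalarImage", function(object) {
  cat(sprintf("%s: %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              class(object), object@grid@nx, object@grid@ny,
              object@grid@pixelSize, min(object@values),
              max(object@values)))
})

setMethod("show", "VectorField2D", function(object) {
  m <- sqrt(object@compX^2 + object@compY^2)
  cat(sprintf(
    "VectorField2D [%s]: %d x %d nodes, %.4g um spacing, mean |v| = %.4g\n",
    object@units, object@grid@nx, object@grid@ny, object@grid@pixelSize,
    mean(m)))
})

setMethod("show", "ElasticSubstrate", function(object) {
  cat(sprintf("ElasticSubstrate: E = %.4g Pa, nu = %.3g\n",
              object@E, object@nu))
})

setMethod("show", "BilayerSubstrate", function(object) {
  cat(sprintf(
    "BilayerSubstrate: Em = %.4g Pa, Ep = %.4g Pa (ratio %.3g), h = %.3g um\n",
    object@Em, object@Ep, object@Ep / object@Em, object@h))
})

setMethod("show", "StressSummary", function(object) {
  cat(sprintf(
    paste0("StressSummary: mean traction %.3g Pa, fP = %.3g Pa, ",
           "phiS = %.1f deg, isotropy = %s\n"),
    object@meanTraction, object@fP, object@phiS,
    ifelse(is.na(object@isotropy), "undefined",
           sprintf("%.3g", object@isotropy))))
})

setMethod("show", "WrinkleSummary", function(object) {
  cat(sprintf(
    "WrinkleSummary: length %d px (%.3g um), phiW = %s, %d region(s), %s\n",
    as.integer(object@lengthPx), object@lengthUm,
    ifelse(is.na(object@phiW), "undefined", sprintf("%.1f deg", object@phiW)),
    object@nComponents, object@topologyLabel))
})

setMethod("show", "LCurve", function(object) {
  cat(sprintf("LCurve: %d lambdas in [%.3g, %.3g], corner at lambda = %.3g\n",
              length(object@lambdas), min(object@lambdas),
              max(object@lambdas), object@lambdas[object@chosenIndex]))
})

setMethod("show", "TrainedTranslator", function(object) {
  cat(sprintf(
    "TrainedTranslator (%s): %d x %d input, %d epoch(s) trained\n",
    object@kind, object@config@imageSize, object@config@imageSize,
    nrow(object@history)))
})
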