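## Force <-> grayscale codec and prediction error metrics.

#' Encode a force component as a grayscale intensity
#'
#' The arctangent codec \eqn{I(f_d) = a \arctan(f_d / b) + I_{mid}}: a
#' strictly increasing, odd mapping about \eqn{(0, I_{mid})} that
#' compresses arbitrarily large forces into a bounded intensity range.
#' The quantized variant rounds half-up and clamps to [0, 255].
#'
#' @param fd force component(s), Pa (vector or matrix).
#' @param params a \linkS4class{CodecParams}.
#' @param quantize if TRUE, round to 8-bit integers.
#' @return Intensities, same shape as \code{fd}.
#' @export
encodeForce <- function(fd, params = CodecParams(), quantize = FALSE) {
  stopifnot(is(params, "CodecParams"))
  I <- params@a * atan(fd / params@b) + params@Imid
  if (quantize) I <- pmin(pmax(floor(I + 0.5), 0), 255)
  I
}

#' Decode a grayscale intensity back to a force component
#'
#' Exact inverse of the unquantized [encodeForce()]:
#' \eqn{f_d = b \tan((I - I_{mid}) / a)}. Intensities at or beyond the
#' arctangent asymptotes \eqn{I_{mid} \pm a\pi/2} cannot be decoded.
#'
#' @param I intensities (vector or matrix).
#' @param params a \linkS4class{CodecParams}.
#' @return Force components in Pa.
#' @export
decodeForce <- function(I, params = CodecParams()) {
  stopifnot(is(params, "CodecParams"))
  lo <- params@Imid - params@a * pi / 2
  hi <- params@Imid + params@a * pi / 2
  if (any(I <= lo) || any(I >= hi))
    wfmStop(sprintf(
      "intensity outside the decodable range (%.6g, %.6g): codec saturated",
      lo, hi))
  params@b * tan((I - params@Imid) / params@a)
}

#' Single-axis training pairs by 90-degree rotation
#'
#' The translator predicts one force component at a time. A pair (input
#' image, traction field) therefore yields two training pairs: the image
#' with the encoded x-component map, and the 90-degree-rotated image with
#' the encoded x-component of the co-rotated field (which carries the
#' original y-component information).
#'
#' @param image a square \linkS4class{ScalarImage}.
#' @param traction a co-registered square \linkS4class{VectorField2D}.
#' @param params codec constants for the force maps.
#' @return List of two pairs, each with \code{image} (ScalarImage) and
#'   \code{forceMap} (ScalarImage of encoded intensities, on the traction
#'   grid).
#' @export
axisSplitRotate <- function(image, traction, params = CodecParams()) {
  stopifnot(is(image, "ScalarImage"), is(traction, "VectorField2D"))
  if (image@grid@nx != image@grid@ny || traction@grid@nx != traction@grid@ny)
    wfmStop("axisSplitRotate requires square image and traction grids")
  tps <- traction@grid@pixelSize
  rotImg <- ScalarImage(rotate90Matrix(image@values),
                        pixelSize = image@grid@pixelSize)
  rotTr <- rotate90Field(traction)
  list(
    list(image = image,
         forceMap = ScalarImage(encodeForce(traction@compX, params),
                                pixelSize = tps)),
    list(image = rotImg,
         forceMap = ScalarImage(encodeForce(rotTr@compX, params),
                                pixelSize = tps))
  )
}

#' Weighted force-magnitude error
#'
#' \deqn{\varepsilon_f = \frac{1}{M} \sum_m
#'   \frac{|f_m^{pred} - f_m^{true}|}{f_m^{true}} \omega_m,\qquad
#'   \omega_m = f_m^{true} / \bar f}
#' The weight cancels the per-node division exactly, so the implementation
#' uses the reduced, singularity-free form
#' \eqn{\sum_m |f_m^{pred} - f_m^{true}| / (M \bar f)}; zero-magnitude
#' true nodes contribute their absolute deviation. Scale-free: multiplying
#' both fields by a positive constant leaves the error unchanged.
#'
#' @param pred,true \linkS4class{VectorField2D}s on the same grid;
#'   per-node magnitudes are compared.
#' @return Dimensionless error (fraction), or NA when the true field is
#'   identically zero.
#' @export
forceMagnitudeError <- function(pred, true) {
  stopifnot(is(pred, "VectorField2D"), is(true, "VectorField2D"))
  checkSameGrid(pred, true, "prediction and ground truth")
  mp <- fieldMagnitude(pred); mt <- fieldMagnitude(true)
  fbar <- mean(mt)
  if (fbar == 0) return(NA_real_)
  sum(abs(mp - mt)) / (length(mt) * fbar)
}

#' Weighted force-direction error
#'
#' \deqn{\varepsilon_\theta = \frac{1}{M} \sum_m
#'   |\theta_m^{pred} - \theta_m^{true}| \, \omega_m}
#' with \eqn{\theta} the full-quadrant force direction and
#' \eqn{\omega_m = f_m^{true}/\bar f}. Differences are wrapped into
#' [0, 180] degrees by default; \code{wrap = FALSE} uses the raw
#' principal-value arctangent difference instead.
#'
#' @param pred,true \linkS4class{VectorField2D}s on the same grid.
#' @param wrap wrap angle differences to [0, 180] (default TRUE).
#' @return Error in degrees, or NA when the true field is identically
#'   zero.
#' @export
forceAngleError <- function(pred, true, wrap = TRUE) {
  stopifnot(is(pred, "VectorField2D"), is(true, "VectorField2D"))
  checkSameGrid(pred, true, "prediction and ground truth")
  thp <- atan2(pred@compY, pred@compX) * 180 / pi
  tht <- atan2(true@compY, true@compX) * 180 / pi
  d <- abs(thp - tht)
  if (wrap) {
    d <- d %% 360
    d <- pmin(d, 360 - d)
  }
  mt <- fieldMagnitude(true)
  fbar <- mean(mt)
  if (fbar == 0) return(NA_real_)
  sum(d * mt / fbar) / length(mt)
}

#' Pooled component correlation
#'
#' Pearson correlation between the pooled x- and y-components of the
#' predicted and true fields (all nodes, both components in one vector).
#'
#' @param pred,true \linkS4class{VectorField2D}s on the same grid with at
#'   least 3 nodes.
#' @return Correlation coefficient in [-1, 1], or NA when either pooled
#'   vector has zero variance.
#' @export
correlationR <- function(pred, true) {
  stopifnot(is(pred, "VectorField2D"), is(true, "VectorField2D"))
  checkSameGrid(pred, true, "prediction and ground truth")
  if (length(pred@compX) < 3) wfmStop("correlation needs >= 3 nodes")
  p <- c(pred@compX, pred@compY)
  t <- c(true@compX, true@compY)
  if (stats::sd(p) == 0 || stats::sd(t) == 0) return(NA_real_)
  stats::cor(p, t)
}

#' Full error report for a predicted traction field
#'
#' @param pred,true \linkS4class{VectorField2D}s on the same grid.
#' @return List with \code{epsF} (fraction), \code{epsTheta} (degrees) and
#'   \code{R}.
#' @export
evaluatePrediction <- function(pred, true) {
  list(epsF = forceMagnitudeError(pred, true),
       epsTheta = forceAngleError(pred, true),
       R = correlationR(pred, true))
}
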