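#' @import methods
NULL

## ---------------------------------------------------------------------------
## Grid and raster containers
## ---------------------------------------------------------------------------

#' Regular pixel grid
#'
#' Geometry shared by all raster and field containers: a regular grid of
#' square pixels. Grid nodes sit at pixel centers; node (row 1, col 1) is the
#' top-left pixel center at physical (0, 0) micrometres. Arrays are stored in
#' image convention (row index increasing downward).
#'
#' @slot nx integer, number of columns (>= 2).
#' @slot ny integer, number of rows (>= 2).
#' @slot pixelSize numeric, micrometres per pixel (> 0, square pixels).
#' @exportClass Grid2D
setClass("Grid2D",
  representation(nx = "integer", ny = "integer", pixelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@nx) != 1L || object@nx < 2L)
      msg <- c(msg, "nx must be a single integer >= 2")
    if (length(object@ny) != 1L || object@ny < 2L)
      msg <- c(msg, "ny must be a single integer >= 2")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' @param nx,ny grid dimensions (columns, rows).
#' @param pixelSize micrometres per pixel.
#' @return A \code{Grid2D} object.
#' @rdname Grid2D-class
#' @export
Grid2D <- function(nx, ny, pixelSize = 1) {
  new("Grid2D", nx = as.integer(nx), ny = as.integer(ny),
      pixelSize = as.numeric(pixelSize))
}

#' Grayscale raster image
#'
#' A single-channel raster (micrograph, encoded force image, ...) on a
#' \linkS4class{Grid2D}. Values are stored as a numeric \code{ny x nx}
#' matrix, rows running top to bottom.
#'
#' @slot grid a \linkS4class{Grid2D}.
#' @slot values numeric matrix of intensities, dim \code{c(ny, nx)}.
#' @exportClass ScalarImage
setClass("ScalarImage",
  representation(grid = "Grid2D", values = "matrix"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@values)
    if (!identical(d, c(object@grid@ny, object@grid@nx)))
      msg <- c(msg, sprintf("values must be a %d x %d matrix (ny x nx)",
                            object@grid@ny, object@grid@nx))
    if (!all(is.finite(object@values)))
      msg <- c(msg, "intensities must all be finite")
    if (is.null(msg)) TRUE else msg
  })

#' @param values numeric matrix (ny x nx) of intensities.
#' @param pixelSize micrometres per pixel.
#' @return A \code{ScalarImage}.
#' @rdname ScalarImage-class
#' @export
ScalarImage <- function(values, pixelSize = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ScalarImage", grid = Grid2D(ncol(values), nrow(values), pixelSize),
      values = values)
}

#' Binary raster mask
#'
#' A \linkS4class{ScalarImage} restricted to values in \{0, 1\}; used for
#' extracted wrinkle masks and cell outlines.
#'
#' @exportClass BinaryMask
setClass("BinaryMask", contains = "ScalarImage",
  validity = function(object) {
    if (!all(object@values %in% c(0, 1)))
      "mask values must all be 0 or 1"
    else TRUE
  })

#' @param values numeric/logical matrix; coerced to 0/1.
#' @param pixelSize micrometres per pixel.
#' @return A \code{BinaryMask}.
#' @rdname BinaryMask-class
#' @export
BinaryMask <- function(values, pixelSize = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  values[] <- as.numeric(values != 0)
  new("BinaryMask", grid = Grid2D(ncol(values), nrow(values), pixelSize),
      values = values)
}

#' Two-component vector field on a regular grid
#'
#' The central currency of the pipeline: a displacement field (micrometres)
#' or traction field (Pascal) sampled on a regular grid. Components are
#' stored in image convention (row = y index increasing downward); angles
#' derived from fields are reported in a y-up physical frame by the
#' angle-producing operations.
#'
#' @slot grid a \linkS4class{Grid2D}.
#' @slot compX,compY numeric matrices, dim \code{c(ny, nx)}.
#' @slot units one of \code{"um"} (displacement) or \code{"Pa"} (traction).
#' @exportClass VectorField2D
setClass("VectorField2D",
  representation(grid = "Grid2D", compX = "matrix", compY = "matrix",
                 units = "character"),
  validity = function(object) {
    msg <- NULL
    d <- c(object@grid@ny, object@grid@nx)
    if (!identical(dim(object@compX), d) || !identical(dim(object@compY), d))
      msg <- c(msg, "compX and compY must both be ny x nx matrices")
    if (any(is.infinite(object@compX)) || any(is.infinite(object@compY)))
      msg <- c(msg, "field components must not be infinite (NaN marks invalid nodes)")
    if (length(object@units) != 1L || !object@units %in% c("um", "Pa"))
      msg <- c(msg, "units must be \"um\" or \"Pa\"")
    if (is.null(msg)) TRUE else msg
  })

#' @param compX,compY numeric matrices (ny x nx).
#' @param pixelSize grid spacing in micrometres.
#' @param units \code{"um"} or \code{"Pa"}.
#' @return A \code{VectorField2D}.
#' @rdname VectorField2D-class
#' @export
VectorField2D <- function(compX, compY, pixelSize = 1, units = c("Pa", "um")) {
  units <- match.arg(units)
  compX <- as.matrix(compX); compY <- as.matrix(compY)
  storage.mode(compX) <- "double"; storage.mode(compY) <- "double"
  new("VectorField2D", grid = Grid2D(ncol(compX), nrow(compX), pixelSize),
      compX = compX, compY = compY, units = units)
}

## ---------------------------------------------------------------------------
## Substrates
## ---------------------------------------------------------------------------

#' Linear elastic half-space substrate
#'
#' Material parameters of the gel treated as an isotropic, linearly elastic
#' half-space. Defaults are a soft silicone: Young's modulus 5400 Pa and
#' Poisson ratio 0.5 (incompressible).
#'
#' @slot E Young's modulus, Pa (> 0).
#' @slot nu Poisson's ratio in [0, 0.5].
#' @exportClass ElasticSubstrate
setClass("ElasticSubstrate",
  representation(E = "numeric", nu = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.finite(object@E) || object@E <= 0)
      msg <- c(msg, "E must be a positive number")
    if (!is.finite(object@nu) || object@nu < 0 || object@nu > 0.5)
      msg <- c(msg, "nu must lie in [0, 0.5]")
    if (is.null(msg)) TRUE else msg
  })

#' @param E Young's modulus, Pa.
#' @param nu Poisson's ratio.
#' @return An \code{ElasticSubstrate}.
#' @rdname ElasticSubstrate-class
#' @export
ElasticSubstrate <- function(E = 5400, nu = 0.5) {
  new("ElasticSubstrate", E = as.numeric(E), nu = as.numeric(nu))
}

#' Bilayer (stiff skin on elastomer) substrate
#'
#' Parameters of the buckling model: a soft elastomer of modulus \code{Em}
#' carrying a thin, stiff oxidized surface layer of modulus \code{Ep} and
#' thickness \code{h}; both layers share one Poisson ratio.
#'
#' @slot Em elastomer Young's modulus, Pa.
#' @slot Ep skin Young's modulus, Pa (> Em).
#' @slot h skin thickness, micrometres.
#' @slot nu shared Poisson's ratio.
#' @exportClass BilayerSubstrate
setClass("BilayerSubstrate",
  representation(Em = "numeric", Ep = "numeric", h = "numeric",
                 nu = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@Em > 0)) msg <- c(msg, "Em must be positive")
    if (!(object@Ep > object@Em))
      msg <- c(msg, "Ep must exceed Em (stiff skin on soft elastomer)")
    if (!(object@h > 0)) msg <- c(msg, "h must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' @param Em,Ep elastomer / skin Young's moduli, Pa.
#' @param h skin thickness, micrometres.
#' @param nu shared Poisson's ratio.
#' @return A \code{BilayerSubstrate}.
#' @rdname BilayerSubstrate-class
#' @export
BilayerSubstrate <- function(Em = 5400, Ep = 300 * 5400, h = 0.1, nu = 0.5) {
  new("BilayerSubstrate", Em = as.numeric(Em), Ep = as.numeric(Ep),
      h = as.numeric(h), nu = as.numeric(nu))
}

## ---------------------------------------------------------------------------
## Inverse-problem configuration and diagnostics
## ---------------------------------------------------------------------------

#' Tikhonov regularization settings
#'
#' @slot lambdaReg regularization parameter (>= 0); the per-wavevector solve
#'   applies its square, as is conventional for Tikhonov damping.
#' @slot mode boundary handling, \code{"periodic"} (cyclic convolution,
#'   exact inverse pair with the forward model) or \code{"padded"}
#'   (zero-padding x2 each axis, default for experiment-like data).
#' @slot lambdaGrid strictly increasing positive values scanned by the
#'   L-curve criterion.
#' @exportClass TikhonovConfig
setClass("TikhonovConfig",
  representation(lambdaReg = "numeric", mode = "character",
                 lambdaGrid = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.finite(object@lambdaReg) || object@lambdaReg < 0)
      msg <- c(msg, "lambdaReg must be >= 0")
    if (!object@mode %in% c("periodic", "padded"))
      msg <- c(msg, "mode must be \"periodic\" or \"padded\"")
    if (length(object@lambdaGrid) &&
        (any(object@lambdaGrid <= 0) || is.unsorted(object@lambdaGrid,
                                                    strictly = TRUE)))
      msg <- c(msg, "lambdaGrid must be strictly increasing and positive")
    if (is.null(msg)) TRUE else msg
  })

#' @param lambdaReg regularization parameter.
#' @param mode \code{"periodic"} or \code{"padded"}.
#' @param lambdaGrid values for the L-curve scan (may be empty).
#' @return A \code{TikhonovConfig}.
#' @rdname TikhonovConfig-class
#' @export
TikhonovConfig <- function(lambdaReg = 0, mode = c("padded", "periodic"),
                           lambdaGrid = numeric(0)) {
  mode <- match.arg(mode)
  new("TikhonovConfig", lambdaReg = as.numeric(lambdaReg), mode = mode,
      lambdaGrid = as.numeric(lambdaGrid))
}

#' L-curve of a Tikhonov scan
#'
#' Residual norm and solution norm per scanned regularization parameter,
#' with the index chosen by the corner criterion.
#'
#' @slot lambdas scanned parameters.
#' @slot residualNorms \eqn{\|G t - u\|} per lambda (non-decreasing).
#' @slot solutionNorms \eqn{\|t\|} per lambda (non-increasing).
#' @slot chosenIndex index of the selected corner.
#' @exportClass LCurve
setClass("LCurve",
  representation(lambdas = "numeric", residualNorms = "numeric",
                 solutionNorms = "numeric", chosenIndex = "integer"),
  validity = function(object) {
    n <- length(object@lambdas)
    msg <- NULL
    if (length(object@residualNorms) != n || length(object@solutionNorms) != n)
      msg <- c(msg, "lambdas, residualNorms, solutionNorms must share length")
    if (length(object@chosenIndex) != 1L || object@chosenIndex < 1L ||
        object@chosenIndex > n)
      msg <- c(msg, "chosenIndex out of range")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Per-cell summaries
## ---------------------------------------------------------------------------

#' Traction statistics of one cell
#'
#' Scalars derived from a traction field: the mean traction magnitude, the
#' contractile stress tensor, its principal direction and eigenvalues, and
#' the isotropy ratio. The principal eigenvalue is signed: negative means
#' contraction (forces pointing inward).
#'
#' @slot meanTraction mean per-node traction magnitude, Pa.
#' @slot S symmetric 2x2 stress tensor, Pa.
#' @slot phiS principal traction angle, degrees in [0, 180), y-up frame.
#' @slot fP principal (largest-magnitude) eigenvalue, Pa, signed.
#' @slot fPMin second eigenvalue, Pa.
#' @slot isotropy |fP / fPMin| (>= 1), or NA when fPMin is negligible.
#' @slot degenerate TRUE when the eigenvalues are (near-)equal so the
#'   principal direction is arbitrary.
#' @exportClass StressSummary
setClass("StressSummary",
  representation(meanTraction = "numeric", S = "matrix", phiS = "numeric",
                 fP = "numeric", fPMin = "numeric", isotropy = "numeric",
                 degenerate = "logical"))

#' Wrinkle geometry of one cell
#'
#' @slot lengthPx skeleton length in pixels.
#' @slot lengthUm skeleton length in micrometres.
#' @slot phiW wrinkle principal angle, degrees in [0, 180), y-up frame;
#'   NA when no dominant direction exists.
#' @slot nComponents count of connected wrinkle regions above the minimum
#'   area.
#' @slot topologyLabel \code{"clustered"} (single region) or
#'   \code{"dispersed"}.
#' @exportClass WrinkleSummary
setClass("WrinkleSummary",
  representation(lengthPx = "numeric", lengthUm = "numeric",
                 phiW = "numeric", nComponents = "integer",
                 topologyLabel = "character"))

## ---------------------------------------------------------------------------
## Codec
## ---------------------------------------------------------------------------

#' Force-to-grayscale codec parameters
#'
#' The arctangent codec maps one signed force component f (Pa) to an image
#' intensity \code{I = a * atan(f / b) + Imid}, compressing large forces
#' smoothly into the 8-bit range.
#'
#' @slot a intensity scale.
#' @slot b force scale, Pa.
#' @slot Imid mid-gray intensity.
#' @exportClass CodecParams
setClass("CodecParams",
  representation(a = "numeric", b = "numeric", Imid = "numeric"),
  validity = function(object) {
    if (!(object@a > 0) || !(object@b > 0))
      "codec scales a and b must be positive"
    else TRUE
  })

#' @param a intensity scale (default 81.2).
#' @param b force scale in Pa (default 50).
#' @param Imid mid intensity (default 255/2).
#' @return A \code{CodecParams}.
#' @rdname CodecParams-class
#' @export
CodecParams <- function(a = 81.2, b = 50.0, Imid = 255 / 2) {
  new("CodecParams", a = as.numeric(a), b = as.numeric(b),
      Imid = as.numeric(Imid))
}

## ---------------------------------------------------------------------------
## Synthetic cells
## ---------------------------------------------------------------------------

#' Synthetic contractile-cell settings
#'
#' Parameters of the generator that emulates contractile adherent cells:
#' inward-pointing Gaussian force spots on an elliptical boundary, balanced
#' so net force and net torque vanish, rendered onto a 26 x 26 force grid at
#' 3.44 um spacing by default.
#'
#' @slot nAdhesions integer range (min, max) of adhesion sites per cell.
#' @slot cellRadius mean semi-major axis, micrometres.
#' @slot tractionScale peak traction magnitude, Pa.
#' @slot adhesionSpotSigma Gaussian force-spot width, micrometres.
#' @slot noiseSdDisplacement additive displacement noise, micrometres.
#' @slot beadDensity fluorescent beads per square micrometre.
#' @slot wrinkleFloor mean traction below which no wrinkles form, Pa.
#' @slot nx,ny force-grid size.
#' @slot gridSpacing force-grid spacing, micrometres.
#' @slot seed integer seed; a fixed seed reproduces every output exactly.
#' @exportClass SyntheticCellSpec
setClass("SyntheticCellSpec",
  representation(nAdhesions = "integer", cellRadius = "numeric",
                 tractionScale = "numeric", adhesionSpotSigma = "numeric",
                 noiseSdDisplacement = "numeric", beadDensity = "numeric",
                 wrinkleFloor = "numeric", nx = "integer", ny = "integer",
                 gridSpacing = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@nAdhesions) != 2L || any(object@nAdhesions < 2L))
      msg <- c(msg, "nAdhesions must be a (min, max) pair >= 2")
    sc <- c(object@cellRadius, object@tractionScale, object@adhesionSpotSigma,
            object@beadDensity, object@wrinkleFloor, object@gridSpacing)
    if (any(!is.finite(sc)) || any(sc <= 0))
      msg <- c(msg, "all scale parameters must be positive")
    if (object@noiseSdDisplacement < 0)
      msg <- c(msg, "noiseSdDisplacement must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param nAdhesions (min, max) adhesion count.
#' @param cellRadius semi-major axis, micrometres.
#' @param tractionScale peak traction, Pa.
#' @param adhesionSpotSigma force-spot width, micrometres.
#' @param noiseSdDisplacement bead displacement noise, micrometres.
#' @param beadDensity beads per square micrometre.
#' @param wrinkleFloor wrinkle extinction floor, Pa.
#' @param nx,ny force grid size.
#' @param gridSpacing force grid spacing, micrometres.
#' @param seed integer seed.
#' @return A \code{SyntheticCellSpec}.
#' @rdname SyntheticCellSpec-class
#' @export
SyntheticCellSpec <- function(nAdhesions = c(6L, 16L), cellRadius = 25,
                              tractionScale = 200, adhesionSpotSigma = 5,
                              noiseSdDisplacement = 0.02, beadDensity = 0.3,
                              wrinkleFloor = 10, nx = 26L, ny = 26L,
                              gridSpacing = 3.44, seed = 1L) {
  new("SyntheticCellSpec", nAdhesions = as.integer(nAdhesions),
      cellRadius = as.numeric(cellRadius),
      tractionScale = as.numeric(tractionScale),
      adhesionSpotSigma = as.numeric(adhesionSpotSigma),
      noiseSdDisplacement = as.numeric(noiseSdDisplacement),
      beadDensity = as.numeric(beadDensity),
      wrinkleFloor = as.numeric(wrinkleFloor), nx = as.integer(nx),
      ny = as.integer(ny), gridSpacing = as.numeric(gridSpacing),
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Translator
## ---------------------------------------------------------------------------

#' Training configuration for the image-to-force translator
#'
#' Defaults follow the conditional-GAN recipe used for image translation:
#' batch size 1, Adam with learning rate 2e-4, beta1 = 0.5, beta2 = 0.9, and
#' L1 weight 100. \code{imageSize} must be a power of two >= 32; the network
#' depth scales with it (log2(size) - 2 encoder blocks).
#'
#' @slot imageSize square image side, pixels.
#' @slot epochs training epochs.
#' @slot batchSize samples per update (1).
#' @slot learningRate Adam step size.
#' @slot adamBeta1,adamBeta2 Adam moment decays.
#' @slot lambdaL1 weight of the L1 reconstruction term.
#' @slot ngf,ndf base channel widths of generator / discriminator.
#' @slot seed integer seed governing init and shuffling.
#' @exportClass GANConfig
setClass("GANConfig",
  representation(imageSize = "integer", epochs = "integer",
                 batchSize = "integer", learningRate = "numeric",
                 adamBeta1 = "numeric", adamBeta2 = "numeric",
                 lambdaL1 = "numeric", ngf = "integer", ndf = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    s <- object@imageSize
    if (s < 32L || bitwAnd(s, s - 1L) != 0L)
      msg <- c(msg, "imageSize must be a power of 2 and >= 32")
    if (any(c(object@epochs, object@batchSize, object@learningRate,
              object@lambdaL1, object@ngf, object@ndf) <= 0))
      msg <- c(msg, "epochs, batchSize, learningRate, lambdaL1, ngf, ndf must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' @param imageSize square image side in pixels (power of 2, >= 32).
#' @param epochs training epochs (default 100).
#' @param batchSize samples per update.
#' @param learningRate Adam step size.
#' @param adamBeta1,adamBeta2 Adam moment decays.
#' @param lambdaL1 L1 weight.
#' @param ngf,ndf base channel widths.
#' @param seed integer seed.
#' @return A \code{GANConfig}.
#' @rdname GANConfig-class
#' @export
GANConfig <- function(imageSize = 256L, epochs = 100L, batchSize = 1L,
                      learningRate = 2e-4, adamBeta1 = 0.5, adamBeta2 = 0.9,
                      lambdaL1 = 100, ngf = 16L, ndf = 16L, seed = 1L) {
  new("GANConfig", imageSize = as.integer(imageSize),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate),
      adamBeta1 = as.numeric(adamBeta1), adamBeta2 = as.numeric(adamBeta2),
      lambdaL1 = as.numeric(lambdaL1), ngf = as.integer(ngf),
      ndf = as.integer(ndf), seed = as.integer(seed))
}

#' Fitted image-to-force translator
#'
#' Opaque handle to a trained generator (and, for the adversarial model, its
#' discriminator), with the configuration snapshot and per-epoch loss
#' history. Prediction is deterministic given the parameters and input;
#' save/load round trips are bit-identical.
#'
#' @slot kind \code{"gan"} or \code{"cnn_baseline"}.
#' @slot generator,discriminator parameter lists (discriminator empty for
#'   the baseline).
#' @slot config the \linkS4class{GANConfig} used.
#' @slot codec the \linkS4class{CodecParams} used to encode targets.
#' @slot history data.frame of per-epoch losses.
#' @exportClass TrainedTranslator
setClass("TrainedTranslator",
  representation(kind = "character", generator = "list",
                 discriminator = "list", config = "GANConfig",
                 codec = "CodecParams", history = "data.frame"))
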