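## Synthetic contractile cells: traction fields, bead images, wrinkles,
## and paired datasets. Every output is a deterministic function of the
## integer seed carried by the SyntheticCellSpec; each sub-step draws from
## its own seeded stream so partial re-runs are reproducible.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sample a balanced contractile traction field
#'
#' Emulates a contractile adherent cell: adhesion sites scattered on an
#' elliptical cell boundary exert inward-pointing forces spread as Gaussian
#' spots. The field is then balanced exactly: the mean vector is removed
#' (zero net force) and a rigid-rotation pattern is subtracted (zero net
#' torque), both to machine precision.
#'
#' @param spec a \linkS4class{SyntheticCellSpec}; the seed fixes the cell.
#' @return A \linkS4class{VectorField2D} in Pa on the spec's force grid,
#'   with attribute \code{"cell"} (list: center, semi-axes, orientation in
#'   raster radians, adhesion positions).
#' @export
sampleTraction <- function(spec = SyntheticCellSpec()) {
  stopifnot(is(spec, "SyntheticCellSpec"))
  withSeed(spec@seed, {
    ps <- spec@gridSpacing
    g <- Grid2D(spec@nx, spec@ny, ps)
    co <- nodeCoords(g)
    extent <- c(spec@nx, spec@ny) * ps
    ctr <- extent / 2 + stats::runif(2, -0.05, 0.05) * extent
    aspect <- stats::runif(1, 1.3, 3)
    a <- spec@cellRadius * stats::runif(1, 0.8, 1.2)
    b <- a / aspect
    psi <- stats::runif(1, 0, pi)
    nAd <- sample(seq(spec@nAdhesions[1], spec@nAdhesions[2]), 1)
    ## adhesions cluster at the two poles of the major axis, as in
    ## elongated contractile cells (dipole-dominated traction)
    nA <- ceiling(nAd / 2)
    th <- c(stats::rnorm(nA, 0, 0.45), stats::rnorm(nAd - nA, pi, 0.45))
    px <- ctr[1] + a * cos(th) * cos(psi) - b * sin(th) * sin(psi)
    py <- ctr[2] + a * cos(th) * sin(psi) + b * sin(th) * cos(psi)
    mag <- spec@tractionScale * stats::runif(nAd, 0.5, 1.5)
    fx <- matrix(0, spec@ny, spec@nx)
    fy <- matrix(0, spec@ny, spec@nx)
    s2 <- 2 * spec@adhesionSpotSigma^2
    for (i in seq_len(nAd)) {
      dx <- ctr[1] - px[i]; dy <- ctr[2] - py[i]
      dn <- sqrt(dx^2 + dy^2)
      if (dn == 0) next
      w <- exp(-((co$x - px[i])^2 + (co$y - py[i])^2) / s2)
      fx <- fx + mag[i] * (dx / dn) * w
      fy <- fy + mag[i] * (dy / dn) * w
    }
    ## exact force balance
    fx <- fx - mean(fx); fy <- fy - mean(fy)
    ## exact torque balance: subtract a rigid-rotation force pattern
    rx <- co$x - mean(co$x); ry <- co$y - mean(co$y)
    torque <- sum(rx * fy - ry * fx)
    cc <- torque / sum(rx^2 + ry^2)
    fx <- fx + cc * ry; fy <- fy - cc * rx
    out <- VectorField2D(fx, fy, pixelSize = ps, units = "Pa")
    attr(out, "cell") <- list(center = ctr, semiAxes = c(a, b), psi = psi,
                              adhesions = cbind(px, py))
    out
  })
}

#' Render a fluorescent bead image pair
#'
#' Scatters beads uniformly at the spec's density over an oversampled pixel
#' grid, renders them as Gaussian point-spread spots, and warps the bead
#' positions by the forward displacement of the traction field (plus
#' optional Gaussian displacement noise) to produce the deformed image.
#'
#' @param traction a \linkS4class{VectorField2D} in Pa.
#' @param substrate an \linkS4class{ElasticSubstrate}.
#' @param spec a \linkS4class{SyntheticCellSpec} (bead density, noise,
#'   seed).
#' @param oversample image pixels per force-grid node (default 16, giving
#'   0.215 um pixels on the default grid).
#' @param mode boundary handling for the forward model.
#' @param psfSigma bead spot width, image pixels.
#' @param imageNoiseSd additive intensity noise (8-bit scale).
#' @return List with \code{reference} and \code{deformed}
#'   \linkS4class{ScalarImage}s and the true \code{displacement} field on
#'   the force grid.
#' @export
renderBeadImages <- function(traction, substrate = ElasticSubstrate(),
                             spec = SyntheticCellSpec(), oversample = 16L,
                             mode = c("padded", "periodic"), psfSigma = 1.5,
                             imageNoiseSd = 2) {
  stopifnot(is(traction, "VectorField2D"))
  mode <- match.arg(mode)
  g <- traction@grid
  psImg <- g@pixelSize / oversample
  nxp <- g@nx * oversample; nyp <- g@ny * oversample
  u <- forwardDisplacement(traction, substrate, mode)
  withSeed(spec@seed + 1000003L, {
    areaUm2 <- (nxp * psImg) * (nyp * psImg)
    nBeads <- max(10L, round(spec@beadDensity * areaUm2))
    winUm2 <- (32 * psImg)^2
    if (spec@beadDensity * winUm2 < 10)
      warning("bead density gives < 10 beads per 32 px PIV window")
    bx <- stats::runif(nBeads, 0, nxp * psImg)
    by <- stats::runif(nBeads, 0, nyp * psImg)
    ## displacement at bead positions (bilinear on the force grid)
    rows <- by / g@pixelSize + 1; cols <- bx / g@pixelSize + 1
    ux <- bilinearSample(u@compX, rows, cols)
    uy <- bilinearSample(u@compY, rows, cols)
    if (spec@noiseSdDisplacement > 0) {
      ux <- ux + stats::rnorm(nBeads, 0, spec@noiseSdDisplacement)
      uy <- uy + stats::rnorm(nBeads, 0, spec@noiseSdDisplacement)
    }
    amp <- stats::runif(nBeads, 140, 220)
    ref <- renderSpots(nyp, nxp, by / psImg + 1, bx / psImg + 1, amp,
                       psfSigma)
    def <- renderSpots(nyp, nxp, (by + uy) / psImg + 1,
                       (bx + ux) / psImg + 1, amp, psfSigma)
    if (imageNoiseSd > 0) {
      ref <- ref + stats::rnorm(length(ref), 0, imageNoiseSd)
      def <- def + stats::rnorm(length(def), 0, imageNoiseSd)
    }
    clamp <- function(m) pmin(pmax(m, 0), 255)
    list(reference = ScalarImage(clamp(ref), pixelSize = psImg),
         deformed = ScalarImage(clamp(def), pixelSize = psImg),
         displacement = u)
  })
}

## accumulate Gaussian spots at fractional (row, col) centers
renderSpots <- function(nr, nc, rows, cols, amp, sigma) {
  img <- matrix(0, nr, nc)
  rad <- ceiling(4 * sigma)
  off <- -rad:rad
  for (i in seq_along(rows)) {
    r0 <- round(rows[i]); c0 <- round(cols[i])
    rr <- r0 + off; cc <- c0 + off
    okr <- rr >= 1 & rr <= nr; okc <- cc >= 1 & cc <= nc
    if (!any(okr) || !any(okc)) next
    gr <- exp(-(rr[okr] - rows[i])^2 / (2 * sigma^2))
    gc <- exp(-(cc[okc] - cols[i])^2 / (2 * sigma^2))
    img[rr[okr], cc[okc]] <- img[rr[okr], cc[okc]] + amp[i] * outer(gr, gc)
  }
  img
}

#' Render wrinkles consistent with a traction field
#'
#' Builds a smoothed local stress field from the traction (structure-tensor
#' orientation and blurred magnitude, bilinearly upsampled to the target
#' grid) and draws sinusoidal ridges where the local stress exceeds the
#' wrinkle floor. Ridge crests run perpendicular to the local principal
#' force direction; the ridge wavelength follows the bilayer buckling
#' relation (clamped below at 4 pixels, the raster resolution limit for a
#' representable sinusoid). Fields whose mean traction is below the floor
#' produce an empty mask. The pseudo-micrograph adds a soft cell body and
#' Gaussian noise to the ridges.
#'
#' @param traction a \linkS4class{VectorField2D} in Pa.
#' @param bilayer a \linkS4class{BilayerSubstrate} fixing the wavelength.
#' @param grid target \linkS4class{Grid2D}; its extent should match the
#'   traction grid.
#' @param wrinkleFloor extinction floor, Pa (default 10).
#' @param seed integer seed for the micrograph noise.
#' @return List with \code{mask} (\linkS4class{BinaryMask}) and
#'   \code{pseudoMicrograph} (\linkS4class{ScalarImage}, 8-bit range).
#' @export
renderWrinkles <- function(traction, bilayer = BilayerSubstrate(),
                           grid = NULL, wrinkleFloor = 10, seed = 1L) {
  stopifnot(is(traction, "VectorField2D"), is(bilayer, "BilayerSubstrate"))
  if (is.null(grid)) {
    ps <- traction@grid@pixelSize * traction@grid@nx / 192
    grid <- Grid2D(192L, 192L, ps)
  }
  psF <- traction@grid@pixelSize
  fx <- resampleMatrix(traction@compX, psF, grid@ny, grid@nx,
                       grid@pixelSize)
  fy <- resampleMatrix(traction@compY, psF, grid@ny, grid@nx,
                       grid@pixelSize)
  lambdaUm <- wavelengthRatio(bilayer) * bilayer@h
  lambdaPx <- max(lambdaUm / grid@pixelSize, 4)
  ## orientation coherence length ~ a fifth of the field of view: wrinkle
  ## trains span the cell rather than single adhesions
  sm <- max(2, lambdaPx / 2)
  smOri <- max(grid@nx / 5, sm)
  Txx <- gaussBlur(fx * fx, smOri)
  Txy <- gaussBlur(fx * fy, smOri)
  Tyy <- gaussBlur(fy * fy, smOri)
  theta <- 0.5 * atan2(2 * Txy, Txx - Tyy)  # raster-frame force axis
  s <- gaussBlur(sqrt(fx^2 + fy^2), sm)
  fbar <- meanTraction(traction)
  if (fbar < wrinkleFloor) {
    mask <- BinaryMask(matrix(0, grid@ny, grid@nx),
                       pixelSize = grid@pixelSize)
  } else {
    rows <- matrix(seq_len(grid@ny), grid@ny, grid@nx)
    cols <- matrix(seq_len(grid@nx), grid@ny, grid@nx, byrow = TRUE)
    phase <- 2 * pi / lambdaPx * (cols * cos(theta) + rows * sin(theta))
    ridge <- cos(phase) > 0.3
    ## wrinkled region: the strongest-stress pixels above the floor, with
    ## area growing linearly in the mean traction so that total ridge
    ## length is linear in traction (the measured linear length-force law
    ## is built into the generator)
    npx <- grid@ny * grid@nx
    targetArea <- min(0.002 * npx * (fbar - wrinkleFloor), 0.35 * npx)
    tau <- stats::quantile(s, 1 - targetArea / npx, names = FALSE)
    region <- s > max(tau, wrinkleFloor)
    mask <- BinaryMask(ridge & region, pixelSize = grid@pixelSize)
  }
  withSeed(seed + 2000003L, {
    body <- gaussBlur((s > wrinkleFloor * 0.3) * 1, max(4, sm))
    img <- 60 * body + 150 * mask@values +
      stats::rnorm(grid@ny * grid@nx, 0, 3)
    img <- pmin(pmax(img, 0), 255)
    list(mask = mask,
         pseudoMicrograph = ScalarImage(img, pixelSize = grid@pixelSize))
  })
}

#' Build a paired image/traction dataset with rotation augmentation
#'
#' Generates \code{nCells} synthetic cells, renders each cell's
#' pseudo-micrograph at the training resolution, and augments every pair by
#' the four 90-degree rotations (image and traction components co-rotated),
#' yielding exactly \code{4 * nCells} pairs. Images are written as 8-bit
#' TIFF, traction fields as delimited text, plus a JSON manifest recording
#' the pairs, the train/test split (the last \code{nTest} base cells are
#' held out, with all their rotations) and the seeds.
#'
#' @param nCells number of base cells.
#' @param spec a \linkS4class{SyntheticCellSpec}; cell i uses seed
#'   \code{spec@seed + i}.
#' @param outDir output directory (created if needed).
#' @param nTest base cells held out for testing.
#' @param imageSize rendered image side, pixels.
#' @param bilayer \linkS4class{BilayerSubstrate} for the wrinkle
#'   wavelength.
#' @return The manifest, invisibly (also written to
#'   \code{outDir/manifest.json}).
#' @export
buildDataset <- function(nCells, spec = SyntheticCellSpec(), outDir,
                         nTest = 0L, imageSize = 64L,
                         bilayer = BilayerSubstrate()) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    wfmStop(sprintf("cannot create output directory '%s'", outDir))
  psImg <- spec@nx * spec@gridSpacing / imageSize
  grid <- Grid2D(imageSize, imageSize, psImg)
  pairs <- list()
  for (i in seq_len(nCells)) {
    cellSpec <- spec
    cellSpec@seed <- spec@seed + i
    tr <- sampleTraction(cellSpec)
    wr <- renderWrinkles(tr, bilayer, grid,
                         wrinkleFloor = spec@wrinkleFloor,
                         seed = cellSpec@seed)
    split <- if (i > nCells - nTest) "test" else "train"
    for (k in 0:3) {
      img <- ScalarImage(rotate90Matrix(wr$pseudoMicrograph@values, k),
                         pixelSize = psImg)
      trk <- rotate90Field(tr, k)
      imgPath <- sprintf("cell%04d_rot%d_img.tif", i, k)
      trPath <- sprintf("cell%04d_rot%d_traction.csv", i, k)
      writeScalarImage(img, file.path(outDir, imgPath))
      writeVectorField(trk, file.path(outDir, trPath))
      pairs[[length(pairs) + 1L]] <- list(
        id = sprintf("cell%04d_rot%d", i, k), image = imgPath,
        traction = trPath, baseCell = i, rotation = k, split = split,
        seed = cellSpec@seed)
    }
  }
  manifest <- list(nBaseCells = nCells, nPairs = length(pairs),
                   nTestCells = nTest, imageSize = imageSize,
                   imagePixelSizeUm = psImg,
                   forceGrid = list(nx = spec@nx, ny = spec@ny,
                                    spacing = spec@gridSpacing),
                   seed = spec@seed, pairs = pairs)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
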