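## Internal helpers shared across modules.

## stop() with a consistent prefix, no call
wfmStop <- function(...) stop(..., call. = FALSE)

## check two objects share an identical grid
checkSameGrid <- function(a, b, what = "inputs") {
  ga <- if (is(a, "Grid2D")) a else a@grid
  gb <- if (is(b, "Grid2D")) b else b@grid
  if (ga@nx != gb@nx || ga@ny != gb@ny ||
      abs(ga@pixelSize - gb@pixelSize) > 1e-9 * ga@pixelSize)
    wfmStop(sprintf("grid mismatch between %s: %dx%d@%g vs %dx%d@%g",
                    what, ga@nx, ga@ny, ga@pixelSize,
                    gb@nx, gb@ny, gb@pixelSize))
  invisible(TRUE)
}

## DFT sample frequencies (cycles per sample), matching fft() ordering
fftFreq <- function(n) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq_len(floor(n / 2)) - floor(n / 2) - 1L)
  k / n
}

## fold an angle in degrees into [0, 180)
foldAxial <- function(deg) {
  out <- deg %% 180
  out[abs(out - 180) < 1e-12] <- 0
  out
}

## rotate a matrix 90 degrees counter-clockwise on screen, k quarter turns
rotate90Matrix <- function(m, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

## rotate a vector field 90 deg CCW on screen (k quarter turns), co-rotating
## components; in the raster frame one CCW screen turn maps (vx, vy) to
## (vy, -vx), which is the physical y-up rule (vx, vy) -> (-vy, vx).
rotate90Field <- function(field, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  cx <- field@compX; cy <- field@compY
  for (i in seq_len(k)) {
    ncx <- rotate90Matrix(cy)
    ncy <- -rotate90Matrix(cx)
    cx <- ncx; cy <- ncy
  }
  VectorField2D(cx, cy, pixelSize = field@grid@pixelSize,
                units = field@units)
}

## bilinear sampling of matrix m at fractional row/col positions (1-based);
## positions outside the matrix are clamped to the border
bilinearSample <- function(m, rows, cols) {
  rows <- as.vector(rows); cols <- as.vector(cols)
  nr <- nrow(m); nc <- ncol(m)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1L); c0 <- pmin(floor(cols), nc - 1L)
  fr <- rows - r0; fc <- cols - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}

## resample a matrix defined on grid (ny,nx,ps) onto a target grid by
## bilinear interpolation in physical coordinates (pixel centers aligned at
## the top-left origin)
resampleMatrix <- function(m, psFrom, nyTo, nxTo, psTo) {
  rowsTo <- (seq_len(nyTo) - 1) * psTo / psFrom + 1
  colsTo <- (seq_len(nxTo) - 1) * psTo / psFrom + 1
  grid <- expand.grid(r = rowsTo, cc = colsTo)
  matrix(bilinearSample(m, grid$r, grid$cc), nrow = nyTo, ncol = nxTo)
}

## interpolate a VectorField2D onto a target Grid2D (bilinear, physical
## coordinates). `origin` is the physical position (um) of the source
## field's node (1,1) in the target frame (e.g. PIV window-center offset).
interpField <- function(field, grid, origin = c(0, 0)) {
  ps <- field@grid@pixelSize
  rowsTo <- ((seq_len(grid@ny) - 1) * grid@pixelSize - origin[2]) / ps + 1
  colsTo <- ((seq_len(grid@nx) - 1) * grid@pixelSize - origin[1]) / ps + 1
  gr <- expand.grid(r = rowsTo, cc = colsTo)
  cx <- matrix(bilinearSample(field@compX, gr$r, gr$cc), grid@ny, grid@nx)
  cy <- matrix(bilinearSample(field@compY, gr$r, gr$cc), grid@ny, grid@nx)
  VectorField2D(cx, cy, pixelSize = grid@pixelSize, units = field@units)
}

## block-average downsample of a matrix by integer factor
blockAverage <- function(m, fac) {
  nr <- nrow(m) %/% fac; nc <- ncol(m) %/% fac
  m <- m[seq_len(nr * fac), seq_len(nc * fac), drop = FALSE]
  a <- array(m, dim = c(fac, nr, fac, nc))
  apply(a, c(2, 4), mean)
}

## Gaussian blur safe for kernels wider than the image: EBImage::gblur with
## the brush clamped to the image size (odd radius)
gaussBlur <- function(m, sigma) {
  rad <- 2 * ceiling(3 * sigma) + 1
  maxRad <- min(dim(m)) - 1
  if (maxRad %% 2 == 0) maxRad <- maxRad - 1
  EBImage::gblur(m, sigma = sigma, radius = min(rad, maxRad))
}

#' Resample a vector field onto another grid
#'
#' Bilinear interpolation in physical coordinates, clamped at the borders.
#' Used e.g. to move a PIV displacement field (whose first node sits at the
#' first window center) onto the traction force grid before inversion.
#'
#' @param field a \linkS4class{VectorField2D}.
#' @param grid target \linkS4class{Grid2D}.
#' @param origin physical position (x, y in micrometres) of the field's
#'   first node in the target frame; PIV fields carry this as attribute
#'   \code{"originUm"}.
#' @return A \linkS4class{VectorField2D} on \code{grid}.
#' @export
resampleField <- function(field, grid, origin = NULL) {
  stopifnot(is(field, "VectorField2D"), is(grid, "Grid2D"))
  if (is.null(origin))
    origin <- attr(field, "originUm") %||% c(0, 0)
  interpField(field, grid, origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## node physical coordinates of a grid (raster frame, origin at node (1,1))
nodeCoords <- function(grid) {
  ps <- grid@pixelSize
  list(x = matrix((seq_len(grid@nx) - 1) * ps, grid@ny, grid@nx,
                  byrow = TRUE),
       y = matrix((seq_len(grid@ny) - 1) * ps, grid@ny, grid@nx))
}
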