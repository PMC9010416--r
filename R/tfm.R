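## Forward and inverse traction force microscopy on an elastic half-space.

#' Boussinesq surface Green's tensor
#'
#' In-plane displacement response of an elastic half-space surface to a
#' tangential point force:
#' \deqn{G(r) = \frac{1+\nu}{\pi E r^3}
#'   \begin{pmatrix} (1-\nu) r^2 + \nu r_x^2 & \nu r_x r_y \\
#'                   \nu r_x r_y & (1-\nu) r^2 + \nu r_y^2 \end{pmatrix}}
#' with units of um / (Pa um^2): contracting with a traction (Pa) over an
#' area element (um^2) yields micrometres of displacement.
#'
#' @param r numeric length-2 vector, micrometres; must be nonzero (callers
#'   needing the self term use the Fourier kernel or cell-averaged
#'   quadrature).
#' @param substrate an \linkS4class{ElasticSubstrate}.
#' @return Symmetric 2x2 numeric matrix.
#' @export
greensTensor <- function(r, substrate = ElasticSubstrate()) {
  stopifnot(length(r) == 2, is(substrate, "ElasticSubstrate"))
  rn <- sqrt(sum(r^2))
  if (rn == 0)
    wfmStop("Green's tensor is singular at r = 0")
  E <- substrate@E; nu <- substrate@nu
  pref <- (1 + nu) / (pi * E * rn^3)
  pref * matrix(c((1 - nu) * rn^2 + nu * r[1]^2, nu * r[1] * r[2],
                  nu * r[1] * r[2], (1 - nu) * rn^2 + nu * r[2]^2), 2, 2)
}

## wavevector lattice (rad/um) for a grid, fft ordering
waveVectors <- function(ny, nx, ps) {
  list(kx = matrix(2 * pi * fftFreq(nx) / ps, ny, nx, byrow = TRUE),
       ky = matrix(2 * pi * fftFreq(ny) / ps, ny, nx))
}

#' Spectral half-space kernel
#'
#' The analytic Fourier transform of [greensTensor()] evaluated on the
#' discrete wavevector lattice of a grid:
#' \deqn{\tilde G(k) = \frac{2(1+\nu)}{E k^3}
#'   \begin{pmatrix} (1-\nu)k^2 + \nu k_y^2 & -\nu k_x k_y \\
#'                   -\nu k_x k_y & (1-\nu)k^2 + \nu k_x^2 \end{pmatrix}}
#' The k = 0 entry is set to zero (zero-mean traction convention: the net
#' force on an adherent cell vanishes). Entries decay as 1/|k|.
#'
#' @param grid a \linkS4class{Grid2D} (or object carrying one).
#' @param substrate an \linkS4class{ElasticSubstrate}.
#' @param boxFilter if TRUE, multiply by the pixel-box window
#'   \eqn{\mathrm{sinc}(k_x p/2)\,\mathrm{sinc}(k_y p/2)}, modelling the
#'   gridded traction as constant over each cell rather than
#'   trigonometrically interpolated; the forward/inverse solvers use this
#'   variant. The unfiltered kernel decays as 1/|k|.
#' @return List with matrices \code{Gxx}, \code{Gxy}, \code{Gyy} (units
#'   um/Pa) and the wavevector matrices \code{kx}, \code{ky} (rad/um).
#' @export
fourierKernel <- function(grid, substrate = ElasticSubstrate(),
                          boxFilter = FALSE) {
  if (!is(grid, "Grid2D")) grid <- gridGeometry(grid)
  kv <- waveVectors(grid@ny, grid@nx, grid@pixelSize)
  kx <- kv$kx; ky <- kv$ky
  k2 <- kx^2 + ky^2
  k <- sqrt(k2)
  E <- substrate@E; nu <- substrate@nu
  pref <- 2 * (1 + nu) / (E * pmax(k, .Machine$double.xmin)^3)
  if (boxFilter) {
    sinc <- function(z) ifelse(abs(z) < 1e-12, 1, sin(z) / z)
    pref <- pref * sinc(kx * grid@pixelSize / 2) *
      sinc(ky * grid@pixelSize / 2)
  }
  Gxx <- pref * ((1 - nu) * k2 + nu * ky^2)
  Gyy <- pref * ((1 - nu) * k2 + nu * kx^2)
  Gxy <- pref * (-nu * kx * ky)
  Gxx[1, 1] <- 0; Gyy[1, 1] <- 0; Gxy[1, 1] <- 0
  list(Gxx = Gxx, Gxy = Gxy, Gyy = Gyy, kx = kx, ky = ky)
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

## pad a matrix with zeros to (2ny, 2nx), content in the top-left block
padZero2 <- function(m) {
  out <- matrix(0, 2 * nrow(m), 2 * ncol(m))
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

#' Forward problem: displacement from traction
#'
#' Computes the substrate surface displacement produced by a traction field
#' by convolution with the half-space Green's function, evaluated in Fourier
#' space. \code{"periodic"} mode uses the cyclic convolution on the field's
#' own lattice and forms an exact inverse pair with
#' [solveTractionFTTC()]; \code{"padded"} mode zero-pads the traction by a
#' factor 2 per axis to suppress wrap-around and is the default for
#' experiment-like data.
#'
#' @param traction a \linkS4class{VectorField2D} in Pa.
#' @param substrate an \linkS4class{ElasticSubstrate}.
#' @param mode \code{"padded"} or \code{"periodic"}.
#' @return A \linkS4class{VectorField2D} in micrometres on the same grid.
#' @export
forwardDisplacement <- function(traction, substrate = ElasticSubstrate(),
                                mode = c("padded", "periodic")) {
  stopifnot(is(traction, "VectorField2D"))
  mode <- match.arg(mode)
  if (traction@units != "Pa")
    wfmStop("forwardDisplacement expects a traction field in Pa")
  if (any(is.na(traction@compX)) || any(is.na(traction@compY)))
    wfmStop("traction field contains non-finite values")
  g <- traction@grid
  tx <- traction@compX; ty <- traction@compY
  if (mode == "padded") { tx <- padZero2(tx); ty <- padZero2(ty) }
  kern <- fourierKernel(Grid2D(ncol(tx), nrow(tx), g@pixelSize), substrate, boxFilter = TRUE)
  txh <- fft2(tx); tyh <- fft2(ty)
  uxh <- kern$Gxx * txh + kern$Gxy * tyh
  uyh <- kern$Gxy * txh + kern$Gyy * tyh
  ux <- Re(ifft2(uxh)); uy <- Re(ifft2(uyh))
  if (mode == "padded") {
    ux <- ux[seq_len(g@ny), seq_len(g@nx)]
    uy <- uy[seq_len(g@ny), seq_len(g@nx)]
  }
  VectorField2D(ux, uy, pixelSize = g@pixelSize, units = "um")
}

## per-wavevector Tikhonov solve; returns spectra of the traction
tikhonovSolveSpectra <- function(kern, uxh, uyh, lambda) {
  ## A = G^T G (G symmetric real per k)
  Axx <- kern$Gxx^2 + kern$Gxy^2
  Axy <- kern$Gxy * (kern$Gxx + kern$Gyy)
  Ayy <- kern$Gyy^2 + kern$Gxy^2
  Mxx <- Axx + lambda^2; Myy <- Ayy + lambda^2
  det <- Mxx * Myy - Axy^2
  bx <- kern$Gxx * uxh + kern$Gxy * uyh
  by <- kern$Gxy * uxh + kern$Gyy * uyh
  sing <- det <= .Machine$double.xmin
  if (any(sing & row(det) + col(det) > 2)) {
    warning("near-singular wavevector system; pseudo-inverse fallback applied")
    det[sing] <- Inf  # zero those modes (minimum-norm solution)
  }
  txh <- (Myy * bx - Axy * by) / det
  tyh <- (-Axy * bx + Mxx * by) / det
  txh[1, 1] <- 0; tyh[1, 1] <- 0
  list(txh = txh, tyh = tyh)
}

#' Inverse problem: traction from displacement (FTTC)
#'
#' Fourier-transform traction cytometry: per wavevector the damped
#' least-squares solution
#' \deqn{\tilde t = (\tilde G^T \tilde G + \lambda^2 I)^{-1} \tilde G^T \tilde u}
#' is evaluated with the analytic half-space kernel. The k = 0 traction is
#' set to zero, so the recovered field always has zero net force.
#'
#' @param displacement a \linkS4class{VectorField2D} in micrometres; NaN
#'   nodes (invalid PIV windows) are replaced by zero displacement before
#'   the transform.
#' @param substrate an \linkS4class{ElasticSubstrate}.
#' @param config a \linkS4class{TikhonovConfig} giving the regularization
#'   parameter and boundary mode.
#' @return A \linkS4class{VectorField2D} in Pa on the displacement grid.
#' @export
solveTractionFTTC <- function(displacement, substrate = ElasticSubstrate(),
                              config = TikhonovConfig()) {
  stopifnot(is(displacement, "VectorField2D"),
            is(config, "TikhonovConfig"))
  if (displacement@units != "um")
    wfmStop("solveTractionFTTC expects a displacement field in um")
  g <- displacement@grid
  ux <- displacement@compX; uy <- displacement@compY
  nbad <- sum(is.na(ux) | is.na(uy))
  if (nbad > 0) {
    ux[is.na(ux)] <- 0; uy[is.na(uy)] <- 0
  }
  if (config@mode == "padded") { ux <- padZero2(ux); uy <- padZero2(uy) }
  kern <- fourierKernel(Grid2D(ncol(ux), nrow(ux), g@pixelSize), substrate, boxFilter = TRUE)
  sol <- tikhonovSolveSpectra(kern, fft2(ux), fft2(uy), config@lambdaReg)
  tx <- Re(ifft2(sol$txh)); ty <- Re(ifft2(sol$tyh))
  if (config@mode == "padded") {
    tx <- tx[seq_len(g@ny), seq_len(g@nx)]
    ty <- ty[seq_len(g@ny), seq_len(g@nx)]
    ## the k = 0 convention zeroes the mean over the padded domain; apply
    ## the zero-net-force convention on the observation window as well
    tx <- tx - mean(tx); ty <- ty - mean(ty)
  }
  VectorField2D(tx, ty, pixelSize = g@pixelSize, units = "Pa")
}

#' L-curve selection of the regularization parameter
#'
#' Scans a grid of regularization parameters, records the residual norm
#' \eqn{\|\tilde G \tilde t - \tilde u\|} and solution norm
#' \eqn{\|\tilde t\|} (Parseval, computed spectrally), and picks the corner
#' of the log-log curve: the point of maximum curvature of a
#' spline-smoothed parametrization, falling back to the maximum
#' chord-distance (triangle) point when the curvature signal is flat.
#'
#' @param displacement a \linkS4class{VectorField2D} in micrometres.
#' @param substrate an \linkS4class{ElasticSubstrate}.
#' @param lambdaGrid strictly increasing positive values; at least 5 points
#'   spanning at least 3 decades. Default: 29 points over 7 decades scaled
#'   to the kernel magnitude.
#' @param mode boundary handling for the scan.
#' @return List with \code{lambda} (the selected value) and \code{lcurve}
#'   (an \linkS4class{LCurve}).
#' @export
selectLambdaLCurve <- function(displacement, substrate = ElasticSubstrate(),
                               lambdaGrid = NULL,
                               mode = c("periodic", "padded")) {
  stopifnot(is(displacement, "VectorField2D"))
  mode <- match.arg(mode)
  g <- displacement@grid
  ux <- displacement@compX; uy <- displacement@compY
  ux[is.na(ux)] <- 0; uy[is.na(uy)] <- 0
  if (mode == "padded") { ux <- padZero2(ux); uy <- padZero2(uy) }
  kern <- fourierKernel(Grid2D(ncol(ux), nrow(ux), g@pixelSize), substrate, boxFilter = TRUE)
  if (is.null(lambdaGrid)) {
    gref <- max(abs(kern$Gxx), abs(kern$Gyy))
    lambdaGrid <- gref * 10^seq(-6, 1, length.out = 29)
  }
  if (length(lambdaGrid) < 5 ||
      log10(max(lambdaGrid) / min(lambdaGrid)) < 3)
    wfmStop("lambdaGrid needs >= 5 points spanning >= 3 decades")
  uxh <- fft2(ux); uyh <- fft2(uy)
  res <- numeric(length(lambdaGrid)); soln <- numeric(length(lambdaGrid))
  rough <- NA_real_
  kmag <- sqrt(kern$kx^2 + kern$ky^2)
  highK <- kmag > 0.5 * max(kmag)
  for (i in seq_along(lambdaGrid)) {
    s <- tikhonovSolveSpectra(kern, uxh, uyh, lambdaGrid[i])
    if (i == 1L) {
      pw <- Mod(s$txh)^2 + Mod(s$tyh)^2
      rough <- sum(pw[highK]) / max(sum(pw), .Machine$double.xmin)
    }
    rx <- kern$Gxx * s$txh + kern$Gxy * s$tyh - uxh
    ry <- kern$Gxy * s$txh + kern$Gyy * s$tyh - uyh
    rx[1, 1] <- 0; ry[1, 1] <- 0  # k = 0 is outside the model space
    res[i] <- sqrt(sum(Mod(rx)^2 + Mod(ry)^2)) / length(rx)
    soln[i] <- sqrt(sum(Mod(s$txh)^2 + Mod(s$tyh)^2)) / length(rx)
  }
  tol <- 1e-7
  if (any(diff(res) < -tol * max(res)) ||
      any(diff(soln) > tol * max(soln)))
    wfmStop("L-curve monotonicity violated: numerical failure in the scan")
  idx <- lcurveCorner(lambdaGrid, res, soln, rough)
  lc <- new("LCurve", lambdas = lambdaGrid, residualNorms = res,
            solutionNorms = soln, chosenIndex = as.integer(idx))
  list(lambda = lambdaGrid[idx], lcurve = lc)
}

## corner of the (log residual, log solution) curve; `rough` is the
## high-wavevector power fraction of the unregularized solution
lcurveCorner <- function(lambdas, res, soln, rough = NA_real_) {
  eps <- .Machine$double.xmin
  ## noise-free degenerate case: the per-wavevector system is invertible,
  ## so the residual vanishes as lambda -> 0 for any data and the curve
  ## carries no corner when the data are consistent. Consistent (clean)
  ## data yield a smooth unregularized solution; measurement noise shows
  ## up as high-wavevector power. With a smooth lambda->0 solution, take
  ## the largest lambda still at the residual floor.
  if (is.finite(rough) && rough < 0.02)
    return(max(which(res <= 10 * res[1])))
  lr <- log10(pmax(res, eps)); ls <- log10(pmax(soln, eps))
  t <- log10(lambdas)
  n <- length(t)
  ## normalize so both axes weigh equally
  nr <- (lr - min(lr)) / max(diff(range(lr)), eps)
  ns <- (ls - min(ls)) / max(diff(range(ls)), eps)
  kappa <- rep(NA_real_, n)
  fitOk <- n >= 7
  if (fitOk) {
    sr <- try(stats::smooth.spline(t, nr, df = min(8, n - 2)), silent = TRUE)
    ss <- try(stats::smooth.spline(t, ns, df = min(8, n - 2)), silent = TRUE)
    fitOk <- !inherits(sr, "try-error") && !inherits(ss, "try-error")
    if (fitOk) {
      d1r <- stats::predict(sr, t, deriv = 1)$y
      d2r <- stats::predict(sr, t, deriv = 2)$y
      d1s <- stats::predict(ss, t, deriv = 1)$y
      d2s <- stats::predict(ss, t, deriv = 2)$y
      kappa <- (d1r * d2s - d2r * d1s) / (d1r^2 + d1s^2)^1.5
    }
  }
  ## corner curvature of an L is negative in this orientation (residual
  ## increasing, solution decreasing); look for the strongest bend
  kappa[!is.finite(kappa)] <- 0
  if (fitOk && max(abs(kappa)) > 1e-3) {
    which.max(abs(kappa))
  } else {
    ## triangle fallback: farthest point from the endpoint chord
    p1 <- c(nr[1], ns[1]); p2 <- c(nr[n], ns[n])
    dv <- p2 - p1
    dv <- dv / max(sqrt(sum(dv^2)), eps)
    d <- abs((nr - p1[1]) * dv[2] - (ns - p1[2]) * dv[1])
    which.max(d)
  }
}

#' Displacement field by particle image velocimetry
#'
#' Multi-pass block-matching PIV with window deformation: the two images
#' are divided into square interrogation windows; each window pair is
#' cross-correlated (cyclic, via FFT) and the correlation peak is
#' localized to sub-pixel precision with a three-point Gaussian fit
#' (parabolic fallback when a neighbour is non-positive). After each pass
#' the deformed image is warped back by the interpolated predictor field
#' and the next pass measures the residual, which removes the bias that
#' displacement gradients induce in single-pass correlation. Outliers are
#' replaced by the local 3x3 median between passes. Windows with
#' near-zero intensity variance yield NaN (invalid-node flag).
#'
#' @param imgRef,imgDef reference and deformed \linkS4class{ScalarImage}s
#'   on the same grid.
#' @param window interrogation window side, pixels (>= 16; default 32).
#' @param step window spacing, pixels (<= window; default 16).
#' @param passes number of predictor-corrector passes (default 3).
#' @param weightSigma standard deviation (px) of an optional Gaussian
#'   weighting of the interrogation windows; narrows the effective
#'   averaging footprint, reducing smoothing of displacement gradients.
#'   \code{Inf} (default) uses plain unweighted windows.
#' @return A \linkS4class{VectorField2D} in micrometres with node spacing
#'   \code{step * pixelSize}; components are raster displacements (x right,
#'   y down). Attribute \code{"originUm"} holds the physical position of
#'   the first window center.
#' @export
pivDisplacement <- function(imgRef, imgDef, window = 32L, step = 16L,
                            passes = 3L, weightSigma = Inf) {
  stopifnot(is(imgRef, "ScalarImage"), is(imgDef, "ScalarImage"))
  checkSameGrid(imgRef, imgDef, "PIV image pair")
  window <- as.integer(window); step <- as.integer(step)
  if (window < 16L) wfmStop("PIV window must be >= 16 px")
  if (step > window) wfmStop("PIV step must be <= window")
  a <- imgRef@values; b <- imgDef@values
  ps <- imgRef@grid@pixelSize
  oy <- seq(1L, nrow(a) - window + 1L, by = step)
  ox <- seq(1L, ncol(a) - window + 1L, by = step)
  if (length(oy) < 2L || length(ox) < 2L)
    wfmStop("images too small for the requested window/step")
  orig <- (window / 2 - 0.5)  # first window center, px
  cen <- (0:(window - 1)) - (window - 1) / 2
  wgt <- if (is.finite(weightSigma))
    outer(exp(-cen^2 / (2 * weightSigma^2)),
          exp(-cen^2 / (2 * weightSigma^2)))
  else 1
  nr <- nrow(a); nc <- ncol(a)
  prow <- matrix(seq_len(nr), nr, nc)
  pcol <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dx <- matrix(0, length(oy), length(ox))
  dy <- matrix(0, length(oy), length(ox))
  for (pass in seq_len(max(1L, as.integer(passes)))) {
    if (pass == 1L) {
      bw <- b
    } else {
      ## warp the deformed image back by the predictor: sample b at
      ## x + u_pred(x); residual correlation then measures u - u_pred
      prC <- (pcol - 1 - orig) / step + 1
      prR <- (prow - 1 - orig) / step + 1
      ux <- bilinearSample(dx, prR, prC)
      uy <- bilinearSample(dy, prR, prC)
      bw <- matrix(bilinearSample(b, prow + uy, pcol + ux), nr, nc)
    }
    rx <- matrix(NA_real_, length(oy), length(ox))
    ry <- matrix(NA_real_, length(oy), length(ox))
    for (iy in seq_along(oy)) {
      for (ix in seq_along(ox)) {
        wa <- a[oy[iy]:(oy[iy] + window - 1L),
                ox[ix]:(ox[ix] + window - 1L)]
        wb <- bw[oy[iy]:(oy[iy] + window - 1L),
                 ox[ix]:(ox[ix] + window - 1L)]
        sa <- stats::sd(wa); sb <- stats::sd(wb)
        if (!is.finite(sa) || !is.finite(sb) ||
            sa < 1e-10 * (abs(mean(wa)) + 1) ||
            sb < 1e-10 * (abs(mean(wb)) + 1)) next
        pk <- crossCorrPeak((wa - mean(wa)) * wgt, (wb - mean(wb)) * wgt)
        rx[iy, ix] <- pk[1]; ry[iy, ix] <- pk[2]
      }
    }
    bad <- is.na(rx) | is.na(ry)
    rx[bad] <- 0; ry[bad] <- 0
    dx <- dx + rx; dy <- dy + ry
    ## median validation: replace outliers by the local median
    mx <- medianFilter3(dx); my <- medianFilter3(dy)
    out <- (abs(dx - mx) > pmax(2, 2 * abs(mx))) |
      (abs(dy - my) > pmax(2, 2 * abs(my)))
    dx[out] <- mx[out]; dy[out] <- my[out]
    if (pass == max(1L, as.integer(passes))) { dx[bad] <- NA; dy[bad] <- NA }
  }
  out <- VectorField2D(dx * ps, dy * ps, pixelSize = step * ps,
                       units = "um")
  ## physical position of the first window center in the image frame
  attr(out, "originUm") <- rep(orig * ps, 2)
  out
}

## 3x3 median filter with border replication
medianFilter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  idx <- function(i, n) pmin(pmax(i, 1L), n)
  st <- array(NA_real_, c(nr, nc, 9))
  k <- 0
  for (di in -1:1) for (dj in -1:1) {
    k <- k + 1
    st[, , k] <- m[idx(seq_len(nr) + di, nr), idx(seq_len(nc) + dj, nc)]
  }
  apply(st, c(1, 2), stats::median, na.rm = TRUE)
}

## cyclic cross-correlation peak with sub-pixel refinement; returns c(dx, dy)
crossCorrPeak <- function(wa, wb) {
  n <- nrow(wa)
  cc <- Re(ifft2(Conj(fft2(wa)) * fft2(wb)))
  im <- which.max(cc)
  pr <- (im - 1L) %% n + 1L
  pc <- (im - 1L) %/% n + 1L
  wrap <- function(i) ((i - 1L) %% n) + 1L
  sub <- function(ctr, m1, p1) {
    c0 <- cc[ctr[1], ctr[2]]; cm <- cc[m1[1], m1[2]]; cp <- cc[p1[1], p1[2]]
    if (cm > 0 && cp > 0 && c0 > 0 && (c0 >= cm) && (c0 >= cp)) {
      den <- 2 * log(cm) - 4 * log(c0) + 2 * log(cp)
      if (abs(den) > 1e-14) return((log(cm) - log(cp)) / den)
    }
    den <- cm - 2 * c0 + cp
    if (abs(den) > 1e-14) (cm - cp) / (2 * den) else 0
  }
  ddr <- sub(c(pr, pc), c(wrap(pr - 1L), pc), c(wrap(pr + 1L), pc))
  ddc <- sub(c(pr, pc), c(pr, wrap(pc - 1L)), c(pr, wrap(pc + 1L)))
  shift <- function(p, d) {
    s <- p - 1L + d
    if (s > n / 2) s <- s - n
    s
  }
  c(shift(pc, ddc), shift(pr, ddr))
}
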