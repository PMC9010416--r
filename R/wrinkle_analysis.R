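## Wrinkle geometry and traction statistics.

#' Mean traction magnitude
#'
#' Arithmetic mean of the per-node traction vector norms,
#' \eqn{\bar f = (1/M) \sum_m |f_m|}.
#'
#' @param traction a \linkS4class{VectorField2D} in Pa.
#' @return Mean traction in Pa.
#' @export
meanTraction <- function(traction) {
  stopifnot(is(traction, "VectorField2D"))
  m <- fieldMagnitude(traction)
  if (!length(m)) wfmStop("empty traction field")
  mean(m)
}

#' Contractile stress tensor from point forces
#'
#' The discrete first-moment sum
#' \deqn{S_{ij} = \frac{1}{2M} \sum_m \{ n_j(x_m, x_0) f_i(x_m)
#'               + n_i(x_m, x_0) f_j(x_m) \}}
#' over M observation points, where \eqn{n = r/|r|} and
#' \eqn{r = x_m - x_0}. Points coinciding with the center (n undefined) are
#' skipped; M stays the full point count.
#'
#' @param x,y point coordinates, micrometres (raster frame).
#' @param fx,fy force components at the points, Pa.
#' @param center length-2 center \eqn{x_0}.
#' @return Symmetric 2x2 matrix, Pa.
#' @seealso [stressTensor()] for the gridded-field interface.
#' @export
stressTensorPoints <- function(x, y, fx, fy, center) {
  M <- length(x)
  rx <- x - center[1]; ry <- y - center[2]
  rn <- sqrt(rx^2 + ry^2)
  keep <- rn > 0
  if (!any(keep)) wfmStop("all points coincide with the center")
  nx <- rx[keep] / rn[keep]; ny <- ry[keep] / rn[keep]
  fx <- fx[keep]; fy <- fy[keep]
  Sxx <- sum(nx * fx) / M
  Syy <- sum(ny * fy) / M
  Sxy <- sum(ny * fx + nx * fy) / (2 * M)
  matrix(c(Sxx, Sxy, Sxy, Syy), 2, 2)
}

#' Contractile stress tensor of a traction field
#'
#' Evaluates [stressTensorPoints()] over all grid nodes of a traction
#' field. The center defaults to the image center
#' \eqn{x_0 = ((n_x-1)/2, (n_y-1)/2) \cdot \mathrm{pixelSize}}.
#'
#' @param traction a \linkS4class{VectorField2D} in Pa.
#' @param center optional length-2 center, micrometres.
#' @return Symmetric 2x2 matrix, Pa.
#' @export
stressTensor <- function(traction, center = NULL) {
  stopifnot(is(traction, "VectorField2D"))
  g <- traction@grid
  if (is.null(center))
    center <- c((g@nx - 1) / 2, (g@ny - 1) / 2) * g@pixelSize
  co <- nodeCoords(g)
  stressTensorPoints(as.vector(co$x), as.vector(co$y),
                     as.vector(traction@compX), as.vector(traction@compY),
                     center)
}

#' Principal traction direction, magnitude and isotropy
#'
#' Diagonalizes the stress tensor. The principal traction \code{fP} is the
#' eigenvalue of largest absolute value (negative = contractile); its
#' eigenvector gives the principal angle \code{phiS}, reported in degrees
#' counter-clockwise from +x in the y-up physical frame and folded into
#' [0, 180). Isotropy is \eqn{I = |f_P / f_P^{min}|}, undefined (NA) when
#' the second eigenvalue is negligible. Near-equal eigenvalues set the
#' degeneracy flag and report phiS = 0.
#'
#' @param S symmetric 2x2 matrix, Pa.
#' @param tol relative tolerance for the undefined/degenerate checks.
#' @return List with \code{phiS} (degrees), \code{fP}, \code{fPMin} (Pa),
#'   \code{isotropy} and \code{degenerate}.
#' @export
principalTraction <- function(S, tol = 1e-9) {
  stopifnot(is.matrix(S), all(dim(S) == 2))
  if (abs(S[1, 2] - S[2, 1]) > 1e-8 * (max(abs(S)) + 1e-300))
    wfmStop("stress tensor must be symmetric")
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ix <- which.max(abs(e$values))
  fP <- e$values[ix]; fPMin <- e$values[-ix]
  v <- e$vectors[, ix]
  degenerate <- isTRUE(abs(fP - fPMin) < 1e-9 * max(abs(fP), 1e-300))
  phiS <- if (degenerate) 0 else foldAxial(-atan2(v[2], v[1]) * 180 / pi)
  iso <- if (abs(fPMin) < tol * abs(fP)) NA_real_ else abs(fP / fPMin)
  list(phiS = phiS, fP = fP, fPMin = fPMin, isotropy = iso,
       degenerate = degenerate)
}

#' Full traction statistics of one field
#'
#' Convenience wrapper combining [meanTraction()], [stressTensor()] and
#' [principalTraction()] into a \linkS4class{StressSummary}.
#'
#' @param traction a \linkS4class{VectorField2D} in Pa.
#' @param center optional stress-tensor center, micrometres.
#' @return A \linkS4class{StressSummary}.
#' @export
stressSummary <- function(traction, center = NULL) {
  S <- stressTensor(traction, center)
  p <- principalTraction(S)
  new("StressSummary", meanTraction = meanTraction(traction), S = S,
      phiS = p$phiS, fP = p$fP, fPMin = p$fPMin, isotropy = p$isotropy,
      degenerate = p$degenerate)
}

## ---------------------------------------------------------------------------
## Skeleton, direction, topology
## ---------------------------------------------------------------------------

## Zhang-Suen morphological thinning to a 1-px skeleton
thinZhangSuen <- function(m) {
  m <- (m != 0) * 1L
  pad <- function(x) {
    out <- matrix(0L, nrow(x) + 2L, ncol(x) + 2L)
    out[2:(nrow(x) + 1L), 2:(ncol(x) + 1L)] <- x
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- pad(m)
      nr <- nrow(m); nc <- ncol(m)
      ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
      P2 <- p[ri - 1L, ci]; P3 <- p[ri - 1L, ci + 1L]; P4 <- p[ri, ci + 1L]
      P5 <- p[ri + 1L, ci + 1L]; P6 <- p[ri + 1L, ci]
      P7 <- p[ri + 1L, ci - 1L]; P8 <- p[ri, ci - 1L]; P9 <- p[ri - 1L, ci - 1L]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (phase == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

#' Wrinkle length by skeletonization
#'
#' Thins the wrinkle mask to a one-pixel-wide skeleton (Zhang-Suen
#' morphological thinning) and counts skeleton pixels; masks already one
#' pixel wide are unchanged.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return List with \code{lengthPx} (skeleton pixel count),
#'   \code{lengthUm} (count times pixel size) and \code{skeleton}
#'   (a \linkS4class{BinaryMask}).
#' @export
wrinkleLength <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  sk <- thinZhangSuen(mask@values)
  list(lengthPx = sum(sk), lengthUm = sum(sk) * mask@grid@pixelSize,
       skeleton = BinaryMask(sk, pixelSize = mask@grid@pixelSize))
}

#' Principal wrinkle direction from the 2D power spectrum
#'
#' Applies a Hann window, takes the 2D FFT, masks the DC region (radius
#' below \code{kMin} cycles per image), accumulates spectral power in 2-degree
#' angular bins over the half-plane, and reports the direction perpendicular
#' to the strongest spectral direction, folded into [0, 180) in the y-up
#' physical frame. Returns NA (undefined flag) for masks with fewer than 10
#' foreground pixels or for isotropic spectra (max/median bin power below
#' \code{anisotropyMin}).
#'
#' @param image a \linkS4class{ScalarImage} or \linkS4class{BinaryMask}
#'   of the wrinkles.
#' @param binWidth angular bin width, degrees.
#' @param kMin masked low-frequency radius, cycles per image.
#' @param anisotropyMin minimal max/median bin-power ratio.
#' @return Wrinkle principal angle phiW in degrees, or NA.
#' @export
wrinkleDirectionFFT <- function(image, binWidth = 2, kMin = 2,
                                anisotropyMin = 1.5) {
  stopifnot(is(image, "ScalarImage"))
  v <- image@values
  if (is(image, "BinaryMask") && sum(v) < 10) return(NA_real_)
  ny <- nrow(v); nx <- ncol(v)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  w <- outer(hann(ny), hann(nx))
  F <- fft2((v - mean(v)) * w)
  P <- Mod(F)^2
  fx <- matrix(fftFreq(nx) * nx, ny, nx, byrow = TRUE)
  fy <- matrix(fftFreq(ny) * ny, ny, nx)
  kc <- sqrt(fx^2 + fy^2)
  keep <- kc >= kMin
  ## physical angle of the wavevector (y-flip: raster row frequency points
  ## down); axial fold into [0, 180)
  ang <- foldAxial(atan2(-fy, fx) * 180 / pi)
  bins <- floor(ang[keep] / binWidth)
  ## mean power per bin: the k-lattice samples angles non-uniformly, so
  ## raw bin sums would be biased toward the densely sampled directions
  pow <- tapply(P[keep], bins, mean)
  full <- rep(0, ceiling(180 / binWidth))
  full[as.integer(names(pow)) + 1L] <- pow
  if (max(full) < anisotropyMin * max(stats::median(full),
                                      .Machine$double.xmin))
    return(NA_real_)
  kDir <- (which.max(full) - 1L) * binWidth + binWidth / 2
  foldAxial(kDir + 90)
}

#' Axial difference between two principal angles
#'
#' Both inputs are axial quantities (defined modulo 180 degrees); the
#' difference is the smaller of the two wrap directions and lies in
#' [0, 90]. NA inputs propagate.
#'
#' @param phiW,phiS angles in degrees.
#' @return Difference in degrees in [0, 90], or NA.
#' @export
angleDifference <- function(phiW, phiS) {
  d <- abs(foldAxial(phiW) - foldAxial(phiS))
  pmin(d, 180 - d)
}

## 8-connected labeling: 4-connected bwlabel plus union-find merge of
## labels that touch diagonally
labelComponents8 <- function(m) {
  lab <- EBImage::bwlabel(m)
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-1, -1]; b1 <- lab[-nr, -nc]       # down-right diagonal
  a2 <- lab[-1, -nc]; b2 <- lab[-nr, -1]       # down-left diagonal
  pairs <- rbind(cbind(a1[a1 > 0 & b1 > 0 & a1 != b1],
                       b1[a1 > 0 & b1 > 0 & a1 != b1]),
                 cbind(a2[a2 > 0 & b2 > 0 & a2 != b2],
                       b2[a2 > 0 & b2 > 0 & a2 != b2]))
  if (nrow(pairs))apply(unique(pairs), 1, function(p) unite(p[1], p[2]))
  roots <- vapply(seq_len(n), findRoot, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Wrinkle topology: clustered or dispersed
#'
#' Counts 8-connected wrinkle regions with at least \code{minRegionPx}
#' pixels. A single region (or none) is labeled \code{"clustered"},
#' several regions \code{"dispersed"}.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param minRegionPx minimum region area in pixels (default 20).
#' @return List with \code{nComponents} and \code{label}.
#' @export
wrinkleTopology <- function(mask, minRegionPx = 20L) {
  stopifnot(is(mask, "BinaryMask"))
  lab <- labelComponents8(mask@values)
  sizes <- tabulate(lab[lab > 0])
  n <- sum(sizes >= minRegionPx)
  list(nComponents = as.integer(n),
       label = if (n <= 1) "clustered" else "dispersed")
}

#' Full wrinkle geometry of one mask
#'
#' Convenience wrapper combining [wrinkleLength()],
#' [wrinkleDirectionFFT()] and [wrinkleTopology()] into a
#' \linkS4class{WrinkleSummary}.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param minRegionPx minimum region area for the topology count.
#' @return A \linkS4class{WrinkleSummary}.
#' @export
wrinkleSummary <- function(mask, minRegionPx = 20L) {
  len <- wrinkleLength(mask)
  topo <- wrinkleTopology(mask, minRegionPx)
  new("WrinkleSummary", lengthPx = len$lengthPx, lengthUm = len$lengthUm,
      phiW = wrinkleDirectionFFT(mask),
      nComponents = topo$nComponents, topologyLabel = topo$label)
}

#' Cell area and roundness
#'
#' Area is the foreground pixel count times the squared pixel size.
#' Roundness is \eqn{4\pi A / P^2} with the perimeter estimated from the
#' count of 4-neighbour foreground/background edges scaled by \eqn{\pi/4}
#' (exact for digitized disks), clamped to (0, 1].
#'
#' @param cellMask a \linkS4class{BinaryMask} with a single foreground
#'   component.
#' @return List with \code{areaUm2} and \code{roundness}.
#' @export
cellMorphometrics <- function(cellMask) {
  stopifnot(is(cellMask, "BinaryMask"))
  v <- cellMask@values
  if (sum(v) == 0) wfmStop("empty cell mask")
  lab <- labelComponents8(v)
  if (max(lab) != 1L)
    wfmStop(sprintf("cell mask must contain one component, found %d",
                    max(lab)))
  areaPx <- sum(v)
  nr <- nrow(v); nc <- ncol(v)
  pz <- rbind(0, v); pd <- rbind(v, 0)
  pl <- cbind(0, v); pr <- cbind(v, 0)
  edges <- sum(pz != pd) + sum(pl != pr)
  per <- edges * pi / 4
  ps <- cellMask@grid@pixelSize
  list(areaUm2 = areaPx * ps^2,
       roundness = min(4 * pi * areaPx / per^2, 1))
}
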