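test_that("arctangent codec matches direct evaluation and is odd", {
  p <- CodecParams()
  expect_equal(encodeForce(0, p), 127.5)
  expect_equal(encodeForce(50, p), 81.2 * pi / 4 + 127.5)
  expect_equal(encodeForce(50, p), 191.28, tolerance = 1e-4)
  expect_equal(encodeForce(-50, p), 127.5 - 81.2 * pi / 4)
  ## odd about (0, Imid), strictly increasing
  f <- seq(-400, 400, by = 7)
  expect_equal(encodeForce(f, p) - 127.5, -(encodeForce(-f, p) - 127.5))
  expect_true(all(diff(encodeForce(f, p)) > 0))
})

test_that("decode is the exact inverse of the unquantized encoder", {
  p <- CodecParams()
  f <- seq(-500, 500, length.out = 2001)
  expect_lt(max(abs(decodeForce(encodeForce(f, p), p) - f)), 1e-9)
  expect_equal(decodeForce(127.5, p), 0)
  ## with a = 81.2 the asymptotes sit just outside the 8-bit range
  expect_error(decodeForce(127.5 - 81.2 * pi / 2, p), "saturated")
  expect_error(decodeForce(127.5 + 81.2 * pi / 2, p), "saturated")
  expect_error(decodeForce(300, p), "saturated")
})

test_that("8-bit round-trip error obeys the local-slope bound", {
  p <- CodecParams()
  ## quantization step 1 over local slope dI/df = a*b/(b^2+f^2);
  ## max decode error is 0.5 * (1 + (f/b)^2) * b / a
  for (f in c(0, 25, -70, 120, 200, -200, 350)) {
    q <- encodeForce(f, p, quantize = TRUE)
    bound <- 0.5 * (1 + (f / p@b)^2) * p@b / p@a
    expect_lte(abs(decodeForce(q, p) - f), bound * 1.001)
  }
  ## the spec's worked bound at 200 Pa
  expect_equal(0.5 * (1 + (200 / 50)^2) * 50 / 81.2, 5.234, tolerance = 1e-3)
  ## quantized values clamp to [0, 255]
  expect_equal(encodeForce(1e9, p, quantize = TRUE), 255)
  expect_equal(encodeForce(-1e9, p, quantize = TRUE), 0)
})

test_that("axis-split rotation builds equivariant single-axis pairs", {
  n <- 26
  tr <- dipoleTraction(n = n, axisDeg = 0)
  img <- ScalarImage(matrix(seq_len(n * n), n, n),
                     pixelSize = pixelSize(tr))
  pairs <- axisSplitRotate(img, tr)
  expect_length(pairs, 2)
  ## pure x-dipole: pair 2's force map is pair 1's map under the rotation
  m1 <- pixelValues(pairs[[1]]$forceMap)
  m2 <- pixelValues(pairs[[2]]$forceMap)
  r1 <- wrinklefm:::rotate90Matrix(m1, 1L)
  ## rotated field x-component = original fy = 0 here, but the rotated
  ## map of the x-dipole contains the same values transported by the
  ## rotation with the component swap; verify via the field rotation
  trR <- wrinklefm:::rotate90Field(tr, 1L)
  expect_equal(m2, encodeForce(compX(trR), CodecParams()))
  ## four rotations recover the original pair exactly
  cur <- list(image = img, traction = tr)
  for (k in 1:4) {
    cur$image <- ScalarImage(wrinklefm:::rotate90Matrix(pixelValues(cur$image)),
                             pixelSize = pixelSize(cur$image))
    cur$traction <- wrinklefm:::rotate90Field(cur$traction)
  }
  expect_equal(pixelValues(cur$image), pixelValues(img))
  expect_equal(compX(cur$traction), compX(tr))
  expect_equal(compY(cur$traction), compY(tr))
  ## zero traction encodes to uniform mid-gray in both pairs
  z <- VectorField2D(matrix(0, n, n), matrix(0, n, n),
                     pixelSize = pixelSize(tr), units = "Pa")
  pz <- axisSplitRotate(img, z)
  expect_true(all(pixelValues(pz[[1]]$forceMap) == 127.5))
  expect_true(all(pixelValues(pz[[2]]$forceMap) == 127.5))
  ## non-square input rejected
  expect_error(axisSplitRotate(ScalarImage(matrix(0, 4, 6)), z), "square")
})

test_that("weighted magnitude error reproduces the hand-computed case", {
  mk <- function(m1, m2) VectorField2D(matrix(c(m1, m2, 0, 0), 2, 2),
                                       matrix(0, 2, 2), units = "Pa")
  ## M = 2 worked example embedded in a 2x2 grid with two zero nodes:
  ## reduced form sum|df| / (M fbar) with M = 4, fbar = 150/4
  pred <- mk(110, 40); true <- mk(100, 50)
  expect_equal(forceMagnitudeError(pred, true), (10 + 10) / (4 * 150 / 4))
  expect_equal(forceMagnitudeError(pred, true), 0.13333, tolerance = 1e-4)
  expect_equal(forceMagnitudeError(true, true), 0)
  ## uniform scaling by (1+c) gives error exactly c
  tr <- dipoleTraction()
  sc <- rescalePrediction(tr, 1, 1.17)
  expect_equal(forceMagnitudeError(sc, tr), 0.17)
  ## scale-free in the common factor
  expect_equal(forceMagnitudeError(rescalePrediction(sc, 1, 3),
                                   rescalePrediction(tr, 1, 3)), 0.17)
  ## zero-magnitude true nodes are handled without division by zero
  expect_true(is.finite(forceMagnitudeError(pred, mk(100, 0))))
})

test_that("reduced magnitude error equals the literal weighted form", {
  set.seed(11)
  n <- 8
  mkpos <- function() matrix(runif(n * n, 10, 100), n, n)
  true <- VectorField2D(mkpos(), mkpos(), units = "Pa")
  pred <- VectorField2D(mkpos(), mkpos(), units = "Pa")
  mt <- fieldMagnitude(true); mp <- fieldMagnitude(pred)
  fbar <- mean(mt)
  literal <- mean(abs(mp - mt) / mt * (mt / fbar))
  expect_equal(forceMagnitudeError(pred, true), literal)
})

test_that("weighted angle error reproduces the hand-computed case", {
  ## two nodes with angle errors 10 and 20 deg, magnitudes 100 and 50,
  ## embedded with two zero nodes: weights scale by fbar = 150/4
  a1 <- 10 * pi / 180; a2 <- 20 * pi / 180
  true <- VectorField2D(matrix(c(100, 50, 0, 0), 2, 2),
                        matrix(0, 2, 2), units = "Pa")
  pred <- VectorField2D(matrix(c(100 * cos(a1), 50 * cos(a2), 0, 0), 2, 2),
                        matrix(c(100 * sin(a1), 50 * sin(a2), 0, 0), 2, 2),
                        units = "Pa")
  expect_equal(forceAngleError(pred, true),
               (10 * 100 + 20 * 50) / (4 * 150 / 4), tolerance = 1e-9)
  expect_equal(forceAngleError(pred, true), 13.333, tolerance = 1e-3)
  expect_equal(forceAngleError(true, true), 0)
})

test_that("angle differences wrap into [0, 180]", {
  ## a raw 350-degree difference contributes 10 after wrapping; oracle by
  ## brute force over +-360 shifts
  th <- 175 * pi / 180; th2 <- -175 * pi / 180
  true <- VectorField2D(matrix(cos(th), 2, 2), matrix(sin(th), 2, 2),
                        units = "Pa")
  pred <- VectorField2D(matrix(cos(th2), 2, 2), matrix(sin(th2), 2, 2),
                        units = "Pa")
  raw <- (th2 - th) * 180 / pi
  oracle <- min(abs(raw + c(-360, 0, 360)))
  expect_equal(forceAngleError(pred, true), oracle, tolerance = 1e-9)
  expect_equal(forceAngleError(pred, true), 10, tolerance = 1e-9)
  ## unwrapped mode reports the principal-value difference instead
  expect_gt(forceAngleError(pred, true, wrap = FALSE), 300)
})

test_that("metrics are invariant under global rotation of both fields", {
  tr <- dipoleTraction(axisDeg = 20, tilt = 40)
  set.seed(5)
  noise <- VectorField2D(matrix(rnorm(26^2, 0, 15), 26, 26),
                         matrix(rnorm(26^2, 0, 15), 26, 26),
                         pixelSize = 3.44, units = "Pa")
  pred <- VectorField2D(compX(tr) + compX(noise), compY(tr) + compY(noise),
                        pixelSize = 3.44, units = "Pa")
  rot <- function(f) wrinklefm:::rotate90Field(f, 1L)
  expect_equal(forceMagnitudeError(rot(pred), rot(tr)),
               forceMagnitudeError(pred, tr))
  expect_equal(forceAngleError(rot(pred), rot(tr)),
               forceAngleError(pred, tr), tolerance = 1e-12)
})

test_that("pooled correlation behaves as a Pearson coefficient", {
  tr <- dipoleTraction()
  expect_equal(correlationR(tr, tr), 1)
  neg <- rescalePrediction(tr, 1, 1)
  neg@compX <- -neg@compX; neg@compY <- -neg@compY
  expect_equal(correlationR(neg, tr), -1)
  ## R increases monotonically as noise shrinks
  set.seed(6)
  base <- matrix(rnorm(26^2), 26, 26)
  rs <- vapply(c(2, 1, 0.5, 0.2, 0.05), function(s) {
    pred <- VectorField2D(compX(tr) + s * 100 * base,
                          compY(tr) + s * 100 * base,
                          pixelSize = 3.44, units = "Pa")
    correlationR(pred, tr)
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[5], 0.95)
  ## degenerate inputs flagged
  z <- VectorField2D(matrix(0, 4, 4), matrix(0, 4, 4), units = "Pa")
  expect_true(is.na(correlationR(z, z)))
  expect_true(is.na(forceMagnitudeError(z, z)))
})
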