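sub <- ElasticSubstrate()

test_that("Green's tensor matches direct evaluation and its symmetries", {
  G <- greensTensor(c(1, 0), sub)
  expect_equal(G[1, 2], 0)
  expect_equal(G[2, 1], 0)
  expect_equal(G[1, 1], (1 + 0.5) / (pi * 5400), tolerance = 1e-12)
  expect_equal(G[1, 1], 8.842e-5, tolerance = 1e-3)
  ## G(r) = G(-r), symmetric, for random directions and general nu
  set.seed(2)
  s2 <- ElasticSubstrate(E = 2100, nu = 0.33)
  for (i in 1:20) {
    r <- rnorm(2)
    G1 <- greensTensor(r, s2)
    expect_equal(G1, greensTensor(-r, s2))
    expect_equal(G1[1, 2], G1[2, 1])
  }
  expect_error(greensTensor(c(0, 0), sub), "singular")
})

test_that("spectral kernel is zero at k = 0 and decays as 1/|k|", {
  kern <- fourierKernel(Grid2D(64, 64, 3.44), sub)
  expect_equal(kern$Gxx[1, 1], 0)
  expect_equal(kern$Gxy[1, 1], 0)
  ## along the kx ray, Gxx * k approaches a constant
  ray <- kern$Gxx[1, 2:32] * abs(kern$kx[1, 2:32])
  expect_lt(max(abs(ray / ray[1] - 1)), 1e-9)
  ## k-dependence is exactly 1/k on the ray: doubling k halves the entry
  expect_equal(kern$Gxx[1, 3] / kern$Gxx[1, 5], 2, tolerance = 1e-12)
})

test_that("spectral forward model agrees with cell-averaged direct summation", {
  ## 8x8 smooth balanced traction; free-space oracle: Eq.-style direct sum
  ## with the Green tensor averaged over each source cell (midpoint
  ## quadrature); kernel route embedded x4 to suppress wrap-around
  n <- 8; ps <- 3.44
  tr <- dipoleTraction(n = n, ps = ps, mag = 100, sep = 2, sigma = 1.5,
                       tilt = 30)
  tx <- compX(tr); ty <- compY(tr)
  ## vectorized independent oracle (Green formula inlined)
  nq <- 16
  qs <- ((seq_len(nq) - 0.5) / nq - 0.5) * ps
  qq <- expand.grid(qx = qs, qy = qs)
  E <- sub@E; nu <- sub@nu
  cellG <- function(rx, ry) {
    gx <- rx + qq$qx; gy <- ry + qq$qy
    r2 <- gx^2 + gy^2
    keep <- r2 > 1e-18
    pref <- (1 + nu) / (pi * E * r2[keep]^1.5)
    c(mean(pref * ((1 - nu) * r2[keep] + nu * gx[keep]^2)),
      mean(pref * nu * gx[keep] * gy[keep]),
      mean(pref * ((1 - nu) * r2[keep] + nu * gy[keep]^2)))
  }
  offs <- expand.grid(di = -(n - 1):(n - 1), dj = -(n - 1):(n - 1))
  Gtab <- t(mapply(function(di, dj) cellG(dj * ps, di * ps),
                   offs$di, offs$dj))
  key <- function(di, dj) (di + n) + (2 * n - 1) * (dj + n - 1)
  ux <- matrix(0, n, n); uy <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    k <- key(i - (1:n), j - rep(1:n, each = n))
    G <- Gtab[match(k, key(offs$di, offs$dj)), , drop = FALSE]
    ux[i, j] <- sum((G[, 1] * as.vector(tx) + G[, 2] * as.vector(ty))) * ps^2
    uy[i, j] <- sum((G[, 2] * as.vector(tx) + G[, 3] * as.vector(ty))) * ps^2
  }
  ## kernel route: embed in 32x32, periodic
  big <- matrix(0, 4 * n, 4 * n)
  bx <- big; bx[1:n, 1:n] <- tx
  by <- big; by[1:n, 1:n] <- ty
  uf <- forwardDisplacement(VectorField2D(bx, by, ps, "Pa"), sub,
                            "periodic")
  rel <- sqrt(sum((compX(uf)[1:n, 1:n] - ux)^2 +
                    (compY(uf)[1:n, 1:n] - uy)^2) / sum(ux^2 + uy^2))
  expect_lt(rel, 0.02)
})

test_that("forward displacement is linear and points toward a contraction", {
  tr <- dipoleTraction()
  z <- VectorField2D(matrix(0, 26, 26), matrix(0, 26, 26),
                     pixelSize = 3.44, units = "Pa")
  expect_equal(max(abs(compX(forwardDisplacement(z, sub)))), 0)
  u1 <- forwardDisplacement(tr, sub, "periodic")
  u2 <- forwardDisplacement(rescalePrediction(tr, 1, 2), sub, "periodic")
  expect_equal(compX(u2), 2 * compX(u1), tolerance = 1e-12)
  ## inward x-dipole: displacement on the left half points right (+x)
  ## toward the dipole center and vice versa
  left <- compX(u1)[13, 5]; right <- compX(u1)[13, 22]
  expect_gt(left, 0)
  expect_lt(right, 0)
})

test_that("periodic FTTC at lambda 0 inverts the forward model exactly", {
  for (seed in 1:50) {
    tr <- randomBalancedTraction(seed = seed)
    u <- forwardDisplacement(tr, sub, "periodic")
    t2 <- solveTractionFTTC(u, sub, TikhonovConfig(0, "periodic"))
    expect_lt(relL2(t2, tr), 1e-6)
  }
})

test_that("the recovered traction always carries zero net force", {
  set.seed(3)
  for (seed in c(4, 9)) {
    tr <- randomBalancedTraction(seed = seed)
    u <- forwardDisplacement(tr, sub, "padded")
    un <- VectorField2D(compX(u) + rnorm(676, 0, 0.01),
                        compY(u) + rnorm(676, 0, 0.01),
                        pixelSize = 3.44, units = "um")
    t2 <- solveTractionFTTC(un, sub, TikhonovConfig(1e-4, "padded"))
    expect_lt(abs(sum(compX(t2))), 1e-9 * sum(abs(compX(t2))))
    expect_lt(abs(sum(compY(t2))), 1e-9 * sum(abs(compY(t2))))
  }
})

test_that("huge regularization and zero data drive the solution to zero", {
  tr <- dipoleTraction()
  u <- forwardDisplacement(tr, sub, "periodic")
  kern <- fourierKernel(gridGeometry(u), sub)
  big <- 1e6 * max(abs(kern$Gxx))
  tBig <- solveTractionFTTC(u, sub, TikhonovConfig(big, "periodic"))
  expect_lt(max(abs(compX(tBig))), 1e-9 * max(abs(compX(tr))))
  z <- VectorField2D(matrix(0, 26, 26), matrix(0, 26, 26),
                     pixelSize = 3.44, units = "um")
  for (l in c(0, 1e-5)) {
    tz <- solveTractionFTTC(z, sub, TikhonovConfig(l, "periodic"))
    expect_equal(max(abs(compX(tz))), 0)
  }
})

test_that("rotating the traction by 90 degrees rotates the displacement", {
  tr <- randomBalancedTraction(seed = 7)
  u <- forwardDisplacement(tr, sub, "periodic")
  uR <- forwardDisplacement(wrinklefm:::rotate90Field(tr), sub, "periodic")
  expect_equal(compX(uR), compX(wrinklefm:::rotate90Field(u)),
               tolerance = 1e-10)
  expect_equal(compY(uR), compY(wrinklefm:::rotate90Field(u)),
               tolerance = 1e-10)
})

test_that("L-curve scan is monotone and finds a sound parameter", {
  tr <- dipoleTraction()
  u <- forwardDisplacement(tr, sub, "periodic")
  ## noiseless: residual floor, lambda in the bottom decade of the grid
  sel <- selectLambdaLCurve(u, sub, mode = "periodic")
  lc <- sel$lcurve
  expect_true(all(diff(lc@residualNorms) >= -1e-7 * max(lc@residualNorms)))
  expect_true(all(diff(lc@solutionNorms) <= 1e-7 * max(lc@solutionNorms)))
  expect_lt(sel$lambda, min(lc@lambdas) * 10)
  expect_lt(relL2(solveTractionFTTC(u, sub,
                                    TikhonovConfig(sel$lambda, "periodic")),
                  tr), 0.02)
  ## 5% noise: reconstruction within 2x of the best achievable on the grid
  set.seed(8)
  sdu <- 0.05 * sqrt(mean(compX(u)^2 + compY(u)^2))
  un <- VectorField2D(compX(u) + rnorm(676, 0, sdu),
                      compY(u) + rnorm(676, 0, sdu),
                      pixelSize = 3.44, units = "um")
  sel2 <- selectLambdaLCurve(un, sub, mode = "periodic")
  errs <- vapply(sel2$lcurve@lambdas, function(l)
    relL2(solveTractionFTTC(un, sub, TikhonovConfig(l, "periodic")), tr),
    numeric(1))
  expect_lte(errs[sel2$lcurve@chosenIndex], 2 * min(errs))
  expect_error(selectLambdaLCurve(un, sub, lambdaGrid = c(1, 2, 3)),
               "decades")
})

test_that("PIV recovers trivial and integer-shift displacements", {
  set.seed(10)
  img <- ScalarImage(matrix(runif(128 * 128, 0, 255), 128, 128),
                     pixelSize = 0.5)
  ## identical images: zero field
  pv0 <- pivDisplacement(img, img, 32, 16, passes = 1)
  expect_equal(max(abs(compX(pv0)), abs(compY(pv0))), 0)
  ## cyclic shift by (3, 0) px: uniform field of 3 * pixelSize
  sh <- pixelValues(img)[, c(126:128, 1:125)]
  pvS <- pivDisplacement(img, ScalarImage(sh, pixelSize = 0.5), 32, 16,
                         passes = 1)
  ## uniform (3 px, 0) field up to sub-pixel fit noise on random texture
  ## (white-noise autocorrelation gives a delta-like peak, so the
  ## three-point fit carries ~0.1 px of noise)
  expect_lt(max(abs(compX(pvS) - 3 * 0.5)), 0.15 * 0.5)
  expect_lt(max(abs(compY(pvS))), 0.15 * 0.5)
  expect_lt(abs(mean(compX(pvS)) - 1.5), 0.02 * 0.5)
})

test_that("PIV resolves sub-pixel shifts of a rendered bead image", {
  set.seed(12)
  n <- 256
  nb <- 500
  bx <- runif(nb, 1, n); by <- runif(nb, 1, n)
  amp <- runif(nb, 140, 220)
  ref <- wrinklefm:::renderSpots(n, n, by, bx, amp, 1.5)
  def <- wrinklefm:::renderSpots(n, n, by, bx + 2.5, amp, 1.5)
  pv <- pivDisplacement(ScalarImage(ref), ScalarImage(def), 32, 16)
  dxPx <- compX(pv)  # pixelSize 1
  expect_lt(abs(mean(dxPx) - 2.5), 0.2)
  expect_lt(sqrt(mean((dxPx - 2.5)^2)), 0.15)
  expect_lt(sqrt(mean(compY(pv)^2)), 0.15)
})

test_that("windows without texture are flagged NaN", {
  set.seed(13)
  base <- matrix(0, 96, 96)
  base[1:48, ] <- matrix(runif(48 * 96, 0, 255), 48, 96)
  img <- ScalarImage(base)
  pv <- pivDisplacement(img, img, 32, 32, passes = 1)
  expect_true(all(is.na(compX(pv)[3, ])))   # blank lower band
  expect_false(anyNA(compX(pv)[1, ]))
})
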