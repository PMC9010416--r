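test_that("mean traction is the average per-node vector norm", {
  n <- 4
  f <- VectorField2D(matrix(30, n, n), matrix(40, n, n), units = "Pa")
  expect_equal(meanTraction(f), 50)
  f2 <- VectorField2D(matrix(c(100, rep(0, 15)), n, n), matrix(0, n, n),
                      units = "Pa")
  expect_equal(meanTraction(f2), 100 / 16)
  ## independent loop oracle on a random field
  set.seed(21)
  fr <- VectorField2D(matrix(rnorm(n^2), n, n), matrix(rnorm(n^2), n, n),
                      units = "Pa")
  acc <- 0
  for (i in 1:n) for (j in 1:n)
    acc <- acc + sqrt(compX(fr)[i, j]^2 + compY(fr)[i, j]^2)
  expect_equal(meanTraction(fr), acc / n^2)
})

test_that("stress tensor reproduces hand-evaluated dipole sums", {
  ## two points at (+-d, 0) pulling inward with force F: S_xx = -F
  S <- stressTensorPoints(x = c(-5, 5), y = c(0, 0), fx = c(3, -3),
                          fy = c(0, 0), center = c(0, 0))
  expect_equal(S, matrix(c(-3, 0, 0, 0), 2, 2))
  ## superposed y-dipole of weaker magnitude: S = diag(-F, -G)
  S2 <- stressTensorPoints(x = c(-5, 5, 0, 0), y = c(0, 0, -4, 4),
                           fx = c(6, -6, 0, 0), fy = c(0, 0, 2, -2),
                           center = c(0, 0))
  expect_equal(S2, matrix(c(-3, 0, 0, -1), 2, 2))
  ## zero traction gives the zero tensor; symmetry and linearity in f
  z <- VectorField2D(matrix(0, 5, 5), matrix(0, 5, 5), units = "Pa")
  expect_equal(stressTensor(z), matrix(0, 2, 2))
  set.seed(22)
  a <- randomBalancedTraction(seed = 1); b <- randomBalancedTraction(seed = 2)
  Sa <- stressTensor(a); Sb <- stressTensor(b)
  ab <- VectorField2D(2 * compX(a) + compX(b), 2 * compY(a) + compY(b),
                      pixelSize = 3.44, units = "Pa")
  expect_equal(stressTensor(ab), 2 * Sa + Sb, tolerance = 1e-12)
  expect_equal(Sa, t(Sa))
  expect_error(stressTensorPoints(0, 0, 1, 1, center = c(0, 0)),
               "coincide")
})

test_that("principal traction extraction matches the analytic eigensystem", {
  p <- principalTraction(matrix(c(-7, 0, 0, 0), 2, 2))
  expect_equal(p$phiS, 0)
  expect_equal(p$fP, -7)
  expect_true(is.na(p$isotropy))
  ## radial contraction: isotropy 1, degenerate direction
  p2 <- principalTraction(diag(c(-5, -5)))
  expect_equal(p2$isotropy, 1)
  expect_true(p2$degenerate)
  expect_equal(p2$phiS, 0)
  ## rotating the tensor rotates the principal angle, eigenvalues fixed
  S0 <- diag(c(-6, -2))
  th <- 30 * pi / 180
  ## y-up physical rotation appears as R(-th) on raster-frame tensors
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  S30 <- R %*% S0 %*% t(R)
  p0 <- principalTraction(S0); p30 <- principalTraction(S30)
  expect_equal(angleDifference(p30$phiS, p0$phiS + 30), 0, tolerance = 1e-9)
  expect_equal(sort(c(p30$fP, p30$fPMin)), sort(c(p0$fP, p0$fPMin)))
  expect_equal(p30$isotropy, 3)
  expect_gte(p30$isotropy, 1)
  expect_error(principalTraction(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("principal angle is rotation-equivariant on random fields", {
  for (seed in c(31, 32, 33)) {
    tr <- sampleTraction(SyntheticCellSpec(seed = seed))
    p0 <- stressSummary(tr)
    p90 <- stressSummary(wrinklefm:::rotate90Field(tr))
    expect_equal(angleDifference(p90@phiS, p0@phiS + 90), 0,
                 tolerance = 1e-6)
    expect_equal(p90@fP, p0@fP, tolerance = 1e-12)
  }
})

test_that("skeleton length counts thinned pixels", {
  empty <- BinaryMask(matrix(0, 20, 20))
  expect_equal(wrinkleLength(empty)$lengthPx, 0)
  ## 50 x 3 horizontal bar thins to a ~50 px line (end effects allowed)
  bar <- matrix(0, 20, 60)
  bar[9:11, 6:55] <- 1
  wl <- wrinkleLength(BinaryMask(bar, pixelSize = 2))
  expect_gte(wl$lengthPx, 46)
  expect_lte(wl$lengthPx, 52)
  expect_equal(wl$lengthUm, wl$lengthPx * 2)
  ## a 1-px curve is its own skeleton (idempotence)
  thin <- matrix(0, 30, 30)
  thin[cbind(5:25, 5:25)] <- 1
  wt <- wrinkleLength(BinaryMask(thin))
  expect_equal(pixelValues(wt$skeleton), thin)
  expect_equal(wt$lengthPx, 21)
})

test_that("FFT direction finds stripe orientation and flags isotropy", {
  ## stripes varying along x (crests parallel to y): phi_w = 90
  expect_equal(wrinkleDirectionFFT(stripeMask(0)), 90, tolerance = 2)
  ## the same stripes rotated by 45 degrees (phase along raster (1,1))
  expect_equal(wrinkleDirectionFFT(stripeMask(45)), 45, tolerance = 2)
  expect_equal(wrinkleDirectionFFT(stripeMask(-45)), 135, tolerance = 2)
  expect_equal(wrinkleDirectionFFT(stripeMask(70)),
               foldAxialFixture(-70 + 90), tolerance = 2)
  ## white noise has no dominant direction
  set.seed(40)
  noise <- ScalarImage(matrix(runif(128^2), 128, 128))
  expect_true(is.na(wrinkleDirectionFFT(noise)))
  ## near-empty masks are undefined
  tiny <- matrix(0, 64, 64); tiny[30, 30:33] <- 1
  expect_true(is.na(wrinkleDirectionFFT(BinaryMask(tiny))))
})

test_that("axial angle difference folds into [0, 90]", {
  expect_equal(angleDifference(90, 0), 90)
  expect_equal(angleDifference(170, 10), 20)
  expect_equal(angleDifference(179, 1), 2)
  for (x in seq(0, 350, by = 37)) expect_equal(angleDifference(x, x), 0)
  ## brute-force oracle over representative shifts
  set.seed(41)
  for (i in 1:20) {
    a <- runif(1, 0, 360); b <- runif(1, 0, 360)
    cand <- abs(outer(a + c(-360, -180, 0, 180, 360), b, `-`))
    expect_equal(angleDifference(a, b), min(cand), tolerance = 1e-9)
  }
  expect_true(is.na(angleDifference(NA, 10)))
})

test_that("wrinkle topology separates clustered from dispersed masks", {
  one <- matrix(0, 50, 50); one[10:20, 10:30] <- 1
  t1 <- wrinkleTopology(BinaryMask(one))
  expect_equal(t1$nComponents, 1L)
  expect_equal(t1$label, "clustered")
  three <- matrix(0, 50, 60)
  three[5:10, 5:20] <- 1; three[20:25, 5:20] <- 1; three[35:40, 30:50] <- 1
  t3 <- wrinkleTopology(BinaryMask(three))
  expect_equal(t3$nComponents, 3L)
  expect_equal(t3$label, "dispersed")
  ## two bars bridged by a 1-px line are one 8-connected component
  ## (flood-fill oracle: the bridge connects everything)
  bridged <- matrix(0, 40, 40)
  bridged[5:10, 5:15] <- 1; bridged[25:30, 5:15] <- 1
  bridged[11:24, 10] <- 1
  tb <- wrinkleTopology(BinaryMask(bridged))
  expect_equal(tb$nComponents, 1L)
  expect_equal(tb$label, "clustered")
  ## diagonal contact counts as connected (8-connectivity)
  diag2 <- matrix(0, 30, 30)
  diag2[5:10, 5:10] <- 1; diag2[11:16, 11:16] <- 1
  expect_equal(wrinkleTopology(BinaryMask(diag2), minRegionPx = 10)$nComponents,
               1L)
  ## regions below the minimum area are ignored
  speck <- matrix(0, 30, 30); speck[2, 2] <- 1; speck[10:20, 10:20] <- 1
  expect_equal(wrinkleTopology(BinaryMask(speck))$nComponents, 1L)
})

test_that("cell morphometrics recover analytic area and roundness", {
  ## disk of radius 50 px
  n <- 128
  rows <- matrix(seq_len(n), n, n); cols <- t(rows)
  disk <- (rows - 64)^2 + (cols - 64)^2 <= 50^2
  m <- cellMorphometrics(BinaryMask(disk, pixelSize = 0.5))
  expect_equal(m$areaUm2, pi * 50^2 * 0.25, tolerance = 0.02)
  expect_gte(m$roundness, 0.95)
  ## 100 x 4 rectangle is far from round
  rect <- matrix(0, 20, 120); rect[9:12, 11:110] <- 1
  m2 <- cellMorphometrics(BinaryMask(rect))
  expect_lt(m2$roundness, 0.25)
  expect_equal(m2$areaUm2, 400)
  expect_error(cellMorphometrics(BinaryMask(matrix(0, 10, 10))), "empty")
  two <- matrix(0, 30, 30); two[2:5, 2:5] <- 1; two[20:25, 20:25] <- 1
  expect_error(cellMorphometrics(BinaryMask(two)), "one component")
})

test_that("summary wrappers assemble consistent objects", {
  tr <- sampleTraction(SyntheticCellSpec(seed = 77L))
  ss <- stressSummary(tr)
  expect_s4_class(ss, "StressSummary")
  expect_equal(ss@meanTraction, meanTraction(tr))
  expect_equal(ss@S, stressTensor(tr))
  expect_true(is.na(ss@isotropy) || ss@isotropy >= 1)
  wr <- renderWrinkles(tr, seed = 77L)
  ws <- wrinkleSummary(wr$mask)
  expect_s4_class(ws, "WrinkleSummary")
  expect_equal(ws@lengthPx, wrinkleLength(wr$mask)$lengthPx)
  expect_true(ws@topologyLabel %in% c("clustered", "dispersed"))
})
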