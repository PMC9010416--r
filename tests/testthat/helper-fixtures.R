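## Shared fixtures: small analytic fields and oracles built in code.

## balanced two-spot (dipole) traction field, smooth enough for the
## spectral model; axisDeg is the dipole axis in raster degrees
dipoleTraction <- function(n = 26, ps = 3.44, mag = 200, sep = 2.5,
                           sigma = 1.5, axisDeg = 0, tilt = 0) {
  co <- expand.grid(r = seq_len(n), c = seq_len(n))
  x <- (co$c - 1) * ps; y <- (co$r - 1) * ps
  ctr <- (n - 1) / 2 * ps
  th <- axisDeg * pi / 180
  dx <- cos(th) * sep * ps; dy <- sin(th) * sep * ps
  s2 <- 2 * (sigma * ps)^2
  w1 <- exp(-((x - (ctr - dx))^2 + (y - (ctr - dy))^2) / s2)
  w2 <- exp(-((x - (ctr + dx))^2 + (y - (ctr + dy))^2) / s2)
  fx <- mag * cos(th) * (w1 - w2) + tilt * (w1 + w2)
  fy <- mag * sin(th) * (w1 - w2)
  fx <- fx - mean(fx); fy <- fy - mean(fy)
  VectorField2D(matrix(fx, n, n), matrix(fy, n, n), pixelSize = ps,
                units = "Pa")
}

## random balanced band-limited traction (Gaussian-smoothed white noise)
randomBalancedTraction <- function(n = 26, ps = 3.44, seed = 1) {
  set.seed(seed)
  smooth <- function() {
    m <- matrix(stats::rnorm(n * n), n, n)
    m <- gaussBlurFixture(m, 1.5)
    m - mean(m)
  }
  VectorField2D(100 * smooth(), 100 * smooth(), pixelSize = ps,
                units = "Pa")
}

## small standalone Gaussian blur (periodic, via FFT) so fixtures do not
## depend on package internals
gaussBlurFixture <- function(m, sigma) {
  n1 <- nrow(m); n2 <- ncol(m)
  f1 <- c(seq_len(ceiling(n1 / 2)) - 1, seq_len(floor(n1 / 2)) - floor(n1 / 2) - 1) / n1
  f2 <- c(seq_len(ceiling(n2 / 2)) - 1, seq_len(floor(n2 / 2)) - floor(n2 / 2) - 1) / n2
  H <- exp(-2 * pi^2 * sigma^2 * outer(f1^2, f2^2, `+`))
  Re(stats::fft(stats::fft(m) * H, inverse = TRUE)) / (n1 * n2)
}

relL2 <- function(a, b) {
  sqrt(sum((compX(a) - compX(b))^2 + (compY(a) - compY(b))^2) /
         sum(compX(b)^2 + compY(b)^2))
}

## striped binary mask whose phase varies along raster direction thetaDeg
stripeMask <- function(thetaDeg, n = 128, wavelengthPx = 6.4, ps = 1) {
  th <- thetaDeg * pi / 180
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  ph <- 2 * pi / wavelengthPx * (cols * cos(th) + rows * sin(th))
  BinaryMask(cos(ph) > 0.3, pixelSize = ps)
}

## one shared desk-scale dataset for translator tests (built on first use)
translatorFixtureDir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      d <- file.path(tempdir(), "wfm-fixture-ds")
      if (!file.exists(file.path(d, "manifest.json")))
        buildDataset(6, SyntheticCellSpec(seed = 900L), d, nTest = 2L,
                     imageSize = 32L)
      dir <<- d
    }
    dir
  }
})

foldAxialFixture <- function(deg) deg %% 180
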