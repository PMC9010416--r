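## The image-to-force translator: U-Net-style generator, patch
## discriminator, adversarial + L1 objective, training loop, prediction.

genChannels <- function(config) {
  nd <- as.integer(log2(config@imageSize)) - 2L
  list(nd = nd, enc = config@ngf * pmin(2^(seq_len(nd) - 1L), 4L))
}

#' Build an untrained generator
#'
#' Encoder-decoder with skip connections: log2(size) - 2 stride-2
#' convolution blocks down to a bottleneck, mirrored nearest-neighbour
#' upsampling blocks with the symmetric encoder activation concatenated at
#' each scale, and a tanh output head rescaled to the 8-bit intensity
#' range by the prediction code. Weights are drawn N(0, 0.02) from R's
#' RNG (seed the session for reproducible init).
#'
#' @param config a \linkS4class{GANConfig}.
#' @return Parameter list (opaque; consumed by [trainTranslator()] and
#'   [predictTraction()]), with attribute \code{"nParams"}.
#' @export
buildGenerator <- function(config = GANConfig()) {
  ch <- genChannels(config)
  if (ch$nd < 2L) wfmStop("imageSize below the architecture minimum")
  enc <- list(); cin <- 1L
  for (i in seq_len(ch$nd)) {
    enc[[i]] <- list(conv = nnConvInit(4L, 4L, cin, ch$enc[i]),
                     inorm = if (i > 1L) nnInormInit(ch$enc[i]))
    cin <- ch$enc[i]
  }
  dec <- list()
  dIn <- ch$enc[ch$nd]
  for (j in seq_len(ch$nd - 1L)) {
    i <- ch$nd - j + 1L
    cout <- ch$enc[i - 1L]
    dec[[j]] <- list(conv = nnConvInit(3L, 3L, dIn, cout),
                     inorm = nnInormInit(cout))
    dIn <- 2L * cout  # concat with the skip activation
  }
  gen <- list(enc = enc, dec = dec,
              final = list(conv = nnConvInit(3L, 3L, dIn, 1L)))
  attr(gen, "nParams") <- sum(lengths(lapply(flattenParams(gen), c)))
  gen
}

#' Build an untrained patch discriminator
#'
#' Four convolution blocks (stride 2, 2, 1, 1) mapping the 2-channel
#' concatenation of input image and force image to a grid of patch
#' logits; each patch scores a local receptive field as real or fake
#' through a sigmoid.
#'
#' @param config a \linkS4class{GANConfig}.
#' @return Parameter list (opaque), with attribute \code{"nParams"}.
#' @export
buildDiscriminator <- function(config = GANConfig()) {
  ndf <- config@ndf
  chans <- c(2L, ndf, 2L * ndf, 4L * ndf, 1L)
  strides <- c(2L, 2L, 1L, 1L)
  blocks <- list()
  for (k in 1:4)
    blocks[[k]] <- list(conv = nnConvInit(4L, 4L, chans[k], chans[k + 1L]),
                        inorm = if (k %in% c(2L, 3L)) nnInormInit(chans[k + 1L]),
                        stride = strides[k])
  disc <- list(blocks = blocks)
  attr(disc, "nParams") <- sum(lengths(lapply(flattenParams(disc), c)))
  disc
}

## ---------------------------------------------------------------------------
## Forward / backward passes
## ---------------------------------------------------------------------------

genForward <- function(gen, x) {
  nd <- length(gen$enc)
  h <- vector("list", nd)
  caches <- list(enc = vector("list", nd), dec = vector("list", nd - 1L))
  cur <- asCube(x)
  for (i in seq_len(nd)) {
    cv <- nnConvFwd(cur, gen$enc[[i]]$conv, stride = 2L, pad = 1L)
    z <- cv$y; ino <- NULL
    if (!is.null(gen$enc[[i]]$inorm)) {
      ino <- nnInormFwd(z, gen$enc[[i]]$inorm)
      z <- ino$y
    }
    ac <- nnLReluFwd(z)
    caches$enc[[i]] <- list(cv = cv, ino = ino, ac = ac)
    h[[i]] <- ac$y
    cur <- ac$y
  }
  d <- h[[nd]]
  for (j in seq_len(nd - 1L)) {
    i <- nd - j + 1L
    up <- nnUp2Fwd(d)
    cv <- nnConvFwd(up, gen$dec[[j]]$conv, stride = 1L, pad = 1L)
    ino <- nnInormFwd(cv$y, gen$dec[[j]]$inorm)
    ac <- nnReluFwd(ino$y)
    caches$dec[[j]] <- list(cv = cv, ino = ino, ac = ac,
                            cSelf = dim(ac$y)[3])
    d <- nnConcat(ac$y, h[[i - 1L]])
  }
  up <- nnUp2Fwd(d)
  cv <- nnConvFwd(up, gen$final$conv, stride = 1L, pad = 1L)
  th <- nnTanhFwd(cv$y)
  caches$final <- list(cv = cv, th = th)
  list(y = th$y, caches = caches)
}

genBackward <- function(gen, caches, gy) {
  nd <- length(gen$enc)
  grads <- list(enc = vector("list", nd), dec = vector("list", nd - 1L))
  g <- nnTanhBwd(caches$final$th, asCube(gy))
  cb <- nnConvBwd(caches$final$cv, gen$final$conv, g, stride = 1L, pad = 1L)
  grads$final <- list(conv = list(W = cb$gW, b = cb$gb))
  gd <- nnUp2Bwd(cb$gx)
  gh <- vector("list", nd)  # skip gradients
  for (j in rev(seq_len(nd - 1L))) {
    i <- nd - j + 1L
    sp <- nnSplit(gd, caches$dec[[j]]$cSelf)
    gh[[i - 1L]] <- sp$b
    g <- nnReluBwd(caches$dec[[j]]$ac, sp$a)
    ib <- nnInormBwd(caches$dec[[j]]$ino, gen$dec[[j]]$inorm, g)
    cb <- nnConvBwd(caches$dec[[j]]$cv, gen$dec[[j]]$conv, ib$gx,
                    stride = 1L, pad = 1L)
    grads$dec[[j]] <- list(conv = list(W = cb$gW, b = cb$gb),
                           inorm = list(g = ib$gg, b = ib$gb))
    gd <- nnUp2Bwd(cb$gx)
  }
  gcur <- gd  # gradient flowing into h[[nd]]
  for (i in rev(seq_len(nd))) {
    if (!is.null(gh[[i]])) gcur <- gcur + gh[[i]]
    g <- nnLReluBwd(caches$enc[[i]]$ac, gcur)
    if (!is.null(caches$enc[[i]]$ino)) {
      ib <- nnInormBwd(caches$enc[[i]]$ino, gen$enc[[i]]$inorm, g)
      g <- ib$gx
      grads$enc[[i]] <- list(conv = NULL,
                             inorm = list(g = ib$gg, b = ib$gb))
    } else {
      grads$enc[[i]] <- list(conv = NULL)
    }
    cb <- nnConvBwd(caches$enc[[i]]$cv, gen$enc[[i]]$conv, g,
                    stride = 2L, pad = 1L)
    grads$enc[[i]]$conv <- list(W = cb$gW, b = cb$gb)
    gcur <- cb$gx
  }
  list(grads = grads, gx = gcur)
}

discForward <- function(disc, x) {
  cur <- asCube(x)
  caches <- vector("list", length(disc$blocks))
  for (k in seq_along(disc$blocks)) {
    bl <- disc$blocks[[k]]
    cv <- nnConvFwd(cur, bl$conv, stride = bl$stride, pad = 1L)
    z <- cv$y; ino <- NULL; ac <- NULL
    if (!is.null(bl$inorm)) { ino <- nnInormFwd(z, bl$inorm); z <- ino$y }
    if (k < length(disc$blocks)) { ac <- nnLReluFwd(z); z <- ac$y }
    caches[[k]] <- list(cv = cv, ino = ino, ac = ac)
    cur <- z
  }
  list(z = cur, p = nnSigmoid(cur), caches = caches)
}

discBackward <- function(disc, caches, gz) {
  grads <- list(blocks = vector("list", length(disc$blocks)))
  g <- asCube(gz)
  for (k in rev(seq_along(disc$blocks))) {
    bl <- disc$blocks[[k]]
    if (!is.null(caches[[k]]$ac)) g <- nnLReluBwd(caches[[k]]$ac, g)
    gb <- list(conv = NULL)
    if (!is.null(caches[[k]]$ino)) {
      ib <- nnInormBwd(caches[[k]]$ino, bl$inorm, g)
      g <- ib$gx
      gb$inorm <- list(g = ib$gg, b = ib$gb)
    }
    cb <- nnConvBwd(caches[[k]]$cv, bl$conv, g, stride = bl$stride,
                    pad = 1L)
    gb$conv <- list(W = cb$gW, b = cb$gb)
    grads$blocks[[k]] <- gb
    g <- cb$gx
  }
  list(grads = grads, gx = g)
}

gradTreeAdd <- function(a, b) {
  fa <- flattenParams(a); fb <- flattenParams(b)
  for (k in names(fb)) fa[[k]] <- if (is.null(fa[[k]])) fb[[k]] else fa[[k]] + fb[[k]]
  assignFlat(a, fa)
}

## ---------------------------------------------------------------------------
## Objective
## ---------------------------------------------------------------------------

#' Adversarial + L1 objective
#'
#' The conditional-GAN loss
#' \deqn{L(G, D) = E[\log D(x, y)] + E[\log(1 - D(x, G(x)))]
#'   + \lambda L_1(y, G(x))}
#' which the discriminator maximizes (its two log terms) and the generator
#' minimizes (the second log term plus the weighted L1 distance).
#' Probabilities are clamped to (1e-7, 1 - 1e-7) before the logs.
#'
#' @param dReal discriminator patch probabilities on the real pair.
#' @param dFake patch probabilities on the generated pair.
#' @param y ground-truth force image.
#' @param gx generated force image (same shape as \code{y}).
#' @param lambdaL1 weight of the L1 term.
#' @return List with \code{lossD} (quantity the discriminator maximizes,
#'   equal to the adversarial part), \code{lossG} (quantity the generator
#'   minimizes) and \code{l1} (the mean absolute difference).
#' @export
ganObjective <- function(dReal, dFake, y, gx, lambdaL1 = 100) {
  eps <- 1e-7
  pR <- pmin(pmax(dReal, eps), 1 - eps)
  pF <- pmin(pmax(dFake, eps), 1 - eps)
  adv <- mean(log(pR)) + mean(log(1 - pF))
  l1 <- mean(abs(y - gx))
  list(lossD = adv, lossG = mean(log(1 - pF)) + lambdaL1 * l1, l1 = l1)
}

## ---------------------------------------------------------------------------
## Data preparation
## ---------------------------------------------------------------------------

## nearest-neighbour upsample of a matrix to (nOut x nOut)
nearestUpsample <- function(m, nOut) {
  ri <- pmin(pmax(ceiling(seq_len(nOut) * nrow(m) / nOut), 1L), nrow(m))
  ci <- pmin(pmax(ceiling(seq_len(nOut) * ncol(m) / nOut), 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

## block-average a matrix down to (nOut x nOut) by index binning
blockAverageTo <- function(m, nOut) {
  rb <- floor((seq_len(nrow(m)) - 1L) * nOut / nrow(m)) + 1L
  cb <- floor((seq_len(ncol(m)) - 1L) * nOut / ncol(m)) + 1L
  sums <- rowsum(m, rb)
  sums <- t(rowsum(t(sums), cb))
  cnt <- outer(tabulate(rb, nOut), tabulate(cb, nOut))
  out <- sums / cnt
  dimnames(out) <- NULL
  out
}

readManifest <- function(manifest, dataDir = NULL) {
  if (is.character(manifest)) {
    if (is.null(dataDir)) dataDir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  if (is.null(dataDir))
    wfmStop("dataDir is required when the manifest is given as a list")
  list(manifest = manifest, dataDir = dataDir)
}

## load training samples: x = image in [-1, 1], y = encoded x-component
## force map upsampled to the image size, in [-1, 1]
loadPairs <- function(manifest, dataDir, config, codec, split = "train") {
  pairs <- Filter(function(p) p$split == split, manifest$pairs)
  if (!length(pairs)) return(list())
  lapply(pairs, function(p) {
    img <- readScalarImage(file.path(dataDir, p$image))
    tr <- readVectorField(file.path(dataDir, p$traction))
    x <- img@values
    if (nrow(x) != config@imageSize)
      x <- as.matrix(EBImage::resize(x, w = config@imageSize,
                                     h = config@imageSize))
    xs <- x / 127.5 - 1
    enc <- encodeForce(tr@compX, codec)
    y <- nearestUpsample(enc, config@imageSize) / 127.5 - 1
    list(x = xs, y = y, id = p$id, baseCell = p$baseCell,
         rotation = p$rotation)
  })
}

## ---------------------------------------------------------------------------
## Training
## ---------------------------------------------------------------------------

#' Train the image-to-force translator
#'
#' Alternating discriminator/generator Adam updates with batch size 1
#' (adversarial model), or pure weighted-L1 regression through the same
#' generator (\code{"cnn_baseline"}: the adversarial terms disabled).
#' Fully seeded: the same seed and configuration reproduce the loss
#' trajectory exactly.
#'
#' @param manifest manifest list or path to \code{manifest.json} from
#'   [buildDataset()].
#' @param dataDir directory with the referenced files (defaults to the
#'   manifest's directory).
#' @param kind \code{"gan"} or \code{"cnn_baseline"}.
#' @param config a \linkS4class{GANConfig}.
#' @param codec \linkS4class{CodecParams} used to encode target force
#'   maps.
#' @param checkpointDir if non-NULL, a checkpoint is written here every
#'   \code{checkpointEvery} epochs.
#' @param checkpointEvery checkpoint interval, epochs.
#' @param verbose print per-epoch losses to stderr.
#' @return A \linkS4class{TrainedTranslator}.
#' @export
trainTranslator <- function(manifest, dataDir = NULL,
                            kind = c("gan", "cnn_baseline"),
                            config = GANConfig(), codec = CodecParams(),
                            checkpointDir = NULL, checkpointEvery = 10L,
                            verbose = FALSE) {
  kind <- match.arg(kind)
  mf <- readManifest(manifest, dataDir)
  samples <- loadPairs(mf$manifest, mf$dataDir, config, codec, "train")
  if (!length(samples)) wfmStop("empty training set")
  withSeed(config@seed, {
    gen <- buildGenerator(config)
    disc <- if (kind == "gan") buildDiscriminator(config)
    stG <- adamInit(gen)
    stD <- if (kind == "gan") adamInit(disc)
    lr <- config@learningRate; b1 <- config@adamBeta1; b2 <- config@adamBeta2
    lam <- config@lambdaL1
    hist <- data.frame(epoch = integer(0), lossD = numeric(0),
                       lossG = numeric(0), l1 = numeric(0))
    N <- config@imageSize^2
    for (ep in seq_len(config@epochs)) {
      ord <- sample(length(samples))
      eD <- 0; eG <- 0; eL1 <- 0
      for (s in ord) {
        x <- samples[[s]]$x; y <- asCube(samples[[s]]$y)
        gf <- genForward(gen, x)
        fake <- gf$y
        if (kind == "gan") {
          xin <- asCube(x)
          dfR <- discForward(disc, nnConcat(xin, y))
          dfF <- discForward(disc, nnConcat(xin, fake))
          Np <- length(dfR$z)
          pR <- pmin(pmax(dfR$p, 1e-7), 1 - 1e-7)
          pF <- pmin(pmax(dfF$p, 1e-7), 1 - 1e-7)
          gR <- discBackward(disc, dfR$caches, (pR - 1) / Np)
          gF <- discBackward(disc, dfF$caches, pF / Np)
          upd <- adamStep(disc, gradTreeAdd(gR$grads, gF$grads), stD,
                          lr, b1, b2)
          disc <- upd$params; stD <- upd$state
          ## generator step against the updated discriminator
          dfF2 <- discForward(disc, nnConcat(xin, fake))
          pF2 <- pmin(pmax(dfF2$p, 1e-7), 1 - 1e-7)
          db <- discBackward(disc, dfF2$caches, -pF2 / length(pF2))
          gAdv <- db$gx[, , 2L, drop = FALSE]
          obj <- ganObjective(pR, pF2, y, fake, lam)
          eD <- eD + obj$lossD; eG <- eG + obj$lossG
        } else {
          gAdv <- 0
          obj <- list(l1 = mean(abs(y - fake)))
          eG <- eG + lam * obj$l1
        }
        gFake <- gAdv + lam * sign(fake - y) / N
        gb <- genBackward(gen, gf$caches, gFake)
        upd <- adamStep(gen, gb$grads, stG, lr, b1, b2)
        gen <- upd$params; stG <- upd$state
        eL1 <- eL1 + obj$l1
        if (!is.finite(eL1) || !is.finite(eG))
          wfmStop(sprintf("non-finite loss at epoch %d, step %d", ep, s))
      }
      n <- length(samples)
      hist <- rbind(hist, data.frame(epoch = ep, lossD = eD / n,
                                     lossG = eG / n, l1 = eL1 / n))
      if (verbose)
        message(sprintf("epoch %3d  lossD %8.4f  lossG %8.4f  L1 %8.5f",
                        ep, eD / n, eG / n, eL1 / n))
      if (!is.null(checkpointDir) && ep %% checkpointEvery == 0L) {
        mdl <- new("TrainedTranslator", kind = kind, generator = gen,
                   discriminator = if (kind == "gan") disc else list(),
                   config = config, codec = codec, history = hist)
        saveTranslator(mdl, file.path(checkpointDir,
                                      sprintf("checkpoint_ep%03d.rds", ep)))
      }
    }
    new("TrainedTranslator", kind = kind, generator = gen,
        discriminator = if (kind == "gan") disc else list(),
        config = config, codec = codec, history = hist)
  })
}

#' Identity stub translator
#'
#' A diagnostic translator whose "generator" returns its input unchanged:
#' feeding it an encoded ground-truth force image exercises the full
#' prediction plumbing (rotation handling, decoding, downsampling) without
#' any learned component.
#'
#' @param config a \linkS4class{GANConfig}.
#' @param codec \linkS4class{CodecParams}.
#' @return A \linkS4class{TrainedTranslator} of kind \code{"identity"}.
#' @export
identityTranslator <- function(config = GANConfig(), codec = CodecParams()) {
  new("TrainedTranslator", kind = "identity", generator = list(),
      discriminator = list(), config = config, codec = codec,
      history = data.frame())
}

translatorApply <- function(model, x) {
  if (model@kind == "identity") return(asCube(x))
  genForward(model@generator, x)$y
}

#' Predict a traction field from an image
#'
#' Runs the generator twice: on the image for the x-component and on the
#' 90-degree-rotated image (inverse-rotating the result) for the
#' y-component, decodes both maps through the arctangent codec, and
#' block-averages down to the force grid. Intensities at the codec
#' asymptotes are clipped just inside the decodable range; the number of
#' clipped pixels is reported as a warning.
#'
#' @param model a \linkS4class{TrainedTranslator}.
#' @param image a square \linkS4class{ScalarImage}; resampled to the
#'   model's input size if needed.
#' @param forceGridN output force-grid side (default 26).
#' @return A \linkS4class{VectorField2D} in Pa on the
#'   \code{forceGridN} x \code{forceGridN} grid spanning the image extent.
#' @export
predictTraction <- function(model, image, forceGridN = 26L) {
  stopifnot(is(model, "TrainedTranslator"), is(image, "ScalarImage"))
  if (image@grid@nx != image@grid@ny)
    wfmStop("predictTraction requires a square image")
  v <- image@values
  S <- model@config@imageSize
  extent <- image@grid@nx * image@grid@pixelSize
  if (nrow(v) != S) {
    message(sprintf("resampling input %d px -> %d px", nrow(v), S))
    v <- as.matrix(EBImage::resize(v, w = S, h = S))
  }
  xs <- v / 127.5 - 1
  codec <- model@codec
  outX <- translatorApply(model, xs)[, , 1]
  outYrot <- translatorApply(model, rotate90Matrix(xs))[, , 1]
  outY <- rotate90Matrix(outYrot, -1L)
  toForce <- function(out) {
    I <- (out + 1) * 127.5
    lo <- codec@Imid - codec@a * pi / 2
    hi <- codec@Imid + codec@a * pi / 2
    nClip <- sum(I <= lo | I >= hi)
    if (nClip > 0)
      warning(sprintf("%d pixel(s) at codec saturation bounds were clipped",
                      nClip))
    I <- pmin(pmax(I, lo + 1e-6), hi - 1e-6)
    blockAverageTo(decodeForce(I, codec), forceGridN)
  }
  VectorField2D(toForce(outX), toForce(outY),
                pixelSize = extent / forceGridN, units = "Pa")
}

#' Save / load a trained translator
#'
#' Single-file serialization with the configuration snapshot embedded;
#' load followed by predict is bit-identical to predicting before the
#' save.
#'
#' @param model a \linkS4class{TrainedTranslator}.
#' @param path destination / source file.
#' @return \code{path} invisibly (save); the model (load).
#' @export
saveTranslator <- function(model, path) {
  stopifnot(is(model, "TrainedTranslator"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveTranslator
#' @export
loadTranslator <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "TrainedTranslator"))
  model
}

#' Evaluate a translator on the held-out split
#'
#' Predicts the traction field for every unrotated test pair and reports
#' the weighted magnitude error, weighted angle error, pooled component
#' correlation across all test cells, and the held-out L1 loss on encoded
#' force maps (the quantity the baseline optimizes, for
#' baseline-vs-adversarial comparison).
#'
#' @param model a \linkS4class{TrainedTranslator}.
#' @param manifest manifest list or path.
#' @param dataDir data directory (defaults to the manifest's directory).
#' @return List with \code{epsF}, \code{epsTheta}, \code{R},
#'   \code{l1Heldout}, \code{nCells} and a per-cell data.frame
#'   \code{perCell}.
#' @export
evaluateTranslator <- function(model, manifest, dataDir = NULL) {
  mf <- readManifest(manifest, dataDir)
  pairs <- Filter(function(p) p$split == "test" && p$rotation == 0,
                  mf$manifest$pairs)
  if (!length(pairs)) wfmStop("manifest has no held-out test cells")
  codec <- model@codec
  S <- model@config@imageSize
  psImg <- mf$manifest$imagePixelSizeUm %||% 1
  poolP <- c(); poolT <- c()
  rows <- list(); l1s <- numeric(0)
  for (p in pairs) {
    img <- readScalarImage(file.path(mf$dataDir, p$image),
                           pixelSize = psImg)
    tr <- readVectorField(file.path(mf$dataDir, p$traction))
    pred <- suppressWarnings(
      predictTraction(model, img, forceGridN = tr@grid@nx))
    m <- evaluatePrediction(pred, tr)
    rows[[length(rows) + 1L]] <-
      data.frame(id = p$id, epsF = m$epsF, epsTheta = m$epsTheta, R = m$R)
    poolP <- c(poolP, c(pred@compX, pred@compY))
    poolT <- c(poolT, c(tr@compX, tr@compY))
    ## held-out L1 in the encoded-image space
    xs <- img@values
    if (nrow(xs) != S) xs <- as.matrix(EBImage::resize(xs, w = S, h = S))
    out <- translatorApply(model, xs / 127.5 - 1)[, , 1]
    yEnc <- nearestUpsample(encodeForce(tr@compX, codec), S) / 127.5 - 1
    l1s <- c(l1s, mean(abs(out - yEnc)))
  }
  perCell <- do.call(rbind, rows)
  list(epsF = mean(perCell$epsF), epsTheta = mean(perCell$epsTheta),
       R = stats::cor(poolP, poolT), l1Heldout = mean(l1s),
       nCells = nrow(perCell), perCell = perCell)
}
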