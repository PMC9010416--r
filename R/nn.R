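## Minimal convolutional-network layers with hand-derived backward passes.
## Activations are arrays dim (H, W, C); convolution weights are stored as
## (kh*kw*Cin) x Cout matrices (column-major flattening of (kh, kw, Cin)).
## All randomness is drawn from R's RNG so a single seed fixes training.

asCube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

nnConvInit <- function(kh, kw, cin, cout, sd = 0.02) {
  list(W = matrix(stats::rnorm(kh * kw * cin * cout, 0, sd),
                  kh * kw * cin, cout),
       b = numeric(cout), kh = kh, kw = kw, cin = cin, cout = cout)
}

nnConvFwd <- function(x, p, stride, pad) {
  x <- asCube(x)
  res <- .convForward(x, p$W, p$b, p$kh, p$kw, stride, pad)
  list(y = res$y, col = res$col, dims = dim(x))
}

nnConvBwd <- function(cache, p, gy, stride, pad) {
  d <- cache$dims
  .convBackward(cache$col, p$W, asCube(gy), d[1], d[2], d[3],
                p$kh, p$kw, stride, pad)
}

nnLReluFwd <- function(x, slope = 0.2) {
  mask <- x > 0
  y <- x
  y[!mask] <- slope * y[!mask]
  list(y = y, mask = mask, slope = slope)
}
nnLReluBwd <- function(cache, gy) {
  g <- gy
  g[!cache$mask] <- cache$slope * g[!cache$mask]
  g
}

nnReluFwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
nnReluBwd <- function(cache, gy) gy * cache$mask

nnTanhFwd <- function(x) { y <- tanh(x); list(y = y) }
nnTanhBwd <- function(cache, gy) gy * (1 - cache$y^2)

nnSigmoid <- function(x) 1 / (1 + exp(-x))

## instance normalization: per-channel standardization with learned
## scale/shift; internally works on the (H*W) x C matrix view
nnInormInit <- function(c) list(g = rep(1, c), b = numeric(c))

nnInormFwd <- function(x, p, eps = 1e-5) {
  x <- asCube(x)
  d <- dim(x); n <- d[1] * d[2]
  xm <- x; dim(xm) <- c(n, d[3])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  istd <- 1 / sqrt(colMeans(xc^2) + eps)
  xh <- xc * rep(istd, each = n)
  y <- xh * rep(p$g, each = n) + rep(p$b, each = n)
  dim(y) <- d; dim(xh) <- d
  list(y = y, xh = xh, istd = istd, n = n)
}

nnInormBwd <- function(cache, p, gy) {
  gy <- asCube(gy)
  d <- dim(gy); n <- cache$n
  gm <- gy; dim(gm) <- c(n, d[3])
  xh <- cache$xh; dim(xh) <- c(n, d[3])
  gg <- colSums(gm * xh)
  gb <- colSums(gm)
  gxh <- gm * rep(p$g, each = n)
  m1 <- colMeans(gxh)
  m2 <- colMeans(gxh * xh)
  gx <- (gxh - rep(m1, each = n) - xh * rep(m2, each = n)) *
    rep(cache$istd, each = n)
  dim(gx) <- d
  list(gx = gx, gg = gg, gb = gb)
}

## nearest-neighbour 2x upsampling
nnUp2Fwd <- function(x) {
  x <- asCube(x)
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}
nnUp2Bwd <- function(gy) {
  gy <- asCube(gy)
  d <- dim(gy)
  o1 <- seq(1, d[1], by = 2); o2 <- seq(1, d[2], by = 2)
  gy[o1, o2, , drop = FALSE] + gy[o1 + 1, o2, , drop = FALSE] +
    gy[o1, o2 + 1, , drop = FALSE] + gy[o1 + 1, o2 + 1, , drop = FALSE]
}

nnConcat <- function(a, b) {
  a <- asCube(a); b <- asCube(b)
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}
nnSplit <- function(g, ca) {
  g <- asCube(g)
  list(a = g[, , seq_len(ca), drop = FALSE],
       b = g[, , -seq_len(ca), drop = FALSE])
}

## ---------------------------------------------------------------------------
## Adam over a named flat list of parameter arrays
## ---------------------------------------------------------------------------

adamInit <- function(params) {
  flat <- flattenParams(params)
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0), t = 0L)
}

flattenParams <- function(params, prefix = "") {
  out <- list()
  nms <- names(params)
  if (is.null(nms)) nms <- rep("", length(params))
  for (i in seq_along(params)) {
    p <- params[[i]]
    nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p)) out <- c(out, flattenParams(p, key))
    else if (is.numeric(p) && nms[i] %in% c("W", "b", "g"))
      out[[key]] <- p
  }
  out
}

assignFlat <- function(params, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    suppressWarnings(ip <- as.integer(path))
    idx <- lapply(seq_along(path),
                  function(j) if (is.na(ip[j])) path[j] else ip[j])
    ## recursive [[<- with mixed name/position indices
    params <- assignPath(params, idx, flat[[key]])
  }
  params
}

assignPath <- function(obj, idx, value) {
  if (length(idx) == 1L) { obj[[idx[[1]]]] <- value; return(obj) }
  obj[[idx[[1]]]] <- assignPath(obj[[idx[[1]]]], idx[-1], value)
  obj
}

adamStep <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  fp <- flattenParams(params); fg <- flattenParams(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (key in names(fp)) {
    g <- fg[[key]]
    if (is.null(g)) next
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    fp[[key]] <- fp[[key]] -
      lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
  }
  list(params = assignFlat(params, fp), state = state)
}
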