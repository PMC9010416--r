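## Raster and vector-field I/O, configuration.

#' Read a grayscale image
#'
#' Reads a single-channel TIFF or PNG into a \linkS4class{ScalarImage}.
#' Integer intensities are preserved exactly as stored (a 16-bit TIFF with
#' maximum 65535 reads back as 65535, not 1.0). Multi-channel files are
#' rejected unless a conversion rule is given.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param pixelSize micrometres per pixel; raster metadata carries no
#'   physical scale here, so this comes from configuration (default 1).
#' @param channel conversion rule for multi-channel files: a channel index,
#'   or \code{"mean"} to average channels; \code{NULL} (default) rejects
#'   multi-channel input unless all channels are identical.
#' @return A \linkS4class{ScalarImage}.
#' @seealso [writeScalarImage()], [readBinaryMask()]
#' @export
readScalarImage <- function(path, pixelSize = 1, channel = NULL) {
  if (!file.exists(path))
    wfmStop(sprintf("cannot read image: file '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    tif = , tiff = {
      v <- try(tiff::readTIFF(path, as.is = TRUE), silent = TRUE)
      if (inherits(v, "try-error"))
        wfmStop(sprintf("unreadable TIFF file '%s'", path))
      v
    },
    png = {
      v <- try(png::readPNG(path, info = TRUE), silent = TRUE)
      if (inherits(v, "try-error"))
        wfmStop(sprintf("unreadable PNG file '%s'", path))
      info <- attr(v, "info")
      depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8
      round(v * (2^depth - 1))
    },
    wfmStop(sprintf("unsupported image format '%s' (use TIFF or PNG)", ext))
  )
  if (length(dim(vals)) == 3L) {
    nch <- dim(vals)[3]
    if (is.null(channel)) {
      same <- all(vapply(seq_len(nch)[-1], function(i)
        identical(vals[, , i], vals[, , 1]), logical(1)))
      if (!same)
        wfmStop(sprintf(
          "'%s' has %d distinct channels; pass channel = index or \"mean\"",
          path, nch))
      vals <- vals[, , 1]
    } else if (identical(channel, "mean")) {
      vals <- apply(vals, c(1, 2), mean)
    } else {
      vals <- vals[, , as.integer(channel)]
    }
  }
  vals <- matrix(as.numeric(vals), nrow(vals), ncol(vals))
  ScalarImage(vals, pixelSize = pixelSize)
}

#' Write a grayscale image
#'
#' Writes intensities to TIFF (8 or 16 bit) or PNG (8 bit), clamping to the
#' representable range and rounding to integers. Reading the file back with
#' [readScalarImage()] recovers the written integers exactly.
#'
#' @param image a \linkS4class{ScalarImage} or \linkS4class{BinaryMask}.
#' @param path destination path (.tif/.tiff/.png).
#' @param bits bit depth, 8 (default) or 16 (TIFF only).
#' @return \code{path}, invisibly.
#' @export
writeScalarImage <- function(image, path, bits = 8L) {
  stopifnot(is(image, "ScalarImage"))
  ext <- tolower(tools::file_ext(path))
  scale <- 2^bits - 1
  v <- pmin(pmax(round(image@values), 0), scale)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v / scale, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    if (bits != 8L) wfmStop("PNG output is written at 8 bits")
    png::writePNG(v / scale, path)
  } else {
    wfmStop(sprintf("unsupported image format '%s' (use TIFF or PNG)", ext))
  }
  invisible(path)
}

#' Read a binary mask
#'
#' Reads an image and thresholds it at zero: any positive intensity becomes
#' foreground.
#'
#' @inheritParams readScalarImage
#' @return A \linkS4class{BinaryMask}.
#' @export
readBinaryMask <- function(path, pixelSize = 1, channel = NULL) {
  img <- readScalarImage(path, pixelSize = pixelSize, channel = channel)
  BinaryMask(img@values > 0, pixelSize = pixelSize)
}

#' Write a vector field as delimited text
#'
#' One row per grid node with columns \code{x_um, y_um, cx, cy} (positions
#' of the node and the two field components), preceded by comment lines
#' recording the units and grid spacing. [readVectorField()] is the exact
#' inverse up to text precision.
#'
#' @param field a \linkS4class{VectorField2D}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeVectorField <- function(field, path) {
  stopifnot(is(field, "VectorField2D"))
  g <- field@grid
  co <- nodeCoords(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# units: %s", field@units),
               sprintf("# pixel_size_um: %.12g", g@pixelSize),
               "x_um,y_um,cx,cy"), con)
  df <- data.frame(x = as.vector(t(co$x)), y = as.vector(t(co$y)),
                   cx = as.vector(t(field@compX)),
                   cy = as.vector(t(field@compY)))
  writeLines(sprintf("%.12g,%.12g,%.17g,%.17g", df$x, df$y, df$cx, df$cy),
             con)
  invisible(path)
}

#' Read a vector field from delimited text
#'
#' Accepts comma- or tab-delimited tables (auto-detected) with header
#' columns \code{x_um, y_um, cx, cy} as written by [writeVectorField()].
#' The grid is reconstructed from the node positions, which must form a
#' complete regular grid.
#'
#' @param path file path.
#' @return A \linkS4class{VectorField2D}.
#' @export
readVectorField <- function(path) {
  if (!file.exists(path))
    wfmStop(sprintf("cannot read field: file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  units <- "Pa"
  um <- grep("^#\\s*units:", lines, value = TRUE)
  if (length(um)) units <- trimws(sub("^#\\s*units:\\s*", "", um[1]))
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(body)) wfmStop(sprintf("'%s' contains no data", path))
  hline <- body[1]
  delim <- if (grepl("\t", lines[hline])) "\t" else ","
  header <- trimws(strsplit(lines[hline], delim, fixed = TRUE)[[1]])
  need <- c("x_um", "y_um", "cx", "cy")
  if (!all(need %in% header))
    wfmStop(sprintf("malformed header at line %d of '%s': need columns %s",
                    hline, path, paste(need, collapse = ", ")))
  rows <- body[-1]
  parts <- strsplit(lines[rows], delim, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header)))
    wfmStop(sprintf("ragged row at line %d of '%s' (%d fields, expected %d)",
                    rows[which(nf != length(header))[1]], path,
                    nf[which(nf != length(header))[1]], length(header)))
  raw <- unlist(parts)
  tab <- matrix(suppressWarnings(as.numeric(raw)), ncol = length(header),
                byrow = TRUE)
  colnames(tab) <- header
  ## NaN is legal (invalid-node flag); anything else unparseable is an error
  bad <- is.na(tab) & !grepl("^\\s*[Nn][Aa][Nn]\\s*$",
                             matrix(raw, ncol = length(header), byrow = TRUE))
  if (any(bad))
    wfmStop(sprintf("non-numeric value at line %d of '%s'",
                    rows[which(apply(bad, 1, any))[1]], path))
  xs <- sort(unique(tab[, "x_um"])); ys <- sort(unique(tab[, "y_um"]))
  nx <- length(xs); ny <- length(ys)
  if (nx < 2L || ny < 2L || nrow(tab) != nx * ny)
    wfmStop(sprintf("'%s' does not describe a complete regular grid", path))
  ps <- xs[2] - xs[1]
  ci <- round(tab[, "x_um"] / ps) + 1L
  ri <- round(tab[, "y_um"] / ps) + 1L
  cxm <- matrix(NA_real_, ny, nx); cym <- matrix(NA_real_, ny, nx)
  filled <- matrix(FALSE, ny, nx)
  cxm[cbind(ri, ci)] <- tab[, "cx"]
  cym[cbind(ri, ci)] <- tab[, "cy"]
  filled[cbind(ri, ci)] <- TRUE
  if (!all(filled))
    wfmStop(sprintf("'%s' does not describe a complete regular grid", path))
  cxm[is.na(cxm) & !is.nan(cxm)] <- NaN
  cym[is.na(cym) & !is.nan(cym)] <- NaN
  VectorField2D(cxm, cym, pixelSize = ps,
                units = match.arg(units, c("Pa", "um")))
}

#' Default toolkit configuration
#'
#' Key-value defaults shared by the command-line tools: micrograph pixel
#' size, substrate elasticity, codec constants, and training
#' hyperparameters. [readWfmConfig()] overlays a YAML file on these.
#'
#' @return A named list.
#' @export
wfmDefaultConfig <- function() {
  list(
    pixel_size = 1.0,
    E = 5400, nu = 0.5,
    force_grid = list(nx = 26L, ny = 26L, spacing = 3.44),
    codec = list(a = 81.2, b = 50.0, I_mid = 255 / 2),
    training = list(image_size = 256L, epochs = 100L, batch_size = 1L,
                    learning_rate = 2e-4, adam_beta1 = 0.5, adam_beta2 = 0.9,
                    lambda_l1 = 100)
  )
}

#' Read a YAML configuration file
#'
#' @param path YAML file; keys override [wfmDefaultConfig()] entries,
#'   recursively for nested lists.
#' @return The merged configuration list.
#' @export
readWfmConfig <- function(path) {
  if (!file.exists(path))
    wfmStop(sprintf("config file '%s' does not exist", path))
  user <- yaml::read_yaml(path)
  utils::modifyList(wfmDefaultConfig(), user)
}
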