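# Native PNG writer/reader for 8-bit RGBA images. The IDAT stream is a zlib
# deflate stream (memCompress/memDecompress); chunk CRCs use the compiled
# CRC-32. The writer emits filter type 0 on every scanline; the reader
# understands all five standard filters.

#' Create an RGBA image
#'
#' @param width,height pixel dimensions (>= 1)
#' @param fill RGBA fill color, values 0-255
#' @return `molimage`: integer array `height x width x 4`
#' @export
new_image <- function(width, height, fill = c(0, 0, 0, 0)) {
  if (width < 1 || height < 1) stop("image dimensions must be >= 1", call. = FALSE)
  stopifnot(length(fill) == 4, all(fill >= 0 & fill <= 255))
  arr <- array(rep(as.integer(round(fill)), each = width * height),
               dim = c(height, width, 4))
  structure(arr, class = "molimage")
}

.as_image <- function(arr) {
  stopifnot(length(dim(arr)) == 3, dim(arr)[3] == 4)
  if (!is.integer(arr) || anyNA(arr) || min(arr) < 0L || max(arr) > 255L) {
    arr <- pmin(pmax(round(arr), 0), 255)
    storage.mode(arr) <- "integer"
  }
  structure(arr, class = "molimage")
}

.u32be <- function(x) {
  if (x >= 2^31) x <- x - 2^32          # unsigned 32-bit wrap (CRC values)
  writeBin(as.integer(x), raw(), 4, endian = "big")
}

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32_raw(body)
  c(.u32be(length(data)), body, .u32be(crc))
}

#' Write an RGBA image as PNG
#'
#' The alpha channel is preserved exactly (color type 6, bit depth 8).
#'
#' @param image a `molimage` (see [new_image()]) or height x width x 4 array
#' @param path output file path
#' @export
write_png <- function(image, path) {
  arr <- unclass(image)
  if (is.null(dim(arr)) || length(dim(arr)) != 3 || dim(arr)[3] != 4)
    stop("image must be a height x width x 4 RGBA array", call. = FALSE)
  h <- dim(arr)[1]; w <- dim(arr)[2]
  if (h < 1 || w < 1) stop("image dimensions must be >= 1", call. = FALSE)
  if (any(arr < 0 | arr > 255)) stop("channel values must be in [0, 255]", call. = FALSE)
  bytes <- as.raw(aperm(arr, c(3, 2, 1)))           # RGBA, cols, rows
  scan <- matrix(bytes, nrow = 4L * w)
  filt <- rbind(matrix(as.raw(0), 1, h), scan)      # filter byte 0 per row
  idat <- memCompress(as.vector(filt), type = "gzip")  # zlib stream
  ihdr <- c(.u32be(w), .u32be(h), as.raw(c(8, 6, 0, 0, 0)))
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           .png_chunk("IHDR", ihdr),
           .png_chunk("IDAT", idat),
           .png_chunk("IEND", raw(0)))
  ok <- tryCatch({ writeBin(out, path); TRUE },
                 error = function(e) stop("cannot write PNG to '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read an 8-bit RGBA PNG written by this package (or any non-interlaced
#' 8-bit RGBA PNG using filters 0-4)
#'
#' @param path PNG file path
#' @return a `molimage`
#' @export
read_png <- function(path) {
  data <- readBin(path, "raw", file.info(path)$size)
  sig <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))
  if (length(data) < 8 || !identical(data[1:8], sig))
    stop("not a PNG file", call. = FALSE)
  pos <- 9L
  idat <- list()
  w <- h <- NA_integer_
  while (pos + 8 <= length(data)) {
    len <- readBin(data[pos:(pos + 3)], "integer", 1, 4, endian = "big")
    type <- rawToChar(data[(pos + 4):(pos + 7)])
    body <- if (len > 0) data[(pos + 8):(pos + 7 + len)] else raw(0)
    if (type == "IHDR") {
      w <- readBin(body[1:4], "integer", 1, 4, endian = "big")
      h <- readBin(body[5:8], "integer", 1, 4, endian = "big")
      if (as.integer(body[9]) != 8 || as.integer(body[10]) != 6)
        stop("only 8-bit RGBA PNGs are supported", call. = FALSE)
      if (as.integer(body[13]) != 0)
        stop("interlaced PNGs are not supported", call. = FALSE)
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- body
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.na(w) || !length(idat)) stop("PNG lacks IHDR/IDAT", call. = FALSE)
  stream <- memDecompress(do.call(c, idat), type = "gzip")
  stride <- 4L * w
  bytes <- png_unfilter(stream, h, stride, 4L)
  arr <- aperm(array(as.integer(bytes), dim = c(4, w, h)), c(3, 2, 1))
  .as_image(arr)
}
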