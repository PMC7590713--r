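# Minimal lossless PNG writer/reader for 8-bit RGB truecolor images
# (filter type None), backed by the package's zlib bindings. PNG is used
# because rendered training images must be byte-reproducible.

.png_magic <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))

.u32be <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

.from_u32be <- function(r) {
  sum(as.integer(r) * c(16777216, 65536, 256, 1))
}

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- .Call(c_crc32, body)
  c(.u32be(length(data)), body, .u32be(crc))
}

#' Write an RGB pixel array as a PNG file
#'
#' @param pixels integer array of dim (height, width, 3), values 0..255
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_png <- function(pixels, path) {
  d <- dim(pixels)
  stopifnot(length(d) == 3L, d[3] == 3L)
  h <- d[1]; w <- d[2]
  # scanlines: filter byte 0, then RGB triples left to right
  px <- as.integer(pixels)
  # reorder to row-major interleaved: index (y, x, c) -> ((y-1)*w + (x-1))*3 + c
  arr <- aperm(array(px, d), c(3L, 2L, 1L))  # now [c, x, y]
  interleaved <- as.raw(as.vector(arr))
  lines <- matrix(interleaved, nrow = 3L * w, ncol = h)
  raw_data <- as.vector(rbind(as.raw(0L), lines))
  ihdr <- c(.u32be(w), .u32be(h), as.raw(c(8L, 2L, 0L, 0L, 0L)))
  idat <- .Call(c_zlib_compress, raw_data, 6L)
  out <- c(.png_magic,
           .png_chunk("IHDR", ihdr),
           .png_chunk("IDAT", idat),
           .png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a PNG file written by [write_png()]
#'
#' Supports 8-bit RGB truecolor with filter type None (what this package
#' writes); other PNG variants are rejected.
#'
#' @param path PNG file path
#' @return integer array of dim (height, width, 3)
#' @export
read_png <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (!identical(bytes[1:8], .png_magic)) {
    stop(ocsr_condition("ocsr_png_error", paste0("not a PNG file: ", path)))
  }
  i <- 9L
  w <- h <- NULL
  idat <- raw(0)
  while (i <= length(bytes)) {
    len <- .from_u32be(bytes[i:(i + 3L)])
    type <- rawToChar(bytes[(i + 4L):(i + 7L)])
    data <- if (len > 0L) bytes[(i + 8L):(i + 7L + len)] else raw(0)
    if (type == "IHDR") {
      w <- .from_u32be(data[1:4]); h <- .from_u32be(data[5:8])
      if (as.integer(data[9]) != 8L || as.integer(data[10]) != 2L) {
        stop(ocsr_condition("ocsr_png_error",
          "only 8-bit RGB truecolor PNGs are supported"))
      }
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    i <- i + 12L + len
  }
  raw_data <- .Call(c_zlib_uncompress, idat, h * (1 + 3 * w))
  lines <- matrix(raw_data, nrow = 1L + 3L * w, ncol = h)
  filters <- as.integer(lines[1, ])
  if (any(filters != 0L)) {
    stop(ocsr_condition("ocsr_png_error",
      "only filter type None is supported"))
  }
  body <- as.integer(lines[-1, , drop = FALSE])     # [3*w, h] column-per-row
  arr <- array(body, c(3L, w, h))
  aperm(arr, c(3L, 2L, 1L))
}
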