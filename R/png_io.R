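# Minimal 8-bit grayscale PNG codec.
#
# No binary-image package is assumed at runtime; scenes rendered by this
# package are single-channel, so colour type 0 / bit depth 8 covers every
# file the package itself produces. The zlib stream comes from
# memCompress(type = "gzip"), which emits RFC1950 (zlib) framing as PNG
# requires; CRC32 is table-driven in R.

.fundusroi_env <- new.env(parent = emptyenv())

.crc32_table <- function() {
  tab <- get0("crc32_table", envir = .fundusroi_env)
  if (!is.null(tab)) return(tab)
  poly <- -306674912L # bit pattern 0xEDB88320 as signed 32-bit
  tab <- integer(256L)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(poly, bitwShiftR(c, 1L))
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1L] <- c
  }
  assign("crc32_table", tab, envir = .fundusroi_env)
  tab
}

.crc32 <- function(bytes) {
  tab <- .crc32_table()
  crc <- -1L # 0xFFFFFFFF
  ints <- as.integer(bytes)
  for (b in ints) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

.u32_be <- function(x) {
  # unsigned 32-bit big-endian bytes; x may be a signed int bit pattern
  writeBin(as.integer(x), raw(), size = 4L, endian = "big")
}

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.u32_be(length(data)), body, .u32_be(.crc32(body)))
}

#' Write a grayscale image as PNG
#'
#' Encodes a numeric matrix with values in `[0, 1]` (rows = image rows,
#' top to bottom) as an 8-bit grayscale PNG. Values outside `[0, 1]` are
#' clamped. The encoding is fully deterministic: identical matrices give
#' byte-identical files.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(image, path) {
  stopifnot(is.matrix(image), is.numeric(image))
  h <- nrow(image)
  w <- ncol(image)
  px <- as.integer(round(pmin(pmax(image, 0), 1) * 255))
  # scanlines: filter byte 0 + row bytes
  raster <- matrix(as.raw(0L), nrow = h, ncol = w + 1L)
  raster[, -1L] <- as.raw(t(px))
  idat <- memCompress(as.raw(t(raster)), type = "gzip")
  ihdr <- c(.u32_be(w), .u32_be(h), as.raw(c(8L, 0L, 0L, 0L, 0L)))
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  out <- c(sig,
           .png_chunk("IHDR", ihdr),
           .png_chunk("IDAT", idat),
           .png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

.paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  if (pa <= pb && pa <= pc) a else if (pb <= pc) b else c
}

#' Read a grayscale PNG
#'
#' Decodes an 8-bit grayscale (colour type 0), non-interlaced PNG into a
#' numeric matrix in `[0, 1]`. All five scanline filter types are
#' supported; other colour types or bit depths raise an error.
#'
#' @param path PNG file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_png <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(bytes) < 8L || !identical(bytes[1:8], sig)) {
    stop("not a PNG file: ", path)
  }
  pos <- 9L
  idat <- raw(0)
  w <- h <- NA_integer_
  while (pos + 8L <= length(bytes)) {
    len <- sum(as.integer(bytes[pos:(pos + 3L)]) * c(2^24, 2^16, 2^8, 1))
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) bytes[(pos + 8L):(pos + 7L + len)] else raw(0)
    if (type == "IHDR") {
      w <- sum(as.integer(data[1:4]) * c(2^24, 2^16, 2^8, 1))
      h <- sum(as.integer(data[5:8]) * c(2^24, 2^16, 2^8, 1))
      depth <- as.integer(data[9]); ctype <- as.integer(data[10])
      if (depth != 8L || ctype != 0L) {
        stop("only 8-bit grayscale PNG is supported (got depth ", depth,
             ", colour type ", ctype, ")")
      }
      if (as.integer(data[13]) != 0L) stop("interlaced PNG not supported")
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") {
      break
    }
    pos <- pos + 12L + len
  }
  if (is.na(w)) stop("missing IHDR chunk")
  flat <- as.integer(memDecompress(idat, type = "gzip"))
  stride <- w + 1L
  if (length(flat) != h * stride) stop("corrupt PNG scanline data")
  out <- matrix(0L, nrow = h, ncol = w)
  prev <- integer(w)
  for (y in seq_len(h)) {
    off <- (y - 1L) * stride
    filt <- flat[off + 1L]
    row <- flat[(off + 2L):(off + stride)]
    if (filt == 0L) {
      # unfiltered
    } else if (filt == 1L) { # Sub
      for (x in 2:w) row[x] <- (row[x] + row[x - 1L]) %% 256L
    } else if (filt == 2L) { # Up
      row <- (row + prev) %% 256L
    } else if (filt == 3L) { # Average
      row[1L] <- (row[1L] + prev[1L] %/% 2L) %% 256L
      for (x in 2:w) {
        row[x] <- (row[x] + (row[x - 1L] + prev[x]) %/% 2L) %% 256L
      }
    } else if (filt == 4L) { # Paeth
      row[1L] <- (row[1L] + .paeth(0L, prev[1L], 0L)) %% 256L
      for (x in 2:w) {
        row[x] <- (row[x] + .paeth(row[x - 1L], prev[x], prev[x - 1L])) %% 256L
      }
    } else {
      stop("unknown PNG filter type ", filt)
    }
    out[y, ] <- row
    prev <- row
  }
  out / 255
}
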