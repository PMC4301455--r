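# Grayscale image and label-mask I/O.
#
# The package reads single-plane grayscale TIFF (uncompressed or deflate)
# and 8/16-bit grayscale PNG, and writes label masks as unsigned-integer
# TIFF (16-bit, escalating to 32-bit when a label exceeds 65535). Minimal
# codecs for these two formats are implemented here in base R; intensities
# are never rescaled on read, so all downstream percentile logic is
# scale-invariant by construction.

#' Read a grayscale image
#'
#' Reads a single-plane grayscale TIFF (uncompressed or deflate-compressed)
#' or an 8/16-bit grayscale PNG. Pixel values are returned exactly as stored,
#' without normalization.
#'
#' @param path Path to an existing `.tif`/`.tiff` or `.png` file.
#' @return Numeric matrix (`height x width`) of pixel intensities.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) >= 8 && identical(bytes[1:8], png_signature()))
    return(png_read(bytes))
  if (length(bytes) >= 4 &&
      (identical(as.integer(bytes[1:2]), c(73L, 73L)) ||
       identical(as.integer(bytes[1:2]), c(77L, 77L))))
    return(tiff_read(bytes))
  stop("unrecognized image format (expected TIFF or PNG): ", path, call. = FALSE)
}

#' Read a labeled mask
#'
#' Same as [read_gray()] but coerces to integer storage and checks that the
#' values are non-negative integers.
#'
#' @inheritParams read_gray
#' @return Integer matrix; 0 is background, positive values are object ids.
#' @export
read_labels <- function(path) {
  img <- read_gray(path)
  if (any(img < 0) || any(img != round(img)))
    stop("not a label image (negative or fractional values): ", path, call. = FALSE)
  storage.mode(img) <- "integer"
  img
}

#' Write a labeled mask as TIFF
#'
#' Labels are stored as unsigned 16-bit TIFF, escalating to 32-bit when the
#' maximum label exceeds 65535. The round trip through [read_labels()] is
#' lossless.
#'
#' @param labels Integer matrix of non-negative labels.
#' @param path Destination path.
#' @export
write_labels <- function(labels, path) {
  assert_labels(labels)
  bits <- if (max(labels) > 65535) 32L else 16L
  tiff_write_gray(labels, path, bits = bits)
  invisible(path)
}

#' Write a grayscale image
#'
#' Dispatches on the file extension: `.png` writes 8-bit (or 16-bit when
#' needed) grayscale PNG, anything else writes grayscale TIFF.
#'
#' @param img Numeric matrix of non-negative integer intensities.
#' @param path Destination path.
#' @export
write_gray <- function(img, path) {
  assert_gray(img)
  if (any(img < 0) || any(img != round(img)))
    stop("write_gray stores integer intensities; round/offset the image first",
         call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png_write_gray(img, path, bit_depth = if (max(img) > 255) 16L else 8L)
  } else {
    bits <- if (max(img) > 65535) 32L else if (max(img) > 255) 16L else 8L
    tiff_write_gray(img, path, bits = bits)
  }
  invisible(path)
}

## ------------------------------------------------------------------ TIFF

rd_uint <- function(bytes, off, size, endian) {
  # off is 0-based; values < 2^31 assumed (file offsets, dims)
  b <- as.integer(bytes[off + seq_len(size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

tiff_read <- function(bytes) {
  endian <- if (identical(as.integer(bytes[1:2]), c(77L, 77L))) "big" else "little"
  if (rd_uint(bytes, 2, 2, endian) != 42)
    stop("not a valid TIFF file", call. = FALSE)
  ifd <- rd_uint(bytes, 4, 4, endian)
  nent <- rd_uint(bytes, ifd, 2, endian)
  type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)
  tags <- list()
  for (i in seq_len(nent) - 1) {
    e <- ifd + 2 + 12 * i
    tag <- rd_uint(bytes, e, 2, endian)
    typ <- rd_uint(bytes, e + 2, 2, endian)
    cnt <- rd_uint(bytes, e + 4, 4, endian)
    sz <- type_size[typ] * cnt
    voff <- if (sz > 4) rd_uint(bytes, e + 8, 4, endian) else e + 8
    step <- type_size[typ]
    vals <- vapply(seq_len(cnt) - 1, function(j)
      rd_uint(bytes, voff + j * step, step, endian), numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  nxt <- rd_uint(bytes, ifd + 2 + 12 * nent, 4, endian)
  if (nxt != 0) stop("multi-page image not supported", call. = FALSE)

  gtag <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  width <- gtag(256); height <- gtag(257)
  if (is.null(width) || is.null(height)) stop("malformed TIFF: no dimensions", call. = FALSE)
  spp <- gtag(277, 1)
  if (spp != 1) stop("multi-channel image not supported", call. = FALSE)
  photo <- gtag(262, 1)
  if (!photo %in% c(0, 1)) stop("multi-channel image not supported", call. = FALSE)
  bits <- gtag(258, 1)
  if (!bits %in% c(8, 16, 32)) stop("unsupported bit depth: ", bits, call. = FALSE)
  comp <- gtag(259, 1)
  if (!comp %in% c(1, 8, 32946)) stop("unsupported TIFF compression: ", comp, call. = FALSE)
  fmt <- gtag(339, 1)
  if (!fmt %in% c(1, 2, 3)) stop("non-numeric pixel type", call. = FALSE)
  offs <- gtag(273); cnts <- gtag(279)
  if (is.null(offs) || is.null(cnts)) stop("malformed TIFF: no strip data", call. = FALSE)

  data <- raw(0)
  for (i in seq_along(offs)) {
    strip <- bytes[offs[i] + seq_len(cnts[i])]
    if (comp != 1) strip <- memDecompress(strip, type = "gzip")
    data <- c(data, strip)
  }
  n <- width * height
  vals <- if (bits == 8) {
    as.numeric(data[seq_len(n)])
  } else if (fmt == 3) {
    readBin(data, "double", n = n, size = bits / 8, endian = endian)
  } else {
    readBin(data, "integer", n = n, size = bits / 8, endian = endian,
            signed = (bits == 32 || fmt == 2))
  }
  if (bits == 32 && fmt == 1 && any(vals < 0))
    stop("32-bit unsigned values exceed R integer range", call. = FALSE)
  t(matrix(vals, nrow = width, ncol = height))
}

tiff_write_gray <- function(img, path, bits = 16L) {
  height <- nrow(img); width <- ncol(img)
  vals <- as.integer(t(img)) # scanline order
  if (any(vals >= 2^bits)) stop("pixel value does not fit in ", bits, " bits", call. = FALSE)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); u16(42)
  data_bytes <- width * height * bits / 8
  u32(8 + data_bytes) # IFD offset, data first
  if (bits == 8) writeBin(as.raw(vals), con)
  else writeBin(vals, con, size = bits / 8, endian = "little")
  entry <- function(tag, typ, cnt, val) { u16(tag); u16(typ); u32(cnt); u32(val) }
  n_entries <- 10L
  u16(n_entries)
  entry(256, 4, 1, width)         # ImageWidth
  entry(257, 4, 1, height)        # ImageLength
  entry(258, 3, 1, bits)          # BitsPerSample
  entry(259, 3, 1, 1)             # Compression: none
  entry(262, 3, 1, 1)             # Photometric: BlackIsZero
  entry(273, 4, 1, 8)             # StripOffsets: data right after header
  entry(277, 3, 1, 1)             # SamplesPerPixel
  entry(278, 4, 1, height)        # RowsPerStrip
  entry(279, 4, 1, data_bytes)    # StripByteCounts
  entry(339, 3, 1, 1)             # SampleFormat: unsigned
  u32(0) # no next IFD
  writeBin(rawConnectionValue(con), path)
  invisible(path)
}

## ------------------------------------------------------------------- PNG

png_signature <- function() as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))

.crc_env <- new.env(parent = emptyenv())

crc_table <- function() {
  if (is.null(.crc_env$tab)) {
    tab <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L) != 0L) bitwXor(-306674912L, bitwShiftR(c, 1L))
             else bitwShiftR(c, 1L)
      tab[n + 1] <- c
    }
    .crc_env$tab <- tab
  }
  .crc_env$tab
}

crc32 <- function(bytes) {
  tab <- crc_table()
  c <- -1L
  for (b in as.integer(bytes))
    c <- bitwXor(tab[bitwAnd(bitwXor(c, b), 255L) + 1L], bitwShiftR(c, 8L))
  bitwXor(c, -1L)
}

u32be_raw <- function(x) {
  x <- as.numeric(x); if (x < 0) x <- x + 2^32
  as.raw(c(x %/% 2^24, x %/% 2^16, x %/% 2^8, x) %% 256)
}

rd_u32be <- function(bytes, off) rd_uint(bytes, off, 4, "big")

png_read <- function(bytes) {
  pos <- 8
  width <- height <- bitdepth <- colortype <- interlace <- NULL
  idat <- raw(0)
  while (pos + 8 <= length(bytes)) {
    len <- rd_u32be(bytes, pos)
    type <- rawToChar(bytes[pos + 4 + 1:4])
    data_off <- pos + 8
    if (type == "IHDR") {
      width <- rd_u32be(bytes, data_off)
      height <- rd_u32be(bytes, data_off + 4)
      bitdepth <- as.integer(bytes[data_off + 9])
      colortype <- as.integer(bytes[data_off + 10])
      interlace <- as.integer(bytes[data_off + 13])
    } else if (type == "IDAT") {
      idat <- c(idat, bytes[data_off + seq_len(len)])
    } else if (type == "IEND") break
    pos <- data_off + len + 4
  }
  if (is.null(width)) stop("malformed PNG: no IHDR", call. = FALSE)
  if (colortype != 0L) stop("multi-channel image not supported", call. = FALSE)
  if (!bitdepth %in% c(8L, 16L)) stop("unsupported PNG bit depth: ", bitdepth, call. = FALSE)
  if (interlace != 0L) stop("interlaced PNG not supported", call. = FALSE)

  out <- memDecompress(idat, type = "gzip") # zlib stream
  bpp <- bitdepth / 8L
  stride <- width * bpp
  recon <- matrix(0L, nrow = stride, ncol = height)
  prev <- integer(stride)
  for (r in seq_len(height)) {
    off <- (r - 1) * (stride + 1)
    ftype <- as.integer(out[off + 1])
    line <- as.integer(out[off + 1 + seq_len(stride)])
    cur <- integer(stride)
    if (ftype == 0L) {
      cur <- line
    } else if (ftype == 2L) {
      cur <- (line + prev) %% 256L
    } else if (ftype == 1L) {
      for (i in seq_len(stride))
        cur[i] <- (line[i] + if (i > bpp) cur[i - bpp] else 0L) %% 256L
    } else if (ftype == 3L) {
      for (i in seq_len(stride)) {
        left <- if (i > bpp) cur[i - bpp] else 0L
        cur[i] <- (line[i] + (left + prev[i]) %/% 2L) %% 256L
      }
    } else if (ftype == 4L) {
      for (i in seq_len(stride)) {
        a <- if (i > bpp) cur[i - bpp] else 0L
        b <- prev[i]
        cc <- if (i > bpp) prev[i - bpp] else 0L
        p <- a + b - cc
        pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
        pr <- if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
        cur[i] <- (line[i] + pr) %% 256L
      }
    } else stop("unsupported PNG filter type: ", ftype, call. = FALSE)
    recon[, r] <- cur
    prev <- cur
  }
  vals <- if (bitdepth == 8L) as.numeric(recon)
          else as.numeric(recon[seq(1, stride, 2), ] * 256L + recon[seq(2, stride, 2), ])
  t(matrix(vals, nrow = width, ncol = height))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be_raw(length(data)), body, u32be_raw(crc32(body)))
}

# Internal PNG writer (grayscale; `rgb = TRUE` writes an 8-bit truecolor
# image from an height x width x 3 array — used only to build test fixtures
# for the multi-channel rejection path).
png_write_gray <- function(img, path, bit_depth = 8L, rgb = FALSE) {
  if (rgb) {
    height <- dim(img)[1]; width <- dim(img)[2]
    colortype <- 2L; bit_depth <- 8L
    lines <- vapply(seq_len(height), function(r)
      as.raw(as.integer(t(img[r, , ]))), raw(width * 3)) # per-row RGB triples
    scan <- lapply(seq_len(height), function(r) c(as.raw(0), lines[, r]))
  } else {
    height <- nrow(img); width <- ncol(img)
    colortype <- 0L
    scan <- lapply(seq_len(height), function(r) {
      v <- as.integer(img[r, ])
      bytes <- if (bit_depth == 8L) as.raw(v)
               else as.raw(as.integer(rbind(v %/% 256L, v %% 256L)))
      c(as.raw(0), bytes)
    })
  }
  ihdr <- c(u32be_raw(width), u32be_raw(height),
            as.raw(c(bit_depth, colortype, 0, 0, 0)))
  z <- memCompress(do.call(c, scan), type = "gzip") # zlib stream
  out <- c(png_signature(), png_chunk("IHDR", ihdr),
           png_chunk("IDAT", z), png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
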