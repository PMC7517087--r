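# Raster I/O. The package carries its own minimal PNG codec (8-bit,
# non-interlaced; gray / gray+alpha / RGB / RGBA) built on R's zlib
# bindings, plus netpbm PGM/PPM support (both ASCII and binary variants).
# No system image library is required.

PNG_SIG <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))

# ---- CRC32 (PNG chunk checksums) ----------------------------------------

u32_to_int <- function(x) {
  x <- x %% 2^32
  as.integer(ifelse(x >= 2^31, x - 2^32, x))
}

int_to_u32 <- function(x) ifelse(x < 0, x + 2^32, as.numeric(x))

crc32_table <- local({
  tab <- integer(256)
  poly <- u32_to_int(0xEDB88320)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) bitwXor(poly, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

write_u32_be <- function(con, x) {
  u <- int_to_u32(x)
  writeBin(as.raw(c(u %/% 2^24, (u %/% 2^16) %% 256, (u %/% 2^8) %% 256, u %% 256)), con)
}

read_u32_be <- function(bytes) {
  sum(as.numeric(bytes) * c(2^24, 2^16, 2^8, 1))
}

# ---- PNG ----------------------------------------------------------------

#' Write an 8-bit grayscale PNG
#'
#' @param img gray image matrix (see [as_gray_image()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  img <- as_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(PNG_SIG, con)
  put_chunk <- function(type, data) {
    write_u32_be(con, length(data))
    payload <- c(charToRaw(type), data)
    writeBin(payload, con)
    write_u32_be(con, crc32(payload))
  }
  ihdr <- raw(13)
  dims <- c(w, h)
  for (i in 1:2) {
    u <- dims[i]
    ihdr[(i - 1) * 4 + 1:4] <- as.raw(c(u %/% 2^24, (u %/% 2^16) %% 256, (u %/% 2^8) %% 256, u %% 256))
  }
  ihdr[9] <- as.raw(8L)   # bit depth
  ihdr[10] <- as.raw(0L)  # color type: grayscale
  put_chunk("IHDR", ihdr)
  # scanlines: filter byte 0 then row bytes (row-major)
  scan <- raw((w + 1L) * h)
  rowbytes <- t(img)  # column-major transpose = row-major pixels
  for (r in seq_len(h)) {
    scan[((r - 1L) * (w + 1L) + 2L):((r) * (w + 1L))] <- as.raw(rowbytes[, r])
  }
  put_chunk("IDAT", memCompress(scan, type = "gzip"))
  put_chunk("IEND", raw(0))
  invisible(path)
}

# Undo PNG scanline filtering; returns an h x (w*ch) integer matrix of samples.
png_unfilter <- function(raw_data, h, w, ch) {
  stride <- w * ch
  out <- matrix(0L, nrow = h, ncol = stride)
  pos <- 1L
  prior <- integer(stride)
  for (r in seq_len(h)) {
    ft <- as.integer(raw_data[pos]); pos <- pos + 1L
    row <- as.integer(raw_data[pos:(pos + stride - 1L)]); pos <- pos + stride
    if (ft == 0L) {
      rec <- row
    } else if (ft == 1L) {  # Sub: per-channel cumulative sum mod 256
      rec <- row
      for (c0 in seq_len(ch)) {
        sel <- seq.int(c0, stride, by = ch)
        rec[sel] <- cumsum(row[sel]) %% 256L
      }
    } else if (ft == 2L) {  # Up
      rec <- (row + prior) %% 256L
    } else if (ft == 3L) {  # Average
      rec <- integer(stride)
      for (i in seq_len(stride)) {
        left <- if (i > ch) rec[i - ch] else 0L
        rec[i] <- (row[i] + (left + prior[i]) %/% 2L) %% 256L
      }
    } else if (ft == 4L) {  # Paeth
      rec <- integer(stride)
      for (i in seq_len(stride)) {
        a <- if (i > ch) rec[i - ch] else 0L
        b <- prior[i]
        cc <- if (i > ch) prior[i - ch] else 0L
        p <- a + b - cc
        pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
        pred <- if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
        rec[i] <- (row[i] + pred) %% 256L
      }
    } else {
      stop("unsupported PNG filter type ", ft, call. = FALSE)
    }
    out[r, ] <- rec
    prior <- rec
  }
  out
}

#' Read a PNG image
#'
#' Supports 8-bit, non-interlaced grayscale, gray+alpha, RGB and RGBA.
#' Color is reduced to one channel with ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114); alpha is ignored.
#'
#' @param path file path.
#' @return gray image matrix.
#' @export
read_png <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 8 || !identical(bytes[1:8], PNG_SIG)) {
    stop("not a PNG file: ", path, call. = FALSE)
  }
  pos <- 9L
  width <- height <- bitdepth <- coltype <- interlace <- NA
  idat <- list()
  while (pos + 8 <= length(bytes)) {
    len <- read_u32_be(bytes[pos:(pos + 3L)])
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) bytes[(pos + 8L):(pos + 7L + len)] else raw(0)
    if (type == "IHDR") {
      width <- read_u32_be(data[1:4]); height <- read_u32_be(data[5:8])
      bitdepth <- as.integer(data[9]); coltype <- as.integer(data[10])
      interlace <- as.integer(data[13])
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- data
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.na(width)) stop("corrupt PNG (no IHDR): ", path, call. = FALSE)
  if (bitdepth != 8L) stop("only 8-bit PNGs are supported: ", path, call. = FALSE)
  if (interlace != 0L) stop("interlaced PNGs are not supported: ", path, call. = FALSE)
  ch <- switch(as.character(coltype), "0" = 1L, "2" = 3L, "4" = 2L, "6" = 4L,
               stop("unsupported PNG color type ", coltype, call. = FALSE))
  raw_data <- memDecompress(do.call(c, idat), type = "gzip")
  samples <- png_unfilter(raw_data, height, width, ch)
  if (ch == 1L) {
    img <- samples
  } else if (ch == 2L) {
    img <- samples[, seq.int(1L, width * 2L, by = 2L), drop = FALSE]
  } else {
    rch <- samples[, seq.int(1L, width * ch, by = ch), drop = FALSE]
    gch <- samples[, seq.int(2L, width * ch, by = ch), drop = FALSE]
    bch <- samples[, seq.int(3L, width * ch, by = ch), drop = FALSE]
    img <- round_half_up(0.299 * rch + 0.587 * gch + 0.114 * bch)
  }
  as_gray_image(matrix(as.integer(img), nrow = height))
}

# ---- netpbm (PGM/PPM) ---------------------------------------------------

#' Read a PGM/PPM image (P2, P3, P5, P6; maxval <= 255)
#' @param path file path.
#' @return gray image matrix (color reduced by BT.601 luma).
#' @export
read_pnm <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  txt_head <- rawToChar(bytes[1:min(2L, length(bytes))])
  if (!(txt_head %in% c("P2", "P3", "P5", "P6"))) {
    stop("not a supported PGM/PPM file: ", path, call. = FALSE)
  }
  # tokenize header: magic, width, height, maxval (comments start with #)
  pos <- 1L
  tokens <- character(0)
  n <- length(bytes)
  while (length(tokens) < 4L && pos <= n) {
    b <- bytes[pos]
    c1 <- rawToChar(b)
    if (c1 == "#") {
      while (pos <= n && !rawToChar(bytes[pos]) %in% c("\n", "\r")) pos <- pos + 1L
    } else if (grepl("[[:space:]]", c1)) {
      pos <- pos + 1L
    } else {
      start <- pos
      while (pos <= n && !grepl("[[:space:]]", rawToChar(bytes[pos])) &&
             rawToChar(bytes[pos]) != "#") pos <- pos + 1L
      tokens <- c(tokens, rawToChar(bytes[start:(pos - 1L)]))
    }
  }
  if (length(tokens) < 4L) stop("corrupt PGM/PPM header: ", path, call. = FALSE)
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3]); maxval <- as.integer(tokens[4])
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval > 255L) {
    stop("unsupported PGM/PPM header (need maxval <= 255): ", path, call. = FALSE)
  }
  ch <- if (magic %in% c("P3", "P6")) 3L else 1L
  npx <- as.numeric(w) * h * ch
  if (magic %in% c("P5", "P6")) {
    pos <- pos + 1L  # single whitespace after maxval
    vals <- as.integer(bytes[pos:(pos + npx - 1L)])
  } else {
    body <- rawToChar(bytes[pos:n])
    body <- gsub("#[^\n]*", "", body)
    vals <- as.integer(strsplit(trimws(body), "[[:space:]]+")[[1]])
    if (length(vals) < npx) stop("truncated PGM/PPM body: ", path, call. = FALSE)
    vals <- vals[seq_len(npx)]
  }
  if (ch == 1L) {
    img <- matrix(vals, nrow = h, byrow = TRUE)
  } else {
    m <- matrix(vals, ncol = 3L, byrow = TRUE)
    luma <- round_half_up(0.299 * m[, 1] + 0.587 * m[, 2] + 0.114 * m[, 3])
    img <- matrix(as.integer(luma), nrow = h, byrow = TRUE)
  }
  if (maxval != 255L) img <- requantize(img * (255 / maxval))
  as_gray_image(img)
}

#' Write a PGM image (binary P5, or ASCII P2)
#' @param img gray image matrix.
#' @param path output path.
#' @param ascii write the plain-text P2 variant.
#' @return `path`, invisibly.
#' @export
write_pnm <- function(img, path, ascii = FALSE) {
  img <- as_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  if (ascii) {
    lines <- c("P2", paste(w, h), "255",
               apply(img, 1, paste, collapse = " "))
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", w, h)), con)
    writeBin(as.raw(as.vector(t(img))), con)
  }
  invisible(path)
}

#' Load an image as an 8-bit grayscale raster
#'
#' Reads PNG and PGM/PPM files (format detected from the file's magic
#' bytes, not its extension). Color inputs are reduced to one channel with
#' ITU-R BT.601 luma weights (0.299, 0.587, 0.114), rounded half away from
#' zero.
#'
#' @param path path to an image file.
#' @return gray image matrix with values in \[0, 255\].
#' @export
#' @examples
#' img <- make_toy_image("checkerboard", 8, levels = c(0, 255))
#' f <- tempfile(fileext = ".png")
#' write_png(img, f)
#' identical(load_image(f), img)
load_image <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  head <- readBin(path, "raw", n = 8L)
  if (length(head) >= 8 && identical(head, PNG_SIG)) return(read_png(path))
  if (length(head) >= 2) {
    magic <- rawToChar(head[1:2])
    if (magic %in% c("P2", "P3", "P5", "P6")) return(read_pnm(path))
  }
  stop("unreadable or unsupported image file: ", path,
       " (supported: PNG, PGM/PPM)", call. = FALSE)
}

#' Save a grayscale raster to disk
#' @param img gray image matrix.
#' @param path output path; format chosen by extension (`.png`, `.pgm`).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = write_png(img, path),
    pgm = write_pnm(img, path),
    stop("unsupported output format: .", ext, " (use .png or .pgm)", call. = FALSE)
  )
}
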