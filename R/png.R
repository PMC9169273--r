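## Minimal PNG encoder.
##
## The target environment has no R package that writes pixel arrays to
## PNG, so the format is emitted directly: 8-bit RGB, colour type 2, no
## interlace, filter 0 on every scanline, one zlib-compressed IDAT via
## base R memCompress. Output is deterministic, which the replayable
## manifests rely on.

.crc_env <- new.env(parent = emptyenv())

.crc_table <- function() {
  if (is.null(.crc_env$tab)) {
    tab <- numeric(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (c %% 2 == 1) xor32(3988292384, c %/% 2) else c %/% 2
      }
      tab[n + 1] <- c
    }
    .crc_env$tab <- tab
  }
  .crc_env$tab
}

crc32_bytes <- function(bytes) {
  tab <- .crc_table()
  crc <- 4294967295
  for (b in bytes) {
    idx <- bitwXor(as.integer(crc %% 256), b)
    crc <- xor32(tab[idx + 1L], crc %/% 256)
  }
  xor32(crc, 4294967295)
}

u32_bytes <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  tb <- as.integer(charToRaw(type))
  payload <- c(tb, as.integer(data))
  c(u32_bytes(length(data)), charToRaw(type), data,
    u32_bytes(crc32_bytes(payload)))
}

#' Write a raster image as a PNG file
#'
#' @param img raster array (`[0, 1]` values, `h x w x 3`).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_png <- function(img, path) {
  h <- img_height(img); w <- img_width(img)
  px <- round(clamp01(img) * 255)
  ## interleave to RGB scanlines, filter byte 0 per row
  inter <- aperm(px, c(3L, 2L, 1L)) # channel, col, row
  rows <- matrix(as.integer(inter), nrow = 3L * w, ncol = h)
  raw_stream <- as.raw(rbind(0L, rows))
  idat <- memCompress(raw_stream, type = "gzip")
  ihdr <- c(u32_bytes(w), u32_bytes(h), as.raw(c(8L, 2L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
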