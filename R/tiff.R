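# Minimal single-channel 32-bit float TIFF codec.
#
# Heights are stored as uncompressed IEEE float32 strips, little-endian on
# write; both byte orders are accepted on read. Only the single layout this
# package writes is accepted back (one sample per pixel, 32-bit IEEE float,
# no compression): anything else -- in particular integer or multi-channel
# TIFFs from instrument software -- is rejected with a named violation
# rather than silently reinterpreted.

.tiff_tag <- function(tag, type, count, value) {
  # 12-byte IFD entry, little-endian; `value` fits in the 4-byte field
  con <- raw(0)
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    if (type == 3L) # SHORT padded to 4 bytes
      c(writeBin(as.integer(value), raw(), size = 2, endian = "little"),
        as.raw(c(0, 0)))
    else
      writeBin(as.integer(value), raw(), size = 4, endian = "little"))
}

write_tiff_f32 <- function(heights, path) {
  stopifnot(is.matrix(heights))
  nr <- nrow(heights); nc <- ncol(heights)
  pix <- writeBin(as.numeric(t(heights)), raw(), size = 4, endian = "little")
  data_offset <- 8L
  ifd_offset <- data_offset + length(pix)
  if (ifd_offset %% 2L == 1L) { pix <- c(pix, as.raw(0)); ifd_offset <- ifd_offset + 1L }
  tags <- c(
    .tiff_tag(256L, 4L, 1L, nc),                 # ImageWidth
    .tiff_tag(257L, 4L, 1L, nr),                 # ImageLength
    .tiff_tag(258L, 3L, 1L, 32L),                # BitsPerSample
    .tiff_tag(259L, 3L, 1L, 1L),                 # Compression: none
    .tiff_tag(262L, 3L, 1L, 1L),                 # Photometric: BlackIsZero
    .tiff_tag(273L, 4L, 1L, data_offset),        # StripOffsets
    .tiff_tag(277L, 3L, 1L, 1L),                 # SamplesPerPixel
    .tiff_tag(278L, 4L, 1L, nr),                 # RowsPerStrip
    .tiff_tag(279L, 4L, 1L, length(pix)),        # StripByteCounts
    .tiff_tag(339L, 3L, 1L, 3L))                 # SampleFormat: IEEE float
  n_tags <- 10L
  header <- c(charToRaw("II"),
              writeBin(42L, raw(), size = 2, endian = "little"),
              writeBin(ifd_offset, raw(), size = 4, endian = "little"))
  ifd <- c(writeBin(n_tags, raw(), size = 2, endian = "little"),
           tags,
           writeBin(0L, raw(), size = 4, endian = "little"))
  writeBin(c(header, pix, ifd), path)
  invisible(path)
}

.read_uint <- function(raw, offset, size, endian) {
  # offset is 0-based
  b <- raw[(offset + 1):(offset + size)]
  if (endian == "big") b <- rev(b)
  sum(as.numeric(b) * 256^(seq_len(size) - 1))
}

read_tiff_f32 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path, call. = FALSE)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file (bad byte-order mark): ", path, call. = FALSE)
  if (.read_uint(raw, 2, 2, endian) != 42)
    stop("not a TIFF file (bad magic): ", path, call. = FALSE)
  ifd_off <- .read_uint(raw, 4, 4, endian)
  n_tags <- .read_uint(raw, ifd_off, 2, endian)
  tags <- list()
  for (k in seq_len(n_tags)) {
    e <- ifd_off + 2 + (k - 1) * 12
    tag <- .read_uint(raw, e, 2, endian)
    type <- .read_uint(raw, e + 2, 2, endian)
    count <- .read_uint(raw, e + 4, 4, endian)
    size <- switch(as.character(type), "3" = 2L, "4" = 4L, "1" = 1L, NA_integer_)
    if (is.na(size)) next
    vals <- if (count * size <= 4) {
      vapply(seq_len(count) - 1,
             function(i) .read_uint(raw, e + 8 + i * size, size, endian), 0)
    } else {
      off <- .read_uint(raw, e + 8, 4, endian)
      vapply(seq_len(count) - 1,
             function(i) .read_uint(raw, off + i * size, size, endian), 0)
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag, call. = FALSE)
      default
    } else v
  }
  width <- need(256); height <- need(257)
  spp <- need(277, 1); bits <- need(258, 1); fmt <- need(339, 1)
  comp <- need(259, 1)
  if (length(spp) != 1 || spp != 1 || length(bits) != 1)
    stop("unsupported TIFF: multi-channel image (expected a single-channel float32 height map)",
         call. = FALSE)
  if (fmt != 3 || bits != 32)
    stop("unsupported TIFF: not 32-bit IEEE float samples (integer or non-float TIFFs are rejected)",
         call. = FALSE)
  if (comp != 1)
    stop("unsupported TIFF: compressed data (expected uncompressed strips)", call. = FALSE)
  offs <- need(273); counts <- need(279)
  if (length(offs) != length(counts))
    stop("malformed TIFF: strip offset/count mismatch", call. = FALSE)
  pix <- raw(0)
  for (k in seq_along(offs))
    pix <- c(pix, raw[(offs[k] + 1):(offs[k] + counts[k])])
  vals <- readBin(pix, "numeric", n = width * height, size = 4, endian = endian)
  matrix(vals, nrow = height, ncol = width, byrow = TRUE)
}
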