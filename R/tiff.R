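# Minimal baseline-TIFF codec for single-channel quantification images.
#
# The deployment environment provides no R TIFF package, so the package
# carries its own reader/writer for the narrow profile it needs: grayscale,
# uncompressed, single sample per pixel, 8/16-bit unsigned or 32-bit float.
# The writer emits little-endian, single-strip files with the physical pixel
# size and channel recorded as a JSON ImageDescription tag; the reader
# additionally accepts big-endian and multi-strip layouts.  Round trips are
# validated in the test suite against Python's tifffile as an independent
# oracle.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

#' Write a fluorescence image as grayscale TIFF
#'
#' Writes an uncompressed single-strip grayscale TIFF (little-endian).  The
#' pixel size in nm and the channel label are stored as a JSON string in the
#' ImageDescription tag so that [read_image()] can recover them.
#'
#' @param image a [fluor_image()].
#' @param path output file path.
#' @param bits one of 32 (IEEE float, default), 16 or 8 (unsigned integer;
#'   values are rounded and must fit the range).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 32L) {
  stopifnot_image(image)
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L, 32L)) stop("bits must be 8, 16 or 32")
  px <- as_matrix(image)
  desc <- jsonlite::toJSON(list(pixel_size_nm = pixel_size(image),
                                channel = attr(image, "channel")),
                           auto_unbox = TRUE)
  desc <- as.character(desc)                   # NUL terminator added below
  nr <- nrow(px); nc <- ncol(px)
  # row-major pixel stream, top row first
  vals <- as.vector(t(px))
  if (bits == 32L) {
    data_raw <- writeBin(as.numeric(vals), raw(), size = 4L,
                         endian = "little")
    sample_format <- 3L
  } else {
    vmax <- 2^bits - 1
    iv <- round(vals)
    if (any(iv < 0 | iv > vmax))
      stop(sprintf("values out of range for %d-bit unsigned TIFF", bits))
    data_raw <- writeBin(as.integer(iv), raw(), size = bits %/% 8L,
                         endian = "little")
    sample_format <- 1L
  }
  n_data <- length(data_raw)
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  strip_offset <- 8L
  desc_offset <- strip_offset + n_data
  ifd_offset <- desc_offset + length(desc_raw)
  if (ifd_offset %% 2L == 1L) {           # word-align the IFD
    desc_raw <- c(desc_raw, as.raw(0L))
    ifd_offset <- ifd_offset + 1L
  }

  entry <- function(tag, type, count, value) {
    # value packed into 4 bytes (left-justified short, or a long/offset)
    v <- writeBin(as.integer(c(tag, type)), raw(), size = 2L,
                  endian = "little")
    v <- c(v, writeBin(as.integer(count), raw(), size = 4L,
                       endian = "little"))
    if (type == 3L && count == 1L) {
      v <- c(v, writeBin(as.integer(value), raw(), size = 2L,
                         endian = "little"), as.raw(c(0L, 0L)))
    } else {
      v <- c(v, writeBin(as.integer(value), raw(), size = 4L,
                         endian = "little"))
    }
    v
  }
  entries <- list(
    entry(256L, 4L, 1L, nc),                     # ImageWidth
    entry(257L, 4L, 1L, nr),                     # ImageLength
    entry(258L, 3L, 1L, bits),                   # BitsPerSample
    entry(259L, 3L, 1L, 1L),                     # Compression = none
    entry(262L, 3L, 1L, 1L),                     # Photometric = BlackIsZero
    entry(270L, 2L, length(desc_raw), desc_offset),  # ImageDescription
    entry(273L, 4L, 1L, strip_offset),           # StripOffsets
    entry(277L, 3L, 1L, 1L),                     # SamplesPerPixel
    entry(278L, 4L, 1L, nr),                     # RowsPerStrip
    entry(279L, 4L, 1L, n_data),                 # StripByteCounts
    entry(339L, 3L, 1L, sample_format)           # SampleFormat
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42L), con, size = 2L, endian = "little")
  writeBin(as.integer(strip_offset + n_data + length(desc_raw)), con,
           size = 4L, endian = "little")        # == ifd_offset
  writeBin(data_raw, con)
  writeBin(desc_raw, con)
  writeBin(as.integer(length(entries)), con, size = 2L, endian = "little")
  for (e in entries) writeBin(e, con)
  writeBin(0L, con, size = 4L, endian = "little")  # no next IFD
  invisible(path)
}

read_uint <- function(raw, offset, size, endian) {
  b <- as.integer(raw[(offset + 1L):(offset + size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_along(b) - 1L))
}

#' Read a grayscale TIFF as a fluorescence image
#'
#' Reads uncompressed grayscale TIFFs (8/16-bit unsigned or 32-bit float,
#' either byte order, single or multiple strips).  Intensities are cast to
#' double and never rescaled.  The pixel size is taken from the explicit
#' argument if given, otherwise from a JSON `{"pixel_size_nm": ...}`
#' ImageDescription written by [write_image()]; if neither source provides
#' it, an error is raised rather than silently assuming a default.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm optional override for the physical pixel size (nm).
#' @param channel optional override for the channel label.
#' @return a [fluor_image()].
#' @export
read_image <- function(path, pixel_size_nm = NULL, channel = NULL) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  if (read_uint(raw, 2L, 2L, endian) != 42L)
    stop("not a TIFF file: ", path)
  ifd <- read_uint(raw, 4L, 4L, endian)
  n_entries <- read_uint(raw, ifd, 2L, endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tag <- read_uint(raw, off, 2L, endian)
    type <- read_uint(raw, off + 2L, 2L, endian)
    count <- read_uint(raw, off + 4L, 4L, endian)
    tsize <- TIFF_TYPE_SIZES[type]
    nbytes <- tsize * count
    voff <- if (nbytes <= 4L) off + 8L else read_uint(raw, off + 8L, 4L, endian)
    vals <- if (type == 2L) {
      b <- raw[(voff + 1L):(voff + count)]
      nul <- which(b == as.raw(0L))
      if (length(nul)) b <- b[seq_len(nul[1] - 1L)]
      rawToChar(b)
    } else {
      vapply(seq_len(count) - 1L,
             function(k) read_uint(raw, voff + k * tsize, tsize, endian), 0)
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag)
      default
    } else v
  }
  nc <- need(256L); nr <- need(257L)
  bits <- need(258L, 1L)
  if (need(259L, 1L) != 1L) stop("compressed TIFF not supported")
  spp <- need(277L, 1L)
  if (length(bits) > 1L || spp != 1L)
    stop("RGB / multi-sample TIFF not supported; supply a grayscale image")
  fmt <- need(339L, 1L)
  offsets <- need(273L)
  counts <- need(279L, nr * nc * bits / 8L)
  data_raw <- raw(0)
  for (i in seq_along(offsets))
    data_raw <- c(data_raw,
                  raw[(offsets[i] + 1L):(offsets[i] + counts[i])])
  n_px <- nr * nc
  vals <- if (fmt == 3L) {
    if (bits != 32L) stop("only 32-bit float TIFF supported")
    readBin(data_raw, "double", n = n_px, size = 4L, endian = endian)
  } else if (fmt %in% c(1L, 2L)) {
    readBin(data_raw, "integer", n = n_px, size = bits / 8L,
            signed = (fmt == 2L || bits == 32L), endian = endian)
  } else stop("unsupported TIFF sample format ", fmt)
  if (bits == 16L && fmt == 1L) vals <- ifelse(vals < 0, vals + 65536, vals)
  px <- matrix(as.numeric(vals), nrow = nr, ncol = nc, byrow = TRUE)

  meta <- list()
  if (!is.null(tags[["270"]])) {
    meta <- tryCatch(jsonlite::fromJSON(tags[["270"]]),
                     error = function(e) list())
  }
  if (is.null(pixel_size_nm)) pixel_size_nm <- meta$pixel_size_nm
  if (is.null(pixel_size_nm))
    stop("pixel size not found: pass pixel_size_nm or use a TIFF written ",
         "by write_image()")
  if (is.null(channel)) channel <- meta$channel %||% "unknown"
  fluor_image(pmax(px, 0), pixel_size_nm, channel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a label map as an 8-bit TIFF
#'
#' @param labels an integer label map (values 0..255).
#' @param path output path.
#' @param pixel_size_nm pixel size recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path, pixel_size_nm = pixel_size(labels)) {
  img <- fluor_image(unclass(labels), pixel_size_nm, channel = "labels")
  write_image(img, path, bits = 8L)
}
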