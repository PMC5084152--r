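# Minimal baseline TIFF 6.0 reader/writer (uncompressed, single-sample
# grayscale, multi-page). Pixel data are written as 32-bit IEEE floats so
# image sequences round-trip bit-exactly. No compression, tiling or colour
# support: this is deliberately the smallest dialect that tifffile/ImageJ/
# Bio-Formats all read, not a general TIFF library.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

read_uint <- function(con, size, endian) {
  if (size == 2L)
    readBin(con, "integer", n = 1L, size = 2L, signed = FALSE, endian = endian)
  else readBin(con, "integer", n = 1L, size = 4L, endian = endian)
}

# Reads one IFD at `offset`; returns list(tags = named list, next_offset).
read_ifd <- function(con, offset, endian) {
  seek(con, offset)
  n <- read_uint(con, 2L, endian)
  entries <- vector("list", n)
  raw_entries <- lapply(seq_len(n), function(i) {
    tag <- read_uint(con, 2L, endian)
    type <- read_uint(con, 2L, endian)
    count <- read_uint(con, 4L, endian)
    value_raw <- readBin(con, "raw", n = 4L)
    list(tag = tag, type = type, count = count, value_raw = value_raw)
  })
  next_offset <- read_uint(con, 4L, endian)
  tags <- list()
  for (e in raw_entries) {
    if (e$type < 1L || e$type > 12L) next
    esz <- TIFF_TYPE_SIZES[e$type]
    nbytes <- esz * e$count
    payload <- if (nbytes <= 4L) e$value_raw[seq_len(nbytes)] else {
      off <- readBin(e$value_raw, "integer", size = 4L, endian = endian)
      seek(con, off)
      readBin(con, "raw", n = nbytes)
    }
    val <- switch(as.character(e$type),
      "1" = as.integer(payload),
      "2" = rawToChar(payload[payload != as.raw(0)]),
      "3" = readBin(payload, "integer", n = e$count, size = 2L,
                    signed = FALSE, endian = endian),
      "4" = readBin(payload, "integer", n = e$count, size = 4L, endian = endian),
      NULL)
    if (!is.null(val)) tags[[as.character(e$tag)]] <- val
  }
  list(tags = tags, next_offset = next_offset)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports uncompressed baseline TIFF with 8/16-bit unsigned or 32-bit float
#' samples, little- or big-endian, one sample per pixel.
#'
#' @param path TIFF file path.
#' @return List with `pages` (list of numeric `height x width` matrices) and
#'   `description` (ImageDescription string of the first page, or `NULL`).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  endian <- if (identical(rawToChar(magic), "II")) "little"
            else if (identical(rawToChar(magic), "MM")) "big"
            else stop("not a TIFF file (bad byte-order mark)")
  if (read_uint(con, 2L, endian) != 42L) stop("not a TIFF file (bad magic)")
  offset <- read_uint(con, 4L, endian)
  pages <- list(); description <- NULL
  while (offset != 0L) {
    ifd <- read_ifd(con, offset, endian)
    tg <- ifd$tags
    width <- tg[["256"]]; height <- tg[["257"]]
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions")
    bits <- if (is.null(tg[["258"]])) 1L else tg[["258"]][1L]
    if (!is.null(tg[["259"]]) && tg[["259"]] != 1L)
      stop("only uncompressed TIFF is supported (compression tag ",
           tg[["259"]], ")")
    sample_format <- if (is.null(tg[["339"]])) 1L else tg[["339"]][1L]
    strip_offsets <- tg[["273"]]; strip_counts <- tg[["279"]]
    if (is.null(strip_offsets)) stop("TIFF page has no strip offsets")
    if (is.null(strip_counts))
      strip_counts <- rep(width * height * bits / 8L / length(strip_offsets),
                          length(strip_offsets))
    raw_all <- raw(0)
    for (k in seq_along(strip_offsets)) {
      seek(con, strip_offsets[k])
      raw_all <- c(raw_all, readBin(con, "raw", n = strip_counts[k]))
    }
    npx <- width * height
    vals <- if (sample_format == 3L && bits == 32L) {
      readBin(raw_all, "double", n = npx, size = 4L, endian = endian)
    } else if (sample_format %in% c(1L, 2L) && bits == 8L) {
      as.numeric(readBin(raw_all, "integer", n = npx, size = 1L,
                         signed = FALSE, endian = endian))
    } else if (sample_format %in% c(1L, 2L) && bits == 16L) {
      as.numeric(readBin(raw_all, "integer", n = npx, size = 2L,
                         signed = FALSE, endian = endian))
    } else if (sample_format == 1L && bits == 32L) {
      as.numeric(readBin(raw_all, "integer", n = npx, size = 4L,
                         endian = endian))
    } else stop("unsupported TIFF sample layout: ", bits, "-bit, format ",
                sample_format)
    if (length(vals) < npx) stop("truncated TIFF strip data")
    pages[[length(pages) + 1L]] <- matrix(vals[seq_len(npx)], nrow = height,
                                          ncol = width, byrow = TRUE)
    if (is.null(description) && !is.null(tg[["270"]]))
      description <- tg[["270"]]
    offset <- ifd$next_offset
  }
  list(pages = pages, description = description)
}

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2L, endian = "little")
write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "little")

write_ifd_entry <- function(con, tag, type, count, value, is_offset = FALSE) {
  write_u16(con, tag); write_u16(con, type); write_u32(con, count)
  if (is_offset) write_u32(con, value)
  else if (type == 3L) { write_u16(con, value); write_u16(con, 0L) }
  else write_u32(con, value)
}

#' Write a multi-page grayscale TIFF (32-bit float, uncompressed)
#'
#' @param path Output path.
#' @param pages List of numeric matrices (`height x width`), all the same
#'   shape.
#' @param description Optional ImageDescription string stored on the first
#'   page (used for acquisition metadata).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(path, pages, description = NULL) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L)
  dims <- dim(pages[[1L]])
  if (any(!vapply(pages, function(p) identical(dim(p), dims), logical(1L))))
    stop("all pages must share the same dimensions")
  height <- dims[1L]; width <- dims[2L]
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL); write_u16(con, 42L)
  page_bytes <- 4L * width * height
  desc_raw <- if (is.null(description)) raw(0) else {
    r <- c(charToRaw(description), as.raw(0))
    if (length(r) %% 2L == 1L) r <- c(r, as.raw(0))
    r
  }
  n <- length(pages)
  data_start <- 8L
  desc_offset <- data_start + n * page_bytes
  ifd_start <- desc_offset + length(desc_raw)
  n_entries <- function(i) if (i == 1L && length(desc_raw)) 10L else 9L
  ifd_size <- function(i) 2L + 12L * n_entries(i) + 4L
  ifd_offsets <- integer(n)
  off <- ifd_start
  for (i in seq_len(n)) { ifd_offsets[i] <- off; off <- off + ifd_size(i) }
  write_u32(con, ifd_offsets[1L])
  for (i in seq_len(n)) {
    # row-major pixel stream, rows top to bottom
    writeBin(as.numeric(t(pages[[i]])), con, size = 4L, endian = "little")
  }
  if (length(desc_raw)) writeBin(desc_raw, con)
  for (i in seq_len(n)) {
    write_u16(con, n_entries(i))
    write_ifd_entry(con, 256L, 4L, 1L, width)
    write_ifd_entry(con, 257L, 4L, 1L, height)
    write_ifd_entry(con, 258L, 3L, 1L, 32L)
    write_ifd_entry(con, 259L, 3L, 1L, 1L)
    write_ifd_entry(con, 262L, 3L, 1L, 1L)
    if (i == 1L && length(desc_raw))
      write_ifd_entry(con, 270L, 2L, length(desc_raw), desc_offset,
                      is_offset = TRUE)
    write_ifd_entry(con, 273L, 4L, 1L, data_start + (i - 1L) * page_bytes)
    write_ifd_entry(con, 278L, 4L, 1L, height)
    write_ifd_entry(con, 279L, 4L, 1L, page_bytes)
    write_ifd_entry(con, 339L, 3L, 1L, 3L)
    write_u32(con, if (i < n) ifd_offsets[i + 1L] else 0L)
  }
  invisible(path)
}
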