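#' Image time-series container
#'
#' Bundles the frames of one plate with its acquisition geometry. Frames are
#' numeric matrices (rows = image rows, gray levels on the 8-bit scale).
#'
#' @param frames list of numeric matrices of identical shape, time-ordered.
#' @param timestep_h hours between successive observations.
#' @param px_size_um pixel size in micrometres.
#' @param transforms optional list of per-frame transforms (see
#'   [compose_daisychain()]); `NULL` for an unregistered series.
#' @return an `image_timeseries` object.
#' @export
image_timeseries <- function(frames, timestep_h = 8, px_size_um = 19,
                             transforms = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  shp <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), shp), logical(1))
  if (!all(ok)) stop("all frames must share the same shape")
  structure(list(frames = frames, timestep_h = timestep_h,
                 px_size_um = px_size_um, transforms = transforms),
            class = "image_timeseries")
}

#' @export
print.image_timeseries <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<image_timeseries> %d frames of %d x %d px, %g h timestep, %g um/px%s\n",
    length(x$frames), d[1], d[2], x$timestep_h, x$px_size_um,
    if (is.null(x$transforms)) " (unregistered)" else " (registered)"))
  invisible(x)
}

#' @export
length.image_timeseries <- function(x) length(x$frames)

tiff_tag <- function(id, type, count, value) {
  # value: raw payload already encoded, or integer scalar fitting 4 bytes
  c(writeBin(as.integer(id), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value)
}

#' Write a grayscale image as uncompressed TIFF
#'
#' Minimal baseline TIFF (little-endian, single strip, 8- or 16-bit
#' grayscale). Values are clamped to the representable range and rounded.
#'
#' @param img numeric matrix of gray levels.
#' @param path output path.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff_gray <- function(img, path, bits = 8) {
  stopifnot(bits %in% c(8L, 16L))
  nr <- nrow(img); nc <- ncol(img)
  maxv <- 2^bits - 1
  v <- as.integer(round(clamp(t(img), 0, maxv)))  # row-major pixel order
  px <- writeBin(v, raw(), size = bits / 8, endian = "little")
  data_offset <- 8L
  ifd_offset <- data_offset + length(px)
  header <- c(charToRaw("II"),
              writeBin(42L, raw(), size = 2, endian = "little"),
              writeBin(ifd_offset, raw(), size = 4, endian = "little"))
  int4 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                               endian = "little")
  short_val <- function(x) c(writeBin(as.integer(x), raw(), size = 2,
                                      endian = "little"), as.raw(c(0, 0)))
  tags <- list(
    tiff_tag(256, 3, 1, short_val(nc)),          # ImageWidth
    tiff_tag(257, 3, 1, short_val(nr)),          # ImageLength
    tiff_tag(258, 3, 1, short_val(bits)),        # BitsPerSample
    tiff_tag(259, 3, 1, short_val(1)),           # Compression: none
    tiff_tag(262, 3, 1, short_val(1)),           # Photometric: BlackIsZero
    tiff_tag(273, 4, 1, int4(data_offset)),      # StripOffsets
    tiff_tag(277, 3, 1, short_val(1)),           # SamplesPerPixel
    tiff_tag(278, 3, 1, short_val(nr)),          # RowsPerStrip
    tiff_tag(279, 4, 1, int4(length(px)))        # StripByteCounts
  )
  ifd <- c(writeBin(length(tags), raw(), size = 2, endian = "little"),
           do.call(c, tags),
           int4(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, px, ifd), con)
  invisible(path)
}

read_uint <- function(raw, offset, size, endian) {
  b <- as.integer(raw[(offset + 1):(offset + size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

#' Read a grayscale TIFF
#'
#' Reads the subset of TIFF written by [write_tiff_gray()] plus common
#' single-channel uncompressed variants (multiple strips, either byte
#' order).
#'
#' @param path file path.
#' @return numeric matrix of gray levels.
#' @export
read_tiff_gray <- function(path) {
  rw <- readBin(path, "raw", n = file.size(path))
  byte_order <- rawToChar(rw[1:2])
  endian <- if (byte_order == "II") "little"
            else if (byte_order == "MM") "big"
            else stop("not a TIFF file: ", path)
  ifd_off <- read_uint(rw, 4, 4, endian)
  n_tags <- read_uint(rw, ifd_off, 2, endian)
  tags <- list()
  for (i in seq_len(n_tags)) {
    base <- ifd_off + 2 + (i - 1) * 12
    id <- read_uint(rw, base, 2, endian)
    type <- read_uint(rw, base + 2, 2, endian)
    count <- read_uint(rw, base + 4, 4, endian)
    size <- c(1, 1, 2, 4, 8)[type]
    if (is.na(size)) size <- 4
    if (count * size <= 4) {
      vals <- vapply(seq_len(count), function(k)
        read_uint(rw, base + 8 + (k - 1) * size, size, endian), numeric(1))
    } else {
      voff <- read_uint(rw, base + 8, 4, endian)
      vals <- vapply(seq_len(count), function(k)
        read_uint(rw, voff + (k - 1) * size, size, endian), numeric(1))
    }
    tags[[as.character(id)]] <- vals
  }
  need <- function(id) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) stop("TIFF missing tag ", id)
    v
  }
  nc <- need(256)[1]; nr <- need(257)[1]
  bits <- (tags[["258"]] %||% 8)[1]
  comp <- (tags[["259"]] %||% 1)[1]
  if (comp != 1) stop("only uncompressed TIFF supported")
  if (!bits %in% c(8, 16)) stop("only 8/16-bit grayscale TIFF supported")
  offsets <- need(273)
  counts <- tags[["279"]] %||% (nr * nc * bits / 8)
  px <- numeric(0)
  for (k in seq_along(offsets)) {
    n_px <- counts[k] / (bits / 8)
    seg <- rw[(offsets[k] + 1):(offsets[k] + counts[k])]
    if (bits == 8) {
      px <- c(px, as.integer(seg))
    } else {
      v <- readBin(seg, "integer", n = n_px, size = 2, signed = FALSE,
                   endian = endian)
      px <- c(px, v)
    }
  }
  matrix(px, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Write a grayscale image as binary PGM
#'
#' @inheritParams write_tiff_gray
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  v <- as.integer(round(clamp(t(img), 0, 255)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con,
            eos = NULL)
  writeBin(as.raw(v), con)
  invisible(path)
}

#' Read a time series of TIFF frames from a directory
#'
#' Frames are matched by `pattern` and sorted by their embedded frame
#' number (`t<k>` suffix) when present, lexicographically otherwise.
#'
#' @param dir directory containing the frames.
#' @param pattern regular expression selecting frame files.
#' @param timestep_h,px_size_um acquisition geometry.
#' @return an [image_timeseries()].
#' @export
read_timeseries <- function(dir, pattern = "\\.tif$", timestep_h = 8,
                            px_size_um = 19) {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) < 2) stop("needs >=2 observations, found ",
                              length(files), " in ", dir)
  base <- basename(files)
  key <- regmatches(base, regexpr("t[0-9]+", base))
  if (length(key) == length(files)) {
    files <- files[order(as.integer(sub("t", "", key)))]
  } else {
    files <- sort(files)
  }
  image_timeseries(lapply(files, read_tiff_gray), timestep_h = timestep_h,
                   px_size_um = px_size_um)
}

#' Write an image time series as numbered TIFF frames
#'
#' @param stack an [image_timeseries()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; frames are `<prefix>_t<k>.tif`.
#' @param bits bit depth for [write_tiff_gray()].
#' @return the written paths, invisibly.
#' @export
write_timeseries <- function(stack, dir, prefix = "plate_1", bits = 8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(stack$frames))
  for (k in seq_along(stack$frames)) {
    paths[k] <- file.path(dir, sprintf("%s_t%02d.tif", prefix, k))
    write_tiff_gray(stack$frames[[k]], paths[k], bits = bits)
  }
  invisible(paths)
}
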