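#' Frame stack container
#'
#' An ordered sequence of equally sized 8-bit grayscale frames with the
#' acquisition metadata needed by the processing chain. Frames are stored
#' packed as raw bytes (one byte per pixel, column-major) to keep long
#' sequences within memory; use [get_frame()] to obtain an integer
#' matrix.
#'
#' @param frames list of integer matrices in 0..255 (or packed raw
#'   matrices when `packed = TRUE`)
#' @param frame_rate frames per second
#' @param pixels_per_mm spatial sampling
#' @param packed whether `frames` are already packed raw matrices
#' @return object of class `frame_stack`
#' @export
frame_stack <- function(frames, frame_rate, pixels_per_mm, packed = FALSE) {
  if (length(frames) == 0) .st_stop("frame stack must contain at least one frame")
  if (!packed) frames <- lapply(frames, .st_pack_frame)
  dims <- vapply(frames, function(f) dim(f), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    .st_stop("mixed frame shapes in stack")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixels_per_mm = pixels_per_mm,
                 dim = c(dims[1, 1], dims[2, 1])),
            class = "frame_stack")
}

.st_pack_frame <- function(img) {
  if (is.raw(img)) return(img)
  v <- as.integer(img)
  if (anyNA(v) || any(v < 0 | v > 255)) .st_stop("frame values must be 8-bit (0..255)")
  r <- as.raw(v)
  dim(r) <- dim(img)
  r
}

.st_unpack_frame <- function(praw) {
  m <- matrix(as.integer(praw), nrow(praw), ncol(praw))
  m
}

#' Number of frames in a stack
#' @param stack a [frame_stack()]
#' @return integer frame count
#' @export
n_frames <- function(stack) length(stack$frames)

#' Extract one frame as an integer matrix
#' @param stack a [frame_stack()]
#' @param k frame index (1-based)
#' @return integer matrix in 0..255
#' @export
get_frame <- function(stack, k) {
  if (k < 1 || k > n_frames(stack)) .st_stop("frame index %d out of range", k)
  .st_unpack_frame(stack$frames[[k]])
}

#' Timestamps of the frames
#' @param stack a [frame_stack()]
#' @return numeric vector, frame k at (k-1)/frame_rate seconds
#' @export
frame_times <- function(stack) (seq_len(n_frames(stack)) - 1) / stack$frame_rate

# ---------------------------------------------------------------------------
# Minimal multi-page uncompressed grayscale TIFF (little-endian). Only the
# baseline subset this package writes is read back; anything else errors.

.st_tiff_pack_short <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.st_tiff_pack_long <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

#' Write a frame stack as multi-page TIFF with a JSON sidecar
#'
#' @param stack a [frame_stack()]
#' @param path output file (`.tif`); metadata is written to
#'   `paste0(path, ".json")`
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path) {
  nr <- stack$dim[1]; nc <- stack$dim[2]
  np <- n_frames(stack)
  page_bytes <- nr * nc
  header_len <- 8L
  data_off <- header_len + seq(0, np - 1) * page_bytes
  ifd_base <- header_len + np * page_bytes
  ifd_len <- 2L + 9L * 12L + 4L
  ifd_off <- ifd_base + seq(0, np - 1) * ifd_len
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  for (k in seq_len(np)) {
    img <- stack$frames[[k]]
    writeBin(as.vector(t(.st_unpack_frame(img))) |> as.raw(), con) # row-major
  }
  entry <- function(tag, type, count, value_raw4) {
    c(.st_tiff_pack_short(tag), .st_tiff_pack_short(type),
      .st_tiff_pack_long(count), value_raw4)
  }
  short_val <- function(v) c(.st_tiff_pack_short(v), as.raw(c(0, 0)))
  long_val <- function(v) .st_tiff_pack_long(v)
  for (k in seq_len(np)) {
    ifd <- c(.st_tiff_pack_short(9),
             entry(256, 3, 1, short_val(nc)),
             entry(257, 3, 1, short_val(nr)),
             entry(258, 3, 1, short_val(8)),
             entry(259, 3, 1, short_val(1)),
             entry(262, 3, 1, short_val(1)),
             entry(273, 4, 1, long_val(data_off[k])),
             entry(277, 3, 1, short_val(1)),
             entry(278, 3, 1, short_val(nr)),
             entry(279, 4, 1, long_val(page_bytes)),
             long_val(if (k < np) ifd_off[k + 1] else 0))
    writeBin(ifd, con)
  }
  meta <- list(frame_rate = stack$frame_rate, pixels_per_mm = stack$pixels_per_mm,
               n_frames = np, height_px = nr, width_px = nc)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.st_read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) .st_stop("not a TIFF file: %s", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    .st_stop("not a TIFF file: %s", path)
  rd <- function(off, size, n = 1)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size >= 4)
  if (rd(2, 2) != 42) .st_stop("not a TIFF file: %s", path)
  ifd_off <- readBin(raw[5:8], "integer", size = 4, endian = endian)
  frames <- list()
  while (ifd_off != 0) {
    n_ent <- rd(ifd_off, 2)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- rd(base, 2); type <- rd(base + 2, 2); count <- rd(base + 4, 4)
      val <- if (type == 3 && count == 1) rd(base + 8, 2)
      else if (type == 4 && count == 1) readBin(raw[(base + 9):(base + 12)], "integer",
                                                size = 4, endian = endian)
      else if ((type == 3 || type == 4) && count > 1) {
        off <- readBin(raw[(base + 9):(base + 12)], "integer", size = 4, endian = endian)
        rd(off, if (type == 3) 2 else 4, count)
      } else NULL
      tags[[as.character(tag)]] <- val
    }
    g <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h)) .st_stop("TIFF page missing dimensions")
    bits <- g(258, 1)
    if (any(bits != 8))
      .st_stop("only 8-bit grayscale TIFF is supported (found %d-bit); convert the input to 8-bit first", bits[1])
    if (g(259, 1) != 1) .st_stop("compressed TIFF is not supported")
    if (g(277, 1) != 1) .st_stop("only single-sample (grayscale) TIFF is supported")
    offs <- g(273); cnts <- g(279)
    if (is.null(offs) || is.null(cnts)) .st_stop("TIFF page missing strip layout")
    bytes <- unlist(lapply(seq_along(offs), function(i) raw[(offs[i] + 1):(offs[i] + cnts[i])]))
    img <- matrix(as.integer(bytes), nrow = h, ncol = w, byrow = TRUE)
    frames[[length(frames) + 1]] <- img
    next_off_pos <- ifd_off + 2 + n_ent * 12
    ifd_off <- readBin(raw[(next_off_pos + 1):(next_off_pos + 4)], "integer",
                       size = 4, endian = endian)
  }
  frames
}

# ---------------------------------------------------------------------------
# PGM (P5) directory interchange, one numbered file per frame

.st_write_pgm <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img))), con)
  writeBin(as.raw(as.vector(t(img))), con)
  invisible(path)
}

.st_read_pgm <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 10 || rawToChar(raw[1:2]) != "P5")
    .st_stop("not a binary PGM (P5) file: %s", path)
  # locate the three header fields, skipping comments
  pos <- 3L; fields <- integer(0)
  while (length(fields) < 3) {
    ch <- rawToChar(raw[pos])
    if (ch == "#") { while (rawToChar(raw[pos]) != "\n") pos <- pos + 1L; pos <- pos + 1L }
    else if (grepl("[[:space:]]", ch)) pos <- pos + 1L
    else {
      num <- ""
      while (!grepl("[[:space:]]", rawToChar(raw[pos]))) {
        num <- paste0(num, rawToChar(raw[pos])); pos <- pos + 1L
      }
      fields <- c(fields, as.integer(num))
    }
  }
  pos <- pos + 1L # single whitespace after maxval
  w <- fields[1]; h <- fields[2]; maxval <- fields[3]
  if (maxval > 255)
    .st_stop("only 8-bit PGM is supported (maxval %d); convert the input to 8-bit first", maxval)
  bytes <- raw[pos:(pos + w * h - 1)]
  matrix(as.integer(bytes), nrow = h, ncol = w, byrow = TRUE)
}

#' Read a frame stack
#'
#' Accepts either a multi-page 8-bit grayscale TIFF (with a
#' `<path>.json` sidecar) or a directory of numbered `frame_NNNN.pgm`
#' files with a `metadata.json`. The sidecar must provide `frame_rate`
#' and `pixels_per_mm`.
#'
#' @param path TIFF file or frame directory
#' @return a [frame_stack()]
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    meta_path <- file.path(path, "metadata.json")
    if (!file.exists(meta_path))
      .st_stop("missing metadata.json in %s (required keys: frame_rate, pixels_per_mm)", path)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    files <- sort(list.files(path, pattern = "^frame_\\d+\\.pgm$"))
    if (length(files) == 0) .st_stop("no frame_NNNN.pgm files in %s", path)
    idx <- as.integer(sub("^frame_0*(\\d+)\\.pgm$", "\\1", files))
    expected <- seq(min(idx), max(idx))
    missing <- setdiff(expected, idx)
    if (length(missing) > 0)
      .st_stop("gap in frame numbering: missing index %s", paste(missing, collapse = ", "))
    frames <- lapply(file.path(path, files), .st_read_pgm)
  } else {
    meta_path <- paste0(path, ".json")
    if (!file.exists(meta_path))
      .st_stop("missing sidecar %s (required keys: frame_rate, pixels_per_mm)", meta_path)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    frames <- .st_read_tiff(path)
  }
  for (k in c("frame_rate", "pixels_per_mm"))
    if (is.null(meta[[k]]))
      .st_stop("metadata missing required key: %s", k)
  frame_stack(frames, frame_rate = meta$frame_rate, pixels_per_mm = meta$pixels_per_mm)
}

#' Write a frame stack as a directory of PGM frames
#'
#' @param stack a [frame_stack()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_stack_pgm <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(n_frames(stack)))
    .st_write_pgm(get_frame(stack, k), file.path(dir, sprintf("frame_%04d.pgm", k)))
  jsonlite::write_json(list(frame_rate = stack$frame_rate,
                            pixels_per_mm = stack$pixels_per_mm),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
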