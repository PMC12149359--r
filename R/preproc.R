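#' Anisotropic Gaussian smoothing stage
#'
#' First stage of the frame-conditioning chain: Gaussian smoothing with a
#' kernel support of 2 px in depth by 10 px laterally (smooth along the
#' surface, preserve depth localization). Sigmas are derived as
#' extent / 4 (0.5 px vertical, 2.5 px lateral) so that more than 95% of
#' the kernel mass lies inside the stated support; borders use reflect
#' padding. Set `transpose_kernel = TRUE` for the other reading of the
#' kernel orientation.
#'
#' @param frame numeric/integer grayscale matrix
#' @param extent kernel support c(rows, cols) in px
#' @param transpose_kernel swap the kernel orientation
#' @return smoothed numeric matrix, same shape and range
#' @export
gaussian_stage <- function(frame, extent = c(2, 10), transpose_kernel = FALSE) {
  frame <- .st_as_num(frame)
  if (transpose_kernel) extent <- rev(extent)
  if (nrow(frame) < extent[1] || ncol(frame) < extent[2])
    .st_stop("frame (%d x %d) smaller than the smoothing kernel (%d x %d)",
             nrow(frame), ncol(frame), extent[1], extent[2])
  half_r <- max(1L, as.integer(floor(extent[1] / 2)))
  half_c <- max(1L, as.integer(floor(extent[2] / 2)))
  .cpp_gaussian_sep(frame, extent[1] / 4, extent[2] / 4, half_r, half_c)
}

#' Median filter stage
#'
#' @param frame grayscale matrix
#' @param size kernel side, px (5 x 5)
#' @return filtered numeric matrix
#' @export
median_stage <- function(frame, size = 5) {
  .cpp_median_filter(.st_as_num(frame), as.integer(size), as.integer(size))
}

#' Local-edge enhancement stage
#'
#' Sobel gradient magnitude, normalized to [0, 1] by its maximum;
#' responses below `edge_threshold` are zeroed and survivors are carried
#' on the 0-255 scale (the strongest edge plateau reaches 255). An
#' all-flat frame returns zeros.
#'
#' @param frame grayscale matrix
#' @param edge_threshold normalized gradient cutoff
#' @return numeric matrix in 0..255
#' @export
local_edge_stage <- function(frame, edge_threshold = 0.6) {
  g <- .cpp_sobel_mag(.st_as_num(frame))
  m <- max(g)
  if (m <= 0) return(g)
  g <- g / m
  g[g < edge_threshold] <- 0
  255 * g
}

#' Band thresholding stage
#'
#' Retains pixels whose edge response lies in `[low, high]`.
#'
#' @param frame numeric matrix in 0..255 (edge image)
#' @param low,high inclusive bounds (150-225)
#' @return logical matrix
#' @export
band_threshold_stage <- function(frame, low = 150, high = 225) {
  if (low > high) .st_stop("low threshold (%g) exceeds high threshold (%g)", low, high)
  frame <- .st_as_num(frame)
  frame >= low & frame <= high
}

# structuring elements as (drow, dcol) offset matrices. The "size 1"
# line elements are read as 3-pixel lines through the center (their
# smallest non-trivial extent): the vertical and diagonal dilations
# bridge the 1-2 px gap that the 150-225 band threshold leaves at the
# gradient apex, which is what keeps the refined band covering the true
# interface row. The radius-1 disk and diamond are the 5-pixel plus.
.st_se <- function(name) {
  switch(name,
         line90 = cbind(c(-1, 0, 1), c(0, 0, 0)),
         line45 = cbind(c(-1, 0, 1), c(1, 0, -1)),
         disk1 = cbind(c(-1, 0, 0, 0, 1), c(0, -1, 0, 1, 0)),
         diamond1 = cbind(c(-1, 0, 0, 0, 1), c(0, -1, 0, 1, 0)),
         .st_stop("unknown structuring element: %s", name))
}

.st_dilate <- function(mask, se) .cpp_morph(mask, .st_se(se), TRUE)
.st_erode <- function(mask, se) .cpp_morph(mask, .st_se(se), FALSE)

#' Morphological refinement stage
#'
#' Sequential dilation by a vertical (90 deg) line, a 45 deg line and a
#' radius-1 disk; removal of 8-connected components touching the frame
#' border; erosion by a radius-1 diamond. Returns the binary band with
#' per-column extent statistics.
#'
#' @param mask logical matrix
#' @return object of class `binary_band` with elements `mask` and
#'   `band_stats` (data frame `column`, `top_px`, `bottom_px`, `width_px`)
#' @export
morph_refine_stage <- function(mask) {
  mask <- mask != 0
  m <- .st_dilate(mask, "line90")
  m <- .st_dilate(m, "line45")
  m <- .st_dilate(m, "disk1")
  m <- .cpp_clear_border(m)
  m <- .st_erode(m, "diamond1")
  binary_band(m)
}

#' Binary band container
#'
#' @param mask logical matrix marking the dorsal-surface band
#' @return object of class `binary_band`
#' @export
binary_band <- function(mask) {
  stats <- .st_band_stats(mask)
  structure(list(mask = mask, band_stats = stats), class = "binary_band")
}

.st_band_stats <- function(mask) {
  nc <- ncol(mask)
  top <- bottom <- rep(NA_integer_, nc)
  any_col <- colSums(mask) > 0
  for (c in which(any_col)) {
    r <- which(mask[, c])
    top[c] <- r[1]; bottom[c] <- r[length(r)]
  }
  data.frame(column = seq_len(nc), top_px = top, bottom_px = bottom,
             width_px = ifelse(any_col, bottom - top + 1L, 0L))
}

#' Full frame-conditioning chain
#'
#' Composition gaussian -> median -> local edge -> band threshold ->
#' morphological refinement, converting a raw B-mode frame into the
#' binary band that marks the dorsal-surface interface.
#'
#' @param frame 8-bit grayscale matrix
#' @param params optional list overriding `gaussian_extent`,
#'   `transpose_kernel`, `median_size`, `edge_threshold`, `band_low`,
#'   `band_high`
#' @param keep_stages also return every intermediate stage (for the
#'   debug export)
#' @return a [binary_band()]; with `keep_stages = TRUE`, attribute
#'   `stages` holds the named intermediates
#' @export
preprocess_frame <- function(frame, params = list(), keep_stages = FALSE) {
  p <- modifyList(list(gaussian_extent = c(2, 10), transpose_kernel = FALSE,
                       median_size = 5, edge_threshold = 0.6,
                       band_low = 150, band_high = 225), params)
  g <- gaussian_stage(frame, p$gaussian_extent, p$transpose_kernel)
  m <- median_stage(g, p$median_size)
  e <- local_edge_stage(m, p$edge_threshold)
  b <- band_threshold_stage(e, p$band_low, p$band_high)
  band <- morph_refine_stage(b)
  if (keep_stages)
    attr(band, "stages") <- list(gaussian = g, median = m, edge = e, threshold = b)
  band
}

#' Export the intermediate stages of the chain for one frame
#'
#' Writes each stage as a page of a multi-page TIFF together with the
#' band statistics CSV (debugging aid mirroring the chain's panel
#' figure).
#'
#' @param frame 8-bit grayscale matrix
#' @param dir output directory
#' @param params see [preprocess_frame()]
#' @return invisible list of written paths
#' @export
export_preproc_debug <- function(frame, dir, params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  band <- preprocess_frame(frame, params, keep_stages = TRUE)
  st <- attr(band, "stages")
  clamp8 <- function(x) matrix(as.integer(pmin(255, pmax(0, round(x)))), nrow(x), ncol(x))
  pages <- list(clamp8(.st_as_num(frame)), clamp8(st$gaussian), clamp8(st$median),
                clamp8(st$edge), clamp8(st$threshold * 255), clamp8(band$mask * 255))
  stk <- frame_stack(pages, frame_rate = 1, pixels_per_mm = 1)
  tif <- file.path(dir, "preproc_stages.tif")
  write_stack(stk, tif)
  csv <- file.path(dir, "band_stats.csv")
  write.csv(band$band_stats, csv, row.names = FALSE)
  invisible(list(tif = tif, csv = csv))
}

.st_as_num <- function(frame) {
  if (is.raw(frame)) return(.st_unpack_frame(frame) * 1.0)
  if (!is.matrix(frame)) .st_stop("frame must be a matrix")
  if (any(!is.finite(frame))) .st_stop("non-finite frame values")
  frame * 1.0
}
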