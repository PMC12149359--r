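#' Contrast-limited adaptive histogram equalization
#'
#' Per-tile histogram equalization with a normalized clip limit and
#' bilinear blending between neighboring tile mappings, applied before
#' PIV to boost local speckle contrast. `tile` counts tiles per
#' dimension (an 8 x 8 tile grid, as in MATLAB's adapthisteq whose
#' parameters these mirror), so each tile spans image-size / 8 pixels.
#'
#' @param image 8-bit grayscale matrix
#' @param tile number of tiles per dimension (scalar or c(rows, cols))
#' @param clip normalized clip limit (fraction of the tile pixel count)
#' @return numeric matrix in 0..255
#' @export
clahe <- function(image, tile = 8, clip = 0.01) {
  image <- .st_as_num(image)
  if (length(tile) == 1) tile <- c(tile, tile)
  if (tile[1] > nrow(image) || tile[2] > ncol(image))
    .st_stop("CLAHE tile grid (%d x %d) larger than image (%d x %d)",
             tile[1], tile[2], nrow(image), ncol(image))
  tile_px <- pmax(1L, as.integer(ceiling(dim(image) / tile)))
  .cpp_clahe(image, tile_px[1], tile_px[2], clip)
}

#' Region-of-interest specification for PIV
#'
#' The ROI has fixed dimensions for all experiments (370 x 105 px),
#' is centered laterally, and its upper edge coincides with the tracked
#' dorsal surface at the reference frame, so ROI row coordinates measure
#' distance below the surface.
#'
#' @param width,height ROI dimensions, px
#' @return object of class `roi_spec`
#' @export
roi_spec <- function(width = 370, height = 105) {
  structure(list(width = as.integer(width), height = as.integer(height)),
            class = "roi_spec")
}

#' Anchor the ROI under the tracked surface
#'
#' The top edge is placed at the median tracked surface row (over the
#' central half of the stations) of a reference frame -- by default the
#' first frame, but for an experiment whose surface has descended under
#' compression the reference should be the first frame of the analyzed
#' window, so the upper ROI limit coincides with the dorsal surface as
#' seen in the analyzed images. The ROI is centered laterally and kept
#' fixed over time.
#'
#' @param contour an [st_contour()] or [contour_table()]
#' @param spec a [roi_spec()]
#' @param frame_dim frame dimensions c(rows, cols)
#' @param frame reference frame index (contour tables only)
#' @return object of class `roi_placement`: `row0`, `col0` (top-left,
#'   1-based), `width`, `height`
#' @export
anchor_roi <- function(contour, spec, frame_dim, frame = 1L) {
  depth <- if (inherits(contour, "contour_table")) contour$row_px[frame, ]
  else if (inherits(contour, "st_contour")) contour$depth
  else .st_stop("contour must be an st_contour or contour_table")
  n <- length(depth)
  central <- seq(floor(n / 4) + 1, ceiling(3 * n / 4))
  row0 <- as.integer(round(median(depth[central])))
  col0 <- as.integer(floor((frame_dim[2] - spec$width) / 2)) + 1L
  if (row0 < 1 || row0 + spec$height - 1 > frame_dim[1] ||
      col0 < 1 || col0 + spec$width - 1 > frame_dim[2])
    .st_stop("ROI (%d x %d at row %d, col %d) exceeds the %d x %d frame",
             spec$height, spec$width, row0, col0, frame_dim[1], frame_dim[2])
  structure(list(row0 = row0, col0 = col0, width = spec$width,
                 height = spec$height), class = "roi_placement")
}

#' PIV configuration
#'
#' @param pass_windows interrogation-window sides per pass, px,
#'   decreasing (64 then 32)
#' @param overlap_fraction window overlap in [0, 0.75]
#' @param peak_ratio_min minimum primary-to-secondary correlation peak
#'   ratio for a vector to be valid
#' @param nmt_max maximum normalized-median-test residual
#' @param apply_clahe run [clahe()] on each frame before cropping
#' @param clahe_tile,clahe_clip CLAHE parameters
#' @return object of class `piv_config`
#' @export
piv_config <- function(pass_windows = c(64, 32), overlap_fraction = 0.5,
                       peak_ratio_min = 1.3, nmt_max = 4,
                       apply_clahe = TRUE, clahe_tile = 8, clahe_clip = 0.01) {
  if (is.unsorted(rev(pass_windows), strictly = TRUE) && length(pass_windows) > 1)
    .st_stop("pass windows must be decreasing")
  if (overlap_fraction < 0 || overlap_fraction > 0.75)
    .st_stop("overlap_fraction must lie in [0, 0.75]")
  structure(list(pass_windows = as.integer(pass_windows),
                 overlap_fraction = overlap_fraction,
                 peak_ratio_min = peak_ratio_min, nmt_max = nmt_max,
                 apply_clahe = apply_clahe, clahe_tile = clahe_tile,
                 clahe_clip = clahe_clip),
            class = "piv_config")
}

#' Interrogation grid dimensions
#'
#' `n = floor((side - window) / step) + 1` with
#' `step = window * (1 - overlap)`; the published 370 px ROI width with a
#' final 32 px window at 50% overlap gives 22 columns.
#'
#' @param roi a [roi_spec()] (or `roi_placement`)
#' @param config a [piv_config()]
#' @return c(n_rows, n_cols)
#' @export
grid_shape <- function(roi, config) {
  w <- config$pass_windows[length(config$pass_windows)]
  if (w > roi$height || w > roi$width)
    .st_stop("final window (%d px) larger than the ROI (%d x %d)",
             w, roi$height, roi$width)
  step <- w * (1 - config$overlap_fraction)
  c(floor((roi$height - w) / step) + 1, floor((roi$width - w) / step) + 1)
}

# top-left offsets (0-based) and centers of the interrogation windows
.st_window_layout <- function(side, w, overlap) {
  step <- w * (1 - overlap)
  n <- floor((side - w) / step) + 1
  off <- round((seq_len(n) - 1) * step)
  list(n = n, offset = off, center = off + (w + 1) / 2)
}

#' Circular FFT cross-correlation of an interrogation window pair
#'
#' Windows are mean-subtracted; the correlation peak position encodes the
#' modal displacement of `window_b` relative to `window_a` (positive =
#' pattern moved toward larger row/column). Zero-variance windows are
#' flagged invalid via the `valid` attribute rather than raising.
#'
#' @param window_a,window_b equal square numeric matrices
#' @return correlation surface (matrix) with attribute `valid`
#' @export
correlate_pair <- function(window_a, window_b) {
  if (!all(dim(window_a) == dim(window_b)))
    .st_stop("windows must have identical dimensions")
  a <- window_a - mean(window_a)
  b <- window_b - mean(window_b)
  va <- sum(a * a); vb <- sum(b * b)
  if (va <= 0 || vb <= 0) {
    out <- matrix(0, nrow(a), ncol(a))
    attr(out, "valid") <- FALSE
    return(out)
  }
  Fa <- fft(a); Fb <- fft(b)
  corr <- Re(fft(Conj(Fa) * Fb, inverse = TRUE)) / length(a)
  corr <- corr / sqrt(va * vb)
  # unbiased normalization: compensate the circular loss-of-pairs factor
  # (w - |lag|)/w per axis, which otherwise biases broad speckle peaks
  # toward zero displacement
  ny <- nrow(corr); nx <- ncol(corr)
  lag <- function(n) { l <- seq_len(n) - 1; pmin(l, n - l) }
  wy <- pmax(1 - lag(ny) / ny, 0.5); wx <- pmax(1 - lag(nx) / nx, 0.5)
  corr <- corr / outer(wy, wx)
  attr(corr, "valid") <- TRUE
  corr
}

# wrap a 0-based circular index into a signed displacement
.st_wrap_disp <- function(idx0, n) ifelse(idx0 > n / 2, idx0 - n, idx0)

#' Sub-pixel correlation peak location
#'
#' Integer peak plus a 3-point Gaussian fit per axis (circular
#' neighborhoods); if any of the three samples is non-positive the fit
#' falls back to a parabola. Returns the signed displacement
#' `c(dy, dx)` with attribute `method`.
#'
#' @param corr correlation surface from [correlate_pair()]
#' @param peak_ratio_also return the primary/secondary peak ratio
#'   attribute (used by validation); logical
#' @param max_disp restrict the peak search to displacements of at most
#'   this many pixels per axis (the quarter-window rule of PIV practice;
#'   Inf searches the whole surface). Keeps the unbiased normalization
#'   from promoting spurious rim maxima on laterally uniform content.
#' @return numeric c(dy, dx), attributes `method`, `peak_ratio`
#' @export
subpixel_peak <- function(corr, peak_ratio_also = TRUE, max_disp = Inf) {
  nr <- nrow(corr); nc <- ncol(corr)
  search <- corr
  if (is.finite(max_disp)) {
    lagv <- function(n) { l <- seq_len(n) - 1; pmin(l, n - l) }
    search[outer(lagv(nr) > max_disp, lagv(nc) > max_disp, "|")] <- -Inf
  }
  pk <- which.max(search)
  pr <- ((pk - 1) %% nr)       # 0-based row
  pc <- ((pk - 1) %/% nr)      # 0-based col
  wrap <- function(i, n) ((i %% n) + n) %% n
  method <- "gaussian"
  fit1 <- function(cm, c0, cp) {
    if (cm > 0 && c0 > 0 && cp > 0 && (2 * log(c0) - log(cm) - log(cp)) > 0) {
      (log(cm) - log(cp)) / (2 * (log(cm) + log(cp) - 2 * log(c0)))
    } else {
      method <<- "parabolic"
      den <- cm - 2 * c0 + cp
      if (den < 0) 0.5 * (cm - cp) / den else 0
    }
  }
  c0 <- corr[pr + 1, pc + 1]
  dr <- fit1(corr[wrap(pr - 1, nr) + 1, pc + 1], c0, corr[wrap(pr + 1, nr) + 1, pc + 1])
  dc <- fit1(corr[pr + 1, wrap(pc - 1, nc) + 1], c0, corr[pr + 1, wrap(pc + 1, nc) + 1])
  dr <- max(-0.99, min(0.99, dr)); dc <- max(-0.99, min(0.99, dc))
  out <- c(.st_wrap_disp(pr, nr) + dr, .st_wrap_disp(pc, nc) + dc)
  attr(out, "method") <- method
  if (peak_ratio_also) {
    # exclude a radius-5 region around the primary peak: the envelope
    # speckle correlation peak is several pixels wide, so nearer maxima
    # are its own shoulder, not a competing peak
    excl <- search
    rr <- wrap(pr + (-5:5), nr) + 1
    cc <- wrap(pc + (-5:5), nc) + 1
    excl[rr, cc] <- -Inf
    second <- max(excl)
    attr(out, "peak_ratio") <- if (is.finite(second) && second > 0) c0 / second else Inf
  }
  out
}

# normalized median test (Westerweel-Scarano), 8-neighborhood
.st_nmt <- function(u, eps = 0.1) {
  nr <- nrow(u); nc <- ncol(u)
  res <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if ((di || dj) && ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        nb <- c(nb, u[ii, jj])
    }
    med <- median(nb, na.rm = TRUE)
    if (is.na(med) || is.na(u[i, j])) next
    rmed <- median(abs(nb - med), na.rm = TRUE)
    res[i, j] <- abs(u[i, j] - med) / (rmed + eps)
  }
  res
}

# iterative local-mean infill of invalid nodes
.st_infill <- function(u, valid) {
  it <- 0
  while (any(!valid) && it < 20) {
    it <- it + 1
    for (i in seq_len(nrow(u))) for (j in seq_len(ncol(u))) {
      if (!valid[i, j]) {
        nb_v <- valid[max(1, i - 1):min(nrow(u), i + 1), max(1, j - 1):min(ncol(u), j + 1)]
        nb_u <- u[max(1, i - 1):min(nrow(u), i + 1), max(1, j - 1):min(ncol(u), j + 1)]
        if (any(nb_v)) { u[i, j] <- mean(nb_u[nb_v]); valid[i, j] <- TRUE }
      }
    }
  }
  u[!valid] <- 0
  u
}

# single correlation pass over an ROI pair; returns node grids
.st_piv_pass <- function(a, b, w, overlap, peak_ratio_min, nmt_max) {
  lr <- .st_window_layout(nrow(a), w, overlap)
  lc <- .st_window_layout(ncol(a), w, overlap)
  u <- v <- matrix(NA_real_, lr$n, lc$n)
  ok <- matrix(FALSE, lr$n, lc$n)
  for (j in seq_len(lc$n)) for (i in seq_len(lr$n)) {
    r0 <- lr$offset[i]; c0 <- lc$offset[j]
    wa <- a[(r0 + 1):(r0 + w), (c0 + 1):(c0 + w)]
    wb <- b[(r0 + 1):(r0 + w), (c0 + 1):(c0 + w)]
    corr <- correlate_pair(wa, wb)
    if (!attr(corr, "valid")) next
    d <- subpixel_peak(corr, max_disp = w / 4)
    v[i, j] <- d[1]; u[i, j] <- d[2]
    ok[i, j] <- attr(d, "peak_ratio") >= peak_ratio_min
  }
  ok[is.na(u)] <- FALSE
  u[!ok] <- NA; v[!ok] <- NA
  # normalized median validation on the surviving field
  if (sum(ok) >= 4) {
    ru <- .st_nmt(ifelse(ok, u, NA))
    rv <- .st_nmt(ifelse(ok, v, NA))
    bad <- (ru > nmt_max | rv > nmt_max) & ok
    ok[bad] <- FALSE
  }
  u[!ok] <- NA; v[!ok] <- NA
  u_f <- .st_infill(ifelse(ok, u, 0), ok)
  v_f <- .st_infill(ifelse(ok, v, 0), ok)
  list(u = u_f, v = v_f, valid = ok,
       node_rows = lr$center, node_cols = lc$center)
}

# bilinear interpolation of a node grid to arbitrary ROI coordinates
.st_grid_interp <- function(grid, node_rows, node_cols, q_rows, q_cols) {
  # bilinear on the uniform node grid, with linear extrapolation beyond
  # the node hull (clamping would flatten the predictor near the ROI
  # edges and bias the outer rows of the final field)
  nrw <- length(node_rows); ncl <- length(node_cols)
  fi <- if (nrw > 1) (q_rows - node_rows[1]) / (node_rows[2] - node_rows[1]) + 1
        else rep(1, length(q_rows))
  fj <- if (ncl > 1) (q_cols - node_cols[1]) / (node_cols[2] - node_cols[1]) + 1
        else rep(1, length(q_cols))
  i0 <- pmin(pmax(floor(fi), 1), max(nrw - 1, 1)); wi <- fi - i0
  j0 <- pmin(pmax(floor(fj), 1), max(ncl - 1, 1)); wj <- fj - j0
  if (nrw == 1) wi <- rep(0, length(fi))
  if (ncl == 1) wj <- rep(0, length(fj))
  i1 <- i0 + (nrw > 1); j1 <- j0 + (ncl > 1)
  g <- function(i, j) grid[cbind(i, j)]
  (1 - wi) * ((1 - wj) * g(i0, j0) + wj * g(i0, j1)) +
    wi * ((1 - wj) * g(i1, j0) + wj * g(i1, j1))
}

#' Two-pass FFT PIV with window deformation on one frame pair
#'
#' Pass 1 (64 px windows) produces a predictor displacement field; the
#' second frame is warped by the bilinearly interpolated predictor
#' before pass 2 (32 px windows), whose correction is added to the
#' predictor. Vectors failing peak-ratio or normalized-median validation
#' are masked and infilled from valid neighbors.
#'
#' @param frame_a,frame_b full grayscale frames (equal shape)
#' @param roi a `roi_placement` from [anchor_roi()]
#' @param config a [piv_config()]
#' @param preprocessed set TRUE when `frame_a`/`frame_b` are already
#'   CLAHE-processed ROI crops
#' @return object of class `velocity_grid`: matrices `u`, `v`
#'   (px/frame), `valid`, node coordinates within the ROI
#' @export
piv_pair <- function(frame_a, frame_b, roi, config = piv_config(),
                     preprocessed = FALSE) {
  if (!preprocessed) {
    if (!all(dim(frame_a) == dim(frame_b))) .st_stop("frames must have equal shape")
    a <- .st_piv_prep(frame_a, roi, config)
    b <- .st_piv_prep(frame_b, roi, config)
  } else { a <- frame_a; b <- frame_b }
  ov <- config$overlap_fraction
  wins <- config$pass_windows
  pass1 <- .st_piv_pass(a, b, wins[1], ov, config$peak_ratio_min, config$nmt_max)
  if (length(wins) == 1) {
    out <- pass1
  } else {
    # dense predictor and window deformation
    px_rows <- seq_len(nrow(a)); px_cols <- seq_len(ncol(a))
    qg <- expand.grid(r = px_rows, c = px_cols)
    up <- .st_grid_interp(pass1$u, pass1$node_rows, pass1$node_cols, qg$r, qg$c)
    vp <- .st_grid_interp(pass1$v, pass1$node_rows, pass1$node_cols, qg$r, qg$c)
    bw <- matrix(.cpp_bilinear_sample(b, qg$r + vp, qg$c + up), nrow(a), ncol(a))
    w2 <- wins[2]
    pass2 <- .st_piv_pass(a, bw, w2, ov, config$peak_ratio_min, config$nmt_max)
    u_pred <- .st_grid_interp(pass1$u, pass1$node_rows, pass1$node_cols,
                              pass2$node_rows[row(pass2$u)], pass2$node_cols[col(pass2$u)])
    v_pred <- .st_grid_interp(pass1$v, pass1$node_rows, pass1$node_cols,
                              pass2$node_rows[row(pass2$v)], pass2$node_cols[col(pass2$v)])
    out <- pass2
    out$u <- matrix(u_pred, nrow(pass2$u)) + pass2$u
    out$v <- matrix(v_pred, nrow(pass2$v)) + pass2$v
  }
  structure(list(u = out$u, v = out$v, valid = out$valid,
                 node_rows = out$node_rows, node_cols = out$node_cols,
                 roi = roi), class = "velocity_grid")
}

.st_piv_prep <- function(frame, roi, config) {
  img <- .st_as_num(frame)
  if (config$apply_clahe)
    img <- clahe(img, config$clahe_tile, config$clahe_clip)
  img[roi$row0:(roi$row0 + roi$height - 1), roi$col0:(roi$col0 + roi$width - 1)]
}

#' PIV over a time window of a frame stack
#'
#' One velocity grid per consecutive frame pair whose first frame falls
#' in `[t_start, t_end)`; the default window (10-22 s) covers one
#' complete back-and-forth shearing motion.
#'
#' @param stack a [frame_stack()]
#' @param roi a `roi_placement` from [anchor_roi()]
#' @param config a [piv_config()]
#' @param t_start,t_end analysis window, s
#' @return object of class `velocity_history`: `grids` (list of
#'   [piv_pair()] results), `times` (first-frame timestamps), frame
#'   period and geometry
#' @export
piv_sequence <- function(stack, roi, config = piv_config(),
                         t_start = 10, t_end = 22) {
  times <- frame_times(stack)
  nf <- n_frames(stack)
  first <- which(times >= t_start & times < t_end)
  first <- first[first < nf]
  if (length(first) == 0) .st_stop("empty PIV window [%g, %g) s", t_start, t_end)
  idx_needed <- sort(unique(c(first, first + 1)))
  prep <- new.env()
  get_prep <- function(k) {
    key <- as.character(k)
    if (is.null(prep[[key]]))
      prep[[key]] <- .st_piv_prep(get_frame(stack, k), roi, config)
    prep[[key]]
  }
  grids <- vector("list", length(first))
  for (n in seq_along(first)) {
    k <- first[n]
    grids[[n]] <- piv_pair(get_prep(k), get_prep(k + 1), roi, config,
                           preprocessed = TRUE)
    rm(list = as.character(k), envir = prep) # frame k no longer needed
  }
  structure(list(grids = grids, times = times[first],
                 frame_period = 1 / stack$frame_rate, roi = roi,
                 config = config), class = "velocity_history")
}

#' Surface-adjacent center velocity trace
#'
#' u(t) at the top-row, lateral-center interrogation node (closest to the
#' dorsal surface, middle of the array).
#'
#' @param history a [piv_sequence()] result
#' @return data frame `time_s`, `u_px_per_frame`, `v_px_per_frame`,
#'   `valid` (FALSE where the node value was infilled)
#' @export
surface_trace <- function(history) {
  if (length(history$grids) == 0) .st_stop("empty velocity history")
  g1 <- history$grids[[1]]
  i <- 1L
  j <- as.integer(ceiling(ncol(g1$u) / 2))
  data.frame(time_s = history$times,
             u_px_per_frame = vapply(history$grids, function(g) g$u[i, j], numeric(1)),
             v_px_per_frame = vapply(history$grids, function(g) g$v[i, j], numeric(1)),
             valid = vapply(history$grids, function(g) g$valid[i, j], logical(1)))
}

#' Depth profile of the laterally averaged horizontal velocity
#'
#' @param history a [piv_sequence()] result
#' @return matrix (ROI grid rows, top to bottom) x (time steps) of the
#'   mean u over valid nodes in each row; rows with no valid node give NA
#' @export
depth_profile_map <- function(history) {
  if (length(history$grids) == 0) .st_stop("empty velocity history")
  vapply(history$grids, function(g) {
    sapply(seq_len(nrow(g$u)), function(i) {
      v <- g$u[i, g$valid[i, ]]
      if (length(v) == 0) NA_real_ else mean(v)
    })
  }, numeric(nrow(history$grids[[1]]$u)))
}

#' Export a velocity history as long-format CSV
#'
#' @param history a [piv_sequence()] result
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_velocity_csv <- function(history, path) {
  rows <- lapply(seq_along(history$grids), function(n) {
    g <- history$grids[[n]]
    data.frame(time_s = history$times[n],
               row = as.vector(row(g$u)), col = as.vector(col(g$u)),
               u_px_per_frame = as.vector(g$u), v_px_per_frame = as.vector(g$v),
               valid = as.vector(g$valid))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
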