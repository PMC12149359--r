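#' Pixel / millimetre / time-of-flight conversions
#'
#' The scanner maps 183 pixels to 10 mm; pulse-echo two-way
#' time-of-flight assumes 1540 m/s (propagation speed in a 10% PVA gel).
#'
#' @param d depth in px (>= 0)
#' @param px_per_10mm pixels per 10 mm
#' @return millimetres
#' @export
depth_px_to_mm <- function(d, px_per_10mm = 183) {
  if (any(d < 0)) .st_stop("negative depth")
  d * 10 / px_per_10mm
}

#' @rdname depth_px_to_mm
#' @param mm depth in millimetres (>= 0)
#' @export
depth_mm_to_px <- function(mm, px_per_10mm = 183) {
  if (any(mm < 0)) .st_stop("negative depth")
  mm * px_per_10mm / 10
}

#' @rdname depth_px_to_mm
#' @param c_sound speed of sound, m/s
#' @return microseconds (two-way)
#' @export
depth_mm_to_tof <- function(mm, c_sound = 1540) {
  if (c_sound <= 0) .st_stop("speed of sound must be > 0")
  if (any(mm < 0)) .st_stop("negative depth")
  2 * (mm * 1e-3) / c_sound * 1e6
}

#' Snake parameters
#'
#' Defaults mirror the published contour-fitting configuration: Gaussian
#' smoothing sigmas 5 then 2 px (coarse-to-fine), step size delta = 2 px,
#' band penalty 2 (second-difference stiffness), internal-energy weight
#' alpha = 0.80 and external-energy weight lambda = 0.95.
#'
#' @param sigma_coarse,sigma_fine image smoothing sigmas, px
#' @param delta greedy search step, px
#' @param band_penalty weight of the second-difference (bending) term
#' @param alpha internal-energy weight
#' @param lambda external-energy weight
#' @param max_iterations greedy sweeps per stage
#' @param convergence_tol stop when the largest node move in a sweep is
#'   below this, px
#' @param external external-energy attractor: `"ridge"` (smoothed
#'   intensity; locks onto the bright interface line) or `"gradient"`
#'   (Sobel magnitude; locks onto step-edge flanks)
#' @return object of class `snake_params`
#' @export
snake_params <- function(sigma_coarse = 5, sigma_fine = 2, delta = 2,
                         band_penalty = 2, alpha = 0.80, lambda = 0.95,
                         max_iterations = 60, convergence_tol = 0.5,
                         external = c("ridge", "gradient")) {
  if (alpha < 0 || alpha > 1 || lambda < 0 || lambda > 1)
    .st_stop("alpha and lambda must lie in [0, 1]")
  if (delta < 1) .st_stop("delta must be >= 1")
  structure(list(sigma_coarse = sigma_coarse, sigma_fine = sigma_fine,
                 delta = delta, band_penalty = band_penalty,
                 alpha = alpha, lambda = lambda,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 external = match.arg(external)),
            class = "snake_params")
}

#' Open contour of the dorsal surface
#'
#' Node lateral positions (`stations`, px, fixed) span the frame width at
#' 100 uniformly spaced columns, endpoints inclusive; only the depth (row
#' coordinate, sub-pixel) evolves.
#'
#' @param stations lateral node positions, px
#' @param depth node row coordinates, px
#' @return object of class `st_contour`
#' @export
st_contour <- function(stations, depth) {
  if (length(stations) != length(depth)) .st_stop("stations/depth length mismatch")
  if (is.unsorted(stations, strictly = TRUE)) .st_stop("stations must be strictly increasing")
  structure(list(stations = stations, depth = depth), class = "st_contour")
}

#' Default 100 lateral stations for a frame width
#' @param width_px frame width in px
#' @param n number of stations
#' @return numeric vector of column positions
#' @export
contour_stations <- function(width_px, n = 100) seq(1, width_px, length.out = n)

#' Initialize a contour from the binary surface band
#'
#' Per-station depth is the vertical centroid of the band in the nearest
#' column; stations whose column is empty are filled by linear
#' interpolation between valid neighbors (constant extrapolation at the
#' ends).
#'
#' @param band a [binary_band()]
#' @param n_stations number of contour nodes
#' @return an [st_contour()]
#' @export
initialize_contour <- function(band, n_stations = 100) {
  mask <- band$mask
  nc <- ncol(mask)
  stations <- contour_stations(nc, n_stations)
  cols <- pmin(nc, pmax(1L, round(stations)))
  depth <- vapply(cols, function(c) {
    r <- which(mask[, c])
    if (length(r) == 0) NA_real_ else mean(r)
  }, numeric(1))
  frac_empty <- mean(is.na(depth))
  if (frac_empty > 0.5)
    .st_stop("initialization failed: band empty in %.0f%% of columns", 100 * frac_empty)
  if (anyNA(depth)) {
    ok <- which(!is.na(depth))
    depth <- approx(stations[ok], depth[ok], xout = stations, rule = 2)$y
  }
  st_contour(stations, depth)
}

# normalized external-strength map on the sigma-smoothed image, scaled to
# [0, 1] by its maximum. "ridge" attracts nodes to the bright interface
# line itself (the apex of the echo); "gradient" to the Sobel magnitude
# (the flanks of a step edge).
.st_edge_map <- function(image, sigma, external = "ridge") {
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  sm <- .cpp_gaussian_sep(image, sigma, sigma, half, half)
  g <- if (external == "gradient") .cpp_sobel_mag(sm) else sm
  m <- max(g)
  if (m > 0) g / m else g
}

.st_edge_at <- function(edge, cols, rows) .cpp_bilinear_sample(edge, rows, cols)

# total snake energy; first/second differences are normalized by the
# station spacing so the internal term measures slope/curvature rather
# than raw pixel offsets (keeps the published alpha/lambda weights
# meaningful at any station spacing)
.st_snake_energy <- function(depth, edge_vals, spacing, params) {
  d1 <- diff(depth) / spacing
  d2 <- diff(depth, differences = 2) / spacing^2
  e_int <- sum(d1^2) + params$band_penalty * sum(d2^2)
  e_ext <- -sum(edge_vals)
  params$alpha * e_int + params$lambda * e_ext
}

# one greedy stage on a fixed edge map with step `step`; energy changes
# are evaluated locally (only the difference/curvature terms touching the
# moved node), which keeps a sweep O(n)
.st_snake_stage <- function(edge, contour, params, step) {
  depth <- contour$depth
  stations <- contour$stations
  spacing <- stations[2] - stations[1]
  nr <- nrow(edge)
  n <- length(depth)
  energy_trace <- numeric(0)
  ev <- .st_edge_at(edge, stations, depth)
  energy <- .st_snake_energy(depth, ev, spacing, params)
  a <- params$alpha; lam <- params$lambda; bp <- params$band_penalty
  sp1 <- 1 / spacing^2; sp2 <- 1 / spacing^4
  local_int <- function(d, i) {
    # internal-energy terms involving node i
    e <- 0
    if (i > 1) e <- e + (d[i] - d[i - 1])^2 * sp1
    if (i < n) e <- e + (d[i + 1] - d[i])^2 * sp1
    for (j in max(2, i - 1):min(n - 1, i + 1))
      e <- e + bp * (d[j + 1] - 2 * d[j] + d[j - 1])^2 * sp2
    e
  }
  for (it in seq_len(params$max_iterations)) {
    max_move <- 0
    # collective move: shifting every node together changes no internal
    # term, so a uniformly offset contour can ride toward the interface
    # without paying the tension cost a single-node move would incur
    for (off in c(-step, step)) {
      cand <- depth + off
      if (min(cand) < 1 || max(cand) > nr) next
      ev_c <- .st_edge_at(edge, stations, cand)
      de <- -lam * (sum(ev_c) - sum(ev))
      if (de < -1e-12) {
        depth <- cand; ev <- ev_c; energy <- energy + de
        max_move <- max(max_move, abs(off))
      }
    }
    for (i in seq_len(n)) {
      cands <- depth[i] + c(-step, step)
      cands <- cands[cands >= 1 & cands <= nr]
      if (length(cands) == 0) next
      ev_c <- .st_edge_at(edge, rep(stations[i], length(cands)), cands)
      base_int <- local_int(depth, i)
      best_de <- 0; best <- depth[i]; best_ev <- ev[i]
      for (k in seq_along(cands)) {
        d2 <- depth; d2[i] <- cands[k]
        de <- a * (local_int(d2, i) - base_int) - lam * (ev_c[k] - ev[i])
        if (de < best_de - 1e-12) { best_de <- de; best <- cands[k]; best_ev <- ev_c[k] }
      }
      if (best != depth[i]) {
        max_move <- max(max_move, abs(best - depth[i]))
        depth[i] <- best
        ev[i] <- best_ev
        energy <- energy + best_de
      }
    }
    energy_trace <- c(energy_trace, energy)
    if (max_move < params$convergence_tol) break
  }
  list(depth = depth, energy_trace = energy_trace)
}

#' Evolve a contour on an image (open active contour)
#'
#' Minimizes `alpha * E_internal + lambda * E_external` with
#' `E_internal` the squared first differences plus `band_penalty` times
#' the squared second differences of the node depths (normalized by the
#' station spacing) and `E_external` minus the normalized edge strength
#' sampled at the nodes. Runs a greedy per-node search over depth offsets
#' of +/- delta on the coarse-sigma edge map, refines on the fine-sigma
#' map, performs a final 1 px pass and a parabolic sub-pixel fit of the
#' edge profile at each node. Total energy is non-increasing within every
#' stage (recorded in the `energy_trace` attribute).
#'
#' @param image grayscale matrix
#' @param contour an [st_contour()]
#' @param params a [snake_params()]
#' @return the evolved [st_contour()] with attribute `energy_trace`
#' @export
snake_evolve <- function(image, contour, params = snake_params()) {
  image <- .st_as_num(image)
  edge_c <- .st_edge_map(image, params$sigma_coarse, params$external)
  edge_f <- .st_edge_map(image, params$sigma_fine, params$external)
  s1 <- .st_snake_stage(edge_c, contour, params, params$delta)
  c2 <- st_contour(contour$stations, s1$depth)
  s2 <- .st_snake_stage(edge_f, c2, params, params$delta)
  c3 <- st_contour(contour$stations, s2$depth)
  s3 <- .st_snake_stage(edge_f, c3, params, 1)
  depth <- s3$depth
  # parabolic sub-pixel refinement on the fine edge profile
  nr <- nrow(image)
  for (i in seq_along(depth)) {
    d0 <- depth[i]
    if (d0 <= 1.5 || d0 >= nr - 0.5) next
    v <- .st_edge_at(edge_f, rep(contour$stations[i], 3), d0 + c(-1, 0, 1))
    den <- v[1] - 2 * v[2] + v[3]
    if (den < 0) {
      off <- 0.5 * (v[1] - v[3]) / den
      if (abs(off) <= 0.5) depth[i] <- d0 + off
    }
  }
  out <- st_contour(contour$stations, depth)
  attr(out, "energy_trace") <- list(coarse = s1$energy_trace,
                                    fine = s2$energy_trace,
                                    refine = s3$energy_trace)
  out
}

#' Track the dorsal surface across a frame stack
#'
#' Frame 1 is initialized from the frame-conditioning chain
#' ([preprocess_frame()] then [initialize_contour()]); every later frame
#' starts from the previous solution and is refined by [snake_evolve()].
#' A tracking loss (mean inter-frame jump above `loss_jump_px`) triggers
#' re-initialization from the band with a warning.
#'
#' @param stack a [frame_stack()]
#' @param params a [snake_params()]
#' @param preproc_params parameters for [preprocess_frame()]
#' @param n_stations number of lateral stations
#' @param loss_jump_px mean jump that counts as a tracking loss
#' @return object of class `contour_table`: matrix `row_px` (frames x
#'   stations) plus metadata; see [contour_table_view()]
#' @export
track_sequence <- function(stack, params = snake_params(),
                           preproc_params = list(), n_stations = 100,
                           loss_jump_px = 30) {
  nf <- n_frames(stack)
  if (nf == 0) .st_stop("empty frame stack")
  f1 <- get_frame(stack, 1)
  band <- preprocess_frame(f1, preproc_params)
  ct <- initialize_contour(band, n_stations)
  ct <- snake_evolve(f1, ct, params)
  rows <- matrix(NA_real_, nf, n_stations)
  rows[1, ] <- ct$depth
  if (nf > 1) for (k in 2:nf) {
    fk <- get_frame(stack, k)
    new <- snake_evolve(fk, ct, params)
    if (mean(abs(new$depth - ct$depth)) > loss_jump_px) {
      warning(sprintf("tracking loss at frame %d; re-initializing from band", k))
      bandk <- preprocess_frame(fk, preproc_params)
      new <- snake_evolve(fk, initialize_contour(bandk, n_stations), params)
    }
    ct <- new
    rows[k, ] <- ct$depth
  }
  contour_table(rows, frame_rate = stack$frame_rate,
                frame_height_px = stack$dim[1],
                pixels_per_mm = stack$pixels_per_mm,
                stations = ct$stations)
}

#' Contour table (frames x stations) with unit views
#'
#' Stores the tracked surface row coordinate per frame and station.
#' `contour_table_view()` converts to the three unit views: `"px"` gives
#' the acoustic range of the surface above the transducer (bottom edge)
#' in pixels, `"mm"` applies the 183 px / 10 mm conversion and `"tof"`
#' the two-way pulse-echo time at 1540 m/s, so the views satisfy
#' mm = px * 10/183 and us = 2 mm / 1540 * 1e3 cell by cell.
#'
#' @param row_px matrix of surface row coordinates, frames x stations
#' @param frame_rate frames per second
#' @param frame_height_px frame height (transducer at the bottom edge)
#' @param pixels_per_mm spatial sampling
#' @param stations lateral node positions, px
#' @return object of class `contour_table`
#' @export
contour_table <- function(row_px, frame_rate, frame_height_px, pixels_per_mm,
                          stations = seq_len(ncol(row_px))) {
  structure(list(row_px = row_px, frame_rate = frame_rate,
                 frame_height_px = frame_height_px,
                 pixels_per_mm = pixels_per_mm, stations = stations),
            class = "contour_table")
}

#' @rdname contour_table
#' @param table a `contour_table`
#' @param units one of "row", "px", "mm", "tof"
#' @param c_sound speed of sound, m/s
#' @export
contour_table_view <- function(table, units = c("px", "mm", "tof", "row"),
                               c_sound = 1540) {
  units <- match.arg(units)
  range_px <- table$frame_height_px + 0.5 - table$row_px
  px_per_10mm <- table$pixels_per_mm * 10
  switch(units,
         row = table$row_px,
         px = range_px,
         mm = depth_px_to_mm(range_px, px_per_10mm),
         tof = depth_mm_to_tof(depth_px_to_mm(range_px, px_per_10mm), c_sound))
}

#' Time-of-flight fluctuation map
#'
#' Deviation of the surface echo time-of-flight from the first-frame
#' baseline, Delta(x, t) = ToF(x, t) - ToF(x, frame 1), as a stations x
#' frames matrix (first column all zeros). Compression moves the surface
#' toward the transducer, so deformation shows as negative Delta.
#'
#' @param table a [contour_table()]
#' @param c_sound speed of sound, m/s
#' @return numeric matrix, stations x frames
#' @export
fluctuation_map <- function(table, c_sound = 1540) {
  tof <- contour_table_view(table, "tof", c_sound)
  if (nrow(tof) < 2) .st_stop("fluctuation map needs at least 2 frames")
  delta <- sweep(tof, 2, tof[1, ])
  t(delta)
}

#' Lateral extent of the deformation
#'
#' Per-frame number of stations whose absolute fluctuation exceeds
#' `fraction` of the global maximum absolute fluctuation.
#'
#' @param map a [fluctuation_map()] (stations x frames)
#' @param fraction threshold fraction in (0, 1)
#' @return integer vector, one per frame
#' @export
deformation_width <- function(map, fraction = 0.1) {
  if (length(map) == 0) .st_stop("empty map")
  if (fraction <= 0 || fraction >= 1) .st_stop("fraction must lie in (0, 1)")
  m <- max(abs(map))
  if (m == 0) return(rep(0L, ncol(map)))
  as.integer(colSums(abs(map) > fraction * m))
}

#' Write a contour table as CSV in a chosen unit view
#'
#' @param table a [contour_table()]
#' @param path output CSV
#' @param units see [contour_table_view()]
#' @return `path`, invisibly
#' @export
write_contour_csv <- function(table, path, units = "px") {
  v <- contour_table_view(table, units)
  df <- as.data.frame(v)
  names(df) <- sprintf("station_%d", seq_len(ncol(v)))
  df <- cbind(frame = seq_len(nrow(v)),
              time_s = (seq_len(nrow(v)) - 1) / table$frame_rate, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
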