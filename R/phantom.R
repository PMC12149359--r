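#' Kinematic deformation model of the artificial tongue
#'
#' Analytic displacement field imposed on the phantom. Vertical
#' compression: a fraction `compression_share` of the stage displacement
#' is absorbed by the tongue (the rest by the food gel, the two acting as
#' springs in series); the indentation decays laterally as a Gaussian of
#' width `contact_width` and linearly with height above the base (the
#' base, in contact with the transducer, is fixed). Horizontal shear:
#' the dorsal surface loads elastically against the palate while static
#' friction holds (stick), slips once the surface displacement demand
#' exceeds `static_friction_threshold`, and relaxes exponentially toward
#' a residual when the stroke stops. During stick the surface
#' displacement follows a quadratic-in-time loading profile, so the
#' surface velocity ramps up linearly and peaks exactly at slip onset,
#' reproducing the triangular onset peaks seen in bench velocity traces;
#' the stick duration still equals (distance to slip)/(stage speed).
#'
#' @param tongue_height tongue height above the transducer, mm
#' @param compression_share fraction of vertical stage displacement
#'   absorbed by the tongue (0-1)
#' @param contact_width lateral Gaussian width of the indentation, mm
#' @param shear_gradient ratio of dorsal-surface horizontal displacement
#'   to the stick-slip elastic displacement (depth profile is linear in
#'   height above base)
#' @param static_friction_threshold surface displacement at which slip
#'   starts, mm
#' @param slip_retention fraction of the threshold displacement retained
#'   once sliding has started (0-1)
#' @param fracture_time optional gel fracture time, s (NULL for none)
#' @param slip_tau time constant of the displacement release after slip
#'   onset, s
#' @param rest_tau relaxation time constant after a stroke stops, s
#' @param rest_retention fraction of the stroke-end surface displacement
#'   retained as residual after relaxation (0-1)
#' @param vertical_recovery_tau recovery time constant of the vertical
#'   deformation after the compression ends (gel rearrangement), s;
#'   `Inf` keeps the compression imprint constant
#' @param vertical_residual fraction of vertical deformation never
#'   recovered
#' @return object of class `deformation_model`
#' @export
deformation_model <- function(tongue_height = 18,
                              compression_share = 0.35,
                              contact_width = 8,
                              shear_gradient = 1,
                              static_friction_threshold = 1.2,
                              slip_retention = 0.6,
                              fracture_time = NULL,
                              slip_tau = 0.4,
                              rest_tau = 0.25,
                              rest_retention = 0.5,
                              vertical_recovery_tau = 10,
                              vertical_residual = 0.15) {
  if (tongue_height <= 0) .st_stop("tongue_height must be > 0")
  if (compression_share < 0 || compression_share > 1) .st_stop("compression_share must be in [0, 1]")
  if (slip_retention < 0 || slip_retention > 1) .st_stop("slip_retention must be in [0, 1]")
  structure(list(tongue_height = tongue_height,
                 compression_share = compression_share,
                 contact_width = contact_width,
                 shear_gradient = shear_gradient,
                 static_friction_threshold = static_friction_threshold,
                 slip_retention = slip_retention,
                 fracture_time = fracture_time,
                 slip_tau = slip_tau,
                 rest_tau = rest_tau,
                 rest_retention = rest_retention,
                 vertical_recovery_tau = vertical_recovery_tau,
                 vertical_residual = vertical_residual),
            class = "deformation_model")
}

#' Imaging configuration of the synthetic B-mode renderer
#'
#' The image is oriented with the transducer under the tongue at the
#' bottom edge; the dorsal surface appears as a bright line above the
#' speckle-filled bulk and descends (row index increases) during
#' compression. Pixel row index is the image-space "depth" used by the
#' processing chain; the acoustic range from the transducer of a pixel at
#' row r is (nrow - r) pixels.
#'
#' @param pixels_per_mm spatial sampling (183 px per 10 mm)
#' @param frame_size c(depth px, width px)
#' @param psf_sigma_axial,psf_sigma_lateral Gaussian point-spread sigmas, px
#' @param rf_mode simulate an RF carrier with envelope detection instead
#'   of envelope-only Gaussian splats
#' @param noise_floor additive noise mean, gray levels
#' @param noise_sd additive noise sd, gray levels
#' @param log_compression_gain gain of the log compression mapping
#' @param seed master seed for scatterers / image noise / force noise
#' @param gel_thickness food gel layer thickness above the surface, mm
#' @param interface_amp_factor dorsal interface reflectivity relative to
#'   the mean bulk scatterer amplitude
#' @param interface_spacing spacing of interface scatterers along the
#'   surface, mm
#' @param gel_amp_factor gel speckle amplitude relative to bulk
#' @param intensity_ref fixed envelope reference for log compression;
#'   NULL calibrates it once from the first rendered frame of a sequence
#' @param carrier_freq_mhz RF central frequency (rf_mode only)
#' @param sound_speed speed of sound, m/s
#' @param lateral_margin_mm dark margin at the lateral frame edges
#'   (aperture falloff), mm; keeps the surface line off the image border
#' @return object of class `imaging_config`
#' @export
imaging_config <- function(pixels_per_mm = 18.3,
                           frame_size = c(512, 768),
                           psf_sigma_axial = 1.2,
                           psf_sigma_lateral = 2.0,
                           rf_mode = FALSE,
                           noise_floor = 8,
                           noise_sd = 2,
                           log_compression_gain = 20,
                           seed = 1L,
                           gel_thickness = 8,
                           interface_amp_factor = 6,
                           interface_spacing = 0.1,
                           gel_amp_factor = 0.1,
                           intensity_ref = NULL,
                           carrier_freq_mhz = 6,
                           sound_speed = 1540,
                           lateral_margin_mm = 1) {
  if (pixels_per_mm <= 0) .st_stop("pixels_per_mm must be > 0")
  if (length(frame_size) != 2 || any(frame_size < 8)) .st_stop("frame_size must be c(depth, width) in px")
  structure(list(pixels_per_mm = pixels_per_mm, frame_size = as.integer(frame_size),
                 psf_sigma_axial = psf_sigma_axial, psf_sigma_lateral = psf_sigma_lateral,
                 rf_mode = rf_mode, noise_floor = noise_floor, noise_sd = noise_sd,
                 log_compression_gain = log_compression_gain, seed = as.integer(seed),
                 gel_thickness = gel_thickness,
                 interface_amp_factor = interface_amp_factor,
                 interface_spacing = interface_spacing,
                 gel_amp_factor = gel_amp_factor,
                 intensity_ref = intensity_ref,
                 carrier_freq_mhz = carrier_freq_mhz,
                 sound_speed = sound_speed,
                 lateral_margin_mm = lateral_margin_mm),
            class = "imaging_config")
}

#' Phantom geometry helper
#'
#' @param width_mm lateral extent of the imaged region, mm
#' @param tongue_height_mm tongue height above the transducer, mm
#' @param gel_thickness_mm gel layer thickness above the dorsal surface, mm
#' @return a geometry list
#' @export
phantom_geometry <- function(width_mm, tongue_height_mm, gel_thickness_mm = 0) {
  if (width_mm <= 0 || tongue_height_mm <= 0 || gel_thickness_mm < 0)
    .st_stop("degenerate phantom geometry")
  list(width_mm = width_mm, tongue_height_mm = tongue_height_mm,
       gel_thickness_mm = gel_thickness_mm)
}

.st_geometry_from_config <- function(config, model) {
  # a small dark margin at the lateral frame edges (aperture falloff of the
  # outermost array elements) keeps the bright surface line off the image
  # border, as in the bench images, so the clear-border step preserves it
  phantom_geometry(width_mm = config$frame_size[2] / config$pixels_per_mm -
                     2 * config$lateral_margin_mm,
                   tongue_height_mm = model$tongue_height,
                   gel_thickness_mm = config$gel_thickness)
}

#' Draw a random scatterer field
#'
#' Bulk scatterers are a homogeneous Poisson field with Rayleigh
#' amplitudes (sub-resolution cellulose particles); the dorsal surface
#' carries a dense line of strong reflectors; the gel layer above is weak
#' speckle. Material coordinates: `x_mm` lateral offset from the array
#' center, `h_mm` height above the transducer face.
#'
#' @param geometry a [phantom_geometry()]
#' @param density bulk scatterer density, scatterers per mm^2
#' @param seed integer seed
#' @param interface_amp_factor,interface_spacing,gel_amp_factor see
#'   [imaging_config()]
#' @param gel_density gel speckle density, scatterers per mm^2
#' @return data frame `x_mm`, `h_mm`, `amplitude`, `region`
#' @export
generate_scatterers <- function(geometry, density, seed = 1L,
                                interface_amp_factor = 6,
                                interface_spacing = 0.1,
                                gel_amp_factor = 0.1,
                                gel_density = NULL) {
  if (density < 0) .st_stop("density must be >= 0")
  if (is.null(gel_density)) gel_density <- density
  W <- geometry$width_mm; H <- geometry$tongue_height_mm
  if (density == 0)
    return(data.frame(x_mm = numeric(0), h_mm = numeric(0),
                      amplitude = numeric(0), region = character(0),
                      stringsAsFactors = FALSE))
  set.seed(seed)
  n_bulk <- rpois(1, density * W * H)
  rayleigh <- function(n) sqrt(-2 * log(runif(n)))
  bulk <- data.frame(x_mm = runif(n_bulk, -W / 2, W / 2),
                     h_mm = runif(n_bulk, 0, H),
                     amplitude = rayleigh(n_bulk),
                     region = rep("tongue_bulk", n_bulk),
                     stringsAsFactors = FALSE)
  mean_amp <- if (n_bulk > 0) mean(bulk$amplitude) else 1
  n_iface <- max(2, ceiling(W / interface_spacing))
  iface <- data.frame(x_mm = seq(-W / 2, W / 2, length.out = n_iface),
                      h_mm = rep(H, n_iface),
                      amplitude = interface_amp_factor * mean_amp *
                        (1 + 0.05 * rnorm(n_iface)),
                      region = rep("surface_interface", n_iface),
                      stringsAsFactors = FALSE)
  gel <- NULL
  if (geometry$gel_thickness_mm > 0 && gel_density > 0) {
    n_gel <- rpois(1, gel_density * W * geometry$gel_thickness_mm)
    gel <- data.frame(x_mm = runif(n_gel, -W / 2, W / 2),
                      h_mm = H + runif(n_gel, 0, geometry$gel_thickness_mm),
                      amplitude = gel_amp_factor * rayleigh(n_gel),
                      region = rep("gel", n_gel),
                      stringsAsFactors = FALSE)
  }
  out <- rbind(bulk, iface, gel)
  out$amplitude <- pmax(out$amplitude, 1e-6)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Stick-slip surface kinematics (closed form)

#' Closed-form stick-slip profile of the shear strokes
#'
#' For each shear stroke, returns the entering elastic displacement `s0`,
#' the direction `sigma`, the analytic static-phase (stick) duration
#' `t_stick = (threshold - sigma * s0) / speed`, whether slip occurs
#' before the stroke ends, and the displacement at stroke end. This is
#' the independent oracle used to validate friction-phase detection.
#'
#' @param model a [deformation_model()]
#' @param schedule a [build_schedule()] result
#' @return data frame with one row per shear stroke: `stroke`, `t_start`,
#'   `t_end`, `sigma`, `s0`, `t_stick`, `slips`, `t_slip` (absolute slip
#'   time or NA), `s_end`, `s_residual` (after the following rest)
#' @export
stick_slip_profile <- function(model, schedule) {
  thr <- model$static_friction_threshold
  strokes <- shear_strokes(schedule)
  out <- NULL
  s <- 0
  if (nrow(strokes) > 0) {
    for (i in seq_len(nrow(strokes))) {
      v <- strokes$velocity_mm_s[i]
      sigma <- sign(v); speed <- abs(v)
      dur <- strokes$t_end[i] - strokes$t_start[i]
      delta <- thr - sigma * s        # distance-to-slip along sigma
      t_stick <- delta / speed
      slips <- t_stick < dur
      if (slips) {
        dt_slip <- dur - t_stick
        s_end <- sigma * (model$slip_retention * thr +
                            (1 - model$slip_retention) * thr * exp(-dt_slip / model$slip_tau))
      } else {
        s_end <- s + sigma * delta * (dur / t_stick)^2
      }
      s_res <- model$rest_retention * s_end
      out <- rbind(out, data.frame(stroke = i,
                                   t_start = strokes$t_start[i],
                                   t_end = strokes$t_end[i],
                                   sigma = sigma, s0 = s,
                                   t_stick = t_stick, slips = slips,
                                   t_slip = if (slips) strokes$t_start[i] + t_stick else NA_real_,
                                   s_end = s_end, s_residual = s_res))
      s <- s_res
    }
  }
  out
}

# vectorized surface elastic displacement s(t), mm (signed); t past the
# schedule continues the final relaxation
.st_surface_s <- function(model, schedule, t) {
  prof <- stick_slip_profile(model, schedule)
  thr <- model$static_friction_threshold
  s <- numeric(length(t))
  if (is.null(prof) || nrow(prof) == 0) return(s)
  for (i in seq_len(nrow(prof))) {
    p <- prof[i, ]
    rest_end <- if (i < nrow(prof)) prof$t_start[i + 1] else Inf
    # stick
    in_stick <- t >= p$t_start & t < p$t_start + min(p$t_stick, p$t_end - p$t_start)
    tau_rel <- (t[in_stick] - p$t_start) / p$t_stick
    s[in_stick] <- p$s0 + p$sigma * (thr - p$sigma * p$s0) * tau_rel^2
    if (p$slips) {
      in_slip <- t >= p$t_slip & t < p$t_end
      dt <- t[in_slip] - p$t_slip
      s[in_slip] <- p$sigma * (model$slip_retention * thr +
                                 (1 - model$slip_retention) * thr * exp(-dt / model$slip_tau))
    }
    in_rest <- t >= p$t_end & t < rest_end
    dt <- t[in_rest] - p$t_end
    s[in_rest] <- p$s_residual + (p$s_end - p$s_residual) * exp(-dt / model$rest_tau)
  }
  s
}

# vertical deformation recovery factor: 1 until compression ends (or the
# gel fractures), then exponential recovery toward vertical_residual
.st_vertical_factor <- function(model, schedule, t) {
  seg <- schedule$segments
  comp <- seg[seg$phase == "compression", , drop = FALSE]
  t0 <- if (!is.null(model$fracture_time)) model$fracture_time
        else if (nrow(comp) > 0) comp$t_end[1] else 0
  f <- rep(1, length(t))
  if (is.finite(model$vertical_recovery_tau)) {
    late <- t > t0
    f[late] <- model$vertical_residual + (1 - model$vertical_residual) *
      exp(-(t[late] - t0) / model$vertical_recovery_tau)
  }
  f
}

#' Displacement of a material point at time t
#'
#' Evaluates the analytic displacement field of the phantom. `u_y` is
#' positive downward (toward the transducer): the point's height above
#' the base becomes `h_mm - u_y`. `u_x` is positive in the direction of
#' positive stage motion.
#'
#' @param model a [deformation_model()]
#' @param schedule a [build_schedule()] result
#' @param x_mm,h_mm material coordinates (lateral offset from center,
#'   height above base), vectors of equal length
#' @param t time, s; must be >= 0 (times past the schedule continue the
#'   final relaxation with stages stopped)
#' @return list with vectors `u_x`, `u_y` (mm)
#' @export
displacement_at <- function(model, schedule, x_mm, h_mm, t) {
  if (length(t) != 1 || t < 0) .st_stop("t must be a single time >= 0")
  if (any(h_mm < 0)) .st_stop("points must lie at or above the base")
  H <- model$tongue_height
  pos <- .st_stage_positions(schedule, t)
  hprof <- pmin(h_mm, H) / H
  G <- exp(-x_mm^2 / (2 * model$contact_width^2))
  fy <- .st_vertical_factor(model, schedule, t)
  u_y <- model$compression_share * pos$vertical * hprof * G * fy
  s <- .st_surface_s(model, schedule, t)
  u_x <- model$shear_gradient * s * hprof
  list(u_x = u_x, u_y = u_y)
}

# ---------------------------------------------------------------------------
# Rendering

# material (x_mm, h_mm) -> fractional 1-based pixel coordinates
.st_px_coords <- function(config, x_mm, h_mm) {
  nr <- config$frame_size[1]; nc <- config$frame_size[2]
  list(row = nr + 0.5 - h_mm * config$pixels_per_mm,
       col = (nc + 1) / 2 + x_mm * config$pixels_per_mm)
}

.st_envelope_rf <- function(rf_img) {
  # per-column analytic-signal magnitude along depth (Hilbert transform)
  n <- nrow(rf_img)
  F <- mvfft(rf_img)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  analytic <- mvfft(F * h, inverse = TRUE) / n
  Mod(analytic)
}

#' Render one B-mode frame
#'
#' Displaces the scatterers, splats a separable Gaussian point-spread
#' function, applies log compression and quantizes to 8 bits with an
#' additive noise floor. With `rf_mode = TRUE` the axial profile is
#' modulated at the two-way carrier period with a random phase per
#' scatterer and the envelope is taken as the magnitude of the analytic
#' signal along depth.
#'
#' @param scatterers a [generate_scatterers()] field
#' @param config an [imaging_config()]
#' @param displacement list with `u_x`, `u_y` (mm, one per scatterer), or
#'   NULL for the rest state
#' @param noise optional precomputed noise matrix (frame-size); NULL
#'   draws a fresh one from `config$seed`
#' @param ref envelope reference for log compression (overrides
#'   `config$intensity_ref`)
#' @return integer matrix in 0..255 with attributes `ref` (the reference
#'   used)
#' @export
render_frame <- function(scatterers, config, displacement = NULL,
                         noise = NULL, ref = NULL) {
  nr <- config$frame_size[1]; nc <- config$frame_size[2]
  if (is.null(displacement))
    displacement <- list(u_x = numeric(nrow(scatterers)), u_y = numeric(nrow(scatterers)))
  x <- scatterers$x_mm + displacement$u_x
  h <- scatterers$h_mm - displacement$u_y
  px <- .st_px_coords(config, x, h)
  if (nrow(scatterers) == 0) {
    env <- matrix(0, nr, nc)
  } else if (config$rf_mode) {
    period_px <- config$sound_speed / (2 * config$carrier_freq_mhz * 1e6) * 1e3 *
      config$pixels_per_mm # two-way carrier period in px
    phi <- (sin(seq_len(nrow(scatterers)) * 12.9898) * 43758.5453) %% (2 * pi)
    ar <- scatterers$amplitude * cos(phi)
    ai <- scatterers$amplitude * sin(phi)
    re1 <- .cpp_splat_gaussians(px$row, px$col, ar, nr, nc,
                                config$psf_sigma_axial, config$psf_sigma_lateral)
    im1 <- .cpp_splat_gaussians(px$row, px$col, ai, nr, nc,
                                config$psf_sigma_axial, config$psf_sigma_lateral)
    carrier <- 2 * pi * (seq_len(nr)) / period_px
    rf <- re1 * cos(carrier) - im1 * sin(carrier)
    env <- .st_envelope_rf(rf)
  } else {
    env <- .cpp_splat_gaussians(px$row, px$col, scatterers$amplitude, nr, nc,
                                config$psf_sigma_axial, config$psf_sigma_lateral)
  }
  if (is.null(ref)) ref <- config$intensity_ref
  if (is.null(ref)) {
    ref <- as.numeric(quantile(env, 0.999))
    if (ref <= 0) ref <- 1
  }
  g <- config$log_compression_gain
  img <- 255 * log1p(g * env / ref) / log1p(g)
  if (is.null(noise)) {
    set.seed(.st_child_seed(config$seed, "frame_noise"))
    noise <- matrix(config$noise_floor + config$noise_sd * rnorm(nr * nc), nr, nc)
  }
  img <- img + noise
  out <- matrix(as.integer(pmin(255, pmax(0, round(img)))), nr, nc)
  attr(out, "ref") <- ref
  out
}

#' Render a full synthetic experiment
#'
#' Generates the scatterer field, renders one frame per video period over
#' the schedule (plus an optional tail to observe post-stroke
#' relaxation), and returns the frame stack together with the analytic
#' ground truth and a synthetic force trace.
#'
#' @param protocol a [motion_protocol()]
#' @param model a [deformation_model()]
#' @param config an [imaging_config()]
#' @param density bulk scatterer density, per mm^2
#' @param gel_stiffness,tongue_stiffness Young's moduli, kPa, for the
#'   synthetic force trace
#' @param tail_s extra quiescent time rendered after the schedule ends, s
#' @return list of class `phantom_sequence` with `stack` (a
#'   [frame_stack()]), `ground_truth`, `forces`, `schedule`, `model`,
#'   `config`, `scatterers`
#' @export
render_sequence <- function(protocol = motion_protocol(),
                            model = deformation_model(),
                            config = imaging_config(),
                            density = 3,
                            gel_stiffness = 18.35,
                            tongue_stiffness = 25.57,
                            tail_s = 0) {
  schedule <- build_schedule(protocol)
  geom <- .st_geometry_from_config(config, model)
  sc <- generate_scatterers(geom, density, seed = .st_child_seed(config$seed, "scatterers"),
                            interface_amp_factor = config$interface_amp_factor,
                            interface_spacing = config$interface_spacing,
                            gel_amp_factor = config$gel_amp_factor)
  fr <- protocol$frame_rate
  n_frames <- floor((schedule$total_duration + tail_s) * fr + 1e-9) + 1
  times <- (seq_len(n_frames) - 1) / fr
  nr <- config$frame_size[1]; nc <- config$frame_size[2]
  # sanity: maximal vertical descent must stay inside the frame
  max_desc_px <- model$compression_share * protocol$compression_amplitude *
    config$pixels_per_mm
  surf_row0 <- nr + 0.5 - model$tongue_height * config$pixels_per_mm
  if (surf_row0 < 2 || surf_row0 + max_desc_px > nr - 1)
    .st_stop("deformation leaves the frame: surface row %.1f + descent %.1f px vs %d rows",
             surf_row0, max_desc_px, nr)
  frames <- vector("list", n_frames)
  ref <- config$intensity_ref
  base_noise_seed <- .st_child_seed(config$seed, "frame_noise")
  for (k in seq_len(n_frames)) {
    disp <- displacement_at(model, schedule, sc$x_mm, sc$h_mm, times[k])
    # electronic noise is time-varying, but its stream is keyed to the
    # kinematic state so that identical states (e.g. every frame of a
    # zero-amplitude protocol) render bitwise-identical frames; a frozen
    # per-sequence field would act as a static overlay pattern and bias
    # PIV toward zero displacement
    state_hash <- floor((sum(abs(disp$u_x)) + sum(abs(disp$u_y))) * 1e4) %% 1048573
    set.seed((base_noise_seed + state_hash * 883) %% 2147483647L)
    noise <- matrix(config$noise_floor + config$noise_sd * rnorm(nr * nc), nr, nc)
    img <- render_frame(sc, config, disp, noise = noise, ref = ref)
    if (is.null(ref)) ref <- attr(img, "ref")
    frames[[k]] <- .st_pack_frame(img)
  }
  stack <- frame_stack(frames, frame_rate = fr, pixels_per_mm = config$pixels_per_mm,
                       packed = TRUE)
  gt <- .st_ground_truth(model, schedule, config, times)
  forces <- synthesize_forces(protocol, model, gel_stiffness, tongue_stiffness,
                              seed = .st_child_seed(config$seed, "force_noise"),
                              tail_s = tail_s)
  structure(list(stack = stack, ground_truth = gt, forces = forces,
                 schedule = schedule, model = model, config = config,
                 scatterers = sc),
            class = "phantom_sequence")
}

# analytic ground truth bundle
.st_ground_truth <- function(model, schedule, config, times) {
  nr <- config$frame_size[1]; nc <- config$frame_size[2]
  ppmm <- config$pixels_per_mm
  stations <- seq(1, nc, length.out = 100)
  H <- model$tongue_height
  surface_row_at <- function(t) {
    s <- .st_surface_s(model, schedule, t) * model$shear_gradient
    x_query <- (stations - (nc + 1) / 2) / ppmm     # lateral position, mm
    x_mat <- x_query - s                            # material coordinate
    G <- exp(-x_mat^2 / (2 * model$contact_width^2))
    pos <- .st_stage_positions(schedule, t)
    fy <- .st_vertical_factor(model, schedule, t)
    u_y <- model$compression_share * pos$vertical * G * fy
    nr + 0.5 - (H - u_y) * ppmm
  }
  surface_row <- t(vapply(times, surface_row_at, numeric(length(stations))))
  disp_px <- function(col_px, row_px, t) {
    x_mm <- (col_px - (nc + 1) / 2) / ppmm
    h_mm <- (nr + 0.5 - row_px) / ppmm
    d <- displacement_at(model, schedule, x_mm, pmax(h_mm, 0), t)
    list(u = d$u_x * ppmm, v = d$u_y * ppmm)  # v positive = downward (row+)
  }
  velocity_px <- function(k, col_px, row_px) {
    # px/frame between frames k and k+1 (1-based), at the material points
    # whose frame-k position is (col_px, row_px). The material point is
    # located by fixed-point iteration of m = q - d(m, t0), then the
    # displacement is differenced at that same point.
    t0 <- times[k]; t1 <- times[k + 1]
    d <- disp_px(col_px, row_px, t0)
    for (it in 1:6) d <- disp_px(col_px - d$u, row_px - d$v, t0)
    m_c <- col_px - d$u; m_r <- row_px - d$v
    d0 <- disp_px(m_c, m_r, t0)
    d1 <- disp_px(m_c, m_r, t1)
    list(u = d1$u - d0$u, v = d1$v - d0$v)
  }
  list(times = times, stations = stations, surface_row = surface_row,
       displacement_px = disp_px, velocity_px = velocity_px,
       surface_s_mm = function(t) .st_surface_s(model, schedule, t),
       model = model, schedule = schedule,
       frame_size = config$frame_size, pixels_per_mm = ppmm)
}

#' Series stiffness of two springs
#'
#' @param k1,k2 spring constants
#' @return equivalent stiffness `k1 k2 / (k1 + k2)`
#' @export
series_stiffness <- function(k1, k2) {
  if (any(k1 <= 0) || any(k2 <= 0)) .st_stop("stiffnesses must be > 0")
  k1 * k2 / (k1 + k2)
}

#' Synthesize bench force signals
#'
#' Normal force follows the two-springs-in-series response of the
#' gel/tongue stack to the imposed vertical displacement (with the same
#' recovery factor as the vertical deformation, and an optional fracture
#' drop with exponential decay of the gel contribution). Tangential force
#' is Coulomb friction with a higher static than dynamic coefficient and
#' the sign of the horizontal stage velocity. Gaussian sensor noise with
#' sd = 1% of the +/-50 N range is added.
#'
#' @param protocol a [motion_protocol()]
#' @param model a [deformation_model()]
#' @param gel_stiffness,tongue_stiffness Young's moduli, kPa
#' @param contact_area contact area, mm^2 (25 x 25 mm sample)
#' @param gel_height initial gel height, mm
#' @param mu_static,mu_dynamic friction coefficients
#' @param seed noise seed
#' @param tail_s extra time simulated after the schedule ends, s
#' @return a [force_trace()] at `protocol$force_rate`
#' @export
synthesize_forces <- function(protocol, model, gel_stiffness, tongue_stiffness,
                              contact_area = 625, gel_height = NULL,
                              mu_static = 0.6, mu_dynamic = 0.3,
                              seed = 1L, tail_s = 0) {
  if (gel_stiffness <= 0 || tongue_stiffness <= 0) .st_stop("stiffnesses must be > 0")
  if (is.null(gel_height)) gel_height <- protocol$sample_height
  schedule <- build_schedule(protocol)
  rate <- protocol$force_rate
  n <- floor((schedule$total_duration + tail_s) * rate + 1e-9) + 1
  t <- (seq_len(n) - 1) / rate
  # spring constants in N/mm: E [kPa -> N/mm^2] * A / h
  k_gel <- gel_stiffness * 1e-3 * contact_area / gel_height
  k_t <- tongue_stiffness * 1e-3 * contact_area / model$tongue_height
  if (!is.null(model$fracture_time)) {
    decay <- ifelse(t > model$fracture_time,
                    exp(-(t - model$fracture_time) / 0.3), 1)
    k_gel_t <- k_gel * decay
  } else k_gel_t <- rep(k_gel, n)
  k_eq <- series_stiffness(pmax(k_gel_t, 1e-9), k_t)
  pos <- .st_stage_positions(schedule, t)
  fy <- .st_vertical_factor(model, schedule, t)
  fn <- k_eq * pos$vertical * fy
  # friction state from the closed-form profile
  prof <- stick_slip_profile(model, schedule)
  mu <- numeric(n); sgn <- numeric(n)
  if (!is.null(prof)) for (i in seq_len(nrow(prof))) {
    p <- prof[i, ]
    act <- t >= p$t_start & t < p$t_end
    mu[act] <- ifelse(p$slips & t[act] >= p$t_slip, mu_dynamic, mu_static)
    sgn[act] <- p$sigma
  }
  ft <- mu * fn * sgn
  set.seed(seed)
  fn <- fn + rnorm(n, 0, 0.5)
  ft <- ft + rnorm(n, 0, 0.5)
  force_trace(t, fn, ft, rate)
}
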