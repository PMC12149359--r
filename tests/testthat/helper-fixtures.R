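# Shared fixtures, built lazily once per test session. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fx_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- build()
  .fx_env[[name]]
}

# A scaled-down bench protocol: same structure (compression, then
# alternating shear strokes with rests) at a fraction of the duration so
# the full pipeline stays fast in unit tests.
tiny_protocol <- function(shear_amplitudes = c(1.5, 3, 3),
                          compression_amplitude = 4) {
  motion_protocol(compression_amplitude = compression_amplitude,
                  compression_speed = 2.5,
                  shear_amplitudes = shear_amplitudes,
                  shear_speed = 2.5, rest_duration = 0.8,
                  frame_rate = 60, force_rate = 5000, sample_height = 20)
}

tiny_model <- function(...) {
  args <- utils::modifyList(
    list(tongue_height = 9, compression_share = 0.35,
         contact_width = 5, static_friction_threshold = 0.8,
         slip_retention = 0.6, slip_tau = 0.25, rest_tau = 0.15,
         rest_retention = 0.5, vertical_recovery_tau = 4,
         vertical_residual = 0.15),
    list(...))
  do.call(deformation_model, args)
}

tiny_config <- function(seed = 42L, ...) {
  imaging_config(frame_size = c(256, 384), seed = seed, ...)
}

# one static default-geometry frame plus its generating field (used by
# preproc and contour tests)
fx_static_frame <- function() fixture("static_frame", function() {
  cfg <- imaging_config(seed = 7)
  mod <- deformation_model()
  geom <- sonotongue:::.st_geometry_from_config(cfg, mod)
  sc <- generate_scatterers(geom, 3, seed = 11,
                            interface_amp_factor = cfg$interface_amp_factor,
                            interface_spacing = cfg$interface_spacing,
                            gel_amp_factor = cfg$gel_amp_factor)
  img <- render_frame(sc, cfg)
  list(img = img, config = cfg, model = mod, scatterers = sc,
       surface_row = nrow(img) + 0.5 - mod$tongue_height * cfg$pixels_per_mm,
       margin_px = cfg$lateral_margin_mm * cfg$pixels_per_mm)
})

# a short dynamic phantom (tiny geometry, ~3.7 s, ~220 frames)
fx_tiny_sequence <- function() fixture("tiny_sequence", function() {
  render_sequence(tiny_protocol(), tiny_model(), tiny_config(),
                  density = 3, tail_s = 0.5)
})

# speckle-only pair factory for PIV oracles: returns frame_a and a
# closure rendering frame_b under an imposed per-scatterer displacement
fx_piv_world <- function() fixture("piv_world", function() {
  cfg <- imaging_config(frame_size = c(256, 512), seed = 5, noise_sd = 1)
  geom <- phantom_geometry(width_mm = 512 / cfg$pixels_per_mm, tongue_height_mm = 13)
  sc <- generate_scatterers(geom, 4, seed = 9, interface_amp_factor = 0)
  f0 <- render_frame(sc, cfg)
  ref <- attr(f0, "ref")
  roi <- structure(list(row0 = 60, col0 = 60, width = 370, height = 105),
                   class = "roi_placement")
  list(cfg = cfg, sc = sc, f0 = f0, ref = ref, roi = roi,
       shifted = function(ux_px_fun, uy_px_fun = NULL) {
         upx <- ux_px_fun(sc)
         vpx <- if (is.null(uy_px_fun)) rep(0, nrow(sc)) else uy_px_fun(sc)
         render_frame(sc, cfg, list(u_x = upx / cfg$pixels_per_mm,
                                    u_y = vpx / cfg$pixels_per_mm), ref = ref)
       },
       rowpx = function(s) 256 + 0.5 - s$h_mm * cfg$pixels_per_mm)
})

# analytic surface-velocity trace (px/frame at 60 Hz) from the stick-slip
# closed form -- the independent oracle for friction-event detection
gt_surface_trace <- function(model, schedule, t_end = NULL, frame_rate = 60,
                             pixels_per_mm = 18.3) {
  if (is.null(t_end)) t_end <- schedule$total_duration + 1
  tt <- seq(0, t_end, by = 1 / frame_rate)
  s <- sonotongue:::.st_surface_s(model, schedule, tt) * model$shear_gradient
  u <- diff(s) * pixels_per_mm
  data.frame(time_s = tt[-length(tt)], u_px_per_frame = u,
             v_px_per_frame = 0, valid = TRUE)
}

# Full-scale bench emulation shared by the acceptance criteria: the
# default 26 s protocol at 60 Hz (1561 in-schedule frames) plus a 1.5 s
# quiescent tail so the last stroke's stop peak is observable, tracked
# end to end and measured by PIV over the whole shear phase. Built once.
fx_default_run <- function() fixture("default_run", function() {
  seqd <- render_sequence(motion_protocol(), deformation_model(),
                          imaging_config(seed = 2026L), density = 3,
                          tail_s = 1.5)
  tab <- track_sequence(seqd$stack)
  strokes <- shear_strokes(seqd$schedule)
  t_piv <- strokes$t_start[1] - 0.5
  # ROI anchored at the surface as seen at the start of the analyzed
  # window (the compression imprint has moved it well below its rest row)
  k_ref <- which.min(abs(frame_times(seqd$stack) - t_piv))
  roi <- anchor_roi(tab, roi_spec(), seqd$stack$dim, frame = k_ref)
  hist <- piv_sequence(seqd$stack, roi, piv_config(),
                       t_start = t_piv,
                       t_end = max(frame_times(seqd$stack)))
  list(seq = seqd, table = tab, roi = roi, history = hist,
       trace = surface_trace(hist))
})
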