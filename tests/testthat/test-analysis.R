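test_that("no events are reported on a quiet trace", {
  sch <- build_schedule(tiny_protocol())
  tr <- data.frame(time_s = seq(0, sch$total_duration, by = 1 / 60),
                   u_px_per_frame = 0)
  ev <- detect_friction_events(tr, sch)
  expect_equal(nrow(ev), 0)
})

test_that("stick-slip traces yield one onset and one stop peak per stroke", {
  mod <- tiny_model()
  sch <- build_schedule(tiny_protocol())
  set.seed(8)
  tr <- gt_surface_trace(mod, sch)
  tr$u_px_per_frame <- tr$u_px_per_frame + rnorm(nrow(tr), 0, 0.003)
  ev <- detect_friction_events(tr, sch)
  n_strokes <- nrow(shear_strokes(sch))
  expect_equal(nrow(ev), 2 * n_strokes)
  for (k in seq_len(n_strokes)) {
    on <- ev[ev$stroke == k & ev$kind == "onset_peak", ]
    off <- ev[ev$stroke == k & ev$kind == "stop_peak", ]
    expect_equal(nrow(on), 1)
    expect_equal(nrow(off), 1)
    # opposite polarity, onset amplitude exceeds stop amplitude
    expect_lt(on$amplitude * off$amplitude, 0)
    expect_gt(abs(on$amplitude), abs(off$amplitude))
    # durations are positive and shorter than the stroke
    expect_gt(on$duration_s, 0)
  }
  # mirror experiment: flipping the trace sign negates amplitudes only
  tr2 <- tr; tr2$u_px_per_frame <- -tr2$u_px_per_frame
  ev2 <- detect_friction_events(tr2, sch)
  expect_equal(ev2$kind, ev$kind)
  expect_equal(ev2$stroke, ev$stroke)
  expect_equal(ev2$amplitude, -ev$amplitude, tolerance = 1e-12)
})

test_that("phase classification matches the kinematic closed form", {
  mod <- tiny_model()
  sch <- build_schedule(tiny_protocol())
  set.seed(9)
  tr <- gt_surface_trace(mod, sch)
  tr$u_px_per_frame <- tr$u_px_per_frame + rnorm(nrow(tr), 0, 0.003)
  ev <- detect_friction_events(tr, sch)
  ph <- classify_phases(ev, sch)
  prof <- stick_slip_profile(mod, sch)
  expect_true(all(ph$determined))
  for (k in seq_len(nrow(ph))) {
    # static + dynamic intervals tile the stroke exactly
    expect_equal(ph$static_start[k], prof$t_start[k])
    expect_equal(ph$dynamic_end[k], prof$t_end[k])
    expect_equal(ph$static_end[k], ph$dynamic_start[k])
    # detected static duration within 2 frames of the closed form
    expect_lt(abs((ph$static_end[k] - ph$static_start[k]) - prof$t_stick[k]),
              2 / 60 + 1e-9)
  }
  # pure stick: dynamic interval collapses to (at most) a frame
  mod2 <- tiny_model(static_friction_threshold = 50)
  tr2 <- gt_surface_trace(mod2, sch)
  ev2 <- detect_friction_events(tr2, sch, noise_floor = 0.001)
  ph2 <- classify_phases(ev2, sch)
  det <- ph2[ph2$determined, ]
  expect_gt(nrow(det), 0)
  expect_lt(max(det$dynamic_end - det$dynamic_start), 2 / 60 + 1e-9)
  # onset-peak delay grows monotonically with the friction threshold
  delays <- vapply(c(0.4, 0.6, 0.8, 1.0, 1.2), function(thr) {
    m <- tiny_model(static_friction_threshold = thr)
    e <- detect_friction_events(gt_surface_trace(m, sch), sch,
                                noise_floor = 0.001)
    on <- e[e$kind == "onset_peak" & e$stroke == 1, ]
    on$time_s - shear_strokes(sch)$t_start[1]
  }, numeric(1))
  expect_true(all(diff(delays) > 0))
  expect_gte(cor(delays, c(0.4, 0.6, 0.8, 1.0, 1.2), method = "spearman"), 0.9)
})

test_that("decay fitting recovers exponential time constants", {
  tt <- seq(0, 5, by = 1 / 60)
  tr <- data.frame(time_s = tt,
                   u_px_per_frame = 2 * exp(-pmax(tt - 1, 0) / 0.5))
  ev <- data.frame(time_s = 1, amplitude = 2, kind = "onset_peak")
  tau <- decay_time(tr, ev, t_end = 4)
  expect_equal(as.numeric(tau), 0.5, tolerance = 0.02)
  # constant trace is flagged non-exponential
  trc <- data.frame(time_s = tt, u_px_per_frame = rep(1, length(tt)))
  tauc <- decay_time(trc, ev, t_end = 4)
  expect_true(is.na(tauc))
  expect_true(isTRUE(attr(tauc, "non_exponential")))
  # slower slip release in the model gives a larger fitted tau
  sch <- build_schedule(tiny_protocol())
  taus <- vapply(c(0.2, 0.3, 0.45), function(st) {
    m <- tiny_model(slip_tau = st)
    tr <- gt_surface_trace(m, sch)
    e <- detect_friction_events(tr, sch, noise_floor = 0.001)
    on <- e[e$kind == "onset_peak" & e$stroke == 2, ]
    as.numeric(decay_time(tr, on, t_end = shear_strokes(sch)$t_end[2]))
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("residual deformation follows the relaxation of the phantom", {
  sch <- build_schedule(tiny_protocol())
  cfg <- tiny_config()
  rest <- 0.8
  t_grid <- seq(0, sch$total_duration + rest, by = 1 / 60)
  # static table: zero residuals
  rows0 <- matrix(150, length(t_grid), 100)
  tab0 <- contour_table(rows0, 60, cfg$frame_size[1], cfg$pixels_per_mm)
  r0 <- residual_deformation(tab0, sch)
  expect_true(all(abs(r0$residual_tof_us) < 1e-12))
  # relaxing phantom: |residual| decreases stroke over stroke and ends
  # near zero for a fast-relaxing model
  gt_tab <- function(mod) {
    gt <- sonotongue:::.st_ground_truth(mod, sch, cfg, t_grid)
    contour_table(gt$surface_row, 60, cfg$frame_size[1], cfg$pixels_per_mm,
                  gt$stations)
  }
  rr <- residual_deformation(gt_tab(tiny_model(vertical_recovery_tau = 1,
                                               vertical_residual = 0)), sch)
  expect_true(all(diff(abs(rr$residual_tof_us)) < 0))
  expect_lt(abs(rr$residual_tof_us[nrow(rr)]), 0.1)
  # without recovery the residual persists
  rk <- residual_deformation(gt_tab(tiny_model(vertical_recovery_tau = Inf)), sch)
  expect_gt(abs(rk$residual_tof_us[nrow(rk)]), 1)
})

test_that("Young's modulus is the OLS slope in the 2.5-5% strain window", {
  strain <- seq(0, 0.2, by = 0.002)
  curve <- stress_strain_curve(strain, 18.35 * strain)
  expect_equal(young_modulus(curve), 18.35, tolerance = 1e-10)
  # bilinear stiffening above 5% does not leak into the window
  stress2 <- ifelse(strain <= 0.05, 10 * strain, 10 * 0.05 + 40 * (strain - 0.05))
  expect_equal(young_modulus(stress_strain_curve(strain, stress2)), 10,
               tolerance = 1e-10)
  # noise of sd 1% of the local stress: slope within 5% of truth over
  # 100 seeded repeats (strain grid as a 10 mm/s test sampled at 500 Hz)
  strain_f <- seq(0, 0.2, by = 0.001)
  truth <- 18.35 * strain_f
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- truth + rnorm(length(strain_f), 0, 0.01 * pmax(truth, 1e-9))
    abs(young_modulus(stress_strain_curve(strain_f, noisy)) - 18.35) / 18.35
  }, numeric(1))
  expect_lt(max(errs), 0.05)
  expect_error(young_modulus(stress_strain_curve(c(0, 0.1, 0.2), c(0, 1, 2))),
               "fewer than 3")
  expect_error(stress_strain_curve(c(0.2, 0.1), c(1, 2)), "increasing")
})
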