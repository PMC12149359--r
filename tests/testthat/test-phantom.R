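test_that("scatterer generation follows the declared field statistics", {
  geom <- phantom_geometry(80, 15)
  expect_equal(nrow(generate_scatterers(geom, 0)), 0)
  sc <- generate_scatterers(geom, 2, seed = 3)
  n_bulk <- sum(sc$region == "tongue_bulk")
  expect_lt(abs(n_bulk - 2400), 3 * sqrt(2400))
  expect_true(all(sc$amplitude > 0))
  expect_true(all(abs(sc$x_mm) <= 40 & sc$h_mm >= 0))
  # interface line is dense and strong relative to the bulk
  iface <- sc[sc$region == "surface_interface", ]
  expect_gt(nrow(iface), 80 / 0.2)
  expect_gt(mean(iface$amplitude),
            3 * mean(sc$amplitude[sc$region == "tongue_bulk"]))
  # reproducibility
  sc2 <- generate_scatterers(geom, 2, seed = 3)
  expect_identical(sc, sc2)
  expect_false(identical(sc, generate_scatterers(geom, 2, seed = 4)))
  expect_error(phantom_geometry(0, 10), "degenerate")
})

test_that("displacement field obeys its closed forms", {
  mod <- tiny_model()
  sch <- build_schedule(tiny_protocol())
  # t = 0 and base points are fixed
  d0 <- displacement_at(mod, sch, c(-3, 0, 3), c(1, 5, 9), 0)
  expect_equal(d0$u_x, c(0, 0, 0))
  expect_equal(d0$u_y, c(0, 0, 0))
  db <- displacement_at(mod, sch, c(-3, 0, 3), c(0, 0, 0), 2.5)
  expect_equal(db$u_x, c(0, 0, 0))
  expect_equal(db$u_y, c(0, 0, 0))
  # compression: u_y = share * stage * (h/H) * G(x) at mid-compression
  tq <- 0.8
  d <- displacement_at(mod, sch, 2, 6, tq)
  expect_equal(d$u_y,
               0.35 * 2.5 * tq * (6 / 9) * exp(-4 / (2 * 25)),
               tolerance = 1e-12)
  # stick phase: surface velocity matches the finite difference of the
  # quadratic loading profile, and peaks at slip onset
  prof <- stick_slip_profile(mod, sch)
  p1 <- prof[1, ]
  h <- 1e-5
  tm <- p1$t_start + 0.5 * p1$t_stick
  fd <- (displacement_at(mod, sch, 0, 9, tm + h)$u_x -
           displacement_at(mod, sch, 0, 9, tm - h)$u_x) / (2 * h)
  speed <- abs(shear_strokes(sch)$velocity_mm_s[1])
  analytic <- 2 * speed * (tm - p1$t_start) / p1$t_stick
  expect_equal(fd, analytic, tolerance = 1e-4)
  # depth profile of shear is linear in h
  ds <- displacement_at(mod, sch, 0, c(3, 6, 9), tm)
  expect_equal(ds$u_x[1] / ds$u_x[3], 3 / 9, tolerance = 1e-12)
  # surface displacement never exceeds the static friction threshold
  for (tt in seq(0, sch$total_duration, by = 0.05)) {
    s <- displacement_at(mod, sch, 0, 9, tt)$u_x
    expect_lte(abs(s), mod$static_friction_threshold + 1e-9)
  }
  expect_error(displacement_at(mod, sch, 0, -1, 1), "base")
})

test_that("stick-slip closed form has the stated structure", {
  mod <- tiny_model()
  sch <- build_schedule(tiny_protocol())
  prof <- stick_slip_profile(mod, sch)
  expect_equal(nrow(prof), 3)
  # first stroke starts unloaded: stick time = threshold / speed
  expect_equal(prof$t_stick[1], 0.8 / 2.5, tolerance = 1e-12)
  # later strokes start from the opposite residual: longer stick
  expect_gt(prof$t_stick[2], prof$t_stick[1])
  # alternating directions, residuals carry over
  expect_equal(prof$sigma, c(1, -1, 1))
  expect_equal(prof$s0[-1], prof$s_residual[-nrow(prof)])
  # pure stick when the threshold exceeds the stroke demand
  mod2 <- tiny_model(static_friction_threshold = 50)
  prof2 <- stick_slip_profile(mod2, sch)
  expect_false(any(prof2$slips))
})

test_that("rendering places energy where the scatterers are", {
  cfg <- tiny_config()
  # empty field: mean within 1 gray level of the noise floor
  empty <- generate_scatterers(phantom_geometry(10, 5), 0)
  img <- render_frame(empty, cfg)
  expect_lt(abs(mean(img) - cfg$noise_floor), 1)
  # single scatterer: intensity argmax within 1 px of its position
  # (explicit reference keeps the stamp below saturation)
  one <- data.frame(x_mm = 1.7, h_mm = 6.3, amplitude = 1, region = "tongue_bulk")
  img1 <- render_frame(one, cfg, noise = matrix(0, 256, 384), ref = 5)
  pk <- arrayInd(which.max(img1), dim(img1))
  expect_lt(abs(pk[1] - (256 + 0.5 - 6.3 * cfg$pixels_per_mm)), 1)
  expect_lt(abs(pk[2] - ((384 + 1) / 2 + 1.7 * cfg$pixels_per_mm)), 1)
  # surface interface outshines the bulk
  fx <- fx_static_frame()
  srow <- round(fx$surface_row)
  interior <- (fx$margin_px + 5):(ncol(fx$img) - fx$margin_px - 5)
  expect_gt(mean(apply(fx$img[(srow - 3):(srow + 3), interior], 2, max)),
            2 * mean(fx$img[(srow + 30):(srow + 200), interior]))
})

test_that("rf mode localizes scatterers through envelope detection", {
  cfg <- tiny_config(rf_mode = TRUE, noise_floor = 0, noise_sd = 0)
  one <- data.frame(x_mm = 0.4, h_mm = 7.1, amplitude = 1, region = "tongue_bulk")
  img <- render_frame(one, cfg, noise = matrix(0, 256, 384), ref = 5)
  pk <- arrayInd(which.max(img), dim(img))
  expect_lt(abs(pk[1] - (256 + 0.5 - 7.1 * cfg$pixels_per_mm)), 2)
  expect_lt(abs(pk[2] - ((384 + 1) / 2 + 0.4 * cfg$pixels_per_mm)), 2)
  expect_true(all(img >= 0))
})

test_that("rendering is translation-equivariant for integer shifts", {
  cfg <- tiny_config(noise_floor = 0, noise_sd = 0)
  geom <- phantom_geometry(384 / cfg$pixels_per_mm, 10)
  sc <- generate_scatterers(geom, 3, seed = 2, interface_amp_factor = 0)
  zn <- matrix(0, 256, 384)
  f0 <- render_frame(sc, cfg, noise = zn)
  ref <- attr(f0, "ref")
  shift <- 5
  fs <- render_frame(sc, cfg,
                     list(u_x = rep(shift / cfg$pixels_per_mm, nrow(sc)),
                          u_y = rep(0, nrow(sc))),
                     noise = zn, ref = ref)
  expect_identical(fs[, (1 + shift):384], f0[, 1:(384 - shift)])
})

test_that("rendered sequences carry consistent ground truth", {
  seqd <- fx_tiny_sequence()
  p <- tiny_protocol()
  sch <- seqd$schedule
  expect_equal(n_frames(seqd$stack),
               floor((sch$total_duration + 0.5) * 60) + 1)
  gt <- seqd$ground_truth
  # surface at lateral center descends monotonically during compression
  comp_frames <- which(gt$times <= 4 / 2.5)
  center <- gt$surface_row[comp_frames, 50]
  expect_true(all(diff(center) > -1e-9))
  expect_gt(center[length(center)] - center[1], 10)
  # ground-truth velocity is consistent with the finite difference of the
  # ground-truth displacement at the same material point (located here by
  # an independent fixed-point iteration)
  k <- which.min(abs(gt$times - 1.0))
  v <- gt$velocity_px(k, c(100, 192, 300), c(150, 180, 210))
  qc <- c(100, 192, 300); qr <- c(150, 180, 210)
  mc <- qc; mr <- qr
  for (it in 1:20) {
    d <- gt$displacement_px(mc, mr, gt$times[k])
    mc <- qc - d$u; mr <- qr - d$v
  }
  d0 <- gt$displacement_px(mc, mr, gt$times[k])
  d1 <- gt$displacement_px(mc, mr, gt$times[k + 1])
  expect_equal(v$v, d1$v - d0$v, tolerance = 0.02)
  expect_equal(v$u, d1$u - d0$u, tolerance = 0.02)
  # zero-amplitude protocol gives bitwise-identical frames
  p0 <- motion_protocol(compression_amplitude = 0, shear_amplitudes = 0,
                        rest_duration = 0.25)
  seq0 <- render_sequence(p0, tiny_model(), tiny_config(), density = 2)
  expect_gt(n_frames(seq0$stack), 2)
  for (k in 2:n_frames(seq0$stack))
    expect_identical(seq0$stack$frames[[k]], seq0$stack$frames[[1]])
  # out-of-frame deformation raises a diagnostic
  expect_error(render_sequence(motion_protocol(compression_amplitude = 60),
                               deformation_model(), imaging_config()),
               "frame")
})

test_that("synthetic forces behave like two springs in series", {
  expect_equal(series_stiffness(4, 4), 2)
  expect_equal(series_stiffness(2, 6), 1.5)
  p <- tiny_protocol()
  mod <- tiny_model()
  f_soft <- synthesize_forces(p, mod, 6.45, 25.57, seed = 1)
  f_stiff <- synthesize_forces(p, mod, 18.35, 25.57, seed = 1)
  expect_gt(max(f_stiff$normal_force), max(f_soft$normal_force))
  # peak normal force coincides with the end of compression
  t_comp <- 4 / 2.5
  expect_lt(abs(f_stiff$time[which.max(f_stiff$normal_force)] - t_comp), 0.1)
  # zero protocol: zero-mean sensor noise only
  p0 <- motion_protocol(compression_amplitude = 0, shear_amplitudes = 0)
  f0 <- synthesize_forces(p0, mod, 10, 10, seed = 2)
  expect_lt(abs(mean(f0$normal_force)), 0.05)
  expect_equal(sd(f0$normal_force), 0.5, tolerance = 0.1)
  # fracture drops the gel contribution
  modf <- tiny_model(fracture_time = 1.0)
  ff <- synthesize_forces(p, modf, 18.35, 25.57, seed = 1)
  i_end <- which.min(abs(ff$time - t_comp))
  expect_lt(ff$normal_force[i_end], 0.5 * f_stiff$normal_force[i_end])
  # tangential force flips sign with the stroke direction
  fs <- synthesize_forces(p, mod, 18.35, 25.57, seed = 3)
  strokes <- shear_strokes(build_schedule(p))
  m1 <- mean(fs$tangential_force[fs$time > strokes$t_start[1] & fs$time < strokes$t_end[1]])
  m2 <- mean(fs$tangential_force[fs$time > strokes$t_start[2] & fs$time < strokes$t_end[2]])
  expect_gt(m1, 0)
  expect_lt(m2, 0)
})
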