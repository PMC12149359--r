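#' Detect stick-slip friction events in a surface velocity trace
#'
#' For every shear stroke fully covered by the trace: the onset peak is
#' the signed extremum of u within the stroke (elastic loading under
#' static friction, ending at slip onset) and the stop peak
#' is the extremum of opposite sign between the stroke end and the end of
#' the following rest (elastic recoil). Peaks below the noise floor
#' (3 x the standard deviation of u before the first covered stroke, or
#' over the quietest rest if no pre-stroke samples exist) are not
#' recorded. Durations are widths at half amplitude.
#'
#' @param trace data frame with `time_s` and `u_px_per_frame` (e.g. from
#'   [surface_trace()])
#' @param schedule a [build_schedule()] result
#' @param noise_floor optional explicit amplitude floor (overrides the
#'   3-sigma rule)
#' @return data frame of class `friction_events`: `stroke`, `kind`
#'   (`onset_peak`/`stop_peak`), `time_s`, `amplitude` (signed,
#'   px/frame), `duration_s`, `decay_tau_s` (onset peaks only, NA when
#'   non-exponential)
#' @export
detect_friction_events <- function(trace, schedule, noise_floor = NULL) {
  u <- trace$u_px_per_frame; tt <- trace$time_s
  if (length(u) < 3) .st_stop("trace too short")
  if (min(tt) > schedule$total_duration)
    .st_stop("trace does not overlap the schedule")
  strokes <- shear_strokes(schedule)
  rest <- schedule$protocol$rest_duration
  if (is.null(noise_floor)) {
    pre <- u[tt < (if (nrow(strokes)) strokes$t_start[1] else Inf)]
    if (length(pre) < 5) {
      # fall back to the quietest covered rest period
      in_stroke <- rep(FALSE, length(tt))
      for (i in seq_len(nrow(strokes)))
        in_stroke <- in_stroke | (tt >= strokes$t_start[i] - 0.5 &
                                    tt < strokes$t_end[i] + rest + 0.5)
      pre <- u[!in_stroke]
    }
    noise_floor <- if (length(pre) >= 5) 3 * sd(pre) else 0
  }
  events <- NULL
  for (i in seq_len(nrow(strokes))) {
    s <- strokes[i, ]
    # search the whole stroke: with slip the |u| extremum sits at slip
    # onset (early); without slip the loading velocity keeps rising and
    # peaks at the stroke end
    win <- tt >= s$t_start & tt <= s$t_end
    if (!any(win)) next
    io <- which(win)[which.max(abs(u[win]))]
    amp_on <- u[io]
    if (abs(amp_on) <= noise_floor) next
    events <- rbind(events, data.frame(
      stroke = s$stroke, kind = "onset_peak", time_s = tt[io],
      amplitude = amp_on,
      duration_s = .st_half_width(tt, u, io),
      decay_tau_s = .st_decay_tau(tt, u, io, s$t_end),
      stringsAsFactors = FALSE))
    stop_win <- tt >= s$t_end & tt <= s$t_end + rest
    if (any(stop_win)) {
      us <- u[stop_win]
      opp <- us * sign(amp_on) < 0
      if (any(opp)) {
        cand <- which(stop_win)[opp][which.max(abs(us[opp]))]
        amp_off <- u[cand]
        if (abs(amp_off) > noise_floor) {
          events <- rbind(events, data.frame(
            stroke = s$stroke, kind = "stop_peak", time_s = tt[cand],
            amplitude = amp_off,
            duration_s = .st_half_width(tt, u, cand),
            decay_tau_s = NA_real_, stringsAsFactors = FALSE))
        }
      }
    }
  }
  structure(if (is.null(events))
    data.frame(stroke = integer(0), kind = character(0), time_s = numeric(0),
               amplitude = numeric(0), duration_s = numeric(0),
               decay_tau_s = numeric(0))
    else events, class = c("friction_events", "data.frame"))
}

# width at half amplitude around sample io
.st_half_width <- function(tt, u, io) {
  half <- abs(u[io]) / 2
  sgn <- sign(u[io])
  above <- sgn * u >= half
  lo <- io
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- io
  while (hi < length(u) && above[hi + 1]) hi <- hi + 1
  tt[hi] - tt[lo] + (tt[2] - tt[1])
}

# exponential decay fit |u| ~ A exp(-(t - t_peak)/tau) after the peak
.st_decay_tau <- function(tt, u, io, t_end) {
  post <- which(tt > tt[io] & tt <= t_end)
  if (length(post) < 10) return(NA_real_)
  y <- abs(u[post])
  floor_y <- max(abs(u[io]) * 1e-3, 1e-9)
  keep <- y > floor_y
  if (sum(keep) < 10) return(NA_real_)
  fit <- lm(log(y[keep]) ~ tt[post][keep])
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  as.numeric(-1 / slope)
}

#' Fit the post-peak exponential decay time of one onset event
#'
#' @param trace data frame with `time_s`, `u_px_per_frame`
#' @param event one row of [detect_friction_events()] (an onset peak)
#' @param t_end end of the dynamic interval (defaults to peak + 10 s)
#' @return tau in seconds, or NA with a `"non_exponential"` attribute
#'   when the post-peak segment does not decay
#' @export
decay_time <- function(trace, event, t_end = NULL) {
  tt <- trace$time_s; u <- trace$u_px_per_frame
  io <- which.min(abs(tt - event$time_s))
  if (is.null(t_end)) t_end <- event$time_s + 10
  tau <- .st_decay_tau(tt, u, io, t_end)
  if (is.na(tau)) attr(tau, "non_exponential") <- TRUE
  tau
}

#' Classify static and dynamic friction intervals per stroke
#'
#' The static interval runs from the stroke start to the onset-peak time
#' (elastic loading, no relative sliding); the dynamic interval from the
#' onset peak to the stroke end (sliding). The two tile the stroke.
#' Strokes without a detected onset peak are labeled undetermined.
#'
#' @param events a [detect_friction_events()] result
#' @param schedule a [build_schedule()] result
#' @return data frame: `stroke`, `static_start`, `static_end`,
#'   `dynamic_start`, `dynamic_end`, `determined`
#' @export
classify_phases <- function(events, schedule) {
  strokes <- shear_strokes(schedule)
  out <- NULL
  for (i in seq_len(nrow(strokes))) {
    s <- strokes[i, ]
    ev <- events[events$stroke == s$stroke & events$kind == "onset_peak", ]
    if (nrow(ev) == 1) {
      out <- rbind(out, data.frame(stroke = s$stroke,
                                   static_start = s$t_start, static_end = ev$time_s,
                                   dynamic_start = ev$time_s, dynamic_end = s$t_end,
                                   determined = TRUE))
    } else {
      out <- rbind(out, data.frame(stroke = s$stroke,
                                   static_start = s$t_start, static_end = NA_real_,
                                   dynamic_start = NA_real_, dynamic_end = s$t_end,
                                   determined = FALSE))
    }
  }
  out
}

#' Residual surface deformation after each stroke
#'
#' Mean center-station time-of-flight deviation from the first-frame
#' baseline over the rest period following each shear stroke. Negative
#' values mean the surface sits closer to the transducer than at rest.
#'
#' @param table a [contour_table()]
#' @param schedule a [build_schedule()] result
#' @param c_sound speed of sound, m/s
#' @return data frame `stroke`, `t_rest_start`, `t_rest_end`,
#'   `residual_tof_us`
#' @export
residual_deformation <- function(table, schedule, c_sound = 1540) {
  map <- fluctuation_map(table, c_sound)      # stations x frames
  center <- map[round(nrow(map) / 2), ]
  times <- (seq_len(ncol(map)) - 1) / table$frame_rate
  strokes <- shear_strokes(schedule)
  rest <- schedule$protocol$rest_duration
  out <- NULL
  for (i in seq_len(nrow(strokes))) {
    s <- strokes[i, ]
    w <- times >= s$t_end & times <= s$t_end + rest
    out <- rbind(out, data.frame(stroke = s$stroke,
                                 t_rest_start = s$t_end,
                                 t_rest_end = s$t_end + rest,
                                 residual_tof_us = if (any(w)) mean(center[w]) else NA_real_))
  }
  out
}

#' Stress-strain curve container
#'
#' @param strain dimensionless strain, strictly increasing
#' @param stress stress, kPa
#' @return object of class `stress_strain_curve`
#' @export
stress_strain_curve <- function(strain, stress) {
  if (length(strain) != length(stress)) .st_stop("strain/stress length mismatch")
  if (is.unsorted(strain, strictly = TRUE)) .st_stop("strain must be strictly increasing")
  structure(list(strain = strain, stress = stress), class = "stress_strain_curve")
}

#' Young's modulus from the stress-strain slope
#'
#' Ordinary least-squares slope of stress versus strain restricted to the
#' window over which linear elasticity holds (2.5% to 5% strain).
#'
#' @param curve a [stress_strain_curve()]
#' @param window strain window, default c(0.025, 0.05)
#' @return modulus in kPa
#' @export
young_modulus <- function(curve, window = c(0.025, 0.05)) {
  keep <- curve$strain >= window[1] & curve$strain <= window[2]
  if (sum(keep) < 3)
    .st_stop("fewer than 3 points in the strain window [%g, %g]", window[1], window[2])
  as.numeric(coef(lm(curve$stress[keep] ~ curve$strain[keep]))[2])
}
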