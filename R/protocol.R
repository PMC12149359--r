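#' Imposed tongue-palate motion protocol
#'
#' Describes the automatic sequence of stage displacements applied on the
#' biomimetic bench: a single uniaxial compression of the vertical stage,
#' followed by successive horizontal shearing strokes whose directions
#' alternate so that the motion stays centered on the initial position.
#' Each motion is followed by a rest period. Defaults reproduce the bench
#' sequence: 15 mm compression at 2.5 mm/s (75% engineering strain on a
#' 20 mm sample), four shear strokes of 5, 10, 10, 10 mm at 2.5 mm/s,
#' 1.5 s rests, 60 Hz video and 25 kHz force sampling.
#'
#' @param compression_amplitude vertical stroke, mm
#' @param compression_speed vertical stage speed, mm/s
#' @param shear_amplitudes ordered shear stroke amplitudes, mm
#' @param shear_speed horizontal stage speed, mm/s
#' @param rest_duration rest after each motion, s
#' @param frame_rate video frame rate, Hz
#' @param force_rate force sampling rate, Hz
#' @param sample_height initial food sample height, mm
#' @return an object of class `motion_protocol`
#' @export
motion_protocol <- function(compression_amplitude = 15,
                            compression_speed = 2.5,
                            shear_amplitudes = c(5, 10, 10, 10),
                            shear_speed = 2.5,
                            rest_duration = 1.5,
                            frame_rate = 60,
                            force_rate = 25000,
                            sample_height = 20) {
  if (compression_amplitude < 0 || any(shear_amplitudes < 0))
    .st_stop("invalid protocol: amplitudes must be >= 0")
  if (compression_speed <= 0 || shear_speed <= 0)
    .st_stop("invalid protocol: speeds must be > 0")
  if (rest_duration < 0) .st_stop("invalid protocol: rest_duration must be >= 0")
  if (frame_rate <= 0 || force_rate <= 0) .st_stop("invalid protocol: rates must be > 0")
  if (sample_height <= 0) .st_stop("invalid protocol: sample_height must be > 0")
  structure(list(compression_amplitude = compression_amplitude,
                 compression_speed = compression_speed,
                 shear_amplitudes = as.numeric(shear_amplitudes),
                 shear_speed = shear_speed,
                 rest_duration = rest_duration,
                 frame_rate = frame_rate,
                 force_rate = force_rate,
                 sample_height = sample_height),
            class = "motion_protocol")
}

#' Build the segmented motion schedule for a protocol
#'
#' Expands a [motion_protocol()] into contiguous, non-overlapping segments
#' `(axis, phase, t_start, t_end, velocity_mm_s)`. Compression starts at
#' t = 0; every motion is followed by a rest, except that the schedule
#' ends when the last stroke ends (for the default protocol the segment
#' boundaries are 0, 6, 7.5, 9.5, 11, 15, 16.5, 20.5, 22, 26 s). Shear
#' directions alternate sign starting positive, so the default strokes
#' visit +5, -5, +5, -5 mm.
#'
#' @param protocol a [motion_protocol()]
#' @return an object of class `motion_schedule` with elements `segments`
#'   (data frame) and `total_duration`
#' @export
build_schedule <- function(protocol) {
  if (!inherits(protocol, "motion_protocol")) .st_stop("protocol must be a motion_protocol")
  seg <- list()
  t <- 0
  add <- function(axis, phase, dur, vel) {
    seg[[length(seg) + 1]] <<- data.frame(axis = axis, phase = phase,
                                          t_start = t, t_end = t + dur,
                                          velocity_mm_s = vel,
                                          stringsAsFactors = FALSE)
    t <<- t + dur
  }
  if (protocol$compression_amplitude > 0)
    add("vertical", "compression",
        protocol$compression_amplitude / protocol$compression_speed,
        protocol$compression_speed)
  amps <- protocol$shear_amplitudes[protocol$shear_amplitudes > 0]
  sign <- 1
  for (a in amps) {
    if (protocol$rest_duration > 0) add("vertical", "rest", protocol$rest_duration, 0)
    add("horizontal", "shear", a / protocol$shear_speed, sign * protocol$shear_speed)
    sign <- -sign
  }
  if (length(amps) == 0 && protocol$rest_duration > 0)
    add("vertical", "rest", protocol$rest_duration, 0)
  segments <- do.call(rbind, seg)
  rownames(segments) <- NULL
  structure(list(segments = segments, total_duration = t,
                 protocol = protocol),
            class = "motion_schedule")
}

# signed displacement accumulated by each axis at the end of every segment
.st_segment_cumdisp <- function(schedule) {
  seg <- schedule$segments
  d <- seg$velocity_mm_s * (seg$t_end - seg$t_start)
  dv <- cumsum(ifelse(seg$axis == "vertical" & seg$phase != "rest", d, 0))
  dh <- cumsum(ifelse(seg$axis == "horizontal", d, 0))
  list(vertical = dv, horizontal = dh)
}

# analytic stage positions at arbitrary times; t beyond the schedule is
# clamped to the final position (the stages simply stop)
.st_stage_positions <- function(schedule, t) {
  seg <- schedule$segments
  n <- nrow(seg)
  v <- numeric(length(t)); h <- numeric(length(t))
  if (n == 0) return(list(vertical = v, horizontal = h))
  cum <- .st_segment_cumdisp(schedule)
  v0 <- c(0, cum$vertical[-n]); h0 <- c(0, cum$horizontal[-n])
  tc <- pmin(pmax(t, 0), schedule$total_duration)
  idx <- findInterval(tc, seg$t_start, rightmost.closed = FALSE)
  idx[idx < 1] <- 1; idx[idx > n] <- n
  dt <- tc - seg$t_start[idx]
  vel <- seg$velocity_mm_s[idx]
  vert <- seg$axis[idx] == "vertical"
  v <- v0[idx] + ifelse(vert, vel * dt, 0)
  h <- h0[idx] + ifelse(!vert, vel * dt, 0)
  list(vertical = v, horizontal = h)
}

#' Sample stage trajectories at a uniform rate
#'
#' @param schedule a [build_schedule()] result
#' @param rate sampling rate, Hz
#' @return data frame with columns `time_s`, `vertical_mm`,
#'   `horizontal_mm`, `phase` (one row per sample, including t = 0 and the
#'   final instant)
#' @export
sample_trajectory <- function(schedule, rate) {
  if (!inherits(schedule, "motion_schedule")) .st_stop("schedule must be a motion_schedule")
  if (rate <= 0) .st_stop("rate must be > 0")
  n <- floor(schedule$total_duration * rate + 1e-9)
  t <- seq(0, n) / rate
  pos <- .st_stage_positions(schedule, t)
  phase <- if (nrow(schedule$segments) > 0)
    vapply(t, function(tt) phase_at(schedule, tt)$phase, character(1))
  else rep("rest", length(t))
  data.frame(time_s = t, vertical_mm = pos$vertical,
             horizontal_mm = pos$horizontal, phase = phase,
             stringsAsFactors = FALSE)
}

#' Engineering strain of the compressed sample
#'
#' @param displacement imposed displacement, mm (>= 0)
#' @param initial_height initial sample height, mm (> 0)
#' @return dimensionless strain fraction (0.75 for 15 mm on 20 mm)
#' @export
engineering_strain <- function(displacement, initial_height) {
  if (any(initial_height <= 0)) .st_stop("initial_height must be > 0")
  if (any(displacement < 0)) .st_stop("displacement must be >= 0")
  displacement / initial_height
}

#' Construct a force trace
#'
#' @param time sample times, s (uniform)
#' @param normal_force normal force, N
#' @param tangential_force tangential force, N
#' @param rate sampling rate, Hz
#' @return object of class `force_trace`
#' @export
force_trace <- function(time, normal_force, tangential_force = NULL, rate) {
  if (length(time) == 0) .st_stop("empty force trace")
  if (is.null(tangential_force)) tangential_force <- numeric(length(time))
  stopifnot(length(normal_force) == length(time),
            length(tangential_force) == length(time))
  structure(list(time = time, normal_force = normal_force,
                 tangential_force = tangential_force, rate = rate),
            class = "force_trace")
}

#' Align a high-rate force trace to video frames
#'
#' Each frame k (timestamped k / frame_rate) receives the mean of the
#' force samples falling in the right-open interval
#' `[k/frame_rate, (k+1)/frame_rate)`.
#'
#' @param trace a [force_trace()]
#' @param frame_rate video frame rate, Hz (must not exceed the trace rate)
#' @return data frame `time_s`, `normal_force`, `tangential_force`, one
#'   row per frame interval covered by the trace
#' @export
resample_force_to_frames <- function(trace, frame_rate) {
  if (!inherits(trace, "force_trace")) .st_stop("trace must be a force_trace")
  if (length(trace$time) == 0) .st_stop("empty force trace")
  if (trace$rate < frame_rate) .st_stop("trace rate must be >= frame rate")
  frame_idx <- floor(trace$time * frame_rate + 1e-9)
  nfr <- max(frame_idx) + 1
  agg_n <- tapply(trace$normal_force, frame_idx, mean)
  agg_t <- tapply(trace$tangential_force, frame_idx, mean)
  k <- as.integer(names(agg_n))
  out <- data.frame(time_s = k / frame_rate,
                    normal_force = as.numeric(agg_n),
                    tangential_force = as.numeric(agg_t))
  out[order(out$time_s), , drop = FALSE]
}

#' Phase lookup at an instant
#'
#' Segments are right-open: an instant falling exactly on a boundary
#' belongs to the later segment. The final instant belongs to the last
#' segment.
#'
#' @param schedule a [build_schedule()] result
#' @param t time, s, within `[0, total_duration]`
#' @return list with `phase`, `axis`, `segment` (row index),
#'   `t_start`, `t_end`, `velocity_mm_s`, `stroke` (shear stroke index or
#'   NA)
#' @export
phase_at <- function(schedule, t) {
  if (!inherits(schedule, "motion_schedule")) .st_stop("schedule must be a motion_schedule")
  if (length(t) != 1 || !is.finite(t)) .st_stop("t must be a single finite time")
  if (t < 0 || t > schedule$total_duration) .st_stop("t = %g outside schedule [0, %g]", t, schedule$total_duration)
  seg <- schedule$segments
  i <- findInterval(t, seg$t_start, rightmost.closed = FALSE)
  if (i > nrow(seg)) i <- nrow(seg)
  strokes <- cumsum(seg$phase == "shear")
  list(phase = seg$phase[i], axis = seg$axis[i], segment = i,
       t_start = seg$t_start[i], t_end = seg$t_end[i],
       velocity_mm_s = seg$velocity_mm_s[i],
       stroke = if (seg$phase[i] == "shear") strokes[i] else NA_integer_)
}

#' Shear strokes of a schedule
#'
#' @param schedule a [build_schedule()] result
#' @return data frame of the shear segments with a `stroke` index column
#' @export
shear_strokes <- function(schedule) {
  seg <- schedule$segments
  s <- seg[seg$phase == "shear", , drop = FALSE]
  if (nrow(s)) s$stroke <- seq_len(nrow(s))
  s
}

#' Write a sampled trajectory to CSV
#'
#' @param trajectory result of [sample_trajectory()]
#' @param path output file
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}
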