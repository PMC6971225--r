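#' Trapezoidal indentation profile
#'
#' The canonical stimulus of the tactile experiments: force ramps linearly
#' from zero to `amplitude` over `rise`, holds for `hold`, and ramps back to
#' zero over `fall`. All times are in ms, force in mN (treated as the
#' dimensionless digitized sensor signal downstream).
#'
#' @param t_on Onset time of the rising ramp (ms).
#' @param rise,hold,fall Phase durations (ms), each `>= 0`.
#' @param amplitude Plateau force (mN), `>= 0`.
#' @return A `trapezoid_spec` object.
#' @examples
#' trapezoid_spec(t_on = 4000, rise = 2000, hold = 3500, fall = 1000, amplitude = 10)
#' @export
trapezoid_spec <- function(t_on = 0, rise, hold, fall, amplitude) {
  vals <- c(t_on = t_on, rise = rise, hold = hold, fall = fall, amplitude = amplitude)
  if (anyNA(vals) || !all(is.finite(vals)) || any(vals < 0)) {
    abort("all trapezoid fields must be finite and non-negative")
  }
  structure(as.list(vals), class = "trapezoid_spec")
}

trapezoid_end <- function(spec) spec$t_on + spec$rise + spec$hold + spec$fall

#' Sample a trapezoid onto a uniform force grid
#'
#' Piecewise-linear interpolation, exact on grid points (no smoothing).
#'
#' @param spec A [trapezoid_spec()], or a list of them (summed; used for
#'   multi-episode channels).
#' @param h Sampling step (ms).
#' @param duration Total profile duration (ms); the trapezoid must fit inside.
#' @return A `force_profile`: tibble with `time_ms` and `force`, carrying
#'   `h` as an attribute.
#' @examples
#' trapezoid(trapezoid_spec(5, 10, 70, 10, 14), duration = 100)
#' @export
trapezoid <- function(spec, h = 0.0078125, duration) {
  specs <- if (inherits(spec, "trapezoid_spec")) list(spec) else spec
  stopifnot(all(vapply(specs, inherits, TRUE, "trapezoid_spec")))
  ends <- vapply(specs, trapezoid_end, 1)
  if (any(ends > duration + 1e-9)) abort("trapezoid exceeds profile duration")
  n <- as.integer(round(duration / h))
  t <- seq_len(n) * h
  f <- numeric(n)
  for (sp in specs) f <- f + trap_values(sp, t)
  new_force_profile(t, f, h)
}

# exact piecewise-linear evaluation (no smoothing); zero-width ramps give a
# rectangular pulse with the plateau closed on both ends
trap_values <- function(sp, t) {
  f <- numeric(length(t))
  r1 <- sp$t_on; r2 <- r1 + sp$rise
  p2 <- r2 + sp$hold; e <- p2 + sp$fall
  if (sp$rise > 0) {
    i <- t >= r1 & t < r2
    f[i] <- sp$amplitude * (t[i] - r1) / sp$rise
  }
  i <- t >= r2 & t <= p2
  f[i] <- sp$amplitude
  if (sp$fall > 0) {
    i <- t > p2 & t < e
    f[i] <- sp$amplitude * (e - t[i]) / sp$fall
  }
  f
}

new_force_profile <- function(t, f, h) {
  out <- tibble(time_ms = t, force = f)
  attr(out, "h") <- h
  class(out) <- c("force_profile", class(out))
  out
}

profile_h <- function(profile) {
  h <- attr(profile, "h")
  if (is.null(h)) {
    dt <- diff(profile$time_ms)
    if (length(dt) && max(abs(dt - dt[[1]])) > 1e-9) abort("profile is not uniformly sampled")
    h <- if (length(dt)) dt[[1]] else stop("empty profile")
  }
  h
}

#' The frozen reference trapezoid of the 100-ms characterization runs
#'
#' The model-characterization figures show a 100-ms simulation driven by a
#' trapezoidal input whose exact shape is only graphical. This package
#' freezes the shape once: onset at 5 ms, 10 ms rise, 70 ms hold, 10 ms
#' fall. The amplitude is the quantity fixed by [calibrate_amplitude()].
#'
#' @param amplitude Plateau amplitude.
#' @param h Sampling step (ms).
#' @param duration Window length (ms).
#' @return A `force_profile`.
#' @export
reference_trapezoid <- function(amplitude, h = 0.0078125, duration = 100) {
  trapezoid(trapezoid_spec(5, 10, 70, 10, amplitude), h = h, duration = duration)
}

#' Multi-sensor grid touch scenario
#'
#' Composes per-sensor force channels for a sensor grid from a list of touch
#' episodes. Each episode touches a set of sensors with (possibly
#' randomized) trapezoids; untouched sensors stay at zero. Episodes on the
#' same sensor must not overlap in time.
#'
#' @param pattern A list of episodes. Each episode is a list with `sensors`
#'   (integer vector) and either `spec` (a [trapezoid_spec()] applied to all
#'   of them) or `t_on` plus randomization bounds (`rise`, `hold`, `fall`,
#'   `amplitude` as length-2 ranges) drawn per sensor.
#' @param n_sensors Number of sensors in the grid (row-major order).
#' @param duration Scenario duration (ms).
#' @param h Sampling step (ms).
#' @param seed Seed for the randomized episode parameters.
#' @return A `stimulus_scenario`: list with an `episodes` tibble
#'   (`sensor`, `t_on`, `rise`, `hold`, `fall`, `amplitude`), `n_sensors`,
#'   `duration`, `h`.
#' @examples
#' sc <- grid_scenario(demo_grid_pattern(), duration = 60e3, seed = 1)
#' sc$episodes
#' @export
grid_scenario <- function(pattern, n_sensors = 9, duration, h = 0.0078125,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (ep in pattern) {
    sensors <- as.integer(ep$sensors)
    if (any(sensors < 1 | sensors > n_sensors)) abort("episode touches a sensor outside the grid")
    for (s in sensors) {
      if (!is.null(ep$spec)) {
        sp <- ep$spec
      } else {
        draw <- function(x) if (length(x) == 2) runif(1, x[[1]], x[[2]]) else x[[1]]
        sp <- trapezoid_spec(ep$t_on, draw(ep$rise), draw(ep$hold),
                             draw(ep$fall), draw(ep$amplitude))
      }
      if (trapezoid_end(sp) > duration) abort("episode exceeds scenario duration")
      rows[[length(rows) + 1]] <- tibble(
        sensor = s, t_on = sp$t_on, rise = sp$rise, hold = sp$hold,
        fall = sp$fall, amplitude = sp$amplitude
      )
    }
  }
  episodes <- if (length(rows)) bind_rows(rows) else
    tibble(sensor = integer(), t_on = numeric(), rise = numeric(),
           hold = numeric(), fall = numeric(), amplitude = numeric())
  # reject overlapping episodes per sensor
  for (s in unique(episodes$sensor)) {
    e <- episodes[episodes$sensor == s, ]
    e <- e[order(e$t_on), ]
    ends <- e$t_on + e$rise + e$hold + e$fall
    if (nrow(e) > 1 && any(e$t_on[-1] < ends[-nrow(e)] - 1e-9)) {
      abort(sprintf("overlapping episodes on sensor %d", s))
    }
  }
  structure(list(episodes = episodes, n_sensors = as.integer(n_sensors),
                 duration = duration, h = h),
            class = "stimulus_scenario")
}

#' @rdname grid_scenario
#' @param scenario A `stimulus_scenario`.
#' @return `scenario_profiles()` returns a list of one `force_profile` per
#'   sensor.
#' @export
scenario_profiles <- function(scenario) {
  stopifnot(inherits(scenario, "stimulus_scenario"))
  lapply(seq_len(scenario$n_sensors), function(s) {
    e <- scenario$episodes[scenario$episodes$sensor == s, ]
    if (!nrow(e)) {
      n <- as.integer(round(scenario$duration / scenario$h))
      return(new_force_profile(seq_len(n) * scenario$h, numeric(n), scenario$h))
    }
    specs <- lapply(seq_len(nrow(e)), function(i) {
      trapezoid_spec(e$t_on[[i]], e$rise[[i]], e$hold[[i]], e$fall[[i]], e$amplitude[[i]])
    })
    trapezoid(specs, h = scenario$h, duration = scenario$duration)
  })
}

#' @rdname grid_scenario
#' @return `demo_grid_pattern()` returns the eight-stage demo touch sequence
#'   over the 3x3 grid: single, paired, and triple touches with randomized
#'   timing and onset/offset velocities, the first touching S1 with the
#'   published timing (force rising 4-6 s, held to 9.5 s, released by 10.5 s).
#' @export
demo_grid_pattern <- function() {
  s <- function(x) x * 1000 # seconds to ms
  list(
    list(sensors = 1, spec = trapezoid_spec(s(4), s(2), s(3.5), s(1), 10)),
    list(sensors = c(3, 5), t_on = s(14), rise = s(3), hold = s(2), fall = s(1),
         amplitude = c(6, 14)),
    list(sensors = 2, t_on = s(22), rise = c(s(0.5), s(2)), hold = c(s(1), s(3)),
         fall = c(s(0.5), s(2)), amplitude = c(4, 14)),
    list(sensors = c(4, 6, 8), t_on = s(28), rise = c(s(0.5), s(2)),
         hold = c(s(1), s(3)), fall = c(s(0.5), s(2)), amplitude = c(4, 14)),
    list(sensors = 6, t_on = s(35), rise = c(s(0.5), s(2)), hold = c(s(1), s(3)),
         fall = c(s(0.5), s(2)), amplitude = c(4, 14)),
    list(sensors = c(2, 8), t_on = s(41), rise = c(s(0.5), s(2)), hold = c(s(1), s(3)),
         fall = c(s(0.5), s(2)), amplitude = c(4, 14)),
    list(sensors = 4, t_on = s(47), rise = c(s(0.5), s(2)), hold = c(s(1), s(3)),
         fall = c(s(0.5), s(2)), amplitude = c(4, 14)),
    list(sensors = c(8, 9), t_on = s(53), rise = c(s(0.5), s(2)), hold = c(s(1), s(3)),
         fall = c(s(0.5), s(2)), amplitude = c(4, 14))
  )
}

#' Design of the glove haptic-grasp experiment
#'
#' Describes the synthetic analogue of the glove experiment: three objects of
#' increasing weight are grasped with 3, 4, or 5 fingers, 20 repetitions
#' each, giving 180 labelled 4-s trials with a fixed 3-s hold phase. Each
#' engaged finger carries one force sensor feeding a subpopulation of 10 SA-I
#' and 17 FA-I afferents (135 afferents over 5 sensors).
#'
#' The per-finger plateau force is the object force level divided equally
#' among the engaged fingers, perturbed per trial and finger by
#' multiplicative lognormal noise with coefficient of variation
#' `force_noise_cv` (default 0.1, a typical trial-to-trial grip-force
#' variability).
#'
#' @param objects Named force levels of the three objects (A < B < C).
#' @param finger_conditions Grasp conditions (numbers of engaged fingers).
#' @param repetitions Repetitions per object x condition.
#' @param trial_duration,hold_duration Trial length and hold phase (ms).
#' @param grasp_rise,grasp_fall Ramp durations within the trial (ms).
#' @param force_noise_cv Coefficient of variation of the per-finger force.
#' @param layout Population layout for the glove (defaults to 5 sensors x
#'   (10 SA + 17 FA) improved L-QIF shift-arithmetic afferents).
#' @param h Sampling step (ms).
#' @return A `haptic_design` object.
#' @examples
#' haptic_design()
#' @export
haptic_design <- function(objects = c(A = 6, B = 12, C = 18),
                          finger_conditions = c(3, 4, 5),
                          repetitions = 20,
                          trial_duration = 4000, hold_duration = 3000,
                          grasp_rise = 400, grasp_fall = 400,
                          force_noise_cv = 0.1,
                          layout = population_layout(n_sensors = 5),
                          h = 0.0078125) {
  if (is.null(names(objects)) || any(names(objects) == "")) {
    names(objects) <- LETTERS[seq_along(objects)]
  }
  if (hold_duration + grasp_rise + grasp_fall > trial_duration) {
    abort("rise + hold + fall must fit inside the trial")
  }
  if (force_noise_cv < 0) abort("`force_noise_cv` must be >= 0")
  structure(
    list(objects = objects, finger_conditions = as.integer(finger_conditions),
         repetitions = as.integer(repetitions),
         trial_duration = trial_duration, hold_duration = hold_duration,
         grasp_rise = grasp_rise, grasp_fall = grasp_fall,
         force_noise_cv = force_noise_cv, layout = layout, h = h),
    class = "haptic_design"
  )
}

#' @export
print.haptic_design <- function(x, ...) {
  cat(sprintf("<haptic_design> %d objects x {%s}-finger grasps x %d reps = %d trials\n",
              length(x$objects), paste(x$finger_conditions, collapse = ","),
              x$repetitions,
              length(x$objects) * length(x$finger_conditions) * x$repetitions))
  cat(sprintf("  trial %g ms (hold %g ms), force cv %.2f, %d afferents\n",
              x$trial_duration, x$hold_duration, x$force_noise_cv,
              x$layout$n_sensors * (x$layout$sa_per_sensor + x$layout$fa_per_sensor)))
  invisible(x)
}

#' Generate the labelled synthetic haptic trial set
#'
#' Runs the glove population over every trial of the design: the engaged
#' fingers (always starting from the thumb, sensor 1) receive trapezoids
#' whose plateau amplitude is the object force divided by the number of
#' engaged fingers, perturbed by lognormal noise; disengaged fingers stay at
#' zero. Each trial yields the spike trains of all afferents.
#'
#' @param design A [haptic_design()].
#' @param seed Integer seed; drives both the force noise and the per-afferent
#'   gain jitter.
#' @return A `trial_set`: tibble with `trial`, `object`, `fingers`, `rep`,
#'   and a `spikes` list-column (per trial, a list of spike-time vectors, one
#'   per afferent), carrying the afferent table and the design as attributes.
#' @examples
#' d <- haptic_design(repetitions = 1, trial_duration = 400, hold_duration = 300,
#'                    grasp_rise = 40, grasp_fall = 40)
#' ts <- haptic_dataset(d, seed = 1)
#' nrow(ts)
#' @export
haptic_dataset <- function(design, seed = 1) {
  stopifnot(inherits(design, "haptic_design"))
  pop <- build_population(design$layout, seed = seed)
  afferents <- as_tibble(pop)
  grid <- expand.grid(rep = seq_len(design$repetitions),
                      fingers = design$finger_conditions,
                      object = names(design$objects),
                      stringsAsFactors = FALSE)
  set.seed(seed + 1L)
  n_aff <- nrow(afferents)
  t_on <- (design$trial_duration - design$hold_duration -
           design$grasp_rise - design$grasp_fall) / 2
  spikes <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fingers <- grid$fingers[[i]]
    level <- design$objects[[grid$object[[i]]]] / fingers
    amp <- level * lognormal_cv(fingers, design$force_noise_cv)
    episodes <- lapply(seq_len(fingers), function(fi) {
      list(sensors = fi,
           spec = trapezoid_spec(t_on, design$grasp_rise, design$hold_duration,
                                 design$grasp_fall, amp[[fi]]))
    })
    scenario <- grid_scenario(episodes, n_sensors = design$layout$n_sensors,
                              duration = design$trial_duration, h = design$h)
    raster <- run_population(pop, scenario)
    spikes[[i]] <- split_spike_times(raster, n_aff)
  }
  out <- tibble(
    trial = seq_len(nrow(grid)),
    object = grid$object, fingers = as.integer(grid$fingers), rep = grid$rep,
    spikes = spikes
  )
  attr(out, "afferents") <- afferents
  attr(out, "duration") <- design$trial_duration
  attr(out, "design") <- design
  class(out) <- c("trial_set", class(out))
  out
}

# multiplicative lognormal factors with unit mean and the given cv
lognormal_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

split_spike_times <- function(raster, n_aff) {
  out <- vector("list", n_aff)
  idx <- split(raster$spike_time_ms, factor(raster$afferent_idx, levels = seq_len(n_aff)))
  for (j in seq_len(n_aff)) out[[j]] <- as.numeric(idx[[j]])
  out
}
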