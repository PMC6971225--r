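#' Layout of a population of digital afferents
#'
#' The hardware population replicates, for every force sensor, a
#' subpopulation of 10 SA-I and 17 FA-I digital afferents; the default 3x3
#' grid therefore carries 9 x 27 = 243 afferents (90 SA-I, 153 FA-I), the
#' SA/FA ratio of the human fingertip. The default unit is the improved
#' L-QIF circuit in shift-only fixed-point arithmetic.
#'
#' @param n_sensors Number of sensors (row-major grid order, S1 first).
#' @param sa_per_sensor,fa_per_sensor Afferents per sensor and type.
#' @param model Spiking model for every unit.
#' @param params A [neuron_params()]; defaults to [improved_lqif_params()]
#'   when `model = "lqif"`, else the simulation parameters.
#' @param arithmetic `"float"`, `"fixed"`, or `"shift"`.
#' @param fmt Register format for the fixed-point arithmetics.
#' @param gain_jitter_sd Lognormal sdlog of per-unit gain jitter (0 = identical
#'   units).
#' @param noise_rate Background Poisson rate per unit (Hz, default off).
#' @return A `population_layout` object.
#' @examples
#' population_layout()            # 243 afferents over the 3x3 grid
#' population_layout(n_sensors = 5)  # glove: 135 afferents
#' @export
population_layout <- function(n_sensors = 9, sa_per_sensor = 10, fa_per_sensor = 17,
                              model = "lqif", params = NULL,
                              arithmetic = c("shift", "fixed", "float"),
                              fmt = fixed_format(),
                              gain_jitter_sd = 0.05, noise_rate = 0) {
  model <- match_model(model)
  if (is.null(params)) {
    params <- if (model == "lqif") improved_lqif_params() else neuron_params(model)
  }
  if (n_sensors < 1 || sa_per_sensor < 0 || fa_per_sensor < 0 ||
      sa_per_sensor + fa_per_sensor < 1) {
    abort("layout counts must be positive")
  }
  structure(
    list(n_sensors = as.integer(n_sensors),
         sa_per_sensor = as.integer(sa_per_sensor),
         fa_per_sensor = as.integer(fa_per_sensor),
         model = model, params = params,
         arithmetic = match.arg(arithmetic), fmt = fmt,
         gain_jitter_sd = gain_jitter_sd, noise_rate = noise_rate),
    class = "population_layout"
  )
}

#' @export
print.population_layout <- function(x, ...) {
  total <- x$n_sensors * (x$sa_per_sensor + x$fa_per_sensor)
  cat(sprintf("<population_layout> %d sensors x (%d SA + %d FA) = %d afferents, %s/%s\n",
              x$n_sensors, x$sa_per_sensor, x$fa_per_sensor, total,
              x$model, x$arithmetic))
  invisible(x)
}

#' Instantiate the afferent population
#'
#' Creates one afferent per unit of the layout: per sensor, SA units first
#' and FA units after, sensors in row-major order (S1..S9 on the 3x3 grid).
#' Per-unit gain jitter is drawn up front from a single seeded stream, so the
#' population is reproducible and independent of execution order.
#'
#' @param layout A [population_layout()].
#' @param seed Integer seed for the per-unit jitter.
#' @return An `afferent_population`: tibble with `afferent_idx`,
#'   `afferent_id`, `sensor`, `type`, `gain`, carrying the layout as an
#'   attribute.
#' @examples
#' pop <- build_population(population_layout(), seed = 1)
#' table(pop$type)
#' @export
build_population <- function(layout, seed = 1) {
  stopifnot(inherits(layout, "population_layout"))
  per <- layout$sa_per_sensor + layout$fa_per_sensor
  units <- tidyr::expand_grid(
    sensor = seq_len(layout$n_sensors),
    within = seq_len(per)
  ) %>%
    mutate(
      type = ifelse(.data$within <= layout$sa_per_sensor, "SA", "FA"),
      unit = ifelse(.data$type == "SA", .data$within,
                    .data$within - layout$sa_per_sensor),
      afferent_idx = dplyr::row_number(),
      afferent_id = sprintf("S%d_%s%02d", .data$sensor, .data$type, .data$unit)
    )
  set.seed(seed)
  gains <- if (layout$gain_jitter_sd > 0) {
    rlnorm(nrow(units), meanlog = 0, sdlog = layout$gain_jitter_sd)
  } else rep(1, nrow(units))
  out <- units %>%
    mutate(gain = gains) %>%
    select("afferent_idx", "afferent_id", "sensor", "type", "gain")
  attr(out, "layout") <- layout
  attr(out, "seed") <- seed
  class(out) <- c("afferent_population", class(out))
  out
}

#' Run the population over a multi-sensor stimulus scenario
#'
#' Every afferent of sensor `s` is driven only by channel `s` of the
#' scenario. Returns the concatenated spike raster of all units. With noise
#' enabled, each unit consumes an independent counter-based seed
#' (`seed + afferent_idx`), so results do not depend on scheduling order.
#'
#' @param population An `afferent_population` from [build_population()].
#' @param scenario A `stimulus_scenario` ([grid_scenario()]) supplying one
#'   force channel per sensor, or a list of `force_profile`s.
#' @param seed Base seed for background-noise streams (only used when the
#'   layout enables noise).
#' @return A `spike_raster`: tibble with `afferent_idx`, `afferent_id`,
#'   `type`, `sensor`, `spike_time_ms`, with `duration` and the population as
#'   attributes.
#' @examples
#' pop <- build_population(population_layout(n_sensors = 1, gain_jitter_sd = 0))
#' sc <- grid_scenario(list(list(sensors = 1, spec = trapezoid_spec(5, 10, 70, 10, 8))),
#'                     n_sensors = 1, duration = 100)
#' run_population(pop, sc)
#' @export
run_population <- function(population, scenario, seed = 1) {
  stopifnot(inherits(population, "afferent_population"))
  layout <- attr(population, "layout")
  if (inherits(scenario, "stimulus_scenario")) {
    if (scenario$n_sensors != layout$n_sensors) {
      abort("scenario channel count does not match the population layout")
    }
    profiles <- scenario_profiles(scenario)
    duration <- scenario$duration
    h <- scenario$h
  } else {
    profiles <- scenario
    if (length(profiles) != layout$n_sensors) {
      abort("scenario channel count does not match the population layout")
    }
    duration <- max(profiles[[1]]$time_ms)
    h <- profile_h(profiles[[1]])
  }
  forces <- lapply(profiles, function(p) {
    if (any(p$force < 0)) abort("force must be non-negative")
    p$force
  })

  rows <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    sensor <- population$sensor[[i]]
    type <- population$type[[i]]
    I <- population$gain[[i]] * forces[[sensor]]
    if (layout$noise_rate > 0) {
      set.seed(seed + population$afferent_idx[[i]])
      p_event <- layout$noise_rate * h / 1000
      ev <- which(runif(length(I)) < p_event)
      if (length(ev)) I[ev] <- I[ev] + 1
    }
    code <- MODEL_CODES[[layout$model]]
    pv <- par_vector(layout$params)
    init <- initial_state(layout$params)
    u0 <- if (is.null(init$u)) 0 else init$u
    res <- if (layout$arithmetic == "float") {
      cpp_sim_float(code, type == "FA", I, h, pv, init$v, u0, FALSE, -1L)
    } else {
      cpp_sim_fixed(code, type == "FA", I, h, pv, init$v, u0,
                    layout$fmt$int_bits, layout$fmt$frac_bits,
                    layout$arithmetic == "shift", FALSE, -1L)
    }
    st <- as.integer(res$spike_steps) * h
    if (length(st)) {
      rows[[i]] <- tibble(
        afferent_idx = population$afferent_idx[[i]],
        afferent_id = population$afferent_id[[i]],
        type = type, sensor = sensor, spike_time_ms = st
      )
    }
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(afferent_idx = integer(), afferent_id = character(),
                  type = character(), sensor = integer(),
                  spike_time_ms = numeric())
  }
  attr(out, "duration") <- duration
  attr(out, "population") <- population
  class(out) <- c("spike_raster", class(out))
  out
}

#' Per-sensor firing-rate summary of a raster
#'
#' @param raster A `spike_raster`.
#' @return Tibble with `sensor`, `type`, `n_spikes`, `rate_hz` (mean rate per
#'   afferent of that sensor and type).
#' @export
raster_rates <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  pop <- attr(raster, "population")
  duration <- attr(raster, "duration")
  counts <- raster %>%
    group_by(.data$sensor, .data$type) %>%
    summarise(n_spikes = n(), .groups = "drop")
  meta <- pop %>%
    group_by(.data$sensor, .data$type) %>%
    summarise(n_afferents = n(), .groups = "drop")
  meta %>%
    left_join(counts, by = c("sensor", "type")) %>%
    mutate(n_spikes = ifelse(is.na(.data$n_spikes), 0L, .data$n_spikes),
           rate_hz = 1000 * .data$n_spikes / (.data$n_afferents * duration))
}
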