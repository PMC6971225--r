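#' Read and write the package's CSV interchange formats
#'
#' Plain-text round-trips for the main artifacts: force profiles
#' (`time_ms,value`), spike rasters (`afferent_id,type,sensor,spike_time_ms`),
#' and trial sets (a directory with `labels.csv` and `spikes.csv`). Spike
#' times are written at full double precision (they are exact multiples of
#' the step `h`), so a write/read cycle reproduces the in-memory object
#' exactly.
#'
#' @param profile A `force_profile`.
#' @param path File (or directory, for trial sets) to write to / read from.
#' @return The read functions return the reconstructed object; the write
#'   functions return `path` invisibly.
#' @name tactspike-io
NULL

#' @rdname tactspike-io
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(time_ms = profile$time_ms, value = profile$force)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tactspike-io
#' @export
read_profile_csv <- function(path) {
  df <- read.csv(path)
  new_force_profile(df$time_ms, df$value, h = diff(df$time_ms[1:2]))
}

#' @rdname tactspike-io
#' @param raster A `spike_raster`.
#' @export
write_raster_csv <- function(raster, path) {
  df <- as.data.frame(raster[, c("afferent_id", "type", "sensor", "spike_time_ms")])
  df$spike_time_ms <- format(df$spike_time_ms, digits = 17, trim = TRUE,
                             scientific = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tactspike-io
#' @export
read_raster_csv <- function(path) {
  df <- read.csv(path, colClasses = c(spike_time_ms = "numeric"))
  as_tibble(df)
}

#' @rdname tactspike-io
#' @param trials A `trial_set`.
#' @param dir Directory for the trial-set bundle.
#' @export
write_trial_set <- function(trials, dir) {
  stopifnot(inherits(trials, "trial_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  labels <- as.data.frame(trials[, c("trial", "object", "fingers", "rep")])
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  afferents <- as.data.frame(attr(trials, "afferents"))
  write.csv(afferents, file.path(dir, "afferents.csv"), row.names = FALSE)
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    sp <- trials$spikes[[i]]
    lens <- lengths(sp)
    if (sum(lens)) {
      rows[[length(rows) + 1]] <- data.frame(
        trial = trials$trial[[i]],
        afferent_idx = rep(seq_along(sp), lens),
        spike_time_ms = format(unlist(sp), digits = 17, trim = TRUE,
                               scientific = FALSE)
      )
    }
  }
  spikes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial = integer(), afferent_idx = integer(),
               spike_time_ms = character())
  write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE, quote = FALSE)
  meta <- list(duration = attr(trials, "duration"),
               n_afferents = nrow(attr(trials, "afferents")))
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname tactspike-io
#' @export
read_trial_set <- function(dir) {
  labels <- read.csv(file.path(dir, "labels.csv"))
  afferents <- as_tibble(read.csv(file.path(dir, "afferents.csv")))
  spikes_df <- read.csv(file.path(dir, "spikes.csv"),
                        colClasses = c(spike_time_ms = "numeric"))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  n_aff <- meta$n_afferents
  spikes <- lapply(labels$trial, function(tr) {
    sub <- spikes_df[spikes_df$trial == tr, ]
    out <- split(sub$spike_time_ms,
                 factor(sub$afferent_idx, levels = seq_len(n_aff)))
    lapply(out, as.numeric)
  })
  out <- as_tibble(labels)
  out$spikes <- spikes
  attr(out, "afferents") <- afferents
  attr(out, "duration") <- meta$duration
  class(out) <- c("trial_set", class(out))
  out
}

#' Serialize run configurations to YAML
#'
#' An afferent spec, population layout, or haptic design (minus the nested
#' parameter object, which is stored as its fields) round-trips through a
#' YAML file so a run is reproducible from its saved configuration plus a
#' seed.
#'
#' @param x An `afferent_spec`, `population_layout`, or `haptic_design`.
#' @param path YAML file.
#' @return `read_config_yaml()` returns the reconstructed object.
#' @export
write_config_yaml <- function(x, path) {
  kind <- class(x)[[1]]
  payload <- unclass(x)
  flatten <- function(obj) {
    if (inherits(obj, "neuron_params") || inherits(obj, "fixed_format") ||
        inherits(obj, "population_layout")) {
      lapply(unclass(obj), flatten)
    } else obj
  }
  payload <- lapply(payload, flatten)
  yaml::write_yaml(list(kind = kind, config = payload), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  cfg <- doc$config
  rebuild_params <- function(p) {
    do.call(neuron_params, c(list(model = p$model),
                             p[setdiff(names(p), "model")]))
  }
  rebuild_fmt <- function(f) fixed_format(f$total_bits, f$int_bits, f$frac_bits)
  switch(doc$kind,
    afferent_spec = afferent_spec(
      cfg$afferent_type, cfg$model, params = rebuild_params(cfg$params),
      arithmetic = cfg$arithmetic, fmt = rebuild_fmt(cfg$fmt),
      gain_jitter = cfg$gain_jitter, noise_rate = cfg$noise_rate,
      adc = cfg$adc, adc_full_scale = cfg$adc_full_scale
    ),
    population_layout = population_layout(
      cfg$n_sensors, cfg$sa_per_sensor, cfg$fa_per_sensor, cfg$model,
      params = rebuild_params(cfg$params), arithmetic = cfg$arithmetic,
      fmt = rebuild_fmt(cfg$fmt), gain_jitter_sd = cfg$gain_jitter_sd,
      noise_rate = cfg$noise_rate
    ),
    haptic_design = haptic_design(
      objects = unlist(cfg$objects), finger_conditions = unlist(cfg$finger_conditions),
      repetitions = cfg$repetitions, trial_duration = cfg$trial_duration,
      hold_duration = cfg$hold_duration, grasp_rise = cfg$grasp_rise,
      grasp_fall = cfg$grasp_fall, force_noise_cv = cfg$force_noise_cv,
      layout = population_layout(
        cfg$layout$n_sensors, cfg$layout$sa_per_sensor, cfg$layout$fa_per_sensor,
        cfg$layout$model, params = rebuild_params(cfg$layout$params),
        arithmetic = cfg$layout$arithmetic,
        fmt = rebuild_fmt(cfg$layout$fmt),
        gain_jitter_sd = cfg$layout$gain_jitter_sd,
        noise_rate = cfg$layout$noise_rate
      ),
      h = cfg$h
    ),
    abort(sprintf("unknown config kind: %s", doc$kind))
  )
}
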