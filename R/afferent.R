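#' Specification of one artificial tactile afferent
#'
#' Wires a force channel to a spiking model: the sensed force becomes the
#' input current (optionally through a 10-bit ADC), which drives one of the
#' four spiking models in floating-point or fixed-point arithmetic.
#'
#' @param afferent_type `"SA"` or `"FA"`.
#' @param model One of `"izh"`, `"lizh"`, `"qif"`, `"lqif"`.
#' @param params A [neuron_params()] object; defaults to the named model's
#'   simulation parameters (use [improved_lqif_params()] for the shift
#'   circuit).
#' @param arithmetic `"float"`, `"fixed"`, or `"shift"`.
#' @param fmt Register format for the fixed-point arithmetics.
#' @param gain_jitter Multiplicative gain applied to the force (models
#'   unit-to-unit transduction variability), `> 0`.
#' @param noise_rate Background Poisson event rate (Hz); each event injects a
#'   unit current pulse for one sample. Default 0 (off).
#' @param adc Quantize the force through a 10-bit ADC first.
#' @param adc_full_scale Full-scale force of the ADC (mN).
#' @return An `afferent_spec` object.
#' @examples
#' afferent_spec("SA", "lqif", params = improved_lqif_params(), arithmetic = "shift")
#' @export
afferent_spec <- function(afferent_type, model = "lqif",
                          params = NULL,
                          arithmetic = c("float", "fixed", "shift"),
                          fmt = fixed_format(),
                          gain_jitter = 1, noise_rate = 0,
                          adc = FALSE, adc_full_scale = 100) {
  model <- match_model(model)
  if (is.null(params)) params <- neuron_params(model)
  if (params$model != model) abort("`params$model` does not match `model`")
  if (gain_jitter <= 0) abort("`gain_jitter` must be > 0")
  if (noise_rate < 0) abort("`noise_rate` must be >= 0")
  structure(
    list(afferent_type = match_afferent(afferent_type), model = model,
         params = params, arithmetic = match.arg(arithmetic), fmt = fmt,
         gain_jitter = gain_jitter, noise_rate = noise_rate,
         adc = adc, adc_full_scale = adc_full_scale),
    class = "afferent_spec"
  )
}

#' Map a force profile to the afferent input current
#'
#' `I[n] = gain_jitter * f[n]`; the model's C weights are applied inside the
#' spiking equations, not here. With the ADC enabled, the force is first
#' quantized to one of 1024 levels over the full-scale range (level
#' `round(1023 f / full_scale)`, saturating at 1023) and mapped back to force
#' units, so the current keeps ADC granularity.
#'
#' @param profile A `force_profile` (see [trapezoid()]), or any data frame
#'   with `time_ms` and `force` columns; force must be `>= 0`.
#' @param spec An [afferent_spec()].
#' @return The profile tibble with a `current` column appended.
#' @examples
#' pr <- trapezoid(trapezoid_spec(5, 10, 70, 10, 14), duration = 100)
#' force_to_current(pr, afferent_spec("SA"))
#' @export
force_to_current <- function(profile, spec) {
  stopifnot(is.data.frame(profile))
  f <- profile$force
  if (any(f < 0)) abort("force must be non-negative")
  if (isTRUE(spec$adc)) {
    f <- adc_levels(f, spec$adc_full_scale) * spec$adc_full_scale / 1023
  }
  mutate(profile, current = spec$gain_jitter * f)
}

#' @rdname force_to_current
#' @param force Numeric force vector.
#' @param full_scale Full-scale force of the converter.
#' @return `adc_levels()` returns integer levels in 0..1023.
#' @export
adc_levels <- function(force, full_scale) {
  pmin(pmax(round(1023 * force / full_scale), 0), 1023)
}

#' Run a single artificial afferent over a force profile
#'
#' Converts force to current (via [force_to_current()]), optionally injects
#' Poisson-timed unit current pulses as background activity, and delegates to
#' the floating-point or fixed-point engine of [simulate_trace()].
#'
#' @param profile A `force_profile`.
#' @param spec An [afferent_spec()].
#' @param seed Integer seed; required when `noise_rate > 0`.
#' @param return_trace Keep the voltage trace.
#' @return An `afferent_trace` (see [simulate_trace()]).
#' @examples
#' pr <- trapezoid(trapezoid_spec(5, 10, 70, 10, 14), duration = 100)
#' run_afferent(pr, afferent_spec("SA", "izh"))
#' @export
run_afferent <- function(profile, spec, seed = NULL, return_trace = TRUE) {
  stopifnot(inherits(spec, "afferent_spec"))
  h <- profile_h(profile)
  I <- force_to_current(profile, spec)$current
  if (spec$noise_rate > 0) {
    if (is.null(seed)) abort("a `seed` is required when `noise_rate` > 0")
    set.seed(seed)
    p_event <- spec$noise_rate * h / 1000
    events <- which(runif(length(I)) < p_event)
    if (length(events)) I[events] <- I[events] + 1
  }
  cfg <- sim_config(duration = length(I) * h, h = h,
                    afferent_type = spec$afferent_type, model = spec$model)
  simulate_trace(cfg, spec$params, I, arithmetic = spec$arithmetic,
                 fmt = spec$fmt, return_trace = return_trace)
}
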