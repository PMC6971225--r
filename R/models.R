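#' Advance one afferent spiking model by a single Euler step
#'
#' These are the floating-point reference updates of the four discrete
#' models. Each takes the current state, the current input sample `I_now`
#' (and the next sample `I_next`, consumed only by FA-I afferents through the
#' difference term added outside the Euler bracket), and returns the next
#' state with the reset rule applied.
#'
#' The update rules are, with all weights from [neuron_params()]:
#' \describe{
#'   \item{Izh}{`v' = v + h (0.04 v^2 + 5 v + 140 - u + C_sa I)`,
#'     `u' = u + h a (b v - u)`; on `v' >= 30` mV: `v' <- c`, `u' <- u + d`.}
#'   \item{L-Izh}{quadratic term replaced by `k1 |v + 62.5| - k2`; same reset.}
#'   \item{QIF}{`v' = v + h (M1 v^2 + C_sa I)`; on `v' >= v_peak`: `v' <- v_reset`.}
#'   \item{L-QIF}{`v' = v + h (M2 |v| + C_sa I)`; same reset as QIF.}
#' }
#' For FA-I afferents the input instead enters as `C_fa (I_next - I_now)`
#' added after the `h`-multiplied bracket, so a constant input contributes
#' nothing.
#'
#' @param state Named list with membrane potential `v` (mV) and, for the
#'   Izhikevich-family models, recovery variable `u` (mV).
#' @param I_now,I_next Current input samples (digitized force signal).
#'   `I_next` defaults to `I_now`.
#' @param params A [neuron_params()] object for the matching model.
#' @param h Time step (ms), `> 0`.
#' @param afferent_type `"SA"` or `"FA"`.
#'
#' @return A named list: `v`, (`u`,) and logical `spiked` for the step taken.
#'
#' @examples
#' p <- neuron_params("izh")
#' step_izh(list(v = -65, u = -13), I_now = 0, params = p)
#' @export
step_izh <- function(state, I_now, I_next = I_now, params = neuron_params("izh"),
                     h = 0.0078125, afferent_type = "SA") {
  check_step_inputs(state, I_now, I_next, h, need_u = TRUE)
  fa <- match_afferent(afferent_type) == "FA"
  v <- state$v; u <- state$u
  acc <- 0.04 * (v * v) + 5 * v + 140 - u
  if (!fa) acc <- acc + params$C_in_sa * I_now
  vn <- v + h * acc
  if (fa) vn <- vn + params$C_in_fa * (I_next - I_now)
  un <- u + h * (params$a * ((params$b * v) - u))
  apply_reset_2var(vn, un, u, params)
}

#' @rdname step_izh
#' @export
step_lizh <- function(state, I_now, I_next = I_now, params = neuron_params("lizh"),
                      h = 0.0078125, afferent_type = "SA") {
  check_step_inputs(state, I_now, I_next, h, need_u = TRUE)
  fa <- match_afferent(afferent_type) == "FA"
  v <- state$v; u <- state$u
  acc <- params$k1 * abs(v + 62.5) - params$k2 - u
  if (!fa) acc <- acc + params$C_in_sa * I_now
  vn <- v + h * acc
  if (fa) vn <- vn + params$C_in_fa * (I_next - I_now)
  un <- u + h * (params$a * ((params$b * v) - u))
  apply_reset_2var(vn, un, u, params)
}

#' @rdname step_izh
#' @export
step_qif <- function(state, I_now, I_next = I_now, params = neuron_params("qif"),
                     h = 0.0078125, afferent_type = "SA") {
  check_step_inputs(state, I_now, I_next, h, need_u = FALSE)
  fa <- match_afferent(afferent_type) == "FA"
  v <- state$v
  acc <- params$M1 * (v * v)
  if (!fa) acc <- acc + params$C_in_sa * I_now
  vn <- v + h * acc
  if (fa) vn <- vn + params$C_in_fa * (I_next - I_now)
  apply_reset_1var(vn, params)
}

#' @rdname step_izh
#' @export
step_lqif <- function(state, I_now, I_next = I_now, params = neuron_params("lqif"),
                      h = 0.0078125, afferent_type = "SA") {
  check_step_inputs(state, I_now, I_next, h, need_u = FALSE)
  fa <- match_afferent(afferent_type) == "FA"
  v <- state$v
  acc <- params$M2 * abs(v)
  if (!fa) acc <- acc + params$C_in_sa * I_now
  vn <- v + h * acc
  if (fa) vn <- vn + params$C_in_fa * (I_next - I_now)
  apply_reset_1var(vn, params)
}

check_step_inputs <- function(state, I_now, I_next, h, need_u) {
  if (!is.list(state) || is.null(state$v) || !is.finite(state$v)) {
    abort("`state` must contain a finite membrane potential `v`")
  }
  if (need_u && (is.null(state$u) || !is.finite(state$u))) {
    abort("this model needs a finite recovery variable `u` in `state`")
  }
  if (!is.finite(I_now) || !is.finite(I_next)) abort("inputs must be finite")
  if (!is.numeric(h) || h <= 0) abort("`h` must be positive")
  invisible(TRUE)
}

# reset per the Izhikevich-family rule: u[n+1] <- u[n] + d (the pre-step u)
apply_reset_2var <- function(vn, un, u_prev, params) {
  if (vn >= 30) {
    list(v = params$c, u = u_prev + params$d, spiked = TRUE)
  } else {
    list(v = vn, u = un, spiked = FALSE)
  }
}

apply_reset_1var <- function(vn, params) {
  if (vn >= params$v_peak) {
    list(v = params$v_reset, spiked = TRUE)
  } else {
    list(v = vn, spiked = FALSE)
  }
}

step_fun <- function(model) {
  switch(model, izh = step_izh, lizh = step_lizh, qif = step_qif, lqif = step_lqif)
}

#' Simulate a full voltage trace for one afferent model
#'
#' Runs the Euler-discretized model over a uniformly sampled current series
#' and returns the voltage trace together with the spike times. FA-I
#' afferents consume the input one sample ahead through the difference term;
#' the final step reuses the last sample (zero difference). At spike steps the
#' stored trace value is `v_peak` (the plotted spike tip); the carried state
#' is the post-reset value.
#'
#' @param config A [sim_config()].
#' @param params A [neuron_params()] object; defaults to the model named in
#'   `config`.
#' @param current Numeric vector of input samples, length `duration / h`.
#' @param v0,u0 Optional initial conditions; default to the model's
#'   resting/reset point (`v = c`, `u = b c` for Izh/L-Izh; `v = v_reset`
#'   for QIF/L-QIF).
#' @param arithmetic `"float"` (reference), `"fixed"` (Q-format registers), or
#'   `"shift"` (fixed point with shift-only multiplies; improved L-QIF).
#' @param fmt A [fixed_format()] used when `arithmetic != "float"`.
#' @param return_trace Keep the full voltage trace (set `FALSE` for long
#'   population runs where only spike times are needed).
#'
#' @return An object of class `afferent_trace`: a list with `trace`
#'   (tibble `time_ms`, `v`), `spike_times` (ms), `spike_steps`, the final
#'   state, `overflow_events` (fixed point only), plus the config used.
#'
#' @examples
#' cfg <- sim_config(20, model = "lqif")
#' tr <- simulate_trace(cfg, current = rep(2, cfg$n_steps))
#' glance(tr)
#' @export
simulate_trace <- function(config, params = neuron_params(config$model), current,
                           v0 = NULL, u0 = NULL,
                           arithmetic = c("float", "fixed", "shift"),
                           fmt = fixed_format(), return_trace = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  arithmetic <- match.arg(arithmetic)
  if (params$model != config$model) {
    abort("`params$model` does not match `config$model`")
  }
  if (length(current) != config$n_steps) {
    abort(sprintf("`current` must have length duration/h = %d (got %d)",
                  config$n_steps, length(current)))
  }
  if (anyNA(current) || !all(is.finite(current))) abort("`current` must be finite")
  init <- initial_state(params)
  if (is.null(v0)) v0 <- init$v
  if (is.null(u0)) u0 <- if (is.null(init$u)) 0 else init$u
  fa <- config$afferent_type == "FA"
  code <- MODEL_CODES[[config$model]]
  pv <- par_vector(params)

  if (arithmetic == "float") {
    res <- cpp_sim_float(code, fa, as.numeric(current), config$h, pv,
                         v0, u0, return_trace, -1L)
    ovf <- 0
  } else {
    res <- cpp_sim_fixed(code, fa, as.numeric(current), config$h, pv,
                         v0, u0, fmt$int_bits, fmt$frac_bits,
                         arithmetic == "shift", return_trace, -1L)
    ovf <- res$overflow_events
  }
  steps <- as.integer(res$spike_steps)
  new_afferent_trace(
    trace = if (return_trace) {
      tibble(time_ms = seq_len(config$n_steps) * config$h, v = res$v)
    } else NULL,
    spike_times = steps * config$h,
    spike_steps = steps,
    v_end = res$v_end, u_end = res$u_end,
    overflow_events = ovf,
    config = config, params = params, arithmetic = arithmetic
  )
}

new_afferent_trace <- function(...) {
  structure(list(...), class = "afferent_trace")
}

#' @export
print.afferent_trace <- function(x, ...) {
  cat(sprintf("<afferent_trace> %s %s-I, %s arithmetic: %d spikes in %g ms (%.0f Hz)\n",
              x$params$model, x$config$afferent_type, x$arithmetic,
              length(x$spike_times), x$config$duration,
              1000 * length(x$spike_times) / x$config$duration))
  invisible(x)
}

#' @rdname simulate_trace
#' @param x An `afferent_trace`.
#' @export
tidy.afferent_trace <- function(x, ...) {
  if (is.null(x$trace)) abort("trace was not retained (return_trace = FALSE)")
  mutate(x$trace, spike = .data$time_ms %in% x$spike_times)
}

#' @rdname simulate_trace
#' @export
glance.afferent_trace <- function(x, ...) {
  tibble(
    model = x$params$model,
    afferent_type = x$config$afferent_type,
    arithmetic = x$arithmetic,
    n_spikes = length(x$spike_times),
    duration_ms = x$config$duration,
    rate_hz = 1000 * length(x$spike_times) / x$config$duration,
    overflow_events = x$overflow_events
  )
}
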