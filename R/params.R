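#' Spiking-model parameters for the tactile afferent models
#'
#' Returns the full parameter set shared by the four afferent spiking models
#' (Izhikevich, linearized Izhikevich, quadratic integrate-and-fire, and
#' linearized QIF), at the simulation defaults. The input-weight pair
#' (`C_in_sa`, `C_in_fa`) is selected per model: the SA-I weight multiplies
#' the force-derived current inside the Euler bracket, while the FA-I weight
#' multiplies the one-sample current difference added outside it.
#'
#' Units follow the hardware convention: voltages in mV, the time step `h` in
#' ms, and the current treated as the dimensionless digitized force signal
#' (the C weights are printed unitless).
#'
#' @param model One of `"izh"`, `"lizh"`, `"qif"`, `"lqif"`.
#' @param ... Named overrides for individual fields (e.g. `C_in_sa = 2`).
#'
#' @return An object of class `neuron_params`: a named list with fields
#'   `a`, `b`, `c`, `d`, `k1`, `k2`, `M1`, `M2`, `v_peak`, `v_reset`,
#'   `C_m`, `tau`, `C_in_sa`, `C_in_fa`, and `model`.
#'
#' @examples
#' neuron_params("izh")
#' neuron_params("lqif", C_in_sa = 0.5)
#' @export
neuron_params <- function(model = c("izh", "lizh", "qif", "lqif"), ...) {
  model <- match_model(match.arg(model))
  c_in <- switch(model,
    izh  = c(20, 960),
    lizh = c(24, 960),
    qif  = c(0.015625, 0.5),
    lqif = c(1, 40)
  )
  p <- list(
    a = 0.02, b = 0.2, c = -65, d = 8,
    k1 = 0.75, k2 = 20,
    M1 = 1, M2 = 0.0625,
    v_peak = 30, v_reset = 0,
    C_m = 1, tau = 1,
    C_in_sa = c_in[[1]], C_in_fa = c_in[[2]],
    model = model
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  p[names(dots)] <- dots
  validate_neuron_params(structure(p, class = "neuron_params"))
}

#' Improved L-QIF parameters (all coefficients powers of two)
#'
#' The shift-only variant of the L-QIF circuit replaces every multiplier by a
#' logical shifter, which requires each coefficient to be `+/- 2^k`. These are
#' the tuned circuit values (`M2 = 0.25`, `C41 = 0.5`, `C42 = 16`), distinct
#' from the simulation defaults of [neuron_params()].
#'
#' @param ... Named overrides passed on to [neuron_params()].
#' @return A `neuron_params` object for the L-QIF model.
#' @examples
#' improved_lqif_params()
#' @export
improved_lqif_params <- function(...) {
  neuron_params("lqif", M2 = 0.25, C_in_sa = 0.5, C_in_fa = 16, ...)
}

validate_neuron_params <- function(p) {
  num <- p[setdiff(names(p), "model")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), TRUE))) {
    abort("all neuron parameters must be finite scalars")
  }
  if (p$v_peak <= p$v_reset) abort("`v_peak` must exceed `v_reset`")
  p
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params> model:", x$model, "\n")
  num <- unlist(x[setdiff(names(x), "model")])
  print(num)
  invisible(x)
}

# parameter vector in the fixed layout the C++ engines expect
par_vector <- function(p) {
  as.numeric(c(p$a, p$b, p$c, p$d, p$k1, p$k2, p$M1, p$M2,
               p$v_peak, p$v_reset, p$C_in_sa, p$C_in_fa))
}

#' Simulation configuration
#'
#' Bundles the discretization step, total duration, afferent type, and model
#' choice for a single-afferent simulation. The default step
#' `h = 0.0078125` ms (`2^-7`, exactly representable in Q13.18) is the one
#' used by the digital circuits.
#'
#' @param duration Total simulated time (ms); must be an integer multiple of `h`.
#' @param h Time step (ms), `> 0`.
#' @param afferent_type `"SA"` or `"FA"`.
#' @param model One of `"izh"`, `"lizh"`, `"qif"`, `"lqif"`.
#' @return A `sim_config` object.
#' @examples
#' sim_config(100)
#' @export
sim_config <- function(duration, h = 0.0078125,
                       afferent_type = c("SA", "FA"),
                       model = c("izh", "lizh", "qif", "lqif")) {
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0) {
    abort("`h` must be a positive finite scalar")
  }
  if (!is.numeric(duration) || duration <= 0) abort("`duration` must be positive")
  n <- duration / h
  if (abs(n - round(n)) > 1e-9) {
    abort("`duration` must be an integer multiple of `h`")
  }
  structure(
    list(h = h, duration = duration, n_steps = as.integer(round(n)),
         afferent_type = match_afferent(match.arg(afferent_type)),
         model = match_model(match.arg(model))),
    class = "sim_config"
  )
}

# canonical initial conditions: resting/reset values are the only
# distinguished points of each model
initial_state <- function(params) {
  if (params$model %in% c("izh", "lizh")) {
    v0 <- params$c
    list(v = v0, u = params$b * v0)
  } else {
    list(v = params$v_reset)
  }
}
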