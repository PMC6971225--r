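# shared fixture builders (everything is generated in code)

ALL_MODELS <- c("izh", "lizh", "qif", "lqif")

# short trapezoidal current for single-afferent runs (ms units)
short_trapezoid_current <- function(amplitude = 14, duration = 100,
                                    h = 0.0078125) {
  reference_trapezoid(amplitude, h = h, duration = duration)$force
}

# random plausible states per model, for state-space equivalence checks;
# the lookahead sample I1 stays close to I so that the FA jump term
# (weighted by C_fa up to 960) remains inside the 13-integer-bit range
random_states <- function(model, n, seed) {
  set.seed(seed)
  out <- if (model %in% c("izh", "lizh")) {
    list(v = runif(n, -80, 29), u = runif(n, -20, 20), I = runif(n, 0, 20))
  } else {
    list(v = runif(n, 0, 29), u = rep(0, n), I = runif(n, 0, 20))
  }
  out$I1 <- out$I + runif(n, -0.01, 0.01)
  out
}

# spike counts inside a phase window, excluding a settling margin
phase_count <- function(spike_times, from, to, settle_ms = 0) {
  sum(spike_times > from + settle_ms & spike_times <= to)
}

# a hand-built labelled trial set (no simulation): per-afferent spike counts
# are drawn around class-dependent means, then turned into sorted spike times
fake_trial_set <- function(n_per_class = 10, separation = 30, noise_sd = 2,
                           duration = 1000, seed = 1,
                           fingers = c(3L, 4L, 5L)) {
  set.seed(seed)
  afferents <- tibble::tibble(
    afferent_idx = 1:135,
    afferent_id = sprintf("S%d_%s%02d",
                          rep(1:5, each = 27),
                          rep(rep(c("SA", "FA"), c(10, 17)), 5),
                          unlist(rep(list(1:10, 1:17), 5))),
    sensor = rep(1:5, each = 27),
    type = rep(rep(c("SA", "FA"), c(10, 17)), 5)
  )
  grid <- expand.grid(rep = seq_len(n_per_class), fingers = fingers,
                      object = c("A", "B", "C"), stringsAsFactors = FALSE)
  base <- c(A = 10, B = 10 + separation, C = 10 + 2 * separation)
  spikes <- lapply(seq_len(nrow(grid)), function(i) {
    mu <- base[[grid$object[[i]]]]
    lapply(seq_len(135), function(j) {
      n <- max(0L, round(rnorm(1, mu, noise_sd)))
      sort(runif(n, 0, duration))
    })
  })
  out <- tibble::tibble(trial = seq_len(nrow(grid)), object = grid$object,
                        fingers = as.integer(grid$fingers), rep = grid$rep,
                        spikes = spikes)
  attr(out, "afferents") <- afferents
  attr(out, "duration") <- duration
  class(out) <- c("trial_set", class(out))
  out
}

# small, fast haptic design (short trials) for pipeline tests
small_haptic_design <- function(repetitions = 2, force_noise_cv = 0.1) {
  haptic_design(repetitions = repetitions, trial_duration = 400,
                hold_duration = 280, grasp_rise = 50, grasp_fall = 50,
                force_noise_cv = force_noise_cv)
}
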