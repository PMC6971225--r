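#' Signed fixed-point register format
#'
#' Describes the two's-complement Q-format used by the digital circuits:
#' 1 sign bit, `int_bits` integer bits, and `frac_bits` fractional bits
#' (default Q13.18 in a 32-bit register). The representable range is
#' `[-2^int_bits, 2^int_bits - 2^-frac_bits]` with resolution `2^-frac_bits`.
#'
#' @param total_bits Register width in bits.
#' @param int_bits Integer bits.
#' @param frac_bits Fractional bits.
#' @return A `fixed_format` object.
#' @examples
#' fixed_format()           # Q13.18 in 32 bits
#' fixed_format(64, 13, 48) # wide format used for oracle comparisons
#' @export
fixed_format <- function(total_bits = 32L, int_bits = 13L, frac_bits = 18L) {
  total_bits <- as.integer(total_bits)
  int_bits <- as.integer(int_bits)
  frac_bits <- as.integer(frac_bits)
  if (1L + int_bits + frac_bits != total_bits) {
    abort("sign (1) + int_bits + frac_bits must equal total_bits")
  }
  if (int_bits < 0 || frac_bits < 0 || total_bits > 63) {
    abort("unsupported register format (need 0 <= bits, total <= 63)")
  }
  structure(
    list(total_bits = total_bits, sign_bits = 1L,
         int_bits = int_bits, frac_bits = frac_bits,
         resolution = 2^-frac_bits,
         min_value = -2^int_bits,
         max_value = 2^int_bits - 2^-frac_bits),
    class = "fixed_format"
  )
}

#' @export
print.fixed_format <- function(x, ...) {
  cat(sprintf("<fixed_format> Q%d.%d in %d bits: range [%g, %g], resolution 2^-%d\n",
              x$int_bits, x$frac_bits, x$total_bits,
              x$min_value, x$max_value, x$frac_bits))
  invisible(x)
}

raw_bounds <- function(fmt) {
  vb <- fmt$int_bits + fmt$frac_bits
  c(-(2^vb), 2^vb - 1)
}

#' Quantize real numbers onto a fixed-point grid
#'
#' Rounds to the nearest representable value (ties away from zero) and
#' saturates at the range bounds. The raw register image is
#' `value * 2^frac_bits`.
#'
#' @param x Numeric vector (finite).
#' @param fmt A [fixed_format()]. R-side raw images are stored in doubles, so
#'   formats up to 53 value bits are supported here; the simulation engines
#'   handle wider formats internally.
#' @return A `fixed_value`: list with integer-valued `raw` vector and `fmt`.
#' @examples
#' quantize(0.0078125)            # exact: raw 2048 on the 2^-18 grid
#' dequantize(quantize(pi))
#' @export
quantize <- function(x, fmt = fixed_format()) {
  stopifnot(inherits(fmt, "fixed_format"))
  if (fmt$int_bits + fmt$frac_bits > 53) {
    abort("R-side quantize() supports at most 53 value bits; use the simulation engines for wider formats")
  }
  if (anyNA(x) || !all(is.finite(x))) abort("`x` must be finite")
  s <- x * 2^fmt$frac_bits
  raw <- sign(s) * floor(abs(s) + 0.5)
  b <- raw_bounds(fmt)
  raw <- pmin(pmax(raw, b[[1]]), b[[2]])
  structure(list(raw = raw, fmt = fmt), class = "fixed_value")
}

#' @rdname quantize
#' @param fv A `fixed_value`.
#' @return `dequantize()` returns the represented real values.
#' @export
dequantize <- function(fv) {
  stopifnot(inherits(fv, "fixed_value"))
  fv$raw * 2^-fv$fmt$frac_bits
}

#' @export
print.fixed_value <- function(x, ...) {
  cat(sprintf("<fixed_value> Q%d.%d, %d value(s):\n",
              x$fmt$int_bits, x$fmt$frac_bits, length(x$raw)))
  print(head(dequantize(x), 10))
  invisible(x)
}

#' Multiply a fixed-point value by a power of two using a shifter
#'
#' Realizes `x * coeff` for `coeff = +/- 2^k` as a bit shift of the raw
#' register: left shifts saturate on overflow, right shifts truncate toward
#' `-Inf` (arithmetic shift). For in-range exact cases this equals full
#' multiplication, which is what lets the improved L-QIF circuit drop its
#' multipliers.
#'
#' @param x A `fixed_value`.
#' @param coeff A (signed) power of two.
#' @return A `fixed_value` of the same format.
#' @examples
#' shift_mul(quantize(1), 0.25)  # raw 262144 -> 65536
#' shift_mul(quantize(1), 16)
#' @export
shift_mul <- function(x, coeff) {
  stopifnot(inherits(x, "fixed_value"))
  if (length(coeff) != 1 || !is.finite(coeff) || coeff == 0) {
    abort("`coeff` must be a single nonzero power of two")
  }
  k <- log2(abs(coeff))
  if (abs(k - round(k)) > 1e-12) abort("`coeff` must be a power of two")
  k <- as.integer(round(k))
  raw <- if (coeff < 0) -x$raw else x$raw
  raw <- if (k >= 0) raw * 2^k else floor(raw / 2^(-k))
  b <- raw_bounds(x$fmt)
  raw <- pmin(pmax(raw, b[[1]]), b[[2]])
  structure(list(raw = raw, fmt = x$fmt), class = "fixed_value")
}

#' One fixed-point update of an afferent spiking model
#'
#' Computes a single Euler step entirely in fixed-point arithmetic: every
#' constant is pre-quantized to the register format, every product is
#' truncated back to the format (one shared register width per signal), adds
#' saturate, and the reset comparison is made against the quantized
#' `v_peak`. With `use_shift = TRUE` (improved L-QIF only) all coefficient
#' multiplies are realized as shifts.
#'
#' @param model One of `"izh"`, `"lizh"`, `"qif"`, `"lqif"`.
#' @param state Named list with `v` (and `u` for Izh/L-Izh), in real units.
#' @param I_now,I_next Input samples (quantized internally).
#' @param params A [neuron_params()] object.
#' @param fmt A [fixed_format()].
#' @param afferent_type `"SA"` or `"FA"`.
#' @param use_shift Replace coefficient multipliers by shifters.
#' @param h Time step (ms).
#' @return Named list `v`, (`u`,) `spiked`, `overflow_events`.
#' @examples
#' p <- improved_lqif_params()
#' fixed_step("lqif", list(v = 0), I_now = 1, params = p, use_shift = TRUE)
#' @export
fixed_step <- function(model, state, I_now, I_next = I_now,
                       params = neuron_params(model), fmt = fixed_format(),
                       afferent_type = "SA", use_shift = FALSE, h = 0.0078125) {
  model <- match_model(model)
  need_u <- model %in% c("izh", "lizh")
  check_step_inputs(state, I_now, I_next, h, need_u = need_u)
  fa <- match_afferent(afferent_type) == "FA"
  res <- cpp_sim_fixed(MODEL_CODES[[model]], fa, c(I_now, I_next), h,
                       par_vector(params),
                       state$v, if (need_u) state$u else 0,
                       fmt$int_bits, fmt$frac_bits, use_shift,
                       FALSE, 1L)
  out <- list(v = res$v_end, spiked = 1L %in% res$spike_steps,
              overflow_events = res$overflow_events)
  if (need_u) out <- c(out[1], list(u = res$u_end), out[-1])
  out
}

#' Export register images as hex words
#'
#' Writes one two's-complement register word per line (uppercase hex), the
#' interchange format used to cross-check traces against HDL simulators.
#'
#' @param fv A `fixed_value` in a format of at most 32 bits.
#' @param path Optional file to write to.
#' @return Character vector of hex words (invisibly when writing to a file).
#' @examples
#' as_hex(quantize(c(1, -1, 0.0078125)))
#' @export
as_hex <- function(fv, path = NULL) {
  stopifnot(inherits(fv, "fixed_value"))
  bits <- fv$fmt$total_bits
  if (bits > 32) abort("hex export supports register widths up to 32 bits")
  val <- fv$raw %% 2^bits # two's complement image
  width <- ceiling(bits / 4)
  hi <- floor(val / 65536)
  lo <- val %% 65536
  hex <- if (bits > 16) {
    sprintf(paste0("%0", width - 4, "X%04X"), hi, lo)
  } else {
    sprintf(paste0("%0", width, "X"), lo)
  }
  if (!is.null(path)) {
    writeLines(hex, path)
    return(invisible(hex))
  }
  hex
}
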