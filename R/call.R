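#' Broadband FM echolocation call
#'
#' Synthesizes a descending frequency-modulated sweep (linear or hyperbolic
#' law) and records the band discretization used throughout the pipeline:
#' `band_bins` frequency bins uniformly spanning `[f_lo, f_hi]`. The call also
#' carries its closed-form dechirp delay law `dt(f)` with `dt(f_hi) = 0` and
#' `dt(f_lo) = T` for a descending sweep.
#'
#' @param f_hi sweep start frequency, Hz.
#' @param f_lo sweep end frequency, Hz (`f_hi > f_lo > 0`).
#' @param duration sweep duration, s (rounded to the nearest whole sample; the
#'   realized value is stored in `$duration`).
#' @param law `"linear"` or `"hyperbolic"` sweep law.
#' @param sample_rate sampling rate, Hz; must exceed `2 * f_hi`.
#' @param band_bins number of band frequency bins (default 47).
#' @param taper Tukey amplitude-taper fraction applied to the sweep.
#' @return Object of class `sono_call` with elements `signal` (time series),
#'   `band_freqs`, and the generating parameters.
#' @examples
#' cl <- make_call(100e3, 40e3, 1e-3, sample_rate = 400e3)
#' dechirp_delay(cl, c(100e3, 70e3, 40e3))  # 0, 0.5 ms, 1 ms
#' @export
make_call <- function(f_hi = 100e3, f_lo = 40e3, duration = 1e-3,
                      law = c("linear", "hyperbolic"), sample_rate = 400e3,
                      band_bins = 47, taper = 0.1) {
  law <- match.arg(law)
  if (!(f_hi > f_lo && f_lo > 0)) stop("make_call: need f_hi > f_lo > 0")
  if (sample_rate <= 2 * f_hi)
    stop("make_call: sample_rate must exceed 2 * f_hi (Nyquist)")
  n <- max(2L, as.integer(round(duration * sample_rate)))
  dur <- n / sample_rate
  t <- (seq_len(n) - 1) / sample_rate
  if (law == "linear") {
    # instantaneous frequency f_hi + (f_lo - f_hi) t / T
    phase <- 2 * pi * (f_hi * t + (f_lo - f_hi) * t^2 / (2 * dur))
  } else {
    # 1/f linear in t
    b <- (1 / f_lo - 1 / f_hi) / dur
    phase <- 2 * pi * log1p(f_hi * b * t) / b
  }
  sig <- sin(phase) * tukey_window(n, taper)
  structure(list(f_hi = f_hi, f_lo = f_lo, duration = dur,
                 requested_duration = duration, law = law,
                 sample_rate = sample_rate, band_bins = band_bins,
                 band_freqs = seq(f_lo, f_hi, length.out = band_bins),
                 taper = taper, signal = sig),
            class = "sono_call")
}

#' @export
print.sono_call <- function(x, ...) {
  cat(sprintf("call: %s sweep %.1f -> %.1f kHz, %.3f ms @ %.0f kHz, %d band bins\n",
              x$law, x$f_hi / 1e3, x$f_lo / 1e3, x$duration * 1e3,
              x$sample_rate / 1e3, x$band_bins))
  invisible(x)
}

tukey_window <- function(n, alpha) {
  if (alpha <= 0) return(rep(1, n))
  w <- rep(1, n)
  edge <- floor(alpha * (n - 1) / 2)
  if (edge > 0) {
    k <- 0:edge
    ramp <- 0.5 * (1 + cos(pi * (2 * k / (alpha * (n - 1)) - 1)))
    w[1 + k] <- ramp
    w[n - k] <- ramp
  }
  w
}

#' Dechirp delay law of a call
#'
#' Time offset at which the sweep passes through frequency `f`, used to
#' shift spectrogram rows so that one reflector's energy aligns in a single
#' time column (a semi-coherent, phase-less matched filter).
#'
#' @param call a [make_call()] object.
#' @param freqs frequencies, Hz (clamped to the band).
#' @return delays in seconds; 0 at `f_hi`, `duration` at `f_lo`.
#' @export
dechirp_delay <- function(call, freqs) {
  f <- pmin(pmax(freqs, call$f_lo), call$f_hi)
  if (call$law == "linear") {
    call$duration * (call$f_hi - f) / (call$f_hi - call$f_lo)
  } else {
    b <- (1 / call$f_lo - 1 / call$f_hi) / call$duration
    (1 / f - 1 / call$f_hi) / b
  }
}
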