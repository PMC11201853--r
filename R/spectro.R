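#' Observation (spectrogram) configuration
#'
#' Parameters of the short-time Fourier analysis and of the logarithmic
#' compression that turn a time-domain binaural echo into the model's input
#' representation.
#'
#' @param window_len analysis window length, samples (Hann window).
#' @param overlap fractional window overlap in `[0, 1)`; the default hop of
#'   `window_len / 16` yields on the order of 500 range columns for the
#'   default 0.6 m max-range call setup.
#' @param nfft FFT length (zero-padded beyond `window_len` for smoother
#'   frequency interpolation onto the band bins).
#' @param floor_db compression floor, dB relative to the reference.
#' @param ceiling_db compression ceiling, dB relative to the reference.
#' @param epsilon small positive amplitude guard inside the log.
#' @return Object of class `sono_obsconfig`.
#' @export
obs_config <- function(window_len = 64, overlap = 0.9375, nfft = 4 * window_len,
                       floor_db = -60, ceiling_db = 0, epsilon = 1e-6) {
  stopifnot(window_len >= 8, overlap >= 0, overlap < 1,
            ceiling_db > floor_db, epsilon > 0, nfft >= window_len)
  structure(list(window_len = as.integer(window_len), overlap = overlap,
                 nfft = as.integer(nfft), floor_db = floor_db,
                 ceiling_db = ceiling_db, epsilon = epsilon),
            class = "sono_obsconfig")
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' Short-time Fourier magnitude on a band grid
#'
#' Frames the signal with a Hann window, computes zero-padded FFT magnitudes
#' per frame, and (when `band` is given) linearly interpolates the magnitude
#' rows onto `n_bins` uniformly spaced band-bin centers. Column times refer to
#' window centers.
#'
#' @param x numeric time series.
#' @param sample_rate Hz.
#' @param window_len window length, samples (>= 8).
#' @param overlap fractional overlap in `[0, 1)`.
#' @param band `c(f_lo, f_hi)` band limits, Hz, or `NULL` to return the raw
#'   FFT bin rows up to Nyquist.
#' @param n_bins number of band bins when `band` is given.
#' @param nfft FFT length (>= `window_len`).
#' @return list with `values` (nonnegative magnitude matrix, rows =
#'   frequencies), `freqs`, `times` (s, window centers).
#' @export
stft_magnitude <- function(x, sample_rate, window_len = 64, overlap = 0.75,
                           band = NULL, n_bins = 47, nfft = 4 * window_len) {
  stopifnot(window_len >= 8, overlap >= 0, overlap < 1, nfft >= window_len)
  if (!is.null(band)) {
    if (band[2] > sample_rate / 2 || band[1] < 0 || band[1] >= band[2])
      stop("stft_magnitude: band must lie within [0, Nyquist]")
  }
  hop <- max(1L, as.integer(round(window_len * (1 - overlap))))
  n <- length(x)
  if (n < window_len) x <- c(x, rep(0, window_len - n))
  n <- length(x)
  starts <- seq(1L, n - window_len + 1L, by = hop)
  w <- hann_window(window_len)
  frames <- matrix(x[outer(0:(window_len - 1L), starts, "+")],
                   window_len, length(starts)) * w
  if (nfft > window_len)
    frames <- rbind(frames, matrix(0, nfft - window_len, length(starts)))
  sp <- stats::mvfft(frames)
  nfreq <- nfft %/% 2 + 1
  mag <- Mod(sp[seq_len(nfreq), , drop = FALSE])
  fft_freqs <- (seq_len(nfreq) - 1) * sample_rate / nfft
  times <- (starts - 1 + (window_len - 1) / 2) / sample_rate
  if (is.null(band))
    return(list(values = mag, freqs = fft_freqs, times = times))
  bf <- seq(band[1], band[2], length.out = n_bins)
  W <- interp_weights(fft_freqs, bf)       # n_bins x nfreq
  list(values = W %*% mag, freqs = bf, times = times)
}

# sparse-ish linear interpolation matrix from grid `from` onto points `to`
interp_weights <- function(from, to) {
  W <- matrix(0, length(to), length(from))
  for (i in seq_along(to)) {
    j <- findInterval(to[i], from, all.inside = TRUE)
    t <- (to[i] - from[j]) / (from[j + 1] - from[j])
    W[i, j] <- 1 - t
    W[i, j + 1] <- t
  }
  W
}

#' Stack left and right spectrogram magnitudes into a binaural matrix
#'
#' @param left,right magnitude matrices of identical shape (left ear on top).
#' @return matrix with `2 * nrow(left)` rows.
#' @export
binaural_concat <- function(left, right) {
  if (!all(dim(left) == dim(right)))
    stop("binaural_concat: left and right must have identical shapes")
  rbind(left, right)
}

#' Dechirp a binaural band spectrogram
#'
#' Shifts each frequency row left by the emitted sweep's delay at that row's
#' frequency (rounded to the nearest column), so a single reflector's energy
#' aligns in one time column. Both ear blocks are shifted identically;
#' vacated trailing columns are zero-filled.
#'
#' @param spec binaural magnitude matrix (`2 * n_bins` rows) whose row
#'   frequencies are `band_freqs` repeated for the two ears.
#' @param call a [make_call()].
#' @param column_dt time step between spectrogram columns, s.
#' @return matrix of the same shape.
#' @export
dechirp <- function(spec, call, column_dt) {
  nb <- nrow(spec) / 2
  stopifnot(nb == round(nb))
  shifts <- as.integer(round(dechirp_delay(call, call$band_freqs) / column_dt))
  out <- spec
  nt <- ncol(spec)
  for (i in seq_len(nb)) {
    k <- shifts[i]
    if (k == 0) next
    for (r in c(i, i + nb)) {
      out[r, ] <- if (k >= nt) rep(0, nt) else c(spec[r, (k + 1):nt], rep(0, k))
    }
  }
  out
}

#' Logarithmic compression with linear rescaling
#'
#' `C(x) = clip((20 log10(x / ref + eps) - floor_db) / (ceiling_db -
#' floor_db), 0, 1)`: amplitudes at the reference map to 1, amplitudes at or
#' below the floor map to 0, and the map is monotone nondecreasing.
#'
#' @param x nonnegative magnitudes.
#' @param cfg an [obs_config()] (uses `floor_db`, `ceiling_db`, `epsilon`).
#' @param ref positive reference amplitude (the ensemble maximum).
#' @return values in `[0, 1]`, same shape as `x`.
#' @export
compress <- function(x, cfg = obs_config(), ref) {
  stopifnot(ref > 0)
  u <- (20 * log10(x / ref + cfg$epsilon) - cfg$floor_db) /
    (cfg$ceiling_db - cfg$floor_db)
  u[u < 0] <- 0
  u[u > 1] <- 1
  u
}

# derivative of compress wrt x where unclipped; 0 elsewhere
compress_grad <- function(x, cfg, ref) {
  db <- 20 * log10(x / ref + cfg$epsilon)
  u <- (db - cfg$floor_db) / (cfg$ceiling_db - cfg$floor_db)
  g <- 20 / (log(10) * (cfg$ceiling_db - cfg$floor_db) * (x / ref + cfg$epsilon) * ref)
  g[u < 0 | u > 1] <- 0
  g
}

#' Build a dechirped binaural observation from a simulated echo
#'
#' Composition of the full preprocessing pipeline: band-limited STFT
#' magnitude per ear, binaural concatenation, dechirping, and logarithmic
#' compression, with the round-trip range axis `r = v_s * t / 2` attached.
#'
#' @param echo a [simulate_echo()] result.
#' @param call the emitted [make_call()].
#' @param cfg an [obs_config()].
#' @param ref compression reference amplitude; defaults to this observation's
#'   maximum pre-compression magnitude. Ensembles share one reference (see
#'   [simulate_ensemble()]).
#' @return Object of class `sono_spectrogram`: `values` (`2 n_bins x N_t`
#'   in `[0, 1]`), `freqs`, `times`, `ranges`, `meta`.
#' @export
make_observation <- function(echo, call, cfg = obs_config(), ref = NULL) {
  raw <- observation_magnitude(echo, call, cfg)
  if (is.null(ref)) ref <- max(raw$values)
  if (ref <= 0) ref <- 1
  structure(list(values = compress(raw$values, cfg, ref),
                 freqs = raw$freqs, times = raw$times, ranges = raw$ranges,
                 meta = list(ref = ref, obs_config = cfg,
                             call = call[c("f_hi", "f_lo", "duration", "law",
                                           "sample_rate", "band_bins")],
                             v_s = echo$v_s)),
            class = "sono_spectrogram")
}

# uncompressed dechirped binaural magnitude + axes
observation_magnitude <- function(echo, call, cfg) {
  band <- c(call$f_lo, call$f_hi)
  L <- stft_magnitude(echo$left, echo$sample_rate, cfg$window_len, cfg$overlap,
                      band, call$band_bins, cfg$nfft)
  R <- stft_magnitude(echo$right, echo$sample_rate, cfg$window_len, cfg$overlap,
                      band, call$band_bins, cfg$nfft)
  B <- binaural_concat(L$values, R$values)
  dt <- L$times[2] - L$times[1]
  D <- dechirp(B, call, dt)
  list(values = D, freqs = L$freqs, times = L$times,
       ranges = echo$v_s * L$times / 2)
}

#' @export
print.sono_spectrogram <- function(x, ...) {
  cat(sprintf("binaural spectrogram: %d x %d (2 x %d band bins), ranges %.3f..%.3f m\n",
              nrow(x$values), ncol(x$values), length(x$freqs),
              min(x$ranges), max(x$ranges)))
  invisible(x)
}

#' Plot a binaural dechirped spectrogram
#' @param x a `sono_spectrogram`.
#' @param ... passed to [graphics::image()].
#' @export
plot.sono_spectrogram <- function(x, ...) {
  graphics::image(x$ranges, seq_len(nrow(x$values)), t(x$values),
                  xlab = "range [m]", ylab = "row (left ears then right)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
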