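#' Echo simulation configuration
#'
#' @param v_s speed of sound, m/s.
#' @param max_range maximum one-way range, meters; sets the simulated signal
#'   length.
#' @param spreading apply round-trip geometric spreading loss
#'   `1 / (d_out * d_back)`? Disable for a strictly lossless delay-and-filter
#'   synthesis.
#' @param noise_floor additive white-noise amplitude relative to the peak
#'   signal amplitude (0 disables noise).
#' @param seed integer seed used when `noise_floor > 0`.
#' @return Object of class `sono_simconfig`.
#' @export
sim_config <- function(v_s = 343, max_range = 0.6, spreading = TRUE,
                       noise_floor = 0, seed = 1L) {
  stopifnot(v_s > 0, max_range > 0, noise_floor >= 0)
  structure(list(v_s = v_s, max_range = max_range, spreading = spreading,
                 noise_floor = noise_floor, seed = as.integer(seed)),
            class = "sono_simconfig")
}

#' Simulate the binaural echo of a point-scatterer scene
#'
#' Frequency-domain synthesis of the received left/right ear signals: per
#' scatterer, the emitted call spectrum is multiplied by the ear's ERTF at the
#' scatterer's body-frame direction, the scatterer's reflection filter at its
#' incidence direction, a pure delay `exp(-j 2 pi f r / v_s)` at the full
#' emitter-to-scatterer-to-ear path length `r`, and (optionally) round-trip
#' geometric spreading; contributions sum linearly over scatterers and the
#' result is inverse-transformed to the time domain.
#'
#' @param scene a [scene()].
#' @param pose the sensor [pose()].
#' @param call a [make_call()].
#' @param ertf an [ertf_model()].
#' @param cfg a [sim_config()]. `max_range` must cover the scene from the pose.
#' @return Object of class `sono_echo`: list with numeric `left`, `right`
#'   (equal length), `sample_rate`, and the geometry metadata.
#' @export
simulate_echo <- function(scene, pose, call, ertf, cfg = sim_config()) {
  stopifnot(inherits(scene, "sono_scene"), inherits(call, "sono_call"))
  p <- pose
  if (all(p$position >= scene$bounds[1, ]) && all(p$position <= scene$bounds[2, ]))
    warning("simulate_echo: pose lies inside the scene bounds")
  fs <- call$sample_rate
  n_sig <- as.integer(round((2 * cfg$max_range / cfg$v_s + call$duration) * fs))
  geom <- ensonification_geometry(scene, p, ertf, cfg$v_s)
  if (max(geom$range_left, geom$range_right) / 2 > cfg$max_range + 1e-9)
    warning("simulate_echo: scatterers beyond max_range will wrap around")
  nfreq <- n_sig %/% 2 + 1
  freqs <- (seq_len(nfreq) - 1) * fs / n_sig
  Se <- stats::fft(c(call$signal, rep(0, n_sig - length(call$signal))))[seq_len(nfreq)]
  E <- ertf_gain(ertf, geom$psi, freqs)
  Hp <- reflection_filter(scene, geom$eta, freqs)
  out <- list()
  for (ear in c("left", "right")) {
    r <- if (ear == "left") geom$range_left else geom$range_right
    amp <- if (cfg$spreading) {
      d_back <- r - geom$d_out
      1 / (geom$d_out * d_back)
    } else rep(1, length(r))
    phase <- exp(-2i * pi * outer(r / cfg$v_s, freqs))   # n x nfreq
    S <- colSums((E[[ear]] * Hp * phase) * amp)
    S <- S * Se
    full <- c(S, Conj(rev(S[2:(nfreq - 1L + n_sig %% 2)])))
    out[[ear]] <- Re(stats::fft(full, inverse = TRUE)) / n_sig
  }
  if (cfg$noise_floor > 0) {
    peak <- max(abs(c(out$left, out$right)), 1e-300)
    noise <- with_seed(cfg$seed,
                       matrix(stats::rnorm(2 * n_sig), n_sig, 2)) * cfg$noise_floor * peak
    out$left <- out$left + noise[, 1]
    out$right <- out$right + noise[, 2]
  }
  structure(list(left = out$left, right = out$right, sample_rate = fs,
                 v_s = cfg$v_s, max_range = cfg$max_range,
                 call_duration = call$duration),
            class = "sono_echo")
}

#' Ensonification geometry of a scene from a pose
#'
#' Per scatterer: the unit body-frame direction from the sensor (`psi`), the
#' unit incidence direction at the scatterer pointing back at the sensor
#' (`eta`), the outbound distance, and the full round-trip path lengths
#' through each ear (`emitter -> scatterer -> ear`).
#'
#' @param scene a [scene()].
#' @param pose a [pose()].
#' @param ertf an [ertf_model()] providing ear positions.
#' @param v_s speed of sound, m/s (delays are `range / v_s`).
#' @return list with `psi` (`n x 3`), `eta` (`n x 3`), `d_out`, `range_left`,
#'   `range_right`, `delay_left`, `delay_right`.
#' @export
ensonification_geometry <- function(scene, pose, ertf, v_s = 343) {
  R <- pose_rotation(pose)
  rel <- sweep(scene$positions, 2, pose$position, "-")
  d_out <- sqrt(rowSums(rel^2))
  if (any(d_out <= 0)) stop("ensonification_geometry: scatterer at the sensor position")
  psi <- (rel %*% R) / d_out          # body-frame unit direction
  eta <- -rel / d_out                 # world-frame, scatterer -> sensor
  ear_w <- body_to_world(pose, ertf$ear_positions)
  d_back <- cbind(sqrt(rowSums(sweep(scene$positions, 2, ear_w[1, ], "-")^2)),
                  sqrt(rowSums(sweep(scene$positions, 2, ear_w[2, ], "-")^2)))
  list(psi = psi, eta = eta, d_out = d_out,
       range_left = d_out + d_back[, 1], range_right = d_out + d_back[, 2],
       delay_left = (d_out + d_back[, 1]) / v_s,
       delay_right = (d_out + d_back[, 2]) / v_s)
}

# Per-scatterer reflection filter H_p(eta, f): gain x band spectrum
# (interpolated to `freqs`) x optional cosine-power lobe.
reflection_filter <- function(scene, eta, freqs) {
  n <- n_scatterers(scene)
  H <- matrix(scene$gain, n, length(freqs)) * (1 + 0i)
  if (!is.null(scene$spectra)) {
    nb <- ncol(scene$spectra)
    bf <- attr(scene$spectra, "band_freqs")
    if (is.null(bf)) bf <- seq(min(freqs), max(freqs), length.out = nb)
    for (i in seq_len(n)) {
      re <- stats::approx(bf, Re(scene$spectra[i, ]), freqs, rule = 2)$y
      im <- stats::approx(bf, Im(scene$spectra[i, ]), freqs, rule = 2)$y
      H[i, ] <- H[i, ] * complex(real = re, imaginary = im)
    }
  }
  if (!is.null(scene$lobe_axis)) {
    has <- rowSums(is.finite(scene$lobe_axis)) == 3
    if (any(has)) {
      ax <- scene$lobe_axis[has, , drop = FALSE]
      ax <- ax / sqrt(rowSums(ax^2))
      d <- pmax(0, rowSums(eta[has, , drop = FALSE] * ax))
      H[has, ] <- H[has, ] * (d ^ scene$lobe_exponent[has])
    }
  }
  H
}
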