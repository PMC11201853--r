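#' Echolocation-related transfer function (ERTF) model
#'
#' The ERTF is the product of the emitter's directional transfer function and
#' one ear's head-related transfer function: `E_ear(psi, f) = H_e(psi, f) *
#' H_ear(psi, f)`, evaluated in the body frame. The default is a parametric
#' stand-in built from baffled circular-piston directivities (with a
#' cardioid-style rear taper so rear directions are near-zero): a single
#' emitter piston on the forward axis and two ear pistons tilted in azimuth.
#' Each ear's combined ERTF is normalized to unit gain on the forward axis at
#' every frequency. Tabulated ERTFs measured over (azimuth, elevation,
#' frequency) can be supplied instead via `ertf_from_table()`.
#'
#' @param a_emitter emitter piston radius, meters.
#' @param a_ear ear piston radius, meters.
#' @param ear_positions 2x3 matrix of (left, right) ear positions in the body
#'   frame, meters.
#' @param ear_azimuth length-2 azimuth tilts (radians) of the (left, right)
#'   ear axes; positive toward +Y (body left).
#' @param v_s speed of sound, m/s.
#' @return Object of class `sono_ertf`.
#' @export
ertf_model <- function(a_emitter = 0.004, a_ear = 0.006,
                       ear_positions = rbind(c(0, 0.007, 0.005),
                                             c(0, -0.007, 0.005)),
                       ear_azimuth = c(15, -15) * pi / 180,
                       v_s = 343) {
  stopifnot(a_emitter > 0, a_ear > 0, nrow(ear_positions) == 2,
            length(ear_azimuth) == 2)
  axes <- rbind(c(cos(ear_azimuth[1]), sin(ear_azimuth[1]), 0),
                c(cos(ear_azimuth[2]), sin(ear_azimuth[2]), 0))
  structure(list(kind = "piston", a_emitter = a_emitter, a_ear = a_ear,
                 ear_positions = ear_positions, ear_axes = axes,
                 ear_azimuth = ear_azimuth, v_s = v_s),
            class = "sono_ertf")
}

#' @export
print.sono_ertf <- function(x, ...) {
  if (x$kind == "piston")
    cat(sprintf("ERTF: piston emitter a=%.1f mm, ears a=%.1f mm tilted %+.0f/%+.0f deg\n",
                x$a_emitter * 1e3, x$a_ear * 1e3,
                x$ear_azimuth[1] * 180 / pi, x$ear_azimuth[2] * 180 / pi))
  else cat("ERTF: tabulated over (azimuth, elevation, frequency)\n")
  invisible(x)
}

#' Baffled-piston directivity with rear taper
#'
#' `|2 J1(k a sin(theta)) / (k a sin(theta))| * (1 + cos(theta)) / 2`, where
#' `theta` is the angle off the piston axis and `k = 2 pi f / v_s`. Equals 1
#' on-axis; the cardioid factor drives the rear hemisphere toward zero while
#' leaving the positions of the Bessel nulls unchanged.
#'
#' @param cos_theta cosine of the off-axis angle (vector).
#' @param a piston radius, meters.
#' @param freqs frequencies, Hz (vector).
#' @param v_s speed of sound, m/s.
#' @return matrix `length(cos_theta) x length(freqs)` of nonnegative gains.
#' @export
piston_directivity <- function(cos_theta, a, freqs, v_s = 343) {
  cos_theta <- pmin(1, pmax(-1, cos_theta))
  sin_theta <- sqrt(1 - cos_theta^2)
  k <- 2 * pi * freqs / v_s
  x <- outer(sin_theta, k * a)           # n x nf
  d <- matrix(1, nrow(x), ncol(x))
  nz <- x > 1e-12
  d[nz] <- 2 * besselJ(x[nz], 1) / x[nz]
  abs(d) * ((1 + cos_theta) / 2)
}

#' Evaluate the binaural ERTF
#'
#' @param model a [ertf_model()] or [ertf_from_table()].
#' @param directions `n x 3` matrix of unit direction vectors in the body
#'   frame (from the sensor toward the target).
#' @param freqs frequencies, Hz.
#' @return list with complex gain matrices `left` and `right`, each
#'   `n x length(freqs)`; unit gain on the forward axis.
#' @export
ertf_gain <- function(model, directions, freqs) {
  directions <- as_point_matrix(directions)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("ertf_gain: directions must be unit vectors")
  if (model$kind == "table") return(ertf_gain_table(model, directions, freqs))
  fwd <- c(1, 0, 0)
  ce <- directions %*% fwd
  He <- piston_directivity(ce, model$a_emitter, freqs, model$v_s)
  out <- list()
  for (ear in 1:2) {
    ca <- directions %*% model$ear_axes[ear, ]
    Hr <- piston_directivity(ca, model$a_ear, freqs, model$v_s)
    E <- He * Hr
    # normalize to unit on-axis gain per frequency
    He0 <- piston_directivity(1, model$a_emitter, freqs, model$v_s)
    Hr0 <- piston_directivity(model$ear_axes[ear, 1], model$a_ear, freqs, model$v_s)
    E <- sweep(E, 2, as.numeric(He0 * Hr0), "/")
    out[[ear]] <- E * (1 + 0i)
  }
  names(out) <- c("left", "right")
  out
}

#' Tabulated ERTF over azimuth, elevation and frequency
#'
#' @param azimuth grid of azimuths, radians (increasing).
#' @param elevation grid of elevations, radians (increasing).
#' @param freqs grid of frequencies, Hz (increasing).
#' @param left,right complex arrays `[n_az x n_el x n_f]` of ear gains.
#' @return Object of class `sono_ertf` usable with [ertf_gain()]; gains are
#'   interpolated (nearest grid node per axis).
#' @export
ertf_from_table <- function(azimuth, elevation, freqs, left, right) {
  stopifnot(all(dim(left) == c(length(azimuth), length(elevation), length(freqs))),
            all(dim(right) == dim(left)))
  structure(list(kind = "table", azimuth = azimuth, elevation = elevation,
                 freqs = freqs, left = left, right = right),
            class = "sono_ertf")
}

ertf_gain_table <- function(model, directions, freqs) {
  az <- atan2(directions[, 2], directions[, 1])
  el <- asin(pmin(1, pmax(-1, directions[, 3])))
  ia <- nearest_index(az, model$azimuth)
  ie <- nearest_index(el, model$elevation)
  iff <- nearest_index(freqs, model$freqs)
  n <- nrow(directions)
  nf <- length(freqs)
  gl <- matrix(0i, n, nf)
  gr <- matrix(0i, n, nf)
  for (j in seq_len(nf)) {
    gl[, j] <- model$left[cbind(ia, ie, iff[j])]
    gr[, j] <- model$right[cbind(ia, ie, iff[j])]
  }
  list(left = gl, right = gr)
}

nearest_index <- function(x, grid) {
  vapply(x, function(v) which.min(abs(grid - v)), integer(1))
}
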