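#' Discretized forward hemisphere at constant range
#'
#' Quasi-uniform deterministic lattice of `n` points on the forward
#' hemisphere of a pose at range `r`: the constant-range surface over which
#' the acoustic rendering equation integrates the reflectivity field for one
#' spectrogram range slice. The first lattice point lies exactly on the body
#' forward axis; equal solid-angle weights sum to `2 * pi`.
#'
#' @param pose a [pose()].
#' @param r range, meters (> 0).
#' @param n number of points (>= 4; default 600).
#' @return list with `points_world` (`n x 3`), `directions` (`n x 3` unit
#'   world vectors from the sensor toward each point), `directions_body`,
#'   `range`, and `weights`.
#' @export
hemisphere_samples <- function(pose, r, n = 600) {
  if (r <= 0) stop("hemisphere_samples: r must be positive")
  if (n < 4) stop("hemisphere_samples: n must be >= 4")
  db <- hemisphere_dirs_body(n)
  R <- pose_rotation(pose)
  dw <- db %*% t(R)
  list(points_world = sweep(dw * r, 2, pose$position, "+"),
       directions = dw, directions_body = db, range = r,
       weights = rep(2 * pi / n, n))
}

# forward-hemisphere Fibonacci lattice in the body frame (+X forward);
# point 1 is exactly on-axis, cos(theta) in (0, 1]
hemisphere_dirs_body <- function(n) {
  i <- seq_len(n) - 1
  ct <- 1 - i / n
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- i * golden_angle
  cbind(ct, st * cos(phi), st * sin(phi))
}

#' Per-range-slice loss
#'
#' Mean squared error between a predicted and a measured compressed binaural
#' spectrum (94-vector by default); nonnegative, zero iff equal, symmetric.
#'
#' @param predicted,measured numeric vectors of equal length.
#' @return scalar.
#' @export
slice_loss <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("slice_loss: length mismatch")
  mean((predicted - measured)^2)
}

# Shared rendering context: everything that does not depend on the queried
# slice. `poses` is a list of poses; ERTF gains over the hemisphere lattice
# depend only on body-frame directions so they are computed once.
render_context <- function(poses, call, ertf, n_hemisphere, obs_cfg, ref,
                           v_s, bounds, n_freq_bins = call$band_bins,
                           embed_features = 30) {
  nh <- as.integer(n_hemisphere)
  db <- hemisphere_dirs_body(nh)
  E <- ertf_gain(ertf, db, call$band_freqs)
  P <- length(poses)
  # per-pose quantities stored flat (rows (p-1)*nh + 1:nh) for fast gather
  dirs_world <- matrix(NA_real_, nh * P, 3)
  dir_embed <- matrix(NA_real_, nh * P, 3 * embed_features)
  positions <- matrix(NA_real_, P, 3)
  for (p in seq_len(P)) {
    R <- pose_rotation(poses[[p]])
    dw <- db %*% t(R)
    rows <- (p - 1L) * nh + seq_len(nh)
    dirs_world[rows, ] <- dw
    dir_embed[rows, ] <- embed_block(dw, embed_features)
    positions[p, ] <- poses[[p]]$position
  }
  list(nh = nh, w = 2 * pi / nh, dirs_body = db,
       ELre = Re(E$left), ELim = Im(E$left),
       ERre = Re(E$right), ERim = Im(E$right),
       dirs_world = dirs_world, dir_embed = dir_embed,
       positions = positions, band_freqs = call$band_freqs,
       obs_cfg = obs_cfg, ref = ref, v_s = v_s, bounds = bounds,
       embed_features = embed_features, tiles = new.env(parent = emptyenv()))
}

# hemisphere ERTF matrices tiled to a batch of b slices, memoized per b
ertf_tiles <- function(ctx, b) {
  key <- as.character(b)
  if (!is.null(ctx$tiles[[key]])) return(ctx$tiles[[key]])
  t <- rep(seq_len(ctx$nh), b)
  val <- list(ELre = ctx$ELre[t, , drop = FALSE],
              ELim = ctx$ELim[t, , drop = FALSE],
              ERre = ctx$ERre[t, , drop = FALSE],
              ERim = ctx$ERim[t, , drop = FALSE])
  ctx$tiles[[key]] <- val
  val
}

# sin/cos octave embedding of an arbitrary column block
embed_block <- function(x, n_features) {
  n_oct <- n_features / 2
  out <- matrix(NA_real_, nrow(x), ncol(x) * n_features)
  col <- 1L
  for (d in seq_len(ncol(x))) {
    for (l in 0:(n_oct - 1)) {
      a <- (2 ^ l) * pi * x[, d]
      out[, col] <- sin(a)
      out[, col + 1L] <- cos(a)
      col <- col + 2L
    }
  }
  out
}

# Batched rendering of range slices. pose_idx, r: vectors of length b.
# Returns compressed spectra [b x 2nb] plus everything backward needs.
render_forward <- function(field, ctx, pose_idx, r, keep_cache = FALSE) {
  b <- length(pose_idx)
  nh <- ctx$nh
  nb <- length(ctx$band_freqs)
  rows <- rep((pose_idx - 1L) * nh, each = nh) + rep(seq_len(nh), b)
  dmat <- ctx$dirs_world[rows, , drop = FALSE]
  pts <- dmat * rep(r, each = nh) +
    ctx$positions[rep(pose_idx, each = nh), , drop = FALSE]
  if (is.function(field)) {
    # analytic/delta fields: a function (positions, directions) -> complex n x nb
    Fc <- field(pts, dmat)
    A <- Re(Fc); B <- Im(Fc)
    fwd <- list(cache = NULL)
    keep_cache <- FALSE
  } else {
    np <- normalize_positions(pts, ctx$bounds)
    pe <- embed_block(np, ctx$embed_features)
    E <- cbind(pe, ctx$dir_embed[rows, , drop = FALSE])
    fwd <- mlp_forward(field, E, keep_cache)
    A <- fwd$out[, seq_len(nb), drop = FALSE]
    B <- fwd$out[, nb + seq_len(nb), drop = FALSE]
  }
  tl <- ertf_tiles(ctx, b)
  # blockwise sum over the nh contiguous hemisphere rows of each slice
  blocksum <- function(M) {
    out <- .colSums(M, nh, b * nb)
    dim(out) <- c(b, nb)
    out
  }
  SLre <- blocksum(A * tl$ELre - B * tl$ELim) * ctx$w
  SLim <- blocksum(A * tl$ELim + B * tl$ELre) * ctx$w
  SRre <- blocksum(A * tl$ERre - B * tl$ERim) * ctx$w
  SRim <- blocksum(A * tl$ERim + B * tl$ERre) * ctx$w
  mL <- sqrt(SLre^2 + SLim^2)
  mR <- sqrt(SRre^2 + SRim^2)
  m <- cbind(mL, mR)
  cS <- compress(m, ctx$obs_cfg, ctx$ref)
  # unimodular round-trip delay factor exp(-j w 2r / v_s); carried on the
  # complex spectrum for fidelity, provably inert under the magnitude
  ph <- exp(-2i * pi * outer(r, ctx$band_freqs) * 2 / ctx$v_s)
  res <- list(compressed = cS, magnitude = m,
              spectrum = cbind((SLre + 1i * SLim) * ph, (SRre + 1i * SRim) * ph))
  if (keep_cache)
    res$bw <- list(cache = fwd$cache, SLre = SLre, SLim = SLim, SRre = SRre,
                   SRim = SRim, mL = mL, mR = mR,
                   grp = rep(seq_len(b), each = nh), b = b)
  res
}

# gradient of a scalar loss wrt field parameters given dL/d(compressed) [b x 2nb]
render_backward <- function(field, ctx, fw, dC) {
  bw <- fw$bw
  nb <- length(ctx$band_freqs)
  dm <- dC * compress_grad(fw$magnitude, ctx$obs_cfg, ctx$ref)
  safe <- function(num, den) num / pmax(den, 1e-300) * (den > 1e-300)
  gLre <- dm[, seq_len(nb), drop = FALSE] * safe(bw$SLre, bw$mL)
  gLim <- dm[, seq_len(nb), drop = FALSE] * safe(bw$SLim, bw$mL)
  gRre <- dm[, nb + seq_len(nb), drop = FALSE] * safe(bw$SRre, bw$mR)
  gRim <- dm[, nb + seq_len(nb), drop = FALSE] * safe(bw$SRim, bw$mR)
  g <- bw$grp
  GLre <- gLre[g, , drop = FALSE]; GLim <- gLim[g, , drop = FALSE]
  GRre <- gRre[g, , drop = FALSE]; GRim <- gRim[g, , drop = FALSE]
  tl <- ertf_tiles(ctx, bw$b)
  dA <- (tl$ELre * GLre + tl$ELim * GLim + tl$ERre * GRre + tl$ERim * GRim) * ctx$w
  dB <- (-tl$ELim * GLre + tl$ELre * GLim - tl$ERim * GRre + tl$ERre * GRim) * ctx$w
  mlp_backward(field, bw$cache, cbind(dA, dB))
}

#' Render one spectrogram range slice through the acoustic rendering equation
#'
#' Integrates the reflectivity field over a discretized constant-range
#' forward hemisphere: per ear and band frequency, the weighted sum of
#' `F(P_world, v) * E_ear(psi, f)` over the hemisphere points times the
#' unimodular round-trip delay factor, followed by the magnitude and the
#' logarithmic compression. The whole map is differentiable with respect to
#' the field parameters (used by the trainer via analytic backpropagation).
#'
#' @param field a `sono_field`.
#' @param pose the sensor [pose()].
#' @param r slice range, meters.
#' @param ertf an [ertf_model()].
#' @param call the emitted [make_call()] (defines the band bins).
#' @param n_hemisphere hemisphere points (default 600).
#' @param obs_cfg an [obs_config()] (compression parameters).
#' @param ref compression reference amplitude.
#' @param v_s speed of sound, m/s.
#' @param bounds 2x3 scene bounding box used for position normalization;
#'   defaults to the bounds stored in the trained field.
#' @return list with `spectrum` (compressed 94-vector, left bins then right),
#'   `complex` (the raw complex binaural spectrum), and `range`.
#' @export
render_slice <- function(field, pose, r, ertf, call, n_hemisphere = 600,
                         obs_cfg = obs_config(), ref = 1, v_s = 343,
                         bounds = NULL) {
  if (is.null(bounds) && !is.function(field)) bounds <- field$meta$bounds
  if (is.null(bounds) && !is.function(field))
    stop("render_slice: no scene bounds available")
  if (is.null(bounds)) bounds <- rbind(c(-1, -1, -1), c(1, 1, 1))
  ef <- if (is.function(field)) 30 else field$config$embed_features
  ctx <- render_context(list(pose), call, ertf, n_hemisphere, obs_cfg, ref,
                        v_s, bounds, embed_features = ef)
  fw <- render_forward(field, ctx, 1L, r)
  list(spectrum = as.numeric(fw$compressed), complex = as.vector(fw$spectrum),
       range = r)
}

#' Render a full predicted spectrogram at a pose
#'
#' Applies [render_slice()] per range column and assembles the columns with
#' the same axes and metadata as the training observations.
#'
#' @inheritParams render_slice
#' @param ranges vector of range-column centers, meters.
#' @param times optional column times (defaults to `2 * ranges / v_s`).
#' @param chunk number of columns rendered per internal batch.
#' @return a `sono_spectrogram`.
#' @export
render_spectrogram <- function(field, pose, ranges, ertf, call,
                               n_hemisphere = 600, obs_cfg = obs_config(),
                               ref = 1, v_s = 343,
                               bounds = NULL, times = NULL,
                               chunk = 128L) {
  if (is.null(bounds) && !is.function(field)) bounds <- field$meta$bounds
  if (is.null(bounds)) stop("render_spectrogram: no scene bounds available")
  ef <- if (is.function(field)) 30 else field$config$embed_features
  ctx <- render_context(list(pose), call, ertf, n_hemisphere, obs_cfg, ref,
                        v_s, bounds, embed_features = ef)
  nt <- length(ranges)
  vals <- matrix(NA_real_, 2 * call$band_bins, nt)
  for (s in split(seq_len(nt), ceiling(seq_len(nt) / chunk))) {
    fw <- render_forward(field, ctx, rep(1L, length(s)), ranges[s])
    vals[, s] <- t(fw$compressed)
  }
  structure(list(values = vals, freqs = call$band_freqs,
                 times = if (is.null(times)) 2 * ranges / v_s else times,
                 ranges = ranges,
                 meta = list(ref = ref, obs_config = obs_cfg,
                             call = call[c("f_hi", "f_lo", "duration", "law",
                                           "sample_rate", "band_bins")],
                             v_s = v_s, rendered = TRUE)),
            class = "sono_spectrogram")
}
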