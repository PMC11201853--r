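#' Reflectivity-field architecture configuration
#'
#' The reflectivity field is a multilayer perceptron that maps a 6-vector
#' (scene-normalized voxel position X, Y, Z plus the unit ensonification
#' direction) to a complex reflection spectrum over the call band. The six
#' inputs are lifted by a Fourier embedding (`embed_features` sin/cos
#' features per input, 6 x 30 = 180 by default); hidden layers use leaky-ReLU
#' activations, and selected layers receive a depth-concatenated copy of the
#' embedding (skip connections). The output layer is linear with
#' `2 * n_freq_bins` units: the first `n_freq_bins` are the real parts and the
#' last `n_freq_bins` the imaginary parts of the spectrum.
#'
#' The default hidden profile is chosen so the total learnable parameter
#' count is about 5e5.
#'
#' @param n_freq_bins number of complex output frequency bins (default 47).
#' @param embed_features sin/cos features per input scalar (even; default 30,
#'   i.e. 15 octave-spaced frequencies times sin and cos).
#' @param hidden integer vector of hidden-layer widths.
#' @param skip_at indices of hidden layers whose input is depth-concatenated
#'   with the embedding.
#' @param leaky_slope negative slope of the leaky-ReLU activation.
#' @param seed integer seed for parameter initialization.
#' @return Object of class `sono_fieldconfig`.
#' @export
field_config <- function(n_freq_bins = 47, embed_features = 30,
                         hidden = c(256, 256, 256, 256, 280, 256),
                         skip_at = 5, leaky_slope = 0.01, seed = 1L) {
  hidden <- as.integer(hidden)
  if (length(hidden) < 1 || any(hidden < 1))
    stop("field_config: need at least one hidden layer of positive width")
  if (embed_features %% 2 != 0 || embed_features < 2)
    stop("field_config: embed_features must be a positive even count")
  skip_at <- as.integer(skip_at)
  if (length(skip_at) && (any(skip_at < 1) || any(skip_at > length(hidden))))
    stop("field_config: skip_at indices must lie within the hidden layers")
  structure(list(n_freq_bins = as.integer(n_freq_bins),
                 embed_features = as.integer(embed_features),
                 hidden = hidden, skip_at = skip_at,
                 leaky_slope = leaky_slope, seed = as.integer(seed)),
            class = "sono_fieldconfig")
}

embed_width <- function(cfg) 6L * cfg$embed_features

#' Fourier positional embedding of field inputs
#'
#' Each input scalar `v` (three scene-normalized position components in
#' `[-1, 1]` and three unit-direction components) is expanded into
#' `sin(2^l pi v), cos(2^l pi v)` for octaves `l = 0 .. n/2 - 1`
#' (15 octaves, 30 features per input by default), giving a 180-vector for
#' the 6 inputs. Embedding low-frequency inputs into this high-frequency
#' representation lets the network learn fine spatial detail.
#'
#' @param x numeric matrix `n x 6` (or a length-6 vector).
#' @param n_features sin/cos features per input (even).
#' @return matrix `n x (6 * n_features)`, all values in `[-1, 1]`. Layout:
#'   input dims vary slowest, then octave, with `sin` before `cos`.
#' @export
fourier_embed <- function(x, n_features = 30) {
  if (is.null(dim(x))) x <- matrix(x, ncol = length(x))
  stopifnot(ncol(x) == 6, n_features %% 2 == 0)
  n_oct <- n_features / 2
  out <- matrix(NA_real_, nrow(x), 6 * n_features)
  col <- 1L
  for (d in 1:6) {
    for (l in 0:(n_oct - 1)) {
      a <- (2 ^ l) * pi * x[, d]
      out[, col] <- sin(a)
      out[, col + 1L] <- cos(a)
      col <- col + 2L
    }
  }
  out
}

# layer input widths implied by a config
layer_dims <- function(cfg) {
  ew <- embed_width(cfg)
  widths <- c(cfg$hidden, 2L * cfg$n_freq_bins)
  ins <- integer(length(widths))
  prev <- ew
  for (i in seq_along(widths)) {
    ins[i] <- prev + if (i %in% cfg$skip_at) ew else 0L
    prev <- widths[i]
  }
  # layer 1 always consumes the embedding itself
  ins[1] <- ew + if (1L %in% cfg$skip_at) ew else 0L
  list(ins = ins, outs = widths)
}

#' Initialize reflectivity-field parameters
#'
#' He-style seeded Gaussian initialization (`sd = sqrt(2 / fan_in)`) of all
#' layer weights; biases start at zero. With the default architecture the
#' total learnable parameter count is about 4.6e5.
#'
#' @param config a [field_config()].
#' @return Object of class `sono_field`: lists `W`, `b` per layer plus the
#'   config and a metadata list.
#' @export
init_field <- function(config = field_config()) {
  dims <- layer_dims(config)
  params <- with_seed(config$seed, {
    W <- lapply(seq_along(dims$ins), function(i)
      matrix(stats::rnorm(dims$ins[i] * dims$outs[i], sd = sqrt(2 / dims$ins[i])),
             dims$ins[i], dims$outs[i]))
    b <- lapply(dims$outs, function(o) rep(0, o))
    list(W = W, b = b)
  })
  structure(list(W = params$W, b = params$b, config = config,
                 meta = list(epochs_trained = 0L, loss_curve = numeric(0),
                             seeds = list(init = config$seed))),
            class = "sono_field")
}

#' @export
print.sono_field <- function(x, ...) {
  cat(sprintf("reflectivity field: %d inputs -> [%s] -> %d outputs (%d complex bins), %d parameters\n",
              embed_width(x$config), paste(x$config$hidden, collapse = ", "),
              2 * x$config$n_freq_bins, x$config$n_freq_bins, n_params(x)))
  if (x$meta$epochs_trained > 0)
    cat(sprintf("  trained %d epochs, final mean loss %.3g\n",
                x$meta$epochs_trained, utils::tail(x$meta$loss_curve, 1)))
  invisible(x)
}

#' Total learnable parameter count of a field
#' @param field a `sono_field`.
#' @return integer.
#' @export
n_params <- function(field) {
  sum(vapply(field$W, length, numeric(1))) +
    sum(vapply(field$b, length, numeric(1)))
}

leaky_relu <- function(z, slope) z * (slope + (1 - slope) * (z > 0))

# forward pass on an embedded batch E [n x 180]; returns output and
# (optionally) the per-layer inputs and pre-activations for backprop
mlp_forward <- function(field, E, keep_cache = FALSE) {
  cfg <- field$config
  nl <- length(field$W)
  h <- E
  cache <- if (keep_cache) vector("list", nl) else NULL
  for (i in seq_len(nl)) {
    inp <- if (i %in% cfg$skip_at && i > 1L) cbind(h, E) else h
    if (i == 1L && 1L %in% cfg$skip_at) inp <- cbind(h, E)
    z <- inp %*% field$W[[i]]
    z <- z + rep(field$b[[i]], each = nrow(z))
    if (keep_cache) cache[[i]] <- list(inp = inp, z = z)
    h <- if (i < nl) leaky_relu(z, cfg$leaky_slope) else z
  }
  list(out = h, cache = cache)
}

# backward pass: dOut [n x 2*nb] -> gradients for every W and b
mlp_backward <- function(field, cache, dOut) {
  cfg <- field$config
  nl <- length(field$W)
  ew <- embed_width(cfg)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  delta <- dOut
  for (i in rev(seq_len(nl))) {
    inp <- cache[[i]]$inp
    gW[[i]] <- crossprod(inp, delta)
    gb[[i]] <- colSums(delta)
    if (i > 1L) {
      dInp <- tcrossprod(delta, field$W[[i]])
      # drop the embedding block if this layer had a skip concat
      if (i %in% cfg$skip_at) dInp <- dInp[, seq_len(ncol(inp) - ew), drop = FALSE]
      zprev <- cache[[i - 1L]]$z
      delta <- dInp * (cfg$leaky_slope + (1 - cfg$leaky_slope) * (zprev > 0))
    }
  }
  list(W = gW, b = gb)
}

#' Evaluate the reflectivity field at world positions and directions
#'
#' Positions are normalized to `[-1, 1]` by the scene bounds before
#' embedding; directions must be unit vectors (pointing from the sensor
#' toward the queried point). The raw 94-value network output is decoded as
#' 47 real parts followed by 47 imaginary parts.
#'
#' @param field a `sono_field`.
#' @param positions `n x 3` world positions, meters.
#' @param directions `n x 3` unit ensonification directions.
#' @param bounds 2x3 scene bounding box `rbind(min, max)`.
#' @return complex matrix `n x n_freq_bins`. Queries outside twice the scene
#'   bounds are evaluated but flagged via `attr(, "extrapolated")`.
#' @export
eval_field <- function(field, positions, directions, bounds) {
  positions <- as_point_matrix(positions)
  directions <- as_point_matrix(directions)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("eval_field: directions must be unit vectors")
  np <- normalize_positions(positions, bounds)
  extra <- abs(np) > 2
  E <- fourier_embed(cbind(np, directions), field$config$embed_features)
  out <- mlp_forward(field, E)$out
  nb <- field$config$n_freq_bins
  res <- matrix(complex(real = out[, seq_len(nb)],
                        imaginary = out[, nb + seq_len(nb)]),
                nrow(out), nb)
  if (any(extra)) attr(res, "extrapolated") <- which(rowSums(extra) > 0)
  res
}

normalize_positions <- function(positions, bounds) {
  lo <- bounds[1, ]; hi <- bounds[2, ]
  span <- pmax(hi - lo, 1e-12)
  sweep(sweep(positions, 2, lo, "-"), 2, span, "/") * 2 - 1
}

#' Save / load reflectivity-field parameters
#'
#' Single-file container holding the weights, biases, architecture config and
#' training metadata; round-trips exactly.
#'
#' @param field a `sono_field`.
#' @param path file path.
#' @return `read_field` returns the `sono_field`; `write_field` returns
#'   `path` invisibly.
#' @export
write_field <- function(field, path) {
  saveRDS(field, path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  f <- readRDS(path)
  if (!inherits(f, "sono_field")) stop("read_field: not a reflectivity-field file")
  f
}
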