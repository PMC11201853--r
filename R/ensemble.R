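#' Simulate a training ensemble of (pose, spectrogram) pairs
#'
#' Runs the echo simulator and the preprocessing pipeline for every pose and
#' assembles the observations with one shared compression reference (the
#' maximum pre-compression magnitude across the whole ensemble) so all
#' spectrograms live on a common `[0, 1]` scale.
#'
#' @param scene a [scene()].
#' @param poses list of [pose()] (e.g. from [pose_sphere()]).
#' @param call a [make_call()].
#' @param ertf an [ertf_model()].
#' @param sim_cfg a [sim_config()].
#' @param obs_cfg an [obs_config()].
#' @param ref compression reference amplitude; `NULL` (default) uses this
#'   ensemble's maximum pre-compression magnitude. Paired scenes (e.g. leaf
#'   with/without insect) should share one reference so their volumes are
#'   directly comparable.
#' @param verbose print progress?
#' @return Object of class `sono_ensemble`: `poses`, `spectrograms` (array
#'   `[2 n_bins x N_t x n_poses]`), `freqs`, `times`, `ranges`, `meta`
#'   (call, ERTF, configs, compression reference, scene bounds).
#' @export
simulate_ensemble <- function(scene, poses, call, ertf,
                              sim_cfg = sim_config(), obs_cfg = obs_config(),
                              ref = NULL, verbose = FALSE) {
  stopifnot(length(poses) >= 1)
  raws <- vector("list", length(poses))
  for (i in seq_along(poses)) {
    echo <- simulate_echo(scene, poses[[i]], call, ertf, sim_cfg)
    raws[[i]] <- observation_magnitude(echo, call, obs_cfg)
    if (verbose && i %% 25 == 0)
      message("simulated ", i, "/", length(poses), " ensonifications")
  }
  if (is.null(ref))
    ref <- max(vapply(raws, function(r) max(r$values), numeric(1)))
  if (ref <= 0) ref <- 1
  nt <- ncol(raws[[1]]$values)
  sp <- array(NA_real_, c(nrow(raws[[1]]$values), nt, length(poses)))
  for (i in seq_along(raws))
    sp[, , i] <- compress(raws[[i]]$values, obs_cfg, ref)
  structure(list(poses = poses, spectrograms = sp,
                 freqs = raws[[1]]$freqs, times = raws[[1]]$times,
                 ranges = raws[[1]]$ranges,
                 meta = list(call = call, ertf = ertf, sim_config = sim_cfg,
                             obs_config = obs_cfg, ref = ref,
                             bounds = scene$bounds,
                             norm_bounds = ensonified_bounds(poses,
                                                             sim_cfg$max_range),
                             scene_name = scene$name,
                             v_s = sim_cfg$v_s)),
            class = "sono_ensemble")
}

#' @export
print.sono_ensemble <- function(x, ...) {
  d <- dim(x$spectrograms)
  cat(sprintf("training ensemble '%s': %d poses, spectrograms %d x %d (%d slices total)\n",
              x$meta$scene_name, d[3], d[1], d[2], d[2] * d[3]))
  invisible(x)
}

# Axis-aligned box containing every point any training hemisphere can reach:
# all pose positions dilated by the maximum range. Used to normalize field
# positions before the Fourier embedding, so every query the renderer makes
# lies inside [-1, 1] and the octave features stay coherent; the (much
# tighter) scene bounds would alias distant hemisphere points into
# high-octave noise.
ensonified_bounds <- function(poses, max_range) {
  pos <- do.call(rbind, lapply(poses, function(p) p$position))
  rbind(apply(pos, 2, min) - max_range, apply(pos, 2, max) + max_range)
}

#' Save / load a training ensemble
#' @param ensemble a `sono_ensemble`.
#' @param path file path.
#' @return `read_ensemble` returns the ensemble; `write_ensemble` returns
#'   `path` invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  e <- readRDS(path)
  if (!inherits(e, "sono_ensemble")) stop("read_ensemble: not an ensemble file")
  e
}
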