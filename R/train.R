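#' Training control parameters
#'
#' Optimizer and sampling settings for fitting a reflectivity field. The
#' training unit is one spectrogram range slice: each epoch shuffles all
#' (pose, range-column) pairs, forms minibatches, renders them through the
#' acoustic rendering equation and takes an Adam step on the mean squared
#' error between rendered and measured compressed spectra; the learning rate
#' is multiplied by `lr_drop` after every epoch.
#'
#' @param batch_size slices per minibatch.
#' @param lr initial Adam learning rate.
#' @param lr_drop multiplicative learning-rate factor applied per epoch.
#' @param epochs number of epochs.
#' @param seed integer seed governing shuffling (parameter initialization is
#'   governed by the field config seed).
#' @param n_hemisphere hemisphere points per rendered slice (default 600).
#' @param checkpoint_every write a resumable checkpoint every this many
#'   epochs (0 disables).
#' @param checkpoint_dir directory for checkpoints.
#' @param verbose print per-epoch progress?
#' @return Object of class `sono_traincontrol`.
#' @export
train_control <- function(batch_size = 512, lr = 0.01, lr_drop = 0.97,
                          epochs = 100, seed = 1L, n_hemisphere = 600,
                          checkpoint_every = 0L, checkpoint_dir = NULL,
                          verbose = FALSE) {
  stopifnot(batch_size >= 1, lr > 0, lr_drop > 0, lr_drop <= 1, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 lr_drop = lr_drop, epochs = as.integer(epochs),
                 seed = as.integer(seed), n_hemisphere = as.integer(n_hemisphere),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir, verbose = isTRUE(verbose)),
            class = "sono_traincontrol")
}

# Rescale the freshly initialized output layer so the median rendered
# magnitude sits in the active region of the compression map (about -20 dB
# relative to the ensemble reference). Without this the hard floor clip can
# start every rendered value below the floor, where the compression gradient
# is exactly zero and no learning takes place. Deterministic: probes a fixed
# subsample of slices.
calibrate_output_scale <- function(field, ctx, slice_pose, slice_r,
                                   target_db = -20) {
  idx <- unique(round(seq(1, length(slice_r), length.out = 64)))
  fw <- render_forward(field, ctx, slice_pose[idx], slice_r[idx])
  m0 <- stats::median(fw$magnitude[fw$magnitude > 0])
  if (!is.finite(m0) || m0 <= 0) return(field)
  s <- ctx$ref * 10 ^ (target_db / 20) / m0
  nl <- length(field$W)
  field$W[[nl]] <- field$W[[nl]] * s
  field$b[[nl]] <- field$b[[nl]] * s
  field
}

adam_init <- function(field) {
  list(mW = lapply(field$W, function(w) w * 0),
       vW = lapply(field$W, function(w) w * 0),
       mb = lapply(field$b, function(b) b * 0),
       vb = lapply(field$b, function(b) b * 0),
       t = 0L)
}

adam_step <- function(field, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1 ^ state$t
  c2 <- 1 - beta2 ^ state$t
  for (i in seq_along(field$W)) {
    state$mW[[i]] <- beta1 * state$mW[[i]] + (1 - beta1) * grads$W[[i]]
    state$vW[[i]] <- beta2 * state$vW[[i]] + (1 - beta2) * grads$W[[i]]^2
    field$W[[i]] <- field$W[[i]] -
      lr * (state$mW[[i]] / c1) / (sqrt(state$vW[[i]] / c2) + eps)
    state$mb[[i]] <- beta1 * state$mb[[i]] + (1 - beta1) * grads$b[[i]]
    state$vb[[i]] <- beta2 * state$vb[[i]] + (1 - beta2) * grads$b[[i]]^2
    field$b[[i]] <- field$b[[i]] -
      lr * (state$mb[[i]] / c1) / (sqrt(state$vb[[i]] / c2) + eps)
  }
  list(field = field, state = state)
}

#' Fit a neural reflectivity field to an echolocation training ensemble
#'
#' The main fitting function. Learns a reflectivity field: a neural network
#' mapping (world position, ensonification direction) to a complex reflection
#' spectrum over the call band, such that rendering the field through the
#' acoustic rendering equation reproduces the measured dechirped binaural
#' spectrograms at the training poses. Training minimizes the per-slice mean
#' squared error with Adam; gradients flow through the full rendering
#' pipeline (hemisphere integration, ERTF weighting, magnitude, compression)
#' by analytic backpropagation. All slices are used for fitting (no
#' validation split, the usual practice for radiance-field models);
#' evaluation poses should be generated separately.
#'
#' @param ensemble a [simulate_ensemble()] result (or an ensemble of measured
#'   observations with the same structure).
#' @param field a [field_config()], or an existing `sono_field` to continue
#'   training.
#' @param control a [train_control()].
#' @param resume path to (or object of) a checkpoint written during a
#'   previous run; training continues exactly where it stopped.
#' @return Object of class `sononerf`: the fitted model, with elements
#'   `field` (the trained `sono_field`), `loss` (per-epoch mean training
#'   loss), `lr` (per-epoch learning rate), `control`, and `meta`
#'   (rendering/compression metadata inherited from the ensemble).
#' @seealso [predict.sononerf()], [reconstruct()], [render_slice()]
#' @export
sononerf <- function(ensemble, field = field_config(),
                     control = train_control(), resume = NULL) {
  stopifnot(inherits(ensemble, "sono_ensemble"))
  meta <- ensemble$meta
  d <- dim(ensemble$spectrograms)
  nt <- d[2]; P <- d[3]
  ctx <- render_context(ensemble$poses, meta$call, meta$ertf,
                        control$n_hemisphere, meta$obs_config, meta$ref,
                        meta$v_s,
                        if (is.null(meta$norm_bounds)) meta$bounds else meta$norm_bounds,
                        embed_features = if (inherits(field, "sono_field"))
                          field$config$embed_features else field$embed_features)
  meas <- matrix(ensemble$spectrograms, d[1], nt * P)
  start_epoch <- 1L
  loss_curve <- numeric(0)
  lr_curve <- numeric(0)
  if (!is.null(resume)) {
    ck <- if (is.character(resume)) readRDS(resume) else resume
    fld <- ck$field
    adam <- ck$adam
    start_epoch <- ck$epoch + 1L
    loss_curve <- ck$loss
    lr_curve <- ck$lr
    rng <- ck$rng
  } else {
    fld <- if (inherits(field, "sono_field")) field else init_field(field)
    adam <- adam_init(fld)
    rng <- NULL
  }
  if (2L * fld$config$n_freq_bins != d[1])
    stop("sononerf: ensemble has ", d[1], " spectrogram rows but the field ",
         "outputs ", 2L * fld$config$n_freq_bins)
  slice_pose <- rep(seq_len(P), each = nt)
  slice_col <- rep(seq_len(nt), P)
  slice_r <- ensemble$ranges[slice_col]
  total <- nt * P
  if (is.null(resume) && fld$meta$epochs_trained == 0L)
    fld <- calibrate_output_scale(fld, ctx, slice_pose, slice_r)
  run <- function() {
    if (start_epoch > control$epochs) return(invisible())
    for (epoch in start_epoch:control$epochs) {
      lr <- control$lr * control$lr_drop ^ (epoch - 1)
      perm <- sample.int(total)
      bounds_idx <- split(perm, ceiling(seq_along(perm) / control$batch_size))
      esum <- 0
      for (bi in bounds_idx) {
        fw <- render_forward(fld, ctx, slice_pose[bi], slice_r[bi],
                             keep_cache = TRUE)
        y <- t(meas[, (slice_pose[bi] - 1L) * nt + slice_col[bi], drop = FALSE])
        diffm <- fw$compressed - y
        bloss <- mean(diffm^2)
        if (!is.finite(bloss))
          stop("sononerf: non-finite loss at epoch ", epoch,
               " (lr = ", signif(lr, 3), "); diagnostic state: ",
               "batch size ", length(bi), ", max |param| ",
               signif(max(vapply(fld$W, function(w) max(abs(w)), numeric(1))), 3))
        esum <- esum + bloss * length(bi)
        dC <- 2 * diffm / length(diffm)
        grads <- render_backward(fld, ctx, fw, dC)
        st <- adam_step(fld, grads, adam, lr)
        fld <<- st$field
        adam <<- st$state
      }
      loss_curve <<- c(loss_curve, esum / total)
      lr_curve <<- c(lr_curve, lr)
      if (control$verbose)
        message(sprintf("epoch %d/%d: mean loss %.5g (lr %.4g)",
                        epoch, control$epochs, esum / total, lr))
      if (control$checkpoint_every > 0 &&
          epoch %% control$checkpoint_every == 0 &&
          !is.null(control$checkpoint_dir)) {
        dir.create(control$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(list(field = fld, adam = adam, epoch = epoch,
                     loss = loss_curve, lr = lr_curve,
                     rng = get(".Random.seed", envir = globalenv())),
                file.path(control$checkpoint_dir,
                          sprintf("checkpoint_epoch%03d.rds", epoch)))
      }
    }
  }
  if (!is.null(rng)) {
    # resume: restore the exact RNG stream of the interrupted run
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", rng, envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    run()
  } else {
    with_seed(control$seed, run())
  }
  fld$meta$epochs_trained <- length(loss_curve)
  fld$meta$loss_curve <- loss_curve
  fld$meta$bounds <- meta$bounds
  fld$meta$norm_bounds <- if (is.null(meta$norm_bounds)) meta$bounds else meta$norm_bounds
  fld$meta$seeds$shuffle <- control$seed
  structure(list(field = fld, loss = loss_curve, lr = lr_curve,
                 control = control,
                 meta = c(meta[c("call", "ertf", "obs_config", "ref",
                                 "bounds", "v_s", "scene_name")],
                          list(norm_bounds = if (is.null(meta$norm_bounds))
                                 meta$bounds else meta$norm_bounds,
                               n_poses = P, n_slices = total,
                               ranges = ensemble$ranges,
                               times = ensemble$times))),
            class = "sononerf")
}

#' @export
print.sononerf <- function(x, ...) {
  cat(sprintf("sononerf model: scene '%s', %d poses, %d slices\n",
              x$meta$scene_name, x$meta$n_poses, x$meta$n_slices))
  cat(sprintf("  field: %d parameters; trained %d epochs, loss %.4g -> %.4g\n",
              n_params(x$field), length(x$loss),
              if (length(x$loss)) x$loss[1] else NA, utils::tail(x$loss, 1)))
  invisible(x)
}

#' @export
summary.sononerf <- function(object, ...) {
  print(object)
  cat(sprintf("  hemisphere points per slice: %d; batch size %d; lr %.3g (drop %.3g/epoch)\n",
              object$control$n_hemisphere, object$control$batch_size,
              object$control$lr, object$control$lr_drop))
  cat(sprintf("  compression reference: %.4g; band %.0f-%.0f kHz in %d bins\n",
              object$meta$ref, object$meta$call$f_lo / 1e3,
              object$meta$call$f_hi / 1e3, object$meta$call$band_bins))
  invisible(object)
}

#' @export
coef.sononerf <- function(object, ...) {
  list(W = object$field$W, b = object$field$b)
}

#' Predict dechirped binaural spectrograms at new poses
#'
#' Renders the fitted reflectivity field through the acoustic rendering
#' equation at each requested pose, producing spectrograms on the training
#' range axis (or a supplied one) — the model's answer to "what would this
#' scene sound like from there?".
#'
#' @param object a fitted [sononerf()] model.
#' @param poses a [pose()] or list of poses.
#' @param ranges range axis, meters (defaults to the training axis).
#' @param ... unused.
#' @return a `sono_spectrogram` for a single pose, else a list of them.
#' @export
predict.sononerf <- function(object, poses, ranges = object$meta$ranges, ...) {
  single <- inherits(poses, "sono_pose")
  if (single) poses <- list(poses)
  out <- lapply(poses, function(p)
    render_spectrogram(object$field, p, ranges, object$meta$ertf,
                       object$meta$call,
                       n_hemisphere = object$control$n_hemisphere,
                       obs_cfg = object$meta$obs_config,
                       ref = object$meta$ref,
                       v_s = object$meta$v_s,
                       bounds = object$meta$norm_bounds))
  if (single) out[[1]] else out
}

#' @export
plot.sononerf <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "b", log = "y",
                 xlab = "epoch", ylab = "mean slice loss",
                 main = "training loss", ...)
  invisible(x)
}

#' @export
residuals.sononerf <- function(object, ensemble, ...) {
  stopifnot(inherits(ensemble, "sono_ensemble"))
  pred <- predict(object, ensemble$poses, ranges = ensemble$ranges)
  lapply(seq_along(pred), function(i)
    ensemble$spectrograms[, , i] - pred[[i]]$values)
}
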