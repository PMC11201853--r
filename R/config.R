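#' Default run configuration for the command-line pipeline
#'
#' Nested configuration mirroring the call, simulation, observation, ERTF,
#' field-architecture, training and reconstruction settings, plus one global
#' seed that is expanded into per-stage seeds by fixed offsets (so every
#' stage is independently reproducible from the one number).
#'
#' @return nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    call = list(f_hi = 100e3, f_lo = 40e3, duration = 1e-3, law = "linear",
                sample_rate = 400e3, band_bins = 47L),
    sim = list(v_s = 343, max_range = 0.6, spreading = TRUE, noise_floor = 0),
    obs = list(window_len = 64L, overlap = 0.9375, floor_db = -60,
               ceiling_db = 0, epsilon = 1e-6),
    ertf = list(a_emitter = 0.004, a_ear = 0.006, ear_y = 0.007,
                ear_z = 0.005, ear_azimuth_deg = 15),
    poses = list(n = 100L, radius = 0.45, center = c(0, 0, 0)),
    field = list(n_freq_bins = 47L, embed_features = 30L,
                 hidden = c(256L, 256L, 256L, 256L, 280L, 256L),
                 skip_at = 5L, leaky_slope = 0.01),
    train = list(batch_size = 512L, lr = 0.01, lr_drop = 0.97, epochs = 100L,
                 n_hemisphere = 600L, checkpoint_every = 0L),
    recon = list(voxel_size = 0.005, n_directions = 100L,
                 threshold_frac = 0.5)
  )
}

# seed offsets per pipeline stage
stage_seed <- function(cfg, stage) {
  off <- c(poses = 101L, scene = 211L, sim = 307L, field = 401L,
           train = 503L)
  as.integer(cfg$seed) + off[[stage]]
}

#' Load, override and validate a run configuration
#'
#' Starts from [default_run_config()], merges an optional YAML file, then
#' applies `key=value` overrides in dotted-path form (e.g.
#' `train.epochs=20`). Unknown keys are rejected.
#'
#' @param yaml_path optional YAML file with (a subset of) the configuration.
#' @param sets character vector of `path.to.key=value` overrides.
#' @return validated configuration list.
#' @export
load_run_config <- function(yaml_path = NULL, sets = character(0)) {
  cfg <- default_run_config()
  if (!is.null(yaml_path)) {
    if (!file.exists(yaml_path)) stop("config file not found: ", yaml_path)
    user <- yaml::read_yaml(yaml_path)
    cfg <- merge_config(cfg, user, path = "")
  }
  for (s in sets) {
    kv <- strsplit(s, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad --set (expected key=value): ", s)
    cfg <- set_config_path(cfg, strsplit(kv[1], ".", fixed = TRUE)[[1]], kv[2])
  }
  validate_run_config(cfg)
  cfg
}

merge_config <- function(base, user, path) {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]])) stop("config key ", full, " must be a mapping")
      base[[k]] <- merge_config(base[[k]], user[[k]], full)
    } else {
      base[[k]] <- coerce_like(base[[k]], user[[k]], full)
    }
  }
  base
}

set_config_path <- function(cfg, keys, value) {
  if (length(keys) == 1) {
    if (!keys %in% names(cfg)) stop("unknown config key: ", keys)
    cfg[[keys]] <- coerce_like(cfg[[keys]], value, keys)
  } else {
    if (!keys[1] %in% names(cfg)) stop("unknown config key: ", keys[1])
    cfg[[keys[1]]] <- set_config_path(cfg[[keys[1]]], keys[-1], value)
  }
  cfg
}

coerce_like <- function(old, new, key) {
  if (is.numeric(old)) {
    v <- if (is.character(new)) as.numeric(strsplit(new, ",")[[1]]) else as.numeric(unlist(new))
    if (any(is.na(v))) stop("config key ", key, " must be numeric")
    if (is.integer(old)) v <- as.integer(v)
    v
  } else if (is.logical(old)) {
    as.logical(new)
  } else {
    as.character(new)
  }
}

validate_run_config <- function(cfg) {
  with(cfg, {
    stopifnot(call$f_hi > call$f_lo, call$f_lo > 0,
              call$sample_rate > 2 * call$f_hi,
              sim$v_s > 0, sim$max_range > 0,
              obs$ceiling_db > obs$floor_db, obs$epsilon > 0,
              poses$n >= 1, poses$radius > 0,
              train$batch_size >= 1, train$lr_drop > 0, train$lr_drop <= 1,
              recon$voxel_size > 0)
  })
  invisible(cfg)
}

#' Instantiate pipeline objects from a run configuration
#'
#' @param cfg a validated configuration from [load_run_config()].
#' @return list with `call`, `ertf`, `sim_cfg`, `obs_cfg`, `field_cfg`,
#'   `train_ctl` ready to pass to the pipeline functions.
#' @export
build_run_objects <- function(cfg) {
  a <- cfg$ertf$ear_azimuth_deg * pi / 180
  list(
    call = make_call(cfg$call$f_hi, cfg$call$f_lo, cfg$call$duration,
                     cfg$call$law, cfg$call$sample_rate, cfg$call$band_bins),
    ertf = ertf_model(cfg$ertf$a_emitter, cfg$ertf$a_ear,
                      rbind(c(0, cfg$ertf$ear_y, cfg$ertf$ear_z),
                            c(0, -cfg$ertf$ear_y, cfg$ertf$ear_z)),
                      c(a, -a), cfg$sim$v_s),
    sim_cfg = sim_config(cfg$sim$v_s, cfg$sim$max_range, cfg$sim$spreading,
                         cfg$sim$noise_floor, stage_seed(cfg, "sim")),
    obs_cfg = obs_config(cfg$obs$window_len, cfg$obs$overlap,
                         floor_db = cfg$obs$floor_db,
                         ceiling_db = cfg$obs$ceiling_db,
                         epsilon = cfg$obs$epsilon),
    field_cfg = field_config(cfg$field$n_freq_bins, cfg$field$embed_features,
                             cfg$field$hidden, cfg$field$skip_at,
                             cfg$field$leaky_slope,
                             seed = stage_seed(cfg, "field")),
    train_ctl = train_control(cfg$train$batch_size, cfg$train$lr,
                              cfg$train$lr_drop, cfg$train$epochs,
                              seed = stage_seed(cfg, "train"),
                              n_hemisphere = cfg$train$n_hemisphere,
                              checkpoint_every = cfg$train$checkpoint_every)
  )
}
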