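#' Point-scatterer scenes
#'
#' A scene is an ordered collection of point-like reflectors (a Huygens
#' approximation of surfaces), each with a position, a nonnegative gain and
#' optionally a per-frequency complex reflection spectrum over the call band
#' and/or a directional lobe. Scenes carry an axis-aligned bounding box used
#' for field-input normalization and reconstruction grids.
#'
#' @param positions numeric matrix `n x 3` of scatterer positions (meters).
#' @param gain numeric vector of nonnegative gains (recycled to `n`).
#' @param spectra optional complex matrix `n x band_bins` of per-frequency
#'   reflection coefficients over the call band; `NULL` means flat.
#' @param lobe_axis optional `n x 3` matrix of lobe axes (rows may be `NA`
#'   for isotropic scatterers).
#' @param lobe_exponent numeric vector of lobe exponents (cosine-power lobes).
#' @param name scene label.
#' @param bounds optional 2x3 matrix `rbind(min, max)`; computed from the
#'   scatterers (with a small margin) when omitted.
#' @return Object of class `sono_scene`.
#' @export
scene <- function(positions, gain = 1, spectra = NULL, lobe_axis = NULL,
                  lobe_exponent = 1, name = "scene", bounds = NULL) {
  positions <- as_point_matrix(positions)
  dimnames(positions) <- NULL
  n <- nrow(positions)
  if (n < 1) stop("scene: scatterer count must be >= 1")
  gain <- rep_len(as.numeric(gain), n)
  if (any(gain < 0)) stop("scene: gain must be >= 0")
  if (!is.null(spectra)) {
    spectra <- as.matrix(spectra)
    if (nrow(spectra) != n) stop("scene: spectra must have one row per scatterer")
  }
  if (!is.null(lobe_axis)) {
    lobe_axis <- as_point_matrix(lobe_axis)
    stopifnot(nrow(lobe_axis) == n)
  }
  lobe_exponent <- rep_len(as.numeric(lobe_exponent), n)
  if (is.null(bounds)) {
    margin <- 0.005
    bounds <- rbind(apply(positions, 2, min) - margin,
                    apply(positions, 2, max) + margin)
  }
  bounds <- matrix(as.numeric(bounds), 2, 3)
  if (any(positions < rep(bounds[1, ], each = n)) ||
      any(positions > rep(bounds[2, ], each = n)))
    stop("scene: bounds must contain every scatterer position")
  structure(list(name = name, positions = positions, gain = gain,
                 spectra = spectra, lobe_axis = lobe_axis,
                 lobe_exponent = lobe_exponent, bounds = bounds),
            class = "sono_scene")
}

#' @export
print.sono_scene <- function(x, ...) {
  cat(sprintf("scene '%s': %d scatterers, bounds [%.3f..%.3f, %.3f..%.3f, %.3f..%.3f] m\n",
              x$name, nrow(x$positions),
              x$bounds[1, 1], x$bounds[2, 1], x$bounds[1, 2], x$bounds[2, 2],
              x$bounds[1, 3], x$bounds[2, 3]))
  invisible(x)
}

n_scatterers <- function(s) nrow(s$positions)

# Deterministic quasi-uniform sampling of a sphere surface as point scatterers.
sphere_surface_points <- function(center, diameter, n, seed = 1L) {
  u <- fibonacci_sphere(n, phase = golden_phase(seed))
  sweep(u * (diameter / 2), 2, center, "+")
}

#' Built-in scene: three spheres in an L-shaped configuration
#'
#' Three sphere surfaces (default diameter 3 cm) whose centers form an L:
#' one corner sphere and one sphere along each of two perpendicular arms.
#' Surfaces are sampled as point scatterers on a deterministic lattice.
#'
#' @param diameter sphere diameter, meters.
#' @param spacing center-to-center arm length, meters.
#' @param points_per_sphere scatterers per sphere surface (>= 4).
#' @param seed integer lattice phase.
#' @return `sono_scene` with `3 * points_per_sphere` scatterers.
#' @export
build_three_spheres <- function(diameter = 0.03, spacing = 0.05,
                                points_per_sphere = 64, seed = 1L) {
  if (diameter <= 0) stop("build_three_spheres: diameter must be positive")
  if (points_per_sphere < 4) stop("build_three_spheres: points_per_sphere must be >= 4")
  centers <- rbind(c(0, 0, 0), c(spacing, 0, 0), c(0, 0, spacing))
  centers <- sweep(centers, 2, colMeans(centers), "-")
  pts <- do.call(rbind, lapply(seq_len(3), function(i)
    sphere_surface_points(centers[i, ], diameter, points_per_sphere, seed + i)))
  s <- scene(pts, name = "three-spheres-L")
  attr(s, "cluster_centers") <- centers
  attr(s, "cluster_id") <- rep(seq_len(3), each = points_per_sphere)
  s
}

# Cluster-center layout of the "UA" letters on a unit grid (u = horizontal,
# v = vertical); 7 spheres form the U and 12 the A.
ua_letter_grid <- function() {
  u_letter <- cbind(c(0, 0, 0, 1, 2, 2, 2), c(2, 1, 0, 0, 0, 1, 2))
  a_letter <- cbind(c(4, 4, 4, 4, 6, 6, 6, 6, 4, 5, 6, 5),
                    c(0, 1, 2, 3, 0, 1, 2, 3, 4, 4, 4, 1))
  rbind(u_letter, a_letter)
}

#' Built-in scene: 19 spheres forming the letters "UA"
#'
#' Nineteen sphere clusters laid out on the strokes of a blocky "U" and "A"
#' in the world Y-Z plane (letters facing +X), centered at the origin.
#'
#' @param pitch grid pitch between neighboring sphere centers, meters.
#' @param diameter sphere diameter, meters.
#' @param points_per_sphere scatterers per sphere surface.
#' @param seed integer lattice phase.
#' @return `sono_scene` with 19 sphere clusters.
#' @export
build_ua_scene <- function(pitch = 0.025, diameter = 0.02,
                           points_per_sphere = 48, seed = 1L) {
  g <- ua_letter_grid()
  centers <- cbind(0, (g[, 1] - 3) * pitch, (g[, 2] - 2) * pitch)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sphere_surface_points(centers[i, ], diameter, points_per_sphere, seed + i)))
  s <- scene(pts, name = "ua-letters")
  attr(s, "cluster_centers") <- centers
  attr(s, "cluster_id") <- rep(seq_len(nrow(centers)), each = points_per_sphere)
  s
}

# Deterministic sunflower (Fibonacci) lattice on a unit disc.
fibonacci_disc <- function(n, phase = 0) {
  i <- seq_len(n) - 1
  r <- sqrt((i + 0.5) / n)
  phi <- i * golden_angle + phase
  cbind(r * cos(phi), r * sin(phi))
}

#' Built-in scene: leaf, optionally with a perched insect
#'
#' A disc-shaped planar patch of scatterers (leaf analog, in the world Y-Z
#' plane facing +X), optionally carrying a compact, denser, higher-gain
#' scatterer cluster (insect analog) at a configurable on-leaf location. This
#' is the gleaning-bat scenario: localize motionless prey against the leaf by
#' differencing reconstructions with and without the insect.
#'
#' @param with_insect add the insect cluster?
#' @param leaf_radius leaf disc radius, meters.
#' @param n_leaf number of leaf scatterers.
#' @param insect_center insect cluster centroid (world, meters).
#' @param insect_radius cluster radius, meters.
#' @param n_insect number of insect scatterers.
#' @param insect_gain gain of insect scatterers (leaf gain is 1).
#' @param seed integer lattice phase.
#' @return `sono_scene`; the insect centroid is stored in
#'   `attr(, "insect_center")` when present.
#' @export
build_leaf_scene <- function(with_insect = FALSE, leaf_radius = 0.05,
                             n_leaf = 300,
                             insect_center = c(0.008, 0, 0),
                             insect_radius = 0.006, n_insect = 40,
                             insect_gain = 4, seed = 1L) {
  d <- fibonacci_disc(n_leaf, phase = golden_phase(seed))
  leaf <- cbind(0, d[, 1] * leaf_radius, d[, 2] * leaf_radius)
  pts <- leaf
  gain <- rep(1, n_leaf)
  if (with_insect) {
    u <- fibonacci_sphere(n_insect, phase = golden_phase(seed + 7))
    # fill the small cluster volume, not just its surface
    rr <- insect_radius * ((seq_len(n_insect) - 0.5) / n_insect)^(1 / 3)
    ins <- sweep(u * rr, 2, insect_center, "+")
    pts <- rbind(pts, ins)
    gain <- c(gain, rep(insect_gain, n_insect))
  }
  s <- scene(pts, gain = gain,
             name = if (with_insect) "leaf-with-insect" else "leaf")
  if (with_insect) attr(s, "insect_center") <- insect_center
  s
}

#' Save and load scenes as JSON
#'
#' The JSON schema stores one object per scatterer
#' (`xyz`, `gain`, optional `spectrum_real`/`spectrum_imag`, optional
#' `lobe_axis`/`lobe_exponent`) plus the scene `name` and `bounds`.
#' Round-trip reproduces positions to better than 1e-9 m.
#'
#' @param s a `sono_scene`.
#' @param path file path.
#' @return `load_scene` returns a `sono_scene`; `save_scene` returns `path`
#'   invisibly.
#' @export
save_scene <- function(s, path) {
  scat <- lapply(seq_len(n_scatterers(s)), function(i) {
    o <- list(xyz = s$positions[i, ], gain = s$gain[i])
    if (!is.null(s$spectra)) {
      o$spectrum_real <- Re(s$spectra[i, ])
      o$spectrum_imag <- Im(s$spectra[i, ])
    }
    if (!is.null(s$lobe_axis) && all(is.finite(s$lobe_axis[i, ]))) {
      o$lobe_axis <- s$lobe_axis[i, ]
      o$lobe_exponent <- s$lobe_exponent[i]
    }
    o
  })
  obj <- list(name = s$name, scatterers = scat,
              bounds = list(s$bounds[1, ], s$bounds[2, ]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_scene
#' @export
load_scene <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("load_scene: cannot parse '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(obj$scatterers) || length(obj$scatterers) == 0)
    stop("load_scene: field 'scatterers' missing or empty in '", path, "'")
  getv <- function(o, f) {
    v <- o[[f]]
    if (is.null(v)) return(NULL)
    as.numeric(unlist(v))
  }
  n <- length(obj$scatterers)
  pos <- matrix(NA_real_, n, 3)
  gain <- numeric(n)
  spectra <- NULL
  lobe_axis <- NULL
  lobe_exp <- rep(1, n)
  for (i in seq_len(n)) {
    o <- obj$scatterers[[i]]
    xyz <- getv(o, "xyz")
    if (is.null(xyz) || length(xyz) != 3)
      stop("load_scene: scatterer ", i, ": field 'xyz' missing or not length 3")
    pos[i, ] <- xyz
    gain[i] <- if (is.null(o$gain)) 1 else as.numeric(o$gain)
    sr <- getv(o, "spectrum_real")
    if (!is.null(sr)) {
      si <- getv(o, "spectrum_imag")
      if (is.null(si)) si <- rep(0, length(sr))
      if (is.null(spectra)) spectra <- matrix(1 + 0i, n, length(sr))
      if (ncol(spectra) != length(sr))
        stop("load_scene: scatterer ", i, ": field 'spectrum_real' length mismatch")
      spectra[i, ] <- complex(real = sr, imaginary = si)
    }
    la <- getv(o, "lobe_axis")
    if (!is.null(la)) {
      if (is.null(lobe_axis)) lobe_axis <- matrix(NA_real_, n, 3)
      lobe_axis[i, ] <- la
      if (!is.null(o$lobe_exponent)) lobe_exp[i] <- as.numeric(o$lobe_exponent)
    }
  }
  bounds <- NULL
  if (!is.null(obj$bounds))
    bounds <- rbind(as.numeric(unlist(obj$bounds[[1]])),
                    as.numeric(unlist(obj$bounds[[2]])))
  scene(pos, gain = gain, spectra = spectra, lobe_axis = lobe_axis,
        lobe_exponent = lobe_exp,
        name = if (is.null(obj$name)) "scene" else obj$name, bounds = bounds)
}

#' Convert a triangulated STL mesh to a point-scatterer scene
#'
#' Reads an ASCII or binary STL file and samples `n` points on its surface by
#' area-weighted triangle selection with uniform barycentric coordinates,
#' using a seeded generator (deterministic for a fixed seed).
#'
#' @param path STL file (ASCII or binary).
#' @param n number of surface samples.
#' @param gain scatterer gain.
#' @param seed integer RNG seed.
#' @param name scene label (defaults to the file name).
#' @return `sono_scene` with `n` scatterers.
#' @export
stl_to_scene <- function(path, n = 1000, gain = 1, seed = 1L, name = NULL) {
  tri <- read_stl(path)
  v1 <- tri[, 1:3, drop = FALSE]
  v2 <- tri[, 4:6, drop = FALSE]
  v3 <- tri[, 7:9, drop = FALSE]
  cr <- cross3(v2 - v1, v3 - v1)
  areas <- 0.5 * sqrt(rowSums(cr^2))
  if (sum(areas) <= 0) stop("stl_to_scene: mesh has zero total area")
  pts <- with_seed(seed, {
    idx <- sample.int(length(areas), n, replace = TRUE, prob = areas)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
    a <- 1 - r1
    b <- r1 * (1 - r2)
    cc <- r1 * r2
    v1[idx, , drop = FALSE] * a + v2[idx, , drop = FALSE] * b +
      v3[idx, , drop = FALSE] * cc
  })
  scene(pts, gain = gain,
        name = if (is.null(name)) basename(path) else name)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# evaluate expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
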