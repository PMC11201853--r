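#' Query a trained reflectivity field over a voxel grid
#'
#' Evaluates the field at every voxel center for a deterministic full-sphere
#' lattice of ensonification directions and stores, per (voxel, direction),
#' the reflected band energy: the squared magnitude of the complex spectrum
#' summed over the band bins. This is the directional reflectivity matrix
#' from which the energy volume and all visualizations derive.
#'
#' @param field a `sono_field` or fitted [sononerf()] model.
#' @param bounds 2x3 grid bounding box `rbind(min, max)`, meters; defaults
#'   to the scene bounds stored with the trained field.
#' @param voxel_size cubic voxel side, meters (desk-scale default 5 mm; the
#'   reference fine setting is 0.5 mm).
#' @param n_directions ensonification directions per voxel (default 100).
#' @param max_cells refuse grids whose `n_voxels * n_directions` exceeds
#'   this budget (with a size estimate in the error).
#' @param chunk voxels evaluated per internal batch.
#' @param norm_bounds box used to normalize positions before the Fourier
#'   embedding; defaults to the normalization bounds the field was trained
#'   with (falling back to `bounds`). Must match training.
#' @return Object of class `sono_voxelgrid`: `values` array
#'   `[nx x ny x nz x n_directions]`, `origin`, `voxel_size`, axis centers
#'   `x`, `y`, `z`, and the `directions` matrix.
#' @export
query_grid <- function(field, bounds = NULL, voxel_size = 0.005,
                       n_directions = 100, max_cells = 2e8, chunk = 20000L,
                       norm_bounds = NULL) {
  if (inherits(field, "sononerf")) field <- field$field
  if (is.null(bounds)) bounds <- field$meta$bounds
  if (is.null(bounds)) stop("query_grid: no bounds available")
  if (is.null(norm_bounds))
    norm_bounds <- if (!is.null(field$meta$norm_bounds)) field$meta$norm_bounds
                   else bounds
  stopifnot(voxel_size > 0)
  bounds <- matrix(as.numeric(bounds), 2, 3)
  nax <- pmax(1L, as.integer(ceiling((bounds[2, ] - bounds[1, ]) / voxel_size)))
  nv <- as.integer(n_directions)
  ncell <- prod(nax) * nv
  if (ncell > max_cells)
    stop(sprintf("query_grid: %d voxels x %d directions = %.3g cells exceeds the budget of %.3g; increase voxel_size",
                 prod(nax), nv, ncell, max_cells))
  ax <- lapply(1:3, function(d) bounds[1, d] + (seq_len(nax[d]) - 0.5) * voxel_size)
  centers <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                   KEEP.OUT.ATTRS = FALSE))
  dirs <- fibonacci_sphere(nv)
  nb <- field$config$n_freq_bins
  nvox <- nrow(centers)
  R <- matrix(NA_real_, nvox, nv)
  for (v in seq_len(nv)) {
    dmat <- matrix(dirs[v, ], nvox, 3, byrow = TRUE)
    for (s in split(seq_len(nvox), ceiling(seq_len(nvox) / chunk))) {
      spec <- eval_field(field, centers[s, , drop = FALSE],
                         dmat[s, , drop = FALSE], norm_bounds)
      R[s, v] <- rowSums(Mod(spec)^2)
    }
  }
  structure(list(values = array(R, c(nax, nv)), origin = bounds[1, ],
                 voxel_size = voxel_size, x = ax[[1]], y = ax[[2]],
                 z = ax[[3]], directions = dirs, bounds = bounds),
            class = "sono_voxelgrid")
}

#' Integrate a directional voxel grid over its direction dimension
#'
#' Sums the per-direction reflected energies at each voxel, yielding the
#' scalar energy volume used for isosurfaces, projections and paired-scene
#' differencing.
#'
#' @param grid a [query_grid()] result.
#' @return Object of class `sono_volume`: `values` array `[nx x ny x nz]`
#'   plus the grid frame.
#' @export
integrate_directions <- function(grid) {
  stopifnot(inherits(grid, "sono_voxelgrid"))
  d <- dim(grid$values)
  vol <- array(rowSums(matrix(grid$values, prod(d[1:3]), d[4])), d[1:3])
  structure(list(values = vol, origin = grid$origin,
                 voxel_size = grid$voxel_size, x = grid$x, y = grid$y,
                 z = grid$z, bounds = grid$bounds),
            class = "sono_volume")
}

#' Signed difference of two energy volumes
#'
#' Elementwise `a - b` on identical grids. Differencing the energy volumes of
#' a scene with and without a compact target (e.g. a leaf with and without a
#' perched insect) localizes the target against the shared background.
#'
#' @param a,b `sono_volume`s on the same grid.
#' @return a `sono_volume` with signed values.
#' @export
energy_difference <- function(a, b) {
  stopifnot(inherits(a, "sono_volume"), inherits(b, "sono_volume"))
  if (!all(dim(a$values) == dim(b$values)) ||
      max(abs(a$origin - b$origin)) > 1e-12 ||
      abs(a$voxel_size - b$voxel_size) > 1e-15)
    stop("energy_difference: volumes are on different grids")
  out <- a
  out$values <- a$values - b$values
  out
}

#' Maximum intensity projection of a volume
#'
#' Per-pixel maximum of the volume along one grid axis, optionally normalized
#' by a shared reference (for paired comparisons normalize both projections
#' to the joint maximum of the two volumes).
#'
#' @param volume a `sono_volume`.
#' @param axis projection axis: 1/2/3 or "x"/"y"/"z".
#' @param ref optional normalization reference; `NULL` leaves raw values.
#' @return list with `image` (matrix over the two remaining axes, in grid
#'   order), `axes` (names of the image axes), and `scale` (the reference
#'   used, or `NA`).
#' @export
max_intensity_projection <- function(volume, axis = "z", ref = NULL) {
  stopifnot(inherits(volume, "sono_volume"))
  if (is.character(axis)) axis <- match(tolower(axis), c("x", "y", "z"))
  if (!(axis %in% 1:3)) stop("max_intensity_projection: invalid axis")
  keep <- setdiff(1:3, axis)
  img <- apply(volume$values, keep, max)
  if (!is.null(ref) && ref > 0) img <- img / ref
  list(image = img, axes = c("x", "y", "z")[keep],
       scale = if (is.null(ref)) NA_real_ else ref)
}

# --- marching tetrahedra ----------------------------------------------------

# Kuhn split of the unit cube into 6 tetrahedra around the (0,0,0)-(1,1,1)
# diagonal; corners encoded as offset triples. Shared cube faces are split
# along the same diagonals in neighboring cubes, so surfaces are watertight.
kuhn_tets <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    v <- matrix(0, 4, 3)
    for (k in 1:3) {
      v[k + 1, ] <- v[k, ]
      v[k + 1, p[k]] <- 1
    }
    v
  })
})

# triangles (as triples of tet-edge ids) per inside-bitmask; edges are
# 1:e01 2:e02 3:e03 4:e12 5:e13 6:e23 over tet corners 0..3
tet_case_table <- local({
  tbl <- vector("list", 16)
  tri <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  tbl[[1 + 1]] <- tri(1, 2, 3)              # {0}
  tbl[[1 + 2]] <- tri(1, 5, 4)              # {1}
  tbl[[1 + 4]] <- tri(2, 4, 6)              # {2}
  tbl[[1 + 8]] <- tri(3, 6, 5)              # {3}
  tbl[[1 + 3]] <- tri(2, 4, 5, 2, 5, 3)     # {0,1}
  tbl[[1 + 5]] <- tri(1, 4, 6, 1, 6, 3)     # {0,2}
  tbl[[1 + 9]] <- tri(1, 5, 6, 1, 6, 2)     # {0,3}
  tbl[[1 + 6]] <- tbl[[1 + 9]]              # {1,2} (complement)
  tbl[[1 + 10]] <- tbl[[1 + 5]]             # {1,3}
  tbl[[1 + 12]] <- tbl[[1 + 3]]             # {2,3}
  tbl[[1 + 14]] <- tbl[[1 + 1]]             # {1,2,3}
  tbl[[1 + 13]] <- tbl[[1 + 2]]             # {0,2,3}
  tbl[[1 + 11]] <- tbl[[1 + 4]]             # {0,1,3}
  tbl[[1 + 7]] <- tbl[[1 + 8]]              # {0,1,2}
  tbl
})

#' Isosurface of an energy volume (marching tetrahedra)
#'
#' Extracts the triangle mesh of the level set at `threshold_frac` times the
#' volume maximum. Each grid cube is split into six tetrahedra (consistently
#' across cubes), surface-edge crossings are linearly interpolated, and
#' vertices shared between tetrahedra are merged, so the mesh of a smooth
#' closed level set is watertight.
#'
#' @param volume a `sono_volume`.
#' @param threshold_frac level as a fraction of `max(values)`, in (0, 1).
#' @return Object of class `sono_mesh`: `vertices` (`n x 3`, world meters),
#'   `faces` (`m x 3` integer), `level`. Empty mesh (0 faces) when nothing
#'   crosses the level; a flat volume yields an empty mesh with a warning.
#' @export
isosurface <- function(volume, threshold_frac = 0.5) {
  stopifnot(inherits(volume, "sono_volume"),
            threshold_frac > 0, threshold_frac < 1)
  vals <- volume$values
  vmax <- max(vals)
  vmin <- min(vals)
  empty <- structure(list(vertices = matrix(numeric(0), 0, 3),
                          faces = matrix(integer(0), 0, 3),
                          level = NA_real_), class = "sono_mesh")
  if (vmax == vmin) {
    warning("isosurface: flat volume (max == min); returning empty mesh")
    return(empty)
  }
  level <- threshold_frac * vmax
  d <- dim(vals)
  if (any(d < 2) || !any(vals > level)) {
    empty$level <- level
    return(empty)
  }
  # linear index of every cube's base corner
  bx <- seq_len(d[1] - 1); by <- seq_len(d[2] - 1); bz <- seq_len(d[3] - 1)
  base <- as.matrix(expand.grid(bx, by, bz, KEEP.OUT.ATTRS = FALSE))
  lin <- function(i, j, k) as.integer(i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2])
  # edge-vertex bookkeeping done vectorized per (tet, case)
  edge_corners <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  all_a <- integer(0); all_b <- integer(0)
  tri_list <- list()
  for (tet in kuhn_tets) {
    corn <- vapply(1:4, function(c.) lin(base[, 1] + tet[c., 1],
                                         base[, 2] + tet[c., 2],
                                         base[, 3] + tet[c., 3]),
                   integer(nrow(base)))
    inside <- vals[corn[, 1]] > level
    mask <- as.integer(inside)
    for (c. in 2:4) mask <- mask + as.integer(vals[corn[, c.]] > level) * 2L^(c. - 1L)
    for (case in which(!vapply(tet_case_table, is.null, logical(1)))) {
      sel <- which(mask == case - 1L)
      if (!length(sel)) next
      tris <- tet_case_table[[case]]
      for (ti in seq_len(nrow(tris))) {
        tri_edges <- tris[ti, ]
        ids <- matrix(NA_integer_, length(sel), 3)
        for (ei in 1:3) {
          ec <- edge_corners[tri_edges[ei], ]
          ia <- corn[sel, ec[1]]; ib <- corn[sel, ec[2]]
          sw <- ia > ib
          tmp <- ia[sw]; ia[sw] <- ib[sw]; ib[sw] <- tmp
          all_a <- c(all_a, ia); all_b <- c(all_b, ib)
          ids[, ei] <- length(all_a) - length(ia) + seq_along(ia)
        }
        tri_list[[length(tri_list) + 1L]] <- ids
      }
    }
  }
  if (!length(tri_list)) {
    empty$level <- level
    return(empty)
  }
  # merge duplicate edge vertices
  key <- paste(all_a, all_b)
  uid <- match(key, unique(key))
  first <- !duplicated(key)
  ua <- all_a[first]; ub <- all_b[first]
  t <- (level - vals[ua]) / (vals[ub] - vals[ua])
  coords_of <- function(idx) {
    k <- (idx - 1L) %/% (d[1] * d[2])
    r <- (idx - 1L) %% (d[1] * d[2])
    j <- r %/% d[1]
    i <- r %% d[1]
    cbind(volume$x[i + 1L], volume$y[j + 1L], volume$z[k + 1L])
  }
  pa <- coords_of(ua); pb <- coords_of(ub)
  verts <- pa + (pb - pa) * t
  faces <- do.call(rbind, tri_list)
  faces <- matrix(uid[faces], ncol = 3)
  # drop degenerate triangles (two corners on the same merged vertex)
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  structure(list(vertices = verts, faces = faces[ok, , drop = FALSE],
                 level = level),
            class = "sono_mesh")
}

#' @export
print.sono_mesh <- function(x, ...) {
  cat(sprintf("mesh: %d vertices, %d faces (iso level %.4g)\n",
              nrow(x$vertices), nrow(x$faces), x$level))
  invisible(x)
}

#' Reconstruct the 3D scene from a fitted model
#'
#' Convenience wrapper: queries the trained field over a voxel grid,
#' integrates the directional energies, and extracts the isosurface.
#'
#' @param object a fitted [sononerf()] model or a `sono_field`.
#' @param bounds grid bounds (defaults to the training scene bounds).
#' @param voxel_size cubic voxel side, meters.
#' @param n_directions ensonification directions per voxel.
#' @param threshold_frac isosurface level as a fraction of the volume max.
#' @return list with `grid` (directional voxel grid), `volume` (energy
#'   volume), and `mesh` (isosurface).
#' @export
reconstruct <- function(object, bounds = NULL, voxel_size = 0.005,
                        n_directions = 100, threshold_frac = 0.5) {
  grid <- query_grid(object, bounds = bounds, voxel_size = voxel_size,
                     n_directions = n_directions)
  vol <- integrate_directions(grid)
  mesh <- if (max(vol$values) > min(vol$values)) isosurface(vol, threshold_frac)
          else suppressWarnings(isosurface(vol, threshold_frac))
  list(grid = grid, volume = vol, mesh = mesh)
}

#' World coordinates of the maximum-energy voxel
#' @param volume a `sono_volume`.
#' @return length-3 vector, meters.
#' @export
volume_argmax <- function(volume) {
  idx <- arrayInd(which.max(volume$values), dim(volume$values))
  c(volume$x[idx[1]], volume$y[idx[2]], volume$z[idx[3]])
}
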