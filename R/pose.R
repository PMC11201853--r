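#' Sensor pose
#'
#' A pose is the 6-DOF state of the echolocating sensor: a position in the
#' right-handed world frame (meters) and an intrinsic yaw(Z)-pitch(Y)-roll(X)
#' Euler orientation (radians). The body frame has forward = +X, left = +Y,
#' up = +Z.
#'
#' @param position numeric length-3, world position in meters.
#' @param orientation numeric length-3, Euler angles (yaw, pitch, roll) in
#'   radians; normalized to (-pi, pi].
#' @return An object of class `sono_pose`.
#' @examples
#' p <- pose(c(0.3, 0, 0), c(pi, 0, 0))  # 0.3 m down-range, facing back
#' @export
pose <- function(position = c(0, 0, 0), orientation = c(0, 0, 0)) {
  position <- as.numeric(position)
  orientation <- as.numeric(orientation)
  stopifnot(length(position) == 3, length(orientation) == 3,
            all(is.finite(position)), all(is.finite(orientation)))
  structure(list(position = position,
                 orientation = normalize_angle(orientation)),
            class = "sono_pose")
}

# wrap angles into (-pi, pi]
normalize_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

#' @export
print.sono_pose <- function(x, ...) {
  cat(sprintf("pose: position (%.4f, %.4f, %.4f) m, yaw/pitch/roll (%.3f, %.3f, %.3f) rad\n",
              x$position[1], x$position[2], x$position[3],
              x$orientation[1], x$orientation[2], x$orientation[3]))
  invisible(x)
}

#' Body-to-world rotation matrix of a pose
#'
#' Intrinsic yaw(Z)-pitch(Y)-roll(X) composition: `R = Rz(yaw) Ry(pitch) Rx(roll)`.
#' Columns are the body axes (forward, left, up) expressed in world coordinates.
#'
#' @param p a [pose()].
#' @return 3x3 orthonormal rotation matrix.
#' @export
pose_rotation <- function(p) {
  a <- p$orientation[1]; b <- p$orientation[2]; g <- p$orientation[3]
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(g), sin(g), 0, -sin(g), cos(g)), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Pose forward axis in world coordinates
#' @param p a [pose()].
#' @return unit length-3 vector.
#' @export
pose_forward <- function(p) pose_rotation(p)[, 1]

#' Transform points between body and world frames
#'
#' `body_to_world` applies the pose rotation then translation; `world_to_body`
#' is its exact inverse. Both preserve pairwise distances.
#'
#' @param p a [pose()].
#' @param points numeric matrix `n x 3` (or a length-3 vector).
#' @return numeric matrix `n x 3` of transformed points.
#' @export
body_to_world <- function(p, points) {
  points <- as_point_matrix(points)
  stopifnot(all(is.finite(points)))
  sweep(points %*% t(pose_rotation(p)), 2, p$position, "+")
}

#' @rdname body_to_world
#' @export
world_to_body <- function(p, points) {
  points <- as_point_matrix(points)
  stopifnot(all(is.finite(points)))
  sweep(points, 2, p$position, "-") %*% pose_rotation(p)
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  stopifnot(ncol(points) == 3)
  points
}

# Pose looking from `position` toward `target`, roll = 0.
look_at_pose <- function(position, target) {
  f <- target - position
  nf <- sqrt(sum(f^2))
  stopifnot(nf > 0)
  f <- f / nf
  yaw <- atan2(f[2], f[1])
  pitch <- -asin(max(-1, min(1, f[3])))
  pose(position, c(yaw, pitch, 0))
}

#' Quasi-uniform poses on a sphere, all facing its center
#'
#' Places `n` sensor positions on a sphere using a deterministic Fibonacci
#' spiral lattice, each pose oriented so the body forward axis points at the
#' sphere center. Used to build the ensonification geometries of a training
#' ensemble (e.g. 400 or 100 ensonifications distributed uniformly around a
#' target). The `seed` only rotates the spiral phase, so output is fully
#' deterministic for fixed `(n, radius, center, seed)`.
#'
#' @param n number of poses (>= 1).
#' @param radius sphere radius in meters (> 0).
#' @param center sphere center (world, meters).
#' @param seed integer; perturbs the azimuthal phase of the lattice.
#' @return list of [pose()] objects of length `n`.
#' @export
pose_sphere <- function(n, radius, center = c(0, 0, 0), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("pose_sphere: `n` must be a positive integer")
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("pose_sphere: `radius` must be positive")
  u <- fibonacci_sphere(n, phase = golden_phase(seed))
  lapply(seq_len(n), function(i) {
    pos <- center + radius * u[i, ]
    look_at_pose(pos, center)
  })
}

golden_angle <- pi * (3 - sqrt(5))

golden_phase <- function(seed) {
  (as.numeric(seed) %% 997) * golden_angle
}

# n quasi-uniform unit vectors over the full sphere (Fibonacci lattice)
fibonacci_sphere <- function(n, phase = 0) {
  i <- seq_len(n) - 1
  z <- if (n == 1) 0 else 1 - 2 * (i + 0.5) / n
  s <- sqrt(pmax(0, 1 - z^2))
  phi <- i * golden_angle + phase
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Read and write pose tables
#'
#' CSV with header columns `x,y,z,alpha,beta,gamma` in SI units
#' (meters / radians).
#'
#' @param poses list of [pose()].
#' @param path file path.
#' @return `read_poses` returns a list of poses; `write_poses` returns `path`
#'   invisibly.
#' @export
write_poses <- function(poses, path) {
  df <- do.call(rbind, lapply(poses, function(p)
    data.frame(x = p$position[1], y = p$position[2], z = p$position[3],
               alpha = p$orientation[1], beta = p$orientation[2],
               gamma = p$orientation[3])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_poses
#' @export
read_poses <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z", "alpha", "beta", "gamma")
  if (!all(need %in% names(df)))
    stop("read_poses: missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    pose(c(df$x[i], df$y[i], df$z[i]), c(df$alpha[i], df$beta[i], df$gamma[i])))
}
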