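test_that("pose angles normalize and rotations are orthonormal", {
  p <- pose(c(0, 0, 0), c(3 * pi, -3 * pi / 2, pi / 4))
  expect_true(all(p$orientation > -pi & p$orientation <= pi))
  R <- pose_rotation(p)
  expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-10)
})

test_that("body/world transforms: identity, translation, rotation, inverse", {
  expect_equal(body_to_world(pose(), rbind(c(1, 2, 3))), rbind(c(1, 2, 3)))
  expect_equal(body_to_world(pose(c(1, 0, 0)), c(0.5, 0, 0)), rbind(c(1.5, 0, 0)))
  # yaw +90 deg about vertical takes body forward-offset to world +Y
  expect_equal(body_to_world(pose(c(0, 0, 0), c(pi / 2, 0, 0)), c(0.5, 0, 0)),
               rbind(c(0, 0.5, 0)), tolerance = 1e-12)
  set.seed(4)
  pts <- matrix(rnorm(30), 10, 3)
  p <- pose(c(0.3, -0.2, 0.1), c(0.5, -0.3, 1.1))
  expect_lt(max(abs(world_to_body(p, body_to_world(p, pts)) - pts)), 1e-10)
  # distances preserved
  d0 <- dist(pts); d1 <- dist(body_to_world(p, pts))
  expect_lt(max(abs(d0 - d1)), 1e-10)
})

test_that("pose_sphere places poses on the sphere facing the center", {
  ps <- pose_sphere(400, 0.45, c(0, 0, 0), seed = 3)
  expect_length(ps, 400)
  r <- vapply(ps, function(p) sqrt(sum(p$position^2)), numeric(1))
  expect_lt(max(abs(r - 0.45)), 1e-12)
  fwd_err <- vapply(ps, function(p)
    sum(pose_forward(p) * (-p$position / 0.45)) - 1, numeric(1))
  expect_lt(max(abs(fwd_err)), 1e-10)
  # single pose case
  p1 <- pose_sphere(1, 0.3)
  expect_equal(sqrt(sum(p1[[1]]$position^2)), 0.3)
  # determinism
  expect_identical(pose_sphere(50, 0.3, seed = 7), pose_sphere(50, 0.3, seed = 7))
  expect_error(pose_sphere(0, 0.3), "positive")
  expect_error(pose_sphere(10, -1), "positive")
})

test_that("pose_sphere packing is near the uniform ideal (brute force)", {
  n <- 100
  ps <- pose_sphere(n, 0.3, seed = 1)
  u <- t(vapply(ps, function(p) p$position / 0.3, numeric(3)))
  # brute-force min pairwise angular separation
  cosang <- tcrossprod(u)
  diag(cosang) <- -1
  min_sep <- acos(max(pmin(1, cosang[upper.tri(cosang)])))
  ideal <- sqrt(8 * pi / (sqrt(3) * n))   # hexagonal-packing spacing
  expect_gt(min_sep, 0.7 * ideal)
})

test_that("three-spheres scene matches the L layout and sampling radius", {
  s <- build_three_spheres(points_per_sphere = 4)
  expect_equal(nrow(s$positions), 12)
  s <- build_three_spheres(points_per_sphere = 64)
  cc <- attr(s, "cluster_centers")
  d <- as.matrix(dist(cc))
  expect_equal(sort(d[upper.tri(d)]), c(0.05, 0.05, 0.05 * sqrt(2)),
               tolerance = 1e-12)
  id <- attr(s, "cluster_id")
  for (k in 1:3) {
    rr <- sqrt(rowSums(sweep(s$positions[id == k, ], 2, cc[k, ], "-")^2))
    expect_lt(max(abs(rr - 0.015)), 1e-9)
  }
  # scenes fit inside their declared bounds
  expect_true(all(s$positions >= rep(s$bounds[1, ], each = nrow(s$positions))))
  expect_true(all(s$positions <= rep(s$bounds[2, ], each = nrow(s$positions))))
})

test_that("UA scene has exactly 19 sphere clusters", {
  s <- build_ua_scene(points_per_sphere = 8)
  expect_equal(nrow(attr(s, "cluster_centers")), 19)
  expect_equal(nrow(s$positions), 19 * 8)
})

test_that("leaf scenes differ only by the insect cluster", {
  a <- build_leaf_scene(FALSE, seed = 5)
  b <- build_leaf_scene(TRUE, seed = 5)
  n <- nrow(a$positions)
  expect_equal(b$positions[seq_len(n), ], a$positions)
  extra <- b$positions[-seq_len(n), , drop = FALSE]
  expect_gt(nrow(extra), 0)
  centroid <- colMeans(extra)
  expect_lt(max(abs(centroid - attr(b, "insect_center"))), 0.006)
  expect_true(all(b$gain[-seq_len(n)] > max(a$gain)))
})

test_that("scene JSON round-trip preserves positions and spectra", {
  spec <- matrix(complex(real = seq(0.1, 1, length.out = 5),
                         imaginary = seq(-0.2, 0.2, length.out = 5)),
                 2, 5, byrow = TRUE)
  s <- scene(rbind(c(0.1, 0.2, 0.3), c(-0.1, 0, 0.05)), gain = c(1, 2),
             spectra = spec, name = "two")
  f <- tempfile(fileext = ".json")
  save_scene(s, f)
  s2 <- load_scene(f)
  expect_equal(s2$positions, s$positions, tolerance = 1e-12)
  expect_equal(s2$gain, s$gain)
  expect_equal(s2$spectra, s$spectra, tolerance = 1e-12)
  # three-spheres round trip
  s3 <- build_three_spheres(points_per_sphere = 16)
  f3 <- tempfile(fileext = ".json")
  save_scene(s3, f3)
  expect_equal(load_scene(f3)$positions, s3$positions, tolerance = 1e-9)
})

test_that("malformed scenes are rejected with a field name", {
  f <- tempfile(fileext = ".json")
  writeLines('{"name": "x", "scatterers": []}', f)
  expect_error(load_scene(f), "scatterers")
  writeLines('{"name": "x", "scatterers": [{"gain": 1}]}', f)
  expect_error(load_scene(f), "xyz")
  expect_error(scene(matrix(numeric(0), 0, 3)), "count")
})

test_that("STL sampling is area-weighted within binomial bounds", {
  # unit square split into unequal triangles (areas 1/2 and 1/2 -> then skewed)
  f <- tempfile(fileext = ".stl")
  writeLines(c(
    "solid square",
    " facet normal 0 0 1", "  outer loop",
    "   vertex 0 0 0", "   vertex 1 0 0", "   vertex 1 1 0",
    "  endloop", " endfacet",
    " facet normal 0 0 1", "  outer loop",
    "   vertex 0 0 0", "   vertex 1 1 0", "   vertex 0 1 0",
    "  endloop", " endfacet",
    "endsolid square"), f)
  s <- stl_to_scene(f, n = 1000, seed = 9)
  expect_equal(nrow(s$positions), 1000)
  expect_lt(max(abs(s$positions[, 3])), 1e-12)     # in the square plane
  expect_true(all(s$positions[, 1] >= 0 & s$positions[, 1] <= 1))
  expect_true(all(s$positions[, 2] >= 0 & s$positions[, 2] <= 1))
  # triangle 1 is y < x; equal areas -> binomial 3 sigma around 500
  n1 <- sum(s$positions[, 2] < s$positions[, 1])
  expect_lt(abs(n1 - 500), 3 * sqrt(1000 * 0.25) + 1)
  # deterministic for a fixed seed
  expect_equal(stl_to_scene(f, n = 50, seed = 9)$positions,
               stl_to_scene(f, n = 50, seed = 9)$positions)
})

test_that("binary STL writing round-trips through the reader", {
  mesh <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               faces = rbind(c(1, 2, 3), c(1, 2, 4)))
  f <- tempfile(fileext = ".stl")
  write_stl(mesh, f, binary = TRUE)
  tri <- read_stl(f)
  expect_equal(dim(tri), c(2, 9))
  expect_equal(tri[1, 1:3], c(0, 0, 0), tolerance = 1e-6)
  expect_equal(tri[2, 7:9], c(0, 0, 1), tolerance = 1e-6)
})

test_that("pose CSV round-trips", {
  ps <- pose_sphere(5, 0.4, c(0.1, 0, -0.1), seed = 2)
  f <- tempfile(fileext = ".csv")
  write_poses(ps, f)
  ps2 <- read_poses(f)
  expect_equal(lapply(ps2, unclass), lapply(ps, unclass), tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1, y = 2), bad, row.names = FALSE)
  expect_error(read_poses(bad), "missing columns")
})
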