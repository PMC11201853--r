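test_that("hemisphere discretization: defaults, geometry, weights", {
  p <- pose(c(0.1, -0.2, 0.05), c(0.7, -0.2, 0.3))
  h <- hemisphere_samples(p, 0.25)
  expect_equal(nrow(h$points_world), 600)
  d <- sqrt(rowSums(sweep(h$points_world, 2, p$position, "-")^2))
  expect_lt(max(abs(d - 0.25)), 1e-9)
  fwd <- pose_forward(p)
  expect_true(all(h$directions %*% fwd > 0))
  expect_equal(sum(h$weights), 2 * pi, tolerance = 1e-12)
  expect_error(hemisphere_samples(p, -1), "positive")
  expect_error(hemisphere_samples(p, 0.2, n = 2), ">= 4")
})

test_that("hemisphere packing is near the uniform ideal (brute force)", {
  h <- hemisphere_samples(pose(), 1, n = 200)
  u <- h$directions
  cosang <- tcrossprod(u)
  diag(cosang) <- -1
  # nearest-neighbor angular spacing per point
  nn <- acos(pmin(1, apply(cosang, 1, max)))
  ideal <- sqrt(4 * pi / (sqrt(3) * 200))  # hexagonal packing on 2*pi sr
  expect_gt(stats::median(nn), 0.7 * ideal)
  expect_lt(stats::median(nn), 1.3 * ideal)
})

test_that("slice loss: zero at equality, arithmetic, symmetry", {
  expect_equal(slice_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(slice_loss(c(0.2, 0.4), c(0.0, 0.4)), 0.02)
  a <- runif(94); b <- runif(94)
  expect_equal(slice_loss(a, b), slice_loss(b, a))
  expect_gte(slice_loss(a, b), 0)
  expect_error(slice_loss(1:3, 1:4), "length")
})

test_that("rendering a zero field gives the compressed floor", {
  cfg <- field_config(hidden = c(8, 8), skip_at = 2, seed = 1)
  f <- init_field(cfg)
  nl <- length(f$W)
  f$W[[nl]][] <- 0; f$b[[nl]][] <- 0
  f$meta$bounds <- rbind(c(-1, -1, -1), c(1, 1, 1))
  rs <- render_slice(f, pose(c(-0.3, 0, 0)), 0.3, tiny_ertf(), tiny_call(),
                     n_hemisphere = 64)
  expect_equal(rs$spectrum, rep(0, 94))
  expect_true(all(rs$complex == 0))
})

test_that("the unimodular delay factor does not change rendered magnitudes", {
  # |e^{-j w 2r/vs} z| = |z|: the stored complex spectrum carries the factor,
  # the compressed magnitude must be identical with it stripped
  cfg <- field_config(hidden = c(8, 8), skip_at = 2, seed = 6)
  f <- init_field(cfg)
  f$meta$bounds <- rbind(c(-1, -1, -1), c(1, 1, 1))
  cl <- tiny_call()
  rs <- render_slice(f, pose(c(-0.3, 0, 0)), 0.3, tiny_ertf(), cl,
                     n_hemisphere = 64, ref = 1)
  ph <- exp(-2i * pi * cl$band_freqs * 2 * 0.3 / 343)
  stripped <- rs$complex / c(ph, ph)
  expect_equal(Mod(stripped), Mod(rs$complex), tolerance = 1e-12)
  expect_equal(compress(Mod(rs$complex), obs_config(), 1), rs$spectrum,
               tolerance = 1e-12)
})

test_that("delta-field rendering matches the simulated observation column", {
  # independent oracle: the full echo-formation + preprocessing pipeline for
  # a lone isotropic scatterer; rendering a field that is a flat unit
  # spectrum within 5 mm of the scatterer must reproduce the observation
  # column at the scatterer's range (flat-spectrum sweep, matched unit-max
  # normalization of the compressed spectra)
  cl <- tiny_call(taper = 0)
  ertf <- tiny_ertf()
  r0 <- 0.4
  po <- pose()
  echo <- simulate_echo(scene(rbind(c(r0, 0, 0))), po, cl, ertf,
                        sim_config(max_range = 0.6))
  ocfg <- obs_config()
  obs <- make_observation(echo, cl, ocfg)
  col <- which.min(abs(obs$ranges - r0))
  meas <- obs$values[, col]
  delta_field <- function(positions, directions) {
    d <- sqrt(rowSums(sweep(positions, 2, c(r0, 0, 0), "-")^2))
    out <- matrix(0 + 0i, nrow(positions), 47)
    out[d < 0.005, ] <- 1 + 0i
    out
  }
  rs <- render_slice(delta_field, po, obs$ranges[col], ertf, cl,
                     n_hemisphere = 600, obs_cfg = ocfg, ref = 1)
  nmeas <- meas / max(meas)
  npred <- rs$spectrum / max(rs$spectrum)
  rel <- sqrt(sum((nmeas - npred)^2)) / sqrt(sum(nmeas^2))
  expect_lt(rel, 0.05)
})

test_that("full-spectrogram rendering composes render_slice per column", {
  cfg <- field_config(hidden = c(8, 8), skip_at = 2, seed = 9)
  f <- init_field(cfg)
  f$meta$bounds <- rbind(c(-0.5, -0.5, -0.5), c(0.5, 0.5, 0.5))
  cl <- tiny_call()
  po <- pose(c(-0.3, 0, 0))
  ranges <- seq(0.25, 0.35, by = 0.01)
  sp <- render_spectrogram(f, po, ranges, tiny_ertf(), cl, n_hemisphere = 48,
                           ref = 1)
  expect_equal(dim(sp$values), c(94, length(ranges)))
  rs <- render_slice(f, po, ranges[4], tiny_ertf(), cl, n_hemisphere = 48,
                     ref = 1, bounds = f$meta$bounds)
  expect_equal(sp$values[, 4], rs$spectrum, tolerance = 1e-12)
  # zero field renders a zero spectrogram
  nl <- length(f$W)
  f$W[[nl]][] <- 0; f$b[[nl]][] <- 0
  sp0 <- render_spectrogram(f, po, ranges, tiny_ertf(), cl, n_hemisphere = 48,
                            ref = 1)
  expect_true(all(sp0$values == 0))
})

test_that("rendered pre-compression magnitude is |alpha|-homogeneous in the field", {
  cfg <- field_config(hidden = c(8, 8), skip_at = 2, seed = 10)
  f <- init_field(cfg)
  meta_bounds <- rbind(c(-1, -1, -1), c(1, 1, 1))
  cl <- tiny_call()
  ctx <- sononerf:::render_context(list(pose(c(-0.3, 0, 0))), cl, tiny_ertf(),
                                   64, obs_config(), 1, 343, meta_bounds)
  fw1 <- sononerf:::render_forward(f, ctx, 1L, 0.3)
  fa <- f
  nl <- length(fa$W)
  fa$W[[nl]] <- -2.5 * fa$W[[nl]]
  fa$b[[nl]] <- -2.5 * fa$b[[nl]]
  fw2 <- sononerf:::render_forward(fa, ctx, 1L, 0.3)
  expect_equal(fw2$magnitude, 2.5 * fw1$magnitude, tolerance = 1e-9)
})

test_that("renderer gradient through the loss matches finite differences", {
  cfg <- field_config(hidden = c(12, 12), skip_at = 2, seed = 5)
  fld <- init_field(cfg)
  cl <- tiny_call()
  poses <- pose_sphere(2, 0.3, seed = 3)
  ctx <- sononerf:::render_context(poses, cl, tiny_ertf(), 24, obs_config(),
                                   1, 343, rbind(c(-0.4, -0.4, -0.4), c(0.4, 0.4, 0.4)))
  set.seed(21)
  y <- matrix(runif(2 * 94), 2, 94)
  lossfun <- function(f) {
    fw <- sononerf:::render_forward(f, ctx, c(1L, 2L), c(0.28, 0.31))
    mean((fw$compressed - y)^2)
  }
  fw <- sononerf:::render_forward(fld, ctx, c(1L, 2L), c(0.28, 0.31),
                                  keep_cache = TRUE)
  dC <- 2 * (fw$compressed - y) / length(y)
  gr <- sononerf:::render_backward(fld, ctx, fw, dC)
  h <- 1e-4
  set.seed(33)
  worst <- 0
  for (li in seq_along(fld$W)) {
    for (k in 1:8) {
      i <- sample(length(fld$W[[li]]), 1)
      fp <- fld; fp$W[[li]][i] <- fp$W[[li]][i] + h
      fm <- fld; fm$W[[li]][i] <- fm$W[[li]][i] - h
      fd <- (lossfun(fp) - lossfun(fm)) / (2 * h)
      an <- gr$W[[li]][i]
      if (abs(fd) > 1e-10)
        worst <- max(worst, abs(fd - an) / max(abs(fd), abs(an)))
    }
  }
  expect_lt(worst, 1e-4)
})
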