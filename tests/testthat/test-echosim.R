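test_that("call synthesis enforces the band and dechirp law", {
  cl <- make_call(100e3, 40e3, 1e-3, sample_rate = 400e3)
  expect_equal(dechirp_delay(cl, c(100e3, 70e3, 40e3)),
               c(0, 0.5e-3, 1e-3), tolerance = 1e-12)
  # hyperbolic law: endpoints fixed, midpoint differs from linear
  ch <- make_call(100e3, 40e3, 1e-3, law = "hyperbolic", sample_rate = 400e3)
  expect_equal(dechirp_delay(ch, c(100e3, 40e3)), c(0, 1e-3), tolerance = 1e-9)
  expect_gt(abs(dechirp_delay(ch, 70e3) - 0.5e-3), 1e-5)
  # delay law monotone over the band
  expect_true(all(diff(dechirp_delay(cl, cl$band_freqs)) < 0))
  expect_error(make_call(100e3, 40e3, 1e-3, sample_rate = 150e3), "Nyquist")
  expect_error(make_call(40e3, 100e3, 1e-3), "f_hi > f_lo")
})

test_that("non-integer duration is rounded to whole samples and recorded", {
  cl <- make_call(100e3, 40e3, 1.0004e-3, sample_rate = 400e3)
  expect_equal(length(cl$signal), round(1.0004e-3 * 400e3))
  expect_equal(cl$duration, length(cl$signal) / 400e3)
  expect_equal(cl$requested_duration, 1.0004e-3)
})

test_that("sweep energy is confined to the band (independent DFT oracle)", {
  cl <- make_call(100e3, 40e3, 1e-3, sample_rate = 400e3)
  x <- cl$signal
  n <- length(x)
  # independent DFT by direct evaluation on a coarse frequency grid
  fgrid <- seq(0, 200e3, by = 1e3)
  amps <- vapply(fgrid, function(f)
    abs(sum(x * exp(-2i * pi * f * (0:(n - 1)) / 400e3)))^2, numeric(1))
  inband <- fgrid >= 35e3 & fgrid <= 105e3
  expect_lt(sum(amps[!inband]) / sum(amps), 0.05)
})

test_that("ERTF is unit on-axis, mirror-symmetric, and near-zero behind", {
  ertf <- ertf_model()
  freqs <- c(50e3, 70e3, 100e3)
  on <- ertf_gain(ertf, rbind(c(1, 0, 0)), freqs)
  expect_equal(Mod(on$left), matrix(1, 1, 3), tolerance = 1e-12)
  expect_equal(Mod(on$right), matrix(1, 1, 3), tolerance = 1e-12)
  th <- 20 * pi / 180
  dirs <- rbind(c(cos(th), sin(th), 0), c(cos(th), -sin(th), 0))
  g <- ertf_gain(ertf, dirs, freqs)
  expect_equal(Mod(g$left[1, ]), Mod(g$right[2, ]), tolerance = 1e-12)
  expect_equal(Mod(g$left[2, ]), Mod(g$right[1, ]), tolerance = 1e-12)
  back <- ertf_gain(ertf, rbind(c(-1, 0, 0)), freqs)
  expect_lt(max(Mod(back$left), Mod(back$right)), 1e-6)
  expect_error(ertf_gain(ertf, rbind(c(1, 1, 0)), freqs), "unit")
})

test_that("piston first null matches the aperture-integral oracle", {
  a <- 0.006; f <- 80e3; v <- 343
  # oracle: 2-D quadrature over the disc aperture, scanned over angle
  k <- 2 * pi * f / v
  nq <- 60
  rho <- (seq_len(nq) - 0.5) / nq * a
  phi <- (seq_len(nq) - 0.5) / nq * 2 * pi
  gr <- expand.grid(rho = rho, phi = phi)
  amp <- function(theta)
    abs(sum(gr$rho * exp(1i * k * sin(theta) * gr$rho * cos(gr$phi))))
  thetas <- seq(0.01, pi / 2, length.out = 400)
  vals <- vapply(thetas, amp, numeric(1))
  oracle_null <- thetas[which(diff(sign(diff(vals))) > 0)[1] + 1]
  # first null of the implemented directivity by fine scan
  d <- piston_directivity(cos(thetas), a, f, v)
  impl_null <- thetas[which(diff(sign(diff(d[, 1]))) > 0)[1] + 1]
  expect_equal(impl_null, oracle_null, tolerance = 0.02)
  # and both agree with the closed form asin(3.8317 / (k a))
  expect_equal(impl_null, asin(3.8317 / (k * a)), tolerance = 0.02)
})

test_that("single-reflector echo peaks at the round-trip delay", {
  cl <- tiny_call()
  ertf <- tiny_ertf()
  sc <- scene(rbind(c(0.5, 0, 0)))
  echo <- simulate_echo(sc, pose(), cl, ertf, sim_config(max_range = 0.6))
  fs <- cl$sample_rate
  for (ch in list(echo$left, echo$right)) {
    # cross-correlation with the emitted call via explicit FFTs
    n <- length(ch); m <- length(cl$signal)
    X <- stats::fft(c(ch, rep(0, m)))
    Y <- stats::fft(c(cl$signal, rep(0, n)))
    cc <- Re(stats::fft(X * Conj(Y), inverse = TRUE))
    lag <- which.max(cc[1:n]) - 1
    expect_lt(abs(lag / fs - 2 * 0.5 / 343), 1.5 / fs)
  }
})

test_that("echo synthesis is linear over scatterers", {
  cl <- tiny_call()
  ertf <- tiny_ertf()
  cfg <- sim_config(max_range = 0.5)
  pA <- rbind(c(0.3, 0.05, 0), c(0.35, -0.1, 0.02))
  pB <- rbind(c(0.25, 0, 0.1))
  po <- pose()
  eA <- simulate_echo(scene(pA), po, cl, ertf, cfg)
  eB <- simulate_echo(scene(pB), po, cl, ertf, cfg)
  eAB <- simulate_echo(scene(rbind(pA, pB)), po, cl, ertf, cfg)
  for (ch in c("left", "right")) {
    dev <- max(abs(eAB[[ch]] - (eA[[ch]] + eB[[ch]])))
    expect_lt(dev / max(abs(eAB[[ch]])), 1e-9)
  }
})

test_that("off-axis band energy matches a direct frequency-domain evaluation", {
  cl <- tiny_call()
  ertf <- tiny_ertf()
  cfg <- sim_config(max_range = 0.5, spreading = FALSE)
  r0 <- 0.35
  th <- 30 * pi / 180
  on <- simulate_echo(scene(rbind(c(r0, 0, 0))), pose(), cl, ertf, cfg)
  off <- simulate_echo(scene(rbind(r0 * c(cos(th), sin(th), 0))), pose(), cl,
                       ertf, cfg)
  ratio_impl <- sum(off$left^2) / sum(on$left^2)
  # oracle: directional gain ratio evaluated directly at the band bins,
  # weighted by the emitted spectrum (independent of the simulator code path)
  freqs <- cl$band_freqs
  gon <- ertf_gain(ertf, rbind(c(1, 0, 0)), freqs)$left
  goff <- ertf_gain(ertf, rbind(c(cos(th), sin(th), 0)), freqs)$left
  n <- length(cl$signal)
  Se <- vapply(freqs, function(f)
    abs(sum(cl$signal * exp(-2i * pi * f * (0:(n - 1)) / cl$sample_rate)))^2,
    numeric(1))
  ratio_oracle <- sum(Mod(goff)^2 * Se) / sum(Mod(gon)^2 * Se)
  expect_equal(ratio_impl, ratio_oracle, tolerance = 0.05)
})

test_that("lateralization and distance scaling behave physically", {
  cl <- tiny_call()
  ertf <- tiny_ertf()
  cfg <- sim_config(max_range = 0.5)
  left_sc <- simulate_echo(scene(rbind(0.3 * c(cos(0.4), sin(0.4), 0))),
                           pose(), cl, ertf, cfg)
  expect_gt(sum(left_sc$left^2), sum(left_sc$right^2))
  # doubling distance doubles the delay
  g1 <- ensonification_geometry(scene(rbind(c(0.2, 0, 0))), pose(), ertf)
  g2 <- ensonification_geometry(scene(rbind(c(0.4, 0, 0))), pose(), ertf)
  expect_equal(g2$d_out, 2 * g1$d_out, tolerance = 1e-12)
  expect_equal(g2$delay_left * 343, g2$range_left, tolerance = 1e-12)
  expect_lt(max(abs(sqrt(rowSums(g1$psi^2)) - 1)), 1e-12)
  expect_lt(max(abs(sqrt(rowSums(g1$eta^2)) - 1)), 1e-12)
})

test_that("a pose inside the scene bounds is allowed but warned about", {
  cl <- tiny_call()
  sc <- build_three_spheres(points_per_sphere = 8)
  expect_warning(simulate_echo(sc, pose(c(0, 0, 0)), cl, tiny_ertf(),
                               sim_config(max_range = 0.3)), "inside")
})
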