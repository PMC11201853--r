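test_that("stft magnitude: null input, tone concentration, band validation", {
  z <- stft_magnitude(rep(0, 2048), 400e3, 64, 0.75, band = c(40e3, 100e3))
  expect_true(all(z$values == 0))
  expect_equal(nrow(z$values), 47)
  # a pure tone at a band-bin center concentrates in its row when the
  # window is long enough to resolve the bin spacing
  bf <- seq(40e3, 100e3, length.out = 47)
  f0 <- bf[20]
  x <- sin(2 * pi * f0 * (0:20479) / 400e3)
  s <- stft_magnitude(x, 400e3, 4096, 0.5, band = c(40e3, 100e3), nfft = 8192)
  mid <- ncol(s$values) %/% 2
  expect_gt(s$values[20, mid]^2 / sum(s$values[, mid]^2), 0.9)
  expect_error(stft_magnitude(x, 400e3, 64, 0.5, band = c(40e3, 300e3)),
               "Nyquist")
})

test_that("stft total energy matches a frame-by-frame Fourier sum", {
  set.seed(8)
  x <- rnorm(700)
  win <- 32; hop <- 16; nfft <- 64
  s <- stft_magnitude(x, 1000, win, 0.5, band = NULL, nfft = nfft)
  # independent oracle: direct DFT sums per frame
  w <- 0.5 * (1 - cos(2 * pi * (0:(win - 1)) / (win - 1)))
  starts <- seq(1, length(x) - win + 1, by = hop)
  oracle <- matrix(0, nfft / 2 + 1, length(starts))
  for (ci in seq_along(starts)) {
    fr <- x[starts[ci] + 0:(win - 1)] * w
    for (k in 0:(nfft / 2)) {
      oracle[k + 1, ci] <- abs(sum(fr * exp(-2i * pi * k * (0:(win - 1)) / nfft)))
    }
  }
  expect_equal(sum(s$values^2), sum(oracle^2), tolerance = 1e-6)
  expect_lt(max(abs(s$values - oracle)), 1e-8)
})

test_that("binaural concat stacks left over right and splits back", {
  L <- matrix(runif(47 * 100), 47, 100)
  R <- matrix(runif(47 * 100), 47, 100)
  B <- binaural_concat(L, R)
  expect_equal(dim(B), c(94, 100))
  expect_equal(B[1:47, ], L)
  expect_equal(B[48:94, ], R)
  Z <- binaural_concat(matrix(0, 2, 3), matrix(5, 2, 3))
  expect_true(all(Z[3:4, ] == 5))
  expect_error(binaural_concat(L, R[, 1:10]), "identical shapes")
})

test_that("dechirp is a pure column shift: identity, alignment, energy", {
  cl <- tiny_call()
  # zero-shift call: constant-frequency delay law would be zero; emulate by
  # a call whose delays are all below half a column
  spec <- matrix(runif(94 * 60), 94, 60)
  out <- dechirp(spec, cl, column_dt = 1)   # 1 s columns: all shifts round to 0
  expect_identical(out, spec)
  # single-reflector alignment at the analysis used for the alignment check
  ertf <- tiny_ertf()
  echo <- simulate_echo(scene(rbind(c(0.4, 0, 0))), pose(), cl, ertf,
                        sim_config(max_range = 0.6))
  raw <- sononerf:::observation_magnitude(echo, cl, obs_config(overlap = 0.5))
  pk <- apply(raw$values, 1, max)
  am <- apply(raw$values, 1, which.max)
  sel <- pk >= 0.1 * max(pk)
  expect_lte(diff(range(am[sel])), 1)
  # energy preservation: rows with no content in the dropped leading columns
  cfg <- obs_config(overlap = 0.5)
  sp2 <- matrix(0, 94, 80)
  sp2[, 41:60] <- runif(94 * 20)
  dt <- 32 / cl$sample_rate
  shifted <- dechirp(sp2, cl, dt)
  expect_equal(sum(shifted^2), sum(sp2^2), tolerance = 1e-9)
})

test_that("two reflectors yield ridges at the expected column separation", {
  cl <- tiny_call()
  ertf <- tiny_ertf()
  sc <- scene(rbind(c(0.25, 0, 0), c(0.35, 0, 0)))
  echo <- simulate_echo(sc, pose(), cl, ertf, sim_config(max_range = 0.5))
  ocfg <- obs_config(overlap = 0.5)
  raw <- sononerf:::observation_magnitude(echo, cl, ocfg)
  prof <- colSums(raw$values^2)
  # two local maxima separated by round(2*0.1/v / col_dt) columns
  col_dt <- raw$times[2] - raw$times[1]
  expected_sep <- round(2 * 0.1 / 343 / col_dt)
  pk1 <- which.max(prof)
  away <- abs(seq_along(prof) - pk1) > expected_sep / 2
  pk2 <- which(away)[which.max(prof[away])]
  expect_lte(abs(abs(pk2 - pk1) - expected_sep), 1)
})

test_that("compression maps reference, floor and midpoint correctly", {
  cfg <- obs_config()
  expect_equal(compress(1, cfg, ref = 1), 1, tolerance = 1e-4)
  expect_equal(compress(0, cfg, ref = 1), 0)
  expect_equal(compress(10^(-30 / 20), cfg, ref = 1), 0.5, tolerance = 1e-3)
  x <- seq(0, 2, length.out = 101)
  expect_true(all(diff(compress(x, cfg, ref = 1)) >= 0))
  expect_true(all(compress(x, cfg, ref = 1) >= 0 & compress(x, cfg, ref = 1) <= 1))
  # invertible where unclipped: recover y from C then back
  y <- seq(0.05, 0.95, by = 0.1)
  xinv <- (10^(y * 60 / 20 - 60 / 20) - cfg$epsilon) * 1
  expect_equal(compress(xinv, cfg, ref = 1), y, tolerance = 1e-6)
})

test_that("make_observation produces the documented shape and range axis", {
  cl <- tiny_call()
  ertf <- tiny_ertf()
  r0 <- 0.3
  echo <- simulate_echo(scene(rbind(c(r0, 0, 0))), pose(), cl, ertf,
                        sim_config(max_range = 0.45))
  obs <- make_observation(echo, cl, obs_config(overlap = 0.75))
  expect_equal(nrow(obs$values), 94)
  expect_true(all(obs$values >= 0 & obs$values <= 1))
  expect_true(all(diff(obs$ranges) > 0))
  expect_equal(obs$ranges, 343 * obs$times / 2, tolerance = 1e-12)
  ridge <- obs$ranges[which.max(colSums(obs$values^2))]
  expect_lt(abs(ridge - r0), 0.02)
  # observation pipeline is deterministic
  obs2 <- make_observation(echo, cl, obs_config(overlap = 0.75))
  expect_identical(obs$values, obs2$values)
})

test_that("default full-scale config yields ~500 range columns", {
  cl <- make_call(100e3, 40e3, 1e-3, sample_rate = 400e3)
  ertf <- tiny_ertf()
  echo <- simulate_echo(scene(rbind(c(0.5, 0, 0))), pose(), cl, ertf,
                        sim_config(max_range = 0.6))
  obs <- make_observation(echo, cl, obs_config())
  expect_gt(ncol(obs$values), 380)
  expect_lt(ncol(obs$values), 620)
  expect_equal(nrow(obs$values), 94)
})
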