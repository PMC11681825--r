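test_that("band-pass filter preserves passband and rejects stopband", {
  fs <- 256
  t <- seq(0, 8 - 1 / fs, 1 / fs)
  x <- region_timeseries(matrix(sin(2 * pi * 10 * t), 1), fs)
  mid <- seq(fs + 1, length(t) - fs)      # trim 1 s of edges
  in_alpha <- bandpass(x, band_definition("alpha", 8, 13))
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(in_alpha$data[1, mid]) / rms(x$data[1, mid]) - 1),
            0.05)
  in_theta <- bandpass(x, band_definition("theta", 4, 8))
  expect_lt(rms(in_theta$data[1, mid]) / rms(x$data[1, mid]), 0.10)
  expect_error(bandpass(region_timeseries(matrix(rnorm(256), 1), 64),
                        band_definition("low_gamma", 30, 45)),
               "Nyquist")
})

test_that("analytic signal has the defining phase properties", {
  fs <- 200
  t <- seq(0, 5 - 1 / fs, 1 / fs)
  f0 <- 7
  z <- analytic_signal(region_timeseries(
    rbind(cos(2 * pi * f0 * t), sin(2 * pi * f0 * t)), fs))
  expect_equal(Re(z[1, ]), cos(2 * pi * f0 * t), tolerance = 1e-8)
  mid <- seq(fs, length(t) - fs)
  # per-sample phase increment (wrap-free) gives the instantaneous frequency
  slope <- mean(Arg(z[1, mid + 1] * Conj(z[1, mid]))) * fs / (2 * pi)
  expect_lt(abs(slope / f0 - 1), 0.01)
  # quadrature pair: cos leads sin by pi/2
  dphi <- Arg(z[1, mid] * Conj(z[2, mid]))
  expect_true(all(abs(dphi - pi / 2) < 0.01))
  # degenerate zero input
  z0 <- analytic_signal(region_timeseries(matrix(0, 1, 400), fs))
  expect_true(all(Mod(z0) < 1e-12))
})

test_that("wPLI closed forms: quadrature lag gives 1, zero lag gives 0", {
  fs <- 128
  t <- seq(0, 4 - 1 / fs, 1 / fs)
  zi <- exp(2i * pi * 10 * t)
  zj <- exp(1i * (2 * pi * 10 * t - pi / 2))
  w <- dynamic_wpli(rbind(zi, zj), fs, window_spec())
  expect_equal(max(abs(w[1, 2, ] - 1)), 0, tolerance = 1e-12)
  # identical signals: all imaginary cross-terms vanish
  w0 <- dynamic_wpli(rbind(zi, zi), fs, window_spec())
  expect_true(all(w0[1, 2, ] == 0))
  # constructed cancellation: alternating +s/-s imaginary terms
  zj2 <- rep(c(1i, -1i), length.out = length(t))
  wc <- dynamic_wpli(rbind(rep(1 + 0i, length(t)), zj2), fs,
                     window_spec())
  expect_true(all(wc[1, 2, ] == 0))
})

test_that("vectorized wPLI equals the naive per-pair loop", {
  set.seed(8)
  fs <- 64
  ts <- region_timeseries(matrix(rnorm(5 * fs * 10), 5), fs)
  z <- analytic_signal(bandpass(ts, band_definition("alpha", 8, 13)))
  spec <- window_spec()
  fast <- dynamic_wpli(z, fs, spec)
  slow <- naive_wpli(z, fs, spec)
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("static averaging pools windows arithmetically", {
  a <- array(0.2, c(3, 3, 1)); b <- array(0.4, c(3, 3, 1))
  m <- static_fc(list(a, b))
  expect_equal(m[1, 2], 0.3)
  ident <- static_fc(array(rep(0.7, 9), c(3, 3, 1)))
  expect_equal(ident[1, 2], 0.7)
  set.seed(9)
  win <- array(runif(4 * 4 * 12), c(4, 4, 12))
  expect_equal(static_fc(win), apply(win, c(1, 2), mean),
               tolerance = 1e-14)
})

test_that("wPLI invariants: range, symmetry, scale and zero-lag behavior", {
  set.seed(10)
  fs <- 128
  ts <- region_timeseries(matrix(rnorm(4 * fs * 20), 4), fs)
  z <- analytic_signal(bandpass(ts, band_definition("beta", 13, 30)))
  w <- dynamic_wpli(z, fs, window_spec())
  expect_true(all(w >= 0 & w <= 1))
  for (k in seq_len(dim(w)[3])) {
    expect_equal(w[, , k], t(w[, , k]))
    expect_true(all(diag(w[, , k]) == 0))
  }
  # positive rescaling of one region leaves wPLI unchanged
  z2 <- z; z2[2, ] <- 3.7 * z2[2, ]
  expect_equal(dynamic_wpli(z2, fs, window_spec()), w, tolerance = 1e-12)
})

test_that("a shared zero-lag component does not inflate wPLI", {
  set.seed(12)
  fs <- 128
  dur <- 182
  x1 <- rnorm(fs * dur); x2 <- rnorm(fs * dur)
  common <- rnorm(fs * dur)
  base <- compute_fc(region_timeseries(rbind(x1, x2), fs),
                     default_bands()["beta"], window_spec())[[1]][1, 2]
  mixed <- compute_fc(region_timeseries(rbind(x1 + common, x2 + common),
                                        fs),
                      default_bands()["beta"], window_spec())[[1]][1, 2]
  expect_lt(mixed - base, 0.05)
})

test_that("null white-noise bias stays bounded for wide bands and grows as bands narrow", {
  res <- sapply(1:5, function(s) {
    set.seed(400 + s)
    ts <- region_timeseries(matrix(rnorm(4 * 128 * 182), 4), 128)
    fc <- compute_fc(ts, default_bands(), window_spec())
    vapply(fc, function(m) mean(m[upper.tri(m)]), 0)
  })
  means <- rowMeans(res)
  expect_lt(means[["beta"]], 0.35)
  expect_lt(means[["low_gamma"]], 0.35)
  # 1-s windows resolve fewer independent cross-terms in narrow bands,
  # so the small-sample bias ranks theta > alpha > beta
  expect_gt(means[["theta"]], means[["alpha"]])
  expect_gt(means[["alpha"]], means[["beta"]])
})

test_that("compute_fc composes deterministically over epochs and bands", {
  set.seed(13)
  fs <- 128
  ts <- region_timeseries(matrix(rnorm(3 * fs * 92), 3), fs)
  spec <- window_spec(epoch_s = 30, n_epochs = 3)
  fc1 <- compute_fc(ts, default_bands(), spec)
  fc2 <- compute_fc(ts, default_bands(), spec)
  expect_identical(fc1, fc2)
  expect_equal(length(fc1), 4L)
  expect_error(compute_fc(region_timeseries(matrix(rnorm(3 * fs * 50), 3),
                                            fs),
                          default_bands(), spec), "shorter")
  expect_error(dynamic_wpli(matrix(complex(real = rnorm(32)), 1), 64,
                            window_spec()), "longer than the data")
})
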