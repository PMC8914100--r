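# Filtering, analytic signal, instantaneous frequency, decimation, spectra.
# Full-rate (256 Hz) checks use shorter signals; statistical checks run at
# the 1 Hz analysis rate.

central <- function(x) {
  n <- length(x)
  x[(n %/% 4):(3 * n %/% 4)]
}

test_that("infraslow bandpass passes the band center and rejects 1 Hz", {
  fs <- 256
  t <- seq(0, 4000 - 1 / fs, by = 1 / fs)
  y <- bandpass_isa(sin(2 * pi * 0.05 * t), fs)
  amp <- max(abs(central(y)))
  expect_gt(amp, 0.9)
  expect_lt(amp, 1.1)
  y1 <- bandpass_isa(sin(2 * pi * 1 * t), fs)
  # frequency-response oracle: the effective filter is |H_butter|^2
  # (forward-backward order-2 Butterworth bandpass)
  H2 <- function(f) {
    w <- 2 * pi * f
    lo <- 2 * pi * 0.01; hi <- 2 * pi * 0.1
    bw <- hi - lo; w0 <- sqrt(lo * hi)
    s <- 1i * w
    x <- (s^2 + w0^2) / (bw * s)     # lowpass prototype frequency
    Mod(1 / (x^2 + sqrt(2) * x + 1))^2
  }
  expected_db <- 20 * log10(H2(1))
  expect_lt(expected_db, -20)
  measured_db <- 20 * log10(max(abs(central(y1))))
  expect_lt(measured_db, -20)
  expect_lt(abs(measured_db - expected_db), 6)
  expect_equal(bandpass_isa(numeric(length(t)), fs), numeric(length(t)))
})

test_that("bandpass is linear and enforces a minimum length", {
  fs <- 4
  set.seed(2)
  x <- rnorm(4000)
  expect_equal(bandpass_isa(3.7 * x, fs), 3.7 * bandpass_isa(x, fs),
               tolerance = 1e-9)
  expect_error(bandpass_isa(rnorm(100), fs), "at least")
  expect_error(bandpass_isa(x, fs = 0.15), "fs")
})

test_that("highpass removes DC and drifts but passes the infraslow band", {
  fs <- 4
  t <- seq(0, 4000 - 1 / fs, by = 1 / fs)
  hc <- highpass(rep(5, length(t)), fs)
  expect_lt(max(abs(central(hc))), 5e-6)
  hs <- highpass(sin(2 * pi * 0.05 * t), fs)
  amp <- max(abs(central(hs)))
  expect_gt(amp, 0.9)
  expect_lt(amp, 1.1)
  # ramp oracle: a ramp is DC plus energy concentrated far below cutoff
  hr <- highpass(t, fs)
  expect_lt(max(abs(central(hr))), 0.02 * diff(range(t)))
})

test_that("analytic signal recovers tone phase, quadrature and envelope", {
  fs <- 16
  t <- seq(0, 2000 - 1 / fs, by = 1 / fs)
  a_cos <- analytic(cos(2 * pi * 0.05 * t), fs)
  i20 <- which.min(abs(t - 20))      # exactly one full cycle
  expect_lt(abs(a_cos$phase[i20]), 0.05)
  a_sin <- analytic(sin(2 * pi * 0.05 * t), fs)
  expect_lt(abs(circ_diff(a_cos$phase[i20], a_sin$phase[i20]) - pi / 2), 0.05)
  a_3 <- analytic(3 * cos(2 * pi * 0.05 * t), fs)
  expect_lt(max(abs(a_3$amplitude[a_3$valid] - 3)), 0.1)
  expect_error(analytic(numeric(100), fs), "all-zero")
})

test_that("emitted phases lie in (-pi, pi] and reconstruct the input", {
  fs <- 8
  t <- seq(0, 3000 - 1 / fs, by = 1 / fs)
  for (f0 in c(0.02, 0.05, 0.08)) {
    x <- cos(2 * pi * f0 * t + 1)
    a <- analytic(x, fs)
    expect_true(all(a$phase > -pi & a$phase <= pi))
    rec <- a$amplitude * cos(a$phase)
    cent <- central(seq_along(x))
    rmse <- sqrt(mean((rec[cent] - x[cent])^2)) / sqrt(mean(x[cent]^2))
    expect_lt(rmse, 0.05)
  }
})

test_that("edge guard flags a configurable fraction at each end", {
  a <- analytic(cos(2 * pi * 0.05 * (0:999)), fs = 1, edge_guard = 100)
  expect_equal(sum(!a$valid), 200)
  expect_false(any(a$valid[c(1:100, 901:1000)]))
  a2 <- analytic(cos(2 * pi * 0.05 * (0:999)), fs = 1, edge_guard = 0)
  expect_true(all(a2$valid))
})

test_that("instantaneous frequency tracks tones and a linear chirp", {
  fs <- 4
  t <- seq(0, 2000 - 1 / fs, by = 1 / fs)
  for (f0 in c(0.05, 0.02)) {
    a <- analytic(cos(2 * pi * f0 * t), fs)
    f <- instantaneous_frequency(a)
    expect_lt(max(abs(central(f) - f0)), 0.001)
  }
  # chirp 0.01 -> 0.09 Hz: instantaneous frequency at the midpoint is the
  # derivative of the analytic phase 2*pi*(f0*t + k*t^2/2), i.e. 0.05 Hz
  Tend <- 2000
  k <- (0.09 - 0.01) / Tend
  ch <- cos(2 * pi * (0.01 * t + k * t^2 / 2))
  fmid <- instantaneous_frequency(analytic(ch, fs))[which.min(abs(t - Tend / 2))]
  expect_lt(abs(fmid - 0.05), 0.005)
  expect_error(instantaneous_frequency(0.3, fs = 1), "at least 2")
})

test_that("decimation keeps counts, constants and phase arithmetic", {
  expect_length(downsample(rnorm(2560), 256, 1), 10)
  expect_equal(downsample(rep(2.5, 1024), 256, 1), rep(2.5, 4))
  expect_error(downsample(rnorm(100), 3, 2), "integer ratio")
  # phases of a 0.05 Hz tone advance 2*pi*0.05 rad per 1 Hz output sample
  fs <- 32
  t <- seq(0, 1000 - 1 / fs, by = 1 / fs)
  a <- analytic(cos(2 * pi * 0.05 * t), fs)
  ph1 <- downsample(a, fs_out = 1)
  expect_s3_class(ph1, "analytic_series")
  steps <- wrap_phase(diff(ph1$phase[ph1$valid]))
  expect_lt(max(abs(steps - 2 * pi * 0.05)), 0.01)
})

test_that("magnitude spectrum locates tones, DC and the generator slope", {
  x <- cos(2 * pi * 0.05 * (0:1999))
  sp <- magnitude_spectrum(x, fs = 1)
  expect_true(all(sp$magnitude >= 0))
  expect_true(all(diff(sp$freqs) > 0))
  expect_equal(sp$freqs[which.max(sp$magnitude)], 0.05)
  spc <- magnitude_spectrum(rep(4, 256), fs = 1)
  expect_equal(which.max(spc$magnitude), 1L)
  expect_lt(max(spc$magnitude[-1]) / spc$magnitude[1], 1e-10)
  # PSD slope -2 <=> magnitude slope -1 on log-log axes
  x1f <- gen_pink_noise(2^16, fs = 1, slope = -2, seed = 11)
  expect_lt(abs(loglog_slope(magnitude_spectrum(x1f, 1)) - (-1)), 0.3)
  expect_error(magnitude_spectrum(numeric(0), 1), "empty")
})

test_that("preprocessing Hilbert-transforms at the native rate, then decimates", {
  s <- gen_session(desk_cfg(duration = 2000, fs = 8, seed = 5))
  pp <- preprocess_recording(s$recording)
  # regression: identical to the explicit full-rate chain
  x <- s$recording$data[1, ]
  manual <- downsample(analytic(bandpass_isa(x, 8), 8,
                                edge_guard = 100), fs_out = 1)
  expect_equal(pp$phase[1, ], manual$phase, tolerance = 1e-12)
  expect_equal(pp$amplitude[1, ], manual$amplitude, tolerance = 1e-12)
  # and different from the downsample-first ordering
  wrong <- analytic(bandpass_isa(downsample(x, 8, 1), 1), 1, edge_guard = 100)
  expect_gt(max(abs(wrap_phase(pp$phase[1, pp$valid] -
                                 wrong$phase[pp$valid]))), 0.01)
  expect_equal(ncol(pp$phase), 2000)
  expect_true(all(is.na(pp$ifreq[gsr_row(pp), ])))
  expect_false(any(is.na(pp$ifreq[1, ])))
})
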