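# Mean-resultant coherence over channels (ICPC) and trials (ITPC), the
# pseudo-random-timing permutation null, and the lag scan.

brute_resultant <- function(th) {
  s <- 0 + 0i
  for (v in th) s <- s + complex(modulus = 1, argument = v)
  Mod(s / length(th))
}

test_that("coherence closed forms hold exactly", {
  expect_equal(icpc(rep(1.234, 7)), 1)
  expect_equal(icpc(c(0, pi)), 0)
  expect_equal(icpc(c(0, pi / 2)), 1 / sqrt(2))
  expect_error(icpc(numeric(0)), "empty")
  expect_error(icpc(c(0, NA)), "non-finite")
})

test_that("coherence matches a brute-force complex sum on random vectors", {
  set.seed(20)
  for (i in 1:1000) {
    n <- sample(1:64, 1)
    th <- runif(n, -pi, pi)
    expect_equal(icpc(th), brute_resultant(th), tolerance = 1e-12)
  }
})

test_that("coherence is bounded, rotation-invariant, and 1 iff aligned", {
  set.seed(21)
  for (i in 1:200) {
    th <- runif(sample(2:64, 1), -pi, pi)
    v <- icpc(th)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(icpc(wrap_phase(th + runif(1, -10, 10))), v,
                 tolerance = 1e-12)
  }
  expect_gt(icpc(rep(-2, 50)), 1 - 1e-12)
  th <- runif(30, -1, 1)
  expect_lt(icpc(th), 1 - 1e-12)   # dispersed phases never reach 1
})

test_that("ITPC time courses follow the trial phase structure", {
  # identical trajectories: ITPC = 1 everywhere
  traj <- matrix(rep(seq(-3, 3, length.out = 31), each = 5), nrow = 5)
  expect_equal(itpc_timecourse(traj)$itpc, rep(1, 31))
  # balanced quadrature phases: ITPC = 0 everywhere
  quad <- matrix(rep(c(0, pi / 2, pi, -pi / 2), 31), nrow = 4)
  expect_equal(itpc_timecourse(quad)$itpc, rep(0, 31), tolerance = 1e-12)
  expect_error(itpc_timecourse(traj[1, , drop = FALSE]), "at least 2")
})

test_that("onset-reset trials decay from full coherence as jitter accrues", {
  # constructed ground truth: every trial starts at phase 0 and then
  # accumulates independent phase jitter
  set.seed(22)
  mean_itpc <- matrix(0, 50, 31)
  for (r in 1:50) {
    ph <- t(vapply(1:20, function(i)
      cumsum(c(0, rnorm(30, 0, 0.25))), numeric(31)))
    mean_itpc[r, ] <- itpc_timecourse(wrap_phase(ph))$itpc
  }
  avg <- colMeans(mean_itpc)
  expect_equal(avg[1], 1)
  expect_true(all(diff(avg) < 0.005))        # non-increasing on average
  expect_lt(avg[31], 0.5)
})

test_that("the permutation null is seeded, calibrated at its median, and
           rejects perfect coherence", {
  d <- desk_session(desk_cfg(seed = 30, reset_kappa = 0))
  pool <- ifelse(d$pp$valid, d$pp$phase[1, ], NA)
  n1 <- itpc_null(pool, n_trials = 40, n_perm = 2000, seed = 5)
  n2 <- itpc_null(pool, n_trials = 40, n_perm = 2000, seed = 5)
  expect_identical(n1$values, n2$values)
  med <- stats::median(n1$values)
  expect_lt(abs(itpc_pvalue(n1, med) - 0.5), 0.05)
  # ITPC = 1 with N = 40: far beyond any pseudo-ITPC of a long recording
  expect_lte(itpc_pvalue(n1, 1), 0.001)
  expect_gt(itpc_pvalue(n1, 0), 0.999)
  expect_warning(itpc_null(pool, 10, n_perm = 50, seed = 1), "unstable")
  expect_error(itpc_null(rep(NA_real_, 100), 10, seed = 1), "too short")
})

test_that("lag scans recover designed shifts and reject independence", {
  d <- desk_session(desk_cfg(seed = 31))
  ph <- d$pp$phase[1, d$pp$valid]
  # exact copy: zero lag, coherence 1
  s0 <- lag_scan(ph, ph, n_null = 0)
  expect_equal(s0$best_lag, 0)
  expect_equal(s0$best_icpc, 1, tolerance = 1e-12)
  # pure delayed copy of the phase series
  s5 <- lag_scan(ph, c(rep(ph[1], 5), ph[1:(length(ph) - 5)]), n_null = 0)
  expect_lte(abs(s5$best_lag - 5), 1)
  # injected integer lags via the generator's peripheral coupling,
  # noiseless: recovered exactly at the 1 Hz grid
  for (lag in c(-30, -7, 13, 30)) {
    di <- desk_session(desk_cfg(seed = 31 + lag, gsr_lag = lag,
                                gsr_noise_sd = 0))
    sc <- lag_scan(di$pp$phase[1, ], di$pp$phase[gsr_row(di$pp), ],
                   n_null = 0)
    expect_lte(abs(sc$best_lag - lag), 1)
  }
})

test_that("shift surrogates track phase autocorrelation; uniform ones do not", {
  ref_a <- desk_session(desk_cfg(seed = 498))
  ref_b <- desk_session(desk_cfg(seed = 499))
  pa <- ref_a$pp$phase[1, ref_a$pp$valid][1:7000]
  pb <- ref_b$pp$phase[gsr_row(ref_b$pp), ref_b$pp$valid][1:7000]
  null_shift <- lag_scan_null(pa, pb, n_null = 200, seed = 40)
  null_unif <- lag_scan_null(7000, surrogate = "uniform",
                             n_null = 200, seed = 41)
  expect_gt(null_shift, 0)
  expect_lt(null_shift, 0.3)
  # smooth phases reach far higher chance alignment than i.i.d. phases:
  # a null ignoring autocorrelation is drastically anti-conservative
  expect_gt(null_shift, 2 * null_unif)
  # a coupled pair exceeds its own shift-surrogate level decisively
  d <- desk_session(desk_cfg(seed = 497))
  sc <- lag_scan(d$pp$phase[1, d$pp$valid],
                 d$pp$phase[gsr_row(d$pp), d$pp$valid],
                 n_null = 200, seed = 42)
  expect_gt(sc$best_icpc, sc$null95)
  expect_error(lag_scan_null(7000, surrogate = "shift"), "both phase series")
})

test_that("lags with insufficient overlap are dropped with a warning", {
  set.seed(41)
  th <- runif(400, -pi, pi)
  expect_warning(sc <- lag_scan(th, th, lag_range = 150, min_overlap = 300,
                                n_null = 0),
                 "dropped")
  expect_true(all(abs(sc$lags) <= 100))
  expect_error(suppressWarnings(lag_scan(th[1:10], th[1:10], lag_range = 20,
                                         min_overlap = 300)), "no lag")
})
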