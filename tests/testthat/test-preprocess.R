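test_that("calibration formula is exact at its analytic points", {
  kd <- 0.345; fmin <- 100; fmax <- 200
  expect_equal(calibrate(fmin, kd, fmin, fmax), 0)
  expect_equal(calibrate((fmin + fmax) / 2, kd, fmin, fmax), kd)
  # near-saturation divergence and the clamp
  eps <- 1e-3 * (fmax - fmin)
  expect_equal(calibrate(fmax - eps, kd, fmin, fmax),
               kd * (fmax - eps - fmin) / eps)
  expect_error(calibrate(fmax, kd, fmin, fmax), "Fmax")
  expect_equal(calibrate(fmax, kd, fmin, fmax, clamp = TRUE),
               calibrate(fmax - eps, kd, fmin, fmax))
  expect_error(calibrate(1, kd, fmin = 5, fmax = 5), "fmin < fmax")
})

test_that("calibration is strictly increasing on (Fmin, Fmax)", {
  f <- seq(100.5, 199.5, by = 0.5)
  ca <- calibrate(f, 0.345, 100, 200)
  expect_true(all(diff(ca) > 0))
})

test_that("low-pass filter passes DC, kills supra-cutoff content, preserves phase", {
  n <- 400; dt <- 2
  mk <- function(v) calcium_trace(v, dt = dt, stim_index = 1)
  # constant trace is unchanged
  const <- smooth_trace(mk(rep(0.7, n)))
  expect_equal(const$values, rep(0.7, n), tolerance = 1e-9)
  tt <- (seq_len(n) - 1) * dt
  # 0.2 Hz sits 2x above the 0.1 Hz cutoff: amplitude must drop >= 90%
  hi <- sin(2 * pi * 0.2 * tt)
  hi_f <- smooth_trace(mk(hi))$values
  mid <- 50:350   # interior, away from boundary effects
  expect_lt(sd(hi_f[mid]) / sd(hi[mid]), 0.10)
  # sub-cutoff sinusoid passes with zero phase shift: project the filtered
  # signal onto the quadrature pair and read off the phase angle
  lo <- sin(2 * pi * 0.02 * tt)
  lo_q <- cos(2 * pi * 0.02 * tt)
  lo_f <- smooth_trace(mk(lo))$values
  cf <- coef(lm(lo_f[mid] ~ lo[mid] + lo_q[mid] - 1))
  expect_lt(abs(atan2(cf[2], cf[1])), 0.02)   # radians
  expect_gt(cf[1], 0.95)
})

test_that("reflective padding prevents edge damping of the initial response", {
  # reference transient riding on an elevated basal level: a zero-state
  # filter drags the trace start toward zero, the mirror padding does not
  x <- simulate_trace(rep(0, 17), stimulus_protocol(t_on = 0,
                                                    duration = 400))$values + 0.4
  tr <- calcium_trace(x, dt = 2, stim_index = 1)
  padded <- smooth_trace(tr)$values
  co <- calcistate:::butter2_lowpass(0.1, 0.5)
  unpadded <- rev(calcistate:::iir_filter(co$b, co$a,
                  rev(calcistate:::iir_filter(co$b, co$a, x))))
  err_pad <- max(abs(padded[1:15] - x[1:15]))
  err_unpad <- max(abs(unpadded[1:15] - x[1:15]))
  expect_lt(err_pad, 0.1)             # sharp rise survives
  expect_gt(err_unpad, 3 * err_pad)   # visible edge artifact without padding
  # the smoothed trace starts at the basal level point
  expect_identical(padded[1], x[1])
})

test_that("smoothing is nearly idempotent at the stated noise level", {
  rend <- render_traces(matrix(0, 1, 17), stimulus_protocol(duration = 600),
                        noise_spec(), seed = 21)
  tr <- calcium_trace(rend$traces[1, ], dt = 2, stim_index = 1)
  once <- smooth_trace(tr)
  twice <- smooth_trace(once)
  rms_change <- sqrt(mean((twice$values - once$values)^2))
  expect_lt(rms_change, 0.01 * diff(range(once$values)))
})

test_that("noise floor is zero for clean data and grows with noise", {
  tr <- simulate_trace(rep(0, 17), stimulus_protocol(t_on = 0,
                                                     duration = 600))
  expect_equal(noise_floor(tr, tr), 0)
  set.seed(31)
  eps <- vapply(c(0.01, 0.1, 1), function(s) {
    noisy <- tr
    noisy$values <- tr$values + rnorm(length(tr$values), 0, s)
    noise_floor(noisy, smooth_trace(noisy))
  }, numeric(1))
  expect_true(all(diff(eps) > 0))
  expect_true(all(eps > 0))
})

test_that("per-cell thresholds across a synthetic population are positive", {
  pop <- synthesize_population(8, seed = 41)
  eps <- vapply(seq_len(8), function(i) {
    tr <- calcium_trace(pop$traces[i, ], dt = 2, stim_index = 16,
                        cell_id = paste0("c", i))
    preprocess_trace(tr)$epsilon_final
  }, numeric(1))
  expect_true(all(eps > 0))
  expect_lt(max(eps) / min(eps), 50)  # same noise model: same order of magnitude
})

test_that("features are exact on an analytic triangle pulse", {
  x <- c(seq(0, 1, length.out = 11), seq(0.95, 0, length.out = 20))
  tr <- calcium_trace(x, dt = 1, stim_index = 1)
  fe <- extract_features(tr, response_floor = 0.05)
  expect_true(fe$responder)
  expect_equal(fe$f0, 0)
  expect_equal(fe$fm, 1)
  expect_equal(fe$tm, 10)
  expect_equal(fe$t50u, 5)
  expect_equal(fe$t50d, 10)
  expect_false(fe$t50d_censored)
})

test_that("flat traces are flagged non-responders; plateaus censor t50d", {
  flat <- extract_features(calcium_trace(rep(0.3, 50), 2, 1))
  expect_false(flat$responder)
  expect_true(is.na(flat$fm))
  plateau <- extract_features(calcium_trace(c(0.1, seq(0.1, 1, length.out = 9),
                                              rep(0.9, 40)), 2, 1))
  expect_true(plateau$t50d_censored)
})

test_that("features survive noise followed by filtering (within one sample)", {
  # a transient with a crisp peak (fast IP3 turnover / desensitization and
  # stronger inactivation); the reference transient's top is flat for
  # minutes, which makes the peak-time feature ill-determined by design
  th <- stats::setNames(rep(0, 17), calci_param_names())
  th[c("k_ip3_deg", "k_r", "dinh")] <- c(0.8, 0.8, -0.3)
  clean <- simulate_trace(th, stimulus_protocol(t_on = 0, duration = 900))
  fe0 <- extract_features(clean)
  set.seed(51)
  noisy <- clean
  tt <- (seq_along(clean$values) - 1) * 2
  noisy$values <- clean$values + 0.02 * sin(2 * pi * 0.2 * tt) +
    rnorm(length(tt), 0, 0.02)
  fe1 <- extract_features(smooth_trace(noisy))
  dt <- 2
  expect_lt(abs(fe1$tm - fe0$tm), dt + 1e-9)
  expect_lt(abs(fe1$t50u - fe0$t50u), dt + 1e-9)
  expect_lt(abs(fe1$fm - fe0$fm), 0.05)
  expect_lt(abs(fe1$ff - fe0$ff), 0.05)
})
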