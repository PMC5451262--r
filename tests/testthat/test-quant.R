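test_that("traces are background-subtracted sums over the ROI", {
  k <- default_kym()
  # uniform synthetic grid: value equals background everywhere -> zero trace
  flat <- synthetic_line_kymogram(tibble::tibble(direction = character(0),
                                                 origin_time = numeric(0),
                                                 velocity = numeric(0),
                                                 amplitude = numeric(0)),
                                  duration = 5)
  tr0 <- extract_trace(flat, roi_pool(flat, "exp"))
  expect_true(all(abs(tr0$value) < 1e-9))
  expect_equal(nrow(tr0), nrow(flat))

  tr <- extract_trace(k, roi_pool(k, "exp"))
  expect_equal(nrow(tr), nrow(k))
  expect_error(extract_trace(k, integer(0)), class = "iftpool_input_error")
  expect_error(extract_trace(k, 10^6), class = "iftpool_input_error")
})

test_that("noise-free pool traces are proportional to the true pool content", {
  cfg <- build_default_config("IFT54", duration = 30)
  sim <- run_simulation(cfg, bleach_protocol(bleach_pulse(10)), seed = 41)
  k <- render_kymogram(sim, render_config(read_noise_sd = 0), noise = FALSE)[[1]]
  tr <- extract_trace(k, roi_pool(k, "exp"))
  gt <- sim$pool[sim$pool$structure == "exp", ]
  expect_gt(cor(tr$value, gt$unbleached), 0.999)
  slope <- coef(lm(tr$value ~ 0 + gt$unbleached))[[1]]
  # ROI captures nearly all pool photons
  expect_within(slope / render_config()$photons_per_copy, 1, 0.05,
                "photons per copy recovered")
})

test_that("normalization is an exact frame-by-frame percentage", {
  tm <- seq(0, 10, 0.1)
  a <- tibble::tibble(time = tm, value = 50 + 10 * sin(tm), mask = FALSE)
  expect_true(all(abs(normalize_trace(a, a)$value - 100) < 1e-9))
  b <- a; b$value <- 0.8 * a$value
  expect_true(all(abs(normalize_trace(b, a)$value - 80) < 1e-9))
  expect_error(normalize_trace(a, a[1:50, ]), class = "iftpool_input_error")
})

test_that("normalization cancels decay shared with the control structure", {
  mk <- function(rate) {
    cfg <- build_default_config("IFT54", duration = 40,
                                imaging_bleach_rate = rate)
    sim <- run_simulation(cfg, bleach_protocol(bleach_pulse(10)), seed = 42)
    k <- render_kymogram(sim)[[1]]
    normalize_trace(extract_trace(k, roi_pool(k, "exp")),
                    extract_trace(k, roi_pool(k, "ctrl")))
  }
  nt0 <- mk(0)
  nt5 <- mk(0.005)
  late0 <- mean(nt0$value[nt0$time > 25], na.rm = TRUE)
  late5 <- mean(nt5$value[nt5$time > 25], na.rm = TRUE)
  expect_within(late5, late0, 6, "imaging-decay-insensitive recovery level")
})

test_that("the two-line recovery fit is exact on piecewise-linear traces", {
  tm <- seq(0, 25, 0.1)
  v <- ifelse(tm < 10, 100, pmin(90, 40 + 10 * (tm - 10)))
  f <- fit_frap(tibble::tibble(time = tm, value = v, mask = FALSE), 10)
  expect_false(f$censored)
  expect_equal(f$recovery_time, 5, tolerance = 1e-8)
  expect_equal(f$plateau_level, 90, tolerance = 1e-8)
  expect_equal(f$rising_slope, 10, tolerance = 1e-8)

  # still-rising trace has no plateau
  v2 <- ifelse(tm < 10, 100, 10 + 3.5 * (tm - 10))
  f2 <- fit_frap(tibble::tibble(time = tm, value = v2, mask = FALSE), 10)
  expect_true(f2$censored)
})

test_that("the recovery breakpoint is found within 0.5 s under 2% noise", {
  tm <- seq(0, 30, 0.1)
  base <- ifelse(tm < 10, 100, pmin(80, 30 + 10 * (tm - 10)))  # breakpoint 15 s
  set.seed(43)
  est <- vapply(1:100, function(i) {
    v <- base + rnorm(length(tm), 0, 2)
    f <- fit_frap(tibble::tibble(time = tm, value = v, mask = FALSE), 10)
    f$recovery_time
  }, numeric(1))
  expect_within(mean(est, na.rm = TRUE), 5, 0.5, "recovery under noise")
})

test_that("the FLIP fit recovers slope, loss and plateau on exact traces", {
  tm <- seq(0, 40, 0.1)
  v <- ifelse(tm < 5, 100, pmax(70, 100 - 3 * (tm - 5)))
  f <- fit_flip(tibble::tibble(time = tm, value = v, mask = FALSE), 5)
  expect_equal(f$initial_slope, -3, tolerance = 1e-6)
  expect_equal(f$loss_at_10s, 30, tolerance = 1.5)  # smoothed endpoints
  expect_true(f$declined)
  expect_within(f$plateau_level, 70, 1, "FLIP plateau level")
  expect_within(f$plateau_time, 10, 1.5, "FLIP plateau time")

  flat <- fit_flip(tibble::tibble(time = tm, value = rep(100, length(tm)),
                                  mask = FALSE), 5)
  expect_equal(flat$initial_slope, 0, tolerance = 1e-9)
  expect_false(flat$declined)
})

test_that("the pool trough is measured from decline depth and duration", {
  tm <- seq(0, 30, 0.1)
  v <- ifelse(tm < 10, 100, ifelse(tm < 16, 100 - 8 * (tm - 10),
                                   ifelse(tm < 21, 52, 52 + 9 * (tm - 21))))
  tro <- measure_pool_trough(tibble::tibble(time = tm, value = v, mask = FALSE),
                             10)
  expect_within(tro$decline_pct, 48, 3, "decline depth")
  expect_within(tro$decline_duration, 6, 1.2, "decline duration")
})
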