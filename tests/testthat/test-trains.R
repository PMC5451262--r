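test_that("detection is exact on noise-free constructed lines", {
  one <- synthetic_line_kymogram(
    tibble::tibble(direction = "anterograde", origin_time = 3, velocity = 2,
                   amplitude = 400), duration = 12)
  tj <- detect_trains(one, "exp")
  ant <- tj[tj$direction == "anterograde", ]
  expect_equal(nrow(ant), 1)
  expect_within(ant$velocity, 2, 0.1, "single-line velocity")
  expect_within(ant$origin_time, 3, 0.1, "single-line origin")

  # crossing anterograde and retrograde lines keep their signs and slopes
  cross <- synthetic_line_kymogram(
    tibble::tibble(direction = c("anterograde", "retrograde"),
                   origin_time = c(2, 2), velocity = c(2, -3),
                   amplitude = c(400, 400)), duration = 12)
  tj2 <- detect_trains(cross, "exp")
  expect_equal(nrow(tj2), 2)
  expect_setequal(sign(tj2$velocity), c(1, -1))
  expect_within(tj2$velocity[tj2$velocity > 0], 2, 0.1, "anterograde slope")
  expect_within(tj2$velocity[tj2$velocity < 0], -3, 0.1, "retrograde slope")
})

test_that("recall is 1 with no false positives on separated noise-free lines", {
  lines <- tibble::tibble(direction = "anterograde",
                          origin_time = seq(2, 18, by = 2), velocity = 2,
                          amplitude = 300)
  k <- synthetic_line_kymogram(lines, duration = 26)
  tj <- detect_trains(k, "exp")
  ant <- tj[tj$direction == "anterograde", ]
  expect_equal(nrow(ant), nrow(lines))
  expect_true(all(vapply(lines$origin_time,
                         function(t) min(abs(ant$origin_time - t)) <= 0.15,
                         logical(1))))
})

test_that("detection degrades gracefully with photon budget", {
  sim <- default_sim()
  dep <- sim$trains$departure[sim$trains$structure == "exp"]
  dep <- dep[dep >= 0 & dep <= 55]
  recall <- vapply(c(5, 20, 80), function(ppc) {
    k <- render_kymogram(sim, render_config(photons_per_copy = ppc))[[1]]
    tj <- detect_trains(k, "exp")
    ant <- tj$origin_time[tj$direction == "anterograde"]
    mean(vapply(dep, function(t) any(abs(ant - t) < 0.3), logical(1)))
  }, numeric(1))
  expect_gte(recall[2], 0.8)
  expect_gte(recall[3], recall[1])
  expect_gte(recall[1], 0.3)
})

test_that("traffic statistics count and summarize by direction", {
  tj <- tibble::tibble(structure = "exp",
                       direction = rep("anterograde", 10),
                       origin_time = 1:10, origin_position = 0,
                       velocity = 2, duration = 6, intensity = 100,
                       quality = 50)
  s <- traffic_stats(tj, "anterograde", 10)
  expect_equal(s$frequency, 1)
  expect_equal(s$velocity_mean, 2)
  empty <- traffic_stats(tj[0, ], "retrograde", 10)
  expect_equal(empty$frequency, 0)
  expect_false(empty$velocity_defined)
  expect_error(traffic_stats(tj, "anterograde", 0), class = "iftpool_input_error")
})

test_that("kymogram estimators agree with the event-log ground truth", {
  # an open-class protein: post-bleach trains are either dark or full, so
  # the intensity floor is unambiguous on both routes
  cfg <- build_default_config("D1bLIC", duration = 40)
  prot <- bleach_protocol(bleach_pulse(10))
  for (s in 1:3) {
    sim <- run_simulation(cfg, prot, seed = 50 + s)
    k <- render_kymogram(sim)[[1]]
    tj <- detect_trains(k, "exp")
    g <- measure_gap(tj, 10)
    expect_within(g$gap, oracle_gap(sim, 10), 0.3,
                  sprintf("gap vs oracle (seed %d)", 50 + s))
    # velocity matches the configured transport speed within quantization
    st <- traffic_stats(tj, "anterograde", 40)
    expect_within(st$velocity_mean, cfg$v_antero, 0.1, "anterograde velocity")
  }
})

test_that("without bleaching the gap is just the wait for the next train", {
  cfg <- build_default_config("IFT54", duration = 30)
  sim <- run_simulation(cfg, bleach_protocol(bleach_pulse(10, efficiency = 0)),
                        seed = 55)
  k <- render_kymogram(sim)[[1]]
  g <- measure_gap(detect_trains(k, "exp"), 10)
  expect_lt(g$gap, 3)   # ~1/rate plus the quantization guard
})

test_that("departure drops read the step left by a departing train", {
  tm <- seq(0, 20, 0.1)
  v <- ifelse(tm < 10, 100, 84)   # 16 of 100 copies leave at t = 10
  d <- departure_drops(tibble::tibble(time = tm, value = v, mask = FALSE), 10)
  expect_within(d$drop, 16, 0.5, "clean step drop")

  flat <- departure_drops(tibble::tibble(time = tm, value = rep(100, length(tm)),
                                         mask = FALSE), 10)
  expect_lt(abs(flat$drop), 2)

  # overlapping windows are skipped with a warning
  expect_warning(
    d2 <- departure_drops(tibble::tibble(time = tm, value = v, mask = FALSE),
                          c(10, 10.2)),
    regexp = "skipped")
  expect_equal(nrow(d2), 0)
})

test_that("train intensity ratios compare flagella of the same cell", {
  tj <- tibble::tibble(structure = "exp", direction = "anterograde",
                       origin_time = 1:5, origin_position = 0, velocity = 2,
                       duration = 6, intensity = c(90, 110, 100, 95, 105),
                       quality = 50)
  expect_equal(train_intensity_ratio(tj, tj), 1)
  expect_error(train_intensity_ratio(tj[1:2, ], tj),
               class = "iftpool_input_error")
})
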