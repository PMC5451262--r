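test_that("a single train renders as a straight line at its velocity", {
  cfg <- build_default_config("IFT54", duration = 10, departure_rate = 0.08,
                              departure_cv = 0, dim_fraction = 0,
                              imaging_bleach_rate = 0)
  sim <- run_simulation(cfg, NULL, seed = 31)
  k <- render_kymogram(sim, render_config(read_noise_sd = 0), noise = FALSE)[[1]]
  lay <- attr(k, "layout")
  dep <- sim$trains$departure[sim$trains$structure == "exp"]
  dep <- dep[dep >= 0 & dep <= 6]
  cols <- roi_flagellum(k, "exp")
  # peak position in each frame while the train is mid-flagellum
  frames <- which(attr(k, "time") > dep + 1 & attr(k, "time") < dep + 5)
  peak_px <- apply(unclass(k)[frames, cols], 1, which.max)
  tt <- attr(k, "time")[frames]
  slope_um_s <- coef(lm(peak_px ~ tt))[[2]] * attr(k, "pixel_size")
  expect_within(slope_um_s, cfg$v_antero, 0.1, "rendered line slope")
})

test_that("signal is linear in unbleached copies and zero without photons", {
  sim <- default_sim()
  k0 <- render_kymogram(sim, render_config(photons_per_copy = 0,
                                           read_noise_sd = 0))[[1]]
  expect_within(mean(unclass(k0)), render_config()$background, 0.2,
                "pure background mean")

  k1 <- render_kymogram(sim, render_config(), noise = FALSE)[[1]]
  k2 <- render_kymogram(sim, render_config(photons_per_copy = 40),
                        noise = FALSE)[[1]]
  bg <- render_config()$background
  s1 <- sum(unclass(k1) - bg); s2 <- sum(unclass(k2) - bg)
  expect_within(s2 / s1, 2, 1e-6, "linearity in photons per copy")
})

test_that("pixel noise follows Poisson plus read noise", {
  # static scene: standing pool material only, no traffic, no imaging bleach
  cfg <- build_default_config("IFT54", duration = 40, departure_rate = 1e-4,
                              imaging_bleach_rate = 0)
  sim <- run_simulation(cfg, NULL, seed = 32)
  rc <- render_config(read_noise_sd = 2)
  k <- render_kymogram(sim, rc)[[1]]
  m <- unclass(k)
  lam <- colMeans(m)
  v <- apply(m, 2, var)
  pred <- lam + rc$read_noise_sd^2
  # aggregate over pixels: variance tracks mean + read noise
  expect_within(mean(v / pred), 1, 0.1, "noise variance ratio")
})

test_that("rendering is deterministic under a fixed seed", {
  sim <- default_sim()
  k1 <- render_kymogram(sim)[[1]]
  k2 <- render_kymogram(sim)[[1]]
  expect_identical(unclass(k1), unclass(k2))
})

test_that("a frame stack's line scan reproduces the kymogram exactly", {
  cfg <- build_default_config("IFT54", duration = 10)
  sim <- run_simulation(cfg, NULL, seed = 33)
  k <- render_kymogram(sim)[[1]]
  st <- render_frame_stack(sim)
  k2 <- extract_kymogram_from_stack(st, width = 1, mode = "max")
  expect_equal(unclass(k2), unclass(k), ignore_attr = TRUE)

  # single frozen frame: one Gaussian spot at the train position
  f <- 50
  prof <- st$frames[st$center_row, roi_flagellum(k, "exp"), f]
  expect_gt(max(prof), 3 * mad(prof))
})

test_that("duty-cycle acquisition dialects drop or saturate laser-on frames", {
  cfg <- build_default_config("IFT54", duration = 20)
  L <- cfg$flagellum_length
  prot <- bleach_protocol(bleach_flip(5, 20, window = c(L - 1.5, L)))
  sim <- run_simulation(cfg, prot, seed = 34)

  k_drop <- render_kymogram(sim, render_config())[[1]]
  n_on <- sum(attr(k_drop, "mask"))
  expect_gt(n_on, 10)
  expect_true(all(is.na(unclass(k_drop)[attr(k_drop, "mask"), ])))

  st <- render_frame_stack(sim)
  expect_equal(dim(st$frames)[3], nrow(k_drop) - n_on)

  rc_sat <- render_config(acquisition_dialect = "saturated-frames")
  k_sat <- render_kymogram(sim, rc_sat)[[1]]
  expect_true(all(unclass(k_sat)[attr(k_sat, "mask"), ] == rc_sat$saturation_level))
})

test_that("kymograms round-trip through 16-bit TIFF with JSON sidecar", {
  k <- default_kym()
  path <- withr::local_tempfile(fileext = ".tif")
  write_kymogram_tiff(k, path)
  k2 <- read_kymogram_tiff(path)
  expect_true(max(abs(unclass(k2) - unclass(k)), na.rm = TRUE) <=
                max(unclass(k), na.rm = TRUE) / 65535 + 1e-9)
  expect_equal(attr(k2, "frame_interval"), attr(k, "frame_interval"))
  expect_equal(attr(k2, "layout")$flag_base, attr(k, "layout")$flag_base)
})
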