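test_that("experiments are reproducible bit for bit from their seed", {
  a <- run_gap("D1bLIC", n = 3, seed = 99, duration = 30)
  b <- run_gap("D1bLIC", n = 3, seed = 99, duration = 30)
  expect_identical(a$replicates, b$replicates)
  expect_s3_class(tidy(a), "tbl_df")
  expect_equal(glance(a)$n, 3)
})

test_that("pool FRAP recovers on the recruitment timescale", {
  kap <- cached("frap_kap", run_frap_pool("KAP", n = 6, seed = 1))
  i54 <- cached("frap_ift54", run_frap_pool("IFT54", n = 6, seed = 1))
  rk <- kap$summary[kap$summary$metric == "recovery_time", ]
  r54 <- i54$summary[i54$summary$metric == "recovery_time", ]
  expect_gte(rk$n, 3)
  # recovery tracks the recruitment lead (plus rise-detection offsets)
  expect_within(rk$mean, 5.5, 3, "KAP recovery")
  expect_within(r54$mean, 7, 3, "IFT54 recovery")
})

test_that("a zero-efficiency pulse leaves no recovery dip", {
  e <- run_frap_pool("IFT54", n = 3, seed = 2, efficiency = 0, duration = 40)
  pl <- e$summary[e$summary$metric == "plateau_level", ]
  expect_gt(pl$mean, 80)
})

test_that("the tubulin gap assay is paired within one cell", {
  tg <- run_tubulin_gap(n = 6, seed = 3)
  expect_true(all(c("gap_exp", "gap_ctrl") %in% names(tg$replicates)))
  expect_equal(nrow(tg$replicates), 6)
  expect_s3_class(glance(tg), "tbl_df")
})

test_that("impossible intensity floors are reported as censored", {
  e <- run_gap("D1bLIC", n = 2, seed = 4, duration = 30, intensity_floor = 50)
  expect_true(all(e$replicates$censored))
  s <- e$summary[e$summary$metric == "gap", ]
  expect_equal(s$n_censored, 2)
})

test_that("KAP-only trains reappear before dual-labelled trains", {
  tc <- cached("two_color_small", run_two_color_gap(n = 8, seed = 5))
  expect_gte(tc$n_kap_first, 5)
  expect_lt(mean(tc$replicates$gap_KAP, na.rm = TRUE),
            mean(tc$replicates$gap_IFT140, na.rm = TRUE))
})
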