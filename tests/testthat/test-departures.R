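test_that("a zero-variance renewal is a perfect clock", {
  cfg <- build_default_config("IFT54", departure_cv = 0, duration = 10)
  set.seed(1)
  expect_equal(sample_departure_times(cfg), as.numeric(1:10))
})

test_that("renewal counts and intervals match the configured rate", {
  cfg <- build_default_config("IFT54", departure_cv = 0.3, duration = 1000)
  set.seed(2)
  d <- sample_departure_times(cfg)
  # renewal theory: count fluctuates by ~cv*sqrt(n); 3*sqrt(1000) is generous
  expect_within(length(d), 1000, 3 * sqrt(1000), "departure count")
  expect_within(mean(diff(d)), 1, 0.05, "mean interval")
})

test_that("recruitment precedes departure by the lead, truncated at zero", {
  spec <- protein_registry()[protein_registry()$name == "IFT140", ]
  spec$recruitment_lead <- 7; spec$lead_sd <- 0
  expect_equal(recruitment_time(20, spec), 13)
  expect_equal(recruitment_time(5, spec), 0)  # clamped
  spec$lead_sd <- 1
  set.seed(3)
  draws <- recruitment_time(rep(20, 1e4), spec)
  expect_within(mean(draws), 13, 0.05, "Monte-Carlo recruitment mean")
})

test_that("the bleach primitive is binomial, irreversible and edge-exact", {
  set.seed(4)
  expect_equal(apply_bleach(100, 0, 1)$unbleached, 0)
  expect_equal(apply_bleach(100, 0, 1)$bleached, 100)
  expect_equal(apply_bleach(100, 5, 0), list(unbleached = 100, bleached = 5))
  r <- apply_bleach(rep(1000, 50), rep(0, 50), 0.3)
  expect_within(mean(r$bleached) / 1000, 0.3, 0.02, "bleach fraction")
  expect_error(apply_bleach(10, 0, 1.2), class = "iftpool_protocol_error")
})

test_that("returning copies are routed by recycling class", {
  specs <- protein_registry()
  comp <- tibble::tibble(protein = c("IFT43", "IFT54"),
                         unbleached = c(18L, 15L), bleached = c(2L, 5L))
  set.seed(5)
  fate <- route_returning_train(comp, specs)
  # open class: straight to the cell body
  expect_equal(fate$to_cell_body_unbleached[fate$protein == "IFT43"], 18)
  expect_equal(fate$to_recycling_unbleached[fate$protein == "IFT43"], 0)
  expect_true(is.na(fate$residence[fate$protein == "IFT43"]))
  # semi-open: everything through the recycling compartment
  expect_equal(fate$to_recycling_unbleached[fate$protein == "IFT54"], 15)

  s54 <- specs[specs$name == "IFT54", ]
  s54$residence_sd <- 0
  fate2 <- route_returning_train(
    tibble::tibble(protein = "IFT54", unbleached = 10L, bleached = 0L), s54)
  expect_equal(fate2$residence, 6)

  s54$reuse_prob <- 0   # semi-open degenerates to open after the dwell
  fate3 <- route_returning_train(
    tibble::tibble(protein = "IFT54", unbleached = 10L, bleached = 0L), s54)
  expect_equal(fate3$reused_unbleached, 0)
  expect_equal(fate3$to_cell_body_unbleached, 10)
})
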