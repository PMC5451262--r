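test_that("copy number is conserved exactly and bleaching is irreversible", {
  cfg <- build_default_config("IFT54", duration = 30)
  sim <- run_simulation(cfg, bleach_protocol(bleach_pulse(10)), seed = 11)
  tot <- conservation_totals(sim)
  expect_true(all(tot$total == cfg$proteins$total_cell_copies))
  # bleached count never decreases (pulse + continuous imaging bleach)
  expect_true(all(diff(tot$bleached) >= 0))
  expect_true(all(diff(tot$unbleached) <= 0))
})

test_that("identical configuration and seed reproduce the run bit for bit", {
  cfg <- build_default_config("IFT54", duration = 20)
  prot <- bleach_protocol(bleach_pulse(8))
  a <- run_simulation(cfg, prot, seed = 7)
  b <- run_simulation(cfg, prot, seed = 7)
  expect_identical(a$events, b$events)
  expect_identical(a$pool, b$pool)
  expect_identical(a$trains_frames, b$trains_frames)
  c <- run_simulation(cfg, prot, seed = 8)
  expect_false(identical(a$events, c$events))
})

test_that("queue occupancy follows Little's law", {
  cfg <- build_default_config("IFT54", duration = 400)
  sim <- cached("littles_sim", run_simulation(cfg, NULL, seed = 13))
  tp <- sim$train_proteins[sim$train_proteins$structure == "exp" &
                             sim$train_proteins$carried, ]
  tr <- dplyr::left_join(tp, sim$trains, by = c("structure", "train"))
  # time-averaged number of nascent trains holding the protein
  span <- c(0, 400)
  occ <- sum(pmax(0, pmin(tr$departure, span[2]) -
                    pmax(tr$recruit_time, span[1])),
             na.rm = TRUE) / diff(span)
  lead <- cfg$proteins$recruitment_lead
  # 3 SE over a 400 s window (sd of the occupancy count ~ sqrt(lead))
  tol <- 3 * sqrt(lead) / sqrt(diff(span) / lead)
  expect_within(occ, cfg$departure_rate * lead, tol, "Little's law occupancy")
})

test_that("pool content reflects compartments and bleach events", {
  # almost no traffic: the pool is the standing material only
  cfg <- build_default_config("IFT54", duration = 10, departure_rate = 0.02)
  sim <- run_simulation(cfg, NULL, seed = 17)
  pc <- pool_content(sim, "IFT54", 0)
  standing <- round(cfg$proteins$standing_extra * cfg$proteins$copies_per_train)
  expect_lte(abs(pc$unbleached + pc$bleached - standing),
             cfg$proteins$copies_per_train)  # at most one stray nascent train

  # complete pool bleach empties the unbleached pool
  cfg2 <- build_default_config("IFT54", duration = 15)
  sim2 <- run_simulation(cfg2, bleach_protocol(bleach_pulse(10, efficiency = 1)),
                         seed = 18)
  pc_pre <- pool_content(sim2, "IFT54", 9.9)
  pc_post <- pool_content(sim2, "IFT54", 10.1)
  expect_gt(pc_pre$unbleached, 100)
  expect_equal(pc_post$unbleached, 0)
  expect_error(pool_content(sim2, "IFT999", 5), class = "iftpool_registry_error")
  expect_error(pool_content(sim2, "IFT54", 99), class = "iftpool_input_error")
})

test_that("an open-class pool ignores tip-FLIP while a semi-open pool drains", {
  L <- 12
  prot <- bleach_protocol(bleach_flip(5, 60, window = c(L - 1.5, L)))
  frac_at <- function(protein, t, seed) {
    cfg <- build_default_config(protein, duration = 60,
                                imaging_bleach_rate = 0)
    sim <- run_simulation(cfg, prot, seed = seed)
    p <- sim$pool[abs(sim$pool$time - t) < 0.01, ]
    f <- p$unbleached / (p$unbleached + p$bleached)
    stats::setNames(f, p$structure)
  }
  open_frac <- rowMeans(vapply(1:4, function(s) frac_at("IFT43", 55, 300 + s),
                               numeric(2)))
  semi_frac <- rowMeans(vapply(1:4, function(s) frac_at("IFT54", 55, 300 + s),
                               numeric(2)))
  # open class: the FLIP-side pool declines no faster than the control pool
  # (both dilute together as bleached copies mix into the shared cell body)
  expect_gt(open_frac[["exp"]] / open_frac[["ctrl"]], 0.95)
  expect_gt(open_frac[["exp"]], 0.85)

  # semi-open: converges to the flux-balance prediction
  reg <- protein_registry()
  p54 <- reg[reg$name == "IFT54", ]
  copies <- p54$copies_per_train
  mean_size <- 0.5 * 1 + 0.5 * 0.5
  N <- p54$recruitment_lead * mean_size * copies       # nascent content
  R <- p54$residence_mean * mean_size * copies          # recycling compartment
  A <- 15                                               # staged recycled copies
  S <- round(p54$standing_extra * copies)               # standing material
  plateau <- (S + (1 - p54$reuse_prob) * N) / (S + N + R + A)
  expect_within(semi_frac[["exp"]], plateau, 0.08,
                "semi-open flux-balance plateau")
})

test_that("indefinite FLIP exhausts the finite whole-cell supply", {
  cfg <- build_default_config("IFT54", duration = 150)
  cfg$proteins$total_cell_copies <- 1500L   # small cell so exhaustion shows
  L <- cfg$flagellum_length
  sim <- run_simulation(cfg, bleach_protocol(bleach_flip(5, 150,
                                                         window = c(L - 1.5, L))),
                        seed = 23)
  tot <- conservation_totals(sim)
  expect_true(all(diff(tot$unbleached) <= 0))
  expect_lt(tot$unbleached[nrow(tot)] / tot$unbleached[1], 0.5)
})

test_that("bleach protocols cannot target the control structure", {
  expect_error(bleach_pulse(5, region = "pool-ctrl"),
               class = "iftpool_protocol_error")
  expect_error(bleach_flip(5, 10, window = c(1, 2), duty_on = NA),
               class = "iftpool_protocol_error")
})
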