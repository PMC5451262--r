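#' In-silico photobleaching experiments
#'
#' Each `run_*` function repeats a full virtual experiment — simulate one
#' cell (experimental + control structure), render kymograms, extract and
#' normalize traces, quantify — for `n` independent replicates and returns
#' an `ift_experiment` with per-replicate values and a summary table
#' (mean, SD, n over non-censored replicates; a two-tailed paired t-test
#' where the assay is paired). Every result is reproducible from
#' `(arguments, seed)`.
#'
#' @name ift-experiments
NULL

new_experiment <- function(assay, protein, seed, replicates, paired_test = NULL) {
  num_cols <- names(replicates)[vapply(replicates, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "replicate")
  long <- tidyr::pivot_longer(replicates[, c("replicate", num_cols)],
                              -"replicate", names_to = "metric")
  summary <- long |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)),
                     n_censored = sum(is.na(.data$value)),
                     .groups = "drop")
  structure(list(assay = assay, protein = protein, seed = seed,
                 replicates = replicates, summary = summary,
                 paired_test = paired_test),
            class = "ift_experiment")
}

#' @export
print.ift_experiment <- function(x, ...) {
  cat(sprintf("<ift_experiment> %s (%s), %d replicate(s)\n", x$assay,
              paste(x$protein, collapse = "+"), nrow(x$replicates)))
  print(x$summary)
  if (!is.null(x$paired_test)) {
    cat(sprintf("paired t: t = %.2f, p = %.3f\n",
                x$paired_test$statistic, x$paired_test$p.value))
  }
  invisible(x)
}

# Simulate + render + pool traces for one replicate.
sim_and_traces <- function(cfg, protocol, seed, channels = NULL) {
  sim <- run_simulation(cfg, protocol, seed = seed)
  kyms <- render_kymogram(sim, channels = channels)
  traces <- lapply(kyms, function(k) {
    normalize_trace(extract_trace(k, roi_pool(k, "exp")),
                    extract_trace(k, roi_pool(k, "ctrl")))
  })
  list(sim = sim, kyms = kyms, traces = traces)
}

#' Pool FRAP experiment
#'
#' A brief laser pulse bleaches the experimental basal-body pool; the
#' normalized pool trace is fit with the two-line recovery construction.
#'
#' @param protein Registered protein name.
#' @param n Number of replicate cells.
#' @param seed Master seed.
#' @param duration Recording length (s).
#' @param t_bleach Pulse time (s).
#' @param efficiency Pulse bleach efficiency.
#' @return An `ift_experiment` with metrics `recovery_time` (s) and
#'   `plateau_level` (percent).
#' @export
run_frap_pool <- function(protein, n = 10, seed = 1, duration = 60,
                          t_bleach = 10, efficiency = 0.95) {
  cfg <- build_default_config(protein, duration = duration)
  protocol <- bleach_protocol(bleach_pulse(t_bleach, efficiency))
  reps <- purrr::map_dfr(seq_len(n), function(r) {
    st <- sim_and_traces(cfg, protocol, derive_seed(seed, 1000L + r))
    f <- fit_frap(st$traces[[1]], t_bleach)
    tibble(replicate = r, recovery_time = f$recovery_time,
           plateau_level = f$plateau_level)
  })
  new_experiment("frap_pool", protein, seed, reps)
}

#' Tip-FLIP experiment
#'
#' A duty-cycled laser parked over the distal flagellum bleaches every
#' train that passes while it is on, preventing the return of unbleached
#' protein by retrograde transport. The normalized experimental pool trace
#' is fit for initial loss and plateau, and anterograde train intensities
#' in the experimental vs control flagellum are compared.
#'
#' @inheritParams run_frap_pool
#' @param t_start FLIP onset (s); illumination continues to the end.
#' @param window_depth Extent of the bleached tip window (um from the tip).
#' @return An `ift_experiment` with metrics `loss_at_10s`, `plateau_level`,
#'   `plateau_time` and `intensity_ratio` (experimental/control anterograde
#'   train intensity during FLIP).
#' @export
run_flip_tip <- function(protein, n = 14, seed = 1, duration = 60,
                         t_start = 10, efficiency = 0.95, window_depth = 1.5) {
  cfg <- build_default_config(protein, duration = duration)
  L <- cfg$flagellum_length
  protocol <- bleach_protocol(
    bleach_flip(t_start, duration, efficiency, window = c(L - window_depth, L)))
  reps <- purrr::map_dfr(seq_len(n), function(r) {
    st <- sim_and_traces(cfg, protocol, derive_seed(seed, 2000L + r))
    f <- fit_flip(st$traces[[1]], t_start)
    k <- st$kyms[[1]]
    ratio <- tryCatch({
      te <- detect_trains(k, "exp")
      tc <- detect_trains(k, "ctrl")
      # steady state: the recycling compartment has fully turned over one
      # tip-to-base transit plus one residence plus one lead after onset
      sub <- function(tr) tr[tr$direction == "anterograde" &
                               tr$origin_time > t_start + 20, ]
      train_intensity_ratio(sub(te), sub(tc))
    }, error = function(e) NA_real_)
    tibble(replicate = r, loss_at_10s = f$loss_at_10s,
           plateau_level = f$plateau_level, plateau_time = f$plateau_time,
           intensity_ratio = ratio)
  })
  new_experiment("flip_tip", protein, seed, reps)
}

#' Whole-flagellum bleach experiment
#'
#' The entire experimental flagellum is bleached in one step. The
#' experimental pool then loses its retrograde-derived portion over several
#' seconds (the disassembly compartment flushes), stays in a trough until
#' the first post-bleach train returns, and recovers.
#'
#' @inheritParams run_frap_pool
#' @return An `ift_experiment` with metrics `decline_pct` (pool loss to the
#'   trough, percentage points), `decline_duration` (s), `first_retro_return`
#'   (s after the bleach that the first unbleached retrograde train reaches
#'   the base) and `recovery_time` (s after the bleach that the rising pool
#'   signal intercepts its recovered plateau).
#' @export
run_full_flagellum_bleach <- function(protein = "IFT54", n = 6, seed = 1,
                                      duration = 50, t_bleach = 10,
                                      efficiency = 0.99) {
  cfg <- build_default_config(protein, duration = duration)
  protocol <- bleach_protocol(bleach_whole_flagellum(t_bleach, efficiency))
  reps <- purrr::map_dfr(seq_len(n), function(r) {
    st <- sim_and_traces(cfg, protocol, derive_seed(seed, 3000L + r))
    trace <- st$traces[[1]]
    tro <- measure_pool_trough(trace, t_bleach)
    # recovery = when the smoothed pool signal first regains the prebleach
    # (control-normalized) level, within the pool's own fluctuation band
    ok <- !trace$mask & !is.na(trace$value)
    smth <- rolling_mean(trace$time[ok], trace$value[ok], 2)
    tt <- trace$time[ok]
    depth <- tro$baseline - tro$trough_level
    # re-entry band: the trace's own prebleach variability
    pre_sd <- sd(smth[tt >= t_bleach - 8 & tt <= t_bleach])
    margin <- max(pre_sd, 0.1 * max(depth, 0), na.rm = TRUE)
    rec_idx <- which(tt > tro$trough_time & smth >= tro$baseline - margin)
    recovery <- if (length(rec_idx) > 0) tt[min(rec_idx)] - t_bleach
                else NA_real_
    k <- st$kyms[[1]]
    first_ret <- tryCatch({
      tr <- detect_trains(k, "exp")
      retro <- tr[tr$direction == "retrograde", ]
      pre <- retro[retro$origin_time < t_bleach, ]
      post <- retro[retro$origin_time >= t_bleach, ]
      qual <- post[post$intensity >= 0.3 * median(pre$intensity), ]
      # time the train reaches the base, relative to the bleach
      min(qual$origin_time + qual$duration) - t_bleach
    }, error = function(e) NA_real_)
    tibble(replicate = r, decline_pct = tro$decline_pct,
           decline_duration = tro$decline_duration,
           first_retro_return = first_ret,
           recovery_time = recovery)
  })
  new_experiment("full_flagellum_bleach", protein, seed, reps)
}

#' Post-bleach gap experiment
#'
#' Bleach the experimental pool, then measure the interval until the first
#' anterograde train of at least `intensity_floor` times the prebleach
#' median intensity departs.
#'
#' @inheritParams run_frap_pool
#' @param intensity_floor Fraction of the prebleach median train intensity.
#' @return An `ift_experiment` with metric `gap` (s) and the per-replicate
#'   early-bird counts.
#' @export
run_gap <- function(protein, n = 20, seed = 1, duration = 40, t_bleach = 10,
                    efficiency = 0.95, intensity_floor = 0.3) {
  cfg <- build_default_config(protein, duration = duration)
  protocol <- bleach_protocol(bleach_pulse(t_bleach, efficiency))
  reps <- purrr::map_dfr(seq_len(n), function(r) {
    st <- sim_and_traces(cfg, protocol, derive_seed(seed, 4000L + r))
    g <- tryCatch(
      measure_gap(detect_trains(st$kyms[[1]], "exp"), t_bleach,
                  intensity_floor = intensity_floor),
      error = function(e) tibble(gap = NA_real_, n_early_birds = NA_integer_,
                                 censored = TRUE))
    tibble(replicate = r, gap = g$gap, n_early_birds = g$n_early_birds,
           censored = g$censored)
  })
  new_experiment("gap", protein, seed, reps)
}

#' Two-color gap experiment
#'
#' One cell expresses both KAP and IFT140 in separate channels; the pool is
#' bleached in both channels and the gap is measured per channel. Because
#' KAP joins assembling trains later than IFT140, the first post-bleach
#' train carrying unbleached KAP usually precedes the first carrying
#' unbleached IFT140.
#'
#' @inheritParams run_gap
#' @return An `ift_experiment` with metrics `gap_KAP`, `gap_IFT140` and the
#'   count of replicates where the KAP train came first
#'   (`n_kap_first` attribute of the summary; also a replicate column).
#' @export
run_two_color_gap <- function(n = 49, seed = 1, duration = 40, t_bleach = 10,
                              efficiency = 0.95, intensity_floor = 0.3) {
  cfg <- build_default_config(c("KAP", "IFT140"), duration = duration)
  protocol <- bleach_protocol(bleach_pulse(t_bleach, efficiency))
  reps <- purrr::map_dfr(seq_len(n), function(r) {
    st <- sim_and_traces(cfg, protocol, derive_seed(seed, 5000L + r))
    g <- lapply(c("KAP", "IFT140"), function(ch) {
      tryCatch(
        measure_gap(detect_trains(st$kyms[[ch]], "exp"), t_bleach,
                    intensity_floor = intensity_floor),
        error = function(e) tibble(gap = NA_real_, first_train = NA_real_))
    })
    tibble(replicate = r, gap_KAP = g[[1]]$gap, gap_IFT140 = g[[2]]$gap,
           kap_first = isTRUE(g[[1]]$first_train < g[[2]]$first_train))
  })
  out <- new_experiment("two_color_gap", c("KAP", "IFT140"), seed, reps)
  out$n_kap_first <- sum(reps$kap_first, na.rm = TRUE)
  out
}

#' Tubulin cargo-loading gap experiment
#'
#' After an axoneme prebleach (darkening tubulin already incorporated in
#' the flagellum), the experimental pool is bleached and the gap in
#' anterograde tubulin traffic is measured in both flagella of the same
#' cell. A short experimental gap, indistinguishable from the control
#' flagellum's plain waiting time, indicates that tubulin is loaded onto
#' trains only briefly before departure.
#'
#' @inheritParams run_gap
#' @param bleach_both Also bleach the control pool (wide-beam variant).
#' @return An `ift_experiment` with paired metrics `gap_exp`, `gap_ctrl`
#'   and a two-tailed paired t-test.
#' @export
run_tubulin_gap <- function(n = 25, seed = 1, duration = 45, t_bleach = 15,
                            efficiency = 0.95, intensity_floor = 0.3,
                            bleach_both = FALSE) {
  cfg <- build_default_config("tubulin", duration = duration)
  protocol <- bleach_protocol(bleach_axoneme_prebleach(2),
                              bleach_pulse(t_bleach, efficiency))
  if (bleach_both) {
    extra <- bleach_pulse(t_bleach, efficiency)
    extra$region <- "pool-ctrl"   # internal-only region for the wide beam
    protocol <- dplyr::bind_rows(protocol, extra)
    class(protocol) <- c("ift_protocol", class(protocol))
  }
  reps <- purrr::map_dfr(seq_len(n), function(r) {
    st <- sim_and_traces(cfg, protocol, derive_seed(seed, 6000L + r))
    k <- st$kyms[[1]]
    safe_gap <- function(s) tryCatch(
      measure_gap(detect_trains(k, s), t_bleach,
                  intensity_floor = intensity_floor)$gap,
      error = function(e) NA_real_)
    tibble(replicate = r, gap_exp = safe_gap("exp"), gap_ctrl = safe_gap("ctrl"))
  })
  ok <- stats::complete.cases(reps[, c("gap_exp", "gap_ctrl")])
  tt <- if (sum(ok) >= 3) {
    t.test(reps$gap_exp[ok], reps$gap_ctrl[ok], paired = TRUE)
  } else NULL
  new_experiment("tubulin_gap", "tubulin", seed, reps, paired_test = tt)
}

#' Traffic statistics and per-departure pool drops
#'
#' Unperturbed recordings used for train frequency/velocity statistics and
#' for the pool-size estimate from per-departure intensity drops (bright
#' trains only, as dim-train drops are hard to call on real kymograms).
#'
#' @inheritParams run_frap_pool
#' @return An `ift_experiment` with per-replicate `frequency` (anterograde
#'   trains/s), `velocity` (um/s), and `mean_drop` (percent per bright
#'   departure); the pooled per-departure drops are in
#'   `$drops`.
#' @export
run_traffic <- function(protein, n = 3, seed = 1, duration = 120) {
  cfg <- build_default_config(protein, duration = duration)
  drops_all <- list()
  reps <- purrr::map_dfr(seq_len(n), function(r) {
    sim <- run_simulation(cfg, NULL, seed = derive_seed(seed, 7000L + r))
    k <- render_kymogram(sim)[[1]]
    tr <- detect_trains(k, "exp")
    stats_a <- traffic_stats(tr, "anterograde", duration)
    ant <- tr[tr$direction == "anterograde", ]
    bright <- ant[ant$intensity >= median(ant$intensity), ]
    pool_tr <- extract_trace(k, roi_pool(k, "exp"))
    dr <- suppressWarnings(departure_drops(pool_tr, bright$origin_time))
    drops_all[[r]] <<- dr
    tibble(replicate = r, frequency = stats_a$frequency,
           velocity = stats_a$velocity_mean,
           mean_drop = mean(dr$drop, na.rm = TRUE))
  })
  out <- new_experiment("traffic", protein, seed, reps)
  out$drops <- bind_rows(drops_all)
  out
}

#' Reproduce the headline observables of every assay
#'
#' Runs the full suite of virtual experiments at their default replicate
#' counts and collects the headline numbers in one named list (units:
#' seconds, percent, trains/s).
#'
#' @param seed Master seed.
#' @param n_scale Multiplier on replicate counts (use < 1 for a quick look).
#' @return Named list of numeric values, plus `details` (the experiment
#'   objects).
#' @export
reproduce_all <- function(seed = 1, n_scale = 1) {
  ns <- function(n) max(3L, as.integer(round(n * n_scale)))
  res <- list()
  det <- list()

  det$flip_ift54 <- run_flip_tip("IFT54", n = ns(14), seed = derive_seed(seed, 11))
  s <- det$flip_ift54$summary
  res$flip_plateau_level_pct <- s$mean[s$metric == "plateau_level"]
  res$flip_plateau_time_s <- s$mean[s$metric == "plateau_time"]
  res$flip_train_intensity_deficit_pct <-
    100 * (1 - s$mean[s$metric == "intensity_ratio"])

  det$flip_ift43 <- run_flip_tip("IFT43", n = ns(8), seed = derive_seed(seed, 12))
  s <- det$flip_ift43$summary
  res$flip_ift43_loss_at_10s_pct <- s$mean[s$metric == "loss_at_10s"]
  res$flip_ift43_train_intensity_deficit_pct <-
    100 * (1 - s$mean[s$metric == "intensity_ratio"])

  det$full_bleach <- run_full_flagellum_bleach("IFT54", n = ns(22),
                                               seed = derive_seed(seed, 13))
  s <- det$full_bleach$summary
  res$full_bleach_decline_pct <- s$mean[s$metric == "decline_pct"]
  res$full_bleach_decline_duration_s <- s$mean[s$metric == "decline_duration"]
  res$full_bleach_first_retro_return_s <- s$mean[s$metric == "first_retro_return"]
  res$full_bleach_pool_recovery_s <- s$mean[s$metric == "recovery_time"]

  det$gap_ift140 <- run_gap("IFT140", n = ns(20), seed = derive_seed(seed, 14))
  res$gap_ift140_s <- det$gap_ift140$summary$mean[
    det$gap_ift140$summary$metric == "gap"]
  det$gap_d1blic <- run_gap("D1bLIC", n = ns(20), seed = derive_seed(seed, 15))
  res$gap_d1blic_s <- det$gap_d1blic$summary$mean[
    det$gap_d1blic$summary$metric == "gap"]

  det$two_color <- run_two_color_gap(n = ns(49), seed = derive_seed(seed, 16))
  res$two_color_kap_first_count <- det$two_color$n_kap_first
  res$two_color_n <- nrow(det$two_color$replicates)

  det$tubulin <- run_tubulin_gap(n = ns(25), seed = derive_seed(seed, 17))
  s <- det$tubulin$summary
  res$tubulin_gap_exp_s <- s$mean[s$metric == "gap_exp"]
  res$tubulin_gap_ctrl_s <- s$mean[s$metric == "gap_ctrl"]
  res$tubulin_gap_p_value <- det$tubulin$paired_test$p.value

  det$frap_kap <- run_frap_pool("KAP", n = ns(10), seed = derive_seed(seed, 18))
  res$frap_kap_recovery_s <- det$frap_kap$summary$mean[
    det$frap_kap$summary$metric == "recovery_time"]
  det$frap_ift54 <- run_frap_pool("IFT54", n = ns(10), seed = derive_seed(seed, 19))
  res$frap_ift54_recovery_s <- det$frap_ift54$summary$mean[
    det$frap_ift54$summary$metric == "recovery_time"]

  det$traffic_kap <- run_traffic("KAP", n = ns(3), seed = derive_seed(seed, 20))
  res$departure_drop_kap_pct <- mean(det$traffic_kap$drops$drop, na.rm = TRUE)
  det$traffic_ift54 <- run_traffic("IFT54", n = ns(3), seed = derive_seed(seed, 21))
  res$departure_drop_ift54_pct <- mean(det$traffic_ift54$drops$drop, na.rm = TRUE)
  res$anterograde_frequency_per_s <- mean(
    c(det$traffic_kap$replicates$frequency,
      det$traffic_ift54$replicates$frequency))
  res$anterograde_velocity_um_s <- mean(
    c(det$traffic_kap$replicates$velocity,
      det$traffic_ift54$replicates$velocity))

  res$details <- det
  res
}
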