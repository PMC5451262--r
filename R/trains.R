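#' Detect IFT train trajectories in a kymogram
#'
#' Shear-and-sum line detection: for every candidate velocity on a grid, the
#' background-subtracted kymogram (per-position temporal median removed) is
#' integrated along lines starting at the flagellar base (anterograde) or
#' tip (retrograde). Line scores above `threshold_k` times the robust noise
#' scale of the line mean become trajectories after non-maximum suppression
#' across nearby origins and velocities (ties broken by higher line integral,
#' then earlier origin).
#'
#' @param kym An `ift_kymogram`.
#' @param structure `"exp"` or `"ctrl"`.
#' @param velocities List with `antero` and `retro` velocity grids (um/s,
#'   signed; retro negative).
#' @param threshold_k Detection threshold in units of the line-mean noise SE.
#' @param min_coverage Minimum fraction of the full transit that must lie
#'   inside the recording (and be unmasked).
#' @param nms_dt Suppression radius (s) on the mid-flagellum crossing time.
#' @param robust_frac Minimum fraction of path samples that must individually
#'   exceed the per-pixel noise floor; rejects sheared lines that score only
#'   where they cross genuine trajectories.
#' @return A tibble of class `ift_trajectories`: `structure`, `direction`,
#'   `origin_time` (s; when the train is at its origin position),
#'   `origin_position` (um), `velocity` (signed um/s), `duration` (s),
#'   `intensity` (mean background-subtracted counts along the line) and
#'   `quality`.
#' @export
detect_trains <- function(kym, structure = "exp",
                          velocities = list(antero = seq(1.0, 3.5, by = 0.1),
                                            retro = seq(-4.5, -1.5, by = 0.1)),
                          threshold_k = 5, min_coverage = 0.5, nms_dt = 0.35,
                          robust_frac = 0.7) {
  lay <- attr(kym, "layout")
  dt_f <- attr(kym, "frame_interval")
  px_um <- attr(kym, "pixel_size")
  L <- lay$flag_px * px_um
  cols <- roi_flagellum(kym, structure)
  M <- unclass(kym)[, cols, drop = FALSE]
  # Per-position background: trains cover a flagellar pixel most of the time
  # at ~1 train/s per direction, so the temporal median is signal-biased; a
  # low quantile is robust to that, re-centred by the quantile-median gap of
  # pure noise measured in the empty band between the structure blocks.
  q15 <- function(x) stats::quantile(x, 0.15, na.rm = TRUE, names = FALSE)
  Braw <- unclass(kym)[, roi_background(kym), drop = FALSE]
  corr <- mean(apply(Braw, 2, median, na.rm = TRUE) - apply(Braw, 2, q15))
  bg <- apply(M, 2, q15) + corr
  R <- sweep(M, 2, bg)
  # noise scale from the empty band, so that dense traffic inside the
  # flagellum does not inflate it
  B <- sweep(Braw, 2, apply(Braw, 2, median, na.rm = TRUE))
  # floor of half a count so noise-free synthetic images still reject the
  # psf tails of off-velocity duplicate lines
  noise <- max(mad(B, na.rm = TRUE), 0.5)
  nfr <- nrow(R); npx <- ncol(R)
  time <- attr(kym, "time")

  score_grid <- function(v) {
    speed <- abs(v)
    n_path <- floor(L / (speed * dt_f)) + 1L
    j <- seq_len(n_path) - 1L
    px <- round(j * speed * dt_f / px_um) + 1L
    if (v < 0) px <- npx + 1L - px
    px <- pmin(pmax(px, 1L), npx)
    f0 <- seq_len(nfr)
    Fm <- outer(f0, j, `+`)
    ok <- Fm <= nfr
    Fm[!ok] <- NA_integer_
    vals <- matrix(R[cbind(as.vector(Fm), rep(px, each = nfr))], nfr, n_path)
    cover <- rowSums(!is.na(vals)) / n_path
    sc <- rowMeans(vals, na.rm = TRUE)
    nv <- rowSums(!is.na(vals))
    frac_above <- rowMeans(vals > 2.5 * noise, na.rm = TRUE)
    tibble(origin_frame = f0, velocity = v, score = sc,
           coverage = cover, n_path = nv, frac_above = frac_above)
  }

  detect_dir <- function(vgrid, direction) {
    cand <- bind_rows(lapply(vgrid, score_grid))
    cand <- cand[cand$coverage >= min_coverage & cand$n_path >= 5, ]
    cand$se <- noise / sqrt(pmax(cand$n_path, 1))
    cand <- cand[!is.na(cand$score) & cand$score > threshold_k * cand$se &
                   cand$frac_above >= robust_frac, ]
    if (nrow(cand) == 0) return(NULL)
    # suppress near-duplicates: same origin (a steeper line over the same
    # train) or same mid-flagellum crossing time (same train, offset origin)
    cand$t_mid <- time[cand$origin_frame] + (L / 2) / abs(cand$velocity)
    cand$t0 <- time[cand$origin_frame]
    cand <- cand[order(-cand$score, cand$origin_frame), ]
    keep <- rep(FALSE, nrow(cand))
    taken_mid <- numeric(0); taken_t0 <- numeric(0)
    for (i in seq_len(nrow(cand))) {
      if (all(abs(cand$t_mid[i] - taken_mid) > nms_dt) &&
          all(abs(cand$t0[i] - taken_t0) > nms_dt)) {
        keep[i] <- TRUE
        taken_mid <- c(taken_mid, cand$t_mid[i])
        taken_t0 <- c(taken_t0, cand$t0[i])
      }
    }
    sel <- cand[keep, ]
    origin_pos <- if (direction == "anterograde") 0 else L
    # report the median along the line: robust to crossings with trains
    # running in the other direction
    med_int <- vapply(seq_len(nrow(sel)), function(i) {
      v <- sel$velocity[i]; speed <- abs(v)
      j <- 0:floor(L / (speed * dt_f))
      px <- round(j * speed * dt_f / px_um) + 1L
      if (v < 0) px <- npx + 1L - px
      px <- pmin(pmax(px, 1L), npx)
      fr <- sel$origin_frame[i] + j
      okf <- fr <= nfr
      median(R[cbind(fr[okf], px[okf])], na.rm = TRUE)
    }, numeric(1))
    tibble(structure = structure, direction = direction,
           origin_time = time[sel$origin_frame],
           origin_position = origin_pos,
           velocity = sel$velocity,
           duration = L / abs(sel$velocity),
           intensity = med_int,
           quality = sel$score / sel$se)
  }

  out <- bind_rows(detect_dir(velocities$antero, "anterograde"),
                   detect_dir(velocities$retro, "retrograde"))
  if (nrow(out) == 0) {
    out <- tibble(structure = character(0), direction = character(0),
                  origin_time = numeric(0), origin_position = numeric(0),
                  velocity = numeric(0), duration = numeric(0),
                  intensity = numeric(0), quality = numeric(0))
  }
  out <- arrange(out, .data$origin_time)
  class(out) <- c("ift_trajectories", class(out))
  out
}

#' Traffic statistics over a trajectory set
#'
#' @param trajectories An `ift_trajectories` tibble.
#' @param direction `"anterograde"` or `"retrograde"`.
#' @param interval Observation interval (s) for the frequency.
#' @return One-row tibble: `n`, `frequency` (trains/s), `velocity_mean`,
#'   `velocity_sd` (um/s; `NA` and `velocity_defined = FALSE` when empty).
#' @export
traffic_stats <- function(trajectories, direction = "anterograde", interval) {
  if (interval <= 0) abort("interval must be > 0", class = "iftpool_input_error")
  tr <- trajectories[trajectories$direction == direction, ]
  tibble(direction = direction, n = nrow(tr),
         frequency = nrow(tr) / interval,
         velocity_mean = if (nrow(tr) > 0) mean(abs(tr$velocity)) else NA_real_,
         velocity_sd = if (nrow(tr) > 1) sd(abs(tr$velocity)) else NA_real_,
         velocity_defined = nrow(tr) > 0)
}

#' Post-bleach gap in anterograde traffic
#'
#' The gap is the interval between bleaching of the basal-body pool and the
#' first subsequent anterograde trajectory departing from the base whose
#' mean intensity reaches `intensity_floor` times the median intensity of
#' prebleach trains. Dimmer trains inside the gap are counted as "early
#' birds" (incompletely bleached material) and excluded from the call.
#'
#' @param trajectories An `ift_trajectories` tibble.
#' @param t_bleach Bleach time (s).
#' @param base_window Origin-position window (um) for qualifying trains.
#' @param intensity_floor Fraction of the prebleach median intensity.
#' @param guard Trains whose detected origin falls within `guard` seconds
#'   after the bleach are treated as prebleach departures: detected origins
#'   are quantized to the frame grid, so a train that left just before the
#'   pulse can surface just after it.
#' @return One-row tibble: `gap` (s), `first_train` (s), `n_early_birds`,
#'   `censored`, `prebleach_median`.
#' @export
measure_gap <- function(trajectories, t_bleach, base_window = c(0, 1),
                        intensity_floor = 0.3, guard = 0.25) {
  tr <- trajectories[trajectories$direction == "anterograde" &
                       trajectories$origin_position >= base_window[1] &
                       trajectories$origin_position <= base_window[2], ]
  t_cut <- t_bleach + guard
  pre <- tr[tr$origin_time < t_cut, ]
  if (nrow(pre) < 3) {
    abort("prebleach segment too short to estimate the train intensity floor",
          class = "iftpool_input_error")
  }
  med <- median(pre$intensity)
  post <- tr[tr$origin_time >= t_cut, ]
  qual <- post[post$intensity >= intensity_floor * med, ]
  if (nrow(qual) == 0) {
    return(tibble(gap = NA_real_, first_train = NA_real_,
                  n_early_birds = sum(post$intensity < intensity_floor * med),
                  censored = TRUE, prebleach_median = med))
  }
  first <- min(qual$origin_time)
  tibble(gap = first - t_bleach, first_train = first,
         n_early_birds = sum(post$origin_time < first &
                               post$intensity < intensity_floor * med),
         censored = FALSE, prebleach_median = med)
}

#' Per-departure pool intensity drops
#'
#' The departure of a train transiently lowers the basal-body pool signal.
#' For each departure the drop is read off the trace the way a transient
#' dip is read off a kymogram intensity profile: the last pre-departure
#' level minus the trough right after the departure (`method = "extrema"`,
#' on a lightly smoothed trace, so continuous recruitment between
#' departures does not dilute the step), as a percentage of the
#' pre-departure level. `method = "windows"` compares plain window means
#' instead. Departures whose windows overlap a neighbouring departure are
#' skipped with a warning.
#'
#' @param trace Pool intensity trace (counts or percent).
#' @param departures Departure times (s).
#' @param w Window length (s).
#' @param g Guard interval around the departure (s).
#' @param method `"extrema"` or `"windows"`.
#' @param smooth_s Rolling-mean window (s) for `"extrema"`.
#' @return Tibble `departure`, `drop` (percent) for the usable departures.
#' @export
departure_drops <- function(trace, departures, w = 0.3, g = 0.1,
                            method = c("extrema", "windows"), smooth_s = 0.15) {
  method <- match.arg(method)
  departures <- sort(departures)
  ok <- !trace$mask & !is.na(trace$value)
  tt <- trace$time[ok]
  vv <- if (method == "extrema") rolling_mean(tt, trace$value[ok], smooth_s)
        else trace$value[ok]
  res <- purrr::map_dfr(seq_along(departures), function(k) {
    t <- departures[k]
    lo <- t - g - w; hi <- t + g + w
    nb <- departures[departures != t]
    if (any(nb > lo & nb < hi)) {
      return(tibble(departure = t, drop = NA_real_, skipped = TRUE))
    }
    pre <- vv[tt >= t - g - w & tt < t - g]
    post <- vv[tt > t + g & tt <= t + g + w]
    if (length(pre) < 2 || length(post) < 2) {
      return(tibble(departure = t, drop = NA_real_, skipped = TRUE))
    }
    lvl <- if (method == "extrema") max(pre) else mean(pre)
    after <- if (method == "extrema") min(post) else mean(post)
    if (lvl <= 0) {
      return(tibble(departure = t, drop = NA_real_, skipped = TRUE))
    }
    tibble(departure = t, drop = 100 * (lvl - after) / lvl, skipped = FALSE)
  })
  n_skip <- sum(res$skipped)
  if (n_skip > 0) {
    warn(sprintf("%d departure(s) skipped (overlapping windows or masked frames)",
                 n_skip))
  }
  res[!res$skipped, c("departure", "drop")]
}

#' Mean train-intensity ratio between flagella
#'
#' Mean trajectory intensity in the experimental flagellum divided by the
#' mean in the control flagellum of the same cell.
#'
#' @param exp_traj,ctrl_traj `ift_trajectories` of the two flagella.
#' @param min_n Minimum trajectories per flagellum.
#' @return A single fraction.
#' @export
train_intensity_ratio <- function(exp_traj, ctrl_traj, min_n = 3) {
  if (nrow(exp_traj) < min_n || nrow(ctrl_traj) < min_n) {
    abort(sprintf("need at least %d trajectories in each flagellum", min_n),
          class = "iftpool_input_error")
  }
  mean(exp_traj$intensity) / mean(ctrl_traj$intensity)
}
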