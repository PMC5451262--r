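#' Regions of interest on a kymogram
#'
#' Helpers returning pixel index ranges for the standard regions of a
#' rendered kymogram: the basal-body pool spot of a structure, its
#' flagellum, and an empty background band between the two blocks.
#'
#' @param kym An `ift_kymogram`.
#' @param structure `"exp"` or `"ctrl"`.
#' @return Integer vector of pixel columns.
#' @export
roi_pool <- function(kym, structure = "exp") {
  lay <- attr(kym, "layout")
  ctr <- lay$pool_center[[structure]]
  (ctr - 5L):(ctr + 5L)
}

#' @rdname roi_pool
#' @export
roi_flagellum <- function(kym, structure = "exp") {
  lay <- attr(kym, "layout")
  base <- lay$flag_base[[structure]]
  base:(base + lay$flag_px)
}

#' @rdname roi_pool
#' @export
roi_background <- function(kym) {
  lay <- attr(kym, "layout")
  a <- lay$flag_base[["exp"]] + lay$flag_px + 2L
  b <- lay$pool_center[["ctrl"]] - 7L
  a:b
}

#' Extract an intensity trace from a kymogram
#'
#' Per-frame sum over a pixel range, background-subtracted using the
#' temporal median of a background region. Masked (dropped/saturated)
#' frames propagate as masked values.
#'
#' @param kym An `ift_kymogram`.
#' @param roi Integer pixel columns (e.g. [roi_pool()]).
#' @param background_roi Pixel columns of an empty region (default
#'   [roi_background()]).
#' @return A tibble `time`, `value` (counts), `mask`.
#' @export
extract_trace <- function(kym, roi, background_roi = roi_background(kym)) {
  if (length(roi) == 0) abort("empty roi", class = "iftpool_input_error")
  if (any(roi < 1 | roi > ncol(kym))) {
    abort("roi outside the kymogram", class = "iftpool_input_error")
  }
  m <- unclass(kym)
  bg_level <- median(m[, background_roi], na.rm = TRUE)
  value <- rowSums(m[, roi, drop = FALSE]) - bg_level * length(roi)
  mask <- attr(kym, "mask") | is.na(value)
  tibble(time = attr(kym, "time"), value = value, mask = mask)
}

#' Normalize an experimental trace to the control structure
#'
#' Frame-by-frame percentage of the control signal. Because the control pool
#' sees the same continuous TIRF illumination, any decay shared by the two
#' structures (notably imaging photobleaching) cancels.
#'
#' @param exp_trace,ctrl_trace Traces from [extract_trace()] on aligned
#'   time bases.
#' @param floor_frac Frames where the control falls below `floor_frac` times
#'   its median are masked.
#' @return A tibble `time`, `value` (percent), `mask`.
#' @export
normalize_trace <- function(exp_trace, ctrl_trace, floor_frac = 0.1) {
  if (!isTRUE(all.equal(exp_trace$time, ctrl_trace$time))) {
    abort("traces are not on the same time base", class = "iftpool_input_error")
  }
  ctrl_med <- median(ctrl_trace$value[!ctrl_trace$mask], na.rm = TRUE)
  low <- is.na(ctrl_trace$value) | ctrl_trace$value < floor_frac * ctrl_med
  mask <- exp_trace$mask | ctrl_trace$mask | low
  if (all(mask)) abort("all control frames masked", class = "iftpool_input_error")
  value <- 100 * exp_trace$value / ctrl_trace$value
  value[mask] <- NA_real_
  value <- pmax(value, 0)
  tibble(time = exp_trace$time, value = value, mask = mask)
}

# Centered rolling mean over a time window (partial windows at the edges).
rolling_mean <- function(time, value, window) {
  half <- window / 2
  vapply(seq_along(time), function(i) {
    j <- which(time >= time[i] - half & time <= time[i] + half & !is.na(value))
    if (length(j) == 0) NA_real_ else mean(value[j])
  }, numeric(1))
}

# Rolling least-squares slope over a centered window; NA where the window
# has < 5 valid points.
rolling_slope <- function(time, value, window) {
  n <- length(time)
  out <- rep(NA_real_, n)
  half <- window / 2
  for (i in seq_len(n)) {
    j <- which(time >= time[i] - half & time <= time[i] + half & !is.na(value))
    if (length(j) >= 5) {
      x <- time[j] - time[i]; y <- value[j]
      out[i] <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    }
  }
  out
}

trace_at <- function(trace, t) {
  ok <- !trace$mask & !is.na(trace$value)
  approx(trace$time[ok], trace$value[ok], xout = t, rule = 2)$y
}

#' Two-line FRAP recovery fit
#'
#' Automates the manual two-line construction used on scatter plots of
#' normalized pool recovery: a robust horizontal plateau line over the final
#' region where the local slope stays below `plateau_tol`, a least-squares
#' rising line over the recovery phase (from `delta` after the post-bleach
#' minimum to the first crossing of 90% of the plateau), and the recovery
#' time as the intersection of the two lines minus the bleach time.
#'
#' @param trace Normalized trace (percent) from [normalize_trace()].
#' @param t_bleach Bleach time (s).
#' @param delta Rise-window start offset after the post-bleach minimum (s).
#' @param plateau_tol Absolute slope tolerance (percent/s) above which the
#'   final window is not accepted as a plateau. Pool traces fluctuate by
#'   ~10% as single trains depart and arrive, so this is a coarse guard
#'   against fitting a still-recovering trace, not a noise bound.
#' @param plateau_window Minimum plateau window length (s); the plateau is
#'   the final `max(plateau_window, 30%)` of the post-bleach trace.
#' @param smooth_s Rolling-mean window (s) used to locate the post-bleach
#'   minimum and the 90%-of-plateau crossing; the rising line itself is fit
#'   to raw values.
#' @param trough_search How far past the bleach (s) to look for the
#'   post-bleach minimum; keeps late fluctuation dips of small pools from
#'   being mistaken for the trough.
#' @return An object of class `frap_fit`; `censored = TRUE` with a
#'   diagnostic message when no plateau or no rising phase is found.
#' @export
fit_frap <- function(trace, t_bleach, delta = 0.3, plateau_tol = 3,
                     plateau_window = 5, smooth_s = 1.5, trough_search = 12) {
  post <- trace[trace$time > t_bleach & !trace$mask & !is.na(trace$value), ]
  fail <- function(msg) {
    structure(list(t_bleach = t_bleach, recovery_time = NA_real_,
                   plateau_level = NA_real_, rising_slope = NA_real_,
                   rise_window = c(NA, NA), plateau_start = NA_real_,
                   censored = TRUE, message = msg, trace = trace),
              class = "frap_fit")
  }
  span <- if (nrow(post) > 1) diff(range(post$time)) else 0
  if (nrow(post) < 10 || span < 1.5 * plateau_window) {
    return(fail("trace too short beyond the bleach"))
  }
  t_end <- max(post$time)
  pw <- max(plateau_window, 0.3 * span)
  pl <- post[post$time >= t_end - pw, ]
  plateau_level <- median(pl$value)
  pl_slope <- coef(lm(value ~ time, data = pl))[["time"]]
  if (!is.finite(pl_slope) || abs(pl_slope) > plateau_tol) {
    return(fail("no plateau detected: trace still changing in the final window"))
  }
  plateau_start <- t_end - pw

  # rising phase: starts after the post-bleach minimum (the trough, for
  # traces that first decline) and ends at the first smoothed crossing of
  # 90% of the recovery amplitude. The plateau estimate is then re-read
  # just after that crossing (the way the horizontal dashed line is drawn
  # next to the recovered segment by hand) and the crossing updated; slow
  # late drifts of the normalized signal no longer push the window out.
  pre_pl <- post[post$time <= min(plateau_start, t_bleach + trough_search), ]
  if (nrow(pre_pl) < 3) return(fail("no rising phase before the plateau"))
  smth_pre <- rolling_mean(pre_pl$time, pre_pl$value, smooth_s)
  t_min <- pre_pl$time[which.min(smth_pre)]
  v_min <- min(smth_pre)
  rise_lo <- max(t_min, t_bleach) + delta
  smth <- rolling_mean(post$time, post$value, smooth_s)
  rise_hi <- plateau_start
  for (it in 1:3) {
    th <- v_min + 0.9 * (plateau_level - v_min)
    cross <- post$time[post$time >= rise_lo & smth >= th]
    if (length(cross) == 0) break
    rise_hi <- cross[1]
    pl2 <- post[post$time >= rise_hi + 1 &
                  post$time <= rise_hi + 1 + plateau_window * 2, ]
    if (nrow(pl2) >= 5) plateau_level <- median(pl2$value)
  }
  rw <- post[post$time >= rise_lo & post$time <= rise_hi, ]
  if (nrow(rw) < 3) return(fail("rising window too short"))
  ft <- lm(value ~ time, data = rw)
  slope <- coef(ft)[["time"]]
  if (!is.finite(slope) || slope <= 0) return(fail("no rising slope"))
  t_cross <- (plateau_level - coef(ft)[["(Intercept)"]]) / slope
  if (t_cross > t_end) {
    return(fail("rising line does not reach the plateau within the trace"))
  }
  structure(list(t_bleach = t_bleach,
                 recovery_time = max(0, t_cross - t_bleach),
                 plateau_level = plateau_level, rising_slope = slope,
                 rise_window = c(rise_lo, rise_hi),
                 plateau_start = plateau_start, censored = FALSE,
                 message = NA_character_, trace = trace),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$censored) {
    cat("<frap_fit> censored:", x$message, "\n")
  } else {
    cat(sprintf("<frap_fit> recovery %.2f s to plateau %.1f%% (slope %.2f %%/s)\n",
                x$recovery_time, x$plateau_level, x$rising_slope))
  }
  invisible(x)
}

#' FLIP loss fit
#'
#' Quantifies fluorescence loss in photobleaching on a normalized pool
#' trace: the least-squares slope of a trendline over an initial window
#' (default the first 10 s of illumination; pass `slope_window = c(10, 25)`
#' for the later window variant), the loss after 10 s, and the plateau —
#' the first sustained flat region after the decline has started.
#'
#' @param trace Normalized trace (percent).
#' @param t_start FLIP onset (s).
#' @param slope_window Interval (s, relative to `t_start`) for the trendline.
#' @param depth_min Minimum loss (percentage points) from onset to the late
#'   plateau window for the trace to count as declined; below it the pool
#'   is called unaffected (no-decline flag).
#' @param smooth_s Rolling-mean window (s) applied before plateau detection
#'   (pool traces fluctuate as single trains depart and arrive).
#' @return An object of class `flip_fit` with `initial_slope` (percent/s),
#'   `loss_at_10s` (percent), `plateau_time` (s after `t_start`),
#'   `plateau_level` (percent) and a `declined` flag (`FALSE` when no decline
#'   beyond the slope tolerance was seen).
#' @export
fit_flip <- function(trace, t_start, slope_window = c(0, 10),
                     depth_min = 10, smooth_s = 3) {
  win <- trace[trace$time >= t_start + slope_window[1] &
                 trace$time <= t_start + slope_window[2] &
                 !trace$mask & !is.na(trace$value), ]
  if (nrow(win) < 5) abort("slope window too short", class = "iftpool_input_error")
  ftl <- lm(value ~ time, data = win)
  initial_slope <- coef(ftl)[["time"]]
  # endpoint values from a lightly smoothed trace: single 0.1 s frames carry
  # the ~10% train-departure fluctuation of the pool
  ok <- !trace$mask & !is.na(trace$value)
  sm_all <- rolling_mean(trace$time[ok], trace$value[ok], 1.5)
  at_s <- function(t) approx(trace$time[ok], sm_all, xout = t, rule = 2)$y
  loss_at_10s <- at_s(t_start) - at_s(t_start + 10)

  # plateau: level from a late window (clear of the decline and of
  # end-of-trace edge effects), reached when the smoothed trace has covered
  # 90% of the total depth
  post <- trace[trace$time >= t_start & !trace$mask & !is.na(trace$value), ]
  smth <- rolling_mean(post$time, post$value, smooth_s)
  t_end <- max(post$time)
  fw <- post$time >= max(t_start + 10, t_end - 15) & post$time <= t_end - 2
  if (!any(fw)) fw <- post$time >= t_end - 5
  plateau_level <- median(post$value[fw])
  baseline <- smth[1]
  depth <- baseline - plateau_level
  plateau_time <- NA_real_; declined <- FALSE
  if (is.finite(depth) && depth > depth_min) {
    declined <- TRUE
    reached <- which(smth <= plateau_level + 0.1 * depth)
    if (length(reached) > 0) plateau_time <- post$time[reached[1]] - t_start
  } else {
    plateau_level <- NA_real_
  }
  structure(list(t_start = t_start, initial_slope = initial_slope,
                 loss_at_10s = loss_at_10s, plateau_time = plateau_time,
                 plateau_level = plateau_level, declined = declined,
                 slope_window = slope_window, trace = trace),
            class = "flip_fit")
}

#' Pool decline into a trough after a whole-flagellum bleach
#'
#' After the entire flagellum is bleached, the pool keeps exporting trains
#' while only bleached material returns, so its signal declines by the
#' retrograde-derived fraction and sits in a trough until the first
#' unbleached train returns. This measures the decline depth and duration
#' on a (normalized) pool trace.
#'
#' @param trace Pool trace (percent).
#' @param t_bleach Bleach time (s).
#' @param search_window How far past the bleach (s) to look for the trough.
#' @param frac The decline is called complete when the smoothed trace first
#'   comes within `frac` of the decline depth above the trough.
#' @param smooth_s Rolling-mean window (s).
#' @return A one-row tibble: `baseline`, `trough_level`, `trough_time`,
#'   `decline_pct` (percentage points) and `decline_duration` (s).
#' @export
measure_pool_trough <- function(trace, t_bleach, search_window = 10,
                                frac = 0.1, smooth_s = 2) {
  ok <- !trace$mask & !is.na(trace$value)
  pre <- trace$value[ok & trace$time >= t_bleach - 3 & trace$time <= t_bleach]
  if (length(pre) < 5) abort("prebleach segment too short",
                             class = "iftpool_input_error")
  baseline <- mean(pre)
  post <- trace[ok & trace$time > t_bleach &
                  trace$time <= t_bleach + search_window, ]
  if (nrow(post) < 10) abort("trace too short beyond the bleach",
                             class = "iftpool_input_error")
  smth <- rolling_mean(post$time, post$value, smooth_s)
  i_min <- which.min(smth)
  trough_level <- smth[i_min]
  depth <- baseline - trough_level
  thresh <- trough_level + frac * max(depth, 0)
  i_done <- which(smth <= thresh)
  i_done <- i_done[i_done <= i_min]
  tibble(baseline = baseline, trough_level = trough_level,
         trough_time = post$time[i_min],
         decline_pct = depth,
         decline_duration = if (length(i_done) > 0)
           post$time[min(i_done)] - t_bleach else NA_real_)
}

#' @export
print.flip_fit <- function(x, ...) {
  cat(sprintf("<flip_fit> slope %.2f %%/s, loss at 10 s %.1f%%", x$initial_slope,
              x$loss_at_10s))
  if (x$declined && !is.na(x$plateau_time)) {
    cat(sprintf(", plateau %.1f%% at %.1f s", x$plateau_level, x$plateau_time))
  } else if (!x$declined) cat(" (no decline)")
  cat("\n")
  invisible(x)
}
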