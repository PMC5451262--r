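#' Photobleaching protocols
#'
#' A bleach protocol is a tibble of timed laser events applied to the
#' experimental structure of a simulated cell. Regions:
#'
#' * `"pool-exp"` — the experimental basal-body pool (all pool compartments:
#'   nascent trains, recycling, recycled-available, standing material).
#' * `"tip-window"` — a window `[x0, x1]` (um from the base) near the
#'   flagellar tip; copies on trains inside the window while the laser is on
#'   are bleached. Used for fluorescence loss in photobleaching (FLIP).
#' * `"whole-flagellum-exp"` — every copy on trains currently inside the
#'   experimental flagellum.
#' * `"axoneme-prebleach"` — alias of a whole-flagellum pulse used before
#'   cargo-loading assays to darken material already inside the flagellum.
#'
#' `mode = "pulse"` applies the event once at `t_start`; `mode = "duty"`
#' repeats on/off cycles (`duty_on`/`duty_off`, in ms) from `t_start` to
#' `t_stop`, emulating a shuttered bleach laser with a duty ratio of
#' 100–200 ms on and 400–900 ms off.
#'
#' @param t_start Event start time (s).
#' @param efficiency Per-copy bleach probability in \[0, 1\].
#' @param region Region label (see above).
#' @param window Numeric length-2 `[x0, x1]` in um, required for
#'   `"tip-window"`.
#' @param duty_on,duty_off On/off durations in ms (duty mode only).
#' @param t_stop End of the duty train (s).
#' @param channels Protein/channel labels affected, or `NULL` for all.
#' @return A one-row protocol tibble; combine events with [bleach_protocol()].
#' @name bleach-events
NULL

new_bleach_event <- function(t_start, mode, region, efficiency,
                             window = c(NA_real_, NA_real_),
                             duty_on = NA_real_, duty_off = NA_real_,
                             t_stop = NA_real_, channels = NULL) {
  if (efficiency < 0 || efficiency > 1) {
    abort("bleach efficiency must be in [0, 1]", class = "iftpool_protocol_error")
  }
  if (grepl("ctrl|control", region)) {
    abort("Bleach regions must reference the experimental structure only; the control structure stays untouched.",
          class = "iftpool_protocol_error")
  }
  if (mode == "duty" && (is.na(duty_on) || is.na(duty_off) || is.na(t_stop))) {
    abort("duty mode requires duty_on, duty_off and t_stop",
          class = "iftpool_protocol_error")
  }
  if (mode == "pulse" && !(is.na(duty_on) && is.na(duty_off))) {
    abort("duty fields are only valid with mode = 'duty'",
          class = "iftpool_protocol_error")
  }
  tibble(
    t_start = t_start, mode = mode, region = region, efficiency = efficiency,
    x0 = window[1], x1 = window[2], duty_on = duty_on, duty_off = duty_off,
    t_stop = t_stop, channels = list(channels)
  )
}

#' @rdname bleach-events
#' @export
bleach_pulse <- function(t_start, efficiency = 0.95, region = "pool-exp",
                         window = c(NA_real_, NA_real_), channels = NULL) {
  new_bleach_event(t_start, "pulse", region, efficiency, window = window,
                   channels = channels)
}

#' @rdname bleach-events
#' @export
bleach_flip <- function(t_start, t_stop, efficiency = 0.95,
                        window, duty_on = 150, duty_off = 550,
                        channels = NULL) {
  new_bleach_event(t_start, "duty", "tip-window", efficiency, window = window,
                   duty_on = duty_on, duty_off = duty_off, t_stop = t_stop,
                   channels = channels)
}

#' @rdname bleach-events
#' @export
bleach_whole_flagellum <- function(t_start, efficiency = 0.99, channels = NULL) {
  new_bleach_event(t_start, "pulse", "whole-flagellum-exp", efficiency,
                   channels = channels)
}

#' @rdname bleach-events
#' @export
bleach_axoneme_prebleach <- function(t_start, efficiency = 0.99, channels = NULL) {
  new_bleach_event(t_start, "pulse", "axoneme-prebleach", efficiency,
                   channels = channels)
}

#' Combine bleach events into a protocol
#'
#' @param ... One-row event tibbles from [bleach_pulse()], [bleach_flip()],
#'   [bleach_whole_flagellum()] or [bleach_axoneme_prebleach()].
#' @return A protocol tibble ordered by start time (class `ift_protocol`).
#' @export
#' @examples
#' bleach_protocol(bleach_pulse(10), bleach_flip(20, 50, window = c(10.5, 12)))
bleach_protocol <- function(...) {
  events <- bind_rows(...)
  if (nrow(events) == 0) {
    events <- tibble(t_start = numeric(0), mode = character(0),
                     region = character(0), efficiency = numeric(0),
                     x0 = numeric(0), x1 = numeric(0), duty_on = numeric(0),
                     duty_off = numeric(0), t_stop = numeric(0),
                     channels = list())
  }
  events <- arrange(events, .data$t_start)
  class(events) <- c("ift_protocol", class(events))
  events
}

# Laser-on intervals of a protocol event as a 2-column matrix [on, off).
laser_on_intervals <- function(event) {
  if (event$mode == "pulse") {
    return(matrix(c(event$t_start, event$t_start + 1e-9), ncol = 2))
  }
  period <- (event$duty_on + event$duty_off) / 1000
  on <- event$duty_on / 1000
  starts <- seq(event$t_start, event$t_stop, by = period)
  cbind(starts, pmin(starts + on, event$t_stop))
}
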