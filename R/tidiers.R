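#' Tidy photobleaching fits and experiments
#'
#' Broom-style methods: `tidy()` returns the estimated quantities one row
#' per term (or per metric for experiments), `glance()` a one-row model
#' summary.
#'
#' @param x A `frap_fit`, `flip_fit` or `ift_experiment`.
#' @param ... Unused.
#' @return A tibble.
#' @name iftpool-tidiers
NULL

#' @rdname iftpool-tidiers
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(term = c("recovery_time", "plateau_level", "rising_slope"),
         estimate = c(x$recovery_time, x$plateau_level, x$rising_slope),
         unit = c("s", "percent", "percent/s"))
}

#' @rdname iftpool-tidiers
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(t_bleach = x$t_bleach, recovery_time = x$recovery_time,
         plateau_level = x$plateau_level, censored = x$censored,
         message = x$message)
}

#' @rdname iftpool-tidiers
#' @export
tidy.flip_fit <- function(x, ...) {
  tibble(term = c("initial_slope", "loss_at_10s", "plateau_time",
                  "plateau_level"),
         estimate = c(x$initial_slope, x$loss_at_10s, x$plateau_time,
                      x$plateau_level),
         unit = c("percent/s", "percent", "s", "percent"))
}

#' @rdname iftpool-tidiers
#' @export
glance.flip_fit <- function(x, ...) {
  tibble(t_start = x$t_start, initial_slope = x$initial_slope,
         loss_at_10s = x$loss_at_10s, plateau_time = x$plateau_time,
         plateau_level = x$plateau_level, declined = x$declined)
}

#' @rdname iftpool-tidiers
#' @export
tidy.ift_experiment <- function(x, ...) x$summary

#' @rdname iftpool-tidiers
#' @export
glance.ift_experiment <- function(x, ...) {
  tibble(assay = x$assay, protein = paste(x$protein, collapse = "+"),
         n = nrow(x$replicates), seed = x$seed,
         p_paired = if (!is.null(x$paired_test)) x$paired_test$p.value
                    else NA_real_)
}
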