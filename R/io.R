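#' Load a configuration file
#'
#' Reads a YAML configuration mirroring the simulation, render and protocol
#' settings. Top-level keys: `simulation` (flat keys of
#' [build_default_config()] plus `proteins`, a list of per-protein blocks
#' overriding registry defaults by name), `render` (keys of
#' [render_config()]) and `protocol` (list of events with a `type` of
#' `pulse`, `flip`, `whole_flagellum` or `axoneme_prebleach` plus that
#' constructor's arguments). Unknown keys are rejected with their paths.
#'
#' @param path Path to a YAML file. An empty file yields all defaults.
#' @return A list with elements `sim` (`ift_config`), `render`
#'   (`ift_render_config`) and `protocol` (`ift_protocol`).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("simulation", "render", "protocol"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown top-level key(s): %s", paste(bad, collapse = ", ")),
          class = "iftpool_config_error")
  }
  simr <- raw$simulation %||% list()
  protein_names <- vapply(simr$proteins %||% list(), function(p) p$name %||%
                            abort("protein block without a name",
                                  class = "iftpool_config_error"),
                          character(1))
  flat <- simr[setdiff(names(simr), "proteins")]
  cfg <- do.call(build_default_config,
                 c(list(protein_names = protein_names), flat))
  for (p in simr$proteins %||% list()) {
    i <- match(p$name, cfg$proteins$name)
    flds <- setdiff(names(p), "name")
    bad <- setdiff(flds, names(cfg$proteins))
    if (length(bad) > 0) {
      abort(sprintf("Unknown protein field(s) for %s: %s", p$name,
                    paste(bad, collapse = ", ")),
            class = "iftpool_config_error")
    }
    for (f in flds) cfg$proteins[[f]][i] <- p[[f]]
  }
  validate_config(cfg)

  rc <- do.call(render_config, raw$render %||% list())

  events <- lapply(raw$protocol %||% list(), function(e) {
    type <- e$type %||% abort("protocol event without a type",
                              class = "iftpool_config_error")
    args <- e[setdiff(names(e), "type")]
    if (!is.null(args$window)) args$window <- unlist(args$window)
    fn <- switch(type,
                 pulse = bleach_pulse, flip = bleach_flip,
                 whole_flagellum = bleach_whole_flagellum,
                 axoneme_prebleach = bleach_axoneme_prebleach,
                 abort(sprintf("Unknown protocol event type '%s'", type),
                       class = "iftpool_config_error"))
    do.call(fn, args)
  })
  protocol <- do.call(bleach_protocol, events)
  list(sim = cfg, render = rc, protocol = protocol)
}

#' Serialize simulation outputs
#'
#' The event log is written as line-delimited CSV records, the state trace
#' (pool and cell-body content per frame, by protein and bleach state) as a
#' tabular CSV.
#'
#' @param sim An `ift_sim`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(sim, path) {
  utils::write.csv(sim$events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
write_state_trace <- function(sim, path) {
  pool <- dplyr::mutate(sim$pool, compartment = "pool")
  cb <- dplyr::mutate(sim$cell_body, compartment = "cell_body",
                      structure = "shared")
  fl <- sim$trains_frames |>
    dplyr::group_by(.data$time, .data$structure, .data$protein) |>
    dplyr::summarise(unbleached = sum(.data$unbleached),
                     bleached = sum(.data$bleached), .groups = "drop") |>
    dplyr::mutate(compartment = "flagellum")
  out <- dplyr::bind_rows(pool, cb, fl)[, c("time", "compartment", "structure",
                                            "protein", "unbleached", "bleached")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Writes a small JSON manifest next to an output set: a hash of the
#' configuration, the seed, package version, output paths and a timestamp —
#' enough to re-run the exact computation.
#'
#' @param config The configuration object (any R object; hashed).
#' @param seed Seed used.
#' @param outputs Character vector of output paths.
#' @param path Manifest path (JSON).
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(config, seed, outputs, path) {
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("iftpool")),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE)
  file.rename(tmp, path)
  invisible(manifest)
}

#' Write the canonical test fixture suite
#'
#' Emits the small synthetic fixtures used by the test suite, each with a
#' ground-truth JSON sidecar: a noise-free single-train kymogram, an exact
#' piecewise-linear recovery trace, a noise-free kymogram with crossing
#' anterograde and retrograde lines, and a short default rendering with its
#' conservation totals.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Seed for the default rendering.
#' @return Character vector of files written, invisibly.
#' @export
write_fixture_suite <- function(outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(f) files <<- c(files, f)

  # 1. single noise-free anterograde train at 2 um/s
  cfg <- build_default_config("IFT54", duration = 10, departure_cv = 0,
                              departure_rate = 0.1, imaging_bleach_rate = 0,
                              dim_fraction = 0)
  sim1 <- run_simulation(cfg, NULL, seed = seed)
  k1 <- render_kymogram(sim1, render_config(read_noise_sd = 0),
                        noise = FALSE)[[1]]
  f <- file.path(outdir, "single_train_kymogram.tif")
  write_kymogram_tiff(k1, f); put(f)
  jsonlite::write_json(list(velocity = cfg$v_antero,
                            departures = sim1$trains$departure[
                              sim1$trains$structure == "exp" &
                                sim1$trains$departure >= 0 &
                                sim1$trains$departure <= 10]),
                       file.path(outdir, "single_train_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  put(file.path(outdir, "single_train_truth.json"))

  # 2. exact piecewise-linear recovery trace
  tm <- seq(0, 25, 0.1)
  v <- ifelse(tm < 10, 100, pmin(90, 40 + 10 * (tm - 10)))
  f <- file.path(outdir, "frap_piecewise.csv")
  utils::write.csv(data.frame(time_s = tm, value_percent = v), f,
                   row.names = FALSE); put(f)
  jsonlite::write_json(list(t_bleach = 10, recovery_time = 5,
                            plateau_level = 90),
                       file.path(outdir, "frap_piecewise_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  put(file.path(outdir, "frap_piecewise_truth.json"))

  # 3. crossing anterograde/retrograde lines (constructed, noise-free)
  k3 <- synthetic_line_kymogram(
    lines = tibble(direction = c("anterograde", "retrograde"),
                   origin_time = c(2, 2), velocity = c(2, -3),
                   amplitude = c(400, 400)),
    duration = 12)
  f <- file.path(outdir, "crossing_lines_kymogram.tif")
  write_kymogram_tiff(k3, f); put(f)
  jsonlite::write_json(list(velocities = c(2, -3), origin_times = c(2, 2)),
                       file.path(outdir, "crossing_lines_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  put(file.path(outdir, "crossing_lines_truth.json"))

  # 4. 10 s default rendering with conservation totals
  cfg4 <- build_default_config("IFT54", duration = 10)
  sim4 <- run_simulation(cfg4, NULL, seed = seed)
  k4 <- render_kymogram(sim4)[[1]]
  f <- file.path(outdir, "default_render.tif")
  write_kymogram_tiff(k4, f); put(f)
  tot <- sum(sim4$pool$unbleached[sim4$pool$time == 0],
             sim4$pool$bleached[sim4$pool$time == 0]) +
    sum(sim4$cell_body$unbleached[sim4$cell_body$time == 0],
        sim4$cell_body$bleached[sim4$cell_body$time == 0]) +
    sum(sim4$trains_frames$unbleached[sim4$trains_frames$time == 0],
        sim4$trains_frames$bleached[sim4$trains_frames$time == 0])
  jsonlite::write_json(list(total_cell_copies = cfg4$proteins$total_cell_copies,
                            totals_at_t0 = tot),
                       file.path(outdir, "default_render_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  put(file.path(outdir, "default_render_truth.json"))

  manifest <- run_manifest(list(seed = seed), seed, files,
                           file.path(outdir, "manifest.json"))
  invisible(files)
}

#' Construct a noise-free kymogram of straight lines
#'
#' Draws ideal trajectories (Gaussian line profile, constant velocity) into
#' an otherwise flat kymogram using the default layout — a geometric ground
#' truth for the trajectory detector.
#'
#' @param lines Tibble with `direction`, `origin_time` (s), `velocity`
#'   (um/s, signed) and `amplitude` (photons per frame).
#' @param duration Recording length (s).
#' @param rc Render configuration (geometry and background only).
#' @param structure Structure block to draw into.
#' @return An `ift_kymogram` (noise-free; background level included).
#' @export
synthetic_line_kymogram <- function(lines, duration = 12,
                                    rc = render_config(read_noise_sd = 0),
                                    structure = "exp") {
  cfg <- build_default_config()
  lay <- kym_layout(cfg, rc)
  time <- seq(0, duration, by = 1 / rc$frame_rate)
  S <- matrix(rc$background, length(time), lay$n_px)
  L <- cfg$flagellum_length
  base <- lay$flag_base[[structure]]
  off <- -5:5
  for (i in seq_len(nrow(lines))) {
    v <- lines$velocity[i]
    x0 <- if (v >= 0) 0 else L
    tt <- time - lines$origin_time[i]
    x <- x0 + v * tt
    okf <- which(tt >= 0 & x >= 0 & x <= L)
    px <- base + x[okf] / rc$pixel_size
    ctr <- round(px)
    for (k in seq_along(okf)) {
      cols <- ctr[k] + off
      w <- stats::dnorm(cols - px[k], 0, rc$psf_sigma)
      w <- w / sum(w) * lines$amplitude[i]
      ok <- cols >= 1 & cols <= lay$n_px
      S[okf[k], cols[ok]] <- S[okf[k], cols[ok]] + w[ok]
    }
  }
  new_kymogram(S, rc, lay, "synthetic", time, rep(FALSE, length(time)),
               bleach_protocol())
}
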