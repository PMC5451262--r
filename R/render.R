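#' Rendering configuration for the virtual TIRF microscope
#'
#' The renderer is one-dimensional along the basal-body/flagellum axis:
#' each channel's kymogram holds the experimental block (pool + flagellum)
#' and the control block side by side on one position axis. Signal above
#' background is linear in unbleached copies (`photons_per_copy` expected
#' photons per copy per frame), convolved with a Gaussian line-spread
#' function, then Poisson shot noise and additive Gaussian read noise are
#' applied.
#'
#' For duty-cycled FLIP recordings two acquisition dialects are emulated:
#' `"drop-frames"` (frames while the bleach laser is on are not recorded;
#' they appear as masked `NA` rows so the time base is preserved) and
#' `"saturated-frames"` (those frames are recorded saturated at
#' `saturation_level` and masked).
#'
#' @param frame_rate Frames per second (default 10).
#' @param pixel_size Microns per pixel (default 0.16).
#' @param psf_sigma Line-spread sigma in pixels.
#' @param pool_sigma Sigma of the stationary pool spot, pixels.
#' @param photons_per_copy Expected photons per unbleached copy per frame.
#' @param background Background photons per pixel per frame.
#' @param read_noise_sd Read noise standard deviation (counts).
#' @param acquisition_dialect `"drop-frames"` or `"saturated-frames"`.
#' @param saturation_level Counts recorded in saturated frames.
#' @return A list of class `ift_render_config`.
#' @export
render_config <- function(frame_rate = 10, pixel_size = 0.16, psf_sigma = 1.2,
                          pool_sigma = 2.0, photons_per_copy = 20,
                          background = 10, read_noise_sd = 2,
                          acquisition_dialect = c("drop-frames",
                                                  "saturated-frames"),
                          saturation_level = 65535) {
  structure(list(
    frame_rate = frame_rate, pixel_size = pixel_size, psf_sigma = psf_sigma,
    pool_sigma = pool_sigma, photons_per_copy = photons_per_copy,
    background = background, read_noise_sd = read_noise_sd,
    acquisition_dialect = match.arg(acquisition_dialect),
    saturation_level = saturation_level
  ), class = "ift_render_config")
}

# Pixel layout of the two structures along the position axis.
kym_layout <- function(sim_config, rc) {
  flag_px <- ceiling(sim_config$flagellum_length / rc$pixel_size)
  pool_center <- 7L
  flag_base <- 12L
  block <- flag_base + flag_px + 8L
  list(flag_px = flag_px,
       pool_center = c(exp = pool_center, ctrl = pool_center + block),
       flag_base = c(exp = flag_base, ctrl = flag_base + block),
       block = block, n_px = 2L * block)
}

new_kymogram <- function(mat, rc, layout, channel, time, mask, protocol) {
  structure(mat, class = c("ift_kymogram", "matrix", "array"),
            frame_interval = 1 / rc$frame_rate, pixel_size = rc$pixel_size,
            layout = layout, channel = channel, time = time, mask = mask,
            annotations = protocol, render_config = rc)
}

#' @export
print.ift_kymogram <- function(x, ...) {
  cat(sprintf("<ift_kymogram> channel %s: %d frames x %d px (%.1f s, %.2f um/px), %d masked frame(s)\n",
              attr(x, "channel"), nrow(x), ncol(x),
              nrow(x) * attr(x, "frame_interval"), attr(x, "pixel_size"),
              sum(attr(x, "mask"))))
  invisible(x)
}

# Frames whose exposure overlaps a duty-cycled laser-on interval.
laser_on_frames <- function(sim, time, frame_interval) {
  on <- rep(FALSE, length(time))
  if (nrow(sim$protocol) == 0) return(on)
  duty <- which(sim$protocol$mode == "duty")
  for (r in duty) {
    iv <- sim$laser_on[[r]]
    for (k in seq_len(nrow(iv))) {
      on <- on | (time < iv[k, 2] & (time + frame_interval) > iv[k, 1])
    }
  }
  on
}

# Expected-photon signal grid for one channel (frames x pixels), no noise.
render_signal <- function(sim, rc, channel) {
  cfg <- sim$config
  lay <- kym_layout(cfg, rc)
  frame_interval <- 1 / rc$frame_rate
  step <- frame_interval / sim$record_dt
  if (abs(step - round(step)) > 1e-9) {
    abort("frame interval must be a multiple of the simulation record interval",
          class = "iftpool_render_error")
  }
  time <- sim$time[seq(1, length(sim$time), by = round(step))]
  nfr <- length(time); npx <- lay$n_px
  S <- matrix(0, nfr, npx)
  prot <- cfg$proteins$name[cfg$proteins$channel == channel]
  if (length(prot) == 0) {
    abort(sprintf("no protein renders in channel '%s'", channel),
          class = "iftpool_render_error")
  }

  # stationary pool spots
  off <- -6:6
  w_pool <- stats::dnorm(off, 0, rc$pool_sigma); w_pool <- w_pool / sum(w_pool)
  pool <- dplyr::filter(sim$pool, .data$protein %in% prot, .data$time %in% !!time)
  for (s in c("exp", "ctrl")) {
    amp <- pool |>
      dplyr::filter(.data$structure == s) |>
      dplyr::group_by(.data$time) |>
      dplyr::summarise(u = sum(.data$unbleached), .groups = "drop")
    a <- amp$u[match(time, amp$time)] * rc$photons_per_copy
    a[is.na(a)] <- 0
    cols <- lay$pool_center[[s]] + off
    S[, cols] <- S[, cols] + outer(a, w_pool)
  }

  # moving trains: Gaussian line profile centred at the train position
  tf <- dplyr::filter(sim$trains_frames, .data$protein %in% prot,
                      .data$unbleached > 0, .data$time %in% !!time)
  if (nrow(tf) > 0) {
    off_t <- -5:5
    fi <- match(tf$time, time)
    px <- ifelse(tf$structure == "exp", lay$flag_base[["exp"]],
                 lay$flag_base[["ctrl"]]) + tf$position / rc$pixel_size
    photons <- tf$unbleached * rc$photons_per_copy
    centers <- round(px)
    m <- length(px)
    px_idx <- rep(centers, each = length(off_t)) + rep(off_t, m)
    w <- stats::dnorm(px_idx - rep(px, each = length(off_t)), 0, rc$psf_sigma)
    wsum <- rep(tapply(w, rep(seq_len(m), each = length(off_t)), sum), each = length(off_t))
    vals <- rep(photons, each = length(off_t)) * w / wsum
    f_idx <- rep(fi, each = length(off_t))
    ok <- px_idx >= 1 & px_idx <= npx
    lin <- (px_idx[ok] - 1L) * nfr + f_idx[ok]
    acc <- rowsum(vals[ok], lin)
    S[as.integer(rownames(acc))] <- S[as.integer(rownames(acc))] + acc[, 1]
  }
  list(S = S, layout = lay, time = time)
}

#' Render kymograms from a simulation
#'
#' Converts the ground-truth state trace into one synthetic TIRF kymogram per
#' channel (time frames x position pixels, experimental and control blocks on
#' the same axis). Unbleached copies contribute photons; bleached copies are
#' dark.
#'
#' @param sim An `ift_sim` from [run_simulation()].
#' @param rc An [render_config()].
#' @param channels Channels to render (default: all in the config).
#' @param noise Set `FALSE` for a noise-free expected-photon image
#'   (background still added).
#' @return Named list of `ift_kymogram` objects, one per channel.
#' @export
render_kymogram <- function(sim, rc = render_config(), channels = NULL,
                            noise = TRUE) {
  channels <- channels %||% unique(sim$config$proteins$channel)
  out <- list()
  for (k in seq_along(channels)) {
    ch <- channels[k]
    sig <- render_signal(sim, rc, ch)
    lam <- sig$S + rc$background
    set.seed(derive_seed(sim$seed, 200L + k))
    if (noise) {
      counts <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam))
      counts <- counts + round(rnorm(length(lam), 0, rc$read_noise_sd))
      counts <- pmax(counts, 0)
    } else {
      counts <- lam
    }
    mask <- laser_on_frames(sim, sig$time, 1 / rc$frame_rate)
    if (any(mask)) {
      if (rc$acquisition_dialect == "drop-frames") {
        counts[mask, ] <- NA_real_
      } else {
        counts[mask, ] <- rc$saturation_level
      }
    }
    out[[ch]] <- new_kymogram(counts, rc, sig$layout, ch, sig$time, mask,
                              sim$protocol)
  }
  out
}

#' Render a time-lapse frame stack
#'
#' Builds 2-D frames whose line scan along the flagellum axis (the central
#' row) reproduces [render_kymogram()] exactly for the same seed; off-axis
#' rows carry background only. Under the `"drop-frames"` dialect, frames
#' recorded while the bleach laser is on are omitted from the stack.
#'
#' @inheritParams render_kymogram
#' @param channel Single channel to render.
#' @param height Stack height in pixels (odd).
#' @return A list of class `ift_stack`: `frames` (3-d array y x x x frame),
#'   `center_row`, `time`, plus the metadata of the matching kymogram.
#' @export
render_frame_stack <- function(sim, rc = render_config(), channel = NULL,
                               height = 7) {
  channel <- channel %||% sim$config$proteins$channel[1]
  kym <- render_kymogram(sim, rc, channels = channel)[[channel]]
  keep <- if (rc$acquisition_dialect == "drop-frames") !attr(kym, "mask")
          else rep(TRUE, nrow(kym))
  km <- unclass(kym)[keep, , drop = FALSE]
  nfr <- nrow(km); npx <- ncol(km)
  center <- (height + 1) %/% 2
  arr <- array(0, c(height, npx, nfr))
  set.seed(derive_seed(sim$seed, 300L))
  for (f in seq_len(nfr)) {
    bgrows <- matrix(rpois((height - 1) * npx, rc$background) +
                       round(rnorm((height - 1) * npx, 0, rc$read_noise_sd)),
                     height - 1, npx)
    arr[-center, , f] <- pmax(bgrows, 0)
    arr[center, , f] <- km[f, ]
  }
  structure(list(frames = arr, center_row = center,
                 time = attr(kym, "time")[keep],
                 layout = attr(kym, "layout"), channel = channel,
                 render_config = rc, mask_source = attr(kym, "mask")),
            class = "ift_stack")
}

#' Extract a kymogram from a frame stack
#'
#' Collapses a band of rows around the scan path into one line per frame,
#' taking the per-position maximum (or mean) across the band — the virtual
#' counterpart of drawing a segmented line over a recording in an image
#' analysis program.
#'
#' @param stack An `ift_stack`.
#' @param path Row index of the scan path (default: the stack's center row).
#' @param width Band width in rows (odd).
#' @param mode `"max"` or `"mean"` across the band.
#' @return An `ift_kymogram`.
#' @export
extract_kymogram_from_stack <- function(stack, path = stack$center_row,
                                        width = 1, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  h <- dim(stack$frames)[1]
  half <- (width - 1) %/% 2
  rows <- (path - half):(path + half)
  if (any(rows < 1 | rows > h)) {
    abort("scan path band outside the image", class = "iftpool_input_error")
  }
  nfr <- dim(stack$frames)[3]; npx <- dim(stack$frames)[2]
  out <- matrix(0, nfr, npx)
  fun <- if (mode == "max") function(m) apply(m, 2, max) else colMeans
  for (f in seq_len(nfr)) {
    band <- stack$frames[rows, , f, drop = FALSE]
    out[f, ] <- fun(matrix(band, length(rows), npx))
  }
  new_kymogram(out, stack$render_config, stack$layout, stack$channel,
               stack$time, rep(FALSE, nfr), bleach_protocol())
}

#' Write / read a kymogram as 16-bit TIFF with a JSON sidecar
#'
#' The TIFF stores the count grid linearly scaled to 16 bits; the sidecar
#' records the scale, frame interval, pixel size, layout, channel and masked
#' frames so that reading restores the object (within integer quantization).
#'
#' @param kym An `ift_kymogram`.
#' @param path Output TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly (writer); an `ift_kymogram` (reader).
#' @export
write_kymogram_tiff <- function(kym, path) {
  m <- unclass(kym)
  attributes(m) <- list(dim = dim(m))
  mask <- attr(kym, "mask")
  m[is.na(m)] <- 0
  scale <- max(m, 1)
  tiff::writeTIFF(m / scale, path, bits.per.sample = 16L)
  meta <- list(scale = scale, frame_interval = attr(kym, "frame_interval"),
               pixel_size = attr(kym, "pixel_size"),
               channel = attr(kym, "channel"), time = attr(kym, "time"),
               mask = mask,
               layout = lapply(attr(kym, "layout"), as.list))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kymogram_tiff
#' @export
read_kymogram_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path) * meta$scale
  m <- round(m)
  mask <- as.logical(meta$mask)
  m[mask, ] <- NA_real_
  rc <- render_config(frame_rate = 1 / meta$frame_interval,
                      pixel_size = meta$pixel_size)
  lay <- lapply(meta$layout, function(x) if (is.list(x)) unlist(x) else x)
  new_kymogram(m, rc, lay, meta$channel, meta$time, mask, bleach_protocol())
}
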