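#' Registry of fluorescent-protein tagged IFT proteins
#'
#' Returns the per-protein kinetic, recycling and rendering parameters used by
#' the default calibration of the assembly-queue model. One row per protein;
#' columns map onto the fields of a protein spec (see [build_default_config()]).
#'
#' The registry encodes the behaviour classes observed in photobleaching
#' experiments on *Chlamydomonas reinhardtii*:
#'
#' * **IFT-A** proteins (IFT140, IFT43) are recruited early, so their
#'   post-bleach gap in anterograde traffic is the longest (~7 s); they
#'   disperse into the cell body after one transit ("open" recycling).
#' * **IFT-B** proteins split into a semi-open group (IFT20, IFT46, IFT54)
#'   that re-enters the basal-body pool after retrograde transit, dwells
#'   ~6 s in a disassembly compartment, and is partly reused in nascent
#'   trains, and an open one (IFT27).
#' * **Motors**: the kinesin-2 subunit KAP is added late (gap ~5 s) and
#'   mostly dissociates from trains at the tip; the IFT-dynein subunit
#'   D1bLIC is loaded briefly before departure (gap ~2.5 s) and returns
#'   with the train.
#' * **Cargo**: tubulin is loaded last (gap ~2 s), carried by most trains
#'   during regeneration, and unloaded at the tip.
#'
#' Recruitment leads are calibrated so that the *measured* post-bleach gap —
#' which in a renewal queue equals the lead plus the mean residual wait to
#' the next scheduled departure (~0.5 s at one train per second) —
#' reproduces the gaps observed for each protein.
#'
#' `copies_per_train` is the relative brightness unit of a full-size train;
#' `standing_extra` is pool material (in train equivalents) beyond nascent
#' trains and the recycling compartment; `total_cell_copies` is the finite
#' whole-cell supply shared by both flagella of a cell.
#'
#' @return A tibble with one row per registered protein.
#' @export
#' @examples
#' protein_registry()
protein_registry <- function() {
  tibble::tribble(
    ~name,      ~complex_class,   ~recruitment_lead, ~lead_sd, ~copies_per_train,
    ~carry_prob, ~tip_release_prob, ~recycle_enabled, ~residence_mean, ~residence_sd,
    ~reuse_prob, ~standing_extra, ~total_cell_copies,
    "IFT140",   "IFT-A",          6.5,  1.0, 20L, 1.00, 0.0, FALSE, 0,   0,   0.0, 3.0, 6000L,
    "IFT43",    "IFT-A",          6.5,  1.0, 20L, 1.00, 0.0, FALSE, 0,   0,   0.0, 3.0, 6000L,
    "IFT54",    "IFT-B2",         6.0,  1.0, 20L, 1.00, 0.0, TRUE,  6.0, 1.0, 0.50, 4.25, 6000L,
    "IFT20",    "IFT-B2",         6.0,  1.0, 20L, 1.00, 0.0, TRUE,  6.0, 1.0, 0.50, 4.25, 6000L,
    "IFT46",    "IFT-B1",         5.0,  1.0, 20L, 1.00, 0.0, TRUE,  6.0, 1.0, 0.50, 4.25, 6000L,
    "IFT27",    "IFT-B1",         5.0,  1.0, 20L, 1.00, 0.0, FALSE, 0,   0,   0.0, 3.0, 6000L,
    "KAP",      "motor-kinesin",  4.5,  1.0, 20L, 1.00, 0.9, FALSE, 0,   0,   0.0, 2.5, 6000L,
    "D1bLIC",   "motor-dynein",   2.0,  1.0, 20L, 1.00, 0.0, FALSE, 0,   0,   0.0, 2.5, 6000L,
    "tubulin",  "cargo",          0.5,  0.3, 20L, 0.45, 1.0, FALSE, 0,   0,   0.0, 0.5, 6000L
  ) |>
    dplyr::mutate(channel = .data$name)
}

#' Build the default, calibrated simulation configuration
#'
#' Assembles a simulation configuration for the requested proteins using the
#' calibrated registry defaults: 12 um flagella, anterograde 2.0 um/s,
#' retrograde 3.0 um/s, 0.9 s tip turnaround (so a base-tip-base transit takes
#' 10.9 s), one train departure per second with inter-departure CV 0.3, nine
#' assembly slots, and bright trains alternating stochastically with half-size
#' dim trains.
#'
#' @param protein_names Character vector of protein names drawn from
#'   [protein_registry()]. May be empty.
#' @param ... Named overrides for top-level configuration fields
#'   (e.g. `duration = 120`, `departure_cv = 0`).
#' @return A list of class `ift_config` with a `proteins` tibble.
#' @export
#' @examples
#' cfg <- build_default_config("IFT140")
#' cfg$proteins$recruitment_lead  # 6.5 s; measured gap ~7 s
build_default_config <- function(protein_names = character(), ...) {
  reg <- protein_registry()
  unknown <- setdiff(protein_names, reg$name)
  if (length(unknown) > 0) {
    abort(sprintf(
      "Unknown protein name(s): %s. Registered: %s.",
      paste(unknown, collapse = ", "), paste(reg$name, collapse = ", ")
    ), class = "iftpool_registry_error")
  }
  proteins <- reg[match(protein_names, reg$name), , drop = FALSE]
  cfg <- list(
    flagellum_length    = 12,     # um
    v_antero            = 2.0,    # um/s
    v_retro             = 3.0,    # um/s
    turnaround          = 0.9,    # s dwell at the tip
    departure_rate      = 1.0,    # trains/s
    departure_cv        = 0.3,    # CV of inter-departure intervals
    n_slots             = 9L,     # assembly queue capacity
    bright_dim_ratio    = 0.5,    # dim train size relative to bright
    dim_fraction        = 0.5,    # fraction of dim trains
    imaging_bleach_rate = 0.003,  # /s, first-order loss under TIRF illumination
    duration            = 60,     # s recorded
    dt                  = 0.01,   # s integration step
    seed                = 1L,
    n_structures        = 2L,     # experimental + control flagellum/pool pairs
    proteins            = proteins
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0) {
    abort(sprintf("Unknown configuration field(s): %s", paste(bad, collapse = ", ")),
          class = "iftpool_config_error")
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "ift_config")
}

#' Validate a simulation configuration
#'
#' Checks field types, ranges, and the queue-capacity condition
#' `departure_rate * max(recruitment_lead) <= n_slots` (a train must find a
#' free assembly slot when its earliest protein is recruited).
#'
#' @param config An `ift_config` list.
#' @return The config, invisibly, on success; otherwise an error.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "ift_config"))
  chk <- function(ok, msg) if (!ok) abort(msg, class = "iftpool_config_error")
  chk(config$v_antero > 0 && config$v_retro > 0, "velocities must be > 0")
  chk(config$flagellum_length > 0, "flagellum_length must be > 0")
  chk(config$departure_rate > 0, "departure_rate must be > 0")
  chk(config$departure_cv >= 0, "departure_cv must be >= 0")
  chk(config$dt > 0 && config$dt <= 0.1, "dt must be in (0, 0.1] s")
  chk(config$duration > 0, "duration must be > 0")
  chk(config$dim_fraction >= 0 && config$dim_fraction <= 1, "dim_fraction must be in [0,1]")
  chk(config$imaging_bleach_rate >= 0, "imaging_bleach_rate must be >= 0")
  p <- config$proteins
  if (nrow(p) > 0) {
    frac_cols <- c("carry_prob", "tip_release_prob", "reuse_prob")
    for (cl in frac_cols) {
      chk(all(p[[cl]] >= 0 & p[[cl]] <= 1),
          sprintf("protein field %s must be in [0,1]", cl))
    }
    chk(all(p$recruitment_lead >= 0), "recruitment_lead must be >= 0")
    chk(all(p$copies_per_train >= 1), "copies_per_train must be >= 1")
    chk(all(p$total_cell_copies >= 1), "total_cell_copies must be >= 1")
    max_lead <- max(p$recruitment_lead)
    if (config$departure_rate * max_lead > config$n_slots) {
      abort(sprintf(paste0(
        "Assembly queue overflow: departure_rate (%.2f/s) x longest recruitment ",
        "lead (%.1f s) = %.1f exceeds the %d assembly slots. Reduce the rate, ",
        "the lead, or raise n_slots."),
        config$departure_rate, max_lead, config$departure_rate * max_lead,
        config$n_slots), class = "iftpool_config_error")
    }
  }
  invisible(config)
}

#' @export
print.ift_config <- function(x, ...) {
  cat(sprintf(
    "<ift_config> %d protein(s), duration %g s, departure rate %g/s (CV %g)\n",
    nrow(x$proteins), x$duration, x$departure_rate, x$departure_cv))
  cat(sprintf("  flagellum %g um, v+ %g um/s, v- %g um/s, turnaround %g s, %d slots\n",
              x$flagellum_length, x$v_antero, x$v_retro, x$turnaround, x$n_slots))
  if (nrow(x$proteins) > 0) {
    print(x$proteins[, c("name", "complex_class", "recruitment_lead",
                         "recycle_enabled", "reuse_prob", "standing_extra")])
  }
  invisible(x)
}

# Derive a reproducible child seed (kept below 2^31) from a master seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1103515245 * k) %% 2147483647) + 1L
}
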