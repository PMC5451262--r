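# Shared cache so expensive simulations/experiments are built once per run.
.iftpool_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .iftpool_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .iftpool_cache)
  }
  get(name, envir = .iftpool_cache, inherits = FALSE)
}

# A plain 60 s IFT54 recording (no bleaching), reused by several tests.
default_sim <- function() {
  cached("default_sim", run_simulation(
    build_default_config("IFT54", duration = 60), NULL, seed = 101))
}

default_kym <- function() {
  cached("default_kym", render_kymogram(default_sim())[["IFT54"]])
}

# Whole-cell copy totals per frame (pool + cell body + trains), per state.
conservation_totals <- function(sim) {
  pool <- sim$pool |>
    dplyr::group_by(time) |>
    dplyr::summarise(u = sum(unbleached), b = sum(bleached), .groups = "drop")
  cb <- sim$cell_body |>
    dplyr::group_by(time) |>
    dplyr::summarise(u = sum(unbleached), b = sum(bleached), .groups = "drop")
  fl <- sim$trains_frames |>
    dplyr::group_by(time) |>
    dplyr::summarise(u = sum(unbleached), b = sum(bleached), .groups = "drop")
  out <- dplyr::left_join(pool, cb, by = "time", suffix = c("_pool", "_cb"))
  out <- dplyr::left_join(out, fl, by = "time")
  out$u[is.na(out$u)] <- 0; out$b[is.na(out$b)] <- 0
  dplyr::transmute(out, time = time,
                   unbleached = u_pool + u_cb + u,
                   bleached = b_pool + b_cb + b,
                   total = unbleached + bleached)
}

# Event-log oracle for the post-bleach gap: first scheduled departure whose
# composition at departure clears the intensity floor.
oracle_gap <- function(sim, t_bleach, floor_frac = 0.3, guard = 0.25) {
  tp <- sim$train_proteins[sim$train_proteins$structure == "exp" &
                             !is.na(sim$train_proteins$u_depart), ]
  tr <- dplyr::left_join(tp, sim$trains, by = c("structure", "train"))
  pre <- tr$u_depart[tr$departure > 0 & tr$departure < t_bleach]
  med <- median(pre)
  qual <- tr$departure[tr$departure >= t_bleach + guard &
                         tr$u_depart >= floor_frac * med]
  if (length(qual) == 0) return(NA_real_)
  min(qual) - t_bleach
}

# Trains bright enough and early enough to be detectable in a recording.
oracle_visible_departures <- function(sim, t_end) {
  tp <- sim$train_proteins[sim$train_proteins$structure == "exp" &
                             !is.na(sim$train_proteins$u_depart), ]
  tr <- dplyr::left_join(tp, sim$trains, by = c("structure", "train"))
  sum(tr$departure >= 0 & tr$departure <= t_end - 3 & tr$u_depart >= 4)
}

expect_within <- function(value, target, tol, label = NULL) {
  expect_true(abs(value - target) <= tol,
              label = sprintf("%s: %.3f within %.3f of %.3f",
                              label %||% "value", value, tol, target))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
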