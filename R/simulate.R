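#' Sample train departure times
#'
#' Departures from the basal-body pool form a renewal process with mean
#' interval `1/departure_rate` and coefficient of variation `departure_cv`
#' (gamma-distributed intervals; `departure_cv = 0` gives a perfectly regular
#' clock). Uses the current RNG state.
#'
#' @param config An `ift_config`.
#' @param from,to Time window (s); defaults to `[0, duration]`.
#' @return Ascending numeric vector of departure times in `(from, to]`.
#' @export
#' @examples
#' cfg <- build_default_config("IFT140", departure_cv = 0, duration = 10)
#' sample_departure_times(cfg)  # 1, 2, ..., 10
sample_departure_times <- function(config, from = 0, to = config$duration) {
  rate <- config$departure_rate
  cv <- config$departure_cv
  if (!is.numeric(rate) || rate <= 0) {
    abort("departure_rate must be > 0", class = "iftpool_config_error")
  }
  if (to <= from) abort("duration must be > 0", class = "iftpool_config_error")
  draw <- function(n) {
    if (cv == 0) rep(1 / rate, n)
    else {
      shape <- 1 / cv^2
      rgamma(n, shape = shape, rate = shape * rate)
    }
  }
  span <- to - from
  iv <- draw(ceiling(span * rate * 1.5) + 20L)
  while (sum(iv) < span) iv <- c(iv, draw(ceiling(span * rate * 0.5) + 20L))
  times <- from + cumsum(iv)
  times[times <= to]
}

#' Recruitment time of a protein into a nascent train
#'
#' A protein joins the assembling train `recruitment_lead` seconds (with
#' normal spread `lead_sd`) before the train departs; negative draws are
#' truncated so recruitment never precedes the start of the recording.
#'
#' @param departure_t Departure time(s) of the train (s).
#' @param spec A one-row protein tibble (a row of [protein_registry()]).
#' @return Recruitment time(s), `>= 0`.
#' @export
#' @examples
#' spec <- protein_registry()[1, ]  # IFT140
#' spec$recruitment_lead <- 7
#' spec$lead_sd <- 0
#' recruitment_time(20, spec)  # 13
recruitment_time <- function(departure_t, spec) {
  lead <- pmax(0, rnorm(length(departure_t), spec$recruitment_lead, spec$lead_sd))
  pmax(0, departure_t - lead)
}

#' Bleach a set of copy counts
#'
#' Low-level photobleach primitive: each unbleached copy switches to the
#' bleached state independently with probability `efficiency`. Bleaching is
#' irreversible; bleached counts never decrease.
#'
#' @param unbleached,bleached Non-negative integer counts (vectors).
#' @param efficiency Per-copy bleach probability in \[0, 1\].
#' @return A list with updated `unbleached` and `bleached` vectors.
#' @export
#' @examples
#' apply_bleach(100, 0, efficiency = 1)  # all bleached
apply_bleach <- function(unbleached, bleached, efficiency) {
  if (efficiency < 0 || efficiency > 1) {
    abort("efficiency must be in [0, 1]", class = "iftpool_protocol_error")
  }
  moved <- rbinom(length(unbleached), unbleached, efficiency)
  list(unbleached = unbleached - moved, bleached = bleached + moved)
}

#' Route the composition of a returning train
#'
#' When a retrograde train reaches the base, copies of recycle-enabled
#' proteins enter the pool's disassembly compartment for a truncated-normal
#' residence, after which each copy is staged for reuse in a nascent train
#' with probability `reuse_prob` or released into the cell body. Proteins
#' without recycling disperse into the cell body immediately. Copies released
#' at the tip never reach this routing.
#'
#' @param composition Tibble with columns `protein`, `unbleached`, `bleached`
#'   (counts on the returning train).
#' @param specs Protein tibble (rows of [protein_registry()]) covering the
#'   proteins in `composition`.
#' @return A tibble with per-protein fate records: counts routed to the
#'   recycling compartment vs the cell body, the sampled residence (NA for
#'   non-recycled proteins), and the post-residence reuse/release split.
#' @export
route_returning_train <- function(composition, specs) {
  stopifnot(all(composition$protein %in% specs$name))
  sp <- specs[match(composition$protein, specs$name), ]
  out <- purrr::pmap(list(
    composition$protein, composition$unbleached, composition$bleached,
    seq_len(nrow(sp))
  ), function(pn, u, b, k) {
    s <- sp[k, ]
    if (isTRUE(s$recycle_enabled)) {
      res <- max(0, rnorm(1, s$residence_mean, s$residence_sd))
      ru <- rbinom(1, u, s$reuse_prob)
      rb <- rbinom(1, b, s$reuse_prob)
      tibble(protein = pn, to_recycling_unbleached = u, to_recycling_bleached = b,
             residence = res, reused_unbleached = ru, reused_bleached = rb,
             to_cell_body_unbleached = u - ru, to_cell_body_bleached = b - rb)
    } else {
      tibble(protein = pn, to_recycling_unbleached = 0L, to_recycling_bleached = 0L,
             residence = NA_real_, reused_unbleached = 0L, reused_bleached = 0L,
             to_cell_body_unbleached = u, to_cell_body_bleached = b)
    }
  })
  bind_rows(out)
}

# Event type codes used by the engine and the event log.
EVENT_TYPES <- c("recruit", "depart", "tip_arrival", "base_return",
                 "recycle_expiry", "bleach_pulse", "flip_hit")

# Residence in the recycling compartment is sampled per copy; copies of one
# returning train are spread over this many independently timed sub-batches
# so reused material mixes into several subsequent trains.
REC_SUBBATCHES <- 4L

# Each binding slot of a recruiting train is filled from the staged recycled
# material with probability avail/(avail + REUSE_F0), the rest from the cell
# body: disassembled complexes at the pool are accessible to several trains
# under construction, so reused (bleached) copies spread across consecutive
# trains in proportion to train size, and the staged pool self-regulates
# (outflow matches the post-residence reuse inflow).
REUSE_F0 <- 15

#' Run the assembly-queue simulation
#'
#' Simulates the full protein life cycle for one cell: two flagellum/pool
#' structures (`exp`, `ctrl`) sharing a finite cell-body supply. Trains are
#' seeded per scheduled departure, occupy at most `n_slots` assembly slots
#' (recruitment waits for a free slot), transit the flagellum at the
#' configured velocities with a fixed tip dwell, and their returning copies
#' are routed through the open or semi-open recycling pathway. A photobleach
#' protocol (see [bleach_protocol()]) and continuous low-level imaging bleach
#' act on every copy in the evanescent field (pools and flagella). The
#' simulation burns in long enough before `t = 0` that recordings start in
#' steady state.
#'
#' Copy counts are aggregated per (compartment, protein, bleach state) and
#' per train, so conservation is exact: for every protein,
#' unbleached + bleached summed over the cell body, both pools, and all
#' trains equals `total_cell_copies` at every frame.
#'
#' @param config An `ift_config` (see [build_default_config()]).
#' @param protocol An `ift_protocol` or `NULL` for no bleaching.
#' @param seed Master seed; every random stream derives from it.
#' @param record_dt Snapshot interval (s); the renderer's frame interval must
#'   be a multiple of it.
#' @return An `ift_sim` list with tibbles `pool` (per-frame pool content by
#'   protein and bleach state), `cell_body`, `trains` (per-train records),
#'   `train_proteins` (per-train composition at departure and return),
#'   `trains_frames` (per-frame train positions and compositions, for
#'   rendering), and `events` (the time-ordered event log).
#' @export
run_simulation <- function(config, protocol = NULL, seed = config$seed,
                           record_dt = 0.1) {
  validate_config(config)
  if (is.null(protocol)) protocol <- bleach_protocol()
  pr <- config$proteins
  P <- nrow(pr)
  L <- config$flagellum_length
  va <- config$v_antero; vr <- config$v_retro; turn <- config$turnaround
  dt <- config$dt
  snap <- function(x) round(x / dt) * dt
  transit <- L / va + turn + L / vr
  max_lead <- if (P > 0) max(pr$recruitment_lead + 3 * pr$lead_sd) else 0
  max_res <- if (P > 0) max(pr$residence_mean + 3 * pr$residence_sd) else 0
  burn <- ceiling(max_lead + transit + max_res + 5)
  t0 <- -burn
  t_end <- config$duration

  ## ---- per-structure schedules (independent substreams) -----------------
  dep <- vector("list", 2); size <- vector("list", 2)
  carried <- vector("list", 2); rec_t <- vector("list", 2)
  residence <- vector("list", 2); tip <- vector("list", 2); ret <- vector("list", 2)
  nd <- integer(2)
  for (s in 1:2) {
    set.seed(derive_seed(seed, s))
    # schedule beyond the recording so trains still assembling at the end
    # keep the nascent pool populated
    d <- snap(sample_departure_times(config, from = t0, to = t_end + burn))
    nd[s] <- length(d)
    dep[[s]] <- d
    size[[s]] <- ifelse(stats::runif(nd[s]) < config$dim_fraction,
                        config$bright_dim_ratio, 1)
    if (P > 0) {
      carried[[s]] <- matrix(stats::runif(nd[s] * P) <
                               rep(pr$carry_prob, each = nd[s]), nd[s], P)
      lead_draw <- matrix(pmax(0, rnorm(nd[s] * P,
                                        rep(pr$recruitment_lead, each = nd[s]),
                                        rep(pr$lead_sd, each = nd[s]))), nd[s], P)
      rt <- d - lead_draw
      # assembly slots: recruitment cannot start before the slot n_slots
      # departures back has been vacated
      slot_free <- c(rep(t0, config$n_slots), d)[seq_len(nd[s])]
      rt <- pmax(rt, slot_free, t0)
      rec_t[[s]] <- snap(rt)
      residence[[s]] <- array(pmax(0, rnorm(nd[s] * P * REC_SUBBATCHES,
                                            rep(pr$residence_mean, each = nd[s]),
                                            rep(pr$residence_sd, each = nd[s]))),
                              c(nd[s], P, REC_SUBBATCHES))
    } else {
      carried[[s]] <- matrix(FALSE, nd[s], 0)
      rec_t[[s]] <- matrix(numeric(0), nd[s], 0)
      residence[[s]] <- array(numeric(0), c(nd[s], 0, REC_SUBBATCHES))
    }
    tip[[s]] <- snap(d + L / va)
    ret[[s]] <- snap(tip[[s]] + turn + L / vr)
  }

  ## ---- static event table ------------------------------------------------
  ev <- list()
  for (s in 1:2) {
    if (P > 0 && nd[s] > 0) {
      idx <- which(carried[[s]])
      if (length(idx) > 0) {
        i_of <- (idx - 1L) %% nd[s] + 1L
        p_of <- (idx - 1L) %/% nd[s] + 1L
        ev[[length(ev) + 1]] <- cbind(t = rec_t[[s]][idx], ty = 1, s = s,
                                      i = i_of, p = p_of, x = 0)
        rec_idx <- idx[pr$recycle_enabled[p_of] & ret[[s]][i_of] <= t_end]
        if (length(rec_idx) > 0) {
          ri <- (rec_idx - 1L) %% nd[s] + 1L
          rp <- (rec_idx - 1L) %/% nd[s] + 1L
          for (j in seq_len(REC_SUBBATCHES)) {
            ev[[length(ev) + 1]] <- cbind(
              t = snap(ret[[s]][ri] + residence[[s]][cbind(ri, rp, j)]),
              ty = 5, s = s, i = ri, p = rp, x = j)
          }
        }
      }
    }
    if (nd[s] > 0) {
      ev[[length(ev) + 1]] <- cbind(t = dep[[s]], ty = 2, s = s,
                                    i = seq_len(nd[s]), p = 0, x = 0)
    }
    keep <- tip[[s]] <= t_end
    if (any(keep)) ev[[length(ev) + 1]] <- cbind(t = tip[[s]][keep], ty = 3,
                                                 s = s, i = which(keep), p = 0, x = 0)
    keep <- ret[[s]] <= t_end
    if (any(keep)) ev[[length(ev) + 1]] <- cbind(t = ret[[s]][keep], ty = 4,
                                                 s = s, i = which(keep), p = 0, x = 0)
  }
  laser_on <- vector("list", nrow(protocol))
  if (nrow(protocol) > 0) {
    for (r in seq_len(nrow(protocol))) {
      evt <- protocol[r, ]
      laser_on[[r]] <- laser_on_intervals(evt)
      if (evt$mode == "pulse") {
        ev[[length(ev) + 1]] <- cbind(t = snap(evt$t_start), ty = 6, s = 0,
                                      i = r, p = 0, x = 0)
      } else {
        # tip-window duty cycling: bleach hits on experimental trains whose
        # in-window interval overlaps a laser-on pulse
        x0 <- evt$x0; x1 <- min(evt$x1, L)
        t_in <- dep[[1]] + x0 / va
        t_out <- if (x1 >= L - 1e-9) tip[[1]] + turn + (L - x0) / vr
                 else dep[[1]] + x1 / va
        on <- laser_on[[r]]
        for (i in seq_len(nd[1])) {
          a <- pmax(on[, 1], t_in[i]); b <- pmin(on[, 2], t_out[i])
          hit <- which(b - a > 1e-9)
          if (length(hit) > 0) {
            ev[[length(ev) + 1]] <- cbind(t = snap(a[hit]), ty = 7, s = 1,
                                          i = i, p = 0, x = r)
          }
          # retrograde re-entry through a sub-tip window
          if (x1 < L - 1e-9) {
            t_in2 <- tip[[1]][i] + turn + (L - x1) / vr
            t_out2 <- tip[[1]][i] + turn + (L - x0) / vr
            a <- pmax(on[, 1], t_in2); b <- pmin(on[, 2], t_out2)
            hit <- which(b - a > 1e-9)
            if (length(hit) > 0) {
              ev[[length(ev) + 1]] <- cbind(t = snap(a[hit]), ty = 7, s = 1,
                                            i = i, p = 0, x = r)
            }
          }
        }
      }
    }
  }
  if (length(ev) == 0) {
    ev <- matrix(numeric(0), 0, 6,
                 dimnames = list(NULL, c("t", "ty", "s", "i", "p", "x")))
  } else {
    ev <- do.call(rbind, ev)
  }
  ev <- ev[ev[, "t"] <= t_end + 1e-9, , drop = FALSE]
  ev <- ev[order(ev[, "t"], ev[, "ty"], ev[, "s"], ev[, "i"], ev[, "p"]), ,
           drop = FALSE]
  nev <- nrow(ev)

  ## ---- state -------------------------------------------------------------
  copies <- if (P > 0) pr$copies_per_train else integer(0)
  cb <- matrix(0, P, 2)              # shared cell body (u, b)
  stand <- list(matrix(0, P, 2), matrix(0, P, 2))
  avail <- list(matrix(0, P, 2), matrix(0, P, 2))
  nasc <- list(matrix(0, P, 2), matrix(0, P, 2))
  rec_sum <- list(matrix(0, P, 2), matrix(0, P, 2))
  m_sub <- REC_SUBBATCHES
  rec_m <- list(matrix(0, nd[1] * max(P, 1) * m_sub, 2),
                matrix(0, nd[2] * max(P, 1) * m_sub, 2))
  rec_active <- list(logical(nd[1] * max(P, 1) * m_sub),
                     logical(nd[2] * max(P, 1) * m_sub))
  comp_u <- list(matrix(0, nd[1], max(P, 1)), matrix(0, nd[2], max(P, 1)))
  comp_b <- list(matrix(0, nd[1], max(P, 1)), matrix(0, nd[2], max(P, 1)))
  dep_u <- list(matrix(NA_real_, nd[1], max(P, 1)), matrix(NA_real_, nd[2], max(P, 1)))
  dep_b <- list(matrix(NA_real_, nd[1], max(P, 1)), matrix(NA_real_, nd[2], max(P, 1)))
  ret_u <- list(matrix(NA_real_, nd[1], max(P, 1)), matrix(NA_real_, nd[2], max(P, 1)))
  ret_b <- list(matrix(NA_real_, nd[1], max(P, 1)), matrix(NA_real_, nd[2], max(P, 1)))
  if (P > 0) {
    for (p in seq_len(P)) {
      st <- round(pr$standing_extra[p] * copies[p])
      total <- pr$total_cell_copies[p]
      if (total < 2 * st) {
        abort(sprintf("total_cell_copies for %s is below the standing pool material",
                      pr$name[p]), class = "iftpool_config_error")
      }
      stand[[1]][p, 1] <- st; stand[[2]][p, 1] <- st
      cb[p, 1] <- total - 2 * st
    }
  }

  elog <- matrix(NA_real_, nev + 8L, 7)
  colnames(elog) <- c("time", "type", "structure", "train", "protein",
                      "n_unbleached", "n_bleached")
  nlog <- 0L
  log_row <- function(t, ty, s, i, p, a, b) {
    nlog <<- nlog + 1L
    if (nlog > nrow(elog)) elog <<- rbind(elog, matrix(NA_real_, 256L, 7))
    elog[nlog, ] <<- c(t, ty, s, i, p, a, b)
  }

  channel_mask <- function(r) {
    ch <- protocol$channels[[r]]
    if (is.null(ch)) rep(TRUE, P) else (pr$name %in% ch | pr$channel %in% ch)
  }

  # bleach a subset of train composition entries (matrix indices into comp)
  bleach_comp <- function(s, rows, pcols, eff, t, nascent_adjust) {
    for (p in pcols) {
      u <- comp_u[[s]][rows, p]
      sel <- which(u > 0)
      if (length(sel) == 0) next
      moved <- rbinom(length(sel), u[sel], eff)
      comp_u[[s]][rows[sel], p] <<- u[sel] - moved
      comp_b[[s]][rows[sel], p] <<- comp_b[[s]][rows[sel], p] + moved
      if (nascent_adjust) {
        tot <- sum(moved)
        nasc[[s]][p, 1] <<- nasc[[s]][p, 1] - tot
        nasc[[s]][p, 2] <<- nasc[[s]][p, 2] + tot
      }
    }
  }

  bleach_pool_compartments <- function(s, eff, pmask) {
    for (p in which(pmask)) {
      for (cmp in c("stand", "avail")) {
        m <- get(cmp)[[s]]
        if (m[p, 1] > 0) {
          moved <- rbinom(1, m[p, 1], eff)
          m[p, 1] <- m[p, 1] - moved; m[p, 2] <- m[p, 2] + moved
          if (cmp == "stand") stand[[s]] <<- m else avail[[s]] <<- m
        }
      }
    }
    act <- which(rec_active[[s]])
    if (length(act) > 0) {
      pw <- ((act - 1L) %/% m_sub) %/% nd[s] + 1L
      keep <- pmask[pw] & rec_m[[s]][act, 1] > 0
      act <- act[keep]; pw <- pw[keep]
      if (length(act) > 0) {
        moved <- rbinom(length(act), rec_m[[s]][act, 1], eff)
        rec_m[[s]][act, 1] <<- rec_m[[s]][act, 1] - moved
        rec_m[[s]][act, 2] <<- rec_m[[s]][act, 2] + moved
        for (p in unique(pw)) {
          tot <- sum(moved[pw == p])
          rec_sum[[s]][p, 1] <<- rec_sum[[s]][p, 1] - tot
          rec_sum[[s]][p, 2] <<- rec_sum[[s]][p, 2] + tot
        }
      }
    }
  }

  ## ---- frame loop ---------------------------------------------------------
  frame_t <- seq(0, t_end, by = record_dt)
  nfr <- length(frame_t)
  pool_u_arr <- array(0, c(nfr, 2, max(P, 1)))
  pool_b_arr <- array(0, c(nfr, 2, max(P, 1)))
  cb_u_arr <- matrix(0, nfr, max(P, 1)); cb_b_arr <- matrix(0, nfr, max(P, 1))
  tf_list <- vector("list", nfr)
  p_img <- 1 - exp(-config$imaging_bleach_rate * record_dt)

  set.seed(derive_seed(seed, 99L))
  all_t <- seq(t0, t_end, by = record_dt)
  eptr <- 1L
  for (fstep in seq_along(all_t)) {
    t <- all_t[fstep]
    while (eptr <= nev && ev[eptr, "t"] <= t + 1e-9) {
      e <- ev[eptr, ]; eptr <- eptr + 1L
      s <- e[["s"]]; i <- e[["i"]]; p <- e[["p"]]; ty <- e[["ty"]]
      if (ty == 1) {             # recruit protein p into nascent train i
        need <- round(copies[p] * size[[s]][i])
        got_u <- 0; got_b <- 0
        av <- avail[[s]][p, ]
        if (sum(av) > 0) {
          k <- min(sum(av), rbinom(1, need, sum(av) / (sum(av) + REUSE_F0)))
          ku <- rhyper(1, av[1], av[2], k)
          avail[[s]][p, ] <- av - c(ku, k - ku)
          got_u <- got_u + ku; got_b <- got_b + (k - ku); need <- need - k
        }
        if (need > 0 && sum(cb[p, ]) > 0) {
          k <- min(need, sum(cb[p, ]))
          ku <- rhyper(1, cb[p, 1], cb[p, 2], k)
          cb[p, ] <- cb[p, ] - c(ku, k - ku)
          got_u <- got_u + ku; got_b <- got_b + (k - ku)
        }
        comp_u[[s]][i, p] <- comp_u[[s]][i, p] + got_u
        comp_b[[s]][i, p] <- comp_b[[s]][i, p] + got_b
        nasc[[s]][p, ] <- nasc[[s]][p, ] + c(got_u, got_b)
        log_row(e[["t"]], 1, s, i, p, got_u, got_b)
      } else if (ty == 2) {      # departure: leaves the pool
        if (P > 0) {
          nasc[[s]] <- nasc[[s]] - cbind(comp_u[[s]][i, ], comp_b[[s]][i, ])
          dep_u[[s]][i, ] <- comp_u[[s]][i, ]
          dep_b[[s]][i, ] <- comp_b[[s]][i, ]
        }
        log_row(e[["t"]], 2, s, i, 0,
                if (P > 0) sum(comp_u[[s]][i, ]) else 0,
                if (P > 0) sum(comp_b[[s]][i, ]) else 0)
      } else if (ty == 3) {      # tip arrival: release tip_release_prob copies
        if (P > 0) for (pp in which(carried[[s]][i, ])) {
          tr <- pr$tip_release_prob[pp]
          if (tr > 0) {
            mu <- rbinom(1, comp_u[[s]][i, pp], tr)
            mb <- rbinom(1, comp_b[[s]][i, pp], tr)
            comp_u[[s]][i, pp] <- comp_u[[s]][i, pp] - mu
            comp_b[[s]][i, pp] <- comp_b[[s]][i, pp] - mb
            cb[pp, ] <- cb[pp, ] + c(mu, mb)
            log_row(e[["t"]], 3, s, i, pp, mu, mb)
          }
        }
      } else if (ty == 4) {      # base return: route copies
        if (P > 0) for (pp in which(carried[[s]][i, ])) {
          u <- comp_u[[s]][i, pp]; b <- comp_b[[s]][i, pp]
          ret_u[[s]][i, pp] <- u; ret_b[[s]][i, pp] <- b
          comp_u[[s]][i, pp] <- 0; comp_b[[s]][i, pp] <- 0
          if (pr$recycle_enabled[pp]) {
            # copies spread over independently timed residence sub-batches
            su <- if (u > 0) rmultinom(1, u, rep(1, m_sub))[, 1] else rep(0, m_sub)
            sb <- if (b > 0) rmultinom(1, b, rep(1, m_sub))[, 1] else rep(0, m_sub)
            rid <- ((pp - 1L) * nd[s] + (i - 1L)) * m_sub + seq_len(m_sub)
            rec_m[[s]][rid, 1] <- rec_m[[s]][rid, 1] + su
            rec_m[[s]][rid, 2] <- rec_m[[s]][rid, 2] + sb
            rec_active[[s]][rid] <- TRUE
            rec_sum[[s]][pp, ] <- rec_sum[[s]][pp, ] + c(u, b)
          } else {
            cb[pp, ] <- cb[pp, ] + c(u, b)
          }
          log_row(e[["t"]], 4, s, i, pp, u, b)
        }
      } else if (ty == 5) {      # recycling residence over: reuse or release
        rid <- ((p - 1L) * nd[s] + (i - 1L)) * m_sub + e[["x"]]
        if (rec_active[[s]][rid]) {
          u <- rec_m[[s]][rid, 1]; b <- rec_m[[s]][rid, 2]
          ru <- rbinom(1, u, pr$reuse_prob[p]); rb <- rbinom(1, b, pr$reuse_prob[p])
          avail[[s]][p, ] <- avail[[s]][p, ] + c(ru, rb)
          cb[p, ] <- cb[p, ] + c(u - ru, b - rb)
          rec_sum[[s]][p, ] <- rec_sum[[s]][p, ] - c(u, b)
          rec_m[[s]][rid, ] <- 0
          rec_active[[s]][rid] <- FALSE
          log_row(e[["t"]], 5, s, i, p, ru, rb)
        }
      } else if (ty == 6) {      # protocol pulse
        r <- i
        evt <- protocol[r, ]
        eff <- evt$efficiency
        pmask <- channel_mask(r)
        if (evt$region %in% c("pool-exp", "pool-ctrl")) {
          ss <- if (evt$region == "pool-exp") 1L else 2L
          bleach_pool_compartments(ss, eff, pmask)
          if (P > 0) {
            nrows <- which(dep[[ss]] > e[["t"]] + 1e-9)
            nrows <- nrows[apply(rec_t[[ss]][nrows, , drop = FALSE], 1,
                                 function(z) any(z <= e[["t"]] + 1e-9))]
            if (length(nrows) > 0) bleach_comp(ss, nrows, which(pmask), eff,
                                               e[["t"]], nascent_adjust = TRUE)
          }
        } else if (evt$region %in% c("whole-flagellum-exp", "axoneme-prebleach")) {
          if (P > 0) {
            frows <- which(dep[[1]] <= e[["t"]] + 1e-9 & ret[[1]] > e[["t"]] + 1e-9)
            if (length(frows) > 0) bleach_comp(1L, frows, which(pmask), eff,
                                               e[["t"]], nascent_adjust = FALSE)
          }
        }
        log_row(e[["t"]], 6, 0, r, 0, 0, 0)
      } else if (ty == 7) {      # FLIP laser-on hit on a train in the window
        r <- e[["x"]]
        pmask <- channel_mask(r)
        if (P > 0) bleach_comp(1L, i, which(pmask), protocol$efficiency[r],
                               e[["t"]], nascent_adjust = FALSE)
        log_row(e[["t"]], 7, 1, i, 0, 0, 0)
      }
    }

    # continuous imaging bleach on every copy in the evanescent field
    if (p_img > 0 && P > 0) {
      for (s in 1:2) {
        bleach_pool_compartments(s, p_img, rep(TRUE, P))
        idx <- which(comp_u[[s]] > 0)
        if (length(idx) > 0) {
          moved <- rbinom(length(idx), comp_u[[s]][idx], p_img)
          nz <- which(moved > 0)
          for (k in nz) {
            ii <- (idx[k] - 1L) %% nd[s] + 1L
            pp <- (idx[k] - 1L) %/% nd[s] + 1L
            comp_u[[s]][ii, pp] <- comp_u[[s]][ii, pp] - moved[k]
            comp_b[[s]][ii, pp] <- comp_b[[s]][ii, pp] + moved[k]
            if (dep[[s]][ii] > t + 1e-9) {  # still nascent -> pool totals move
              nasc[[s]][pp, 1] <- nasc[[s]][pp, 1] - moved[k]
              nasc[[s]][pp, 2] <- nasc[[s]][pp, 2] + moved[k]
            }
          }
        }
      }
    }

    # snapshot
    if (t >= -1e-9) {
      fi <- round(t / record_dt) + 1L
      if (fi >= 1 && fi <= nfr) {
        if (P > 0) {
          for (s in 1:2) {
            pool_u_arr[fi, s, ] <- nasc[[s]][, 1] + stand[[s]][, 1] +
              avail[[s]][, 1] + rec_sum[[s]][, 1]
            pool_b_arr[fi, s, ] <- nasc[[s]][, 2] + stand[[s]][, 2] +
              avail[[s]][, 2] + rec_sum[[s]][, 2]
          }
          cb_u_arr[fi, ] <- cb[, 1]; cb_b_arr[fi, ] <- cb[, 2]
        }
        rows <- list()
        for (s in 1:2) {
          inflight <- which(dep[[s]] <= t + 1e-9 & ret[[s]] > t + 1e-9)
          if (length(inflight) > 0 && P > 0) {
            tt <- tip[[s]][inflight]
            pos <- ifelse(t < tt, va * (t - dep[[s]][inflight]),
                          ifelse(t < tt + turn, L,
                                 L - vr * (t - tt - turn)))
            pos <- pmin(pmax(pos, 0), L)
            m <- length(inflight)
            rows[[s]] <- cbind(fi, s, rep(inflight, P), rep(pos, P),
                               rep(seq_len(P), each = m),
                               as.vector(comp_u[[s]][inflight, , drop = FALSE]),
                               as.vector(comp_b[[s]][inflight, , drop = FALSE]))
          }
        }
        rows <- rows[!vapply(rows, is.null, logical(1))]
        if (length(rows) > 0) tf_list[[fi]] <- do.call(rbind, rows)
      }
    }
  }

  ## ---- assemble outputs ---------------------------------------------------
  struct_lab <- c("exp", "ctrl")
  pool <- NULL; cell_body <- NULL
  if (P > 0) {
    pool <- tidyr::expand_grid(time = frame_t, structure = struct_lab,
                               protein = pr$name)
    si <- match(pool$structure, struct_lab)
    pi <- match(pool$protein, pr$name)
    fi <- match(pool$time, frame_t)
    pool$unbleached <- pool_u_arr[cbind(fi, si, pi)]
    pool$bleached <- pool_b_arr[cbind(fi, si, pi)]
    cell_body <- tidyr::expand_grid(time = frame_t, protein = pr$name)
    fi <- match(cell_body$time, frame_t); pi <- match(cell_body$protein, pr$name)
    cell_body$unbleached <- cb_u_arr[cbind(fi, pi)]
    cell_body$bleached <- cb_b_arr[cbind(fi, pi)]
  } else {
    pool <- tibble(time = numeric(0), structure = character(0),
                   protein = character(0), unbleached = numeric(0),
                   bleached = numeric(0))
    cell_body <- tibble(time = numeric(0), protein = character(0),
                        unbleached = numeric(0), bleached = numeric(0))
  }

  trains <- bind_rows(lapply(1:2, function(s) tibble(
    structure = struct_lab[s], train = seq_len(nd[s]),
    size = size[[s]], departure = dep[[s]], tip_arrival = tip[[s]],
    base_return = ifelse(ret[[s]] <= t_end, ret[[s]], NA_real_)
  )))

  train_proteins <- NULL
  if (P > 0) {
    train_proteins <- bind_rows(lapply(1:2, function(s) {
      g <- tidyr::expand_grid(train = seq_len(nd[s]), protein = pr$name)
      idx <- cbind(g$train, match(g$protein, pr$name))
      carried_v <- carried[[s]][idx]
      tibble(structure = struct_lab[s], train = g$train, protein = g$protein,
             carried = carried_v,
             recruit_time = ifelse(carried_v, rec_t[[s]][idx], NA_real_),
             u_depart = dep_u[[s]][idx],
             b_depart = dep_b[[s]][idx],
             u_return = ret_u[[s]][idx],
             b_return = ret_b[[s]][idx])
    }))
  } else {
    train_proteins <- tibble(structure = character(0), train = integer(0),
                             protein = character(0))
  }

  trains_frames <- tf_list[!vapply(tf_list, is.null, logical(1))]
  if (length(trains_frames) > 0) {
    m <- do.call(rbind, trains_frames)
    trains_frames <- tibble(
      time = frame_t[m[, 1]], structure = struct_lab[m[, 2]],
      train = as.integer(m[, 3]), position = m[, 4],
      protein = pr$name[m[, 5]], unbleached = m[, 6], bleached = m[, 7])
  } else {
    trains_frames <- tibble(time = numeric(0), structure = character(0),
                            train = integer(0), position = numeric(0),
                            protein = character(0), unbleached = numeric(0),
                            bleached = numeric(0))
  }

  events <- if (nlog > 0) {
    e <- as_tibble(as.data.frame(elog[seq_len(nlog), , drop = FALSE]))
    e$type <- EVENT_TYPES[e$type]
    e$structure <- c("", struct_lab)[e$structure + 1]
    e$protein <- ifelse(e$protein > 0 & P > 0, pr$name[pmax(e$protein, 1)], NA)
    e
  } else {
    tibble(time = numeric(0), type = character(0), structure = character(0),
           train = numeric(0), protein = character(0),
           n_unbleached = numeric(0), n_bleached = numeric(0))
  }

  structure(list(
    config = config, protocol = protocol, seed = seed, record_dt = record_dt,
    time = frame_t, pool = pool, cell_body = cell_body, trains = trains,
    train_proteins = train_proteins, trains_frames = trains_frames,
    events = events, laser_on = laser_on
  ), class = "ift_sim")
}

#' @export
print.ift_sim <- function(x, ...) {
  cat(sprintf("<ift_sim> %g s, %d protein(s), %d trains, %d bleach event(s)\n",
              max(x$time), nrow(x$config$proteins), nrow(x$trains),
              nrow(x$protocol)))
  invisible(x)
}

#' Pool content of a protein at a time point
#'
#' Sums the nascent-train, recycling, recycled-available and standing
#' compartments of one basal-body pool.
#'
#' @param sim An `ift_sim`.
#' @param protein Protein name.
#' @param t Time (s) within the recording.
#' @param structure `"exp"` or `"ctrl"`.
#' @return A tibble with `unbleached` and `bleached` counts.
#' @export
pool_content <- function(sim, protein, t, structure = "exp") {
  if (!protein %in% sim$config$proteins$name) {
    abort(sprintf("Unknown protein '%s'", protein),
          class = "iftpool_registry_error")
  }
  if (t < min(sim$time) - 1e-9 || t > max(sim$time) + 1e-9) {
    abort("t outside the recorded trace", class = "iftpool_input_error")
  }
  fi <- which.min(abs(sim$time - t))
  row <- dplyr::filter(sim$pool, .data$protein == !!protein,
                       .data$structure == !!structure,
                       .data$time == sim$time[fi])
  tibble(unbleached = row$unbleached, bleached = row$bleached)
}
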