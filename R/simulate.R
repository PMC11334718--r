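#' Kinetic parameters for the synthetic permeation generator
#'
#' The generator emulates the phenomenology of ion conduction through the
#' four-site biomimetic channel at low field: K+ hops stepwise
#' bulk -> S4 -> S3 -> S2 -> S1 -> bulk with exponential dwell times and a
#' knock-on hand-off to the resident ion; each K+ entry is mode 1 (two
#' intervening water tracers between the incoming and the resident
#' cation) with probability `mode1_prob`, else mode 2 (one intervening
#' water, entry swap with the S4 water); Na+ entries jump to S3 off-axis
#' and are flushed by an incoming K+.  Water is represented by tracer
#' oxygens, which is all the mode classification needs.
#'
#' Dwell times are exponential (the underlying microscopic rates are not
#' observable at this level, so this is an explicit modelling assumption)
#' with a floor of two frame intervals inside the channel so that every
#' configuration is resolvable at the output cadence.  If `ref_pmf` is
#' given, mean dwells are scaled by exp(dU/kT) of the forward barrier so
#' that landscape effects are emulated qualitatively.
#'
#' @param site_z Binding-site planes, increasing z (S4 -> S1), Angstrom.
#' @param hop_rate Base hop rate, 1/ns.
#' @param mode1_prob Probability that a K+ entry is mode 1.
#' @param na_fraction Probability that a cycle carries a Na+ event.
#' @param na_radial_offset,k_radial_offset Off-axis displacement of Na+ /
#'   K+ paths, Angstrom (Na+ travels near the wall, K+ near the axis).
#' @param n_events Number of completed permeation events to generate.
#' @param frame_dt Frame interval, ns.
#' @param seed Integer RNG seed.
#' @param ref_pmf Optional [reference_pmf()] for dwell-time scaling.
#' @param temperature Temperature (K) for the dwell scaling.
#' @param jitter_xy,jitter_z Per-frame Gaussian positional jitter,
#'   Angstrom.
#' @return A `kinetic_params` list.
#' @export
kinetic_params <- function(site_z = c(-4.05, -1.35, 1.35, 4.05),
                           hop_rate = 2, mode1_prob = 0.76,
                           na_fraction = 0.02, na_radial_offset = 2.0,
                           k_radial_offset = 0.3, n_events = 100,
                           frame_dt = 0.1, seed = 1, ref_pmf = NULL,
                           temperature = 300,
                           jitter_xy = 0.1, jitter_z = 0.08) {
  stopifnot(length(site_z) == 4, all(diff(site_z) > 0), hop_rate > 0,
            mode1_prob >= 0, mode1_prob <= 1,
            na_fraction >= 0, na_fraction <= 1,
            n_events >= 0, frame_dt > 0)
  structure(
    list(site_z = site_z, hop_rate = hop_rate, mode1_prob = mode1_prob,
         na_fraction = na_fraction, na_radial_offset = na_radial_offset,
         k_radial_offset = k_radial_offset, n_events = as.integer(n_events),
         frame_dt = frame_dt, seed = as.integer(seed), ref_pmf = ref_pmf,
         temperature = temperature,
         jitter_xy = jitter_xy, jitter_z = jitter_z),
    class = "kinetic_params"
  )
}

#' Packaged mixture configuration for the KCl/NaCl system at 0.2 V/nm
#'
#' The low-field study condition: mode-1 entries dominate at 76% of K+
#' events, Na+ permeation is rare, Na+ travels about 2 Angstrom off-axis
#' while K+ stays near the centre.
#'
#' @param n_events Number of events.
#' @param seed RNG seed.
#' @return A [kinetic_params()].
#' @export
kcl_mix_0p2V <- function(n_events = 2000, seed = 1) {
  kinetic_params(mode1_prob = 0.76, na_fraction = 0.02,
                 na_radial_offset = 2.0, k_radial_offset = 0.3,
                 n_events = n_events, seed = seed)
}

#' Generate a synthetic permeation trajectory with ground truth
#'
#' Runs the knock-on conveyor: a resident cation occupies S2; each cycle
#' an incoming ion enters from the entrance-side reservoir, displaces the
#' resident upward (knock-on) and becomes the new resident, while the old
#' resident completes its traversal into the exit-side reservoir.  An
#' event is logged when its ion completes the full crossing, so the
#' emitted trajectory and the log are mutually consistent by
#' construction.
#'
#' @param params A [kinetic_params()].
#' @return List with elements `trajectory` (an `md_traj`), `events` (the
#'   ground-truth log: `event`, `ion_id`, `species`, `true_mode`,
#'   `entry_time`, `exit_time`, `entry_frame`, `exit_frame`,
#'   `site_path`), `geometry` (the matching [channel_geometry()]) and
#'   `params`.
#' @export
generate_permeation_trajectory <- function(params = kinetic_params()) {
  stopifnot(inherits(params, "kinetic_params"))
  set.seed(params$seed)
  dt <- params$frame_dt
  s <- params$site_z                      # s[1]=S4 ... s[4]=S1
  geom <- channel_geometry(site_z = s)
  gap <- mean(diff(s))
  inlet <- geom$entrance_z - 1.3
  outlet <- geom$exit_z + 0.8
  res_bot <- -11; res_top <- 11; w_park <- 10.5
  kT <- kT_kcal(params$temperature)
  site_name <- c("S4", "S3", "S2", "S1")

  U <- if (!is.null(params$ref_pmf)) params$ref_pmf$fun else function(z) 0 * z
  dwell <- function(floor_frames, z_from = NULL, z_to = NULL, speedup = 1) {
    mean_t <- 1 / (params$hop_rate * speedup)
    if (!is.null(z_from)) {
      mean_t <- mean_t * exp(max(0, U(z_to) - U(z_from)) / kT)
    }
    floor_frames * dt + stats::rexp(1, 1 / mean_t)
  }

  # particle cast
  kpool <- paste0("K", 1:4)
  ids <- c(kpool, "Na1", "W1", "W2", paste0("B", 1:4))
  tag <- c(rep("ion_K", 4), "ion_Na", rep("water_O", 6))
  names(tag) <- ids
  home <- list()                          # reservoir xy slot per particle
  for (i in seq_along(ids)) {
    ang <- 2 * pi * (i - 1) / length(ids)
    home[[ids[i]]] <- 5 * c(cos(ang), sin(ang))
  }
  koff <- params$k_radial_offset
  naoff <- params$na_radial_offset

  kf <- new.env(parent = emptyenv())     # keyframes: list of c(t,x,y,z)
  for (id in ids) assign(id, list(), envir = kf)
  mv <- function(id, t, x, y, z) {
    cur <- get(id, envir = kf)
    cur[[length(cur) + 1]] <- c(t, x, y, z)
    assign(id, cur, envir = kf)
  }

  # initial placement
  resident <- kpool[1]
  mv(resident, 0, koff, 0, s[3])
  queue <- kpool[-1]
  for (id in queue) mv(id, 0, home[[id]][1], home[[id]][2], res_bot)
  mv("Na1", 0, home[["Na1"]][1], home[["Na1"]][2], res_bot)
  mv("W1", 0, home[["W1"]][1], home[["W1"]][2], w_park)
  mv("W2", 0, home[["W2"]][1], home[["W2"]][2], w_park)
  mv("B1", 0, 3, 0, -9.5); mv("B2", 0, 0, 3, -9.5)
  mv("B3", 0, -3, 0, 9.5); mv("B4", 0, 0, -3, 9.5)

  res_entry <- NA_real_; res_mode <- NA_character_; res_path <- NA_character_
  events <- list()
  completed <- 0L
  t <- 4 * dt

  log_event <- function(id, species, mode, entry, exit, path) {
    events[[length(events) + 1]] <<- data.frame(
      ion_id = id, species = species, true_mode = mode,
      entry_time = entry, exit_time = exit, site_path = path,
      stringsAsFactors = FALSE
    )
    completed <<- completed + 1L
  }

  while (completed < params$n_events) {
    na_cycle <- stats::runif(1) < params$na_fraction &&
      (params$n_events - completed) >= 2
    if (!na_cycle) {
      e <- queue[1]; queue <- queue[-1]
      mode <- if (stats::runif(1) < params$mode1_prob) "mode1" else "mode2"
      mv(e, t, home[[e]][1], home[[e]][2], res_bot)
      t1 <- t + dwell(4)
      mv(e, t1, koff, 0, inlet)
      t2 <- t1 + dwell(2, inlet, s[1])
      # committed entry; mode decides the water spacing and the knock
      mv(e, t2, koff, 0, s[1])
      if (mode == "mode1") {
        mv(resident, t2, koff, 0, s[4])            # knock-on S2 -> S1
        mv("W1", t2, 0, 0, s[2]); mv("W2", t2, 0, 0, s[3])
      } else {
        mv("W1", t2, 0, 0, s[2])                   # entry swap, one water
      }
      t3 <- t2 + dwell(2, s[1], s[2])
      mv(e, t3, koff, 0, s[2])
      if (mode == "mode1") {
        mv("W1", t3, 0, 0, s[3]); mv("W2", t3, 0, 0, s[4])
        mv(resident, t3, koff, 0, outlet)
      } else {
        mv("W1", t3, 0, 0, s[3]); mv(resident, t3, koff, 0, s[4])
      }
      t4 <- t3 + dwell(2, s[2], s[3])
      mv(e, t4, koff, 0, s[3])
      if (mode == "mode1") {
        mv(resident, t4, home[[resident]][1], home[[resident]][2], res_top)
        mv("W1", t4, home[["W1"]][1], home[["W1"]][2], w_park)
        mv("W2", t4, home[["W2"]][1], home[["W2"]][2], w_park)
        t_exit <- t4
        t_last <- t4
      } else {
        mv(resident, t4, koff, 0, outlet)
        mv("W1", t4, 0, 0, s[4])
        t5 <- t4 + dwell(2)
        mv(resident, t5, home[[resident]][1], home[[resident]][2], res_top)
        mv("W1", t5, home[["W1"]][1], home[["W1"]][2], w_park)
        t_exit <- t5
        t_last <- t5
      }
      if (!is.na(res_entry)) {
        log_event(resident, "K", res_mode, res_entry, t_exit, res_path)
      }
      queue <- c(queue, resident)
      resident <- e; res_entry <- t2; res_mode <- mode
      res_path <- paste(site_name, collapse = ",")
      t <- t_last + dwell(2)
    } else {
      a <- "Na1"
      k <- queue[1]; queue <- queue[-1]
      mv(a, t, home[[a]][1], home[[a]][2], res_bot)
      mv(k, t, home[[k]][1], home[[k]][2], res_bot)
      t1 <- t + dwell(4)
      mv(a, t1, naoff, 0, inlet)
      t2 <- t1 + dwell(2, inlet, s[2])
      mv(a, t2, naoff, 0, s[2])                    # Na jumps to S3
      mv(k, t2, koff, 0, inlet)
      t3 <- t2 + dwell(2)
      # incoming K reaches S4: chain shove, Na is knocked upward
      mv(k, t3, koff, 0, s[1])
      mv(a, t3, naoff, 0, s[3])
      mv(resident, t3, koff, 0, s[4])
      t4 <- t3 + dwell(2, speedup = 5)
      mv(resident, t4, koff, 0, outlet)
      mv(a, t4, naoff, 0, s[4])
      mv(k, t4, koff, 0, s[2])
      t5 <- t4 + dwell(2, speedup = 5)
      mv(resident, t5, home[[resident]][1], home[[resident]][2], res_top)
      mv(a, t5, naoff, 0, outlet)
      mv(k, t5, koff, 0, s[3])
      t6 <- t5 + dwell(2, speedup = 5)
      mv(a, t6, home[[a]][1], home[[a]][2], res_top)
      if (!is.na(res_entry)) {
        log_event(resident, "K", res_mode, res_entry, t5, res_path)
      }
      log_event(a, "Na", NA_character_, t2, t6, "S3,S2,S1")
      queue <- c(queue, resident)
      resident <- k; res_entry <- t3; res_mode <- NA_character_
      res_path <- paste(site_name, collapse = ",")
      t <- t6 + dwell(2)
    }
  }

  t_end <- t + 4 * dt
  n_frames <- floor(t_end / dt) + 1
  tf <- (seq_len(n_frames) - 1) * dt

  rows <- lapply(ids, function(id) {
    m <- do.call(rbind, get(id, envir = kf))
    idx <- findInterval(tf + 1e-9, m[, 1])
    idx[idx < 1] <- 1
    data.table::data.table(
      frame = seq_len(n_frames) - 1L, id = id,
      element = TAG_ELEMENT[[tag[[id]]]], tag = tag[[id]],
      x = m[idx, 2], y = m[idx, 3], z = m[idx, 4]
    )
  })
  atoms <- data.table::rbindlist(rows)
  n <- nrow(atoms)
  atoms[, `:=`(x = x + stats::rnorm(n, 0, params$jitter_xy),
               y = y + stats::rnorm(n, 0, params$jitter_xy),
               z = z + stats::rnorm(n, 0, params$jitter_z))]
  traj <- new_trajectory(atoms, dt = dt, box = c(51, 51, 51))

  ev <- if (length(events) > 0) {
    d <- do.call(rbind, events)
    d <- d[order(d$exit_time), , drop = FALSE]
    d$event <- seq_len(nrow(d))
    d$entry_frame <- as.integer(ceiling(d$entry_time / dt - 1e-9))
    d$exit_frame <- as.integer(ceiling(d$exit_time / dt - 1e-9))
    rownames(d) <- NULL
    d[, c("event", "ion_id", "species", "true_mode", "entry_time",
          "exit_time", "entry_frame", "exit_frame", "site_path")]
  } else {
    data.frame(event = integer(0), ion_id = character(0),
               species = character(0), true_mode = character(0),
               entry_time = numeric(0), exit_time = numeric(0),
               entry_frame = integer(0), exit_frame = integer(0),
               site_path = character(0), stringsAsFactors = FALSE)
  }
  list(trajectory = traj, events = ev, geometry = geom, params = params)
}
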