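#' Detect completed ion traversal events
#'
#' An event is a maximal path of a cation from below
#' `entrance_z - buffer` to above `exit_z + buffer` in the +z direction.
#' The ion must return below the entrance threshold before a new event
#' can begin, so each traversal is counted exactly once; partial
#' excursions are discarded.
#'
#' @param traj An `md_traj` whose particles carry species tags.
#' @param geom A [channel_geometry()].
#' @return A data.frame of event records: `event`, `ion_id`, `species`,
#'   `entry_frame`, `exit_frame`, `entry_time`, `exit_time`,
#'   `site_path`, `radial_mean`, `mode` (unset, see [classify_modes()]).
#' @export
detect_events <- function(traj, geom) {
  stopifnot(inherits(traj, "md_traj"), inherits(geom, "channel_geometry"))
  A <- traj$atoms[tag %in% CATION_TAGS]
  if (nrow(A) == 0) stop("trajectory carries no species-tagged cations")
  lo <- geom$entrance_z - geom$buffer
  hi <- geom$exit_z + geom$buffer
  data.table::setorder(A, id, frame)
  recs <- list()
  for (ion in unique(A$id)) {
    d <- A[id == ion]
    z <- d$z
    below <- which(z < lo)
    above <- z > hi
    crossings <- which(above & !c(FALSE, above[-length(above)]))
    last_exit <- 0L
    for (cr in crossings) {
      lb <- below[below < cr]
      lb <- if (length(lb)) lb[length(lb)] else 0L
      if (lb <= last_exit) next          # not re-armed since last event
      seg <- (lb + 1):cr
      entry <- seg[which(z[seg] > geom$entrance_z)[1]]
      inside <- seg[z[seg] > geom$entrance_z & z[seg] < geom$exit_z]
      path <- site_path_string(z[inside], geom)
      recs[[length(recs) + 1]] <- data.frame(
        ion_id = ion,
        species = if (d$tag[1] == "ion_K") "K" else "Na",
        entry_frame = d$frame[entry], exit_frame = d$frame[cr],
        entry_time = d$time[entry], exit_time = d$time[cr],
        site_path = path,
        radial_mean = if (length(inside)) {
          mean(sqrt(d$x[inside]^2 + d$y[inside]^2))
        } else NA_real_,
        stringsAsFactors = FALSE
      )
      last_exit <- cr
    }
  }
  if (length(recs) == 0) {
    return(data.frame(event = integer(0), ion_id = character(0),
                      species = character(0), entry_frame = integer(0),
                      exit_frame = integer(0), entry_time = numeric(0),
                      exit_time = numeric(0), site_path = character(0),
                      radial_mean = numeric(0), mode = character(0),
                      stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, recs)
  ev <- ev[order(ev$exit_time), , drop = FALSE]
  ev$event <- seq_len(nrow(ev))
  ev$mode <- NA_character_
  rownames(ev) <- NULL
  ev[, c("event", "ion_id", "species", "entry_frame", "exit_frame",
         "entry_time", "exit_time", "site_path", "radial_mean", "mode")]
}

site_path_string <- function(z, geom) {
  if (length(z) == 0) return("")
  lab <- site_labels(z, geom)
  lab <- lab[lab != "inter-site"]
  if (length(lab) == 0) return("")
  paste(rle(lab)$values, collapse = ",")
}

site_labels <- function(z, geom) {
  sz <- geom$site_z
  if (length(sz) == 1) {
    nearest <- rep(1L, length(z))
  } else {
    mids <- sz[-length(sz)] + diff(sz) / 2
    nearest <- findInterval(z, mids) + 1L
  }
  ifelse(abs(z - sz[nearest]) <= geom$site_tolerance,
         names(sz)[nearest], "inter-site")
}

#' Per-frame binding-site occupancy
#'
#' Every in-channel particle (cations and water oxygens by default) is
#' assigned to the nearest binding-site plane if within
#' `site_tolerance`, else labelled `"inter-site"`.
#'
#' @param traj An `md_traj`.
#' @param geom A [channel_geometry()].
#' @param tags Particle tags to include.
#' @return A data.table: `frame`, `time`, `id`, `tag`, `z`, `site`.
#' @export
assign_sites <- function(traj, geom,
                         tags = c(CATION_TAGS, "water_O")) {
  occ <- traj$atoms[tag %in% tags & z > geom$entrance_z &
                      z < geom$exit_z,
                    .(frame, time, id, tag, z)]
  occ[, site := site_labels(z, geom)]
  data.table::setorder(occ, frame, z)
  occ[]
}

#' Classify permeation modes by intervening-water count
#'
#' For each K+ event, over the frames where the event ion is inside the
#' channel together with another cation above it (nearest-above if there
#' are several), the number of water tracers strictly between the two
#' ions is counted.  The event label is the modal count: 2 is mode 1
#' (knock-on with two spacing waters), 1 is mode 2 (single spacing water
#' after the entry swap), anything else is unclassified.  Mode fractions
#' are computed over classified events.
#'
#' @param events Event table from [detect_events()] (or a ground-truth
#'   log with `event`, `ion_id`, `species`, `entry_frame`, `exit_frame`).
#' @param traj The `md_traj` the events came from.
#' @param geom A [channel_geometry()].
#' @return List with `events` (the table with `mode` filled in),
#'   `fractions` (named vector over classified events), `n_classified`.
#' @export
classify_modes <- function(events, traj, geom) {
  if (!any(traj$atoms$tag == "water_O")) {
    stop("trajectory contains no water tracers")
  }
  ev <- as.data.frame(events)
  ev$mode <- NA_character_
  kev <- which(ev$species == "K")
  if (length(kev) > 0) {
    IC <- traj$atoms[tag %in% CATION_TAGS & z > geom$entrance_z &
                       z < geom$exit_z, .(frame, id, z)]
    data.table::setorder(IC, frame, z)
    IC[, z_above := data.table::shift(z, type = "lead"), by = frame]
    IC <- IC[!is.na(z_above)]
    W <- traj$atoms[tag == "water_O" & z > geom$entrance_z &
                      z < geom$exit_z, .(frame, zw = z)]
    if (nrow(IC) > 0) {
      cnt <- W[IC, on = .(frame, zw > z, zw < z_above),
               .N, by = .EACHI]
      IC[, nwat := cnt$N]
      EV <- data.table::data.table(
        event = ev$event[kev], ion = ev$ion_id[kev],
        f0 = ev$entry_frame[kev], f1 = ev$exit_frame[kev]
      )
      hits <- IC[EV, on = .(id == ion, frame >= f0, frame <= f1),
                 .(event = i.event, nwat = x.nwat), nomatch = NULL]
      if (nrow(hits) > 0) {
        modal <- hits[, .(nmod = {
          tb <- table(nwat)
          as.integer(names(tb)[which.max(tb)])
        }), by = event]
        lab <- ifelse(modal$nmod == 2, "mode1",
                      ifelse(modal$nmod == 1, "mode2", NA_character_))
        ev$mode[match(modal$event, ev$event)] <- lab
      }
    }
  }
  classified <- ev$mode[!is.na(ev$mode)]
  fr <- if (length(classified) > 0) {
    c(mode1 = mean(classified == "mode1"),
      mode2 = mean(classified == "mode2"))
  } else c(mode1 = NA_real_, mode2 = NA_real_)
  list(events = ev, fractions = fr, n_classified = length(classified))
}

#' Annotate knock-on transitions
#'
#' A site transition in which a bound cation advances (moves to a higher
#' site or out of the channel top) is annotated as knock-on if another
#' cation has just arrived within `approach_cutoff` behind it: the gap to
#' the follower is within the cutoff at the transition, and was not
#' within it `window_frames` earlier.
#'
#' @param events Event table (used only to restrict to cation ids).
#' @param traj An `md_traj`.
#' @param geom A [channel_geometry()].
#' @param window_frames Look-back window, frames.
#' @param approach_cutoff Maximum follower gap, Angstrom.
#' @return data.frame of annotations: `ion_id`, `frame`, `from`, `to`,
#'   `knocked_by`.
#' @export
detect_knock_on <- function(events, traj, geom, window_frames = 5,
                            approach_cutoff = 6) {
  A <- traj$atoms[tag %in% CATION_TAGS, .(frame, id, z)]
  data.table::setorder(A, id, frame)
  lo <- geom$entrance_z - geom$buffer
  # per-ion state: site label inside, "below"/"above" outside
  A[, state := ifelse(z <= geom$entrance_z, "below",
                      ifelse(z >= geom$exit_z, "above",
                             site_labels(z, geom)))]
  zmat <- data.table::dcast(A, frame ~ id, value.var = "z")
  frames <- zmat$frame
  zm <- as.matrix(zmat[, -1])
  rownames(zm) <- NULL
  ions <- colnames(zm)
  out <- list()
  for (ion in ions) {
    d <- A[id == ion]
    r <- rle(d$state)
    ends <- cumsum(r$lengths)
    starts <- c(1, ends[-length(ends)] + 1)
    for (k in seq_along(r$values)[-1]) {
      from <- r$values[k - 1]; to <- r$values[k]
      if (from %in% c("below", "above", "inter-site")) next
      i_new <- starts[k]; i_old <- ends[k - 1]
      if (d$z[i_new] <= d$z[i_old]) next       # not an advance
      f <- d$frame[i_new]
      z_old <- d$z[i_old]
      fi <- match(f, frames)
      fe <- max(1, fi - window_frames)
      others <- setdiff(ions, ion)
      gap_now <- z_old - zm[fi, others]
      gap_then <- z_old - zm[fe, others]
      ok <- !is.na(gap_now) & gap_now > 0 & gap_now <= approach_cutoff &
        (is.na(gap_then) | gap_then <= 0 | gap_then > approach_cutoff)
      if (any(ok)) {
        cand <- others[ok]
        by <- cand[which.min(gap_now[ok])]
        out[[length(out) + 1]] <- data.frame(
          ion_id = ion, frame = f, from = from, to = to,
          knocked_by = by, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(ion_id = character(0), frame = integer(0),
                      from = character(0), to = character(0),
                      knocked_by = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Cumulative ion flux series
#'
#' Step function per species, incremented at each event's exit time.
#'
#' @param events Event table.
#' @param total_time Total trajectory time, ns.
#' @param field_strength Optional field metadata, V/nm.
#' @return A `flux_series` data.frame with columns `time`, `n_K`, `n_Na`.
#' @export
cumulative_flux <- function(events, total_time, field_strength = NA_real_) {
  stopifnot(total_time > 0)
  tt <- sort(unique(c(0, events$exit_time, total_time)))
  tt <- tt[tt <= total_time]
  out <- data.frame(
    time = tt,
    n_K = vapply(tt, function(t) {
      sum(events$species == "K" & events$exit_time <= t)
    }, numeric(1)),
    n_Na = vapply(tt, function(t) {
      sum(events$species == "Na" & events$exit_time <= t)
    }, numeric(1))
  )
  attr(out, "total_time") <- total_time
  attr(out, "field_strength") <- field_strength
  class(out) <- c("flux_series", "data.frame")
  out
}

#' Permeation rate from a cumulative flux series
#'
#' The rate is the least-squares slope of the cumulative count versus
#' time (the step function is resampled on a uniform grid first), in
#' ions/s; the simple count/duration estimate is reported alongside.
#'
#' @param series A [cumulative_flux()] result.
#' @param species `"K"` or `"Na"`.
#' @param n_grid Uniform resampling points for the regression.
#' @return List: `rate_per_s` (regression), `count_rate_per_s`, `n`
#'   (final count), `total_time_ns`.
#' @export
permeation_rate <- function(series, species = c("K", "Na"),
                            n_grid = 400) {
  species <- match.arg(species)
  total_time <- attr(series, "total_time")
  if (is.null(total_time) || total_time <= 0) {
    stop("flux series has zero duration")
  }
  cnt <- series[[paste0("n_", species)]]
  if (max(cnt) == 0) {
    return(list(rate_per_s = 0, count_rate_per_s = 0, n = 0L,
                total_time_ns = total_time))
  }
  sf <- stats::stepfun(series$time[-1], c(cnt[1], cnt[-1]))
  tg <- seq(0, total_time, length.out = n_grid)
  slope <- unname(stats::coef(stats::lm(sf(tg) ~ tg))[2])   # per ns
  list(rate_per_s = slope * 1e9,
       count_rate_per_s = max(cnt) / total_time * 1e9,
       n = as.integer(max(cnt)),
       total_time_ns = total_time)
}

#' K+/Na+ selectivity ratio
#'
#' SR = rate_K / rate_Na.  When no Na+ event was observed the ratio is
#' reported as a lower bound using one pseudo-event over the simulated
#' time (the observed record may simply be too short to contain a Na+
#' crossing).
#'
#' @param rate_k,rate_na Permeation rates, ions/s.
#' @param count_na Observed Na+ event count.
#' @param total_time_ns Total time, ns (required when `count_na` is 0).
#' @return List: `sr`, `qualifier` in
#'   `{"measured", "lower_bound", "undefined"}`.
#' @export
selectivity_ratio <- function(rate_k, rate_na, count_na,
                              total_time_ns = NULL) {
  stopifnot(rate_k >= 0, rate_na >= 0)
  if (rate_k == 0 && rate_na == 0) {
    warning("both rates are zero; selectivity undefined")
    return(list(sr = NA_real_, qualifier = "undefined"))
  }
  if (count_na == 0) {
    if (is.null(total_time_ns)) {
      stop("total_time_ns needed for the zero-count lower bound")
    }
    pseudo <- 1e9 / total_time_ns
    return(list(sr = rate_k / pseudo, qualifier = "lower_bound"))
  }
  list(sr = rate_k / rate_na, qualifier = "measured")
}
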