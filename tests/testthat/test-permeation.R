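geom <- channel_geometry()

test_that("single crossings and partial excursions are counted correctly", {
  up <- path_traj(seq(-11, 11, by = 0.5))
  expect_equal(nrow(detect_events(up, geom)), 1)
  # oscillation across the entrance only, never past the exit
  osc <- path_traj(c(-11, -5, -11, -5, -11))
  expect_equal(nrow(detect_events(osc, geom)), 0)
  # re-crossing rule: two full traversals with a reset in between
  two <- path_traj(c(seq(-11, 11, 1), seq(11, -11, -1), seq(-11, 11, 1)))
  expect_equal(nrow(detect_events(two, geom)), 2)
  # no reset below the entrance threshold -> still one event
  wig <- path_traj(c(-11, -3, 2, -3, 2, 11))
  expect_equal(nrow(detect_events(wig, geom)), 1)
  expect_error(detect_events(path_traj(0, tag = "water_O"), geom),
               "cations")
})

test_that("event detection recovers the generator ground truth", {
  s <- small_sim()
  ev <- detect_events(s$trajectory, s$geometry)
  expect_equal(nrow(ev), nrow(s$events))
  # invariant under frame subsampling by 2 (dwells >> frame_dt)
  ev2 <- detect_events(subsample_trajectory(s$trajectory, 2),
                       s$geometry)
  expect_equal(nrow(ev2), nrow(ev))
  # detected site paths match the scripted ground truth
  key <- function(d) d[order(d$exit_time), "site_path"]
  expect_equal(key(ev), key(s$events))
})

test_that("site occupancy matches the ground truth at dwell midpoints", {
  s <- small_sim()
  occ <- assign_sites(s$trajectory, s$geometry)
  # midway between sites with a tight tolerance -> inter-site
  tightened <- channel_geometry(site_tolerance = 0.5)
  mid <- (tightened$site_z[1] + tightened$site_z[2]) / 2
  lab <- cntkchan:::site_labels(c(tightened$site_z[2], mid), tightened)
  expect_equal(unname(lab), c("S3", "inter-site"))
  # every K event passes through all four sites in order
  ko <- occ[occ$tag == "ion_K" & occ$site != "inter-site", ]
  expect_setequal(unique(ko$site), c("S1", "S2", "S3", "S4"))
})

test_that("flux series and rates follow the counting oracles", {
  ev <- data.frame(species = c("K", "K", "K"), exit_time = c(1, 2, 3))
  fl <- cumulative_flux(ev, 10)
  expect_equal(max(fl$n_K), 3)
  expect_true(all(diff(fl$n_K) >= 0))
  expect_equal(max(cumulative_flux(ev[0, ], 10)$n_K), 0)
  # interleaved species equal a brute-force tally
  s <- small_sim()
  ev <- detect_events(s$trajectory, s$geometry)
  total <- s$trajectory$n_frames * s$trajectory$dt
  fl <- cumulative_flux(ev, total)
  expect_equal(max(fl$n_K), sum(ev$species == "K"))
  expect_equal(max(fl$n_Na), sum(ev$species == "Na"))
  # 10 events uniformly over 1000 ns -> 1e7 ions/s
  ev10 <- data.frame(species = rep("K", 10),
                     exit_time = seq(50, 950, length.out = 10))
  r <- permeation_rate(cumulative_flux(ev10, 1000), "K")
  expect_equal(r$count_rate_per_s, 1e7)
  expect_lt(abs(r$rate_per_s - 1e7) / 1e7, 0.05)
  # zero events -> zero rate
  r0 <- permeation_rate(cumulative_flux(ev10[0, ], 1000), "Na")
  expect_equal(r0$rate_per_s, 0)
})

test_that("selectivity ratio handles bounds and reciprocity", {
  expect_equal(selectivity_ratio(8, 1, 5)$sr, 8)
  a <- selectivity_ratio(6, 2, 4)$sr
  b <- selectivity_ratio(2, 6, 9)$sr
  expect_equal(a * b, 1)
  lb <- selectivity_ratio(1.2e7, 0, 0, total_time_ns = 1000)
  expect_equal(lb$qualifier, "lower_bound")
  expect_equal(lb$sr, 1.2e7 / 1e6)
  expect_warning(out <- selectivity_ratio(0, 0, 0), "undefined")
  expect_true(is.na(out$sr))
})

test_that("scripted water spacings map to the stated modes", {
  # ion I2 crosses while I1 sits above it with persistent waters between
  mk <- function(nw) {
    frames <- 0:12
    rows <- list()
    z2 <- c(-11, -11, -8, -4, -4, -4, -1.3, -1.3, 1.4, 4, 6, 9, 11)
    for (f in frames) {
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, id = "I1", tag = "ion_K",
        z = c(1.4, 1.4, 1.4, 4, 4, 4, 4, 4, 6.3, 7.5, 9, 11, 11)[f + 1]
      )
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, id = "I2", tag = "ion_K", z = z2[f + 1]
      )
      for (w in seq_len(nw)) {
        gap <- (c(1.4, 1.4, 1.4, 4, 4, 4, 4, 4, 6.3, 7.5, 9, 11,
                  11)[f + 1] - z2[f + 1])
        rows[[length(rows) + 1]] <- data.frame(
          frame = f, id = paste0("W", w), tag = "water_O",
          z = z2[f + 1] + gap * w / (nw + 1)
        )
      }
    }
    script_traj(do.call(rbind, rows))
  }
  for (nw in 1:2) {
    tr <- mk(nw)
    ev <- detect_events(tr, geom)
    cm <- classify_modes(ev, tr, geom)
    lab <- cm$events$mode[cm$events$ion_id == "I2"]
    expect_equal(lab, if (nw == 2) "mode1" else "mode2")
  }
})

test_that("classifier recovers generator mixtures within binomial bounds", {
  for (p in c(0.1, 0.5, 0.9)) {
    s <- generate_permeation_trajectory(
      kinetic_params(n_events = 250, mode1_prob = p, na_fraction = 0,
                     seed = round(1000 * p))
    )
    ev <- detect_events(s$trajectory, s$geometry)
    cm <- classify_modes(ev, s$trajectory, s$geometry)
    expect_equal(sum(cm$fractions), 1)
    n <- cm$n_classified
    expect_lt(abs(cm$fractions[["mode1"]] - p),
              3 * sqrt(p * (1 - p) / n) + 1e-9)
    # per-event agreement with the scripted truth
    m <- merge(cm$events[, c("ion_id", "entry_frame", "mode")],
               s$events[, c("ion_id", "entry_frame", "true_mode")],
               by = c("ion_id", "entry_frame"))
    expect_equal(nrow(m), nrow(s$events))
    both <- !is.na(m$mode) & !is.na(m$true_mode)
    expect_true(all(m$mode[both] == m$true_mode[both]))
  }
})

test_that("knock-on annotation fires on arrivals, not lone crossings", {
  # scripted: bound ion advances one frame after the incomer reaches S4
  rows <- rbind(
    data.frame(frame = 0:6, id = "B", tag = "ion_K",
               z = c(1.4, 1.4, 1.4, 4.0, 4.0, 4.0, 4.0)),
    data.frame(frame = 0:6, id = "A", tag = "ion_K",
               z = c(-11, -11, -4.0, -4.0, -4.0, -4.0, -4.0))
  )
  tr <- script_traj(rows)
  ko <- detect_knock_on(data.frame(), tr, geom)
  expect_true(any(ko$ion_id == "B" & ko$knocked_by == "A"))
  # single-ion traversal: nothing to annotate
  solo <- path_traj(seq(-11, 11, 0.5))
  expect_equal(nrow(detect_knock_on(data.frame(), solo, geom)), 0)
  # generator truth: every Na+ exit is a K+ knock-off
  s <- generate_permeation_trajectory(
    kinetic_params(n_events = 60, na_fraction = 0.25, seed = 8)
  )
  nae <- s$events[s$events$species == "Na", ]
  expect_gt(nrow(nae), 0)
  ko <- detect_knock_on(s$events, s$trajectory, s$geometry)
  hit <- vapply(seq_len(nrow(nae)), function(i) {
    any(ko$ion_id == nae$ion_id[i] & ko$frame >= nae$entry_frame[i] &
          ko$frame <= nae$exit_frame[i] & grepl("^K", ko$knocked_by))
  }, logical(1))
  expect_true(all(hit))
})
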