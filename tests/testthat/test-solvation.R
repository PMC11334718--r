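test_that("ideal-gas RDF is flat and converges like 1/sqrt(N)", {
  g <- rdf(snapshot_trajectory(generate_uniform_gas(4000, seed = 2),
                               box = c(40, 40, 40)),
           "water_O", "water_O", r_max = 10, dr = 0.25)
  sel <- g$r >= 3 & g$r <= 10
  expect_lt(max(abs(g$g_total[sel] - 1)), 0.06)
  err <- function(n) {
    gg <- rdf(snapshot_trajectory(generate_uniform_gas(n, seed = 3),
                                  box = c(40, 40, 40)),
              "water_O", "water_O", r_max = 8, dr = 0.4)
    mean(abs(gg$g_total[gg$r >= 3] - 1))
  }
  expect_lt(err(3200), err(800))
})

test_that("RDF localises a single pair and a constructed first minimum", {
  a <- atom_set(c("K", "O"), c(0, 3), c(0, 0), c(0, 0),
                tag = c("ion_K", "water_O"))
  g <- rdf(snapshot_trajectory(a, box = c(30, 30, 30)), "K", "water_O",
           r_max = 6, dr = 0.2)
  hot <- which(g$g_total > 0)
  expect_length(hot, 1)
  expect_lt(abs(g$r[hot] - 3), 0.2)
  # shell at ~2.9 A and background beyond 4.2 A: first minimum in the gap
  set.seed(1)
  frames <- lapply(0:39, function(f) {
    ns <- 7
    u <- matrix(rnorm(3 * ns), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * rnorm(ns, 2.9, 0.12)
    bg <- generate_uniform_gas(250, box = c(24, 24, 24), seed = 100 + f)
    bgm <- as.matrix(bg[, c("x", "y", "z")]) - 12
    bgm <- bgm[sqrt(rowSums(bgm^2)) > 4.2, , drop = FALSE]
    pos <- rbind(u, bgm)
    data.frame(frame = f, id = c("K1", paste0("w", seq_len(nrow(pos)))),
               tag = c("ion_K", rep("water_O", nrow(pos))),
               element = c("K", rep("O", nrow(pos))),
               x = c(0, pos[, 1]), y = c(0, pos[, 2]),
               z = c(0, pos[, 3]))
  })
  tr <- new_trajectory(do.call(rbind, frames), dt = 1, box = c(24, 24, 24))
  g2 <- rdf(tr, "K", "water_O", r_max = 8, dr = 0.2)
  expect_lt(abs(attr(g2, "first_peak") - 2.9), 0.3)
  expect_lt(abs(attr(g2, "first_min") - 3.6), 0.7)
  expect_error(rdf(tr, "K", character(0)), "empty partner")
})

test_that("coordination counts decompose additively by partner group", {
  snap <- generate_solvation_snapshot("Na", n_water = 2, n_carbonyl = 4,
                                      water_dist = 2.9,
                                      carbonyl_dist = 2.4)
  cp <- coordination_profile(snapshot_trajectory(snap, box = c(30, 30, 30)),
                             z_breaks = seq(-1, 1, 1))
  expect_equal(cp$n_total, 6)
  expect_equal(cp$n_carbonyl_O, 4)
  expect_equal(cp$n_water_O, 2)
  # additivity holds on an arbitrary generator trajectory
  s <- small_sim()
  cpt <- coordination_profile(s$trajectory,
                              shell_spec(partner_groups = "water_O"),
                              z_breaks = seq(-8, 8, 2))
  expect_equal(cpt$n_total, cpt$n_water_O)
  # empty neighbourhood counts zero
  lone <- snapshot_trajectory(
    atom_set("K", 0, 0, 0, tag = "ion_K"), box = c(30, 30, 30)
  )
  cp0 <- coordination_profile(lone, z_breaks = seq(-1, 1, 1))
  expect_equal(cp0$n_total, 0)
})

test_that("hydration histograms are normalised point masses and mixtures", {
  snap <- generate_solvation_snapshot("K", n_water = 6)
  h <- hydration_histogram(snapshot_trajectory(snap, box = c(30, 30, 30)))
  expect_equal(h$p[h$n_water == 6], 1)
  # 50/50 mixture of 5- and 6-coordinated frames
  mk <- function(f, nw) {
    d <- as.data.frame(generate_solvation_snapshot("K", n_water = nw,
                                                   seed = f))
    d$frame <- f
    d$id <- paste0(d$tag, seq_len(nrow(d)))
    d
  }
  tr <- new_trajectory(do.call(rbind, c(lapply(1:10, mk, nw = 5),
                                        lapply(11:20, mk, nw = 6))),
                       dt = 1, box = c(30, 30, 30))
  h2 <- hydration_histogram(tr)
  expect_equal(sum(h2$p), 1)
  expect_equal(h2$p[h2$n_water == 5], 0.5)
  expect_equal(h2$p[h2$n_water == 6], 0.5)
})

test_that("orientation histograms detect alignment and isotropy", {
  up <- snapshot_trajectory(
    generate_solvation_snapshot("K", 20, dipole = c(0, 0, 1)),
    box = c(30, 30, 30)
  )
  hu <- orientation_histogram(up)
  expect_equal(hu$p[1], 1)
  dn <- snapshot_trajectory(
    generate_solvation_snapshot("K", 20, dipole = c(0, 0, -1)),
    box = c(30, 30, 30)
  )
  hd <- orientation_histogram(dn)
  expect_equal(hd$p[nrow(hd)], 1)
  # radial dipoles on a uniform sphere are isotropic in theta
  frames <- lapply(1:60, function(f) {
    d <- as.data.frame(generate_solvation_snapshot("K", 30, seed = f))
    d$frame <- f
    d$id <- paste0(d$tag, seq_len(nrow(d)))
    d
  })
  tr <- new_trajectory(do.call(rbind, frames), dt = 1,
                       box = c(30, 30, 30))
  hi <- orientation_histogram(tr, n_bins = 12)
  n <- 60 * 30
  tol <- 3 * sqrt(hi$p_iso * (1 - hi$p_iso) / n)
  expect_true(all(abs(hi$p - hi$p_iso) <= tol + 1e-9))
  # hydrogens are required
  bare <- snapshot_trajectory(
    atom_set(c("K", "O"), c(0, 2.8), 0, 0,
             tag = c("ion_K", "water_O"), mol = c(0L, 1L)),
    box = c(30, 30, 30)
  )
  expect_error(orientation_histogram(bare), "hydrogens")
})

test_that("density profiles are normalised and shaped as constructed", {
  s <- small_sim()
  dk <- density_profile(s$trajectory, "K", "axial")
  # integral equals the mean in-range count per frame
  expect_equal(sum(dk$density * diff(seq(-9.5, 9.5, 0.5))),
               dk$n_mean, tolerance = 0.01)
  # six local maxima: four sites plus inlet and outlet
  v <- dk$density
  i <- 2:(length(v) - 1)
  peaks <- sum(v[i] > v[i - 1] & v[i] >= v[i + 1] & v[i] > 0.05 * max(v))
  expect_equal(peaks, 6)
  # on-axis K+, off-axis Na+
  dkr <- density_profile(s$trajectory, "K", "radial")
  dnr <- density_profile(s$trajectory, "Na", "radial")
  expect_lt(dkr$r[which.max(dkr$density)], 1)
  expect_gt(dnr$r[which.max(dnr$density)], 1.4)
  # ideal gas: flat axial profile
  gas <- snapshot_trajectory(generate_uniform_gas(60000, seed = 6),
                             box = c(40, 40, 40))
  da <- density_profile(gas, "water_O", "axial",
                        breaks = seq(5, 35, 2.5))
  expect_lt(max(abs(da$density / mean(da$density) - 1)), 0.05)
  # radially uniform disc: flat radial density under annulus weights
  set.seed(2)
  nr <- 60000
  rr <- 4 * sqrt(runif(nr))
  th <- runif(nr, 0, 2 * pi)
  disc <- new_trajectory(
    data.frame(frame = 0L, id = paste0("w", 1:nr), tag = "water_O",
               element = "O", x = rr * cos(th), y = rr * sin(th),
               z = runif(nr, -5, 5)),
    dt = 1, box = c(20, 20, 20)
  )
  dr_ <- density_profile(disc, "water_O", "radial",
                         breaks = seq(0, 4, 0.5), zlim = c(-5, 5))
  expect_lt(max(abs(dr_$density / mean(dr_$density) - 1)), 0.05)
  # a single static particle lands in exactly one cell
  one <- snapshot_trajectory(atom_set("K", 0.6, -0.7, 1, tag = "ion_K"),
                             box = c(20, 20, 20))
  dp <- density_profile(one, "K", "planar", zlim = c(-2, 2))
  expect_equal(sum(dp$density > 0), 1)
})
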