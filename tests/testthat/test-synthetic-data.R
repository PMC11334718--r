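test_that("generators are bit-identical under a fixed seed", {
  p <- kinetic_params(n_events = 20, seed = 9)
  s1 <- generate_permeation_trajectory(p)
  s2 <- generate_permeation_trajectory(p)
  expect_identical(s1$trajectory$atoms, s2$trajectory$atoms)
  expect_identical(s1$events, s2$events)
  g1 <- generate_uniform_gas(100, seed = 4)
  g2 <- generate_uniform_gas(100, seed = 4)
  expect_identical(g1, g2)
  w1 <- generate_umbrella_samples(flat_pmf(),
                                  umbrella_protocol(samples_per_window =
                                                      50, seed = 2))
  w2 <- generate_umbrella_samples(flat_pmf(),
                                  umbrella_protocol(samples_per_window =
                                                      50, seed = 2))
  expect_identical(w1, w2)
})

test_that("degenerate mixtures and empty runs behave as stated", {
  s <- generate_permeation_trajectory(
    kinetic_params(n_events = 50, mode1_prob = 1, na_fraction = 0,
                   seed = 5)
  )
  expect_equal(nrow(s$events), 50)
  expect_true(all(s$events$species == "K"))
  expect_true(all(s$events$true_mode == "mode1"))
  s0 <- generate_permeation_trajectory(kinetic_params(n_events = 0))
  expect_equal(nrow(s0$events), 0)
  expect_gt(s0$trajectory$n_frames, 0)
})

test_that("the emitted mode mixture follows the binomial law", {
  n <- 400
  s <- generate_permeation_trajectory(
    kinetic_params(n_events = n, mode1_prob = 0.5, na_fraction = 0,
                   seed = 11)
  )
  frac <- mean(s$events$true_mode == "mode1")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("ground-truth log and trajectory are mutually consistent", {
  s <- small_sim()
  ev <- detect_events(s$trajectory, s$geometry)
  expect_equal(nrow(ev), nrow(s$events))
  expect_equal(table(ev$species), table(s$events$species))
})

test_that("umbrella sampler reproduces the Gaussian closed forms", {
  prot <- umbrella_protocol(samples_per_window = 10000, seed = 3)
  w <- generate_umbrella_samples(flat_pmf(), prot)
  v <- vapply(w, function(x) stats::var(x$samples), numeric(1))
  expect_lt(abs(mean(v) - kT_kcal(300) / 20) / (kT_kcal(300) / 20), 0.1)
  centers <- seq(-10, 10, 0.5)
  mu <- vapply(w, function(x) mean(x$samples), numeric(1))
  expect_lt(max(abs(mu - centers)), 0.05)
  # harmonic landscape: combined effective spring k + kappa
  kappa <- 3
  wh <- generate_umbrella_samples(harmonic_pmf(kappa), prot)
  vh <- vapply(wh[15:27], function(x) stats::var(x$samples), numeric(1))
  expect_lt(abs(mean(vh) - kT_kcal(300) / (20 + kappa)) /
              (kT_kcal(300) / (20 + kappa)), 0.1)
  # windows must lie inside the reference profile's range
  narrow <- reference_pmf(data.frame(z = c(-5, 5), energy = c(0, 0)))
  expect_error(generate_umbrella_samples(narrow, prot), "narrower")
})

test_that("solvation snapshots realise the requested shell", {
  snap <- generate_solvation_snapshot("K", n_water = 6, water_dist = 2.8)
  o <- snap[snap$tag == "water_O", ]
  expect_equal(nrow(o), 6)
  expect_equal(sqrt(o$x^2 + o$y^2 + o$z^2), rep(2.8, 6),
               tolerance = 1e-9)
  # rigid 3-site geometry
  h <- snap[snap$tag == "water_H", ]
  expect_equal(nrow(h), 12)
  doh <- sqrt((h$x - o$x[match(h$mol, o$mol)])^2 +
                (h$y - o$y[match(h$mol, o$mol)])^2 +
                (h$z - o$z[match(h$mol, o$mol)])^2)
  expect_equal(doh, rep(0.9572, 12), tolerance = 1e-9)
  mix <- generate_solvation_snapshot("Na", n_water = 2, n_carbonyl = 4,
                                     water_dist = 2.9,
                                     carbonyl_dist = 2.4)
  expect_equal(sum(mix$tag == "carbonyl_O"), 4)
  expect_equal(sum(mix$tag == "water_O"), 2)
})

test_that("uniform gas fixture covers the degenerate cases", {
  expect_equal(nrow(generate_uniform_gas(0)), 0)
  g <- generate_uniform_gas(500, box = c(20, 30, 40), seed = 1)
  expect_true(all(g$x >= 0 & g$x <= 20))
  expect_true(all(g$z >= 0 & g$z <= 40))
})
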