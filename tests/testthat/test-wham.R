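test_that("a single unbiased window reduces to -kT log(histogram)", {
  set.seed(1)
  samp <- rnorm(20000, 0, 1.5)
  p <- unbiased_pmf(samp, bin_width = 0.25)
  h <- hist(samp, breaks = seq(floor(min(samp) / 0.25) * 0.25,
                               ceiling(max(samp) / 0.25) * 0.25, 0.25),
            plot = FALSE)
  manual <- -kT_kcal(300) * log(h$counts)
  manual[!is.finite(manual)] <- NA
  ok <- is.finite(p$pmf) & is.finite(manual)
  resid <- (p$pmf - manual)[ok]
  expect_lt(stats::sd(resid), 1e-9)       # equal up to one constant
})

test_that("WHAM recovers a harmonic landscape's curvature", {
  kappa <- 3
  w <- generate_umbrella_samples(
    harmonic_pmf(kappa),
    umbrella_protocol(center_min = -6, center_max = 6,
                      samples_per_window = 4000, seed = 2)
  )
  p <- wham(w, min_count = 10)
  ok <- is.finite(p$pmf) & abs(p$z) < 5
  fit <- stats::lm(p$pmf[ok] ~ p$z[ok] + I(p$z[ok]^2))
  expect_lt(abs(2 * stats::coef(fit)[3] - kappa) / kappa, 0.1)
})

test_that("the zero-referenced PMF ignores constant energy offsets", {
  ref <- reference_pmf_profile("k_two_site")
  shifted <- ref
  shifted$fun <- function(z) ref$fun(z) + 5
  prot <- umbrella_protocol(samples_per_window = 1500, seed = 6)
  p1 <- wham(generate_umbrella_samples(ref, prot))
  p2 <- wham(generate_umbrella_samples(shifted, prot))
  expect_equal(p1$pmf, p2$pmf, tolerance = 1e-9)
})

test_that("doubling window sampling reduces the recovery error", {
  ref <- reference_pmf_profile("k_two_site")
  rmsd_at <- function(nspw, seed) {
    p <- wham(generate_umbrella_samples(
      ref, umbrella_protocol(samples_per_window = nspw, seed = seed)
    ))
    ok <- is.finite(p$pmf) & p$z >= -10 & p$z <= 10
    sqrt(mean((p$pmf[ok] - eval_pmf(ref, p$z[ok]))^2))
  }
  seeds <- 1:5
  lo <- vapply(seeds, function(s) rmsd_at(1000, s), numeric(1))
  hi <- vapply(seeds, function(s) rmsd_at(2000, s), numeric(1))
  expect_lt(mean(hi), mean(lo))
})

test_that("round-trip at reduced sampling stays close to the reference", {
  ref <- reference_pmf_profile("na_two_site")
  w <- generate_umbrella_samples(
    ref, umbrella_protocol(samples_per_window = 2500, seed = 4)
  )
  p <- wham(w)
  expect_true(p$converged)
  ok <- is.finite(p$pmf) & p$z >= -10 & p$z <= 10
  expect_lt(sqrt(mean((p$pmf[ok] - eval_pmf(ref, p$z[ok]))^2)), 0.5)
})

test_that("degenerate window sets are flagged", {
  expect_error(wham(list()), "length")
  expect_error(
    umbrella_window(center = 0, spring_k = 20, samples = numeric(0)),
    "samples"
  )
  # far-separated windows cannot reach self-consistency
  w <- list(
    umbrella_window(-8, 20, rnorm(500, -8, 0.17)),
    umbrella_window(8, 20, rnorm(500, 8, 0.17))
  )
  expect_warning(p <- wham(w, max_iter = 2000, min_count = 1),
                 "do not overlap")
  expect_false(p$overlap_ok)
  # the gap between the two islands is unsupported
  expect_true(anyNA(p$pmf))
})

test_that("barrier extraction reads the analytic profiles exactly", {
  for (cfg in list(c("na_two_site", 6.2, 6.6),
                   c("k_two_site", 3.1, 3.5))) {
    ref <- reference_pmf_profile(cfg[1])
    z <- seq(-11.5, 11.5, 0.1)
    br <- extract_barriers(list(z = z, pmf = eval_pmf(ref, z)))
    expect_equal(unname(br$dE1), as.numeric(cfg[2]), tolerance = 1e-6)
    expect_equal(unname(br$dE2), as.numeric(cfg[3]), tolerance = 1e-6)
  }
  # monotone ramp: single barrier max - start, no dE2
  ramp <- list(z = seq(0, 10, 0.1), pmf = seq(0, 5, length.out = 101))
  br <- extract_barriers(ramp)
  expect_equal(unname(br$dE1), 5)
  expect_true(is.na(br$dE2))
})
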