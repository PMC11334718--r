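test_that("smeared Coulomb sum matches point-charge closed forms", {
  # single +1 e charge, tight smearing, on-axis point at 7.2 A
  q <- atom_set("K", 0, 0, 0, charge = 1, tag = "ion_K")
  pv <- potential_profile(q, z = 7.2, sigma = 0.05, units = "V")
  expect_equal(pv$phi, 14.399645 / 7.2, tolerance = 1e-6)
  pk <- potential_profile(q, z = 7.2, sigma = 0.05, units = "kT/e")
  expect_equal(pk$phi, 332.0637 / kT_kcal(300) / 7.2, tolerance = 1e-6)
  # ring of five -0.51 e charges at radius R, axial point at height h
  R <- 4.7; h <- 7.2
  ring <- atom_set(rep("O", 5), R * cos(2 * pi * (0:4) / 5),
                   R * sin(2 * pi * (0:4) / 5), 0,
                   charge = -0.51, tag = "carbonyl_O")
  pr <- potential_profile(ring, z = h, sigma = 0.1, units = "V")
  closed <- 14.399645 * 5 * (-0.51) / sqrt(R^2 + h^2)
  expect_lt(abs(pr$phi - closed) / abs(closed), 0.01)
  # grid point on top of the charge: finite erf limit
  p0 <- potential_profile(q, z = 0, sigma = 1, units = "V")
  expect_equal(p0$phi, 14.399645 * sqrt(2 / pi), tolerance = 1e-9)
})

test_that("the potential is linear in charges and odd under sign flip", {
  set.seed(4)
  n <- 30
  px <- runif(n, -4, 4); py <- runif(n, -4, 4); pz <- runif(n, -6, 6)
  mk <- function(qs) {
    atom_set(rep("O", n), px, py, pz, charge = qs, tag = "carbonyl_O")
  }
  q1 <- runif(n, -1, 1); q2 <- runif(n, -1, 1)
  z <- seq(-8, 8, 1)
  p1 <- potential_profile(mk(q1), z)$phi
  p2 <- potential_profile(mk(q2), z)$phi
  p12 <- potential_profile(mk(q1 + q2), z)$phi
  expect_equal(p12, p1 + p2, tolerance = 1e-12)
  pneg <- potential_profile(mk(-q1), z)$phi
  expect_equal(pneg, -p1, tolerance = 1e-12)
})

test_that("the decorated channel has its potential valley inside", {
  ch <- build_channel()
  prof <- potential_profile(ch)
  zmin <- prof$z[which.min(prof$phi)]
  expect_lt(abs(zmin), 6.67)
  expect_lt(min(prof$phi), 0)
  # interior is far below the far-field value
  expect_lt(min(prof$phi), min(prof$phi[abs(prof$z) > 10]) - 10)
  # disc averaging stays finite and keeps the valley interior
  pd <- potential_profile(ch, averaging_radius = 2)
  expect_true(all(is.finite(pd$phi)))
  expect_lt(abs(pd$z[which.min(pd$phi)]), 6.67)
})
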