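test_that("closed-form diameter matches the generated lattice", {
  for (n in c(4, 7, 10)) {
    tube <- build_cnt(cnt_spec(chiral_n = n, chiral_m = n, n_periods = 2))
    closed <- cnt_diameter(n, n, 1.415)
    scan <- max(stats::dist(cbind(tube$x, tube$y)))
    expect_lt(abs(closed - scan) / closed, 0.02)
    expect_equal(attr(tube, "diameter"), closed, tolerance = 1e-12)
  }
  # the reference channel is the 0.95 nm (7,7) tube
  expect_equal(round(cnt_diameter(7) / 10, 2), 0.95)
  # (5,5) at 1.42 A bond
  expect_equal(cnt_diameter(5, 5, 1.42), 1.42 * sqrt(3) / pi * sqrt(75))
})

test_that("armchair period holds 4n atoms and invalid specs are rejected", {
  expect_equal(nrow(build_cnt(cnt_spec(n_periods = 1))), 28)
  expect_error(cnt_spec(n_periods = 0), "n_periods")
  expect_error(cnt_spec(cc_bond = 1.7), "cc_bond")
  expect_warning(build_cnt(cnt_spec(chiral_n = 8, chiral_m = 4,
                                    n_periods = 1)),
                 "armchair")
})

test_that("ring spacing is 2.45 A pristine and strain is exactly affine", {
  tube <- build_cnt(cnt_spec())
  expect_equal(round(ring_spacing(tube), 2), 2.45)
  strained <- apply_axial_strain(tube, 0.10)
  # affine to machine precision
  expect_equal(ring_spacing(strained) / ring_spacing(tube), 1.10,
               tolerance = 1e-12)
  expect_equal(round(ring_spacing(strained), 1), 2.7)
  # identity at zero strain
  expect_identical(apply_axial_strain(tube, 0)$z, tube$z)
  # plain affine scaling about the centre
  a <- atom_set("C", c(0, 0), c(0, 0), c(-4, 4), tag = "wall_C")
  expect_equal(apply_axial_strain(a, 0.10)$z, c(-4.4, 4.4))
})

test_that("mid-section excision keeps the right slab and recenters", {
  tube <- apply_axial_strain(build_cnt(cnt_spec()), 0.10)
  sec <- excise_midsection(tube, 13.34)
  expect_lte(diff(range(sec$z)), 13.34)
  expect_lt(abs(diff(range(sec$z)) - 13.34), ring_spacing(sec))
  expect_equal(mean(range(sec$z)), 0, tolerance = 1e-9)
  # level count equals a brute-force clustering of z values
  brute <- length(unique(round(sec$z, 3)))
  expect_equal(attr(sec, "n_levels"), brute)
  # full-extent excision is the identity up to recentring
  full <- excise_midsection(tube, diff(range(tube$z)) + 1)
  expect_equal(nrow(full), nrow(tube))
  expect_error(excise_midsection(tube, -1), "empty")
})

test_that("carbonyl decoration places the right oxygens", {
  tube <- excise_midsection(apply_axial_strain(build_cnt(cnt_spec()),
                                               0.10), 13.34)
  ch <- decorate_carbonyls(tube, default_carbonyl_layout(tube))
  expect_equal(sum(ch$tag == "carbonyl_O"), 20)
  expect_equal(sum(ch$tag == "carbonyl_C"), 20)
  # oxygens sit inside the wall radius
  rw <- sqrt(ch$x^2 + ch$y^2)
  expect_true(all(rw[ch$tag == "carbonyl_O"] <
                    min(rw[ch$tag %in% c("wall_C", "carbonyl_C")])))
  # every oxygen sits one C=O bond from its carbonyl carbon
  co <- ch[ch$tag == "carbonyl_O", ]
  cc <- ch[ch$tag == "carbonyl_C", ]
  d <- vapply(seq_len(nrow(co)), function(i) {
    min(sqrt((cc$x - co$x[i])^2 + (cc$y - co$y[i])^2 +
               (cc$z - co$z[i])^2))
  }, numeric(1))
  expect_equal(d, rep(1.23, 20), tolerance = 1e-9)
  # two layers of five -> 10 oxygens
  lay2 <- default_carbonyl_layout(tube, n_layers = 2)
  expect_equal(sum(decorate_carbonyls(tube, lay2)$tag == "carbonyl_O"),
               10)
  # five per layer -> nearest-neighbour angular gaps of ~72 degrees
  th <- sort(atan2(co$y, co$x)[abs(co$z - co$z[1]) < 0.1] %% (2 * pi))
  gaps <- diff(c(th, th[1] + 2 * pi)) * 180 / pi
  expect_equal(gaps, rep(72, 5), tolerance = 8)
  # decoration cannot be applied twice
  expect_error(decorate_carbonyls(ch, default_carbonyl_layout(tube)),
               "already decorated")
  # layers must sit on wall-carbon levels one ring apart
  bad <- carbonyl_layout(layer_z = c(-2, 2))
  expect_error(decorate_carbonyls(tube, bad), "ring spacing")
})

test_that("charge assignment is tag-driven and auditable", {
  ch <- build_channel()
  expect_equal(net_charge(ch), 0)
  expect_equal(sum(abs(ch$charge)), 20.4)
  # arbitrary user table: reported net equals a brute-force sum
  tab <- c(wall_C = 0.01, carbonyl_C = 0.3, carbonyl_O = -0.2)
  ch2 <- assign_charges(ch, tab)
  expect_equal(attr(ch2, "net_charge"), sum(tab[ch$tag]))
  expect_error(assign_charges(ch, c(wall_C = 0)), "missing tags")
})

test_that("membrane assembly packs a neutral, clash-free system", {
  expect_equal(ion_count(0.5, 96), 29L)
  ch <- build_channel()
  sys <- assemble_membrane_system(ch, box_nm = c(4, 4, 4.6),
                                  salts = c(KCl = 0.5, NaCl = 0.5),
                                  seed = 7)
  allat <- system_to_atomset(sys)
  expect_equal(net_charge(allat), 0)
  expect_true(all(table(allat$tag[allat$tag %in%
                                    c("ion_K", "ion_Na")]) > 0))
  # brute-force pair scan: no heavy-atom clash below the cutoff
  heavy <- allat[allat$tag != "water_H", ]
  d <- as.matrix(stats::dist(heavy[, c("x", "y", "z")]))
  diag(d) <- Inf
  expect_gte(min(d), 1.2)                 # C-C lattice floor
  solv_o <- allat[allat$tag %in% c("water_O", "ion_K", "ion_Na",
                                   "ion_Cl"), ]
  wall <- allat[allat$tag %in% c("wall_C", "carbonyl_C", "carbonyl_O",
                                 "graphene_C"), ]
  dmin <- min(vapply(seq_len(nrow(solv_o)), function(i) {
    min(sqrt((wall$x - solv_o$x[i])^2 + (wall$y - solv_o$y[i])^2 +
               (wall$z - solv_o$z[i])^2))
  }, numeric(1)))
  expect_gte(dmin, 2.4)
  # no salts -> water only
  sys0 <- assemble_membrane_system(ch, box_nm = c(4, 4, 4.6),
                                   salts = c(KCl = 0, NaCl = 0),
                                   seed = 7)
  expect_false(any(sys0$solvent$tag %in%
                     c("ion_K", "ion_Na", "ion_Cl")))
})
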