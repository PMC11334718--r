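#' Umbrella-sampling protocol
#'
#' Defaults follow the study protocol: window centres from -10 to 10
#' Angstrom in 0.5 Angstrom steps, harmonic spring 20 kcal/mol/Angstrom^2,
#' 300 K, with the first half of each chain discarded as equilibration.
#'
#' @param center_min,center_max,center_step Window centre ladder, Angstrom.
#' @param spring_k Harmonic force constant, kcal/mol/Angstrom^2.
#' @param samples_per_window Retained samples per window.
#' @param temperature Temperature in K.
#' @param seed Integer RNG seed.
#' @param proposal_sd Metropolis step width; default 2.4 times the
#'   biased-well width sqrt(kT/spring_k) (near-optimal random-walk
#'   scaling).
#' @param burn_in_frac Fraction of each chain discarded from the front.
#' @return An `umbrella_protocol` list.
#' @export
umbrella_protocol <- function(center_min = -10, center_max = 10,
                              center_step = 0.5, spring_k = 20,
                              samples_per_window = 10000,
                              temperature = 300, seed = 1,
                              proposal_sd = NULL, burn_in_frac = 0.5) {
  stopifnot(center_min < center_max, center_step > 0, spring_k > 0,
            samples_per_window >= 1, temperature > 0,
            burn_in_frac >= 0, burn_in_frac < 1)
  if (is.null(proposal_sd)) {
    proposal_sd <- 2.4 * sqrt(kT_kcal(temperature) / spring_k)
  }
  structure(
    list(center_min = center_min, center_max = center_max,
         center_step = center_step, spring_k = spring_k,
         samples_per_window = as.integer(samples_per_window),
         temperature = temperature, seed = as.integer(seed),
         proposal_sd = proposal_sd, burn_in_frac = burn_in_frac),
    class = "umbrella_protocol"
  )
}

#' One umbrella window
#'
#' @param center Bias centre, Angstrom.
#' @param spring_k Force constant, kcal/mol/Angstrom^2.
#' @param samples Numeric vector of sampled z positions.
#' @param temperature Temperature in K.
#' @return An `umbrella_window`.
#' @export
umbrella_window <- function(center, spring_k, samples, temperature = 300) {
  stopifnot(spring_k > 0, length(samples) > 0, all(is.finite(samples)))
  structure(
    list(center = center, spring_k = spring_k, samples = samples,
         n_effective = length(samples), temperature = temperature),
    class = "umbrella_window"
  )
}

#' Generate biased samples for a ladder of umbrella windows
#'
#' For each window centre z_i, a Metropolis chain samples from the density
#' proportional to exp(-(U(z) + 0.5 k (z - z_i)^2)/kT).  All windows are
#' advanced in lockstep (one vectorised chain per step); the burn-in
#' fraction is discarded, mirroring the equilibration split of the
#' underlying simulations.
#'
#' @param pmf A [reference_pmf()] that spans the window range.
#' @param protocol An [umbrella_protocol()].
#' @return List of [umbrella_window()] objects, one per centre.
#' @export
generate_umbrella_samples <- function(pmf, protocol = umbrella_protocol()) {
  stopifnot(inherits(pmf, "reference_pmf"),
            inherits(protocol, "umbrella_protocol"))
  if (pmf$z_range[1] > protocol$center_min ||
      pmf$z_range[2] < protocol$center_max) {
    stop("reference pmf range is narrower than the umbrella windows")
  }
  centers <- seq(protocol$center_min, protocol$center_max,
                 by = protocol$center_step)
  nw <- length(centers)
  kT <- kT_kcal(protocol$temperature)
  k <- protocol$spring_k
  n_keep <- protocol$samples_per_window
  n_total <- ceiling(n_keep / (1 - protocol$burn_in_frac))
  n_burn <- n_total - n_keep

  set.seed(protocol$seed)
  z <- centers
  e <- pmf$fun(z) + 0.5 * k * (z - centers)^2
  keep <- matrix(NA_real_, nrow = n_keep, ncol = nw)
  lo <- pmf$z_range[1]; hi <- pmf$z_range[2]
  for (s in seq_len(n_total)) {
    zp <- z + stats::rnorm(nw, 0, protocol$proposal_sd)
    inside <- zp >= lo & zp <= hi
    ep <- rep(Inf, nw)
    if (any(inside)) {
      ep[inside] <- pmf$fun(zp[inside]) +
        0.5 * k * (zp[inside] - centers[inside])^2
    }
    acc <- log(stats::runif(nw)) < (e - ep) / kT
    z[acc] <- zp[acc]
    e[acc] <- ep[acc]
    if (s > n_burn) keep[s - n_burn, ] <- z
  }
  lapply(seq_len(nw), function(i) {
    umbrella_window(centers[i], k, keep[, i], protocol$temperature)
  })
}

#' Construct a solvation-shell snapshot around an ion
#'
#' Places the ion at the origin, water oxygens uniformly on a sphere of
#' the given shell distance with rigid 3-site geometry (OH 0.9572
#' Angstrom, HOH 104.52 degrees), and bare carbonyl oxygens at their
#' stated distance.  Water dipoles either point radially away from the
#' ion (`dipole = "radial"`, the physical arrangement around a cation) or
#' along a fixed axis (numeric length-3 vector).
#'
#' @param ion `"K"` or `"Na"`.
#' @param n_water Number of first-shell waters.
#' @param n_carbonyl Number of first-shell carbonyl oxygens.
#' @param water_dist Ion-to-water-oxygen distance, Angstrom.
#' @param carbonyl_dist Ion-to-carbonyl-oxygen distance, Angstrom.
#' @param dipole `"radial"` or a numeric axis for all dipoles.
#' @param seed RNG seed.
#' @return An `atom_set` with a `mol` column grouping water sites.
#' @export
generate_solvation_snapshot <- function(ion = c("K", "Na"), n_water = 6,
                                        n_carbonyl = 0, water_dist = 2.8,
                                        carbonyl_dist = 2.7,
                                        dipole = "radial", seed = 1) {
  ion <- match.arg(ion)
  stopifnot(n_water >= 0, n_carbonyl >= 0)
  set.seed(seed)
  tag_ion <- if (ion == "K") "ion_K" else "ion_Na"
  parts <- list(atom_set(if (ion == "K") "K" else "Na", 0, 0, 0,
                         charge = 1, tag = tag_ion, mol = 0L))
  rand_unit <- function(n) {
    m <- matrix(stats::rnorm(3 * n), ncol = 3)
    m / sqrt(rowSums(m^2))
  }
  if (n_water > 0) {
    u <- rand_unit(n_water)
    o <- u * water_dist
    for (i in seq_len(n_water)) {
      d <- if (is.numeric(dipole)) dipole / sqrt(sum(dipole^2)) else u[i, ]
      # orthonormal partner for the HOH plane
      p <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      p <- p - sum(p * d) * d
      p <- p / sqrt(sum(p^2))
      half <- 104.52 / 2 * pi / 180
      h1 <- o[i, ] + 0.9572 * (cos(half) * d + sin(half) * p)
      h2 <- o[i, ] + 0.9572 * (cos(half) * d - sin(half) * p)
      parts[[length(parts) + 1]] <- atom_set(
        c("O", "H", "H"),
        c(o[i, 1], h1[1], h2[1]), c(o[i, 2], h1[2], h2[2]),
        c(o[i, 3], h1[3], h2[3]),
        charge = c(-0.834, 0.417, 0.417),
        tag = c("water_O", "water_H", "water_H"), mol = i
      )
    }
  }
  if (n_carbonyl > 0) {
    u <- rand_unit(n_carbonyl) * carbonyl_dist
    parts[[length(parts) + 1]] <- atom_set(
      rep("O", n_carbonyl), u[, 1], u[, 2], u[, 3],
      charge = -0.51, tag = "carbonyl_O",
      mol = n_water + seq_len(n_carbonyl)
    )
  }
  do.call(bind_atoms, parts)
}

#' Uniform ideal-gas fixture
#'
#' `n` points i.i.d. uniform in the box, tagged as water oxygens.  Used as
#' the null model for pair-distribution normalisation checks.
#'
#' @param n Number of points.
#' @param box Numeric length-3 box in Angstrom.
#' @param seed RNG seed.
#' @return An `atom_set` with a `"box"` attribute.
#' @export
generate_uniform_gas <- function(n, box = c(40, 40, 40), seed = 1) {
  stopifnot(n >= 0, length(box) == 3, all(box > 0))
  set.seed(seed)
  a <- atom_set(
    rep("O", n),
    stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
    stats::runif(n, 0, box[3]),
    charge = 0, tag = rep("water_O", n), mol = seq_len(n)
  )
  attr(a, "box") <- box
  a
}
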