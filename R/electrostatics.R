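#' Axial electrostatic-potential profile by smeared Coulomb summation
#'
#' Each partial charge is smeared into an isotropic Gaussian of width
#' `sigma`, giving the non-periodic vacuum potential
#' phi(r) = sum_i q_i * erf(|r - r_i| / (sqrt(2) sigma)) / |r - r_i|,
#' finite everywhere (the r -> 0 limit is q * sqrt(2/pi) / sigma).  The
#' profile is evaluated along the channel axis, optionally averaged over
#' a disc about the axis.  There is no solvent or ionic screening: the
#' target is the interior profile shape of the bare charged structure.
#'
#' @param atoms An `atom_set` with charges assigned.
#' @param z Grid of axial positions, Angstrom.
#' @param sigma Gaussian smearing width, Angstrom (> 0).
#' @param averaging_radius Disc radius for transverse averaging,
#'   Angstrom (0 = on-axis values).
#' @param units `"kT/e"` (at `temperature`) or `"V"`.
#' @param temperature Temperature for the kT/e conversion, K.
#' @return A `potential_profile` data.frame with columns `z`, `phi`.
#' @export
potential_profile <- function(atoms, z = seq(-12, 12, by = 0.1),
                              sigma = 1, averaging_radius = 0,
                              units = c("kT/e", "V"),
                              temperature = 300) {
  units <- match.arg(units)
  stopifnot(sigma > 0, nrow(atoms) > 0)
  ch <- atoms[atoms$charge != 0, , drop = FALSE]
  if (nrow(ch) == 0) {
    warning("no non-zero charges; potential is identically zero")
  }
  pts <- if (averaging_radius > 0) {
    # equal-area polar quadrature over the disc
    nr <- 4; nphi <- 8
    rr <- averaging_radius * sqrt(((1:nr) - 0.5) / nr)
    pp <- 2 * pi * ((1:nphi) - 0.5) / nphi
    cbind(as.vector(outer(rr, cos(pp))), as.vector(outer(rr, sin(pp))))
  } else {
    matrix(0, nrow = 1, ncol = 2)
  }
  phi <- numeric(length(z))
  if (nrow(ch) > 0) {
    for (ip in seq_len(nrow(pts))) {
      dx2 <- (pts[ip, 1] - ch$x)^2 + (pts[ip, 2] - ch$y)^2
      for (iz in seq_along(z)) {
        r <- sqrt(dx2 + (z[iz] - ch$z)^2)
        v <- ifelse(r < 1e-10,
                    ch$charge * sqrt(2 / pi) / sigma,
                    ch$charge * erf_base(r / (sqrt(2) * sigma)) / r)
        phi[iz] <- phi[iz] + sum(v)
      }
    }
    phi <- phi / nrow(pts)
  }
  conv <- if (units == "kT/e") {
    COULOMB_KCAL / kT_kcal(temperature)
  } else COULOMB_VOLT
  out <- data.frame(z = z, phi = phi * conv)
  attr(out, "units") <- units
  attr(out, "sigma") <- sigma
  attr(out, "averaging_radius") <- averaging_radius
  class(out) <- c("potential_profile", "data.frame")
  out
}

# erf via pnorm (base R has no erf)
erf_base <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
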