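#' Analytic reference free-energy profiles
#'
#' A `reference_pmf` is a smooth 1-D free-energy curve U(z) used to drive
#' the synthetic umbrella sampler and the dwell-time scaling of the
#' trajectory generator.  It is defined by landmark nodes (bulk plateau,
#' barriers, wells) joined by a monotone cubic Hermite spline, so every
#' local extremum sits exactly at a node with exactly the stated energy.
#' Energy is zero on the entrance-side bulk plateau.
#'
#' @param nodes A data.frame with columns `z` (Angstrom, strictly
#'   increasing), `energy` (kcal/mol) and optionally `label`.
#' @return A `reference_pmf` with elements `nodes`, `fun` (vectorised
#'   U(z)), and `z_range`.
#' @export
reference_pmf <- function(nodes) {
  stopifnot(is.data.frame(nodes), all(c("z", "energy") %in% names(nodes)),
            all(diff(nodes$z) > 0), all(is.finite(nodes$energy)))
  if (!"label" %in% names(nodes)) nodes$label <- ""
  fun <- monotone_hermite(nodes$z, nodes$energy)
  structure(
    list(nodes = nodes, fun = fun, z_range = range(nodes$z)),
    class = "reference_pmf"
  )
}

# Monotone piecewise-cubic Hermite interpolant (Steffen-type slopes:
# harmonic mean of adjacent secants, zero at sign changes).  Guarantees
# that every local extremum of the curve sits exactly at a node with
# exactly the node's value -- an unconstrained cubic spline overshoots
# extrema, which would corrupt the encoded barrier heights.
monotone_hermite <- function(x, y) {
  n <- length(x)
  h <- diff(x); s <- diff(y) / h
  m <- numeric(n)
  m[1] <- s[1]; m[n] <- s[n - 1]
  if (n > 2) {
    for (i in 2:(n - 1)) {
      m[i] <- if (s[i - 1] * s[i] <= 0) 0 else
        2 * s[i - 1] * s[i] / (s[i - 1] + s[i])
    }
  }
  function(z) {
    i <- pmin(pmax(findInterval(z, x), 1L), n - 1L)
    t <- (z - x[i]) / h[i]
    h00 <- (1 + 2 * t) * (1 - t)^2
    h10 <- t * (1 - t)^2
    h01 <- t^2 * (3 - 2 * t)
    h11 <- t^2 * (t - 1)
    h00 * y[i] + h10 * h[i] * m[i] + h01 * y[i + 1] +
      h11 * h[i] * m[i + 1]
  }
}

#' Packaged two-binding-site reference profiles
#'
#' Analytic stand-ins for the free-energy landscapes of Na+ and K+ in the
#' two-binding-site channel.  The entrance barrier (dE1), the
#' entrance-well-to-first-site barrier (dE2 above the intervening well)
#' and the qualitative inter-site/exit structure encode the landscape
#' features of that channel: Na+ faces 6.2 then 6.6 kcal/mol, K+ 3.1 then
#' 3.5 kcal/mol, Na+ has the lower inter-site barrier and both ions face
#' similar exit barriers.
#'
#' @param name One of `"na_two_site"`, `"k_two_site"`.
#' @return A [reference_pmf()].
#' @export
reference_pmf_profile <- function(name = c("na_two_site", "k_two_site")) {
  name <- match.arg(name)
  nodes <- switch(
    name,
    na_two_site = data.frame(
      z = c(-12, -8, -5.5, -3.5, -1.5, 0.5, 2.0, 3.5, 6.0, 9.0, 12),
      energy = c(0, 0, 6.2, 2.8, 9.4, 1.0, 2.0, 0.5, 4.0, 0.8, 0.8),
      label = c("bulk", "bulk", "entrance_barrier", "entrance_well",
                "site_barrier", "site1", "intersite_barrier", "site2",
                "exit_barrier", "exit", "exit")
    ),
    k_two_site = data.frame(
      z = c(-12, -8, -5.5, -3.5, -1.5, 0.5, 2.0, 3.5, 6.0, 9.0, 12),
      energy = c(0, 0, 3.1, 0.8, 4.3, -1.5, 1.5, -1.0, 2.5, 0.3, 0.3),
      label = c("bulk", "bulk", "entrance_barrier", "entrance_well",
                "site_barrier", "site1", "intersite_barrier", "site2",
                "exit_barrier", "exit", "exit")
    )
  )
  out <- reference_pmf(nodes)
  out$name <- name
  out
}

#' Evaluate a reference PMF on a grid
#'
#' @param pmf A `reference_pmf`.
#' @param z Numeric vector of positions (Angstrom).
#' @return Energies in kcal/mol.
#' @export
eval_pmf <- function(pmf, z) pmf$fun(z)
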