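# shared fixtures: small, built in code

flat_pmf <- function(lim = 12) {
  reference_pmf(data.frame(z = c(-lim, lim), energy = c(0, 0)))
}

# harmonic landscape U = 0.5 * kappa * z^2 on the standard range
harmonic_pmf <- function(kappa) {
  p <- flat_pmf()
  p$fun <- function(z) 0.5 * kappa * z^2
  p
}

# hand-built single-ion trajectory from a z path (one particle, on-axis)
path_traj <- function(z, tag = "ion_K", dt = 0.1, id = "I1") {
  new_trajectory(
    data.frame(frame = seq_along(z) - 1L, id = id,
               element = cntkchan:::TAG_ELEMENT[[tag]], tag = tag,
               x = 0, y = 0, z = z),
    dt = dt, box = c(51, 51, 51)
  )
}

# two-cation + waters scripted trajectory for mode/knock-on fixtures:
# `rows` is a data.frame frame/id/tag/z (x,y default 0)
script_traj <- function(rows, dt = 0.1) {
  rows$element <- cntkchan:::TAG_ELEMENT[rows$tag]
  rows$x <- if (is.null(rows$x)) 0 else rows$x
  rows$y <- 0
  new_trajectory(rows, dt = dt, box = c(51, 51, 51))
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_permeation_trajectory(
        kinetic_params(n_events = 150, seed = 42)
      )
    }
    cache
  }
})
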