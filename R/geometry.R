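#' Channel geometry for permeation analysis
#'
#' Describes the channel axis interval, the committed-crossing buffer and
#' the binding-site planes (S4 at the entrance side up to S1 at the exit
#' side, matching the four carbonyl-ring layers).
#'
#' @param site_z Binding-site z positions in increasing z (bottom/entrance
#'   first), Angstrom.  Names default to S4..S1.
#' @param entrance_z,exit_z Channel mouth planes; default one layer
#'   spacing beyond the outer sites.
#' @param buffer Extra distance beyond the mouths an ion must cross for a
#'   committed entry/exit (default 2 Angstrom).
#' @param site_tolerance Half-width for site assignment; default half the
#'   layer spacing.
#' @return A `channel_geometry` list.
#' @export
channel_geometry <- function(site_z = c(-4.05, -1.35, 1.35, 4.05),
                             entrance_z = NULL, exit_z = NULL,
                             buffer = 2, site_tolerance = NULL) {
  stopifnot(length(site_z) >= 1, all(diff(site_z) > 0), buffer >= 0)
  gap <- if (length(site_z) > 1) mean(diff(site_z)) else 2.7
  if (is.null(entrance_z)) entrance_z <- min(site_z) - gap
  if (is.null(exit_z)) exit_z <- max(site_z) + gap
  stopifnot(entrance_z < exit_z,
            all(site_z > entrance_z & site_z < exit_z))
  if (is.null(site_tolerance)) site_tolerance <- gap / 2
  if (is.null(names(site_z))) {
    names(site_z) <- paste0("S", rev(seq_along(site_z)))
  }
  structure(
    list(entrance_z = entrance_z, exit_z = exit_z, buffer = buffer,
         site_z = site_z, site_tolerance = site_tolerance),
    class = "channel_geometry"
  )
}

#' Geometry matching a built channel
#'
#' Reads the carbonyl-layer planes of a decorated channel and uses them as
#' binding sites.
#'
#' @param channel Decorated channel `atom_set`.
#' @param ... Passed to [channel_geometry()].
#' @return A `channel_geometry`.
#' @export
geometry_from_channel <- function(channel, ...) {
  zc <- sort(unique(round(channel$z[channel$tag == "carbonyl_O"], 3)))
  lev <- split(zc, cumsum(c(1, diff(zc) > 0.3)))
  channel_geometry(site_z = vapply(lev, mean, numeric(1)), ...)
}
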