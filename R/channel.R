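#' Specification of a single-walled carbon nanotube
#'
#' The biomimetic channel of this package is based on an armchair (7,7)
#' tube (diameter 0.95 nm), stretched axially by 10% so that the
#' longitudinal hexatomic-ring spacing grows from 2.45 Angstrom to about
#' 2.7 Angstrom, matching the carbonyl-layer spacing of the KcsA
#' selectivity filter; a 13.34 Angstrom mid-section is then excised and
#' decorated with 20 inward-pointing carbonyl oxygens in four rings.
#'
#' @param chiral_n,chiral_m Chiral indices.  The reference channel is
#'   armchair, `chiral_n == chiral_m`; other indices are accepted with a
#'   warning.
#' @param cc_bond C-C bond length in Angstrom (default 1.415, which puts
#'   the pristine armchair ring spacing at sqrt(3)*cc = 2.45 Angstrom).
#' @param n_periods Number of translational periods along the axis.
#' @param strain Axial engineering strain (fraction, >= 0).
#' @param section_length Length of the excised mid-section in Angstrom.
#' @param section_before_strain If `TRUE` the mid-section is cut before
#'   straining (the measured section is then longer by the strain factor);
#'   default `FALSE`: strain first, then cut, so the retained section has
#'   the stated length.
#' @return A `cnt_spec` list.
#' @export
cnt_spec <- function(chiral_n = 7, chiral_m = 7, cc_bond = 1.415,
                     n_periods = 10, strain = 0.10,
                     section_length = 13.34,
                     section_before_strain = FALSE) {
  stopifnot(chiral_n >= 1, chiral_m >= 0)
  if (n_periods < 1) stop("n_periods must be >= 1")
  if (cc_bond <= 1.3 || cc_bond >= 1.6) {
    stop("cc_bond must lie in (1.3, 1.6) Angstrom")
  }
  if (strain < 0) stop("strain must be >= 0")
  if (section_length <= 0) stop("section_length must be > 0")
  structure(
    list(chiral_n = as.integer(chiral_n), chiral_m = as.integer(chiral_m),
         cc_bond = cc_bond, n_periods = as.integer(n_periods),
         strain = strain, section_length = section_length,
         section_before_strain = section_before_strain),
    class = "cnt_spec"
  )
}

#' Nanotube diameter from the rolled-lattice closed form
#'
#' d = (cc * sqrt(3) / pi) * sqrt(n^2 + n*m + m^2), in Angstrom.
#'
#' @param n,m Chiral indices.
#' @param cc_bond C-C bond length in Angstrom.
#' @return Diameter in Angstrom.
#' @export
cnt_diameter <- function(n, m = n, cc_bond = 1.415) {
  cc_bond * sqrt(3) / pi * sqrt(n^2 + n * m + m^2)
}

#' Build a carbon nanotube as wall-carbon coordinates
#'
#' Atoms of the rolled graphene lattice are generated with the tube axis
#' along +z and the origin at the geometric centre.  For armchair (n,n)
#' tubes the translational period is sqrt(3)*cc (the longitudinal
#' hexatomic-ring spacing), with 4n atoms per period on 2n-atom z-levels
#' spaced half a period apart.
#'
#' @param spec A [cnt_spec()].
#' @return An `atom_set` of wall carbons (`wall_C`), charge 0.
#' @export
build_cnt <- function(spec) {
  stopifnot(inherits(spec, "cnt_spec"))
  n <- spec$chiral_n; m <- spec$chiral_m; cc <- spec$cc_bond
  if (n != m) {
    warning("non-armchair chiral indices (", n, ",", m,
            "): the reference channel construction assumes armchair")
  }
  a <- cc * sqrt(3)                      # graphene lattice constant
  # lattice vectors and basis in the flat sheet
  a1 <- a * c(sqrt(3) / 2,  0.5)
  a2 <- a * c(sqrt(3) / 2, -0.5)
  basis <- rbind(c(0, 0), (a1 + a2) / 3)
  Ch <- n * a1 + m * a2                  # chiral (circumference) vector
  dr <- gcd_int(2 * n + m, 2 * m + n)
  Tv <- ((2 * m + n) * a1 - (2 * n + m) * a2) / dr   # translation vector
  Lc <- sqrt(sum(Ch^2)); Lt <- sqrt(sum(Tv^2))
  ch <- Ch / Lc; tv <- Tv / Lt
  n_cell <- 4 * (n^2 + n * m + m^2) / dr # atoms per translational cell
  tube_len <- spec$n_periods * Lt

  # enumerate lattice cells generously, fold onto the cylinder surface
  rng <- -(2 * (n + m) + 4 * spec$n_periods):(2 * (n + m) + 4 * spec$n_periods)
  ij <- expand.grid(i = rng, j = rng)
  pts <- rbind(
    cbind(ij$i * a1[1] + ij$j * a2[1] + basis[1, 1],
          ij$i * a1[2] + ij$j * a2[2] + basis[1, 2]),
    cbind(ij$i * a1[1] + ij$j * a2[1] + basis[2, 1],
          ij$i * a1[2] + ij$j * a2[2] + basis[2, 2])
  )
  s <- pts %*% ch                        # coordinate along circumference
  t <- pts %*% tv                        # coordinate along axis
  keep <- t > -1e-8 & t < tube_len - 1e-8
  s <- s[keep]; t <- t[keep]
  u <- s %% Lc                           # fold circumference
  # deduplicate atoms mapping to the same surface point
  key <- paste(round(u / Lc * 1e6) %% 1e6, round(t * 1e4))
  first <- !duplicated(key)
  u <- u[first]; t <- t[first]
  expected <- n_cell * spec$n_periods
  if (length(u) != expected) {
    stop("internal lattice enumeration error: got ", length(u),
         " atoms, expected ", expected)
  }
  R <- Lc / (2 * pi)
  theta <- 2 * pi * u / Lc
  out <- atom_set(
    element = "C",
    x = R * cos(theta), y = R * sin(theta), z = t - mean(range(t)),
    charge = 0, tag = "wall_C"
  )
  attr(out, "cnt_spec") <- spec
  attr(out, "diameter") <- 2 * R
  out
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Cluster wall-carbon z-coordinates into atomic levels
#'
#' @param atoms An `atom_set` containing wall/carbonyl carbons.
#' @param tol Clustering tolerance in Angstrom.
#' @return Sorted numeric vector of level z-positions.
#' @export
wall_z_levels <- function(atoms, tol = 0.15) {
  zc <- sort(atoms$z[atoms$tag %in% c("wall_C", "carbonyl_C")])
  if (length(zc) == 0) stop("no wall carbons present")
  breaks <- c(0, which(diff(zc) > tol), length(zc))
  vapply(seq_len(length(breaks) - 1),
         function(k) mean(zc[(breaks[k] + 1):breaks[k + 1]]),
         numeric(1))
}

#' Longitudinal hexatomic-ring spacing
#'
#' In an armchair tube each hexagon row spans two atomic z-levels, so rows
#' of rings repeat every second level: the ring spacing is twice the mean
#' adjacent atomic-level gap (sqrt(3)*cc for the pristine tube, 2.45
#' Angstrom at the default bond length).
#'
#' @inheritParams wall_z_levels
#' @return Mean ring spacing in Angstrom.
#' @export
ring_spacing <- function(atoms, tol = 0.15) {
  lev <- wall_z_levels(atoms, tol)
  if (length(lev) < 2) stop("need at least two atomic levels")
  2 * mean(diff(lev))
}

#' Apply axial strain as an affine z-scaling
#'
#' Deterministic surrogate for relaxed stretching: z-coordinates are
#' scaled by (1 + strain) about the geometric centre; x and y are
#' unchanged.
#'
#' @param atoms An `atom_set`.
#' @param strain Engineering strain (>= 0).
#' @return Strained `atom_set`.
#' @export
apply_axial_strain <- function(atoms, strain) {
  if (strain < 0) stop("strain must be >= 0")
  zc <- mean(range(atoms$z))
  atoms$z <- zc + (atoms$z - zc) * (1 + strain)
  atoms
}

#' Excise the channel mid-section
#'
#' Retains atoms with |z - centre| <= length/2 and recentres the result at
#' z = 0.  The number of retained atomic z-levels is recorded in the
#' `"n_levels"` attribute (two levels per hexatomic-ring row).
#'
#' @param atoms An `atom_set`.
#' @param length Section length in Angstrom.
#' @return The excised, recentred `atom_set`.
#' @export
excise_midsection <- function(atoms, length) {
  zc <- mean(range(atoms$z))
  keep <- abs(atoms$z - zc) <= length / 2 + 1e-9
  if (!any(keep)) stop("mid-section selection is empty")
  out <- atoms[keep, , drop = FALSE]
  out$z <- out$z - mean(range(out$z))
  class(out) <- c("atom_set", "data.frame")
  attr(out, "n_levels") <- length(wall_z_levels(out))
  attr(out, "cnt_spec") <- attr(atoms, "cnt_spec")
  attr(out, "diameter") <- attr(atoms, "diameter")
  out
}

#' Carbonyl decoration layout
#'
#' The reference channel carries 20 carbonyl oxygens in four rings of five
#' (mimicking the four carbonyl layers of the KcsA filter), pointing
#' radially inward at a C=O bond length of 1.23 Angstrom.
#'
#' @param layer_z z-positions of the carbonyl layers (must coincide with
#'   wall-carbon levels within 0.3 Angstrom; strictly increasing).
#' @param oxygens_per_layer Oxygens per ring.
#' @param co_bond C=O bond length in Angstrom.
#' @param inward If `TRUE` (default) oxygens point into the tube.
#' @param offset_deg Per-layer azimuthal offset of the first oxygen, in
#'   degrees (recycled to the number of layers).
#' @return A `carbonyl_layout` list.
#' @export
carbonyl_layout <- function(layer_z, oxygens_per_layer = 5, co_bond = 1.23,
                            inward = TRUE, offset_deg = 0) {
  stopifnot(length(layer_z) >= 1, all(diff(layer_z) > 0),
            oxygens_per_layer >= 1, co_bond > 0)
  structure(
    list(n_layers = length(layer_z), oxygens_per_layer = oxygens_per_layer,
         co_bond = co_bond, inward = inward,
         layer_z = layer_z,
         offset_deg = rep_len(offset_deg, length(layer_z))),
    class = "carbonyl_layout"
  )
}

#' Default four-ring layout for an excised section
#'
#' Picks `n_layers` wall-carbon levels spaced one ring period apart (every
#' second atomic level), centred as symmetrically as possible about z = 0.
#'
#' @param atoms Excised `atom_set`.
#' @param n_layers Number of carbonyl layers.
#' @param ... Passed to [carbonyl_layout()].
#' @return A `carbonyl_layout`.
#' @export
default_carbonyl_layout <- function(atoms, n_layers = 4, ...) {
  lev <- wall_z_levels(atoms)
  if (length(lev) < 2 * n_layers - 1) {
    stop("section too short for ", n_layers, " layers")
  }
  starts <- seq_len(length(lev) - 2 * (n_layers - 1))
  centre <- vapply(starts, function(s) {
    abs(mean(lev[seq(s, by = 2, length.out = n_layers)]))
  }, numeric(1))
  s <- starts[which.min(centre)]
  carbonyl_layout(layer_z = lev[seq(s, by = 2, length.out = n_layers)], ...)
}

#' Decorate the tube wall with inward carbonyl groups
#'
#' For each layer, `oxygens_per_layer` wall carbons at maximally even
#' angular spacing are retagged `carbonyl_C` and given an oxygen displaced
#' radially inward by the C=O bond length in the carbon's z-plane.
#'
#' @param atoms Wall-carbon `atom_set` (not previously decorated).
#' @param layout A [carbonyl_layout()].
#' @return Decorated `atom_set` (wall + carbonyl C + carbonyl O).
#' @export
decorate_carbonyls <- function(atoms, layout) {
  stopifnot(inherits(layout, "carbonyl_layout"))
  if (any(atoms$tag %in% c("carbonyl_C", "carbonyl_O"))) {
    stop("atom set is already decorated")
  }
  lev <- wall_z_levels(atoms)
  ring <- ring_spacing(atoms)
  dz_layers <- diff(layout$layer_z)
  if (length(dz_layers) > 0 && any(abs(dz_layers - ring) > 0.05)) {
    stop("adjacent carbonyl layers must be one ring spacing (",
         round(ring, 3), " A) apart")
  }
  ox <- list()
  for (k in seq_along(layout$layer_z)) {
    zk <- layout$layer_z[k]
    if (min(abs(lev - zk)) > 0.3) {
      stop("layer z = ", zk, " does not coincide with a wall-carbon level")
    }
    idx <- which(abs(atoms$z - zk) <= 0.3 &
                   atoms$tag == "wall_C")
    if (length(idx) < layout$oxygens_per_layer) {
      stop("layer at z = ", zk, " has only ", length(idx),
           " carbons for ", layout$oxygens_per_layer, " oxygens")
    }
    th <- atan2(atoms$y[idx], atoms$x[idx]) %% (2 * pi)
    targets <- (layout$offset_deg[k] * pi / 180 +
                  2 * pi * (seq_len(layout$oxygens_per_layer) - 1) /
                  layout$oxygens_per_layer) %% (2 * pi)
    chosen <- integer(0)
    for (tg in targets) {
      d <- abs(((th - tg + pi) %% (2 * pi)) - pi)
      d[match(chosen, idx)] <- Inf
      chosen <- c(chosen, idx[which.min(d)])
    }
    atoms$tag[chosen] <- "carbonyl_C"
    r <- sqrt(atoms$x[chosen]^2 + atoms$y[chosen]^2)
    sgn <- if (layout$inward) -1 else 1
    fac <- (r + sgn * layout$co_bond) / r
    ox[[k]] <- atom_set(
      element = "O",
      x = atoms$x[chosen] * fac, y = atoms$y[chosen] * fac,
      z = atoms$z[chosen],
      charge = 0, tag = "carbonyl_O"
    )
  }
  out <- bind_atoms(atoms, do.call(bind_atoms, ox))
  attr(out, "cnt_spec") <- attr(atoms, "cnt_spec")
  attr(out, "diameter") <- attr(atoms, "diameter")
  attr(out, "layout") <- layout
  out
}

#' Default channel partial charges
#'
#' The backbone-carbonyl convention: +0.51 e on carbonyl carbons, -0.51 e
#' on carbonyl oxygens, all other carbons neutral.  Override with any
#' named table when better (e.g. DFT-derived) values are available.
#'
#' @return Named numeric vector of charges by group tag.
#' @export
default_channel_charges <- function() {
  c(wall_C = 0, carbonyl_C = 0.51, carbonyl_O = -0.51, graphene_C = 0)
}

#' Assign partial charges by group tag
#'
#' @param atoms An `atom_set`.
#' @param table Named numeric vector mapping every present tag to a
#'   charge in e.
#' @return The atom set with charges set; net charge in attribute
#'   `"net_charge"`.
#' @export
assign_charges <- function(atoms, table = default_channel_charges()) {
  present <- unique(atoms$tag)
  missing <- setdiff(present, names(table))
  if (length(missing) > 0) {
    stop("charge table missing tags: ", paste(missing, collapse = ", "))
  }
  atoms$charge <- unname(table[atoms$tag])
  attr(atoms, "net_charge") <- sum(atoms$charge)
  atoms
}

#' Build the decorated, charged channel in one call
#'
#' Runs the full construction recipe: build the tube, strain it, excise
#' the mid-section, decorate with carbonyls and assign charges.
#'
#' @param spec A [cnt_spec()].
#' @param n_layers,oxygens_per_layer,co_bond,offset_deg Decoration
#'   parameters (see [carbonyl_layout()]).
#' @param charges Charge table (see [assign_charges()]).
#' @return The channel `atom_set`.
#' @export
build_channel <- function(spec = cnt_spec(), n_layers = 4,
                          oxygens_per_layer = 5, co_bond = 1.23,
                          offset_deg = 0,
                          charges = default_channel_charges()) {
  tube <- build_cnt(spec)
  if (spec$section_before_strain) {
    tube <- excise_midsection(tube, spec$section_length)
    tube <- apply_axial_strain(tube, spec$strain)
  } else {
    tube <- apply_axial_strain(tube, spec$strain)
    tube <- excise_midsection(tube, spec$section_length)
  }
  layout <- default_carbonyl_layout(
    tube, n_layers = n_layers, oxygens_per_layer = oxygens_per_layer,
    co_bond = co_bond, offset_deg = offset_deg
  )
  assign_charges(decorate_carbonyls(tube, layout), charges)
}
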