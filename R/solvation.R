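#' First-shell specification
#'
#' First hydration-shell radii per species (3.6 Angstrom for K+, 3.2 for
#' Na+, taken at the first minimum of the bulk ion-oxygen RDFs) and the
#' oxygen partner groups counted as ligands.
#'
#' @param radii Named radii in Angstrom (`K`, `Na`).
#' @param partner_groups Partner tags counted as ligands.
#' @return A `shell_spec` list.
#' @export
shell_spec <- function(radii = c(K = 3.6, Na = 3.2),
                       partner_groups = c("water_O", "carbonyl_O")) {
  stopifnot(all(radii > 0), length(partner_groups) >= 1)
  structure(list(radii = radii, partner_groups = partner_groups),
            class = "shell_spec")
}

species_tag <- function(species) {
  if (species %in% ATOM_TAGS) return(species)
  switch(species, K = "ion_K", Na = "ion_Na", Cl = "ion_Cl",
         stop("unknown species: ", species))
}

min_image <- function(d, L) d - L * round(d / L)

#' Radial distribution function, decomposed by partner group
#'
#' Pair-distance histogram between a centre species and oxygen partner
#' groups, normalised by the spherical shell volume 4*pi*r^2*dr and the
#' partner number density measured in a bulk region.  With a box, the
#' minimum-image convention is applied.  In confined geometry the RDF is
#' not globally normalisable, so in-channel curves are shape-only; the
#' bulk region supplies the reference density.
#'
#' @param traj An `md_traj` (or use [snapshot_trajectory()]).
#' @param center_species `"K"` or `"Na"` (or a centre tag).
#' @param partner_groups Partner tags, e.g. `c("water_O", "carbonyl_O")`.
#' @param r_max,dr Histogram range and bin width, Angstrom.
#' @param bulk_region Optional `c(zmin, zmax)` slab used to measure the
#'   partner density; default: the whole box.
#' @return An `rdf_result`: `r` (bin centres), per-group `g` columns,
#'   `g_total`, plus `first_peak` and `first_min` attributes (located on
#'   a 3-point-smoothed total; first local minimum after the global
#'   peak, ties toward smaller r).
#' @export
rdf <- function(traj, center_species, partner_groups, r_max = 10,
                dr = 0.05, bulk_region = NULL) {
  stopifnot(inherits(traj, "md_traj"), dr > 0, r_max > dr)
  if (length(partner_groups) == 0) stop("empty partner set")
  ctag <- species_tag(center_species)
  box <- traj$box
  nb <- floor(r_max / dr)
  edges <- (0:nb) * dr
  counts <- matrix(0, nrow = nb, ncol = length(partner_groups),
                   dimnames = list(NULL, partner_groups))
  n_center_frames <- 0
  A <- traj$atoms
  frames <- unique(A$frame)
  for (f in frames) {
    Fd <- A[frame == f]
    C <- as.matrix(Fd[tag == ctag, .(x, y, z)])
    if (nrow(C) == 0) next
    n_center_frames <- n_center_frames + nrow(C)
    for (g in partner_groups) {
      P <- as.matrix(Fd[tag == g, .(x, y, z)])
      if (nrow(P) == 0) next
      for (i0 in seq(1, nrow(C), by = 256)) {
        i1 <- min(i0 + 255, nrow(C))
        dx <- outer(C[i0:i1, 1], P[, 1], "-")
        dy <- outer(C[i0:i1, 2], P[, 2], "-")
        dz <- outer(C[i0:i1, 3], P[, 3], "-")
        if (!is.null(box)) {
          dx <- min_image(dx, box[1]); dy <- min_image(dy, box[2])
          dz <- min_image(dz, box[3])
        }
        r <- sqrt(dx^2 + dy^2 + dz^2)
        r <- r[r > 1e-8 & r < r_max]
        if (length(r)) {
          counts[, g] <- counts[, g] +
            tabulate(floor(r / dr) + 1L, nbins = nb)
        }
      }
    }
  }
  if (n_center_frames == 0) stop("no centre atoms found")
  # bulk partner densities
  if (is.null(box)) stop("rdf needs a box for density normalisation")
  vol <- if (is.null(bulk_region)) prod(box) else {
    box[1] * box[2] * (bulk_region[2] - bulk_region[1])
  }
  rho <- vapply(partner_groups, function(g) {
    sel <- A$tag == g
    if (!is.null(bulk_region)) {
      sel <- sel & A$z >= bulk_region[1] & A$z <= bulk_region[2]
    }
    sum(sel) / length(frames) / vol
  }, numeric(1))
  mids <- edges[-1] - dr / 2
  shell <- 4 * pi * mids^2 * dr
  gmat <- sweep(counts / n_center_frames / shell, 2,
                pmax(rho, .Machine$double.eps), "/")
  g_total <- rowSums(counts) / n_center_frames / shell /
    max(sum(rho), .Machine$double.eps)
  out <- data.frame(r = mids, gmat, g_total = g_total,
                    check.names = FALSE)
  sm <- smooth3(g_total)
  pk <- which.max(sm)
  fmin <- NA_real_
  if (pk < nb - 1) {
    for (i in (pk + 1):(nb - 1)) {
      if (sm[i] <= sm[i - 1] && sm[i] <= sm[i + 1]) {
        fmin <- mids[i]; break
      }
    }
  }
  attr(out, "first_peak") <- mids[pk]
  attr(out, "first_min") <- fmin
  attr(out, "bulk_density") <- rho
  class(out) <- c("rdf_result", "data.frame")
  out
}

smooth3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  c(v[1], (v[-c(1, 2)] + v[-c(1, n)] + v[-c(n - 1, n)]) / 3, v[n])
}

shell_counts <- function(traj, shells) {
  # per ion-frame ligand counts within the species shell radius
  A <- traj$atoms
  ions <- A[tag %in% CATION_TAGS,
            .(frame, id, tag, x, y, z)]
  ions[, species := ifelse(tag == "ion_K", "K", "Na")]
  ions[, rshell := shells$radii[species]]
  P <- A[tag %in% shells$partner_groups,
         .(frame, ptag = tag, px = x, py = y, pz = z)]
  if (nrow(P) > 0 && nrow(ions) > 0) {
    pairs <- merge(ions, P, by = "frame", allow.cartesian = TRUE)
    pairs <- pairs[(px - x)^2 + (py - y)^2 + (pz - z)^2 <= rshell^2]
    cnt <- data.table::dcast(
      pairs[, .N, by = .(frame, id, ptag)],
      frame + id ~ ptag, value.var = "N", fill = 0L
    )
  } else {
    cnt <- data.table::data.table(frame = integer(0), id = character(0))
  }
  for (g in shells$partner_groups) {
    if (!g %in% names(cnt)) cnt[, (g) := 0L]
  }
  out <- merge(ions[, .(frame, id, species, z)], cnt,
               by = c("frame", "id"), all.x = TRUE)
  for (g in shells$partner_groups) {
    data.table::set(out, which(is.na(out[[g]])), g, 0L)
  }
  out[, n_total := Reduce(`+`, .SD), .SDcols = shells$partner_groups]
  out[]
}

#' Coordination number profile along the channel axis
#'
#' Mean number of ligand oxygens (total and split by partner group)
#' within the species' first-shell radius, as a function of the ion's z
#' position.
#'
#' @param traj An `md_traj`.
#' @param shells A [shell_spec()].
#' @param z_breaks Bin edges along z, Angstrom.
#' @return data.table: `z` (bin centre), `species`, `n_obs`, `n_total`
#'   and one `n_<group>` column per partner group.
#' @export
coordination_profile <- function(traj, shells = shell_spec(),
                                 z_breaks = seq(-12, 12, by = 1)) {
  sc <- shell_counts(traj, shells)
  sc <- sc[z >= min(z_breaks) & z <= max(z_breaks)]
  sc[, zbin := cut(z, z_breaks, labels = FALSE, include.lowest = TRUE)]
  mids <- z_breaks[-length(z_breaks)] + diff(z_breaks) / 2
  cols <- c(shells$partner_groups, "n_total")
  prof <- sc[, c(list(n_obs = .N), lapply(.SD, mean)),
             by = .(species, zbin), .SDcols = cols]
  data.table::setnames(prof, shells$partner_groups,
                       paste0("n_", shells$partner_groups))
  prof[, z := mids[zbin]]
  data.table::setorder(prof, species, z)
  prof[, zbin := NULL]
  prof[]
}

#' Hydration-number distribution
#'
#' Normalised histogram of the water-only coordination number per
#' species.
#'
#' @inheritParams coordination_profile
#' @return data.table: `species`, `n_water`, `p`.
#' @export
hydration_histogram <- function(traj, shells = shell_spec()) {
  if (!"water_O" %in% shells$partner_groups) {
    stop("shell spec does not include water oxygens")
  }
  sc <- shell_counts(traj, shells)
  h <- sc[, .(count = .N), by = .(species, n_water = water_O)]
  h[, p := count / sum(count), by = species]
  data.table::setorder(h, species, n_water)
  h[, .(species, n_water, p)]
}

#' Water dipole orientation distribution in the first shell
#'
#' For every 3-site water whose oxygen lies in an ion's first shell, the
#' angle between the molecular dipole (bisector from O through the HH
#' midpoint) and a reference axis (+z by default, the field direction) is
#' histogrammed over [0, 180] degrees.  The isotropic baseline
#' (proportional to sin theta) is returned alongside.
#'
#' @param traj An `md_traj` whose water has hydrogens and a `mol` column.
#' @param shells A [shell_spec()].
#' @param reference_axis Numeric length-3 axis.
#' @param n_bins Number of angular bins.
#' @return data.table: `theta` (bin centre, degrees), `p`, `p_iso`.
#' @export
orientation_histogram <- function(traj, shells = shell_spec(),
                                  reference_axis = c(0, 0, 1),
                                  n_bins = 36) {
  A <- traj$atoms
  if (!any(A$tag == "water_H")) stop("water hydrogens missing")
  if (!"mol" %in% names(A)) stop("trajectory lacks a mol column")
  ax <- reference_axis / sqrt(sum(reference_axis^2))
  O <- A[tag == "water_O", .(frame, mol, x, y, z)]
  H <- A[tag == "water_H",
         .(hx = mean(x), hy = mean(y), hz = mean(z)),
         by = .(frame, mol)]
  wat <- merge(O, H, by = c("frame", "mol"))
  ions <- A[tag %in% CATION_TAGS, .(frame, ix = x, iy = y, iz = z,
                                    species = ifelse(tag == "ion_K",
                                                     "K", "Na"))]
  ions[, rshell := shells$radii[species]]
  pairs <- merge(wat, ions, by = "frame", allow.cartesian = TRUE)
  pairs <- pairs[(x - ix)^2 + (y - iy)^2 + (z - iz)^2 <= rshell^2]
  if (nrow(pairs) == 0) stop("no first-shell waters found")
  dx <- pairs$hx - pairs$x; dy <- pairs$hy - pairs$y
  dz <- pairs$hz - pairs$z
  nrm <- sqrt(dx^2 + dy^2 + dz^2)
  ct <- (dx * ax[1] + dy * ax[2] + dz * ax[3]) / nrm
  theta <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  breaks <- seq(0, 180, length.out = n_bins + 1)
  cnt <- tabulate(pmin(findInterval(theta, breaks,
                                    rightmost.closed = TRUE), n_bins),
                  nbins = n_bins)
  lo <- breaks[-(n_bins + 1)] * pi / 180
  hi <- breaks[-1] * pi / 180
  iso <- (cos(lo) - cos(hi)) / 2
  data.table::data.table(
    theta = (breaks[-(n_bins + 1)] + breaks[-1]) / 2,
    p = cnt / sum(cnt),
    p_iso = iso
  )
}

#' Spatial density profiles
#'
#' Axial: counts per z-bin per frame divided by the bin width (a linear
#' density, 1/Angstrom; its integral over z is the mean in-range count
#' per frame).  Radial: counts per cylindrical annulus normalised by the
#' exact annulus area times the slab height (1/Angstrom^3).  Planar: 2-D
#' x-y histogram over in-channel frames normalised per cell area and
#' slab height.
#'
#' @param traj An `md_traj`.
#' @param species Species or tag to profile (e.g. `"K"`, `"water_O"`).
#' @param mode `"axial"`, `"radial"` or `"planar"`.
#' @param breaks Bin edges: z edges (axial), r edges (radial) or a list
#'   `list(x =, y =)` (planar).
#' @param zlim In-channel z interval used for radial/planar selection.
#' @return A `density_result` list: `mode`, bin centres, `density`,
#'   `n_mean` (mean selected count per frame).
#' @export
density_profile <- function(traj, species, mode = c("axial", "radial",
                                                    "planar"),
                            breaks = NULL, zlim = c(-6.67, 6.67)) {
  mode <- match.arg(mode)
  tg <- if (species %in% ATOM_TAGS) species else species_tag(species)
  A <- traj$atoms[tag == tg]
  nf <- traj$n_frames
  if (mode == "axial") {
    if (is.null(breaks)) breaks <- seq(-9.5, 9.5, by = 0.5)
    sel <- A[z >= min(breaks) & z <= max(breaks)]
    cnt <- tabulate(cut(sel$z, breaks, labels = FALSE,
                        include.lowest = TRUE),
                    nbins = length(breaks) - 1)
    dz <- diff(breaks)
    res <- list(mode = mode,
                z = breaks[-length(breaks)] + dz / 2,
                density = cnt / nf / dz,
                n_mean = nrow(sel) / nf)
  } else if (mode == "radial") {
    if (is.null(breaks)) breaks <- seq(0, 5, by = 0.25)
    sel <- A[z >= zlim[1] & z <= zlim[2]]
    r <- sqrt(sel$x^2 + sel$y^2)
    cnt <- tabulate(cut(r, breaks, labels = FALSE,
                        include.lowest = TRUE),
                    nbins = length(breaks) - 1)
    area <- pi * (breaks[-1]^2 - breaks[-length(breaks)]^2)
    H <- zlim[2] - zlim[1]
    res <- list(mode = mode,
                r = breaks[-length(breaks)] + diff(breaks) / 2,
                density = cnt / nf / (area * H),
                n_mean = nrow(sel) / nf)
  } else {
    if (is.null(breaks)) {
      breaks <- list(x = seq(-5, 5, by = 0.5), y = seq(-5, 5, by = 0.5))
    }
    sel <- A[z >= zlim[1] & z <= zlim[2] &
               x >= min(breaks$x) & x <= max(breaks$x) &
               y >= min(breaks$y) & y <= max(breaks$y)]
    ix <- cut(sel$x, breaks$x, labels = FALSE, include.lowest = TRUE)
    iy <- cut(sel$y, breaks$y, labels = FALSE, include.lowest = TRUE)
    m <- matrix(0, length(breaks$x) - 1, length(breaks$y) - 1)
    for (k in seq_along(ix)) m[ix[k], iy[k]] <- m[ix[k], iy[k]] + 1
    H <- zlim[2] - zlim[1]
    cell <- outer(diff(breaks$x), diff(breaks$y))
    res <- list(mode = mode,
                x = breaks$x[-length(breaks$x)] + diff(breaks$x) / 2,
                y = breaks$y[-length(breaks$y)] + diff(breaks$y) / 2,
                density = m / nf / (cell * H),
                n_mean = nrow(sel) / nf)
  }
  class(res) <- "density_result"
  res
}
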