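#' Ion count from a molar concentration and a volume
#'
#' round(concentration * N_A * volume), with N_A expressed per nm^3 and
#' mol/L (0.602214 particles per nm^3 per M).
#'
#' @param molarity Concentration, mol/L.
#' @param volume_nm3 Volume, nm^3.
#' @return Integer count.
#' @export
ion_count <- function(molarity, volume_nm3) {
  as.integer(round(molarity * PARTICLES_PER_NM3_PER_M * volume_nm3))
}

#' Build a graphene sheet with a circular pore
#'
#' Honeycomb lattice in the x-y plane at height `z0`, covering
#' `lx` x `ly` centred on the origin, with atoms inside `pore_radius` of
#' the axis removed.
#'
#' @param lx,ly Sheet extent, Angstrom.
#' @param z0 Sheet height, Angstrom.
#' @param pore_radius Pore radius, Angstrom (0 = no pore).
#' @param cc_bond C-C bond length, Angstrom.
#' @return An `atom_set` of `graphene_C`.
#' @export
build_graphene_sheet <- function(lx, ly, z0 = 0, pore_radius = 0,
                                 cc_bond = 1.42) {
  h <- sqrt(3) / 2 * cc_bond
  rows <- seq(-ceiling(ly / 2 / h), ceiling(ly / 2 / h))
  xs <- function(odd) {
    base <- if (odd) c(1.5, 2.5) * cc_bond else c(0, cc_bond)
    k <- seq(-ceiling(lx / 2 / (3 * cc_bond)) - 1,
             ceiling(lx / 2 / (3 * cc_bond)) + 1)
    as.vector(outer(base, k * 3 * cc_bond, "+"))
  }
  pts <- do.call(rbind, lapply(rows, function(m) {
    cbind(xs(m %% 2 == 1), m * h)
  }))
  keep <- abs(pts[, 1]) <= lx / 2 & abs(pts[, 2]) <= ly / 2
  pts <- pts[keep, , drop = FALSE]
  if (pore_radius > 0) {
    pts <- pts[pts[, 1]^2 + pts[, 2]^2 > pore_radius^2, , drop = FALSE]
  }
  atom_set("C", pts[, 1], pts[, 2], rep(z0, nrow(pts)),
           charge = 0, tag = "graphene_C")
}

#' Assemble the full membrane system around a channel
#'
#' Embeds the channel between two pored graphene sheets at its mouths,
#' fills the two chambers with 3-site water on a jittered cubic lattice
#' at the target density, and replaces random waters with ions at the
#' counts implied by the salt concentrations (Cl- balances all cations,
#' so the solvent is electroneutral).
#'
#' @param channel Decorated channel `atom_set`.
#' @param box_nm Box edges in nm (user-facing; internals are Angstrom).
#' @param salts Named molarities of cation chlorides,
#'   e.g. `c(KCl = 0.5, NaCl = 0.5)`.
#' @param seed RNG seed for lattice jitter and ion placement.
#' @param water_density Target molecules/Angstrom^3 (0.0334 = bulk
#'   water).
#' @param clash_cutoff Minimum allowed heavy-atom distance, Angstrom.
#' @param pore_margin Pore radius margin beyond the tube radius,
#'   Angstrom.
#' @return A `system_model` list: `channel`, `membranes`, `solvent`,
#'   `box` (nm), `concentrations`, `counts`.
#' @export
assemble_membrane_system <- function(channel, box_nm = c(5.1, 5.1, 5.1),
                                     salts = c(KCl = 0.5, NaCl = 0.5),
                                     seed = 1, water_density = 0.0334,
                                     clash_cutoff = 2.4,
                                     pore_margin = 1.6) {
  set.seed(seed)
  box <- box_nm * 10
  halflen <- max(abs(channel$z))
  R <- max(sqrt(channel$x^2 + channel$y^2))
  if (2 * halflen > box[3] - 10 || 2 * R > min(box[1:2])) {
    stop("box too small to contain the channel and sheets")
  }
  sheets <- bind_atoms(
    build_graphene_sheet(box[1], box[2], z0 = -halflen,
                         pore_radius = R + pore_margin),
    build_graphene_sheet(box[1], box[2], z0 = halflen,
                         pore_radius = R + pore_margin)
  )
  # chamber water lattice (outside the membrane slab)
  a_w <- water_density^(-1 / 3)
  gx <- seq(-box[1] / 2 + a_w / 2, box[1] / 2 - a_w / 2, by = a_w)
  gy <- seq(-box[2] / 2 + a_w / 2, box[2] / 2 - a_w / 2, by = a_w)
  gz <- seq(-box[3] / 2 + a_w / 2, box[3] / 2 - a_w / 2, by = a_w)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  grid <- grid[abs(grid[, 3]) > halflen + 1.4, , drop = FALSE]
  grid <- grid + matrix(stats::runif(length(grid), -0.2, 0.2),
                        ncol = 3)
  # drop lattice sites clashing with the structure
  struct <- rbind(as.matrix(channel[, c("x", "y", "z")]),
                  as.matrix(sheets[, c("x", "y", "z")]))
  ok <- rep(TRUE, nrow(grid))
  for (i0 in seq(1, nrow(struct), by = 500)) {
    i1 <- min(i0 + 499, nrow(struct))
    dx <- outer(grid[, 1], struct[i0:i1, 1], "-")
    dy <- outer(grid[, 2], struct[i0:i1, 2], "-")
    dz <- outer(grid[, 3], struct[i0:i1, 3], "-")
    d2 <- dx^2 + dy^2 + dz^2
    ok <- ok & (apply(d2, 1, min) > clash_cutoff^2)
  }
  grid <- grid[ok, , drop = FALSE]
  chamber_height <- box[3] - 2 * (halflen + 1.4)
  vol_nm3 <- box[1] * box[2] * chamber_height / 1000
  cat_counts <- vapply(salts, ion_count, integer(1),
                       volume_nm3 = vol_nm3)
  n_cl <- sum(cat_counts)
  n_ion <- sum(cat_counts) + n_cl
  if (n_ion > nrow(grid)) stop("infeasible packing: too few sites")
  ion_sites <- if (n_ion > 0) sample.int(nrow(grid), n_ion) else integer(0)
  cation_tag <- c(KCl = "ion_K", NaCl = "ion_Na")[names(salts)]
  if (anyNA(cation_tag)) stop("unknown salt(s): only KCl/NaCl supported")
  itags <- c(rep(cation_tag, cat_counts), rep("ion_Cl", n_cl))
  ions <- atom_set(
    element = TAG_ELEMENT[itags],
    x = grid[ion_sites, 1], y = grid[ion_sites, 2],
    z = grid[ion_sites, 3],
    charge = ifelse(itags == "ion_Cl", -1, 1), tag = itags
  )
  wsites <- if (n_ion > 0) grid[-ion_sites, , drop = FALSE] else grid
  solvent <- bind_atoms(make_waters(wsites), ions)
  structure(
    list(channel = channel, membranes = sheets, solvent = solvent,
         box = box_nm, concentrations = salts,
         counts = c(water = nrow(wsites), cat_counts, Cl = n_cl)),
    class = "system_model"
  )
}

make_waters <- function(sites) {
  n <- nrow(sites)
  if (n == 0) return(empty_atom_set())
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  p <- cbind(-u[, 2], u[, 1], 0)
  deg <- sqrt(rowSums(p^2)) < 1e-6
  p[deg, ] <- matrix(rep(c(1, 0, 0), sum(deg)), ncol = 3, byrow = TRUE)
  p <- p / sqrt(rowSums(p^2))
  half <- 104.52 / 2 * pi / 180
  h1 <- sites + 0.9572 * (cos(half) * u + sin(half) * p)
  h2 <- sites + 0.9572 * (cos(half) * u - sin(half) * p)
  atom_set(
    element = rep(c("O", "H", "H"), n),
    x = as.vector(rbind(sites[, 1], h1[, 1], h2[, 1])),
    y = as.vector(rbind(sites[, 2], h1[, 2], h2[, 2])),
    z = as.vector(rbind(sites[, 3], h1[, 3], h2[, 3])),
    charge = rep(c(-0.834, 0.417, 0.417), n),
    tag = rep(c("water_O", "water_H", "water_H"), n),
    mol = rep(seq_len(n), each = 3)
  )
}

#' Flatten a system model to one atom set
#'
#' @param sys A `system_model`.
#' @return An `atom_set` with a `"box"` attribute (Angstrom).
#' @export
system_to_atomset <- function(sys) {
  out <- bind_atoms(sys$channel, sys$membranes, sys$solvent)
  attr(out, "box") <- sys$box * 10
  out
}

#' @export
print.system_model <- function(x, ...) {
  cat(sprintf("<system_model> box %s nm; counts: %s\n",
              paste(x$box, collapse = " x "),
              paste(names(x$counts), x$counts, sep = "=",
                    collapse = ", ")))
  invisible(x)
}
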