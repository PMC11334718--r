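#' Trajectory container
#'
#' A trajectory is a long-format table of tagged particle positions over
#' frames, with a frame interval `dt` (ns) and an orthorhombic box
#' (Angstrom).  Frames are 0-based; times are ns.
#'
#' @param atoms A data.frame/data.table with columns `frame`, `id`,
#'   `element`, `tag`, `x`, `y`, `z` (and optionally `time`).
#' @param dt Frame interval in ns.
#' @param box Numeric length-3 box edge vector in Angstrom, or `NULL`.
#' @return An object of class `md_traj`.
#' @export
new_trajectory <- function(atoms, dt = 0.1, box = NULL) {
  a <- data.table::as.data.table(atoms)
  need <- c("frame", "id", "tag", "x", "y", "z")
  if (!all(need %in% names(a))) {
    stop("trajectory table must have columns ", paste(need, collapse = ", "))
  }
  if (!"element" %in% names(a)) a[, element := TAG_ELEMENT[tag]]
  if (!"time" %in% names(a)) a[, time := frame * dt]
  data.table::setkey(a, frame, id)
  structure(
    list(atoms = a, dt = dt, box = box,
         n_frames = length(unique(a$frame))),
    class = "md_traj"
  )
}

#' @export
print.md_traj <- function(x, ...) {
  cat(sprintf("<md_traj> %d frames, dt = %g ns, %d particles/frame (mean)\n",
              x$n_frames, x$dt, round(nrow(x$atoms) / max(1, x$n_frames))))
  invisible(x)
}

#' Wrap a single snapshot as a one-frame trajectory
#'
#' @param a An `atom_set`.
#' @param box Optional box (Angstrom).
#' @param dt Nominal frame interval (ns).
#' @return An `md_traj` with one frame.
#' @export
snapshot_trajectory <- function(a, box = NULL, dt = 1) {
  d <- data.table::as.data.table(as.data.frame(a))
  d[, frame := 0L]
  d[, id := if ("mol" %in% names(d) && !all(is.na(mol))) {
    paste0(tag, "_", seq_len(.N))
  } else paste0(tag, "_", seq_len(.N))]
  if (is.null(box)) box <- attr(a, "box")
  new_trajectory(d[, .(frame, id, element, tag, x, y, z,
                       mol = if ("mol" %in% names(d)) mol else NA_integer_)],
                 dt = dt, box = box)
}

#' Subsample a trajectory by an integer stride
#'
#' Keeps every `by`-th frame (starting at the first).  Frame numbers and
#' times are preserved.
#'
#' @param traj An `md_traj`.
#' @param by Integer stride >= 1.
#' @return Subsampled `md_traj`.
#' @export
subsample_trajectory <- function(traj, by = 2L) {
  stopifnot(inherits(traj, "md_traj"), by >= 1)
  frames <- sort(unique(traj$atoms$frame))
  keep <- frames[seq(1, length(frames), by = by)]
  new_trajectory(traj$atoms[frame %in% keep], dt = traj$dt * by,
                 box = traj$box)
}
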