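PDB_NAME <- c(wall_C = "C", carbonyl_C = "CC", carbonyl_O = "OC",
              graphene_C = "CG", water_O = "OW", water_H = "HW",
              ion_K = "K", ion_Na = "NA", ion_Cl = "CL")
PDB_RES <- c(wall_C = "CNT", carbonyl_C = "CNT", carbonyl_O = "CNT",
             graphene_C = "GRA", water_O = "WAT", water_H = "WAT",
             ion_K = "ION", ion_Na = "ION", ion_Cl = "ION")
ELEMENT_TAG <- c(C = "wall_C", O = "water_O", H = "water_H",
                 K = "ion_K", Na = "ion_Na", Cl = "ion_Cl")

#' Write coordinates as (multi-frame, extended) XYZ
#'
#' Standard XYZ with two extra columns (group tag, particle id) and a
#' comment line carrying the frame time (ns) and box (Angstrom).
#'
#' @param x An `atom_set` or `md_traj`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(el, xx, yy, zz, tg, id, t, box) {
    writeLines(as.character(length(el)), con)
    writeLines(sprintf("t= %.6f box= %s", t,
                       paste(sprintf("%.3f", box), collapse = " ")), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f %s %s",
                       el, xx, yy, zz, tg, id), con)
  }
  if (inherits(x, "md_traj")) {
    box <- if (is.null(x$box)) c(0, 0, 0) else x$box
    A <- x$atoms
    for (f in sort(unique(A$frame))) {
      d <- A[frame == f]
      emit(d$element, d$x, d$y, d$z, d$tag, d$id, d$time[1], box)
    }
  } else {
    box <- attr(x, "box"); if (is.null(box)) box <- c(0, 0, 0)
    emit(x$element, x$x, x$y, x$z, x$tag,
         paste0("a", seq_len(nrow(x))), 0, box)
  }
  invisible(path)
}

#' Read a (multi-frame) XYZ trajectory
#'
#' Accepts plain 4-column XYZ (tags inferred from elements) or the
#' extended 6-column form written by [write_xyz()].  Frame times come
#' from `t=` on the comment line when present, else frame index times
#' `dt`.
#'
#' @param path Input file.
#' @param dt Fallback frame interval, ns.
#' @return An `md_traj`.
#' @export
read_xyz <- function(path, dt = 0.1) {
  lines <- readLines(path)
  i <- 1; frames <- list(); f <- 0L; box <- NULL; n0 <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    if (is.null(n0)) n0 <- n
    if (n != n0) stop("inconsistent atom counts across frames")
    comment <- lines[i + 1]
    t <- frame_time_from_comment(comment, f, dt)
    b <- box_from_comment(comment)
    if (!is.null(b)) box <- b
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "\\s+")
    ncol <- length(parts[[1]])
    el <- vapply(parts, `[[`, "", 1)
    bad <- setdiff(unique(el), names(ELEMENT_TAG))
    if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
    xx <- as.numeric(vapply(parts, `[[`, "", 2))
    yy <- as.numeric(vapply(parts, `[[`, "", 3))
    zz <- as.numeric(vapply(parts, `[[`, "", 4))
    tg <- if (ncol >= 5) vapply(parts, `[[`, "", 5) else
      unname(ELEMENT_TAG[el])
    id <- if (ncol >= 6) vapply(parts, `[[`, "", 6) else
      paste0("a", seq_len(n))
    frames[[length(frames) + 1]] <- data.table::data.table(
      frame = f, id = id, element = el, tag = tg,
      x = xx, y = yy, z = zz, time = t
    )
    f <- f + 1L
    i <- i + 2 + n
  }
  A <- data.table::rbindlist(frames)
  dts <- unique(round(diff(unique(A$time)), 9))
  new_trajectory(A, dt = if (length(dts) == 1 && dts > 0) dts else dt,
                 box = if (!is.null(box) && any(box > 0)) box else NULL)
}

frame_time_from_comment <- function(s, f, dt) {
  m <- regmatches(s, regexec("t=\\s*([-0-9.eE+]+)", s))[[1]]
  if (length(m) == 2) as.numeric(m[2]) else f * dt
}

box_from_comment <- function(s) {
  m <- regmatches(
    s, regexec("box=\\s*([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)", s)
  )[[1]]
  if (length(m) == 4) as.numeric(m[2:4]) else NULL
}

#' Write coordinates as (multi-model) PDB
#'
#' Fixed-width PDB with tag-specific atom/residue names; partial charges
#' go to the B-factor column when `charges_in_bfactor` (documented
#' convention; occupancy is 1.00).
#'
#' @param x An `atom_set` or `md_traj`.
#' @param path Output file.
#' @param charges_in_bfactor Store charges in the B-factor column.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, charges_in_bfactor = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(el, xx, yy, zz, tg, q, model) {
    writeLines(sprintf("MODEL     %4d", model), con)
    nm <- unname(PDB_NAME[tg]); rs <- unname(PDB_RES[tg])
    b <- if (charges_in_bfactor) q else rep(0, length(q))
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_along(el) %% 100000, nm, rs, seq_along(el) %% 10000,
      xx, yy, zz, 1, b, toupper(el)
    ), con)
    writeLines("ENDMDL", con)
  }
  if (inherits(x, "md_traj")) {
    A <- x$atoms
    q <- if ("charge" %in% names(A)) A$charge else 0
    m <- 1
    for (f in sort(unique(A$frame))) {
      d <- A[frame == f]
      qq <- if ("charge" %in% names(d)) d$charge else rep(0, nrow(d))
      emit(d$element, d$x, d$y, d$z, d$tag, qq, m)
      m <- m + 1
    }
  } else {
    emit(x$element, x$x, x$y, x$z, x$tag, x$charge, 1)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a (multi-model) PDB trajectory
#'
#' Parsed with bio3d; group tags are reconstructed from the atom/residue
#' names written by [write_pdb()] (unknown names fall back to
#' element-based tags).
#'
#' @param path Input file.
#' @param dt Frame interval, ns.
#' @return An `md_traj`.
#' @export
read_pdb_traj <- function(path, dt = 0.1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nm <- trimws(pdb$atom$elety); rs <- trimws(pdb$atom$resid)
  key <- paste(nm, rs)
  known <- stats::setNames(names(PDB_NAME), paste(PDB_NAME, PDB_RES))
  tg <- unname(known[key])
  el <- trimws(pdb$atom$elesy)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
  tg[is.na(tg)] <- unname(ELEMENT_TAG[el[is.na(tg)]])
  if (anyNA(tg)) stop("cannot infer group tags from PDB atom names")
  n <- nrow(pdb$atom)
  frames <- lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    data.table::data.table(
      frame = m - 1L, id = paste0("a", seq_len(n)), element = el,
      tag = tg, x = co[, 1], y = co[, 2], z = co[, 3],
      time = (m - 1) * dt
    )
  })
  new_trajectory(data.table::rbindlist(frames), dt = dt, box = NULL)
}

#' Read a trajectory file
#'
#' @param path Input file.
#' @param format `"xyz"` or `"pdb"` (default: by extension).
#' @param dt Fallback frame interval, ns.
#' @return An `md_traj`.
#' @export
read_trajectory <- function(path, format = NULL, dt = 0.1) {
  if (is.null(format)) {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb"
    else "xyz"
  }
  switch(match.arg(format, c("xyz", "pdb")),
         xyz = read_xyz(path, dt = dt),
         pdb = read_pdb_traj(path, dt = dt))
}

#' Write the per-tag charge table sidecar
#'
#' @param atoms An `atom_set`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_charge_table <- function(atoms, path) {
  d <- unique(data.frame(tag = atoms$tag, charge = atoms$charge))
  d <- d[order(d$tag), ]
  utils::write.table(d, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write umbrella windows as WHAM-style metadata plus series files
#'
#' The metadata file lists one window per line: series path, bias
#' centre, spring constant.  Each series file has two columns (time,
#' z).
#'
#' @param windows List of [umbrella_window()] objects.
#' @param dir Output directory (created if needed).
#' @param dt Nominal sample interval for the time column, ns.
#' @return Path of the metadata file, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir, dt = 0.001) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- file.path(dir, "metadata.txt")
  lines <- character(0)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    p <- file.path(dir, sprintf("window_%03d.txt", i))
    utils::write.table(
      data.frame(time = seq_along(w$samples) * dt, z = w$samples),
      p, sep = " ", row.names = FALSE, col.names = FALSE
    )
    lines <- c(lines, sprintf("%s %.6f %.6f", p, w$center, w$spring_k))
  }
  writeLines(lines, meta)
  invisible(meta)
}

#' Read umbrella windows from WHAM-style metadata
#'
#' @param metafile Metadata file (path, centre, spring per line);
#'   series paths are resolved relative to the metadata file when not
#'   found as given.
#' @param temperature Temperature, K.
#' @return List of [umbrella_window()] objects.
#' @export
read_umbrella_windows <- function(metafile, temperature = 300) {
  lines <- readLines(metafile)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  lapply(lines, function(ln) {
    p <- strsplit(trimws(ln), "\\s+")[[1]]
    f <- p[1]
    if (!file.exists(f)) f <- file.path(dirname(metafile), basename(f))
    d <- utils::read.table(f)
    umbrella_window(center = as.numeric(p[2]),
                    spring_k = as.numeric(p[3]),
                    samples = d[[2]], temperature = temperature)
  })
}

#' Write a PMF profile as a delimited table
#'
#' @param pmf A `pmf_profile`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path) {
  utils::write.table(data.frame(z = pmf$z, pmf = pmf$pmf), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
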