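#' Typed atomic structure
#'
#' An `atom_set` is a plain data.frame with one row per atom and columns
#' `element` (symbol), `x`, `y`, `z` (Angstrom), `charge` (e) and `tag`
#' (group tag from the closed vocabulary, see [atom_tags()]).  An optional
#' `mol` integer column groups atoms into molecules (used for 3-site
#' water).
#'
#' @param element Character vector of element symbols.
#' @param x,y,z Numeric coordinates in Angstrom.
#' @param charge Numeric partial charges in e (default 0).
#' @param tag Character vector of group tags.
#' @param mol Optional integer molecule ids.
#' @return An object of class `atom_set` (a data.frame).
#' @export
atom_set <- function(element, x, y, z, charge = 0, tag, mol = NA_integer_) {
  n <- length(x)
  a <- data.frame(
    element = rep_len(as.character(element), n),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    charge = rep_len(as.numeric(charge), n),
    tag = rep_len(as.character(tag), n),
    mol = rep_len(as.integer(mol), n),
    stringsAsFactors = FALSE
  )
  class(a) <- c("atom_set", "data.frame")
  validate_atom_set(a)
  a
}

#' @rdname atom_set
#' @param a An `atom_set`.
#' @export
validate_atom_set <- function(a) {
  stopifnot(is.data.frame(a))
  need <- c("element", "x", "y", "z", "charge", "tag")
  if (!all(need %in% names(a))) {
    stop("atom_set must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(a) > 0) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z))) {
      stop("atom_set coordinates must be finite")
    }
    bad <- setdiff(unique(a$tag), ATOM_TAGS)
    if (length(bad) > 0) {
      stop("unknown atom tags: ", paste(bad, collapse = ", "))
    }
  }
  invisible(a)
}

#' The closed vocabulary of atom group tags
#' @return Character vector of allowed tags.
#' @export
atom_tags <- function() ATOM_TAGS

#' Combine atom sets
#' @param ... `atom_set` objects.
#' @return A single `atom_set`.
#' @export
bind_atoms <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) !is.null(p) && nrow(p) > 0, TRUE)]
  if (length(parts) == 0) return(empty_atom_set())
  a <- do.call(rbind, lapply(parts, as.data.frame))
  class(a) <- c("atom_set", "data.frame")
  a
}

#' @rdname bind_atoms
#' @export
empty_atom_set <- function() {
  atom_set(character(0), numeric(0), numeric(0), numeric(0),
           numeric(0), character(0), integer(0))
}

#' Net charge of an atom set
#' @param a An `atom_set`.
#' @return Total charge in e.
#' @export
net_charge <- function(a) sum(a$charge)

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("<atom_set> %d atoms, net charge %+0.3f e\n",
              nrow(x), net_charge(x)))
  if (nrow(x) > 0) print(table(x$tag))
  invisible(x)
}
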