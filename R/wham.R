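#' Weighted histogram analysis of umbrella windows
#'
#' Self-consistent WHAM on a 1-D grid: iterates
#' P(z) proportional to sum_i n_i(z) / sum_j N_j exp((F_j - w_j(z))/kT)
#' and F_j = -kT log sum_z P(z) exp(-w_j(z)/kT), with harmonic biases
#' w_j(z) = 0.5 k_j (z - z_j)^2, until the window free energies F_j move
#' by less than `tol`.  The PMF is -kT log P, shifted to zero at the
#' entrance-side bulk reference (mean over the 2 Angstrom nearest the
#' lower boundary of the supported range).  Bins never visited by any
#' window are NA.
#'
#' @param windows List of [umbrella_window()] objects.
#' @param bin_width Histogram bin width, Angstrom.
#' @param temperature Temperature, K.
#' @param tol Convergence tolerance on the F_j, kcal/mol.
#' @param max_iter Iteration cap.
#' @param min_count Minimum total histogram count for a bin to be
#'   treated as supported; sparser bins (window tails beyond the centre
#'   ladder) are reported as NA.
#' @param trim Report the PMF only on the window-centre range (bins
#'   outside `[min(centers), max(centers)]` become NA); tail bins are
#'   reached only by rare excursions whose tiny counts carry exploding
#'   reweighting factors.
#' @return A `pmf_profile` list: `z` (bin centres), `pmf` (kcal/mol),
#'   `window_free_energies`, `converged`, `iterations`.
#' @export
wham <- function(windows, bin_width = 0.1, temperature = 300,
                 tol = 1e-6, max_iter = 1e5, min_count = 25,
                 trim = TRUE) {
  stopifnot(length(windows) >= 1)
  if (any(vapply(windows, function(w) length(w$samples) == 0, TRUE))) {
    stop("empty umbrella window")
  }
  kT <- kT_kcal(temperature)
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  lo <- floor(min(all_s) / bin_width) * bin_width
  hi <- ceiling(max(all_s) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  mids <- edges[-1] - bin_width / 2
  nb <- length(mids); nw <- length(windows)

  H <- vapply(windows, function(w) {
    tabulate(pmin(pmax(floor((w$samples - lo) / bin_width) + 1L, 1L), nb),
             nbins = nb)
  }, numeric(nb))                       # nb x nw counts
  N <- colSums(H)
  centers <- vapply(windows, `[[`, numeric(1), "center")
  springs <- vapply(windows, `[[`, numeric(1), "spring_k")
  W <- 0.5 * sweep(outer(mids, centers, "-")^2, 2, springs, "*")
  B <- exp(-W / kT)                     # nb x nw bias factors

  # windows must form one overlap-connected chain for a joint PMF
  occ <- H > 0
  adj <- crossprod(occ) > 0
  comp <- rep(NA_integer_, nw); ncomp <- 0
  for (i in seq_len(nw)) {
    if (!is.na(comp[i])) next
    ncomp <- ncomp + 1; queue <- i
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[j])) next
      comp[j] <- ncomp
      queue <- c(queue, which(adj[j, ] & is.na(comp)))
    }
  }
  overlap_ok <- ncomp == 1
  if (!overlap_ok) {
    warning("umbrella windows do not overlap (", ncomp,
            " disconnected groups); relative free energies between ",
            "groups are undetermined")
  }

  supported <- rowSums(H) >= max(1, min_count)
  Ftot <- rep(0, nw)
  n_tot <- rowSums(H)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    denom <- as.numeric(B %*% (N * exp(Ftot / kT)))
    P <- n_tot / denom
    P[!supported] <- 0
    P <- P / sum(P)
    Fnew <- -kT * log(colSums(P * B))
    Fnew <- Fnew - Fnew[1]
    if (max(abs(Fnew - Ftot)) < tol) {
      Ftot <- Fnew
      converged <- TRUE
      break
    }
    Ftot <- Fnew
  }
  if (!converged) {
    warning("WHAM did not converge in ", max_iter,
            " iterations (check window overlap)")
  }
  denom <- as.numeric(B %*% (N * exp(Ftot / kT)))
  P <- n_tot / denom
  P[!supported] <- NA
  pmf <- -kT * log(P)
  if (trim) {
    pmf[mids < min(centers) - 1e-9 | mids > max(centers) + 1e-9] <- NA
  }
  ref <- reference_level(mids, pmf)
  pmf <- pmf - ref
  structure(
    list(z = mids, pmf = as.numeric(pmf),
         window_free_energies = Ftot, converged = converged,
         overlap_ok = overlap_ok, iterations = it,
         temperature = temperature, bin_width = bin_width),
    class = "pmf_profile"
  )
}

reference_level <- function(z, pmf, width = 2) {
  ok <- which(is.finite(pmf))
  zmin <- z[ok[1]]
  sel <- ok[z[ok] <= zmin + width]
  mean(pmf[sel])
}

#' Unbiased PMF from a single window (definitional limit)
#'
#' With a single unbiased window WHAM reduces to
#' -kT log(histogram) + const; provided for reference and testing.
#'
#' @param samples Numeric samples.
#' @param bin_width Bin width.
#' @param temperature Temperature, K.
#' @return A `pmf_profile`.
#' @export
unbiased_pmf <- function(samples, bin_width = 0.1, temperature = 300) {
  w <- umbrella_window(center = mean(samples), spring_k = 1e-12,
                       samples = samples, temperature = temperature)
  wham(list(w), bin_width = bin_width, temperature = temperature,
       max_iter = 2, tol = Inf, min_count = 1, trim = FALSE)
}

#' Extract barrier heights from a PMF
#'
#' Stationary points are located from sign changes of the smoothed
#' finite-difference derivative (5-point running mean; ties toward
#' smaller z); shallow wiggles below `min_prominence` are merged away.
#' dE1 is the first maximum above the entrance-side bulk reference; dE2
#' is the second maximum minus the intervening well; later barriers are
#' reported in order as `intersite` and `exit`.  A monotone profile
#' yields a single barrier max - start.
#'
#' @param pmf A `pmf_profile` (or list with `z` and `pmf`).
#' @param min_prominence Minimum height difference for a genuine
#'   extremum, kcal/mol.
#' @return A `barrier_set` list: `dE1`, `dE2`, `barriers` (all maxima
#'   minus their preceding reference), `extrema` (table of stationary
#'   points).
#' @export
extract_barriers <- function(pmf, min_prominence = 0.5) {
  ok <- is.finite(pmf$pmf)
  z <- pmf$z[ok]; f <- pmf$pmf[ok]
  if (length(z) < 7) stop("PMF support too short for barrier extraction")
  fs <- stats::filter(f, rep(1 / 5, 5), sides = 2)
  fs[is.na(fs)] <- f[is.na(fs)]
  fs <- as.numeric(fs)
  d <- diff(fs)
  sgn <- sign(d)
  sgn[sgn == 0] <- 1                      # flat ties resolve uphill
  turns <- which(diff(sgn) != 0) + 1L     # first index past the turn
  kind <- ifelse(diff(sgn)[turns - 1L] < 0, "max", "min")
  # refine on the raw curve near each turn, ties toward smaller z
  idx <- vapply(seq_along(turns), function(k) {
    win <- max(1, turns[k] - 3):min(length(f), turns[k] + 3)
    if (kind[k] == "max") win[which.max(f[win])] else win[which.min(f[win])]
  }, integer(1))
  keep <- !duplicated(idx)
  ex <- data.frame(z = z[idx], value = f[idx], kind = kind)[keep, ,
                                                           drop = FALSE]
  ex <- ex[order(ex$z), , drop = FALSE]
  # simplify: enforce max/min alternation (keep the more extreme of
  # same-kind neighbours), then repeatedly drop the least prominent
  # adjacent pair until every step is a genuine feature
  collapse <- function(e) {
    i <- 1
    while (i < nrow(e)) {
      if (e$kind[i] == e$kind[i + 1]) {
        hi <- e$value[i] >= e$value[i + 1]
        drop <- if (e$kind[i] == "max") {
          if (hi) i + 1 else i
        } else {
          if (hi) i else i + 1
        }
        e <- e[-drop, , drop = FALSE]
      } else {
        i <- i + 1
      }
    }
    e
  }
  ex <- collapse(ex)
  repeat {
    if (nrow(ex) < 2) break
    dv <- abs(diff(ex$value))
    k <- which.min(dv)
    if (dv[k] >= min_prominence) break
    ex <- collapse(ex[-c(k, k + 1), , drop = FALSE])
  }
  bulk <- mean(f[z <= z[1] + 2])
  maxima <- ex[ex$kind == "max", , drop = FALSE]
  if (nrow(maxima) == 0) {
    # monotone profile: single barrier = max - start
    return(structure(list(dE1 = max(f) - f[1], dE2 = NA_real_,
                          barriers = c(entrance = max(f) - f[1]),
                          extrema = ex),
                     class = "barrier_set"))
  }
  heights <- numeric(nrow(maxima))
  labs <- character(nrow(maxima))
  prev_ref <- bulk
  for (i in seq_len(nrow(maxima))) {
    heights[i] <- maxima$value[i] - prev_ref
    labs[i] <- c("entrance", "site1", "intersite", "exit")[min(i, 4)]
    wells <- ex[ex$kind == "min" & ex$z > maxima$z[i], , drop = FALSE]
    prev_ref <- if (nrow(wells) > 0) wells$value[1] else maxima$value[i]
  }
  names(heights) <- make.unique(labs)
  structure(
    list(dE1 = heights[1],
         dE2 = if (length(heights) >= 2) heights[2] else NA_real_,
         barriers = heights, extrema = ex),
    class = "barrier_set"
  )
}
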