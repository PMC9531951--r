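#' Batch baseline noise level
#'
#' Estimates the batch noise level sigma_NOISE as the mean over curves of the
#' standard deviation of the final portion of each force array, after
#' per-curve baseline subtraction. This is the scale that sets both the
#' wavy-tail rejection threshold (2 sigma_NOISE) and the alignment force scale
#' F_scoring = 4 sigma_NOISE.
#'
#' @param curves An [fd_curve_set()].
#' @param tail_fraction Fraction of points (from the end of the array) treated
#'   as the non-contact tail (default 0.2, at least 50 points where available).
#' @return sigma_NOISE in pN. An all-constant batch returns 0 with a warning.
#' @export
estimate_batch_noise <- function(curves, tail_fraction = 0.2) {
  stopifnot(nrow(curves) >= 1, tail_fraction > 0, tail_fraction < 1)
  sds <- purrr::map_dbl(curves$force, function(f) {
    idx <- .tail_indices(length(f), tail_fraction)
    tl <- f[idx] - mean(f[idx])
    stats::sd(tl)
  })
  out <- mean(sds)
  if (out == 0) warning("all-constant batch: sigma_NOISE = 0", call. = FALSE)
  out
}

.tail_indices <- function(n, tail_fraction = 0.2, min_points = 50) {
  k <- min(n, max(ceiling(tail_fraction * n), min_points))
  seq.int(n - k + 1, n)
}

# Locate the contact point: the negative-to-positive zero crossing at the
# smallest separation whose negative segment is a genuine adhesion excursion,
# not baseline noise. Returns the index of the first non-negative point after
# the crossing, or NA.
.find_contact <- function(force, sigma) {
  # the depth requirement scales with the trace's own baseline noise but is
  # capped: a wavy tail inflates the noise estimate, yet a 30 pN adhesion
  # excursion is always a genuine contact signature
  thr <- -min(max(2 * sigma, 5), 30)
  n <- length(force)
  neg <- force < 0
  if (!any(neg)) return(NA_integer_)
  runs <- rle(neg)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  # negative segments followed by a non-negative point, deep enough that the
  # excursion is adhesion rather than baseline noise
  seg <- which(runs$values & ends < n)
  if (length(seg) == 0) return(NA_integer_)
  depth <- vapply(seg, function(k) min(force[starts[k]:ends[k]]), numeric(1))
  cross <- ends[seg][depth <= thr]
  if (length(cross) == 0) return(NA_integer_)
  # scanning from large separation toward the surface, the last crossing
  # encountered is the one at the smallest separation: the adhesion dip at
  # contact precedes the whole unfolding pattern, while crossings at larger
  # separation are rupture valleys or baseline noise
  min(cross) + 1L
}

#' Preprocess a single force-distance curve
#'
#' Block-1 preprocessing: (1) the force baseline is zeroed by subtracting the
#' mean of the non-contact tail; (2) unless the positions are already
#' tip-sample separation, the piezo position is corrected for cantilever
#' bending, `s = z - F/k`; (3) the contact point (last adhesion-backed
#' negative-to-positive force transition) is located and the separation axis
#' shifted so contact sits at 0; (4) the force is linearly interpolated onto a
#' uniform 1-nm grid from 0 to the last measured separation.
#'
#' @param z Position array (nm).
#' @param force Force array (pN).
#' @param spring_constant Cantilever stiffness (pN/nm).
#' @param is_tss `TRUE` when `z` is already tip-sample separation.
#' @param tail_fraction Tail definition passed to the baseline estimate.
#' @param grid Grid spacing in nm (default 1).
#' @return A list with `x` (grid, starting at 0), `force` (pN, zero
#'   baseline), `baseline_sigma` (pN), `length_points` (grid points from
#'   contact to the last point above 30 pN), and `contact_found`.
#' @export
preprocess_trace <- function(z, force, spring_constant = 840, is_tss = FALSE,
                             tail_fraction = 0.2, grid = 1) {
  stopifnot(length(z) == length(force), length(z) >= 2,
            all(is.finite(z)), all(is.finite(force)), spring_constant > 0)
  idx <- .tail_indices(length(force), tail_fraction)
  f0 <- force - mean(force[idx])
  bsig <- stats::sd(f0[idx])
  if (!is.finite(bsig)) bsig <- 0
  s <- if (is_tss) z else z - f0 / spring_constant
  # orient so separation increases away from the surface
  if (s[1] > s[length(s)]) { s <- rev(s); f0 <- rev(f0) }
  if (is.unsorted(s)) {
    o <- order(s)
    if (max(abs(s[o] - s)) > 2) {
      # the bending correction itself broke monotonicity (extreme force
      # excursions): fall back to the uncorrected axis so the range filter
      # can reject the trace; a genuinely unsortable acquisition errors
      if (!is_tss && !is.unsorted(if (z[1] > z[length(z)]) rev(z) else z)) {
        s <- if (z[1] > z[length(z)]) rev(z) else z
      } else {
        stop("unsortable_trace", call. = FALSE)
      }
    } else {
      s <- s[o]; f0 <- f0[o]
    }
  }
  ci <- .find_contact(f0, bsig)
  contact_found <- !is.na(ci)
  x0 <- if (contact_found) s[ci] else s[1]
  s <- s - x0
  keep <- s >= 0
  if (sum(keep) < 2) { # contact at the very end: nothing usable beyond it
    return(list(x = c(0, grid), force = c(0, 0), baseline_sigma = bsig,
                length_points = 0L, contact_found = FALSE,
                max_abs_force = max(abs(f0))))
  }
  s <- s[keep]; fk <- f0[keep]
  xg <- seq(0, max(s), by = grid)
  fg <- approx(s, fk, xout = xg, rule = 2, ties = "ordered")$y
  above <- which(fg > 30)
  list(x = xg, force = fg, baseline_sigma = bsig,
       length_points = if (length(above)) max(above) else 0L,
       contact_found = contact_found, max_abs_force = max(abs(f0)))
}

#' Preprocess a curve set
#'
#' Applies [preprocess_trace()] to every curve and returns one tibble row per
#' curve with list-columns `x` and `force` on the common 1-nm grid.
#'
#' @param curves An [fd_curve_set()].
#' @param tail_fraction Tail definition (see [estimate_batch_noise()]).
#' @param grid Grid spacing in nm.
#' @return A tibble with columns `curve_id`, `x`, `force`, `baseline_sigma`,
#'   `length_points`, `contact_found`.
#' @export
preprocess_curves <- function(curves, tail_fraction = 0.2, grid = 1) {
  pp <- purrr::pmap(curves[c("z", "force", "spring_constant", "is_tss")],
                    function(z, force, spring_constant, is_tss) {
    preprocess_trace(z, force, spring_constant, is_tss,
                     tail_fraction = tail_fraction, grid = grid)
  })
  tibble::tibble(
    curve_id = curves$curve_id,
    x = purrr::map(pp, "x"),
    force = purrr::map(pp, "force"),
    baseline_sigma = purrr::map_dbl(pp, "baseline_sigma"),
    length_points = purrr::map_int(pp, ~ as.integer(.x$length_points)),
    contact_found = purrr::map_lgl(pp, "contact_found"),
    max_abs_force = purrr::map_dbl(pp, "max_abs_force")
  )
}

#' Coarse rejection of spurious traces
#'
#' The Block-1 filter. A preprocessed trace is rejected with reason
#' `no_contact` if it has no detectable contact point (no adhesion-backed
#' negative-to-positive force transition about the zeroed baseline);
#' `force_range` if any raw |force| exceeds 5000 pN; `wavy_tail` if the standard
#' deviation of its non-contact tail about zero exceeds twice the batch noise
#' level. Reasons are checked in that order; the filter is total and
#' deterministic.
#'
#' @param preprocessed Output of [preprocess_curves()].
#' @param sigma_noise Batch noise level (pN) from [estimate_batch_noise()].
#' @param tail_fraction Tail definition, matching the preprocessing.
#' @param force_limit Force-range limit in pN (default 5000).
#' @return A tibble `curve_id`, `kept`, `reason` (`NA` for kept curves).
#' @export
filter_spurious <- function(preprocessed, sigma_noise, tail_fraction = 0.2,
                            force_limit = 5000) {
  stopifnot(sigma_noise >= 0)
  if (!("max_abs_force" %in% names(preprocessed))) {
    preprocessed$max_abs_force <- purrr::map_dbl(preprocessed$force,
                                                 ~ max(abs(.x)))
  }
  res <- purrr::pmap_chr(
    preprocessed[c("force", "contact_found", "max_abs_force")],
    function(force, contact_found, max_abs_force) {
      if (!contact_found) return("no_contact")
      if (max_abs_force > force_limit) return("force_range")
      idx <- .tail_indices(length(force), tail_fraction)
      tail_rms <- sqrt(mean(force[idx]^2))
      if (tail_rms > 2 * sigma_noise) return("wavy_tail")
      NA_character_
    })
  tibble::tibble(curve_id = preprocessed$curve_id,
                 kept = is.na(res), reason = res)
}
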