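#' Alignment configuration
#'
#' Settings for the dynamic-programming global alignment of force profiles.
#' The match/mismatch scale is tied to the batch noise, `F_scoring = 4
#' sigma_NOISE`, so that two forces matching within the noise score close to 1
#' while grossly different forces score negatively. To save quadratic work,
#' the distance is only computed for pairs of traces that plausibly share an
#' unfolding pattern: by default pairs must differ by at most `max_peak_diff`
#' meaningful Lc-histogram peaks AND by at most `max_length_diff` in relative
#' trace length (`prefilter = "or"` restores a literal either/or reading).
#'
#' @param f_scoring Force scale in pN (set it to 4 * sigma_NOISE).
#' @param gap_penalty Additive score per gapped position (default 0).
#' @param max_peak_diff Maximum difference in meaningful peak counts.
#' @param max_length_diff Maximum relative trace-length difference.
#' @param prefilter `"and"` (default) or `"or"` combination of the two rules.
#' @return A list of class `alignment_config`.
#' @export
alignment_config <- function(f_scoring, gap_penalty = 0, max_peak_diff = 2,
                             max_length_diff = 0.20,
                             prefilter = c("and", "or")) {
  stopifnot(f_scoring > 0, gap_penalty <= 0)
  structure(list(f_scoring = f_scoring, gap_penalty = gap_penalty,
                 max_peak_diff = max_peak_diff,
                 max_length_diff = max_length_diff,
                 prefilter = match.arg(prefilter)),
            class = "alignment_config")
}

#' Match/mismatch score for a pair of force values
#'
#' `M = 1 - |Fa - Fb|/F_scoring` when the difference is below `F_scoring`,
#' and `-|Fa - Fb|/F_scoring` otherwise. Bounded above by 1, unbounded below.
#'
#' @param f_a,f_b Forces (pN).
#' @param f_scoring Force scale (pN, > 0).
#' @return The score (vectorised).
#' @export
match_score <- function(f_a, f_b, f_scoring) {
  stopifnot(f_scoring > 0)
  d <- abs(f_a - f_b)
  ifelse(d < f_scoring, 1 - d / f_scoring, -d / f_scoring)
}

#' Alignment distance between two traces
#'
#' `d_ab = 1 - SD(Na, Nb) / N_max`, where `SD` is the optimal global-alignment
#' score of the two force profiles under [match_score()] with a linear gap
#' penalty, and `N_max` the longer of the two lengths. Identical traces have
#' distance 0; the distance is not clamped and may exceed 1 for grossly
#' dissimilar pairs.
#'
#' @param force_a,force_b Force profiles on the common 1-nm grid (pN).
#' @param cfg An [alignment_config()].
#' @return The distance (symmetric in its arguments).
#' @export
pair_distance <- function(force_a, force_b, cfg) {
  if (length(force_a) == 0 || length(force_b) == 0) {
    stop("empty trace", call. = FALSE)
  }
  sd_score <- nw_align_score(force_a, force_b, cfg$f_scoring, cfg$gap_penalty)
  1 - sd_score / max(length(force_a), length(force_b))
}

#' Pairwise distance matrix over scored traces
#'
#' Evaluates [pair_distance()] on the force profile of each trace restricted
#' to its informative region (contact to the last point above the force
#' floor), for every pair passing the prefilter. Non-computed pairs carry
#' `Inf` and are treated as unrelated by the clustering.
#'
#' @param scored Output of [score_traces()] (typically restricted to
#'   quality-passing traces).
#' @param cfg An [alignment_config()].
#' @return An object of class `fd_dist`: list with `ids`, the symmetric
#'   matrix `d` (0 diagonal, `Inf` where not computed), and `computed`
#'   (logical matrix).
#' @export
trace_distances <- function(scored, cfg) {
  n <- nrow(scored)
  ids <- scored$curve_id
  fa <- purrr::map2(scored$force, pmax(scored$length_points, 1L),
                    ~ .x[seq_len(.y)])
  len <- scored$length_points
  npk <- scored$n_peaks
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  computed <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(computed) <- TRUE
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        rel_len <- abs(len[i] - len[j]) / max(len[i], len[j], 1L)
        ok_len <- rel_len <= cfg$max_length_diff
        ok_pk <- abs(npk[i] - npk[j]) <= cfg$max_peak_diff
        ok <- if (cfg$prefilter == "and") ok_len && ok_pk else ok_len || ok_pk
        if (ok) {
          d[i, j] <- d[j, i] <- pair_distance(fa[[i]], fa[[j]], cfg)
          computed[i, j] <- computed[j, i] <- TRUE
        }
      }
    }
  }
  structure(list(ids = ids, d = d, computed = computed), class = "fd_dist")
}
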