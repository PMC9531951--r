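#' Contour-length histogram of a trace
#'
#' Bins the valid contour-length values of a trace into fixed-width bins
#' anchored at 0. The default 8-nm bin is wide enough to absorb deviations
#' from the ideal WLC (persistence-length spread) while keeping unfolding
#' intermediates separated.
#'
#' @param lc Contour-length values (nm); `NA`s are ignored.
#' @param bin_width Bin width in nm (default 8).
#' @return A list of class `lc_histogram` with `bin_edges`, `counts`,
#'   `density` (probability density), `bin_width`, `total_valid`.
#' @export
lc_histogram <- function(lc, bin_width = 8) {
  stopifnot(bin_width > 0)
  lc <- lc[is.finite(lc)]
  if (length(lc) == 0) {
    return(structure(list(bin_edges = c(0, bin_width), counts = 0L,
                          density = 0, bin_width = bin_width,
                          total_valid = 0L),
                     class = "lc_histogram"))
  }
  edges <- seq(0, (floor(max(lc) / bin_width) + 1) * bin_width, by = bin_width)
  counts <- as.integer(table(cut(lc, breaks = edges, right = FALSE,
                                 include.lowest = FALSE)))
  structure(list(bin_edges = edges, counts = counts,
                 density = counts / (length(lc) * bin_width),
                 bin_width = bin_width, total_valid = length(lc)),
            class = "lc_histogram")
}

#' Quality score of a histogram peak
#'
#' A high-quality unfolding intermediate produces an isolated maximum in the
#' contour-length histogram, flanked by deep minima. With
#' `f = (P_left/P_max + P_right/P_max)/2`, the score is `W = exp(-2 f^2)`:
#' 1 for an ideally isolated peak, decaying as the flanking minima fill in.
#'
#' @param p_max Probability density at the maximum (> 0).
#' @param p_left,p_right Densities at the flanking minima (0 for a histogram
#'   edge).
#' @return W in (0, 1].
#' @export
#' @examples
#' peak_score(16, 1, 2)   # well separated: ~0.98
#' peak_score(16, 13, 14) # poorly separated: ~0.24
peak_score <- function(p_max, p_left, p_right) {
  if (any(p_max <= 0)) stop("p_max must be > 0", call. = FALSE)
  f <- (p_left / p_max + p_right / p_max) / 2
  exp(-2 * f^2)
}

#' Detect meaningful peaks in a contour-length histogram
#'
#' Finds local maxima of the histogram and, for each, walks outward to the
#' flanking local minima (the histogram edge counts as a zero-density flank).
#' A maximum is meaningful only if the points under it exceed both an absolute
#' floor (`min_points`, default 5, strict) and a relative floor
#' (`min_fraction` of the trace's valid force measures, default 1%). Each
#' retained peak is scored with [peak_score()]. Plateau maxima resolve to
#' their leftmost bin.
#'
#' @param hist An [lc_histogram()].
#' @param min_points Absolute member-count floor (peak kept if n > min_points).
#' @param min_fraction Relative floor on members as a fraction of all valid
#'   points.
#' @return A tibble with one row per peak: `peak_bin`, `left_min_bin`,
#'   `right_min_bin` (0 / nbins+1 denote the histogram edges), `p_max`,
#'   `p_left`, `p_right`, `n_points`, `w`, `lc_lo`, `lc_hi` (span of member
#'   bins, nm).
#' @export
detect_lc_peaks <- function(hist, min_points = 5, min_fraction = 0.01) {
  counts <- hist$counts
  nb <- length(counts)
  empty <- tibble::tibble(peak_bin = integer(0), left_min_bin = integer(0),
                          right_min_bin = integer(0), p_max = numeric(0),
                          p_left = numeric(0), p_right = numeric(0),
                          n_points = integer(0), w = numeric(0),
                          lc_lo = numeric(0), lc_hi = numeric(0))
  if (hist$total_valid == 0 || all(counts == 0)) return(empty)
  cp <- c(0L, counts, 0L) # zero-padded: edges act as zero-density flanks
  np <- length(cp)
  # local maxima on padded counts, plateaus resolved to their leftmost bin
  is_max <- logical(np)
  i <- 2L
  while (i <= np - 1L) {
    if (cp[i] > cp[i - 1L]) {
      j <- i
      while (j < np && cp[j + 1L] == cp[j]) j <- j + 1L
      if (j < np && cp[j + 1L] < cp[j]) is_max[i] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  maxima <- which(is_max)
  if (length(maxima) == 0) return(empty)
  rows <- purrr::map(maxima, function(m) {
    l <- m
    while (l > 1L && cp[l - 1L] <= cp[l]) l <- l - 1L
    r <- m
    while (r < np && cp[r + 1L] <= cp[r]) r <- r + 1L
    members <- seq.int(l + 1L, r - 1L)
    n_pts <- sum(cp[members])
    tibble::tibble(
      peak_bin = m - 1L, left_min_bin = l - 1L, right_min_bin = r - 1L,
      p_max = cp[m] / (hist$total_valid * hist$bin_width),
      p_left = cp[l] / (hist$total_valid * hist$bin_width),
      p_right = cp[r] / (hist$total_valid * hist$bin_width),
      n_points = as.integer(n_pts),
      # members are padded indices; real bin b spans edges [b, b+1]
      lc_lo = hist$bin_edges[members[1] - 1L],
      lc_hi = hist$bin_edges[members[length(members)]]
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::filter(out, .data$n_points > min_points,
                       .data$n_points > min_fraction * hist$total_valid)
  out$w <- peak_score(out$p_max, out$p_left, out$p_right)
  out[c("peak_bin", "left_min_bin", "right_min_bin", "p_max", "p_left",
        "p_right", "n_points", "w", "lc_lo", "lc_hi")]
}

# per-point score assignment for one trace
.point_scores <- function(x, force, lc, peaks, force_floor = 30,
                          low_force_window = 75) {
  n <- length(x)
  scores <- numeric(n)
  if (nrow(peaks) > 0) {
    for (p in seq_len(nrow(peaks))) {
      inpeak <- is.finite(lc) & lc >= peaks$lc_lo[p] & lc < peaks$lc_hi[p]
      scores[inpeak] <- peaks$w[p]
    }
  }
  # sub-floor points inherit the score of the next above-floor point,
  # provided that point lies within the low-force window
  above <- force > force_floor
  if (any(above)) {
    # nxt[i]: nearest index j >= i with force above the floor (Inf if none)
    nxt <- rev(cummin(rev(ifelse(above, seq_len(n), Inf))))
    low <- which(!above & is.finite(nxt))
    if (length(low) > 0) {
      j <- nxt[low]
      ok <- (x[j] - x[low]) <= low_force_window
      scores[low[ok]] <- scores[j[ok]]
    }
  }
  scores
}

#' Score traces against the WLC model
#'
#' Block-2 quality scoring. For each preprocessed trace: its contour-length
#' profile is computed ([trace_lc_profile()]), binned ([lc_histogram()]), and
#' its meaningful peaks detected and scored ([detect_lc_peaks()]). Each grid
#' point under a peak inherits that peak's score W; each sub-30-pN point (no
#' contour length computable there) inherits the score of the next
#' above-30-pN point when that point lies within 75 nm; all other points score
#' 0. The trace quality ratio is the summed score divided by the trace length
#' in grid points (contact to last point above 30 pN); traces below 0.5 are
#' flagged for discarding.
#'
#' @param preprocessed Output of [preprocess_curves()].
#' @param params [wlc_params()].
#' @param bin_width Histogram bin width (nm).
#' @param min_points,min_fraction Peak meaningfulness rules
#'   (see [detect_lc_peaks()]).
#' @param low_force_window Window (nm) for propagating scores to sub-floor
#'   points (default 75).
#' @param quality_min Quality-ratio cut below which a trace is flagged
#'   (default 0.5).
#' @return The input tibble with added list-columns `lc`, `point_scores`,
#'   `peaks` (per-trace peak tibble) and scalar columns `n_peaks`, `s_w`,
#'   `quality_ratio`, `keep_quality`.
#' @export
score_traces <- function(preprocessed, params = wlc_params(), bin_width = 8,
                         min_points = 5, min_fraction = 0.01,
                         low_force_window = 75, quality_min = 0.5) {
  res <- purrr::pmap(preprocessed[c("x", "force", "length_points")],
                     function(x, force, length_points) {
    lc <- wlc_contour_length(x, force, params)
    hist <- lc_histogram(lc, bin_width)
    peaks <- detect_lc_peaks(hist, min_points, min_fraction)
    scores <- .point_scores(x, force, lc, peaks,
                            force_floor = params$force_min,
                            low_force_window = low_force_window)
    s_w <- sum(scores)
    list(lc = lc, peaks = peaks, scores = scores, s_w = s_w,
         qr = if (length_points > 0) s_w / length_points else 0)
  })
  out <- preprocessed
  out$lc <- purrr::map(res, "lc")
  out$peaks <- purrr::map(res, "peaks")
  out$point_scores <- purrr::map(res, "scores")
  out$n_peaks <- purrr::map_int(res, ~ nrow(.x$peaks))
  out$s_w <- purrr::map_dbl(res, "s_w")
  out$quality_ratio <- purrr::map_dbl(res, "qr")
  out$keep_quality <- out$quality_ratio >= quality_min
  out
}
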