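# Index of the last local force maximum above the floor. A 5-point running
# mean is applied first so isolated baseline-noise excursions past the floor
# do not register as rupture peaks; the raw grid index of the smoothed
# maximum is returned.
.last_peak_index <- function(force, floor = 30, smooth = 5) {
  n <- length(force)
  if (n < 3) return(NA_integer_)
  f <- if (n > smooth) {
    as.numeric(stats::filter(force, rep(1 / smooth, smooth), sides = 2))
  } else force
  f[is.na(f)] <- force[is.na(f)]
  is_pk <- f > floor & f >= c(-Inf, f[-n]) & f > c(f[-1], -Inf)
  idx <- which(is_pk)
  if (length(idx) == 0) return(NA_integer_)
  max(idx)
}

# 5 nm x 5 pN cell keys for the eligible points of a trace
.aos_cells <- function(x, force, x_limit, floor = 30,
                       cell_x = 5, cell_y = 5) {
  sel <- force > floor & x < x_limit
  if (!any(sel)) return(character(0))
  unique(paste(floor(x[sel] / cell_x), floor(force[sel] / cell_y), sep = ":"))
}

#' Area of similarity around a cluster center
#'
#' The center trace and its two nearest computed neighbours are superimposed
#' in the separation/force plane; every point above 30 pN and before the
#' center's last force peak stamps a 5 nm x 5 pN cell. The union of stamped
#' cells is the cluster's effective envelope, against which all curves are
#' subsequently scored. Cell membership is exact integer arithmetic
#' (`floor(value/step)`), so there is no floating boundary ambiguity.
#'
#' @param center A one-row slice of the scored-trace tibble (the center).
#' @param neighbors Zero-, one- or two-row slice with the nearest neighbours.
#' @param floor Force floor in pN (default 30).
#' @param cell_x,cell_y Cell size (nm, pN).
#' @return A list of class `aos`: `cells` (character keys), `L` (separation
#'   of the center's last peak, nm), `source_ids`, `flagged` (fewer than two
#'   neighbours available).
#' @export
build_aos <- function(center, neighbors, floor = 30, cell_x = 5, cell_y = 5) {
  li <- .last_peak_index(center$force[[1]], floor)
  if (is.na(li)) stop("center trace has no force peak above the floor",
                      call. = FALSE)
  L <- center$x[[1]][li]
  traces <- dplyr::bind_rows(center, neighbors)
  cells <- unique(unlist(purrr::map2(
    traces$x, traces$force,
    ~ .aos_cells(.x, .y, x_limit = L, floor = floor,
                 cell_x = cell_x, cell_y = cell_y))))
  structure(list(cells = cells, L = L,
                 source_ids = traces$curve_id,
                 flagged = nrow(neighbors) < 2,
                 floor = floor, cell_x = cell_x, cell_y = cell_y),
            class = "aos")
}

# Knee of a descending score curve: optimal breakpoint of a two-segment
# piecewise-linear least-squares fit. The knee is only a genuine threshold
# when the two slopes actually differ (the "two different slopes" signature);
# for a homogeneous population decaying at a single rate there is no slope
# change and no curve should be cut. Returns list(index, real).
.knee_index <- function(y, slope_ratio_min = 3) {
  n <- length(y)
  if (n < 4) return(list(index = n, real = FALSE))
  xs <- seq_len(n)
  seg_fit <- function(idx) {
    f <- stats::lm.fit(cbind(1, xs[idx]), y[idx])
    list(sse = sum(f$residuals^2), slope = f$coefficients[2])
  }
  cand <- 2:(n - 1)
  fits <- purrr::map(cand, function(b) {
    a <- seg_fit(1:b); c <- seg_fit(b:n)
    list(sse = a$sse + c$sse, s1 = a$slope, s2 = c$slope)
  })
  best <- which.min(purrr::map_dbl(fits, "sse"))
  s1 <- abs(fits[[best]]$s1); s2 <- abs(fits[[best]]$s2)
  list(index = cand[best],
       real = is.finite(s1) && s2 >= slope_ratio_min * max(s1, 1e-12))
}

#' Similarity scores and knee threshold against an area of similarity
#'
#' Candidates are first length-filtered: their final force peak must fall
#' between 0.7 and 1.3 times the center length `L`. Each surviving curve is
#' scored by the number of its grid points (above 30 pN, before its own last
#' peak) that land in occupied cells. Sorted in descending order the scores
#' form two slopes; the breakpoint of a two-segment least-squares fit defines
#' the similarity threshold, and curves scoring strictly above it belong to
#' the refined cluster.
#'
#' @param aos An [build_aos()] object.
#' @param candidates Scored-trace tibble (all traces, not just cluster
#'   members).
#' @return A list: `scores` (tibble `curve_id`, `score`, `eligible`),
#'   `threshold`, `above_ids`, `flagged` (fewer than 3 eligible candidates).
#' @export
similarity_threshold <- function(aos, candidates) {
  lastpk <- purrr::map_dbl(seq_len(nrow(candidates)), function(i) {
    li <- .last_peak_index(candidates$force[[i]], aos$floor)
    if (is.na(li)) NA_real_ else candidates$x[[i]][li]
  })
  eligible <- !is.na(lastpk) & lastpk >= 0.7 * aos$L & lastpk <= 1.3 * aos$L
  score <- rep(NA_real_, nrow(candidates))
  for (i in which(eligible)) {
    xi <- candidates$x[[i]]; fi <- candidates$force[[i]]
    sel <- fi > aos$floor & xi < lastpk[i]
    if (!any(sel)) { score[i] <- 0; next }
    keys <- paste(floor(xi[sel] / aos$cell_x),
                  floor(fi[sel] / aos$cell_y), sep = ":")
    score[i] <- sum(keys %in% aos$cells)
  }
  tab <- tibble::tibble(curve_id = candidates$curve_id,
                        score = score, eligible = eligible)
  el <- dplyr::arrange(dplyr::filter(tab, eligible), dplyr::desc(score))
  if (nrow(el) < 3) {
    return(list(scores = tab, threshold = 0,
                above_ids = el$curve_id, flagged = TRUE))
  }
  kn <- .knee_index(el$score)
  # with no genuine slope change the population is one pattern; retain curves
  # sharing at least a quarter of the envelope (relative to the upper scores)
  thr <- if (kn$real) el$score[kn$index] else
    0.25 * stats::quantile(el$score, 0.9, names = FALSE)
  list(scores = tab, threshold = thr,
       above_ids = el$curve_id[el$score > thr], flagged = FALSE)
}

#' Merge refined clusters sharing members
#'
#' Clusters (with their above-threshold member sets) are processed largest
#' first. A cluster is merged into the earliest retained cluster with which it
#' shares more than `overlap_min` of the smaller member set. Stopping rule:
#' once four consecutive clusters have merged and every remaining unprocessed
#' cluster has fewer than 3 members, processing stops and those residual
#' clusters are dropped (reported in the merge log, not silently lost).
#'
#' @param above_sets Named list: cluster id -> character vector of member ids.
#' @param overlap_min Overlap fraction that triggers a merge (default 0.40).
#' @return A list: `clusters` (named list of merged member sets),
#'   `merge_log` (tibble of decisions), `dropped` (ids dropped by the
#'   stopping rule).
#' @export
merge_clusters <- function(above_sets, overlap_min = 0.40) {
  ord <- order(-purrr::map_int(above_sets, length))
  ids <- names(above_sets)[ord]
  retained <- list()
  log <- list()
  consecutive <- 0L
  dropped <- character(0)
  for (pos in seq_along(ids)) {
    cid <- ids[pos]
    set <- above_sets[[cid]]
    target <- NA_character_; ov <- NA_real_
    for (rid in names(retained)) {
      shared <- length(intersect(set, retained[[rid]]))
      denom <- min(length(set), length(retained[[rid]]))
      frac <- if (denom > 0) shared / denom else 0
      if (frac > overlap_min) { target <- rid; ov <- frac; break }
    }
    if (!is.na(target)) {
      retained[[target]] <- union(retained[[target]], set)
      consecutive <- consecutive + 1L
      log[[length(log) + 1]] <- tibble::tibble(
        cluster = cid, action = "merged", into = target, overlap = ov)
      if (consecutive >= 4L && pos < length(ids)) {
        remaining <- ids[(pos + 1L):length(ids)]
        if (all(purrr::map_int(above_sets[remaining], length) < 3)) {
          dropped <- remaining
          log[[length(log) + 1]] <- tibble::tibble(
            cluster = paste(remaining, collapse = ","),
            action = "dropped", into = NA_character_, overlap = NA_real_)
          break
        }
      }
    } else {
      retained[[cid]] <- set
      consecutive <- 0L
      log[[length(log) + 1]] <- tibble::tibble(
        cluster = cid, action = "retained", into = NA_character_,
        overlap = NA_real_)
    }
  }
  list(clusters = retained,
       merge_log = if (length(log)) dplyr::bind_rows(log) else
         tibble::tibble(cluster = character(0), action = character(0),
                        into = character(0), overlap = numeric(0)),
       dropped = dropped)
}

#' Observables of a refined cluster
#'
#' Pools the valid contour-length values of the member traces into an 8-nm
#' histogram and reports: `lc_max`, the contour length of the rightmost
#' meaningful peak (same meaningfulness rule as trace scoring; falls back to
#' the 95th percentile of member final-peak contour lengths when no pooled
#' peak qualifies); `mean_force`, the mean rupture-peak force over members;
#' and `peak_profile`, the pooled histogram restricted to points with force
#' between 40 and 100 pN, normalised to unit area — the unfolding-barrier
#' fingerprint fed to the Bayesian identification.
#'
#' @param members Scored-trace tibble slice of the cluster members.
#' @param bin_width Histogram bin width (nm, default 8).
#' @param profile_band Force band (pN) retained in the peak profile.
#' @param floor Force floor for rupture peaks (pN).
#' @return A list of class `cluster_observables`: `lc_max`, `mean_force`,
#'   `peak_profile` (tibble `lc_mid`, `density`), `n_members`,
#'   `lc_max_fallback`.
#' @export
cluster_observables <- function(members, bin_width = 8,
                                profile_band = c(40, 100), floor = 30) {
  stopifnot(nrow(members) >= 1)
  lc_all <- unlist(members$lc)
  lc_all <- lc_all[is.finite(lc_all)]
  hist <- lc_histogram(lc_all, bin_width)
  peaks <- detect_lc_peaks(hist)
  fallback <- FALSE
  if (nrow(peaks) > 0) {
    pk <- peaks[which.max(peaks$peak_bin), ]
    lc_max <- hist$bin_edges[pk$peak_bin] + bin_width / 2
  } else {
    fallback <- TRUE
    finpk <- purrr::map_dbl(seq_len(nrow(members)), function(i) {
      li <- .last_peak_index(members$force[[i]], floor)
      if (is.na(li)) return(NA_real_)
      lc <- members$lc[[i]]
      near <- lc[seq(max(1, li - 5), min(length(lc), li))]
      near <- near[is.finite(near)]
      if (length(near)) max(near) else NA_real_
    })
    lc_max <- stats::quantile(finpk, 0.95, na.rm = TRUE, names = FALSE)
  }
  # rupture force per unfolding intermediate: the force maximum among the
  # points of each meaningful Lc peak (the top of the WLC branch); traces
  # without meaningful peaks fall back to raw local maxima above the floor
  rupture <- purrr::map(seq_len(nrow(members)), function(i) {
    f <- members$force[[i]]; lc <- members$lc[[i]]
    pks <- if ("peaks" %in% names(members)) members$peaks[[i]] else NULL
    if (!is.null(pks) && nrow(pks) > 0) {
      vapply(seq_len(nrow(pks)), function(p) {
        sel <- is.finite(lc) & lc >= pks$lc_lo[p] & lc < pks$lc_hi[p]
        if (any(sel)) max(f[sel]) else NA_real_
      }, numeric(1))
    } else {
      n <- length(f)
      pk <- which(f > floor & f >= c(-Inf, f[-n]) & f > c(f[-1], -Inf))
      f[pk]
    }
  })
  mean_force <- mean(unlist(rupture), na.rm = TRUE)
  band_lc <- unlist(purrr::map2(members$lc, members$force, function(lc, f) {
    lc[is.finite(lc) & f >= profile_band[1] & f <= profile_band[2]]
  }))
  ph <- lc_histogram(band_lc, bin_width)
  profile <- tibble::tibble(
    lc_mid = utils::head(ph$bin_edges, -1) + bin_width / 2,
    density = ph$density)
  structure(list(lc_max = lc_max, mean_force = mean_force,
                 peak_profile = profile, n_members = nrow(members),
                 lc_max_fallback = fallback),
            class = "cluster_observables")
}

#' Refine a density-peak clustering
#'
#' Block-5 refinement: for each cluster center an area of similarity is built
#' from the center and its two nearest computed neighbours
#' ([build_aos()]), all traces are scored against it and thresholded at the
#' knee of the descending score curve ([similarity_threshold()]), clusters
#' sharing more than 40% of their above-threshold traces are merged
#' ([merge_clusters()]), and per-cluster observables are computed.
#'
#' @param clustering An `smfs_clustering` from [cluster_traces()].
#' @param scored Scored-trace tibble covering (at least) the clustered ids.
#' @param dist The `fd_dist` used for clustering (for nearest neighbours).
#' @param overlap_min Merge threshold (default 0.40).
#' @param min_members Clusters smaller than this after refinement are dropped
#'   (default 3).
#' @return An object of class `smfs_refined`: `clusters` (tibble
#'   `cluster_id`, `n_members`, `members` list-column), `observables` (tibble
#'   with `lc_max`, `mean_force`, `n_members`, `peak_profile` list-column),
#'   `merge_log`, `thresholds`, `dropped`.
#' @export
refine_clusters <- function(clustering, scored, dist, overlap_min = 0.40,
                            min_members = 3) {
  scored <- scored[match(dist$ids, scored$curve_id), ]
  above_sets <- list()
  thresholds <- numeric(0)
  for (cid in clustering$centers) {
    i <- match(cid, dist$ids)
    dd <- dist$d[i, -i]
    dd <- dd[is.finite(dd)]
    nb_ids <- names(sort(dd))[seq_len(min(2, length(dd)))]
    aos <- build_aos(scored[i, , drop = FALSE],
                     scored[match(nb_ids, scored$curve_id), , drop = FALSE])
    st <- similarity_threshold(aos, scored)
    above_sets[[cid]] <- st$above_ids
    thresholds[cid] <- st$threshold
  }
  merged <- merge_clusters(above_sets, overlap_min = overlap_min)
  keep <- purrr::map_int(merged$clusters, length) >= min_members
  clusters <- merged$clusters[keep]
  cl_tbl <- tibble::tibble(
    cluster_id = names(clusters),
    n_members = purrr::map_int(clusters, length),
    members = unname(clusters))
  obs <- purrr::map(clusters, function(mem) {
    cluster_observables(scored[match(mem, scored$curve_id), , drop = FALSE])
  })
  obs_tbl <- tibble::tibble(
    cluster_id = names(clusters),
    n_members = purrr::map_int(obs, "n_members"),
    lc_max = purrr::map_dbl(obs, "lc_max"),
    mean_force = purrr::map_dbl(obs, "mean_force"),
    lc_max_fallback = purrr::map_lgl(obs, "lc_max_fallback"),
    peak_profile = purrr::map(obs, "peak_profile"))
  structure(list(clusters = cl_tbl, observables = obs_tbl,
                 merge_log = merged$merge_log, thresholds = thresholds,
                 dropped = union(merged$dropped,
                                 names(merged$clusters)[!keep])),
            class = "smfs_refined")
}

#' @export
print.smfs_refined <- function(x, ...) {
  cat(sprintf("Refined clustering: %d clusters\n", nrow(x$clusters)))
  if (nrow(x$observables) > 0) {
    print(x$observables[c("cluster_id", "n_members", "lc_max", "mean_force")])
  }
  invisible(x)
}
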