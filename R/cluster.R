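#' k-NN log-density of each trace
#'
#' Density-peak clustering needs only density ranks, so the density is taken
#' as `rho_i = -log r_{k,i}` with `r_{k,i}` the distance to the k-th nearest
#' computed neighbour — a monotone transform of the k-NN density estimate that
#' sidesteps estimating the intrinsic dimension. Each density is weighted by
#' the trace's quality ratio so high-quality traces dominate center selection.
#'
#' @param dist An `fd_dist` from [trace_distances()].
#' @param k Neighbour count; `NULL` uses `max(10, ceiling(sqrt(N)))`.
#' @param quality Per-trace quality ratios aligned with `dist$ids`
#'   (default 1).
#' @return A tibble `curve_id`, `r_k`, `rho`, `n_neighbors`,
#'   `short_neighborhood` (fewer than k computed neighbours available).
#' @export
knn_density <- function(dist, k = NULL, quality = 1) {
  n <- length(dist$ids)
  if (is.null(k)) k <- max(10, ceiling(sqrt(n)))
  if (k <= 0) stop("k must be positive", call. = FALSE)
  quality <- rep_len(quality, n)
  pos <- dist$d[is.finite(dist$d) & dist$d > 0]
  tiny <- if (length(pos)) min(pos) * 1e-3 else 1e-6
  res <- purrr::map(seq_len(n), function(i) {
    dd <- dist$d[i, -i]
    dd <- dd[is.finite(dd)]
    m <- length(dd)
    if (m == 0) return(list(r = NA_real_, m = 0L))
    dd <- sort(dd)
    r <- dd[min(k, m)]
    if (r == 0) r <- tiny # duplicate traces
    list(r = r, m = m)
  })
  r_k <- purrr::map_dbl(res, "r")
  nn <- purrr::map_int(res, "m")
  rho <- ifelse(is.na(r_k), -Inf, quality * (-log(r_k)))
  tibble::tibble(curve_id = dist$ids, r_k = r_k, rho = rho,
                 n_neighbors = nn, short_neighborhood = nn < k)
}

# strict "higher density" order with ties broken by position (earlier wins)
.density_rank_order <- function(rho) {
  order(-rho, seq_along(rho))
}

#' Distance to the nearest higher-density trace
#'
#' For each trace, `delta_i` is the minimum computed distance to any trace of
#' strictly higher density (density ties broken by trace order). The global
#' density maximum — and any trace with no computed path to a denser trace —
#' takes the maximum computed distance in the matrix, so that each connected
#' component's density maximum can surface as a center candidate.
#'
#' @param rho Densities from [knn_density()] (vector aligned with
#'   `dist$ids`).
#' @param dist An `fd_dist`.
#' @return A tibble `curve_id`, `delta`, `nearest_higher` (id or `NA`).
#' @export
local_delta <- function(rho, dist) {
  n <- length(rho)
  dmax <- max(dist$d[is.finite(dist$d)], 0)
  ord <- .density_rank_order(rho)
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)
  delta <- numeric(n); nearest <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    higher <- which(rank_of < rank_of[i])
    if (length(higher) == 0) { delta[i] <- dmax; next }
    dd <- dist$d[i, higher]
    if (all(!is.finite(dd))) { delta[i] <- dmax; next }
    j <- higher[which.min(dd)]
    delta[i] <- dd[which.min(dd)]
    nearest[i] <- dist$ids[j]
  }
  tibble::tibble(curve_id = dist$ids, delta = delta, nearest_higher = nearest)
}

#' Select cluster centers by descending gamma
#'
#' Candidates are scanned by descending `gamma = rho * delta`; a trace becomes
#' a center iff its distance to every previously accepted center is at least
#' `r_cut` (non-computed distances count as infinite, i.e. separated).
#' `r_cut` is the distance below which two traces are on average the same
#' unfolding pattern.
#'
#' @param gamma Per-trace gamma aligned with `dist$ids`.
#' @param dist An `fd_dist`.
#' @param r_cut Center separation threshold (default 0.3).
#' @return Character vector of center ids, in acceptance order.
#' @export
select_centers <- function(gamma, dist, r_cut = 0.3) {
  ord <- order(-gamma, seq_along(gamma))
  centers <- integer(0)
  for (i in ord) {
    if (length(centers) == 0) { centers <- i; next }
    dd <- dist$d[i, centers]
    dd[!is.finite(dd)] <- Inf
    if (all(dd >= r_cut)) centers <- c(centers, i)
  }
  dist$ids[centers]
}

#' Assign non-center traces to clusters
#'
#' Traces are processed in order of decreasing density; every non-center
#' inherits the label of its nearest computed neighbour of strictly higher
#' density, so assignments chain down the density landscape from each center.
#' Traces with no computed higher-density neighbour are left unassigned
#' (label `NA`) — these are the statistically isolated events the clustering
#' deliberately drops.
#'
#' @param rho Densities aligned with `dist$ids`.
#' @param dist An `fd_dist`.
#' @param centers Center ids from [select_centers()].
#' @return A tibble `curve_id`, `label` (center id or `NA`).
#' @export
assign_clusters <- function(rho, dist, centers) {
  n <- length(rho)
  labels <- rep(NA_character_, n)
  labels[match(centers, dist$ids)] <- centers
  nh <- local_delta(rho, dist)$nearest_higher
  ord <- .density_rank_order(rho)
  for (i in ord) {
    if (!is.na(labels[i])) next
    if (!is.na(nh[i])) labels[i] <- labels[match(nh[i], dist$ids)]
  }
  tibble::tibble(curve_id = dist$ids, label = labels)
}

#' Density-peak clustering of scored traces
#'
#' Runs the full density-peak procedure on a distance matrix: k-NN
#' log-density weighted by trace quality, nearest-higher-density distance
#' delta, center selection by descending `gamma = rho * delta` under the
#' `r_cut` separation rule, and chained assignment.
#'
#' @param dist An `fd_dist` from [trace_distances()].
#' @param quality Per-trace quality ratios aligned with `dist$ids`.
#' @param k Neighbour count (`NULL` = `max(10, ceiling(sqrt(N)))`).
#' @param r_cut Center separation threshold (default 0.3).
#' @return An object of class `smfs_clustering`: list with `points` (tibble
#'   `curve_id`, `rho`, `delta`, `gamma`, `label`, `is_center`), `centers`,
#'   `k`, `r_cut`.
#' @export
cluster_traces <- function(dist, quality = 1, k = NULL, r_cut = 0.3) {
  dens <- knn_density(dist, k = k, quality = quality)
  del <- local_delta(dens$rho, dist)
  gamma <- dens$rho * del$delta
  centers <- select_centers(gamma, dist, r_cut = r_cut)
  lab <- assign_clusters(dens$rho, dist, centers)
  pts <- tibble::tibble(curve_id = dist$ids, rho = dens$rho,
                        delta = del$delta, gamma = gamma,
                        label = lab$label,
                        is_center = dist$ids %in% centers)
  structure(list(points = pts, centers = centers,
                 k = if (is.null(k)) max(10, ceiling(sqrt(length(dist$ids)))) else k,
                 r_cut = r_cut),
            class = "smfs_clustering")
}

#' @export
print.smfs_clustering <- function(x, ...) {
  cat(sprintf("Density-peak clustering: %d traces, %d centers (k = %d, r_cut = %.2f)\n",
              nrow(x$points), length(x$centers), x$k, x$r_cut))
  cat(sprintf("  assigned: %d, unassigned: %d\n",
              sum(!is.na(x$points$label)), sum(is.na(x$points$label))))
  invisible(x)
}
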