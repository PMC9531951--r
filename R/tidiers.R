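#' Tidy a density-peak clustering
#'
#' @param x An `smfs_clustering`.
#' @param ... Unused.
#' @return A tibble with one row per trace: `curve_id`, `rho`, `delta`,
#'   `gamma`, `label`, `is_center`.
#' @export
tidy.smfs_clustering <- function(x, ...) x$points

#' One-row summary of a density-peak clustering
#'
#' @param x An `smfs_clustering`.
#' @param ... Unused.
#' @return A one-row tibble: `n_traces`, `n_centers`, `n_assigned`,
#'   `n_unassigned`, `k`, `r_cut`.
#' @export
glance.smfs_clustering <- function(x, ...) {
  tibble::tibble(n_traces = nrow(x$points),
                 n_centers = length(x$centers),
                 n_assigned = sum(!is.na(x$points$label)),
                 n_unassigned = sum(is.na(x$points$label)),
                 k = x$k, r_cut = x$r_cut)
}

#' Tidy a refined clustering
#'
#' @param x An `smfs_refined`.
#' @param ... Unused.
#' @return The observables tibble (one row per cluster).
#' @export
tidy.smfs_refined <- function(x, ...) {
  x$observables[c("cluster_id", "n_members", "lc_max", "mean_force")]
}

#' One-row summary of a refined clustering
#'
#' @param x An `smfs_refined`.
#' @param ... Unused.
#' @return A one-row tibble: `n_clusters`, `n_traces`, `n_merged`,
#'   `n_dropped`.
#' @export
glance.smfs_refined <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_traces = sum(x$clusters$n_members),
    n_merged = if (!is.null(x$merge_log)) sum(x$merge_log$action == "merged")
               else 0L,
    n_dropped = length(x$dropped))
}

#' One-row summary of a pipeline run
#'
#' @param x An `smfs_run`.
#' @param ... Unused.
#' @return A one-row tibble of per-stage counts plus `sigma_noise`.
#' @export
glance.smfs_run <- function(x, ...) {
  tibble::tibble(ingested = x$counts$ingested,
                 kept_block1 = x$counts$kept_block1,
                 kept_quality = x$counts$kept_quality,
                 clustered = x$counts$clustered,
                 n_clusters = x$counts$refined_clusters,
                 sigma_noise = x$sigma_noise)
}

#' Decision graph of a density-peak clustering
#'
#' Plots delta against rho; cluster centers sit in the upper right (high
#' density, far from any denser trace).
#'
#' @param object An `smfs_clustering`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smfs_clustering <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$rho, y = .data$delta,
                               colour = .data$is_center)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red3"),
                                 name = "center") +
    ggplot2::labs(x = expression(rho ~ "(quality-weighted k-NN log-density)"),
                  y = expression(delta ~ "(distance to nearest denser trace)"),
                  title = "Density-peak decision graph")
}

#' Cluster observables overview
#'
#' Bar chart of refined cluster sizes, annotated with the maximal contour
#' length of each cluster.
#'
#' @param object An `smfs_refined`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smfs_refined <- function(object, ...) {
  df <- object$observables
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$cluster_id,
                                                      -.data$n_members),
                                   y = .data$n_members)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f nm", .data$lc_max)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "cluster", y = "traces above threshold",
                  title = "Refined unfolding clusters")
}

#' Plot a force-distance trace
#'
#' @param x Separation grid (nm).
#' @param force Forces (pN).
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_fd_curve <- function(x, force, title = "F-D curve") {
  ggplot2::ggplot(tibble::tibble(x = x, force = force),
                  ggplot2::aes(.data$x, .data$force)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "tip-sample separation (nm)", y = "force (pN)",
                  title = title)
}

#' Plot cluster posterior probabilities
#'
#' Top candidate proteins per cluster, by posterior probability.
#'
#' @param posteriors Output of [identify_clusters()].
#' @param top_n Candidates per cluster to show (default 5).
#' @return A ggplot.
#' @export
plot_posteriors <- function(posteriors, top_n = 5) {
  df <- dplyr::slice_max(dplyr::group_by(posteriors, .data$cluster_id),
                         .data$posterior, n = top_n, with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$posterior, y = .data$protein_id)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::facet_wrap(~cluster_id, scales = "free_y") +
    ggplot2::labs(x = "posterior probability", y = NULL,
                  title = "Bayesian cluster identification")
}
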