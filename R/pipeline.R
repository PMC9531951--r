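#' Pipeline configuration
#'
#' All tunables of the five processing blocks and the identification stage,
#' with defaults equal to the method's stated operating point.
#'
#' @param wlc [wlc_params()].
#' @param tail_fraction Non-contact tail fraction for baseline statistics.
#' @param grid Interpolation grid (nm).
#' @param bin_width Lc histogram bin (nm).
#' @param min_points,min_fraction Peak meaningfulness rules.
#' @param low_force_window Score-propagation window (nm).
#' @param quality_min Quality-ratio cut.
#' @param f_scoring_factor `F_scoring = factor * sigma_NOISE`.
#' @param gap_penalty Alignment gap penalty.
#' @param max_peak_diff,max_length_diff,prefilter Distance prefilter.
#' @param k k-NN neighbour count (`NULL` = automatic).
#' @param r_cut Center separation threshold.
#' @param overlap_min Cluster merge threshold.
#' @param likelihood [likelihood_config()].
#' @param seed Seed recorded in the config snapshot.
#' @return A list of class `smfs_config`.
#' @export
smfs_config <- function(wlc = wlc_params(), tail_fraction = 0.2, grid = 1,
                        bin_width = 8, min_points = 5, min_fraction = 0.01,
                        low_force_window = 75, quality_min = 0.5,
                        f_scoring_factor = 4, gap_penalty = 0,
                        max_peak_diff = 2, max_length_diff = 0.20,
                        prefilter = "and", k = NULL, r_cut = 0.3,
                        overlap_min = 0.40, likelihood = likelihood_config(),
                        seed = NULL) {
  structure(as.list(environment()), class = "smfs_config")
}

#' Run the full classification and identification pipeline
#'
#' Executes the five processing blocks in order — preprocessing and coarse
#' filtering, WLC quality scoring, pairwise alignment distances, density-peak
#' clustering, area-of-similarity refinement and merging — then, if a
#' proteome table is supplied, Bayesian identification of every refined
#' cluster. Per-stage counts are logged with `message()`.
#'
#' @param curves An [fd_curve_set()].
#' @param proteome Optional proteome tibble for identification.
#' @param config An [smfs_config()].
#' @return A list of class `smfs_run`: `sigma_noise`, `filter`, `scored`,
#'   `dist`, `clustering`, `refined`, `posteriors` (or `NULL`), `config`,
#'   `counts` (per-stage bookkeeping).
#' @export
run_smfs_pipeline <- function(curves, proteome = NULL,
                              config = smfs_config()) {
  n_in <- nrow(curves)
  empty_run <- function() {
    structure(list(sigma_noise = NA_real_, filter = NULL, scored = NULL,
                   dist = NULL, clustering = NULL,
                   refined = structure(list(
                     clusters = tibble::tibble(cluster_id = character(0),
                                               n_members = integer(0),
                                               members = list()),
                     observables = tibble::tibble(cluster_id = character(0),
                                                  n_members = integer(0),
                                                  lc_max = numeric(0),
                                                  mean_force = numeric(0)),
                     merge_log = NULL, thresholds = numeric(0),
                     dropped = character(0)), class = "smfs_refined"),
                   posteriors = NULL, config = config,
                   counts = list(ingested = n_in, kept_block1 = 0,
                                 kept_quality = 0, clustered = 0,
                                 refined_clusters = 0)),
              class = "smfs_run")
  }
  if (n_in == 0) {
    message("pipeline: empty input, nothing to do")
    return(empty_run())
  }
  sigma <- estimate_batch_noise(curves, config$tail_fraction)
  message(sprintf("pipeline: %d curves ingested, sigma_NOISE = %.2f pN",
                  n_in, sigma))
  pp <- preprocess_curves(curves, config$tail_fraction, config$grid)
  filt <- filter_spurious(pp, sigma, config$tail_fraction)
  kept <- pp[filt$kept, , drop = FALSE]
  message(sprintf("  block 1: kept %d, rejected %d (%s)",
                  nrow(kept), sum(!filt$kept),
                  paste(sprintf("%s=%d", names(table(filt$reason)),
                                table(filt$reason)), collapse = ", ")))
  scored <- score_traces(kept, config$wlc, config$bin_width,
                         config$min_points, config$min_fraction,
                         config$low_force_window, config$quality_min)
  hq <- scored[scored$keep_quality, , drop = FALSE]
  message(sprintf("  block 2: %d of %d traces pass the quality cut",
                  nrow(hq), nrow(scored)))
  if (nrow(hq) < 3) {
    message("  too few quality traces; stopping before clustering")
    out <- empty_run()
    out$sigma_noise <- sigma; out$filter <- filt; out$scored <- scored
    out$counts$kept_block1 <- nrow(kept)
    out$counts$kept_quality <- nrow(hq)
    return(out)
  }
  acfg <- alignment_config(f_scoring = config$f_scoring_factor * max(sigma, 1e-6),
                           gap_penalty = config$gap_penalty,
                           max_peak_diff = config$max_peak_diff,
                           max_length_diff = config$max_length_diff,
                           prefilter = config$prefilter)
  dist <- trace_distances(hq, acfg)
  message(sprintf("  block 3: %d of %d pairs computed",
                  (sum(dist$computed) - nrow(hq)) / 2,
                  nrow(hq) * (nrow(hq) - 1) / 2))
  clustering <- cluster_traces(dist, quality = hq$quality_ratio,
                               k = config$k, r_cut = config$r_cut)
  message(sprintf("  block 4: %d centers, %d traces assigned",
                  length(clustering$centers),
                  sum(!is.na(clustering$points$label))))
  refined <- refine_clusters(clustering, hq, dist,
                             overlap_min = config$overlap_min)
  message(sprintf("  block 5: %d refined clusters", nrow(refined$clusters)))
  posteriors <- NULL
  if (!is.null(proteome) && nrow(refined$clusters) > 0) {
    posteriors <- identify_clusters(refined, proteome, config$likelihood)
    message(sprintf("  identification: %d clusters scored against %d proteins",
                    nrow(refined$clusters), nrow(proteome)))
  }
  structure(list(sigma_noise = sigma, filter = filt, scored = scored,
                 dist = dist, clustering = clustering, refined = refined,
                 posteriors = posteriors, config = config,
                 counts = list(ingested = n_in, kept_block1 = nrow(kept),
                               kept_quality = nrow(hq),
                               clustered = sum(!is.na(clustering$points$label)),
                               refined_clusters = nrow(refined$clusters))),
            class = "smfs_run")
}

#' @export
print.smfs_run <- function(x, ...) {
  cat("SMFS pipeline run\n")
  cat(sprintf("  ingested %d | block1 kept %d | quality kept %d | clusters %d\n",
              x$counts$ingested, x$counts$kept_block1,
              x$counts$kept_quality, x$counts$refined_clusters))
  if (!is.null(x$posteriors) && nrow(x$posteriors) > 0) {
    top <- dplyr::slice_max(dplyr::group_by(x$posteriors, .data$cluster_id),
                            .data$posterior, n = 1, with_ties = FALSE)
    cat("  top candidates:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %s -> %s (p = %.3f)\n", top$cluster_id[i],
                  top$protein_id[i], top$posterior[i]))
    }
  }
  invisible(x)
}
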