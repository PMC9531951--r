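#' Likelihood configuration for Bayesian identification
#'
#' The contour-length evidence is modelled as a Gaussian centred at
#' `lc_scale` times the protein's nominal contour length (0.4 nm per residue),
#' with a relative standard deviation obtained by adding in quadrature the
#' empirical spread of effective unfolding lengths (`sigma_effective`), the
#' persistence-length uncertainty (`sigma_p`) and the measurement error on the
#' cluster's maximal contour length (`sigma_lc`). Proteins with a terminal
#' soluble domain at least twice `sigma_likelihood` long instead get a
#' non-informative uniform over the domain span, because the membrane pinning
#' point — and hence the measured length — is then undetermined within the
#' domain. The unfolding-force evidence uses a per-secondary-structure-class
#' density (lognormal by default); the parameters are calibration values meant
#' to be refit from literature force tables. The barrier-profile evidence is
#' the maximal cross-correlation (within `max_lag`) between the cluster's
#' normalised Lc peak profile and a profile of Gaussians (FWHM `loop_fwhm`) at
#' the protein's loop centers.
#'
#' @param lc_scale Mean effective length as a fraction of nominal contour
#'   length (default 0.89).
#' @param sigma_effective,sigma_p,sigma_lc Relative error components
#'   (defaults 0.05, 0.07, 0.05).
#' @param nm_per_residue Contour length per residue (nm, default 0.4).
#' @param loop_fwhm FWHM of the loop Gaussians (nm, default 15).
#' @param max_lag Cross-correlation lag bound (nm, default 15).
#' @param profile_force_band Force band of the peak profile (pN).
#' @param force_model Named list per ss_class with `meanlog`, `sdlog` of a
#'   lognormal unfolding-force density.
#' @return A list of class `likelihood_config`; `sigma_likelihood` is the
#'   quadrature sum of the three components.
#' @export
likelihood_config <- function(lc_scale = 0.89, sigma_effective = 0.05,
                              sigma_p = 0.07, sigma_lc = 0.05,
                              nm_per_residue = 0.4, loop_fwhm = 15,
                              max_lag = 15, profile_force_band = c(40, 100),
                              force_model = list(
                                helix = list(meanlog = log(110), sdlog = 0.35),
                                sheet = list(meanlog = log(190), sdlog = 0.30),
                                mixed = list(meanlog = log(150), sdlog = 0.45))) {
  sl <- sqrt(sigma_effective^2 + sigma_p^2 + sigma_lc^2)
  structure(list(lc_scale = lc_scale, sigma_effective = sigma_effective,
                 sigma_p = sigma_p, sigma_lc = sigma_lc,
                 sigma_likelihood = sl, nm_per_residue = nm_per_residue,
                 loop_fwhm = loop_fwhm, max_lag = max_lag,
                 profile_force_band = profile_force_band,
                 force_model = force_model),
            class = "likelihood_config")
}

#' Abundance-topology prior over a proteome
#'
#' The prior probability of each protein is its mass-spectrometry abundance
#' times its membrane flag, normalised over the proteome: only membrane
#' proteins can be pulled from an isolated membrane patch, with probability
#' proportional to how abundant they are.
#'
#' @param proteome Proteome tibble (see [read_proteome_table()]).
#' @return Numeric vector of priors summing to 1.
#' @export
build_prior <- function(proteome) {
  w <- proteome$abundance * proteome$is_membrane
  if (all(w == 0)) stop("empty_prior: no membrane protein with abundance > 0",
                        call. = FALSE)
  w / sum(w)
}

#' Contour-length likelihood of a cluster given a protein
#'
#' Gaussian branch: density of `N(lc_scale * L, sigma_likelihood * L)` at the
#' cluster's maximal contour length, with `L = n_residues * nm_per_residue`.
#' Uniform branch (taken when the terminal domain is at least
#' `2 * sigma_likelihood * L` long): constant `1/final_domain_nm` on
#' `(L - final_domain_nm, L)`, zero elsewhere.
#'
#' @param lc_max Cluster maximal contour length (nm).
#' @param n_residues,final_domain_nm Protein length (residues) and terminal
#'   soluble-domain length (nm).
#' @param cfg A [likelihood_config()].
#' @return Density in 1/nm.
#' @export
lc_likelihood <- function(lc_max, n_residues, final_domain_nm = 0,
                          cfg = likelihood_config()) {
  stopifnot(lc_max > 0)
  L <- n_residues * cfg$nm_per_residue
  if (final_domain_nm >= 2 * cfg$sigma_likelihood * L) {
    as.numeric(lc_max > L - final_domain_nm & lc_max < L) / final_domain_nm
  } else {
    dnorm(lc_max, mean = cfg$lc_scale * L, sd = cfg$sigma_likelihood * L)
  }
}

#' Unfolding-force likelihood of a cluster given a protein
#'
#' Evaluates the configured per-secondary-structure-class density at the
#' cluster's mean unfolding force. An unknown structure class returns the
#' constant 1 (uninformative), mirroring the flat-line convention for missing
#' structure.
#'
#' @param mean_force Cluster mean unfolding force (pN, > 0).
#' @param ss_class One of `"helix"`, `"sheet"`, `"mixed"`, `"unknown"`.
#' @param cfg A [likelihood_config()].
#' @return Density in 1/pN (or 1 for unknown structure).
#' @export
force_likelihood <- function(mean_force, ss_class,
                             cfg = likelihood_config()) {
  if (any(mean_force <= 0)) stop("mean_force must be positive", call. = FALSE)
  if (is.na(ss_class) || !ss_class %in% names(cfg$force_model)) return(1)
  m <- cfg$force_model[[ss_class]]
  dlnorm(mean_force, meanlog = m$meanlog, sdlog = m$sdlog)
}

# resample a binned profile (bin mids -> density) onto a 1-nm grid with unit
# area; zero outside the binned support
.profile_on_grid <- function(lc_mid, density, grid) {
  if (length(lc_mid) == 1) {
    y <- as.numeric(abs(grid - lc_mid) <= 4)
  } else {
    y <- approx(lc_mid, density, xout = grid, yleft = 0, yright = 0)$y
  }
  y[y < 0 | !is.finite(y)] <- 0
  s <- sum(y)
  if (s == 0) return(y)
  y / s
}

#' Barrier-profile likelihood of a cluster given a protein's loops
#'
#' The protein's structure profile is a sum of Gaussians (FWHM
#' `cfg$loop_fwhm`) centred at the loop centers along the unfolded contour —
#' unfolding barriers are far more likely at unstructured loops — normalised
#' to unit area. The score is the maximal cross-correlation between this
#' profile and the cluster's unit-area Lc peak profile over integer-nm lags
#' within `±cfg$max_lag` (fine alignment freedom). A protein with no loop
#' annotation is cross-correlated as a flat line over the cluster support.
#'
#' @param peak_profile Tibble `lc_mid`, `density` from
#'   [cluster_observables()].
#' @param loop_centers_nm Numeric vector (may be empty).
#' @param cfg A [likelihood_config()].
#' @return Nonnegative cross-correlation score.
#' @export
peaks_likelihood <- function(peak_profile, loop_centers_nm,
                             cfg = likelihood_config()) {
  hi <- max(peak_profile$lc_mid,
            if (length(loop_centers_nm)) max(loop_centers_nm) + 30 else 0) +
    cfg$max_lag + 8
  grid <- seq(0, ceiling(hi))
  p <- .profile_on_grid(peak_profile$lc_mid, peak_profile$density, grid)
  if (length(loop_centers_nm) > 0) {
    sd_loop <- cfg$loop_fwhm / (2 * sqrt(2 * log(2)))
    q <- rowSums(vapply(loop_centers_nm,
                        function(c0) dnorm(grid, c0, sd_loop),
                        numeric(length(grid))))
  } else {
    q <- as.numeric(p > 0) # flat line over the cluster support
  }
  if (sum(q) == 0) q <- rep(1, length(q))
  q <- q / sum(q)
  lags <- seq.int(-cfg$max_lag, cfg$max_lag)
  xc <- vapply(lags, function(l) {
    if (l >= 0) {
      n <- length(grid) - l
      sum(p[seq_len(n)] * q[seq_len(n) + l])
    } else {
      n <- length(grid) + l
      sum(p[seq_len(n) - l] * q[seq_len(n)])
    }
  }, numeric(1))
  max(xc)
}

#' Posterior identification table for one cluster
#'
#' Applies Bayes' theorem over the proteome: each protein's posterior is the
#' product of its contour-length, unfolding-force and barrier-profile
#' likelihoods with its abundance-topology prior, normalised over all
#' proteins. Zero-prior (non-membrane) proteins carry posterior 0. If every
#' product vanishes the posterior falls back to the prior restricted to its
#' support, flagged uninformative.
#'
#' @param obs A [cluster_observables()] object (or a one-row slice of the
#'   `observables` tibble of [refine_clusters()]).
#' @param proteome Proteome tibble.
#' @param cfg A [likelihood_config()].
#' @return A tibble of class `smfs_posterior`: `protein_id`, `prior`,
#'   `p_lc`, `p_force`, `p_peaks`, `posterior`, sorted by descending
#'   posterior; attribute `uninformative` marks the fallback.
#' @export
posterior_table <- function(obs, proteome, cfg = likelihood_config()) {
  if (is.data.frame(obs)) {
    obs <- list(lc_max = obs$lc_max[[1]], mean_force = obs$mean_force[[1]],
                peak_profile = obs$peak_profile[[1]])
  }
  prior <- build_prior(proteome)
  p_lc <- purrr::map2_dbl(proteome$n_residues, proteome$final_domain_nm,
                          ~ lc_likelihood(obs$lc_max, .x, .y, cfg))
  p_force <- purrr::map_dbl(proteome$ss_class,
                            ~ force_likelihood(obs$mean_force, .x, cfg))
  p_peaks <- purrr::map_dbl(proteome$loop_centers_nm,
                            ~ peaks_likelihood(obs$peak_profile, .x, cfg))
  num <- p_lc * p_force * p_peaks * prior
  uninformative <- FALSE
  if (sum(num) == 0) {
    uninformative <- TRUE
    num <- prior
  }
  out <- tibble::tibble(protein_id = proteome$protein_id, prior = prior,
                        p_lc = p_lc, p_force = p_force, p_peaks = p_peaks,
                        posterior = num / sum(num))
  out <- dplyr::arrange(out, dplyr::desc(.data$posterior))
  attr(out, "uninformative") <- uninformative
  class(out) <- c("smfs_posterior", class(out))
  out
}

#' Identify all refined clusters against a proteome
#'
#' Runs [posterior_table()] for every cluster and stacks the results.
#'
#' @param refined An `smfs_refined` from [refine_clusters()].
#' @param proteome Proteome tibble.
#' @param cfg A [likelihood_config()].
#' @return A tibble with `cluster_id` plus the [posterior_table()] columns.
#' @export
identify_clusters <- function(refined, proteome, cfg = likelihood_config()) {
  obs <- refined$observables
  purrr::map_dfr(seq_len(nrow(obs)), function(i) {
    tab <- posterior_table(obs[i, ], proteome, cfg)
    dplyr::bind_cols(tibble::tibble(cluster_id = obs$cluster_id[i]),
                     tibble::as_tibble(tab))
  })
}

#' Sampling-yield relation for cluster formation
#'
#' The number of traces landing in one cluster scales linearly with the
#' number of collected traces and the surface concentration of the protein:
#' `N1c = K * Ntot * P2D`, with `K` the pulling-efficiency factor (units of
#' area, micrometer^2). Supply all but one quantity to solve for the missing
#' one: with `ntot` and `p2d` given the function returns `K`; with
#' `k_factor` given it returns the required product `Ntot * P2D`.
#'
#' @param n1c Traces in one cluster.
#' @param ntot Total collected traces (with `p2d`, to solve for K).
#' @param p2d Surface protein concentration (proteins per micrometer^2).
#' @param k_factor Pulling-efficiency factor (micrometer^2), to solve for the
#'   required `Ntot * P2D`.
#' @return `K` (micrometer^2) or `Ntot * P2D` (traces * protein /
#'   micrometer^2), depending on which inputs are supplied.
#' @export
#' @examples
#' required_sampling(n1c = 285, ntot = 106528, p2d = 3e4) # K ~ 9e-8
#' required_sampling(n1c = 50, k_factor = 9e-8)           # ~5.6e8
required_sampling <- function(n1c, ntot = NULL, p2d = NULL, k_factor = NULL) {
  if (n1c <= 0) stop("n1c must be positive", call. = FALSE)
  if (is.null(k_factor)) {
    if (is.null(ntot) || is.null(p2d)) {
      stop("supply either k_factor, or both ntot and p2d", call. = FALSE)
    }
    if (ntot <= 0 || p2d <= 0) stop("inputs must be positive", call. = FALSE)
    n1c / (ntot * p2d)
  } else {
    if (k_factor <= 0) stop("inputs must be positive", call. = FALSE)
    n1c / k_factor
  }
}
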