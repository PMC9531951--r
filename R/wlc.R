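#' Worm-like-chain model parameters
#'
#' Bundles the physical constants of the worm-like-chain (WLC) entropic
#' elasticity model used throughout the package: the persistence length of the
#' unfolded polypeptide, the temperature, and the force window inside which the
#' interpolation formula is considered a valid description of protein
#' stretching.
#'
#' @param lp Persistence length in nm. 0.4 nm is the standard value for
#'   unfolded membrane-protein polypeptide.
#' @param temperature Temperature in K (default 297 K, i.e. 24 degrees C).
#' @param force_min,force_max Validity window of the model in pN. Contour
#'   lengths are only inverted for forces inside `[force_min, force_max]`
#'   (default 30–500 pN).
#' @param constant_term Constant term of the interpolation formula. The
#'   default `-0.25` gives the standard form with F(0) = 0; `+0.25` restores
#'   the variant sometimes seen in print, which has a nonzero force at zero
#'   extension.
#' @return A list of class `wlc_params`.
#' @export
#' @examples
#' p <- wlc_params()
#' wlc_force(40, Lc = 80, params = p)
wlc_params <- function(lp = 0.4, temperature = 297,
                       force_min = 30, force_max = 500,
                       constant_term = -0.25) {
  stopifnot(lp > 0, temperature > 0, force_min > 0, force_max > force_min)
  structure(list(lp = lp, temperature = temperature,
                 force_min = force_min, force_max = force_max,
                 constant_term = constant_term),
            class = "wlc_params")
}

#' WLC force at a given extension and contour length
#'
#' Evaluates the interpolation formula
#' \deqn{F(x) = \frac{k_B T}{l_p}\left[\frac{1}{4}(1 - x/L_c)^{-2} -
#'   \frac{1}{4} + \frac{x}{L_c}\right]}
#' which is strictly increasing in `x` and diverges as `x` approaches the
#' contour length `Lc`.
#'
#' @param x Extension(s) in nm, `0 <= x < Lc`.
#' @param Lc Contour length(s) in nm.
#' @param params A [wlc_params()] object.
#' @return Force(s) in pN.
#' @export
wlc_force <- function(x, Lc, params = wlc_params()) {
  if (any(x < 0) || any(x >= Lc)) {
    stop("wlc_force: extension must satisfy 0 <= x < Lc", call. = FALSE)
  }
  t <- x / Lc
  (.kB * params$temperature / params$lp) *
    (0.25 * (1 - t)^-2 + t + params$constant_term)
}

# dimensionless force g(t) = F lp/(kB T) as a function of t = x/Lc
.wlc_g <- function(t, constant_term) 0.25 * (1 - t)^-2 + t + constant_term

# inverse of g on (0, 1); cc is the dimensionless force
.wlc_g_inv <- function(cc, constant_term) {
  vapply(cc, function(ci) {
    if (!is.finite(ci) || ci <= .wlc_g(1e-12, constant_term)) return(NA_real_)
    upper <- 1 - 1e-12
    if (.wlc_g(upper, constant_term) < ci) return(NA_real_)
    uniroot(function(t) .wlc_g(t, constant_term) - ci,
            lower = 1e-12, upper = upper, tol = 1e-13)$root
  }, numeric(1))
}

#' Invert the WLC model: contour length from extension and force
#'
#' Solves the WLC equation for the contour length `Lc` given a measured
#' extension and force, by bracketed root finding on the relative extension
#' `t = x/Lc` (the force is monotone in `t`, so the root is unique).
#' Forces outside the model's validity window (`force_min`–`force_max`)
#' return `NA`: those points are simply excluded from contour-length
#' histograms rather than raising an error.
#'
#' @param x Extension(s) in nm, `> 0`.
#' @param force Force(s) in pN.
#' @param params A [wlc_params()] object.
#' @return Contour length(s) in nm (`> x`), or `NA` where the force is
#'   outside the validity window.
#' @export
#' @examples
#' Lc <- wlc_contour_length(50, 100)
#' wlc_force(50, Lc) # ~100 pN
wlc_contour_length <- function(x, force, params = wlc_params()) {
  n <- max(length(x), length(force))
  x <- rep_len(x, n); force <- rep_len(force, n)
  out <- rep(NA_real_, n)
  ok <- is.finite(force) & force >= params$force_min &
    force <= params$force_max & is.finite(x) & x > 0
  if (any(ok)) {
    cc <- force[ok] * params$lp / (.kB * params$temperature)
    t <- .wlc_g_inv(cc, params$constant_term)
    out[ok] <- x[ok] / t
  }
  out
}

#' Contour-length profile of a preprocessed trace
#'
#' Applies [wlc_contour_length()] point-wise to a preprocessed trace,
#' producing the per-grid-point contour length Lc wherever the measured force
#' lies inside the WLC validity window. The resulting Lc values are the raw
#' material of the Lc histogram used for quality scoring and clustering.
#'
#' @param x Separation grid (nm).
#' @param force Forces on the grid (pN).
#' @param params A [wlc_params()] object.
#' @return A tibble with columns `x`, `force`, `lc` (NA where invalid) and
#'   `valid`.
#' @export
trace_lc_profile <- function(x, force, params = wlc_params()) {
  lc <- wlc_contour_length(x, force, params)
  tibble::tibble(x = x, force = force, lc = lc,
                 valid = is.finite(lc) & lc > x)
}
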