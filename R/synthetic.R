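#' Protein unfolding template
#'
#' A template describes the mechanical fingerprint of a membrane protein as a
#' ladder of obligatory unfolding intermediates: ascending contour lengths of
#' the barriers and the rupture force at which each intermediate gives way.
#' The implied residue count follows from the last barrier via the
#' 0.4 nm/residue and effective-length (0.89) relations.
#'
#' @param template_id Identifier.
#' @param barrier_lcs Ascending contour lengths of the intermediates (nm).
#' @param rupture_forces Rupture force per barrier (pN, within 30–500).
#' @param ss_class Secondary-structure class of the paired protein record.
#' @param params [wlc_params()] used to validate reachability.
#' @return A list of class `protein_template` with the extension at each
#'   rupture precomputed (`x_rup`).
#' @export
protein_template <- function(template_id, barrier_lcs, rupture_forces,
                             ss_class = "helix", params = wlc_params()) {
  stopifnot(length(barrier_lcs) == length(rupture_forces),
            length(barrier_lcs) >= 1)
  if (is.unsorted(barrier_lcs, strictly = TRUE)) {
    stop("barrier contour lengths must be strictly ascending", call. = FALSE)
  }
  if (any(rupture_forces < params$force_min) ||
      any(rupture_forces > params$force_max)) {
    stop("rupture forces must lie in the WLC validity band", call. = FALSE)
  }
  cc <- rupture_forces * params$lp / (.kB * params$temperature)
  t <- .wlc_g_inv(cc, params$constant_term)
  x_rup <- t * barrier_lcs
  if (is.unsorted(x_rup, strictly = TRUE)) {
    stop("unreachable rupture force: a barrier ruptures before the previous one",
         call. = FALSE)
  }
  structure(list(template_id = template_id, barrier_lcs = barrier_lcs,
                 rupture_forces = rupture_forces, ss_class = ss_class,
                 x_rup = x_rup,
                 n_residues = round(max(barrier_lcs) / (0.4 * 0.89))),
            class = "protein_template")
}

#' Simulation configuration
#'
#' Study conditions of the synthetic data: Gaussian force noise, the fraction
#' of spurious traces (random multi-attachment WLC branches), of
#' constant-force tether plateaus, and of prematurely detaching pulls (the
#' default 0.23 reflects that roughly a quarter of pulls detach before full
#' unfolding).
#'
#' @param noise_sd Force noise standard deviation (pN, default 10 — typical
#'   AFM thermal noise).
#' @param spurious_fraction,tether_fraction,premature_detach_fraction
#'   Fractions in `[0, 1]`.
#' @param spring_constant Cantilever stiffness (pN/nm, default 840).
#' @param sampling Raw sampling step (nm, default 0.5).
#' @param tail_nm Post-detachment baseline length (nm, default 80).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(noise_sd = 10, spurious_fraction = 0,
                       tether_fraction = 0, premature_detach_fraction = 0.23,
                       spring_constant = 840, sampling = 0.5, tail_nm = 80,
                       seed = NULL) {
  fr <- c(spurious_fraction, tether_fraction, premature_detach_fraction)
  stopifnot(all(fr >= 0), all(fr <= 1), noise_sd >= 0)
  structure(list(noise_sd = noise_sd, spurious_fraction = spurious_fraction,
                 tether_fraction = tether_fraction,
                 premature_detach_fraction = premature_detach_fraction,
                 spring_constant = spring_constant, sampling = sampling,
                 tail_nm = tail_nm, seed = seed),
            class = "sim_config")
}

# raw z/force arrays for a sawtooth defined by (barrier_lcs, x_rup); adds the
# adhesion dip, noise, a random baseline offset, and the bending term
.synth_sawtooth <- function(barrier_lcs, x_rup, cfg, params) {
  s <- seq(-6, max(x_rup) + cfg$tail_nm, by = cfg$sampling)
  f <- numeric(length(s))
  f[s >= -4 & s < 0] <- -45 # adhesion dip
  prev <- 0
  for (j in seq_along(barrier_lcs)) {
    seg <- s >= prev & s <= x_rup[j]
    f[seg] <- wlc_force(pmin(s[seg], barrier_lcs[j] * (1 - 1e-9)),
                        barrier_lcs[j], params)
    prev <- x_rup[j] + cfg$sampling / 2
  }
  offset <- runif(1, -20, 20)
  noise <- rnorm(length(s), 0, cfg$noise_sd)
  f_meas <- f + noise + offset
  z <- s + (f + noise) / cfg$spring_constant
  list(z = z, force = f_meas)
}

#' Simulate one force-distance curve from a template
#'
#' Piecewise WLC sawtooth: for each barrier the force follows the WLC branch
#' of that barrier's contour length from the previous rupture until reaching
#' the barrier's rupture force, then drops to baseline. Gaussian noise, a
#' random baseline offset, an adhesion dip at contact and the cantilever
#' bending term are added so the raw curve exercises the full preprocessing.
#' With probability `premature_detach_fraction` the pull detaches at a
#' uniformly chosen intermediate. Uses the current RNG state (seed the
#' simulation at the dataset level).
#'
#' @param template A [protein_template()].
#' @param cfg A [sim_config()].
#' @param params [wlc_params()].
#' @return A list `z`, `force`, `n_barriers_pulled`.
#' @export
simulate_curve <- function(template, cfg = sim_config(),
                           params = wlc_params()) {
  nb <- length(template$barrier_lcs)
  keep <- nb
  if (nb > 1 && runif(1) < cfg$premature_detach_fraction) {
    keep <- sample.int(nb - 1, 1)
  }
  raw <- .synth_sawtooth(template$barrier_lcs[seq_len(keep)],
                         template$x_rup[seq_len(keep)], cfg, params)
  c(raw, list(n_barriers_pulled = keep))
}

# spurious trace: 1-3 unrelated WLC branches from random attachments
.spurious_curve <- function(cfg, params) {
  for (try in 1:20) {
    nb <- sample.int(3, 1)
    lcs <- sort(runif(nb, 40, 250))
    forces <- runif(nb, 50, 250)
    tpl <- try(protein_template("spur", lcs, forces, params = params),
               silent = TRUE)
    if (!inherits(tpl, "try-error")) {
      return(.synth_sawtooth(tpl$barrier_lcs, tpl$x_rup, cfg, params))
    }
  }
  lc <- runif(1, 60, 200)
  tpl <- protein_template("spur", lc, runif(1, 60, 200), params = params)
  .synth_sawtooth(tpl$barrier_lcs, tpl$x_rup, cfg, params)
}

# tether: constant-force plateau, no WLC pattern
.tether_curve <- function(cfg, params) {
  plateau <- runif(1, 35, 80)
  len <- runif(1, 50, 200)
  s <- seq(-6, len + cfg$tail_nm, by = cfg$sampling)
  f <- numeric(length(s))
  f[s >= -4 & s < 0] <- -45
  f[s >= 0 & s <= len] <- plateau
  offset <- runif(1, -20, 20)
  noise <- rnorm(length(s), 0, cfg$noise_sd)
  list(z = s + (f + noise) / cfg$spring_constant, force = f + noise + offset)
}

#' Simulate an abundance-weighted dataset
#'
#' Draws a template per curve from the supplied relative abundances
#' (multinomial), then replaces the configured fractions with spurious
#' multi-attachment traces and tether plateaus. Deterministic given
#' `cfg$seed`.
#'
#' @param templates List of [protein_template()]s.
#' @param abundances Nonnegative relative abundances (recycled names from
#'   templates).
#' @param n_total Number of curves (> 0).
#' @param cfg A [sim_config()].
#' @param params [wlc_params()].
#' @return A list: `curves` (an [fd_curve_set()]) and `truth` (tibble
#'   `curve_id`, `template_id` — `"spurious"` / `"tether"` for pattern-free
#'   traces).
#' @export
simulate_dataset <- function(templates, abundances, n_total,
                             cfg = sim_config(), params = wlc_params()) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  stopifnot(length(templates) == length(abundances),
            all(abundances >= 0), any(abundances > 0))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ids <- purrr::map_chr(templates, "template_id")
  lab <- sample(ids, n_total, replace = TRUE, prob = abundances)
  n_spur <- round(cfg$spurious_fraction * n_total)
  n_teth <- round(cfg$tether_fraction * n_total)
  repl <- sample.int(n_total, min(n_total, n_spur + n_teth))
  lab[repl[seq_len(min(n_spur, length(repl)))]] <- "spurious"
  if (n_teth > 0 && length(repl) > n_spur) {
    lab[repl[(n_spur + 1):length(repl)]] <- "tether"
  }
  curves <- purrr::map(lab, function(l) {
    if (l == "spurious") .spurious_curve(cfg, params)
    else if (l == "tether") .tether_curve(cfg, params)
    else simulate_curve(templates[[match(l, ids)]], cfg, params)
  })
  cid <- sprintf("curve_%04d", seq_len(n_total))
  list(curves = fd_curve_set(curve_id = cid,
                             z = purrr::map(curves, "z"),
                             force = purrr::map(curves, "force"),
                             spring_constant = cfg$spring_constant,
                             sample_id = "synthetic", is_tss = FALSE),
       truth = tibble::tibble(curve_id = cid, template_id = lab))
}

#' Built-in template presets
#'
#' `"separable"`: three templates with clearly distinct lengths and force
#' levels, analogous to a bacteriorhodopsin-like, channelrhodopsin-like and
#' channel-like mixture — the workhorse for end-to-end pipeline checks.
#'
#' @param preset Preset name.
#' @return A named list of [protein_template()]s.
#' @export
smfs_templates <- function(preset = c("separable")) {
  preset <- match.arg(preset)
  list(
    T1 = protein_template("T1", c(35, 88, 130), c(120, 110, 100), "mixed"),
    T2 = protein_template("T2", c(45, 100, 160, 219), c(110, 100, 95, 90),
                          "helix"),
    T3 = protein_template("T3", c(50, 120, 190, 250, 310),
                          c(210, 200, 190, 180, 170), "sheet")
  )
}

#' Generate a spread of synthetic templates
#'
#' Produces `n` templates whose last barriers span `lc_range`, with
#' secondary-structure classes cycling through helix/sheet/mixed and rupture
#' forces drawn near the class-typical level (helix ~110 pN, sheet ~190 pN,
#' mixed ~150 pN). Interior barriers are spaced 50–90 nm apart. Deterministic
#' given `seed`.
#'
#' @param n Number of templates.
#' @param lc_range Range of last-barrier contour lengths (nm).
#' @param seed Integer seed (`NULL` = current RNG state).
#' @return A named list of [protein_template()]s.
#' @export
synth_templates <- function(n = 20, lc_range = c(70, 280), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  classes <- rep(c("helix", "sheet", "mixed"), length.out = n)
  modes <- c(helix = 110, sheet = 190, mixed = 150)
  last <- seq(lc_range[1], lc_range[2], length.out = n)
  setNames(purrr::map(seq_len(n), function(i) {
    lcs <- max(25, last[i] %% 47 + 20)
    while (max(lcs) < last[i] - 45) {
      lcs <- c(lcs, max(lcs) + runif(1, 50, 90))
    }
    lcs <- c(lcs[lcs < last[i] - 30], last[i])
    forces <- pmin(450, pmax(40, modes[classes[i]] * runif(length(lcs), 0.85, 1.15)))
    protein_template(sprintf("P%02d", i), lcs, forces, classes[i])
  }), sprintf("P%02d", seq_len(n)))
}

#' Synthetic proteome table paired with templates
#'
#' One record per template — residue count implied by the last barrier
#' through the 0.89 effective-length and 0.4 nm/residue relations, loop
#' centers at the interior barriers, membrane flag 1 — plus optional decoy
#' proteins with random lengths, abundances, classes and loops. With
#' `separable = TRUE` decoy lengths are resampled until their expected
#' measured length differs from every template's by more than three relative
#' likelihood widths.
#'
#' @param templates Named list of [protein_template()]s.
#' @param n_decoys Number of decoys (>= 0).
#' @param abundances Template abundances (recycled, default 1).
#' @param separable Keep decoys well away from template lengths.
#' @param seed Integer seed (`NULL` = current RNG state).
#' @param cfg A [likelihood_config()] (for the separability margin).
#' @return A proteome tibble (see [read_proteome_table()]).
#' @export
synth_proteome <- function(templates, n_decoys = 0, abundances = 1,
                           separable = TRUE, seed = NULL,
                           cfg = likelihood_config()) {
  if (!is.null(seed)) set.seed(seed)
  abundances <- rep_len(abundances, length(templates))
  tpl_rows <- purrr::imap(templates, function(t, nm) {
    nb <- length(t$barrier_lcs)
    tibble::tibble(
      protein_id = t$template_id,
      n_residues = t$n_residues,
      abundance = abundances[[match(nm, names(templates))]],
      is_membrane = 1,
      ss_class = t$ss_class,
      final_domain_nm = 0,
      loop_centers_nm = list(if (nb > 1) t$barrier_lcs[-nb] else numeric(0)))
  })
  tpl_lcmax <- purrr::map_dbl(templates, ~ max(.x$barrier_lcs))
  decoys <- purrr::map(seq_len(n_decoys), function(i) {
    for (try in 1:100) {
      nres <- round(runif(1, 120, 900))
      L <- nres * cfg$nm_per_residue * cfg$lc_scale
      if (!separable ||
          all(abs(L - tpl_lcmax) > 3 * cfg$sigma_likelihood * nres *
                cfg$nm_per_residue)) break
    }
    nl <- sample.int(4, 1)
    tibble::tibble(
      protein_id = sprintf("DECOY%02d", i),
      n_residues = nres,
      abundance = runif(1, 0.2, 2),
      is_membrane = as.numeric(runif(1) < 0.8),
      ss_class = sample(c("helix", "sheet", "mixed", "unknown"), 1),
      final_domain_nm = 0,
      loop_centers_nm = list(sort(runif(nl, 10, max(20, L - 20)))))
  })
  dplyr::bind_rows(c(tpl_rows, decoys))
}
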