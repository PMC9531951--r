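# Independent oracles and shared fixtures for the test suite.

# Brute-force global alignment: enumerate every monotone alignment
# recursively and take the best score. Exponential; only for tiny arrays.
brute_align <- function(fa, fb, f_scoring, gap_penalty = 0) {
  ms <- function(a, b) {
    d <- abs(a - b)
    if (d < f_scoring) 1 - d / f_scoring else -d / f_scoring
  }
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) best <- max(best, rec(i - 1, j - 1) + ms(fa[i], fb[j]))
    if (i > 0) best <- max(best, rec(i - 1, j) + gap_penalty)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap_penalty)
    best
  }
  rec(length(fa), length(fb))
}

# Bisection directly on the contour length (independent of the package's
# inversion through the relative extension).
oracle_lc <- function(x, force, lp = 0.4, temperature = 297) {
  kB <- 0.01380649
  f_of <- function(Lc) {
    t <- x / Lc
    (kB * temperature / lp) * (0.25 * (1 - t)^-2 + t - 0.25)
  }
  lo <- x * (1 + 1e-9); hi <- x * 1e3
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f_of(mid) > force) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# a noiseless single-WLC-branch trace on a 1-nm grid (already preprocessed
# form: x from 0, zero baseline, instant detachment at the rupture force)
clean_branch <- function(Lc, f_rup, tail_nm = 40, params = wlc_params()) {
  x_r <- Lc * smfsid:::.wlc_g_inv(f_rup * params$lp / (0.01380649 * params$temperature),
                                  params$constant_term)
  x <- seq(0, floor(x_r) + tail_nm)
  f <- numeric(length(x))
  on <- x <= x_r
  f[on] <- wlc_force(pmin(x[on], Lc * (1 - 1e-9)), Lc, params)
  list(x = x, force = f)
}

# cached expensive fixtures (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

fixture_two_template <- function() {
  if (!is.null(.fixture_env$two)) return(.fixture_env$two)
  tpl <- list(
    A = protein_template("A", c(35, 88, 130), c(120, 110, 100), "mixed"),
    B = protein_template("B", c(50, 105, 145), c(150, 140, 130), "helix"))
  sim <- simulate_dataset(tpl, c(1, 1), 100,
                          sim_config(seed = 301, premature_detach_fraction = 0))
  sigma <- estimate_batch_noise(sim$curves)
  pp <- preprocess_curves(sim$curves)
  filt <- filter_spurious(pp, sigma)
  sc <- score_traces(pp[filt$kept, ])
  hq <- sc[sc$keep_quality, ]
  dist <- trace_distances(hq, alignment_config(4 * sigma))
  truth <- sim$truth$template_id[match(hq$curve_id, sim$truth$curve_id)]
  .fixture_env$two <- list(scored = hq, dist = dist, truth = truth,
                           sigma = sigma)
  .fixture_env$two
}

fixture_three_template <- function() {
  if (!is.null(.fixture_env$three)) return(.fixture_env$three)
  tpl <- smfs_templates()
  sim <- simulate_dataset(tpl, c(1, 1, 1), 150,
                          sim_config(seed = 42, premature_detach_fraction = 0))
  run <- suppressMessages(run_smfs_pipeline(sim$curves))
  .fixture_env$three <- list(sim = sim, run = run)
  .fixture_env$three
}
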