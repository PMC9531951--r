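mk_proteome <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(purrr::map(rows, function(r) {
    tibble::tibble(protein_id = r$id, n_residues = r$n,
                   abundance = r$ab %||% 1,
                   is_membrane = r$mem %||% 1,
                   ss_class = r$ss %||% "unknown",
                   final_domain_nm = r$fd %||% 0,
                   loop_centers_nm = list(r$loops %||% numeric(0)))
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the prior is the normalised abundance-membrane product", {
  p <- mk_proteome(list(id = "a", n = 100, ab = 2, mem = 1),
                   list(id = "b", n = 100, ab = 1, mem = 1),
                   list(id = "c", n = 100, ab = 1, mem = 0))
  expect_equal(build_prior(p), c(2 / 3, 1 / 3, 0))
  single <- mk_proteome(list(id = "a", n = 100))
  expect_equal(build_prior(single), 1)
  soluble <- mk_proteome(list(id = "a", n = 100, mem = 0))
  expect_error(build_prior(soluble), "empty_prior")
  set.seed(71)
  rnd <- mk_proteome(list(id = "a", n = 50, ab = runif(1)),
                     list(id = "b", n = 60, ab = runif(1)),
                     list(id = "c", n = 70, ab = runif(1)))
  expect_equal(sum(build_prior(rnd)), 1)
})

test_that("the contour-length likelihood has Gaussian and uniform branches", {
  cfg <- likelihood_config()
  # 500 residues -> L = 200 nm; mode at 0.89 L = 178, sd ~ 0.10 L ~ 20 nm
  sdL <- cfg$sigma_likelihood * 200
  expect_equal(lc_likelihood(178, 500, 0, cfg), 1 / (sdL * sqrt(2 * pi)),
               tolerance = 1e-9)
  expect_equal(lc_likelihood(178, 500, 0, cfg), 1 / (20 * sqrt(2 * pi)),
               tolerance = 0.01)
  scan <- vapply(seq(100, 260, 2), lc_likelihood, numeric(1),
                 n_residues = 500, final_domain_nm = 0, cfg = cfg)
  expect_equal(seq(100, 260, 2)[which.max(scan)], 178)
  # final domain 60 nm >= 2 sigma (40 nm): uniform on (140, 200)
  expect_equal(lc_likelihood(170, 500, 60, cfg), 1 / 60)
  expect_equal(lc_likelihood(130, 500, 60, cfg), 0)
  # small final domain keeps the Gaussian
  expect_equal(lc_likelihood(178, 500, 30, cfg),
               lc_likelihood(178, 500, 0, cfg))
})

test_that("sigma components combine in quadrature to 0.10", {
  cfg <- likelihood_config()
  expect_equal(cfg$sigma_likelihood,
               sqrt(cfg$sigma_effective^2 + cfg$sigma_p^2 + cfg$sigma_lc^2))
  expect_equal(round(cfg$sigma_likelihood, 2), 0.10)
})

test_that("the force likelihood is a proper per-class density", {
  cfg <- likelihood_config()
  expect_equal(force_likelihood(123, "unknown", cfg), 1)
  # helix-band force favours the helix class over the sheet class
  expect_gt(force_likelihood(110, "helix", cfg),
            force_likelihood(110, "sheet", cfg))
  expect_gt(force_likelihood(200, "sheet", cfg),
            force_likelihood(200, "helix", cfg))
  for (cls in c("helix", "sheet", "mixed")) {
    q <- stats::integrate(function(f) {
      vapply(f, force_likelihood, numeric(1), ss_class = cls, cfg = cfg)
    }, 1e-6, 2000)$value
    expect_equal(q, 1, tolerance = 1e-3)
  }
  expect_error(force_likelihood(-5, "helix", cfg), "positive")
})

test_that("the barrier-profile likelihood is shift-equivariant", {
  cfg <- likelihood_config()
  mids <- seq(4, 300, by = 8)
  shape <- function(centers) {
    d <- rowSums(vapply(centers, function(c0) dnorm(mids, c0, 7),
                        numeric(length(mids))))
    d / (sum(d) * 8)
  }
  prof <- tibble::tibble(lc_mid = mids, density = shape(c(80, 150)))
  s0 <- peaks_likelihood(prof, c(80, 150), cfg)
  s10 <- peaks_likelihood(prof, c(90, 160), cfg) # +10 nm, inside the lag
  expect_equal(s0, s10, tolerance = 1e-6)
  s40 <- peaks_likelihood(prof, c(120, 190), cfg) # beyond the lag bound
  expect_lt(s40, s0)
  # aligned loops score higher than misaligned ones
  expect_gt(s0, peaks_likelihood(prof, c(50, 200), cfg))
})

test_that("missing structure falls back to a flat-line correlation", {
  cfg <- likelihood_config()
  mids <- seq(4, 300, by = 8)
  dens <- dnorm(mids, 120, 10); dens <- dens / (sum(dens) * 8)
  prof <- tibble::tibble(lc_mid = mids, density = dens)
  s <- peaks_likelihood(prof, numeric(0), cfg)
  expect_gt(s, 0)
  # the flat line is uninformative: a peaked structure aligned with the
  # profile scores higher
  expect_gt(peaks_likelihood(prof, 120, cfg), s)
})

test_that("posteriors follow Bayes' rule and normalise", {
  single <- mk_proteome(list(id = "only", n = 400, ss = "helix"))
  obs <- list(lc_max = 140, mean_force = 110,
              peak_profile = tibble::tibble(lc_mid = seq(4, 156, 8),
                                            density = rep(1 / 152, 20)))
  post <- posterior_table(obs, single)
  expect_equal(post$posterior, 1)
  # identical likelihoods, priors 3:1 -> posteriors 0.75 / 0.25
  pair <- mk_proteome(list(id = "hi", n = 400, ab = 3, ss = "helix"),
                      list(id = "lo", n = 400, ab = 1, ss = "helix"))
  post <- posterior_table(obs, pair)
  expect_equal(post$posterior[post$protein_id == "hi"], 0.75)
  expect_equal(post$posterior[post$protein_id == "lo"], 0.25)
  expect_equal(sum(post$posterior), 1, tolerance = 1e-9)
})

test_that("raising a protein's abundance never lowers its posterior", {
  set.seed(72)
  prot <- mk_proteome(list(id = "a", n = 300, ab = 1, ss = "helix",
                           loops = c(40, 80)),
                      list(id = "b", n = 420, ab = 2, ss = "sheet",
                           loops = c(60, 120)),
                      list(id = "c", n = 500, ab = 1, ss = "mixed"))
  obs <- list(lc_max = 110, mean_force = 130,
              peak_profile = tibble::tibble(lc_mid = seq(4, 156, 8),
                                            density = rep(1 / 152, 20)))
  base <- posterior_table(obs, prot)
  p0 <- base$posterior[base$protein_id == "a"]
  for (ab in c(2, 5, 20)) {
    prot2 <- prot; prot2$abundance[1] <- ab
    p1 <- posterior_table(obs, prot2)
    expect_gte(p1$posterior[p1$protein_id == "a"], p0)
    p0 <- p1$posterior[p1$protein_id == "a"]
  }
})

test_that("a template cluster is identified inside a decoy proteome", {
  tpl <- synth_templates(3, seed = 73)[2]
  prot <- synth_proteome(tpl, n_decoys = 19, seed = 74)
  sim <- simulate_dataset(tpl, 1, 12, sim_config(seed = 75))
  sigma <- estimate_batch_noise(sim$curves)
  pp <- preprocess_curves(sim$curves)
  sc <- score_traces(pp[filter_spurious(pp, sigma)$kept, ])
  obs <- cluster_observables(sc[sc$keep_quality, ])
  post <- posterior_table(obs, prot)
  expect_equal(post$protein_id[1], tpl[[1]]$template_id)
  expect_equal(sum(post$posterior), 1, tolerance = 1e-9)
  expect_true(all(post$posterior[post$prior == 0] == 0))
})

test_that("the sampling-yield relation solves for either unknown", {
  k <- required_sampling(n1c = 285, ntot = 106528, p2d = 3e4)
  expect_equal(signif(k, 1), 9e-8)
  need <- required_sampling(n1c = 50, k_factor = 9e-8)
  expect_equal(signif(need, 2), 5.6e8)
  expect_equal(required_sampling(n1c = 7, k_factor = 1), 7)
  expect_error(required_sampling(n1c = -1, k_factor = 1), "positive")
  expect_error(required_sampling(n1c = 10), "supply")
})
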