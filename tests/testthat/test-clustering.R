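# toy distance object from an explicit symmetric matrix (Inf = not computed)
toy_dist <- function(d, ids = NULL) {
  n <- nrow(d)
  if (is.null(ids)) ids <- letters[seq_len(n)]
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, computed = is.finite(d)),
            class = "fd_dist")
}

test_that("k-NN density is the quality-weighted negative log radius", {
  d <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(knn_density(toy_dist(d), k = 1)$rho, c(0, 0))
  d <- matrix(exp(-1), 3, 3); diag(d) <- 0
  expect_equal(knn_density(toy_dist(d), k = 2, quality = 0.8)$rho,
               rep(0.8, 3))
  expect_error(knn_density(toy_dist(d), k = 0), "positive")
})

test_that("density ranks match brute-force k-NN radii on a toy set", {
  set.seed(51)
  pts <- matrix(runif(12), 6, 2)
  d <- as.matrix(dist(pts))
  k <- 3
  r_oracle <- apply(d, 1, function(row) sort(row[row > 0])[k])
  rho <- knn_density(toy_dist(d), k = k)$rho
  expect_equal(order(rho), order(-r_oracle))
})

test_that("duplicate traces (zero radius) are handled with a flagged floor", {
  d <- matrix(c(0, 0, 0.5, 0, 0, 0.5, 0.5, 0.5, 0), 3)
  rho <- knn_density(toy_dist(d), k = 1)
  expect_true(all(is.finite(rho$rho)))
})

test_that("delta follows the definition plus the max convention", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2)
  del <- local_delta(c(1, 2), toy_dist(d))
  expect_equal(del$delta, c(0.4, 0.4))
  # five points, hand-assigned densities: exhaustive search oracle
  set.seed(52)
  dm <- as.matrix(dist(matrix(runif(10), 5, 2)))
  rho <- c(3, 1, 4, 2, 5)
  del <- local_delta(rho, toy_dist(dm))$delta
  for (i in 1:5) {
    higher <- which(rho > rho[i])
    expected <- if (length(higher) == 0) max(dm) else min(dm[i, higher])
    expect_equal(del[i], expected)
  }
})

test_that("equal densities break ties by trace order", {
  d <- matrix(0.2, 3, 3); diag(d) <- 0
  del <- local_delta(c(1, 1, 1), toy_dist(d))
  expect_equal(del$delta[1], 0.2) # global max convention: max distance
  expect_equal(del$delta[2], 0.2)
  expect_equal(del$nearest_higher, c(NA, "a", "a"))
})

test_that("center selection respects the separation threshold", {
  d <- matrix(c(0, 0.2, 0.2, 0), 2)
  expect_length(select_centers(c(2, 1), toy_dist(d), 0.3), 1)
  d <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_length(select_centers(c(2, 1), toy_dist(d), 0.3), 2)
})

test_that("assignment chains through the nearest denser neighbour", {
  d <- matrix(c(0, 0.1, 0.5, 0.1, 0, 0.1, 0.5, 0.1, 0), 3)
  lab <- assign_clusters(c(3, 2, 1), toy_dist(d), centers = "a")
  expect_equal(lab$label, c("a", "a", "a"))
  # a point whose only computed neighbours have lower density is unassigned
  d <- matrix(c(0, 0.1, Inf, 0.1, 0, Inf, Inf, Inf, 0), 3)
  lab <- assign_clusters(c(3, 2, 1), toy_dist(d), centers = "a")
  expect_true(is.na(lab$label[3]))
})

test_that("the center set is invariant to input permutation", {
  fx <- fixture_two_template()
  cl1 <- cluster_traces(fx$dist, quality = fx$scored$quality_ratio)
  perm <- sample(length(fx$dist$ids))
  dp <- toy_dist(fx$dist$d[perm, perm], ids = fx$dist$ids[perm])
  cl2 <- cluster_traces(dp, quality = fx$scored$quality_ratio[perm])
  expect_setequal(cl1$centers, cl2$centers)
})

test_that("two-template synthetic mixture is recovered by DPC", {
  tpl <- smfs_templates()[c("T1", "T2")]
  sim <- simulate_dataset(tpl, c(1, 1), 100,
                          sim_config(seed = 303, premature_detach_fraction = 0))
  sigma <- estimate_batch_noise(sim$curves)
  pp <- preprocess_curves(sim$curves)
  sc <- score_traces(pp[filter_spurious(pp, sigma)$kept, ])
  hq <- sc[sc$keep_quality, ]
  dist <- trace_distances(hq, alignment_config(4 * sigma))
  cl <- cluster_traces(dist, quality = hq$quality_ratio)
  pts <- cl$points[!is.na(cl$points$label), ]
  truth <- sim$truth$template_id[match(pts$curve_id, sim$truth$curve_id)]
  # majority-template mapping of each cluster label
  agree <- unsplit(lapply(split(truth, pts$label),
                          function(tt) tt == names(which.max(table(tt)))),
                   pts$label)
  expect_gte(mean(agree), 0.95)
})

test_that("assignment paths terminate at each cluster's center", {
  fx <- fixture_two_template()
  cl <- cluster_traces(fx$dist, quality = fx$scored$quality_ratio)
  nh <- local_delta(cl$points$rho, fx$dist)$nearest_higher
  for (i in seq_along(nh)) {
    if (is.na(cl$points$label[i]) || cl$points$is_center[i]) next
    j <- i
    for (step in seq_along(nh)) {
      j <- match(nh[j], fx$dist$ids)
      if (cl$points$is_center[j]) break
    }
    expect_equal(cl$points$label[j], cl$points$label[i])
  }
})

test_that("balanced three-template mixture recovers balanced clusters", {
  fx <- fixture_three_template()
  sizes <- fx$run$refined$clusters$n_members
  expect_length(sizes, 3)
  # each template contributes ~50 curves; binomial 3 sigma around 50
  sig <- sqrt(150 * (1 / 3) * (2 / 3))
  expect_true(all(abs(sizes - 50) <= 3 * sig))
})
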