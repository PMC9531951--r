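# a minimal scored-trace row for refinement tests
scored_row <- function(id, x, force, lc = NULL) {
  lp <- max(c(0L, which(force > 30)))
  tibble::tibble(curve_id = id, x = list(x), force = list(force),
                 lc = list(if (is.null(lc)) rep(NA_real_, length(x)) else lc),
                 peaks = list(tibble::tibble()),
                 length_points = lp, n_peaks = 0L, quality_ratio = 1)
}

test_that("the area of similarity is a union of exact grid cells", {
  tr <- clean_branch(80, 200, tail_nm = 20)
  center <- scored_row("c", tr$x, tr$force)
  aos1 <- build_aos(center, center[0, ])
  expect_true(aos1$flagged)
  # three identical traces stamp exactly the same cells
  aos3 <- build_aos(center, dplyr::bind_rows(center, center))
  expect_setequal(aos1$cells, aos3$cells)
  # brute-force rasterization oracle on the eligible points
  li <- smfsid:::.last_peak_index(tr$force)
  L <- tr$x[li]
  sel <- tr$force > 30 & tr$x < L
  oracle <- unique(paste(floor(tr$x[sel] / 5), floor(tr$force[sel] / 5),
                         sep = ":"))
  expect_setequal(aos1$cells, oracle)
})

test_that("vertically offset neighbours thicken the envelope", {
  tr <- clean_branch(80, 200, tail_nm = 20)
  center <- scored_row("c", tr$x, tr$force)
  up <- scored_row("u", tr$x, tr$force + 20)
  aos <- build_aos(center, up)
  aos0 <- build_aos(center, center[0, ])
  expect_true(all(aos0$cells %in% aos$cells))
  expect_gt(length(aos$cells), length(aos0$cells))
})

test_that("similarity scoring honours the length filter and scores points", {
  tr <- clean_branch(80, 200, tail_nm = 20)
  center <- scored_row("c", tr$x, tr$force)
  aos <- build_aos(center, center[0, ])
  short <- clean_branch(40, 200, tail_nm = 20)   # final peak ~0.5 L
  long <- clean_branch(124, 200, tail_nm = 20)   # final peak ~1.5 L
  cands <- dplyr::bind_rows(center,
                            scored_row("short", short$x, short$force),
                            scored_row("long", long$x, long$force))
  st <- similarity_threshold(aos, cands)
  expect_false(st$scores$eligible[st$scores$curve_id == "short"])
  expect_false(st$scores$eligible[st$scores$curve_id == "long"])
  # the center scores its own eligible point count
  li <- smfsid:::.last_peak_index(tr$force)
  own <- sum(tr$force > 30 & tr$x < tr$x[li])
  expect_equal(st$scores$score[st$scores$curve_id == "c"], own)
  expect_true(st$flagged) # fewer than 3 eligible candidates
})

test_that("above-threshold recovery separates in- from off-template curves", {
  fx <- fixture_two_template()
  cl <- cluster_traces(fx$dist, quality = fx$scored$quality_ratio)
  # center of the biggest cluster
  main <- names(which.max(table(cl$points$label)))
  i <- match(main, fx$dist$ids)
  dd <- fx$dist$d[i, -i]; dd <- dd[is.finite(dd)]
  nb <- names(sort(dd))[1:2]
  aos <- build_aos(fx$scored[i, ], fx$scored[match(nb, fx$scored$curve_id), ])
  st <- similarity_threshold(aos, fx$scored)
  above_truth <- fx$truth[match(st$above_ids, fx$scored$curve_id)]
  center_truth <- fx$truth[i]
  n_template <- sum(fx$truth == center_truth)
  expect_gte(sum(above_truth == center_truth), round(0.9 * n_template))
})

test_that("clusters sharing above-threshold traces merge; disjoint do not", {
  sets <- list(A = sprintf("t%02d", 1:20), B = sprintf("t%02d", 3:20),
               C = sprintf("u%02d", 1:10))
  m <- merge_clusters(sets)
  expect_length(m$clusters, 2)
  expect_setequal(m$clusters$A, sprintf("t%02d", 1:20))
  expect_true(all(m$merge_log$overlap[m$merge_log$action == "merged"] > 0.4))
  # idempotence: merging the merged sets changes nothing
  m2 <- merge_clusters(m$clusters)
  expect_identical(sort(names(m2$clusters)), sort(names(m$clusters)))
  expect_identical(purrr::map(m2$clusters, sort), purrr::map(m$clusters, sort))
})

test_that("the stopping rule drops residual sub-3 clusters", {
  base <- sprintf("t%02d", 1:20)
  sets <- c(list(A = base),
            purrr::map(1:4, ~ base[seq_len(18 - .x)]),
            list(X = c("z1", "z2"), Y = c("z3", "z4")))
  names(sets) <- c("A", paste0("M", 1:4), "X", "Y")
  m <- merge_clusters(sets)
  expect_setequal(m$dropped, c("X", "Y"))
  expect_length(m$clusters, 1)
})

test_that("a duplicated pattern seeded as two centers survives as one cluster", {
  tpl <- smfs_templates()[1]
  sim <- simulate_dataset(tpl, 1, 40,
                          sim_config(seed = 61, premature_detach_fraction = 0))
  sigma <- estimate_batch_noise(sim$curves)
  pp <- preprocess_curves(sim$curves)
  sc <- score_traces(pp[filter_spurious(pp, sigma)$kept, ])
  hq <- sc[sc$keep_quality, ]
  dist <- trace_distances(hq, alignment_config(4 * sigma))
  cl <- cluster_traces(dist, quality = hq$quality_ratio)
  # force a duplicate center on the same pattern
  extra <- setdiff(dist$ids, cl$centers)[1]
  cl$centers <- c(cl$centers, extra)
  ref <- refine_clusters(cl, hq, dist)
  expect_equal(nrow(ref$clusters), 1)
})

test_that("cluster observables summarise the pooled histogram", {
  tpl <- list(T = protein_template("T", c(40, 120), c(150, 140), "helix"))
  sim <- simulate_dataset(tpl, 1, 15,
                          sim_config(seed = 62, premature_detach_fraction = 0))
  sigma <- estimate_batch_noise(sim$curves)
  pp <- preprocess_curves(sim$curves)
  sc <- score_traces(pp[filter_spurious(pp, sigma)$kept, ])
  obs <- cluster_observables(sc[sc$keep_quality, ])
  expect_gte(obs$lc_max, 112)
  expect_lte(obs$lc_max, 128)
  expect_equal(sum(obs$peak_profile$density) * 8, 1, tolerance = 1e-9)
  expect_gt(obs$mean_force, 100)
  # single member: observables of that trace
  one <- cluster_observables(sc[1, ])
  expect_equal(one$n_members, 1)
})
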