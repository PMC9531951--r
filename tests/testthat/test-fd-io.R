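test_that("curve sets round-trip through the on-disk dialect", {
  dir <- withr::local_tempdir()
  set.seed(81)
  curves <- fd_curve_set(
    c("c1", "c2", "c3"),
    z = purrr::map(1:3, ~ seq(0, 100, by = 0.5)),
    force = purrr::map(1:3, ~ rnorm(201, 50, 10)),
    spring_constant = 840, sample_id = "s1", is_tss = FALSE)
  write_fd_curves(curves, dir)
  back <- read_fd_curves(file.path(dir, "manifest.csv"), dialect = "manifest")
  expect_equal(back$curve_id, curves$curve_id)
  expect_equal(back$spring_constant, rep(840, 3))
  for (i in 1:3) {
    expect_equal(back$z[[i]], curves$z[[i]], tolerance = 1e-9)
    expect_equal(back$force[[i]], curves$force[[i]], tolerance = 1e-9)
  }
  # directory dialect: ids are file stems, lexicographic order
  back2 <- read_fd_curves(dir, dialect = "two_column_tsv")
  expect_equal(back2$curve_id, c("c1", "c2", "c3"))
})

test_that("malformed curve files raise parse errors naming the row", {
  dir <- withr::local_tempdir()
  lines <- c("separation_nm\tforce_pN", paste(1:20, 10 * (1:20), sep = "\t"))
  lines[18] <- "17\tbroken" # data row 17
  writeLines(lines, file.path(dir, "bad.tsv"))
  expect_error(read_fd_curves(dir), "17")
  expect_error(read_fd_curves(file.path(dir, "missing.tsv")), "missing.tsv")
  writeLines(c("wrong\theader", "1\t2"), file.path(dir, "bad.tsv"))
  expect_error(read_fd_curves(file.path(dir, "bad.tsv")), "format|columns")
})

test_that("curve-set invariants are enforced", {
  expect_error(fd_curve_set(c("a", "a"), list(1:3, 1:3),
                            list(1:3, 1:3)), "unique")
  expect_error(fd_curve_set("a", list(1:3), list(1:2)), "lengths differ")
  expect_error(fd_curve_set("a", list(1), list(1)), "fewer than 2")
  expect_error(fd_curve_set("a", list(c(1, NA)), list(c(1, 2))), "finite")
  expect_error(fd_curve_set("a", list(1:3), list(1:3),
                            spring_constant = -1), "> 0")
})

test_that("proteome tables parse, validate, and round-trip", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "prot.tsv")
  writeLines(c(
    "protein_id\tn_residues\tabundance\tis_membrane\tss_class\tfinal_domain_nm\tloop_centers_nm",
    "P1\t248\t3.2\t1\thelix\t0\t12.0;40.5",
    "P2\t500\t1.0\t1\tsheet\t60\t",
    "P3\t300\t0.5\t0\tunknown\t0\t"), path)
  prot <- read_proteome_table(path)
  expect_equal(nrow(prot), 3)
  expect_equal(prot$loop_centers_nm[[1]], c(12, 40.5))
  expect_length(prot$loop_centers_nm[[2]], 0)
  expect_equal(prot$protein_id, c("P1", "P2", "P3")) # order preserved
  # round-trip
  write_proteome_table(prot, file.path(dir, "prot2.tsv"))
  back <- read_proteome_table(file.path(dir, "prot2.tsv"))
  expect_equal(back$n_residues, prot$n_residues)
  expect_equal(back$loop_centers_nm, prot$loop_centers_nm)

  writeLines(c(
    "protein_id\tn_residues\tabundance\tis_membrane\tss_class\tfinal_domain_nm\tloop_centers_nm",
    "P1\t248\t-1\t1\thelix\t0\t"), path)
  expect_error(read_proteome_table(path), "abundance")
  writeLines(c(
    "protein_id\tn_residues\tabundance\tis_membrane\tss_class\tfinal_domain_nm\tloop_centers_nm",
    "P1\t248\t1\t2\thelix\t0\t"), path)
  expect_error(read_proteome_table(path), "is_membrane")
  writeLines(c(
    "protein_id\tn_residues\tabundance\tis_membrane\tss_class\tfinal_domain_nm\tloop_centers_nm",
    "P1\t248\t1\t1\thelix\t0\t",
    "P1\t300\t1\t1\thelix\t0\t"), path)
  expect_error(read_proteome_table(path), "duplicate")
})

test_that("result reports are written with normalised candidate tables", {
  dir <- withr::local_tempdir()
  fx <- fixture_three_template()
  refined <- fx$run$refined
  prot <- synth_proteome(smfs_templates(), n_decoys = 2, seed = 82)
  post <- identify_clusters(refined, prot)
  files <- write_results(refined, post, file.path(dir, "out"),
                         config = list(seed = 1, r_cut = 0.3))
  summ <- readr::read_tsv(file.path(dir, "out", "cluster_summary.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(summ), nrow(refined$clusters))
  for (cid in refined$clusters$cluster_id) {
    tab <- readr::read_tsv(
      file.path(dir, "out", sprintf("candidates_%s.tsv", cid)),
      show_col_types = FALSE)
    expect_equal(sum(tab$posterior), 1, tolerance = 1e-9)
  }
  # member list round-trips to the in-memory assignment
  mem <- readr::read_tsv(file.path(dir, "out", "cluster_members.tsv"),
                         show_col_types = FALSE)
  for (i in seq_len(nrow(refined$clusters))) {
    expect_setequal(mem$members[mem$cluster_id ==
                                  refined$clusters$cluster_id[i]],
                    refined$clusters$members[[i]])
  }
  expect_true(file.exists(file.path(dir, "out", "run_config.json")))
})

test_that("an empty clustering writes an empty summary without error", {
  dir <- withr::local_tempdir()
  empty <- structure(list(
    clusters = tibble::tibble(cluster_id = character(0),
                              n_members = integer(0), members = list()),
    observables = tibble::tibble(cluster_id = character(0),
                                 n_members = integer(0),
                                 lc_max = numeric(0),
                                 mean_force = numeric(0)),
    merge_log = NULL, thresholds = numeric(0), dropped = character(0)),
    class = "smfs_refined")
  expect_no_error(write_results(empty, NULL, file.path(dir, "out")))
  summ <- readr::read_tsv(file.path(dir, "out", "cluster_summary.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(summ), 0)
})
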