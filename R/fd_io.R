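#' Assemble a set of force-distance curves
#'
#' A curve set is a tibble with one row per retraction curve and list-columns
#' holding the numeric arrays. This constructor validates the invariants every
#' downstream stage relies on: equal-length position/force arrays with at
#' least two finite points, positive spring constants, unique curve ids.
#'
#' @param curve_id Character vector of unique curve identifiers.
#' @param z List of numeric position arrays (nm): piezo position, or
#'   tip-sample separation when `is_tss` is `TRUE`.
#' @param force List of numeric force arrays (pN), same lengths as `z`.
#' @param spring_constant Cantilever stiffness in pN/nm (recycled).
#' @param sample_id Sample identifier (recycled).
#' @param is_tss Logical: `TRUE` when `z` is already tip-sample separation and
#'   no bending correction is required (recycled).
#' @return A tibble of class `fd_curve_set`.
#' @export
fd_curve_set <- function(curve_id, z, force, spring_constant = 840,
                         sample_id = "sample", is_tss = FALSE) {
  n <- length(curve_id)
  if (anyDuplicated(curve_id)) stop("curve ids must be unique", call. = FALSE)
  stopifnot(length(z) == n, length(force) == n)
  purrr::pwalk(list(curve_id, z, force), function(id, zi, fi) {
    if (length(zi) != length(fi)) {
      stop(sprintf("curve '%s': position and force lengths differ", id),
           call. = FALSE)
    }
    if (length(zi) < 2) {
      stop(sprintf("curve '%s': fewer than 2 points", id), call. = FALSE)
    }
    if (!all(is.finite(zi)) || !all(is.finite(fi))) {
      stop(sprintf("curve '%s': non-finite values", id), call. = FALSE)
    }
  })
  spring_constant <- rep_len(spring_constant, n)
  if (any(spring_constant <= 0)) {
    stop("spring_constant must be > 0", call. = FALSE)
  }
  out <- tibble::tibble(
    curve_id = as.character(curve_id),
    z = unname(z), force = unname(force),
    spring_constant = spring_constant,
    sample_id = rep_len(as.character(sample_id), n),
    is_tss = rep_len(as.logical(is_tss), n)
  )
  class(out) <- c("fd_curve_set", class(out))
  out
}

# parse one two-column F-D TSV; returns list(z, force, is_tss)
.read_fd_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(sprintf("parse error in '%s' at row %d: %s", path,
                 probs$row[1], probs$expected[1]), call. = FALSE)
  }
  nms <- names(df)
  pos_col <- intersect(c("separation_nm", "piezo_nm"), nms)
  if (length(pos_col) != 1 || !("force_pN" %in% nms)) {
    stop(sprintf("format error in '%s': expected columns %s",
                 path, "'separation_nm' or 'piezo_nm' plus 'force_pN'"),
         call. = FALSE)
  }
  z <- df[[pos_col]]; f <- df[["force_pN"]]
  if (!is.numeric(z) || !is.numeric(f)) {
    bad_col <- if (!is.numeric(z)) pos_col else "force_pN"
    bad_row <- which(is.na(suppressWarnings(
      as.numeric(df[[bad_col]]))) & !is.na(df[[bad_col]]))[1]
    stop(sprintf("parse error in '%s': non-numeric cell at row %s",
                 path, ifelse(is.na(bad_row), "?", bad_row)), call. = FALSE)
  }
  if (anyNA(z) || anyNA(f)) {
    bad_row <- which(is.na(z) | is.na(f))[1]
    stop(sprintf("parse error in '%s': missing value at row %d", path, bad_row),
         call. = FALSE)
  }
  list(z = z, force = f, is_tss = pos_col == "separation_nm")
}

#' Read force-distance curves from disk
#'
#' Two dialects are supported. `"two_column_tsv"`: `path` is a directory (or a
#' vector of files) of headered TSVs with columns `separation_nm` (or
#' `piezo_nm`) and `force_pN`; `#`-prefixed metadata lines are skipped and
#' curve ids are the file stems. `"manifest"`: `path` is a CSV with columns
#' `file`, `spring_constant_pN_per_nm`, `sample_id`; files are resolved
#' relative to the manifest and read in manifest order.
#'
#' @param path Directory, file vector, or manifest CSV path.
#' @param dialect One of `"two_column_tsv"`, `"manifest"`.
#' @param spring_constant Default cantilever stiffness (pN/nm) for curves the
#'   manifest leaves blank, and for all curves in the two-column dialect.
#' @param sample_id Default sample id.
#' @return An [fd_curve_set()] tibble.
#' @export
read_fd_curves <- function(path, dialect = c("two_column_tsv", "manifest"),
                           spring_constant = 840, sample_id = "sample") {
  dialect <- match.arg(dialect)
  if (dialect == "manifest") {
    if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
    man <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("file", "spring_constant_pN_per_nm", "sample_id") %in% names(man))) {
      stop("manifest must have columns file, spring_constant_pN_per_nm, sample_id",
           call. = FALSE)
    }
    files <- file.path(dirname(path), man$file)
    k <- ifelse(is.na(man$spring_constant_pN_per_nm), spring_constant,
                man$spring_constant_pN_per_nm)
    sid <- ifelse(is.na(man$sample_id), sample_id, man$sample_id)
  } else {
    files <- if (length(path) == 1 && dir.exists(path)) {
      sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
    } else path
    k <- rep_len(spring_constant, length(files))
    sid <- rep_len(sample_id, length(files))
  }
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    stop(sprintf("cannot read '%s'", missing[1]), call. = FALSE)
  }
  parsed <- purrr::map(files, .read_fd_tsv)
  out <- fd_curve_set(
    curve_id = tools::file_path_sans_ext(basename(files)),
    z = purrr::map(parsed, "z"),
    force = purrr::map(parsed, "force"),
    spring_constant = k, sample_id = sid,
    is_tss = purrr::map_lgl(parsed, "is_tss")
  )
  attr(out, "provenance") <- files
  out
}

#' Read a proteome table
#'
#' The proteome table carries, for every candidate protein, the information the
#' Bayesian identification consumes: residue count (hence nominal contour
#' length at 0.4 nm/residue), mass-spectrometry abundance (emPAI, PSM count or
#' coverage — assumed pre-normalised to one scheme per run), a binary
#' membrane-protein flag, a secondary-structure class, the length of the
#' terminal soluble domain, and loop-center positions along the unfolded
#' contour measured from the pulled terminus.
#'
#' @param path TSV with columns `protein_id`, `n_residues`, `abundance`,
#'   `is_membrane`, `ss_class`, `final_domain_nm`, `loop_centers_nm`
#'   (semicolon-separated list, may be empty).
#' @return A tibble with one row per protein; `loop_centers_nm` is a
#'   list-column of numeric vectors.
#' @export
read_proteome_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          protein_id = readr::col_character(),
                          ss_class = readr::col_character(),
                          loop_centers_nm = readr::col_character(),
                          .default = readr::col_double()
                        ))
  req <- c("protein_id", "n_residues", "abundance", "is_membrane",
           "ss_class", "final_domain_nm", "loop_centers_nm")
  if (!all(req %in% names(df))) {
    stop("proteome table missing columns: ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$protein_id)) {
    stop("duplicate protein_id in proteome table", call. = FALSE)
  }
  if (any(df$abundance < 0)) stop("negative abundance", call. = FALSE)
  if (!all(df$is_membrane %in% c(0, 1))) {
    stop("is_membrane must be 0 or 1", call. = FALSE)
  }
  if (any(df$n_residues <= 0)) stop("n_residues must be > 0", call. = FALSE)
  loops <- purrr::map(df$loop_centers_nm, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  bad <- purrr::map2_lgl(loops, df$n_residues, function(l, nr) {
    length(l) > 0 && (any(!is.finite(l)) || any(l < 0) || any(l > nr * 0.4))
  })
  if (any(bad)) {
    stop("loop centers outside [0, n_residues * 0.4] for: ",
         paste(df$protein_id[bad], collapse = ", "), call. = FALSE)
  }
  df$ss_class[is.na(df$ss_class)] <- "unknown"
  df$loop_centers_nm <- loops
  df$final_domain_nm[is.na(df$final_domain_nm)] <- 0
  df
}

#' Write a proteome table
#'
#' Inverse of [read_proteome_table()]; loop-center list-columns are serialised
#' as semicolon-separated strings.
#'
#' @param proteome Proteome tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_proteome_table <- function(proteome, path) {
  out <- proteome
  out$loop_centers_nm <- purrr::map_chr(
    proteome$loop_centers_nm, ~ paste(format(.x, trim = TRUE), collapse = ";"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write pipeline result reports
#'
#' Writes (a) a per-cluster member list TSV, (b) a cluster summary TSV
#' (id, size, maximal contour length, mean unfolding force), (c) one
#' ranked-candidate TSV per cluster with posterior probabilities, and (d) a
#' JSON snapshot of the run configuration.
#'
#' @param refined A refined clustering from [refine_clusters()].
#' @param posteriors Posterior tibble from [identify_clusters()], or `NULL`.
#' @param path Output directory (created if needed).
#' @param config Run configuration to snapshot (any list), or `NULL`.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(refined, posteriors = NULL, path, config = NULL) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("cannot write to '%s'", path), call. = FALSE)
  written <- character(0)
  members <- if (nrow(refined$clusters) > 0) {
    tidyr::unnest(refined$clusters[c("cluster_id", "members")],
                  cols = "members")
  } else {
    tibble::tibble(cluster_id = character(0), members = character(0))
  }
  f <- file.path(path, "cluster_members.tsv")
  readr::write_tsv(members, f, progress = FALSE); written <- c(written, f)

  summ <- refined$observables
  f <- file.path(path, "cluster_summary.tsv")
  cols <- intersect(c("cluster_id", "n_members", "lc_max", "mean_force"),
                    names(summ))
  readr::write_tsv(summ[cols], f, progress = FALSE); written <- c(written, f)

  if (!is.null(posteriors) && nrow(posteriors) > 0) {
    for (cid in unique(posteriors$cluster_id)) {
      tab <- dplyr::arrange(
        dplyr::filter(posteriors, .data$cluster_id == cid),
        dplyr::desc(.data$posterior))
      f <- file.path(path, sprintf("candidates_%s.tsv", cid))
      readr::write_tsv(tab, f, progress = FALSE); written <- c(written, f)
    }
  }
  if (!is.null(config)) {
    f <- file.path(path, "run_config.json")
    jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                         null = "null")
    written <- c(written, f)
  }
  invisible(written)
}

#' Write a curve set to two-column TSV files
#'
#' One file per curve (`<curve_id>.tsv`) plus a `manifest.csv`, forming the
#' canonical on-disk dialect read back by [read_fd_curves()].
#'
#' @param curves An [fd_curve_set()].
#' @param path Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_fd_curves <- function(curves, path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("cannot write to '%s'", path), call. = FALSE)
  purrr::pwalk(curves[c("curve_id", "z", "force", "is_tss")],
               function(curve_id, z, force, is_tss) {
    col <- if (is_tss) "separation_nm" else "piezo_nm"
    df <- tibble::tibble(!!col := z, force_pN = force)
    readr::write_tsv(df, file.path(path, paste0(curve_id, ".tsv")),
                     progress = FALSE)
  })
  man <- tibble::tibble(file = paste0(curves$curve_id, ".tsv"),
                        spring_constant_pN_per_nm = curves$spring_constant,
                        sample_id = curves$sample_id)
  mpath <- file.path(path, "manifest.csv")
  readr::write_csv(man, mpath, progress = FALSE)
  invisible(mpath)
}
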