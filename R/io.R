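#' Read the bundled demographic comparison fixture
#'
#' A transcription of a two-group cohort's demographic summaries (mean
#' and sd per measure, 2x2 counts for gender) with the originally
#' printed p-values, in the machine form accepted by [cohort_table()].
#'
#' @param path Optional path to an alternative TSV.
#' @return Tibble with columns `measure`, `type`, `a1`, `a2`, `b1`,
#'   `b2`, `n_a`, `n_b`, `printed_p`.
#' @export
read_table1_fixture <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table1_cohort.tsv",
                                package = "restconn", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    measure = "c", type = "c", printed_p = "c",
                    .default = "d"))
}

#' Read the bundled significant-edge table fixture
#'
#' A transcription of the 46 ROI pairs reported as significantly
#' different between the two groups, with direction blocks and printed
#' permutation p-values.
#'
#' @param path Optional path to an alternative TSV.
#' @return Tibble of class `edge_stat_tbl` with columns `direction`,
#'   `roi_a_name`, `roi_a_abbrev`, `roi_b_name`, `roi_b_abbrev`, `p`.
#' @export
read_table2_fixture <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table2_edges.tsv",
                                package = "restconn", mustWork = TRUE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("direction", "roi_a_name", "roi_a_abbrev",
                "roi_b_name", "roi_b_abbrev", "p_value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop_restconn(paste0("fixture lacks columns: ",
                         paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) stop_restconn("fixture is empty")
  bad <- which(is.na(raw$p_value) | !nzchar(raw$direction))
  if (length(bad)) {
    stop_restconn(sprintf("malformed fixture row(s): %s",
                          paste(bad + 1L, collapse = ", ")))
  }
  out <- raw |>
    dplyr::rename(p = "p_value") |>
    as_tibble()
  attr(out, "direction_labels") <- unique(out$direction)
  class(out) <- c("edge_stat_tbl", class(out))
  out
}

#' Write a simulated cohort to a directory tree
#'
#' Layout: `participants.tsv` (id, group, score), `ground_truth.json`,
#' and per participant a directory with `roi_timeseries.tsv` (one row
#' per ROI, first column the ROI abbreviation, remaining columns the
#' volumes), `motion.par` (T x 6 whitespace-separated), `wm.tsv`
#' and `csf.tsv` nuisance voxel matrices. With `voxel_mode` cohorts and
#' the RNifti package installed, 4D voxel images and an integer ROI
#' label image are written as NIfTI.
#'
#' @param cohort A `restconn_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "restconn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$participants, file.path(dir, "participants.tsv"))
  gt <- cohort$ground_truth
  gt_json <- list(
    effect_edges = gt$effect_edges,
    score_edge = gt$score_edge,
    spike_counts = gt$spike_counts,
    base_correlation = NULL
  )
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  abbrev <- if (!is.null(cohort$parcellation)) cohort$parcellation$abbrev
            else sprintf("ROI%03d", seq_len(cohort$config$n_rois))
  for (id in cohort$participants$id) {
    pdir <- file.path(dir, id)
    dir.create(pdir, showWarnings = FALSE)
    ts <- cohort$timeseries[[id]]
    df <- as.data.frame(ts)
    names(df) <- sprintf("vol%03d", seq_len(ncol(ts)))
    df <- cbind(roi = abbrev, df)
    readr::write_tsv(as_tibble(df), file.path(pdir, "roi_timeseries.tsv"))
    utils::write.table(format(cohort$motion[[id]], digits = 10, trim = TRUE),
                       file.path(pdir, "motion.par"),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    readr::write_tsv(as_tibble(as.data.frame(cohort$wm[[id]]),
                               .name_repair = "unique_quiet"),
                     file.path(pdir, "wm.tsv"), col_names = FALSE)
    readr::write_tsv(as_tibble(as.data.frame(cohort$csf[[id]]),
                               .name_repair = "unique_quiet"),
                     file.path(pdir, "csf.tsv"), col_names = FALSE)
    if (!is.null(cohort$voxels) &&
        requireNamespace("RNifti", quietly = TRUE)) {
      vox <- cohort$voxels[[id]]
      nv <- nrow(vox$voxels)
      arr <- array(t(vox$voxels), dim = c(nv, 1, 1, ncol(vox$voxels)))
      RNifti::writeNifti(RNifti::asNifti(arr),
                         file.path(pdir, "bold.nii.gz"))
      lab <- array(as.numeric(vox$labels), dim = c(nv, 1, 1))
      RNifti::writeNifti(RNifti::asNifti(lab),
                         file.path(pdir, "roi_labels.nii.gz"))
    }
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list with the same shape as a `restconn_cohort`
#'   (participants, timeseries, motion, wm, csf, ground_truth).
#' @export
read_cohort <- function(dir) {
  pfile <- file.path(dir, "participants.tsv")
  if (!file.exists(pfile)) stop_restconn("participants.tsv not found")
  participants <- readr::read_tsv(pfile, show_col_types = FALSE,
                                  progress = FALSE)
  gt_file <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_file)) {
    jsonlite::read_json(gt_file, simplifyVector = TRUE)
  }
  read_mat <- function(path, skip_col = FALSE, col_names = TRUE) {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          col_names = col_names)
    if (skip_col) df <- df[, -1]
    as.matrix(df)
  }
  ids <- participants$id
  timeseries <- lapply(ids, function(id) {
    m <- read_mat(file.path(dir, id, "roi_timeseries.tsv"), skip_col = TRUE)
    unname(m)
  })
  motion <- lapply(ids, function(id) {
    as.matrix(utils::read.table(file.path(dir, id, "motion.par")))
  })
  wm <- lapply(ids, function(id) {
    unname(read_mat(file.path(dir, id, "wm.tsv"), col_names = FALSE))
  })
  csf <- lapply(ids, function(id) {
    unname(read_mat(file.path(dir, id, "csf.tsv"), col_names = FALSE))
  })
  names(timeseries) <- names(motion) <- names(wm) <- names(csf) <- ids
  structure(list(participants = participants, timeseries = timeseries,
                 motion = motion, wm = wm, csf = csf,
                 ground_truth = ground_truth, config = NULL),
            class = "restconn_cohort")
}

#' Write an edge statistics table as TSV
#'
#' @param stats An `edge_stat_tbl`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_stats <- function(stats, path) {
  readr::write_tsv(as_tibble(stats), path)
  invisible(path)
}
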