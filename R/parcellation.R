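#' Read a parcellation label table
#'
#' A parcellation table defines the fixed ordering of regions of interest
#' (ROIs) used by every connectivity matrix in the package: row/column `k`
#' of a matrix always refers to the ROI with `index == k`.
#'
#' The expected format is a tab-separated file with the header
#' `index name abbrev hemisphere`, 1-based contiguous indices and unique
#' abbreviations.
#'
#' @param path Path to a TSV file. Defaults to the bundled 112-region
#'   bilateral grey-matter table (56 regions per hemisphere, subcortical
#'   structures included), whose nomenclature follows common neuroanatomical
#'   labels such as "Left lateral orbital gyrus" (LOrG.L).
#' @return A tibble with columns `index`, `name`, `abbrev`, `hemisphere`
#'   and attribute `region_count`.
#' @export
#' @examples
#' p <- read_parcellation()
#' nrow(p) # 112
read_parcellation <- function(path = NULL) {
  path <- path %||% system.file("extdata", "parcellation_112.tsv",
                                package = "restconn", mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("index", "name", "abbrev", "hemisphere")
  if (!all(required %in% names(tab))) {
    stop_restconn(paste0(
      "parcellation table must have columns: ", paste(required, collapse = ", ")))
  }
  tab <- as_tibble(tab[required])
  if (any(duplicated(tab$abbrev))) {
    dup <- unique(tab$abbrev[duplicated(tab$abbrev)])
    stop_restconn(paste0("duplicated ROI abbreviations: ",
                         paste(dup, collapse = ", ")))
  }
  if (!identical(as.integer(tab$index), seq_len(nrow(tab)))) {
    stop_restconn("parcellation indices must be contiguous starting at 1")
  }
  attr(tab, "region_count") <- nrow(tab)
  class(tab) <- c("restconn_parcellation", class(tab))
  tab
}

#' The bundled 112-region parcellation
#'
#' @return The default parcellation tibble (see [read_parcellation()]).
#' @export
default_parcellation <- function() read_parcellation()

#' Map between edge list positions and ROI pairs
#'
#' Edges are ordered by row-major flattening of the upper triangle of a
#' connectivity matrix: (1,2), (1,3), ..., (1,n), (2,3), ...  For the
#' default 112-region parcellation this yields 6216 edges.
#'
#' @param n_rois Number of ROIs.
#' @param parcellation Optional parcellation tibble used to attach
#'   abbreviations.
#' @return A tibble with columns `edge`, `roi_i`, `roi_j` (1-based ROI
#'   indices, `roi_i < roi_j`) and, when a parcellation is supplied,
#'   `abbrev_i`, `abbrev_j`.
#' @export
edge_index_table <- function(n_rois, parcellation = NULL) {
  n_rois <- check_count(n_rois, "n_rois", min = 2L)
  i <- rep.int(seq_len(n_rois - 1L), times = (n_rois - 1L):1L)
  j <- unlist(lapply(seq_len(n_rois - 1L), function(k) (k + 1L):n_rois),
              use.names = FALSE)
  out <- tibble(edge = seq_along(i), roi_i = i, roi_j = j)
  if (!is.null(parcellation)) {
    out$abbrev_i <- parcellation$abbrev[out$roi_i]
    out$abbrev_j <- parcellation$abbrev[out$roi_j]
  }
  out
}
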