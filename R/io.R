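# Delimited-text readers and writers: dense or sparse-triplet adjacency
# plus region metadata for connectomes, and validated region tables for
# per-mouse pathology. All files are UTF-8 CSV with a header row; writers
# prepend a "#" provenance comment that readers skip.

ns_header <- function(extra = NULL) {
  v <- tryCatch(as.character(utils::packageVersion("netspread")),
                error = function(e) "dev")
  paste0("# netspread ", v,
         if (!is.null(extra)) paste0("; ", extra) else "")
}

write_with_header <- function(df, path, extra = NULL) {
  readr::write_lines(ns_header(extra), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
}

read_csv_quiet <- function(path, ...) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Write a connectome to delimited files
#'
#' @param x A [connectome].
#' @param matrix_path Destination for the adjacency: dense CSV (header row
#'   and leading label column) or sparse triplet CSV
#'   (`source,target,weight`, zero entries omitted).
#' @param metadata_path Destination for the region metadata table
#'   (`acronym, hemisphere, size, x, y, z, parent_acronym, n_daughters,
#'   is_seed`).
#' @param format `"dense"` or `"triplet"`.
#' @return Invisibly, `x`.
#' @export
write_connectome <- function(x, matrix_path, metadata_path,
                             format = c("dense", "triplet")) {
  stopifnot(inherits(x, "connectome"))
  format <- match.arg(format)
  labels <- rownames(x$adjacency)
  if (format == "dense") {
    df <- tibble::as_tibble(x$adjacency)
    df <- dplyr::bind_cols(tibble::tibble(label = labels), df)
    write_with_header(df, matrix_path, "dense adjacency")
  } else {
    idx <- which(x$adjacency > 0, arr.ind = TRUE)
    df <- tibble::tibble(
      source = labels[idx[, 1]],
      target = labels[idx[, 2]],
      weight = x$adjacency[idx]
    )
    write_with_header(df, matrix_path, "triplet adjacency")
  }
  meta <- x$regions
  meta$is_seed <- meta$hemisphere == "ipsi" &
    meta$acronym %in% (x$seeds %||% character(0))
  write_with_header(meta, metadata_path, "region metadata")
  invisible(x)
}

#' Read a connectome from delimited files
#'
#' Accepts the dense or sparse-triplet adjacency format written by
#' [write_connectome()] (auto-detected from the header). Labels in the
#' matrix file are checked exhaustively against the metadata; every
#' unmatched label is reported.
#'
#' @param matrix_path Adjacency file (dense or triplet CSV).
#' @param metadata_path Region metadata CSV.
#' @param format `"auto"` (default), `"dense"`, or `"triplet"`.
#' @return A [connectome]; seeds are restored from the metadata's
#'   `is_seed` column when present.
#' @export
read_connectome <- function(matrix_path, metadata_path,
                            format = c("auto", "dense", "triplet")) {
  format <- match.arg(format)
  meta <- read_csv_quiet(metadata_path)
  required <- c("acronym", "hemisphere", "size", "x", "y", "z")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("Metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  labels <- region_label(meta$acronym, meta$hemisphere)
  mat <- read_csv_quiet(matrix_path)
  if (format == "auto") {
    format <- if (identical(names(mat)[1:3], c("source", "target", "weight")) &&
                  ncol(mat) == 3) "triplet" else "dense"
  }
  if (format == "triplet") {
    bad <- setdiff(unique(c(mat$source, mat$target)), labels)
    if (length(bad) > 0) {
      abort(paste0("Adjacency label(s) absent from metadata: ",
                   paste(bad, collapse = ", ")))
    }
    A <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    A[cbind(match(mat$source, labels), match(mat$target, labels))] <-
      mat$weight
  } else {
    row_labels <- mat[[1]]
    col_labels <- names(mat)[-1]
    bad <- unique(c(setdiff(row_labels, labels),
                    setdiff(col_labels, labels),
                    setdiff(labels, row_labels),
                    setdiff(labels, col_labels)))
    if (length(bad) > 0) {
      abort(paste0("Label mismatch between adjacency and metadata: ",
                   paste(bad, collapse = ", ")))
    }
    A <- as.matrix(mat[, -1])
    rownames(A) <- row_labels
    A <- A[labels, labels, drop = FALSE]
  }
  seeds <- NULL
  if ("is_seed" %in% names(meta) && any(meta$is_seed)) {
    seeds <- sort(meta$acronym[meta$is_seed & meta$hemisphere == "ipsi"])
  }
  meta$is_seed <- NULL
  connectome(A, meta, seeds = seeds)
}

#' Read and validate a per-mouse region table
#'
#' Required columns: `mouse_id`, `genotype`, `treatment`, `sex`, `mpi`,
#'   `hemisphere`, `region`, `pct_area` (`n_daughters` is optional and
#' defaults to 0). Validation rejects negative percent areas, hemisphere
#' values outside ipsi/contra, sexes outside M/F, non-positive
#' timepoints, and duplicated (mouse, hemisphere, region, timepoint)
#' rows, citing the offending row numbers.
#'
#' @param path CSV file (lines starting with `#` are skipped).
#' @return A validated tibble.
#' @export
read_region_table <- function(path) {
  data <- read_csv_quiet(path)
  validate_region_table(data)
}

validate_region_table <- function(data) {
  required <- c("mouse_id", "genotype", "treatment", "sex", "mpi",
                "hemisphere", "region", "pct_area")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Region table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"n_daughters" %in% names(data)) data$n_daughters <- 0L
  cite <- function(rows, what) {
    abort(sprintf("%s at row(s): %s", what,
                  paste(head(rows, 10), collapse = ", ")))
  }
  bad <- which(!is.finite(data$pct_area) | data$pct_area < 0)
  if (length(bad) > 0) cite(bad, "Negative or missing `pct_area`")
  bad <- which(!data$hemisphere %in% c("ipsi", "contra"))
  if (length(bad) > 0) cite(bad, "`hemisphere` must be ipsi/contra")
  bad <- which(!data$sex %in% c("M", "F"))
  if (length(bad) > 0) cite(bad, "`sex` must be M/F")
  bad <- which(!is.finite(data$mpi) | data$mpi <= 0)
  if (length(bad) > 0) cite(bad, "`mpi` must be positive months")
  key <- paste(data$mouse_id, data$hemisphere, data$region, data$mpi,
               sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad) > 0) {
    cite(bad, "Duplicate (mouse, hemisphere, region, mpi) rows")
  }
  tibble::as_tibble(data)
}

#' Write a region table to CSV
#'
#' @param data A region table.
#' @param path Destination CSV path.
#' @return Invisibly, `data`.
#' @export
write_region_table <- function(data, path) {
  write_with_header(data, path, "region table")
  invisible(data)
}
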