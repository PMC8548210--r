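#' Construct a region-by-sample signal matrix
#'
#' The container for CUT&RUN-style read densities: a numeric matrix of
#' regions by samples plus a sample sheet (condition, antibody, replicate,
#' library size). Raw and normalized layers are never conflated: the
#' object records whether, and how, it was normalized.
#'
#' @param values Numeric matrix, regions x samples, non-negative.
#' @param regions Interval tibble with an `id` column (one row per matrix
#'   row).
#' @param samples Tibble with columns `sample_id`, `condition`,
#'   `antibody`, `replicate`, `library_size` (one row per matrix column).
#' @param normalized Logical; label describing the values layer.
#' @param normalization Character description of the normalization applied
#'   (`NULL` for raw).
#'
#' @return An object of class `signal_matrix`.
#' @export
signal_matrix <- function(values, regions, samples, normalized = FALSE,
                          normalization = NULL) {
  values <- as.matrix(values)
  regions <- validate_intervals(regions)
  samples <- tibble::as_tibble(samples)
  if (!"id" %in% names(regions)) {
    regions$id <- sprintf("region_%05d", seq_len(nrow(regions)))
  }
  need <- c("sample_id", "condition", "antibody", "replicate",
            "library_size")
  if (!all(need %in% names(samples))) {
    rlang::abort(paste("sample sheet needs columns:",
                       paste(need, collapse = ", ")),
                 class = "chromclip_validation_error")
  }
  if (nrow(values) != nrow(regions) || ncol(values) != nrow(samples)) {
    rlang::abort("values shape must match regions x samples",
                 class = "chromclip_shape_error")
  }
  if (any(values < 0)) {
    rlang::abort("signal values must be non-negative",
                 class = "chromclip_validation_error")
  }
  rownames(values) <- regions$id
  colnames(values) <- samples$sample_id
  structure(
    list(values = values, regions = regions, samples = samples,
         normalized = normalized, normalization = normalization),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf(
    "<signal_matrix> %d regions x %d samples (%s)\n",
    nrow(x$values), ncol(x$values),
    if (x$normalized) paste0("normalized: ", x$normalization) else "raw"
  ))
  cat("conditions:",
      paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

#' Tidy a signal matrix into long format
#'
#' @param x A `signal_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per (region, sample) cell, joined to the
#'   sample sheet.
#' @export
tidy.signal_matrix <- function(x, ...) {
  long <- tibble::as_tibble(x$values, rownames = "region_id") |>
    tidyr::pivot_longer(-"region_id", names_to = "sample_id",
                        values_to = "value")
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Read and write a signal matrix as plain-text files
#'
#' Three files: regions as BED (with the region id in the name column),
#' values as a TSV of region_id by sample_id, and a sample sheet TSV with
#' columns `sample_id`, `condition`, `antibody`, `replicate`,
#' `library_size`.
#'
#' @param values_path,regions_path,samples_path File paths.
#' @return A `signal_matrix`.
#' @export
read_signal_matrix <- function(values_path, regions_path, samples_path) {
  regions <- read_bed(regions_path)
  samples <- readr::read_tsv(samples_path, col_types = "cccid",
                             progress = FALSE)
  vals <- readr::read_tsv(values_path, col_types = readr::cols(
    region_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(vals[setdiff(names(vals), "region_id")])
  m <- m[match(regions$id, vals$region_id), samples$sample_id, drop = FALSE]
  signal_matrix(m, regions, samples)
}

#' @rdname read_signal_matrix
#' @param x A `signal_matrix`.
#' @export
write_signal_matrix <- function(x, values_path, regions_path,
                                samples_path) {
  write_bed(x$regions, regions_path)
  readr::write_tsv(x$samples, samples_path, progress = FALSE)
  vals <- tibble::as_tibble(x$values, rownames = "region_id")
  readr::write_tsv(vals, values_path, progress = FALSE)
  invisible(x)
}

# Column indices of a condition, in replicate order.
.cond_cols <- function(x, condition) {
  i <- which(x$samples$condition == condition)
  if (length(i) == 0) {
    rlang::abort(sprintf("condition '%s' absent from sample sheet",
                         condition),
                 class = "chromclip_argument_error")
  }
  i[order(x$samples$replicate[i])]
}
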