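#' Read and write chrom.sizes files
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path File path.
#' @return [read_chrom_sizes()] returns a genome layout tibble.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  genome_layout(x$chrom, x$length)
}

#' @rdname read_chrom_sizes
#' @param genome Genome layout tibble.
#' @export
write_chrom_sizes <- function(genome, path) {
  readr::write_tsv(genome, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED3 (`chrom`, `start`, `end`) or BED6 (plus `id`, `score`, `strand`),
#' 0-based half-open. Writers emit records sorted by chromosome and start,
#' tab-separated and newline-terminated.
#'
#' @param path File path.
#' @return A validated interval tibble.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_guess()))
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 6) names(x)[4:6] <- c("id", "score", "strand")
  if (ncol(x) == 4) names(x)[4] <- "id"
  validate_intervals(x)
}

#' @rdname read_bed
#' @param x Interval tibble.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "id", "score", "strand"),
                    names(x))
  if (all(c("id", "strand") %in% cols) && !"score" %in% cols) {
    x$score <- 0
    cols <- append(cols, "score", after = which(cols == "id"))
  }
  out <- dplyr::arrange(x[cols], .data$chrom, .data$start, .data$end)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write gene annotations (BED6 + biotype dialect)
#'
#' Seven tab-separated columns: `chrom`, `start`, `end`, `gene_id`,
#' `score`, `strand`, `biotype` with biotype in
#' `{coding, lincRNA, other}`. The transcription start site is derived
#' from strand: `start` on `+`, `end - 1` on `-`.
#'
#' @param path File path.
#' @return Gene annotation tibble with a computed `tss` column.
#' @export
read_genes <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "gene_id", "score", "strand",
                  "biotype"),
    col_types = "cddcdcc", progress = FALSE
  )
  x <- validate_intervals(x)
  x$tss <- ifelse(x$strand == "-", x$end - 1, x$start)
  x
}

#' @rdname read_genes
#' @param genes Gene annotation tibble.
#' @export
write_genes <- function(genes, path) {
  out <- dplyr::arrange(
    genes[c("chrom", "start", "end", "gene_id", "score", "strand",
            "biotype")],
    .data$chrom, .data$start, .data$end
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write PAR-CLIP peaks (BED6 + 3 dialect)
#'
#' Nine tab-separated columns: BED6 (`chrom`, `start`, `end`, `id`,
#' `score`, `strand`) plus `read_total`, `conversion_count`, `rpkm`.
#'
#' @param path File path.
#' @return Peak tibble.
#' @export
read_peaks <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "id", "score", "strand",
                  "read_total", "conversion_count", "rpkm"),
    col_types = "cddcdcddd", progress = FALSE
  )
  validate_intervals(x)
}

#' @rdname read_peaks
#' @param peaks Peak tibble.
#' @export
write_peaks <- function(peaks, path) {
  if (!"score" %in% names(peaks)) peaks$score <- 0
  if (!"strand" %in% names(peaks)) peaks$strand <- "."
  out <- dplyr::arrange(
    peaks[c("chrom", "start", "end", "id", "score", "strand",
            "read_total", "conversion_count", "rpkm")],
    .data$chrom, .data$start, .data$end
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read repeats from BED6 (family in the name column)
#'
#' @param path File path.
#' @return Repeat annotation tibble with a `family` column.
#' @export
read_repeats_bed <- function(path) {
  x <- read_bed(path)
  if (!"id" %in% names(x)) {
    rlang::abort("repeat BED needs a name column carrying the family",
                 class = "chromclip_validation_error")
  }
  x$family <- as.character(x$id)
  if (any(is.na(x$family) | x$family == "")) {
    rlang::abort("repeat family labels must be non-empty",
                 class = "chromclip_validation_error")
  }
  x
}

#' Read a RepeatMasker .out table
#'
#' Parses the whitespace-delimited RepeatMasker output (three header
#' lines, then one row per repeat match). Query coordinates are 1-based
#' inclusive in the file and are converted to 0-based half-open here.
#' The repeat name column (e.g. `HERVH-int`, `L1PA3`) is taken verbatim
#' as the `family` label; subfamilies are never merged.
#'
#' @param path File path.
#' @return Repeat annotation tibble (`chrom`, `start`, `end`, `strand`,
#'   `family`, `repeat_class`).
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[-seq_len(min(3, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- vapply(fields, length, integer(1)) < 11
  if (any(bad)) {
    rlang::abort("malformed RepeatMasker row(s)",
                 class = "chromclip_validation_error")
  }
  get <- function(k) vapply(fields, `[[`, character(1), k)
  tibble::tibble(
    chrom = get(5),
    start = as.numeric(get(6)) - 1,
    end = as.numeric(get(7)),
    strand = ifelse(get(9) == "C", "-", "+"),
    family = get(10),
    repeat_class = get(11)
  ) |> validate_intervals()
}

#' Read and write bedGraph coverage tracks
#'
#' Four tab-separated columns (`chrom`, `start`, `end`, `value`), 0-based
#' half-open.
#'
#' @param path File path.
#' @return Coverage tibble.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       col_types = "cddd", progress = FALSE)
  validate_intervals(x)
}

#' @rdname read_bedgraph
#' @param track Coverage tibble.
#' @export
write_bedgraph <- function(track, path) {
  out <- dplyr::arrange(track[c("chrom", "start", "end", "value")],
                        .data$chrom, .data$start, .data$end)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
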