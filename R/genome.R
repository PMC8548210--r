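#' Construct a genome layout
#'
#' A genome layout is the coordinate substrate for every overlap, distance
#' and shuffle in the package: an ordered table of chromosome names and
#' lengths, equivalent to a `chrom.sizes` file.
#'
#' @param chrom Character vector of unique, non-empty chromosome names.
#' @param length Positive integer vector of chromosome lengths in bp.
#'
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    rlang::abort("`chrom` and `length` must have equal length",
                 class = "chromclip_validation_error")
  }
  if (any(is.na(chrom)) || any(chrom == "") || anyDuplicated(chrom) > 0) {
    rlang::abort("chromosome names must be unique and non-empty",
                 class = "chromclip_validation_error")
  }
  if (any(is.na(length)) || any(length <= 0) || any(length != floor(length))) {
    rlang::abort("chromosome lengths must be positive integers",
                 class = "chromclip_validation_error")
  }
  tibble::tibble(chrom = chrom, length = length)
}

#' Validate a table of genomic intervals
#'
#' Intervals are plain tibbles in BED convention: 0-based, half-open
#' `[start, end)`. Columns beyond `chrom`, `start`, `end` (e.g. `id`,
#' `strand`) are carried through untouched by every operation.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param genome Optional genome layout; when supplied, intervals must lie
#'   within their chromosome and on a known chromosome.
#'
#' @return `x` as a tibble, invisibly unchanged apart from class.
#' @export
validate_intervals <- function(x, genome = NULL) {
  x <- tibble::as_tibble(x)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    rlang::abort("intervals need columns chrom, start, end",
                 class = "chromclip_validation_error")
  }
  if (nrow(x) > 0) {
    if (any(is.na(x$start)) || any(is.na(x$end)) ||
        any(x$start < 0) || any(x$start >= x$end)) {
      rlang::abort("intervals must satisfy 0 <= start < end",
                   class = "chromclip_validation_error")
    }
    if (!is.null(genome)) {
      len <- genome$length[match(x$chrom, genome$chrom)]
      if (any(is.na(len))) {
        rlang::abort("interval on a chromosome absent from the genome layout",
                     class = "chromclip_validation_error")
      }
      if (any(x$end > len)) {
        rlang::abort("interval end exceeds chromosome length",
                     class = "chromclip_validation_error")
      }
    }
  }
  x
}

#' Distance between genomic intervals
#'
#' Row-wise distance between two interval tables (recycled like base
#' arithmetic). Overlapping or abutting intervals (half-open semantics)
#' have distance 0; intervals on different chromosomes are infinitely far
#' apart (`Inf`), so nearest-feature searches never cross chromosomes.
#' Strand is ignored.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`).
#'
#' @return Numeric vector of distances in bp (`Inf` across chromosomes).
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 200, end = 300)
#' interval_distance(a, b) # 100
#' @export
interval_distance <- function(a, b) {
  a <- validate_intervals(a)
  b <- validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 0 || nrow(b) == 0) return(numeric(0))
  ia <- rep_len(seq_len(nrow(a)), n)
  ib <- rep_len(seq_len(nrow(b)), n)
  gap <- pmax(a$start[ia], b$start[ib]) - pmin(a$end[ia], b$end[ib])
  d <- pmax(gap, 0)
  d[a$chrom[ia] != b$chrom[ib]] <- Inf
  d
}

# Existence-only overlap counter used inside permutation loops.
# `sub` must be a list by chromosome with components start_sorted and
# end_cummax (cumulative max of end in start order). Returns a logical
# per query: does any subject overlap it by >= 1 bp?
.overlaps_any <- function(q_chrom, q_start, q_end, sub_index) {
  out <- logical(length(q_start))
  for (ch in unique(q_chrom)) {
    s <- sub_index[[ch]]
    qi <- which(q_chrom == ch)
    if (is.null(s)) next
    k <- findInterval(q_end[qi] - 0.5, s$start_sorted)
    hit <- k > 0L
    hit[hit] <- s$end_cummax[k[hit]] > q_start[qi][hit]
    out[qi] <- hit
  }
  out
}

.build_sub_index_vec <- function(chrom, start, end) {
  split(seq_along(chrom), chrom) |>
    lapply(function(i) {
      o <- i[order(start[i])]
      list(start_sorted = start[o], end_cummax = cummax(end[o]))
    })
}

.build_sub_index <- function(x) {
  .build_sub_index_vec(x$chrom, x$start, x$end)
}

#' Intersect two interval sets
#'
#' Flags each interval of `a` that shares at least `min_overlap_bp` base
#' pairs with some interval of `b`, and lists every qualifying (a, b) pair
#' exactly once. The result does not depend on input row order (pairs are
#' reported in `a`-then-`b` row order of the inputs as given).
#'
#' @param a,b Interval tibbles.
#' @param min_overlap_bp Minimum shared bp for a hit (default 1).
#'
#' @return A list with `flags` (logical, one per row of `a`) and `pairs`
#'   (tibble with `a_idx`, `b_idx`, `overlap_bp`).
#' @export
intersect_sets <- function(a, b, min_overlap_bp = 1) {
  if (!is.numeric(min_overlap_bp) || min_overlap_bp < 1) {
    rlang::abort("`min_overlap_bp` must be >= 1",
                 class = "chromclip_argument_error")
  }
  a <- validate_intervals(a)
  b <- validate_intervals(b)
  flags <- logical(nrow(a))
  pairs <- list()
  b_by <- split(seq_len(nrow(b)), b$chrom)
  for (ch in intersect(unique(a$chrom), names(b_by))) {
    ai <- which(a$chrom == ch)
    bi <- b_by[[ch]]
    ov <- outer(a$end[ai], b$end[bi], pmin) -
      outer(a$start[ai], b$start[bi], pmax)
    hit <- which(ov >= min_overlap_bp, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      flags[ai[hit[, 1]]] <- TRUE
      pairs[[ch]] <- tibble::tibble(
        a_idx = ai[hit[, 1]], b_idx = bi[hit[, 2]],
        overlap_bp = ov[hit]
      )
    }
  }
  pairs <- if (length(pairs)) {
    dplyr::arrange(dplyr::bind_rows(pairs), .data$a_idx, .data$b_idx)
  } else {
    tibble::tibble(a_idx = integer(), b_idx = integer(),
                   overlap_bp = numeric())
  }
  list(flags = flags, pairs = pairs)
}

#' Reads per kilobase per million mapped reads
#'
#' The density unit behind every cutoff in the pipeline:
#' `RPKM = count / ((length/1000) * (library_size/1e6))`.
#'
#' @param read_count Non-negative read count(s).
#' @param length_bp Positive region length(s) in bp.
#' @param library_size Positive total mapped reads of the library.
#'
#' @return Numeric RPKM, vectorized.
#' @examples
#' compute_rpkm(10, 1000, 1e6) # 10
#' @export
compute_rpkm <- function(read_count, length_bp, library_size) {
  if (any(length_bp <= 0) || any(library_size <= 0)) {
    rlang::abort("length_bp and library_size must be positive",
                 class = "chromclip_argument_error")
  }
  if (any(read_count < 0)) {
    rlang::abort("read_count must be non-negative",
                 class = "chromclip_argument_error")
  }
  read_count / ((length_bp / 1000) * (library_size / 1e6))
}

# Mean RPKM across replicates, each replicate scaled by its own library.
# counts: numeric matrix regions x replicates; lib_sizes: per-replicate.
.mean_rpkm <- function(counts, length_bp, lib_sizes) {
  counts <- as.matrix(counts)
  per_rep <- sweep(counts, 2, (lib_sizes / 1e6), "/") / (length_bp / 1000)
  rowMeans(per_rep)
}

#' Nearest annotated feature for each query interval
#'
#' For each query, the feature minimizing [interval_distance()]; ties are
#' broken by smallest feature start, then lexicographic `gene_id`.
#' Chromosomes with no feature yield the no-neighbor sentinel
#' (`NA` gene with infinite distance).
#'
#' @param query Interval tibble.
#' @param features Gene annotation tibble (`chrom`, `start`, `end`,
#'   `gene_id`).
#'
#' @return Tibble with one row per query: `gene_id`, `distance`.
#' @export
nearest_feature <- function(query, features) {
  query <- validate_intervals(query)
  features <- validate_intervals(features)
  if (!"gene_id" %in% names(features)) {
    rlang::abort("features need a gene_id column",
                 class = "chromclip_validation_error")
  }
  f_by <- split(seq_len(nrow(features)), features$chrom)
  gene_id <- rep(NA_character_, nrow(query))
  distance <- rep(Inf, nrow(query))
  for (i in seq_len(nrow(query))) {
    fi <- f_by[[query$chrom[i]]]
    if (is.null(fi)) next
    gap <- pmax(pmax(query$start[i], features$start[fi]) -
                  pmin(query$end[i], features$end[fi]), 0)
    best <- fi[order(gap, features$start[fi], features$gene_id[fi])][1]
    gene_id[i] <- features$gene_id[best]
    distance[i] <- min(gap)
  }
  tibble::tibble(gene_id = gene_id, distance = distance)
}
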