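#' T-to-C conversion rate per peak
#'
#' In PAR-CLIP, 4-thiouridine crosslinking leaves diagnostic T-to-C
#' transitions in reads at true contact sites; the per-peak rate
#' (conversions per read) separates crosslink-supported peaks from
#' background. Bound peaks typically show rates around 0.1.
#'
#' @param peaks Peak tibble with `conversion_count` and `read_total`
#'   columns.
#' @return The input with a `conversion_rate` column appended.
#' @export
peak_conversion_rate <- function(peaks) {
  peaks <- tibble::as_tibble(peaks)
  if (any(peaks$read_total == 0)) {
    rlang::abort("conversion rate undefined for peaks with zero reads",
                 class = "chromclip_undefined_rate_error")
  }
  dplyr::mutate(peaks,
                conversion_rate = .data$conversion_count / .data$read_total)
}

#' Call enrichment peaks from windowed IP and input tracks
#'
#' A deliberately simple, self-contained peak caller over fixed
#' non-overlapping windows: a window is called when the IP count exceeds
#' the library-scaled input expectation (floored at a pseudo-expectation
#' of one read) by at least `min_fold`, and the one-sided exact test of
#' the IP count against the input count falls below `alpha`. The test
#' conditions on the window total: for two Poisson counts with library
#' totals `S_ip` and `S_in`, the IP count given the total is binomial
#' with success probability `S_ip / (S_ip + S_in)`, which stays
#' calibrated even though the input track is itself noisy (a Poisson
#' tail at the observed input expectation is not). Adjacent called
#' windows merge into one peak. This stage exists so the downstream
#' filters can be exercised end to end on synthetic tracks; it is not a
#' reimplementation of any published caller.
#'
#' @param ip_track,input_track bedGraph-style tibbles (`chrom`, `start`,
#'   `end`, `value`) on an identical window grid.
#' @param min_fold Minimum IP/scaled-input fold (default 2).
#' @param alpha Poisson tail cutoff (default 1e-5).
#'
#' @return Peak tibble: merged intervals with `read_total` (summed IP
#'   reads), `n_windows`, and an `id`.
#' @export
call_enriched_windows <- function(ip_track, input_track, min_fold = 2,
                                  alpha = 1e-5) {
  ip <- validate_intervals(ip_track)
  inp <- validate_intervals(input_track)
  if (nrow(ip) != nrow(inp) ||
      !all(ip$chrom == inp$chrom & ip$start == inp$start &
             ip$end == inp$end)) {
    rlang::abort("IP and input tracks must share one window grid",
                 class = "chromclip_shape_error")
  }
  if (sum(inp$value) <= 0) {
    rlang::abort("input track must have positive total",
                 class = "chromclip_argument_error")
  }
  s_ip <- sum(ip$value)
  s_in <- sum(inp$value)
  scale <- s_ip / s_in
  expectation <- pmax(inp$value * scale, 1)
  fold <- ip$value / expectation
  # conditional binomial: floor the input at the raw-count equivalent of
  # a pseudo-expectation of one IP read
  inp_eff <- pmax(round(inp$value), round(1 / scale), 1)
  ip_ct <- round(ip$value)
  p <- stats::pbinom(ip_ct - 1, size = ip_ct + inp_eff,
                     prob = s_ip / (s_ip + s_in), lower.tail = FALSE)
  called <- fold >= min_fold & p < alpha
  if (!any(called)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), id = character(),
                          read_total = numeric(), n_windows = integer()))
  }
  cw <- ip[called, ]
  cw <- dplyr::arrange(cw, .data$chrom, .data$start)
  new_run <- c(TRUE, cw$chrom[-1] != cw$chrom[-nrow(cw)] |
                 cw$start[-1] != cw$end[-nrow(cw)])
  run <- cumsum(new_run)
  out <- cw |>
    dplyr::group_by(run_id = run) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      read_total = sum(.data$value),
      n_windows = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(-"run_id")
  out$id <- sprintf("peak_%04d", seq_len(nrow(out)))
  out[c("chrom", "start", "end", "id", "read_total", "n_windows")]
}

#' Stringent PAR-CLIP peak set
#'
#' Applies the triple filter that defines the stringent peak set:
#' a replicate-1 peak is retained iff it (i) overlaps at least one
#' replicate-2 peak by >= 1 bp (consistently called in both biological
#' replicates), (ii) overlaps at least one conversion cluster (direct
#' crosslink evidence), and (iii) has RPKM above `rpkm_cutoff`. Retained
#' peaks record which conversion clusters support them. The output is a
#' subset of `rep1`, in `rep1` order, and is invariant to the ordering of
#' all inputs.
#'
#' @param rep1 Peak tibble for replicate 1 (must carry an `rpkm` column);
#'   retained coordinates come from here.
#' @param rep2 Peak tibble for replicate 2.
#' @param conversion_clusters Interval tibble of conversion-supported
#'   clusters; every cluster must have `conversion_count >= 1`.
#' @param rpkm_cutoff Minimum RPKM, exclusive (default 10).
#'
#' @return The retained subset of `rep1` with a `supporting_clusters`
#'   list-column of cluster row indices.
#' @export
stringent_peak_set <- function(rep1, rep2, conversion_clusters,
                               rpkm_cutoff = 10) {
  rep1 <- validate_intervals(rep1)
  rep2 <- validate_intervals(rep2)
  cl <- validate_intervals(conversion_clusters)
  if (!"rpkm" %in% names(rep1)) {
    rlang::abort("rep1 peaks need an rpkm column",
                 class = "chromclip_validation_error")
  }
  if (!"conversion_count" %in% names(cl) ||
      any(cl$conversion_count < 1)) {
    rlang::abort("conversion clusters must carry conversion_count >= 1",
                 class = "chromclip_validation_error")
  }
  in_rep2 <- intersect_sets(rep1, rep2)$flags
  cl_hits <- intersect_sets(rep1, cl)
  in_cluster <- cl_hits$flags
  keep <- in_rep2 & in_cluster & rep1$rpkm > rpkm_cutoff
  support <- split(cl_hits$pairs$b_idx, cl_hits$pairs$a_idx)
  out <- rep1[keep, ]
  out$supporting_clusters <- lapply(which(keep), function(i) {
    as.integer(support[[as.character(i)]])
  })
  out
}

#' Classify peaks by genomic context
#'
#' Assigns each peak exactly one context with precedence
#' coding > lincRNA > intergenic: a peak overlapping both a coding gene
#' and a lincRNA counts as coding.
#'
#' @param peaks Peak tibble.
#' @param genes Gene annotation tibble with a `biotype` column in
#'   `{coding, lincRNA, other}`.
#' @return The peaks with a `context` column appended.
#' @export
classify_peak_context <- function(peaks, genes) {
  peaks <- validate_intervals(peaks)
  genes <- validate_intervals(genes)
  coding <- genes[genes$biotype == "coding", ]
  linc <- genes[genes$biotype == "lincRNA", ]
  in_coding <- if (nrow(coding)) intersect_sets(peaks, coding)$flags
               else logical(nrow(peaks))
  in_linc <- if (nrow(linc)) intersect_sets(peaks, linc)$flags
             else logical(nrow(peaks))
  peaks$context <- dplyr::case_when(
    in_coding ~ "coding",
    in_linc ~ "lincRNA",
    TRUE ~ "intergenic"
  )
  peaks
}

#' Summarise peak contexts
#'
#' @param peaks Output of [classify_peak_context()].
#' @return Tibble with one row per context class (`coding`, `lincRNA`,
#'   `intergenic`) and columns `n`, `fraction`; counts sum to the number
#'   of peaks.
#' @export
context_summary <- function(peaks) {
  lv <- c("coding", "lincRNA", "intergenic")
  tb <- table(factor(peaks$context, levels = lv))
  tibble::tibble(context = lv, n = as.integer(tb),
                 fraction = as.integer(tb) / max(1L, nrow(peaks)))
}

#' Fraction of genes bound, stratified by expression
#'
#' Bins genes by expression (RPKM) and reports, per half-open bin, the
#' fraction whose transcripts carry a bound peak. Distinguishes genuine
#' binding preference from mere abundance: if binding simply tracked
#' expression the fractions would approach one in the top bins.
#'
#' @param expression Tibble with `gene_id` and `rpkm` columns.
#' @param bound_ids Character vector of bound gene ids (must all appear
#'   in `expression`).
#' @param bins Strictly increasing numeric boundaries; bin *i* is
#'   `[bins[i], bins[i+1])`.
#'
#' @return Tibble with `bin_low`, `bin_high`, `n_genes`, `n_bound`,
#'   `fraction` (`NA` for empty bins, never 0).
#' @export
bound_fraction_by_expression <- function(expression, bound_ids, bins) {
  expression <- tibble::as_tibble(expression)
  if (is.unsorted(bins, strictly = TRUE)) {
    rlang::abort("`bins` must be strictly increasing",
                 class = "chromclip_argument_error")
  }
  if (!all(bound_ids %in% expression$gene_id)) {
    rlang::abort("every bound id must appear in `expression`",
                 class = "chromclip_validation_error")
  }
  k <- length(bins) - 1
  idx <- findInterval(expression$rpkm, bins,
                      rightmost.closed = FALSE, left.open = FALSE)
  bound <- expression$gene_id %in% bound_ids
  purrr::map_dfr(seq_len(k), function(i) {
    sel <- idx == i
    n <- sum(sel)
    nb <- sum(sel & bound)
    tibble::tibble(bin_low = bins[i], bin_high = bins[i + 1],
                   n_genes = n, n_bound = nb,
                   fraction = if (n > 0) nb / n else NA_real_)
  })
}
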