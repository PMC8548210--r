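# Expand features so that a >=1 bp overlap with an (expanded) feature is
# exactly "interval distance <= window_bp" on half-open intervals.
.expand_for_window <- function(features, window_bp, anchor) {
  s <- features$start
  e <- features$end
  if (anchor == "tss") {
    if (!"tss" %in% names(features)) {
      rlang::abort("tss anchor requires a tss column",
                   class = "chromclip_validation_error")
    }
    s <- features$tss
    e <- features$tss + 1
  }
  list(chrom = features$chrom, start = s - window_bp - 1,
       end = e + window_bp + 1)
}

#' Count distinct features within a window of any enhancer
#'
#' The counting unit is features (genes), not feature-enhancer pairs: a
#' feature counts once when its interval distance to the nearest
#' enhancer is at most `window_bp`, however many enhancers qualify.
#'
#' @param enhancers Interval tibble.
#' @param features Gene annotation tibble.
#' @param window_bp Window in bp (default 100000).
#' @param anchor `"interval"` (default) measures distance to the gene
#'   interval; `"tss"` to the transcription start site.
#' @return Integer count of qualifying features.
#' @export
count_features_within <- function(enhancers, features,
                                  window_bp = 100000,
                                  anchor = c("interval", "tss")) {
  anchor <- match.arg(anchor)
  if (window_bp < 0) {
    rlang::abort("`window_bp` must be >= 0",
                 class = "chromclip_argument_error")
  }
  enhancers <- validate_intervals(enhancers)
  features <- validate_intervals(features)
  ex <- .expand_for_window(features, window_bp, anchor)
  idx <- .build_sub_index(enhancers)
  sum(.overlaps_any(ex$chrom, ex$start, ex$end, idx))
}

#' Shuffle enhancer positions across the genome
#'
#' Length-preserving random repositioning of each enhancer, the null
#' move of the proximity permutation test. Delegates to
#' [sample_matched_random_loci()].
#'
#' @inheritParams sample_matched_random_loci
#' @param enhancers Interval tibble to shuffle.
#' @return Interval tibble of shuffled enhancers.
#' @export
shuffle_enhancers <- function(enhancers, genome, seed = NULL,
                              mode = c("genome_wide",
                                       "same_chromosome")) {
  sample_matched_random_loci(enhancers, genome, seed = seed,
                             mode = match.arg(mode))
}

#' Permutation test for DEG proximity to enhancers
#'
#' Tests whether differentially expressed genes cluster near a set of
#' enhancers: the observed number of distinct DEGs within `window_bp`
#' of any enhancer is compared to the counts obtained after randomly
#' shuffling the enhancer positions `n_iter` times. Reports the fold
#' over the null mean, the Gaussian Z-score with its one-sided
#' upper-tail probability, a plus-one-smoothed empirical probability,
#' and the null skewness as a normality diagnostic.
#'
#' @param enhancers Interval tibble (e.g. enhancers with up-regulated
#'   acetylation).
#' @param deg_features Gene annotation tibble of the DEG set (non-empty).
#' @param genome Genome layout.
#' @param window_bp Window in bp (default 100000).
#' @param n_iter Number of shuffles (default 1000).
#' @param seed Integer master seed; shuffle *i* uses `seed + i`.
#' @param mode Shuffle placement mode.
#' @param anchor Distance anchor, as [count_features_within()].
#' @return One-row tibble of enrichment statistics.
#' @export
proximity_enrichment_test <- function(enhancers, deg_features, genome,
                                      window_bp = 100000, n_iter = 1000,
                                      seed = 1,
                                      mode = c("genome_wide",
                                               "same_chromosome"),
                                      anchor = c("interval", "tss")) {
  mode <- match.arg(mode)
  anchor <- match.arg(anchor)
  if (!is.numeric(n_iter) || n_iter < 1) {
    rlang::abort("`n_iter` must be >= 1",
                 class = "chromclip_argument_error")
  }
  enhancers <- validate_intervals(enhancers)
  deg_features <- validate_intervals(deg_features)
  if (nrow(deg_features) == 0) {
    rlang::abort("`deg_features` must be non-empty",
                 class = "chromclip_argument_error")
  }
  ex <- .expand_for_window(deg_features, window_bp, anchor)
  count_against <- function(enh) {
    idx <- .build_sub_index(enh)
    sum(.overlaps_any(ex$chrom, ex$start, ex$end, idx))
  }
  observed <- count_against(enhancers)
  len <- enhancers$end - enhancers$start
  withr::local_preserve_seed()
  null <- vapply(seq_len(n_iter), function(i) {
    set.seed((seed + i) %% 2147483647L)
    sh <- .shuffle_fast(len, enhancers$chrom, genome, mode)
    idx <- .build_sub_index_vec(sh$chrom, sh$start, sh$end)
    sum(.overlaps_any(ex$chrom, ex$start, ex$end, idx))
  }, numeric(1))
  out <- .enrichment_row(observed, null, n_iter, seed)
  out$window_bp <- window_bp
  out$mode <- mode
  out$anchor <- anchor
  out
}
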