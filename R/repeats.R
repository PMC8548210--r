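#' Fraction of peaks overlapping each repeat family
#'
#' For every family in the repeat annotation, the fraction of peaks
#' overlapping at least one repeat of that family by >= 1 bp. A peak
#' overlapping several repeats of one family counts once for that
#' family; a peak overlapping repeats of several families counts once in
#' each.
#'
#' @param peaks Peak tibble.
#' @param repeats Repeat annotation tibble with a `family` column.
#' @return Tibble with `family`, `n_overlap`, `fraction`, one row per
#'   family present in `repeats`.
#' @export
family_overlap_fraction <- function(peaks, repeats) {
  peaks <- validate_intervals(peaks)
  repeats <- validate_intervals(repeats)
  if (nrow(peaks) == 0) {
    rlang::abort("peak list must be non-empty",
                 class = "chromclip_argument_error")
  }
  fams <- sort(unique(repeats$family))
  counts <- vapply(fams, function(f) {
    idx <- .build_sub_index(repeats[repeats$family == f, ])
    sum(.overlaps_any(peaks$chrom, peaks$start, peaks$end, idx))
  }, numeric(1))
  counts <- unname(counts)
  tibble::tibble(family = fams, n_overlap = as.integer(counts),
                 fraction = counts / nrow(peaks))
}

#' Sample random genomic loci matched to a template
#'
#' Draws exactly one random locus per template interval, with the same
#' length, placed uniformly over all valid start positions. In
#' `genome_wide` mode the chromosome is chosen with probability
#' proportional to its number of valid starts for that length; in
#' `same_chromosome` mode each locus stays on its template's chromosome.
#' Loci may overlap each other (enforcing non-overlap would bias the
#' null on small genomes) but never overlap `exclusions`.
#'
#' @param template Interval tibble whose length multiset is preserved.
#' @param genome Genome layout.
#' @param seed Optional integer seed; a fixed seed reproduces the draw
#'   exactly and the caller's RNG state is left untouched.
#' @param exclusions Optional interval tibble the loci must avoid.
#' @param mode `"genome_wide"` (default) or `"same_chromosome"`.
#'
#' @return Interval tibble of `nrow(template)` random loci.
#' @export
sample_matched_random_loci <- function(template, genome, seed = NULL,
                                       exclusions = NULL,
                                       mode = c("genome_wide",
                                                "same_chromosome")) {
  mode <- match.arg(mode)
  template <- validate_intervals(template)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nrow(template)
  len <- template$end - template$start
  excl_idx <- if (!is.null(exclusions)) {
    .build_sub_index(validate_intervals(exclusions))
  }
  place <- function(idx) {
    L <- len[idx]
    if (mode == "same_chromosome") {
      ci <- match(template$chrom[idx], genome$chrom)
      if (any(is.na(ci))) {
        rlang::abort("template chromosome absent from genome layout",
                     class = "chromclip_validation_error")
      }
      valid <- genome$length[ci] - L + 1
      if (any(valid < 1)) {
        rlang::abort("template longer than its chromosome",
                     class = "chromclip_placement_error")
      }
      start <- floor(stats::runif(length(idx)) * valid)
      tibble::tibble(chrom = genome$chrom[ci], start = start,
                     end = start + L)
    } else {
      vs <- outer(L, genome$length, function(l, g) pmax(g - l + 1, 0))
      tot <- rowSums(vs)
      if (any(tot <= 0)) {
        rlang::abort("a template length exceeds every chromosome",
                     class = "chromclip_placement_error")
      }
      r <- stats::runif(length(idx)) * tot
      cs <- vs
      for (j in seq_len(ncol(vs))[-1]) cs[, j] <- cs[, j - 1] + vs[, j]
      ci <- rowSums(cs < r) + 1L
      start <- floor(stats::runif(length(idx)) *
                       vs[cbind(seq_along(idx), ci)])
      tibble::tibble(chrom = genome$chrom[ci], start = start,
                     end = start + L)
    }
  }
  out <- place(seq_len(n))
  if (!is.null(excl_idx)) {
    for (round in seq_len(1000)) {
      bad <- which(.overlaps_any(out$chrom, out$start, out$end, excl_idx))
      if (length(bad) == 0) break
      if (round == 1000) {
        rlang::abort("could not place loci outside exclusions",
                     class = "chromclip_placement_error")
      }
      out[bad, ] <- place(bad)
    }
  }
  out$id <- sprintf("random_%05d", seq_len(n))
  out
}

# Lean internal shuffler for permutation loops: same placement law (and
# RNG draw sequence) as sample_matched_random_loci in genome_wide /
# same_chromosome modes, without tibble construction or validation.
# Uses the ambient RNG; callers seed per iteration.
.shuffle_fast <- function(len, tmpl_chrom, genome, mode) {
  # canonical template order so null draws are invariant to input order
  o <- order(tmpl_chrom, len)
  len <- len[o]
  tmpl_chrom <- tmpl_chrom[o]
  n <- length(len)
  if (mode == "same_chromosome") {
    ci <- match(tmpl_chrom, genome$chrom)
    valid <- genome$length[ci] - len + 1
    start <- floor(stats::runif(n) * valid)
  } else {
    vs <- outer(len, genome$length, function(l, g) pmax(g - l + 1, 0))
    tot <- rowSums(vs)
    r <- stats::runif(n) * tot
    cs <- vs
    for (j in seq_len(ncol(vs))[-1]) cs[, j] <- cs[, j - 1] + vs[, j]
    ci <- rowSums(cs < r) + 1L
    start <- floor(stats::runif(n) * vs[cbind(seq_len(n), ci)])
  }
  list(chrom = genome$chrom[ci], start = start, end = start + len)
}

# One-row enrichment summary from an observed statistic and its null draws.
.enrichment_row <- function(observed, null, n_iter, seed) {
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  z <- if (is.na(null_sd) || null_sd == 0) NA_real_ else {
    (observed - null_mean) / null_sd
  }
  tibble::tibble(
    observed = observed,
    null_mean = null_mean,
    null_sd = null_sd,
    fold = if (null_mean > 0) observed / null_mean else NA_real_,
    z = z,
    p_gauss = if (is.na(z)) NA_real_ else {
      stats::pnorm(z, lower.tail = FALSE)
    },
    p_gauss_depletion = if (is.na(z)) NA_real_ else stats::pnorm(z),
    p_emp = (1 + sum(null >= observed)) / (n_iter + 1),
    null_skewness = {
      s <- stats::sd(null)
      if (is.na(s) || s == 0) NA_real_ else {
        mean((null - null_mean)^3) / s^3
      }
    },
    n_iter = n_iter,
    seed = seed
  )
}

#' Repeat-family enrichment of a peak set against random genomic loci
#'
#' For each repeat family, compares the number of peaks overlapping that
#' family with the overlap counts of `n_iter` draws of the same number
#' of random genomic loci with the same length multiset
#' ([sample_matched_random_loci()]). Reports the fold over the null
#' mean, the Gaussian Z-score and its one-sided upper-tail probability
#' (enrichment; the depletion tail is reported separately), and a
#' plus-one-smoothed empirical probability that can never be 0.
#'
#' @param peaks Peak tibble.
#' @param repeats Repeat annotation tibble with `family`.
#' @param genome Genome layout.
#' @param n_iter Number of null draws (default 1000).
#' @param seed Integer master seed; draw *i* uses `seed + i`.
#' @param mode Placement mode passed to the sampler.
#'
#' @return Tibble with one row per family and columns `observed`,
#'   `null_mean`, `null_sd`, `fold`, `z`, `p_gauss`,
#'   `p_gauss_depletion`, `p_emp`, `null_skewness`, `n_iter`, `seed`.
#' @export
repeat_family_enrichment <- function(peaks, repeats, genome,
                                     n_iter = 1000, seed = 1,
                                     mode = c("genome_wide",
                                              "same_chromosome")) {
  mode <- match.arg(mode)
  if (!is.numeric(n_iter) || n_iter < 1) {
    rlang::abort("`n_iter` must be >= 1",
                 class = "chromclip_argument_error")
  }
  peaks <- validate_intervals(peaks)
  repeats <- validate_intervals(repeats)
  fams <- sort(unique(repeats$family))
  fam_idx <- lapply(fams, function(f) {
    .build_sub_index(repeats[repeats$family == f, ])
  })
  names(fam_idx) <- fams
  count_overlaps <- function(x) {
    vapply(fams, function(f) {
      sum(.overlaps_any(x$chrom, x$start, x$end, fam_idx[[f]]))
    }, numeric(1))
  }
  observed <- count_overlaps(peaks)
  len <- peaks$end - peaks$start
  null <- matrix(0, nrow = n_iter, ncol = length(fams))
  withr::local_preserve_seed()
  for (i in seq_len(n_iter)) {
    set.seed((seed + i) %% 2147483647L)
    loci <- .shuffle_fast(len, peaks$chrom, genome, mode)
    null[i, ] <- vapply(fams, function(f) {
      sum(.overlaps_any(loci$chrom, loci$start, loci$end, fam_idx[[f]]))
    }, numeric(1))
  }
  purrr::map_dfr(seq_along(fams), function(k) {
    dplyr::bind_cols(
      tibble::tibble(family = fams[k]),
      .enrichment_row(observed[k], null[, k], n_iter, seed)
    )
  })
}

#' Write an enrichment result table with its seed recorded
#'
#' @param x Enrichment tibble.
#' @param path Output TSV path; the seed is recorded in a `#` header
#'   line.
#' @export
write_enrichment_tsv <- function(x, path) {
  writeLines(sprintf("# chromclip enrichment; seed=%s; n_iter=%s",
                     paste(unique(x$seed), collapse = ","),
                     paste(unique(x$n_iter), collapse = ",")), path)
  suppressWarnings(
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  )
  invisible(path)
}
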