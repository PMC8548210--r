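#' Quantile normalization within antibody groups
#'
#' Forces all samples of a group to share one value distribution:
#' each sample's sorted values are replaced by the across-sample mean of
#' values at that rank, ties receiving the mean of the reference values
#' they span. Groups (by default one per antibody) are normalized
#' independently; a group of size 1 is returned unchanged with a
#' warning. The heavy lifting is `limma::normalizeQuantiles`.
#'
#' @param x A `signal_matrix` (raw layer).
#' @param group_by Sample-sheet column defining the normalization groups
#'   (default `"antibody"`).
#' @return A `signal_matrix` with the normalized layer and provenance
#'   recorded.
#' @export
quantile_normalize <- function(x, group_by = "antibody") {
  stopifnot(inherits(x, "signal_matrix"))
  groups <- split(seq_len(nrow(x$samples)), x$samples[[group_by]])
  vals <- x$values
  for (g in names(groups)) {
    cols <- groups[[g]]
    if (length(cols) < 2) {
      rlang::warn(sprintf(
        "normalization group '%s' has a single sample; left unchanged", g
      ))
      next
    }
    vals[, cols] <- limma::normalizeQuantiles(vals[, cols, drop = FALSE],
                                              ties = TRUE)
  }
  signal_matrix(vals, x$regions, x$samples, normalized = TRUE,
                normalization = sprintf("quantile within %s", group_by))
}

#' Peak specificity filter against a depletion control
#'
#' Keeps regions whose signal is both present in the reference condition
#' and lost in the depletion control: mean wild-type RPKM above
#' `min_rpkm` and mean WT over mean control fold above `min_fc`. A
#' pseudocount of 0.25 RPKM in the denominator avoids division by zero.
#'
#' @param x A `signal_matrix` whose values are RPKM densities.
#' @param wt_condition,ko_condition Condition labels in the sample
#'   sheet.
#' @param min_rpkm Minimum mean WT RPKM, exclusive (default 1).
#' @param min_fc Minimum WT/KO fold, exclusive (default 2).
#' @param pseudocount RPKM added to the KO mean (default 0.25).
#'
#' @return The retained subset of `x$regions`, with `wt_mean`, `ko_mean`
#'   and `wt_ko_fold` columns.
#' @export
specificity_filter <- function(x, wt_condition = "WT",
                               ko_condition = "KO", min_rpkm = 1,
                               min_fc = 2, pseudocount = 0.25) {
  stopifnot(inherits(x, "signal_matrix"))
  wt <- unname(rowMeans(x$values[, .cond_cols(x, wt_condition),
                                 drop = FALSE]))
  ko <- unname(rowMeans(x$values[, .cond_cols(x, ko_condition),
                                 drop = FALSE]))
  fold <- wt / (ko + pseudocount)
  keep <- wt > min_rpkm & fold > min_fc
  out <- x$regions[keep, ]
  out$wt_mean <- wt[keep]
  out$ko_mean <- ko[keep]
  out$wt_ko_fold <- fold[keep]
  out
}

#' Method-of-moments common dispersion for negative-binomial counts
#'
#' For replicate counts within one condition, estimates the shared NB
#' dispersion phi from the median over regions of
#' `max(0, (s^2 - m) / m^2)` where `m` and `s^2` are the per-region
#' replicate mean and variance. Because the median of a sample variance
#' on few replicates sits below its expectation (the chi-square median
#' is below its degrees of freedom), the raw median is rescaled by
#' `qchisq(0.5, r - 1) / (r - 1)`; without this the downstream test is
#' anti-conservative at 4 replicates. Poisson data yield estimates
#' near 0.
#'
#' @param counts Numeric matrix, regions x replicates, one condition.
#' @return Non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts) {
  counts <- as.matrix(counts)
  r <- ncol(counts)
  if (r < 2) {
    rlang::abort("dispersion needs >= 2 replicates",
                 class = "chromclip_argument_error")
  }
  m <- rowMeans(counts)
  v <- apply(counts, 1, stats::var)
  if (all(v == 0, na.rm = TRUE)) return(0)
  phi <- pmax(0, (v - m) / m^2)
  phi <- phi[is.finite(phi)]
  if (length(phi) == 0) return(0)
  cc <- stats::qchisq(0.5, r - 1) / (r - 1)
  mbar <- mean(m[m > 0])
  if (!is.finite(mbar)) return(0)
  max(0, (stats::median(phi) + (1 - cc) / mbar) / cc)
}

# Two-sided NB exact-style p-value for one region: replicate sums ya, yb
# with na, nb replicates and common dispersion phi. Conditions on the
# region total; the conditional law of ya is computed from the NB sum
# distributions (binomial in the Poisson limit). Exact-test style:
# p = sum of conditional probabilities <= P(ya observed).
.nb_exact_p <- function(ya, yb, na, nb, phi) {
  t <- ya + yb
  if (t == 0) return(1)
  k <- 0:t
  if (phi <= 1e-8) {
    logp <- stats::dbinom(k, t, na / (na + nb), log = TRUE)
  } else {
    mu <- t / (na + nb)
    la <- stats::dnbinom(k, size = na / phi, mu = na * mu, log = TRUE)
    lb <- stats::dnbinom(t - k, size = nb / phi, mu = nb * mu, log = TRUE)
    logp <- la + lb
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  p_obs <- logp[ya + 1]
  min(1, sum(exp(logp[logp <= p_obs + 1e-12])))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control:
#' `q_i = min over j with p_(j) >= p_(i) of (m * p_(j) / j)`, clipped to
#' 1 and returned in input order. Equivalent to
#' `p.adjust(method = "BH")`, which does the computation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    rlang::abort("p-values must lie in [0, 1]",
                 class = "chromclip_validation_error")
  }
  stats::p.adjust(p, method = "BH")
}

# Shared engine for differential_regions / call_degs.
.differential_test <- function(counts, group_a_cols, group_b_cols,
                               ids, min_fc, max_fdr,
                               pseudocount = 0.25) {
  counts <- round(as.matrix(counts))
  na <- length(group_a_cols)
  nb <- length(group_b_cols)
  if (na < 2 || nb < 2) {
    rlang::abort("each group needs >= 2 replicates",
                 class = "chromclip_argument_error")
  }
  a <- counts[, group_a_cols, drop = FALSE]
  b <- counts[, group_b_cols, drop = FALSE]
  phi <- mean(c(estimate_common_dispersion(a),
                estimate_common_dispersion(b)))
  ya <- rowSums(a)
  yb <- rowSums(b)
  p <- vapply(seq_along(ya), function(i) {
    .nb_exact_p(ya[i], yb[i], na, nb, phi)
  }, numeric(1))
  fdr <- bh_fdr(p)
  mean_a <- ya / na
  mean_b <- yb / nb
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  # replicate-consistency: per-replicate (paired by index) fold signs
  # must agree before a region is labeled up or down
  npair <- min(na, nb)
  signs <- sign(b[, seq_len(npair), drop = FALSE] -
                  a[, seq_len(npair), drop = FALSE])
  consistent_up <- rowSums(signs > 0) == npair
  consistent_down <- rowSums(signs < 0) == npair
  direction <- dplyr::case_when(
    fdr < max_fdr & log2fc >= log2(min_fc) & consistent_up ~ "up",
    fdr < max_fdr & log2fc <= -log2(min_fc) & consistent_down ~ "down",
    TRUE ~ "ns"
  )
  tibble::tibble(id = ids, mean_a = mean_a, mean_b = mean_b,
                 log2_fold_change = log2fc, p_value = p, fdr = fdr,
                 direction = direction, dispersion = phi)
}

#' Differential signal at regions between two conditions
#'
#' A self-contained negative-binomial exact-style test: densities are
#' rounded to counts, a common dispersion is estimated by the method of
#' moments within each group, and each region's replicate sums are
#' compared by the conditional distribution given the region total.
#' Benjamini-Hochberg correction across regions yields the FDR; the
#' `up`/`down` label additionally requires the fold-change threshold and
#' agreement of per-replicate fold signs (replicate consistency). This
#' is a documented stand-in with the thresholding semantics of the
#' published pipelines, not a re-implementation of any of them.
#'
#' @param x A `signal_matrix` (normalized layer recommended).
#' @param group_a Reference condition label (e.g. `"WT"`).
#' @param group_b Test condition label; `log2_fold_change` is
#'   `log2(group_b / group_a)`.
#' @param min_fc Fold-change threshold for the direction label
#'   (default 1.5).
#' @param max_fdr FDR threshold for the direction label (default 0.01).
#'
#' @return Tibble with one row per region: `id`, group means,
#'   `log2_fold_change`, `p_value`, `fdr`, `direction`, `dispersion`.
#' @export
differential_regions <- function(x, group_a = "WT", group_b = "KO",
                                 min_fc = 1.5, max_fdr = 0.01) {
  stopifnot(inherits(x, "signal_matrix"))
  .differential_test(x$values, .cond_cols(x, group_a),
                     .cond_cols(x, group_b), x$regions$id,
                     min_fc, max_fdr)
}

#' Differentially expressed genes from a count table
#'
#' [differential_regions()] applied to a gene-by-sample count table with
#' the DEG thresholds: at least `min_fc`-fold change (default 2) at FDR
#' below `max_fdr` (default 0.01).
#'
#' @param gene_counts Tibble or matrix of counts, genes x samples, with
#'   gene ids as a `gene_id` column (tibble) or rownames (matrix).
#' @param samples Sample sheet tibble (`sample_id`, `condition`, ...),
#'   one row per count column, in column order.
#' @param group_a,group_b Condition labels (reference, test).
#' @param min_fc,max_fdr Direction thresholds.
#' @return Tibble as [differential_regions()], with `id` = gene id.
#' @export
call_degs <- function(gene_counts, samples, group_a = "WT",
                      group_b = "KD", min_fc = 2, max_fdr = 0.01) {
  if (is.data.frame(gene_counts)) {
    ids <- gene_counts$gene_id
    m <- as.matrix(gene_counts[setdiff(names(gene_counts), "gene_id")])
  } else {
    m <- as.matrix(gene_counts)
    ids <- rownames(m)
  }
  ga <- which(samples$condition == group_a)
  gb <- which(samples$condition == group_b)
  if (length(ga) == 0 || length(gb) == 0) {
    rlang::abort("both conditions must appear in the sample sheet",
                 class = "chromclip_argument_error")
  }
  .differential_test(m, ga, gb, ids, min_fc, max_fdr)
}

#' Fraction of regions bound above genomic background
#'
#' A region counts as bound when its mean read density reaches at least
#' `min_fold` times the background expectation for its length, where
#' `background_density` is the genome-wide per-bp read density (total
#' mapped reads / genome length).
#'
#' @param regions Interval tibble.
#' @param x A `signal_matrix` of read counts over `regions`, or a
#'   numeric vector of per-region mean counts.
#' @param background_density Positive per-bp expected read count.
#' @param min_fold Enrichment threshold (default 1.5).
#' @return Tibble with `fraction`, `n_bound`, `n_total`.
#' @export
bound_region_fraction <- function(regions, x, background_density,
                                  min_fold = 1.5) {
  if (!is.numeric(background_density) || background_density <= 0) {
    rlang::abort("`background_density` must be positive",
                 class = "chromclip_argument_error")
  }
  regions <- validate_intervals(regions)
  dens <- if (inherits(x, "signal_matrix")) rowMeans(x$values)
          else as.numeric(x)
  expected <- background_density * (regions$end - regions$start)
  bound <- dens >= min_fold * expected
  tibble::tibble(fraction = mean(bound), n_bound = sum(bound),
                 n_total = length(bound))
}

#' Rank correlation between two per-region statistics
#'
#' Spearman correlation plus equal-count bin means of `y` over
#' `x`-ordered bins (the usual binned-scatter summary for binding vs
#' mark intensity).
#'
#' @param data Tibble with the two statistics.
#' @param x,y Column names (character).
#' @param n_bins Number of equal-count bins (default 10).
#' @return List with `rho` (NA when either statistic is constant) and
#'   `bins` (tibble of bin index, mean x, mean y, n).
#' @export
signal_correlation <- function(data, x, y, n_bins = 10) {
  xv <- data[[x]]
  yv <- data[[y]]
  if (length(xv) != length(yv) || length(xv) < 3) {
    rlang::abort("need two equal-length statistics with >= 3 values",
                 class = "chromclip_argument_error")
  }
  rho <- if (stats::sd(xv) == 0 || stats::sd(yv) == 0) NA_real_ else {
    stats::cor(xv, yv, method = "spearman")
  }
  bins <- tibble::tibble(xv = xv, yv = yv) |>
    dplyr::mutate(bin = dplyr::ntile(.data$xv, n_bins)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(x_mean = mean(.data$xv), y_mean = mean(.data$yv),
                     n = dplyr::n(), .groups = "drop")
  list(rho = rho, bins = bins)
}

#' Mean coverage metaprofile over regions
#'
#' Expands each region by `flank_bp` on both sides, divides the window
#' into `n_bins` equal bins, computes the per-bin mean coverage from a
#' bedGraph-style track, reverses bins of minus-strand regions, and
#' averages across regions. Windows reaching past the chromosome ends
#' are clipped; the number of clipped regions is reported as a warning.
#'
#' @param track Coverage tibble (`chrom`, `start`, `end`, `value`).
#' @param regions Interval tibble (strand honored when present).
#' @param flank_bp Flank added to each side (default 0).
#' @param n_bins Number of profile bins (>= 1).
#' @param genome Optional genome layout used for right-end clipping.
#' @return Numeric vector of length `n_bins`.
#' @export
region_metaprofile <- function(track, regions, flank_bp = 0, n_bins = 50,
                               genome = NULL) {
  if (n_bins < 1) {
    rlang::abort("`n_bins` must be >= 1",
                 class = "chromclip_argument_error")
  }
  track <- validate_intervals(track)
  regions <- validate_intervals(regions)
  if (nrow(regions) == 0) {
    rlang::abort("`regions` must be non-empty",
                 class = "chromclip_argument_error")
  }
  tr_by <- split(seq_len(nrow(track)), track$chrom)
  profiles <- matrix(0, nrow = nrow(regions), ncol = n_bins)
  clipped <- 0L
  for (i in seq_len(nrow(regions))) {
    ws <- regions$start[i] - flank_bp
    we <- regions$end[i] + flank_bp
    clip_lo <- max(ws, 0)
    clip_hi <- if (!is.null(genome)) {
      min(we, genome$length[match(regions$chrom[i], genome$chrom)])
    } else we
    if (clip_lo > ws || clip_hi < we) clipped <- clipped + 1L
    ws <- clip_lo; we <- clip_hi
    bw <- (we - ws) / n_bins
    acc <- numeric(n_bins)
    ti <- tr_by[[regions$chrom[i]]]
    if (!is.null(ti)) {
      sel <- ti[track$end[ti] > ws & track$start[ti] < we]
      for (j in sel) {
        a <- max(track$start[j], ws)
        b <- min(track$end[j], we)
        b1 <- floor((a - ws) / bw) + 1
        b2 <- min(ceiling((b - ws) / bw), n_bins)
        for (k in b1:b2) {
          lo <- ws + (k - 1) * bw
          hi <- ws + k * bw
          acc[k] <- acc[k] + track$value[j] * max(0, min(b, hi) - max(a, lo))
        }
      }
    }
    prof <- acc / bw
    if ("strand" %in% names(regions) && !is.na(regions$strand[i]) &&
        regions$strand[i] == "-") {
      prof <- rev(prof)
    }
    profiles[i, ] <- prof
  }
  if (clipped > 0) {
    rlang::warn(sprintf("%d region window(s) clipped at chromosome bounds",
                        clipped))
  }
  colMeans(profiles)
}

#' Per-copy summary table for a repeat family's loci
#'
#' One row per locus: expression (RPKM) in reference and knockdown
#' conditions, `log2fc_kd_wt` with a 0.25-RPKM pseudocount on both
#' terms, overlap with the stringent PAR-CLIP peak set, the closest gene
#' and its distance, and a `responsive` flag set when expression drops
#' more than twofold upon knockdown (`log2(WT/KD) > 1`, same
#' pseudocount).
#'
#' @param loci Interval tibble of the family's copies (with `id`).
#' @param wt_rpkm,kd_rpkm Per-locus RPKM vectors aligned to `loci`.
#' @param parclip_peaks Stringent peak tibble.
#' @param genes Gene annotation tibble.
#' @param pseudocount RPKM pseudocount (default 0.25).
#' @return Tibble, one row per locus.
#' @export
hervh_copy_table <- function(loci, wt_rpkm, kd_rpkm, parclip_peaks,
                             genes, pseudocount = 0.25) {
  loci <- validate_intervals(loci)
  stopifnot(length(wt_rpkm) == nrow(loci),
            length(kd_rpkm) == nrow(loci))
  near <- nearest_feature(loci, genes)
  log2fc <- log2((kd_rpkm + pseudocount) / (wt_rpkm + pseudocount))
  tibble::tibble(
    id = if ("id" %in% names(loci)) loci$id else {
      sprintf("locus_%04d", seq_len(nrow(loci)))
    },
    chrom = loci$chrom, start = loci$start, end = loci$end,
    wt_rpkm = wt_rpkm, kd_rpkm = kd_rpkm,
    log2fc_kd_wt = log2fc,
    parclip_overlap = ifelse(
      intersect_sets(loci, parclip_peaks)$flags, "YES", "NO"
    ),
    closest_gene = near$gene_id,
    closest_gene_distance = near$distance,
    responsive = -log2fc > 1
  )
}
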