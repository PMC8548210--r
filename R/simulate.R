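# Derive a bounded substream seed from a master seed and a label index.
.substream <- function(seed, k) as.integer((seed + 7919 * k) %% 2147483647)

# Draw n interval lengths from a clipped log-normal.
.rlengths <- function(n, meanlog, sdlog, min_len) {
  pmax(round(stats::rlnorm(n, meanlog, sdlog)), min_len)
}

#' Simulate a toy genome with repeats, enhancers and genes
#'
#' Generates the annotation substrate the pipeline consumes: a
#' multi-chromosome layout, non-overlapping repeat intervals from
#' several families (log-normal lengths), enhancer intervals and gene
#' models with biotypes, strands and TSSs. The default scale (2
#' chromosomes of 1 Mb, 200 repeats, 300 enhancers, 400 genes) keeps a
#' full pipeline run under two minutes on one CPU while leaving the
#' interval geometry non-trivial. All placements are a pure function of
#' the seed.
#'
#' @param n_chroms Number of chromosomes.
#' @param lengths Chromosome lengths in bp (recycled to `n_chroms`).
#' @param n_repeats,n_enhancers,n_genes Feature counts.
#' @param families Repeat family labels (>= 4 by default).
#' @param seed Integer seed.
#' @return List with `genome`, `repeats`, `enhancers`, `genes` tibbles.
#' @export
simulate_genome <- function(n_chroms = 2, lengths = 1e6,
                            n_repeats = 200, n_enhancers = 300,
                            n_genes = 400,
                            families = c("HERVH", "HERVK", "L1", "SINE"),
                            seed = 1) {
  withr::local_seed(seed)
  lengths <- rep_len(lengths, n_chroms)
  genome <- genome_layout(paste0("chr", seq_len(n_chroms)), lengths)
  rep_len_bp <- .rlengths(n_repeats, log(600), 0.5, 100)
  if (sum(rep_len_bp) > 0.5 * sum(lengths)) {
    rlang::abort("requested repeat mass exceeds half the genome",
                 class = "chromclip_packing_error")
  }
  # non-overlapping repeats: bulk placement with round-based rejection
  # (accept candidates that clash neither with accepted repeats nor
  # with an earlier candidate of the same round)
  accepted <- NULL
  todo <- rep_len_bp
  for (round in seq_len(200)) {
    cand <- .shuffle_fast(todo, rep("chr1", length(todo)), genome,
                          "genome_wide")
    cand <- tibble::tibble(chrom = cand$chrom, start = cand$start,
                           end = cand$end)
    ok <- if (is.null(accepted)) rep(TRUE, nrow(cand)) else {
      !.overlaps_any(cand$chrom, cand$start, cand$end,
                     .build_sub_index(accepted))
    }
    # greedy sweep so survivors of one round do not overlap each other
    surv <- which(ok)[order(cand$chrom[ok], cand$start[ok])]
    run_end <- -Inf
    run_chr <- ""
    keep <- integer(0)
    for (i in surv) {
      if (cand$chrom[i] != run_chr) {
        run_chr <- cand$chrom[i]
        run_end <- -Inf
      }
      if (cand$start[i] >= run_end) {
        keep <- c(keep, i)
        run_end <- cand$end[i]
      }
    }
    new_keep <- sort(keep)
    if (length(new_keep) > 0) {
      accepted <- dplyr::bind_rows(accepted, cand[new_keep, ])
      todo <- todo[-new_keep]
    }
    if (length(todo) == 0) break
    if (round == 200) {
      rlang::abort("could not pack repeats without overlap",
                   class = "chromclip_packing_error")
    }
  }
  repeats <- accepted
  repeats$family <- sample(rep_len(families, n_repeats))
  repeats$id <- sprintf("rep_%s_%04d", repeats$family,
                        seq_len(n_repeats))
  repeats$strand <- sample(c("+", "-"), n_repeats, replace = TRUE)
  enh_tmpl <- tibble::tibble(
    chrom = "chr1", start = 0,
    end = .rlengths(n_enhancers, log(800), 0.35, 200)
  )
  enhancers <- sample_matched_random_loci(enh_tmpl, genome)[, 1:3]
  enhancers$id <- sprintf("enh_%05d", seq_len(n_enhancers))
  enhancers$strand <- "."
  gene_tmpl <- tibble::tibble(
    chrom = "chr1", start = 0,
    end = .rlengths(n_genes, log(2000), 0.6, 300)
  )
  genes <- sample_matched_random_loci(gene_tmpl, genome)[, 1:3]
  genes$gene_id <- sprintf("gene_%05d", seq_len(n_genes))
  genes$score <- 0
  genes$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes$biotype <- sample(c("coding", "lincRNA", "other"), n_genes,
                          replace = TRUE, prob = c(0.7, 0.15, 0.15))
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  list(genome = genome, repeats = repeats, enhancers = enhancers,
       genes = genes)
}

#' Simulate a PAR-CLIP peak set with a planted repeat-family enrichment
#'
#' Places `n_peaks` peaks so that the probability of overlapping the
#' target family equals `enrichment_factor` times the background rate
#' of matched random loci (the background rate is measured by Monte
#' Carlo on the same length distribution). Per-peak read totals are
#' log-normal; T-to-C conversion counts are
#' `Binomial(read_total, conversion_rate)` with the default rate 0.1
#' conversions per read typical of crosslink-supported peaks.
#'
#' @param annotations Output of [simulate_genome()] (uses `genome` and
#'   `repeats`).
#' @param target_family Family to enrich (default `"HERVH"`).
#' @param enrichment_factor Planted fold over background (>= 0).
#' @param n_peaks Number of peaks.
#' @param conversion_rate Conversions per read (default 0.1).
#' @param mean_reads Log-scale location of per-peak read totals.
#' @param seed Integer seed.
#' @return List with `peaks` (tibble incl. `read_total`,
#'   `conversion_count`, `rpkm`) and `truth` (planted and realized
#'   rates).
#' @export
simulate_parclip <- function(annotations, target_family = "HERVH",
                             enrichment_factor = 5, n_peaks = 1000,
                             conversion_rate = 0.1, mean_reads = 200,
                             seed = 1) {
  if (enrichment_factor < 0) {
    rlang::abort("`enrichment_factor` must be >= 0",
                 class = "chromclip_argument_error")
  }
  withr::local_seed(seed)
  genome <- annotations$genome
  repeats <- annotations$repeats
  target <- repeats[repeats$family == target_family, ]
  if (nrow(target) == 0) {
    rlang::abort("target family absent from repeat annotation",
                 class = "chromclip_argument_error")
  }
  t_idx <- .build_sub_index(target)
  peak_len <- .rlengths(n_peaks, log(300), 0.4, 50)
  # background overlap rate for this length distribution, by Monte Carlo
  probe <- sample_matched_random_loci(
    tibble::tibble(chrom = "chr1", start = 0,
                   end = sample(peak_len, 4000, replace = TRUE)),
    genome
  )
  p0 <- mean(.overlaps_any(probe$chrom, probe$start, probe$end, t_idx))
  p_target <- enrichment_factor * p0
  if (p_target > 0.95) {
    rlang::abort(sprintf(
      "planted enrichment unattainable; maximum factor about %.1f",
      0.95 / p0
    ), class = "chromclip_argument_error")
  }
  hit <- stats::runif(n_peaks) < p_target
  chrom <- character(n_peaks)
  start <- numeric(n_peaks)
  # peaks forced onto the target family: anchor on a random copy, with
  # a start uniform over positions guaranteeing >= 1 bp overlap
  todo <- which(hit)
  for (round in seq_len(100)) {
    if (length(todo) == 0) break
    L <- peak_len[todo]
    r <- sample.int(nrow(target), length(todo), replace = TRUE)
    ci <- match(target$chrom[r], genome$chrom)
    lo <- pmax(0, target$start[r] - L + 1)
    hi <- pmin(target$end[r] - 1, genome$length[ci] - L)
    valid <- hi >= lo
    s <- lo + floor(stats::runif(length(todo)) * (hi - lo + 1))
    chrom[todo[valid]] <- target$chrom[r][valid]
    start[todo[valid]] <- s[valid]
    todo <- todo[!valid]
    if (round == 100 && length(todo) > 0) {
      rlang::abort("could not place a peak on the target family",
                   class = "chromclip_placement_error")
    }
  }
  # background peaks: uniform placement, redrawn until off-target
  todo <- which(!hit)
  for (round in seq_len(500)) {
    if (length(todo) == 0) break
    cand <- .shuffle_fast(peak_len[todo], rep("chr1", length(todo)),
                          genome, "genome_wide")
    # .shuffle_fast sorts its templates; undo to keep lengths aligned
    o <- order(rep("chr1", length(todo)), peak_len[todo])
    bad <- .overlaps_any(cand$chrom, cand$start, cand$end, t_idx)
    chrom[todo[o][!bad]] <- cand$chrom[!bad]
    start[todo[o][!bad]] <- cand$start[!bad]
    todo <- todo[o][bad]
    if (round == 500 && length(todo) > 0) {
      rlang::abort("could not place a background peak off the target",
                   class = "chromclip_placement_error")
    }
  }
  peaks <- tibble::tibble(chrom = chrom, start = start,
                          end = start + peak_len)
  peaks$id <- sprintf("clip_%05d", seq_len(n_peaks))
  peaks$strand <- "."
  peaks$read_total <- pmax(1, round(stats::rlnorm(
    n_peaks, log(mean_reads), 0.8
  )))
  peaks$conversion_count <- stats::rbinom(n_peaks, peaks$read_total,
                                          conversion_rate)
  lib <- sum(peaks$read_total)
  peaks$rpkm <- compute_rpkm(peaks$read_total,
                             peaks$end - peaks$start, lib)
  realized <- mean(.overlaps_any(peaks$chrom, peaks$start, peaks$end,
                                 t_idx))
  list(
    peaks = peaks,
    truth = list(seed = seed, target_family = target_family,
                 enrichment_factor = enrichment_factor,
                 background_rate = p0, planted_rate = p_target,
                 realized_rate = realized,
                 conversion_rate = conversion_rate,
                 library_size = lib)
  )
}

#' Simulate a region-by-sample count matrix with planted fold changes
#'
#' Emulates a multi-replicate two-condition design (e.g. 4 wild-type
#' vs 4 knockout CUT&RUN libraries): counts are negative binomial with
#' mean `base_mean` times the planted per-region fold in the test
#' condition and dispersion `phi` (`phi = 0` gives Poisson). Library
#' sizes are jittered by up to 20% and scale the means.
#'
#' @param regions Interval tibble with `id`.
#' @param planted_fold Numeric vector (length `nrow(regions)`) of true
#'   condition/reference folds; 1 means null.
#' @param conditions Two condition labels (reference first).
#' @param n_reps Replicates per condition (default 4).
#' @param phi NB dispersion (>= 0).
#' @param base_mean Expected reference count at library factor 1.
#' @param antibody Antibody label for the sample sheet.
#' @param seed Integer seed.
#' @return List with `matrix` (a `signal_matrix` of raw counts) and
#'   `truth`.
#' @export
simulate_signal_matrix <- function(regions, planted_fold = NULL,
                                   conditions = c("WT", "KO"),
                                   n_reps = 4, phi = 0.1,
                                   base_mean = 100,
                                   antibody = "H3K27ac", seed = 1) {
  withr::local_seed(seed)
  regions <- validate_intervals(regions)
  n <- nrow(regions)
  if (is.null(planted_fold)) planted_fold <- rep(1, n)
  stopifnot(length(planted_fold) == n, phi >= 0, base_mean > 0)
  samples <- tidyr::expand_grid(condition = conditions,
                                replicate = seq_len(n_reps)) |>
    dplyr::mutate(
      sample_id = sprintf("%s_rep%d", .data$condition, .data$replicate),
      antibody = antibody,
      lib_factor = stats::runif(dplyr::n(), 0.8, 1.2),
      library_size = round(1e6 * .data$lib_factor)
    )
  mu <- outer(rep(base_mean, n), samples$lib_factor)
  test_cols <- samples$condition == conditions[2]
  mu[, test_cols] <- mu[, test_cols] * planted_fold
  vals <- matrix(0, n, nrow(samples))
  for (j in seq_len(ncol(vals))) {
    vals[, j] <- if (phi == 0) stats::rpois(n, mu[, j]) else {
      stats::rnbinom(n, size = 1 / phi, mu = mu[, j])
    }
  }
  sm <- signal_matrix(
    vals, regions,
    samples[c("sample_id", "condition", "antibody", "replicate",
              "library_size")]
  )
  list(matrix = sm,
       truth = list(seed = seed, phi = phi, base_mean = base_mean,
                    conditions = conditions, n_reps = n_reps,
                    planted_fold = stats::setNames(planted_fold,
                                                   regions$id)))
}

#' Simulate a DEG label set with planted proximity to enhancers
#'
#' Assigns DEG labels to genes so that the expected number of DEGs
#' within `window_bp` of the enhancer subset equals `planted_fold`
#' times the expectation under uniform assignment. Genes near an
#' enhancer are sampled with probability `planted_fold * q` (where `q`
#' is the fraction of all genes that are near), far genes with the
#' complementary rate, keeping the DEG count fixed.
#'
#' @param enhancers Enhancer subset the DEGs should cluster around.
#' @param genes Gene annotation tibble.
#' @param planted_fold Planted proximity fold (>= 1).
#' @param window_bp Window in bp.
#' @param n_deg Number of DEG labels to assign.
#' @param seed Integer seed.
#' @return List with `degs` (gene annotation subset) and `truth`.
#' @export
simulate_proximity <- function(enhancers, genes, planted_fold = 3,
                               window_bp = 100000, n_deg = 50,
                               seed = 1) {
  if (planted_fold < 1) {
    rlang::abort("`planted_fold` must be >= 1",
                 class = "chromclip_argument_error")
  }
  withr::local_seed(seed)
  genes <- validate_intervals(genes)
  ex <- .expand_for_window(genes, window_bp, "interval")
  idx <- .build_sub_index(validate_intervals(enhancers))
  near <- .overlaps_any(ex$chrom, ex$start, ex$end, idx)
  q <- mean(near)
  p_near <- planted_fold * q
  n_near_target <- round(p_near * n_deg)
  if (p_near > 1 || n_near_target > sum(near) ||
      (n_deg - n_near_target) > sum(!near)) {
    rlang::abort(sprintf(
      "planted fold exceeds the geometric maximum (about %.2f)",
      min(1 / q, sum(near) / (q * n_deg))
    ), class = "chromclip_argument_error")
  }
  pick_near <- sample(which(near), n_near_target)
  pick_far <- sample(which(!near), n_deg - n_near_target)
  degs <- genes[sort(c(pick_near, pick_far)), ]
  list(
    degs = degs,
    truth = list(seed = seed, planted_fold = planted_fold,
                 window_bp = window_bp, n_deg = n_deg,
                 background_near_fraction = q,
                 expected_near = q * n_deg,
                 planted_near = n_near_target)
  )
}

#' Simulate a Hill titration curve
#'
#' `y = Bmax * x^h / (Kd^h + x^h) + Gaussian(0, noise_sd)`, clipped to
#' `[0, 1.05 * Bmax]`.
#'
#' @param Bmax,Kd,h Hill parameters (`Kd > 0`).
#' @param x Concentration grid (nM, strictly positive).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List with `curve` (tibble `concentration_nM`, `response`)
#'   and `truth`.
#' @export
simulate_binding_curve <- function(Bmax = 1, Kd = 10, h = 1,
                                   x = 2^(0:7), noise_sd = 0.03,
                                   seed = 1) {
  stopifnot(Kd > 0, noise_sd >= 0, all(x > 0))
  withr::local_seed(seed)
  y <- .hill_y(x, Bmax, Kd, h) + stats::rnorm(length(x), 0, noise_sd)
  y <- pmin(pmax(y, 0), 1.05 * Bmax)
  list(
    curve = tibble::tibble(concentration_nM = x, response = y),
    truth = list(seed = seed, Bmax = Bmax, Kd = Kd, h = h,
                 noise_sd = noise_sd)
  )
}

#' Serialize and restore planted truth
#'
#' Truth objects round-trip losslessly through JSON; no emitted data
#' file carries planted-truth fields.
#'
#' @param truth Truth list from a simulator.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
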