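#' Build a pipeline run configuration
#'
#' Collects every stage parameter with defaults at the values the
#' analysis is defined by: stringent-peak RPKM cutoff 10, specificity
#' filter at mean WT RPKM > 1 with WT/KO fold > 2, differential
#' enhancers at 1.5-fold / FDR 0.01, DEGs at 2-fold / FDR 0.01, a
#' 100 kb proximity window and 1,000 permutations. The configuration
#' round-trips through YAML-like JSON via [write_run_config()].
#'
#' @param outdir Output directory for stage artifacts.
#' @param seed Master seed; every stage derives a named substream.
#' @param rpkm_cutoff Stringent-peak RPKM cutoff.
#' @param spec_min_rpkm,spec_min_fc Specificity-filter thresholds.
#' @param diff_min_fc,diff_max_fdr Differential-enhancer thresholds.
#' @param deg_min_fc,deg_max_fdr DEG thresholds.
#' @param window_bp Proximity window in bp.
#' @param n_iter Permutation count for both enrichment tests.
#' @param synthetic List of arguments for [simulate_genome()] (the
#'   pipeline is exercised on synthetic data).
#' @return A `run_config` list.
#' @export
run_config <- function(outdir, seed = 1, rpkm_cutoff = 10,
                       spec_min_rpkm = 1, spec_min_fc = 2,
                       diff_min_fc = 1.5, diff_max_fdr = 0.01,
                       deg_min_fc = 2, deg_max_fdr = 0.01,
                       window_bp = 100000, n_iter = 1000,
                       synthetic = list()) {
  cfg <- list(outdir = outdir, seed = as.numeric(seed),
              rpkm_cutoff = as.numeric(rpkm_cutoff),
              spec_min_rpkm = as.numeric(spec_min_rpkm),
              spec_min_fc = as.numeric(spec_min_fc),
              diff_min_fc = as.numeric(diff_min_fc),
              diff_max_fdr = as.numeric(diff_max_fdr),
              deg_min_fc = as.numeric(deg_min_fc),
              deg_max_fdr = as.numeric(deg_max_fdr),
              window_bp = as.numeric(window_bp),
              n_iter = as.numeric(n_iter),
              synthetic = synthetic)
  if (!is.numeric(cfg$n_iter) || cfg$n_iter < 1) {
    rlang::abort("`n_iter` must be >= 1",
                 class = "chromclip_argument_error")
  }
  if (cfg$window_bp < 0 || cfg$rpkm_cutoff < 0) {
    rlang::abort("thresholds must be non-negative",
                 class = "chromclip_argument_error")
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

#' Run the full synthetic pipeline
#'
#' Executes every analysis stage on a simulated genome: annotation
#' simulation, stringent PAR-CLIP peak selection, repeat-family
#' enrichment, quantile normalization plus differential enhancer and
#' DEG calling, the DEG-proximity permutation test, and a Hill-curve
#' fit. Each stage writes its artifacts under `config$outdir`; the run
#' is a pure function of the configuration, so two runs from one config
#' are byte-identical. Returns a manifest listing every artifact with
#' an md5 digest.
#'
#' @param config A [run_config()].
#' @return Tibble manifest (`stage`, `file`, `md5`), invisibly also
#'   written to `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logf("chromclip pipeline; master seed %s", format(seed, scientific = FALSE))
  logf("parameters: %s", jsonlite::toJSON(
    unclass(config)[setdiff(names(config), c("outdir", "synthetic"))],
    auto_unbox = TRUE
  ))
  artifacts <- list()
  emit <- function(stage, path) {
    digest <- unname(tools::md5sum(path))
    artifacts[[length(artifacts) + 1]] <<- tibble::tibble(
      stage = stage, file = basename(path), md5 = digest
    )
  }

  ## stage 1: synthetic annotations
  ann <- do.call(simulate_genome,
                 c(config$synthetic, list(seed = .substream(seed, 1))))
  write_chrom_sizes(ann$genome, file.path(outdir, "genome.chrom.sizes"))
  write_bed(ann$repeats[c("chrom", "start", "end", "family")] |>
              dplyr::rename(id = "family"),
            file.path(outdir, "repeats.bed"))
  write_bed(ann$enhancers, file.path(outdir, "enhancers.bed"))
  write_genes(ann$genes, file.path(outdir, "genes.bed"))
  for (f in c("genome.chrom.sizes", "repeats.bed", "enhancers.bed",
              "genes.bed")) {
    emit("simulate", file.path(outdir, f))
  }

  ## stage 2: PAR-CLIP simulation + stringent set
  clip <- simulate_parclip(ann, seed = .substream(seed, 2),
                           n_peaks = 600)
  rep1 <- clip$peaks
  # replicate 2: jittered copy of a subset; conversion clusters: centers
  withr::with_seed(.substream(seed, 3), {
    keep2 <- stats::runif(nrow(rep1)) < 0.9
    rep2 <- rep1[keep2, c("chrom", "start", "end")]
    jit <- round(stats::runif(nrow(rep2), -40, 40))
    rep2$start <- pmax(0, rep2$start + jit)
    rep2$end <- rep2$end + jit
    keep_cl <- rep1$conversion_count >= 1 & stats::runif(nrow(rep1)) < 0.95
    clusters <- rep1[keep_cl, c("chrom", "start", "end",
                                "conversion_count")]
    mid <- floor((clusters$start + clusters$end) / 2)
    clusters$start <- pmax(clusters$start, mid - 20)
    clusters$end <- pmin(clusters$end, mid + 20)
  })
  stringent <- stringent_peak_set(rep1, rep2, clusters,
                                  rpkm_cutoff = config$rpkm_cutoff)
  stringent <- classify_peak_context(stringent, ann$genes)
  write_peaks(stringent[setdiff(names(stringent),
                                c("supporting_clusters", "context"))],
              file.path(outdir, "stringent_peaks.bed"))
  readr::write_tsv(context_summary(stringent),
                   file.path(outdir, "peak_context.tsv"),
                   progress = FALSE)
  emit("parclip", file.path(outdir, "stringent_peaks.bed"))
  emit("parclip", file.path(outdir, "peak_context.tsv"))
  logf("stringent peaks: %d of %d candidates", nrow(stringent),
       nrow(rep1))

  ## stage 3: repeat-family enrichment
  enr <- repeat_family_enrichment(stringent, ann$repeats, ann$genome,
                                  n_iter = config$n_iter,
                                  seed = .substream(seed, 4))
  write_enrichment_tsv(enr, file.path(outdir, "repeat_enrichment.tsv"))
  emit("repeats", file.path(outdir, "repeat_enrichment.tsv"))

  ## stage 4: differential enhancer signal + DEGs
  n_enh <- nrow(ann$enhancers)
  withr::with_seed(.substream(seed, 5), {
    enh_fold <- rep(1, n_enh)
    affected <- sample.int(n_enh, max(3, round(0.1 * n_enh)))
    up_half <- affected[seq_len(floor(length(affected) / 2))]
    enh_fold[up_half] <- 4
    enh_fold[setdiff(affected, up_half)] <- 0.25
  })
  sig <- simulate_signal_matrix(ann$enhancers, planted_fold = enh_fold,
                                seed = .substream(seed, 6))
  norm <- quantile_normalize(sig$matrix)
  diff_enh <- differential_regions(norm, "WT", "KO",
                                   min_fc = config$diff_min_fc,
                                   max_fdr = config$diff_max_fdr)
  readr::write_tsv(diff_enh, file.path(outdir, "differential_enhancers.tsv"),
                   progress = FALSE)
  emit("diff", file.path(outdir, "differential_enhancers.tsv"))

  # DEG clustering is planted around the two strongest up-regulated
  # enhancers: with 100-kb windows a larger subset would tile the toy
  # genome and leave no room for enrichment
  up_enh_ids <- diff_enh$id[diff_enh$direction == "up"]
  up_enh <- ann$enhancers[ann$enhancers$id %in% up_enh_ids, ]
  if (nrow(up_enh) == 0) up_enh <- ann$enhancers[1:2, ]
  up_enh <- utils::head(
    up_enh[order(-diff_enh$log2_fold_change[match(up_enh$id,
                                                  diff_enh$id)]), ], 2
  )
  prox_sim <- simulate_proximity(
    up_enh, ann$genes, planted_fold = 3,
    window_bp = config$window_bp, n_deg = 40,
    seed = .substream(seed, 7)
  )
  deg_fold <- ifelse(ann$genes$gene_id %in% prox_sim$degs$gene_id, 4, 1)
  gexpr <- simulate_signal_matrix(ann$genes |>
                                    dplyr::mutate(id = .data$gene_id),
                                  planted_fold = deg_fold,
                                  conditions = c("WT", "KD"),
                                  antibody = "RNA",
                                  seed = .substream(seed, 8))
  degs <- call_degs(
    tibble::as_tibble(gexpr$matrix$values) |>
      dplyr::mutate(gene_id = ann$genes$gene_id),
    gexpr$matrix$samples, "WT", "KD",
    min_fc = config$deg_min_fc, max_fdr = config$deg_max_fdr
  )
  readr::write_tsv(degs, file.path(outdir, "degs.tsv"), progress = FALSE)
  emit("diff", file.path(outdir, "degs.tsv"))
  logf("differential enhancers: %d up, %d down of %d",
       sum(diff_enh$direction == "up"),
       sum(diff_enh$direction == "down"), nrow(diff_enh))
  logf("DEGs: %d up, %d down of %d", sum(degs$direction == "up"),
       sum(degs$direction == "down"), nrow(degs))

  ## stage 5: proximity permutation test
  deg_genes <- ann$genes[ann$genes$gene_id %in%
                           degs$id[degs$direction != "ns"], ]
  if (nrow(deg_genes) == 0) deg_genes <- prox_sim$degs
  prox <- proximity_enrichment_test(
    up_enh, deg_genes, ann$genome, window_bp = config$window_bp,
    n_iter = config$n_iter, seed = .substream(seed, 9)
  )
  write_enrichment_tsv(prox, file.path(outdir, "proximity_enrichment.tsv"))
  emit("proximity", file.path(outdir, "proximity_enrichment.tsv"))
  logf("proximity fold %.2f (z = %.2f)", prox$fold, prox$z)

  ## stage 6: binding curve
  curve <- simulate_binding_curve(Bmax = 1, Kd = 7.7, h = 1.5,
                                  seed = .substream(seed, 10))
  fit <- fit_hill(curve$curve)
  readr::write_tsv(glance(fit), file.path(outdir, "hill_fit.tsv"),
                   progress = FALSE)
  emit("curves", file.path(outdir, "hill_fit.tsv"))
  logf("Hill fit: Kd %.3f nM (true %.3f)", glance(fit)$Kd,
       curve$truth$Kd)

  manifest <- dplyr::bind_rows(artifacts)
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"),
                   progress = FALSE)
  manifest
}
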