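test_that("synthetic genome honors counts, bounds and determinism", {
  ann <- simulate_genome(seed = 401)
  expect_equal(nrow(ann$genome), 2)
  expect_equal(nrow(ann$repeats), 200)
  expect_equal(nrow(ann$enhancers), 300)
  expect_equal(nrow(ann$genes), 400)
  expect_gte(length(unique(ann$repeats$family)), 4)
  for (x in list(ann$repeats, ann$enhancers, ann$genes)) {
    len <- ann$genome$length[match(x$chrom, ann$genome$chrom)]
    expect_true(all(x$start >= 0 & x$end <= len))
  }
  # repeats never overlap each other
  self <- intersect_sets(ann$repeats, ann$repeats)
  expect_equal(nrow(self$pairs), nrow(ann$repeats)) # only self-pairs
  expect_true(all(ann$genes$tss >= ann$genes$start &
                    ann$genes$tss < ann$genes$end))

  # same seed: byte-identical BED output
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_bed(ann$enhancers, f1)
  write_bed(simulate_genome(seed = 401)$enhancers, f2)
  expect_equal(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
  expect_false(identical(
    simulate_genome(seed = 402)$enhancers$start, ann$enhancers$start
  ))
})

test_that("excessive repeat mass is a packing error", {
  expect_error(
    simulate_genome(lengths = 20000, n_repeats = 200, n_enhancers = 5,
                    n_genes = 5, seed = 1),
    class = "chromclip_packing_error"
  )
})

test_that("PAR-CLIP simulation plants the requested enrichment", {
  ann <- simulate_genome(seed = 411)
  clip1 <- simulate_parclip(ann, enrichment_factor = 1, n_peaks = 800,
                            seed = 412)
  p0 <- clip1$truth$background_rate
  se <- sqrt(p0 * (1 - p0) / 800)
  expect_lt(abs(clip1$truth$realized_rate - p0), 3 * se + 1e-9)

  clip0 <- simulate_parclip(ann, conversion_rate = 0, n_peaks = 100,
                            seed = 413)
  expect_true(all(clip0$peaks$conversion_count == 0))
  expect_true(all(clip0$peaks$read_total >= 1))

  expect_error(
    simulate_parclip(ann, enrichment_factor = 500, seed = 414),
    regexp = "maximum",
    class = "chromclip_argument_error"
  )
  # determinism
  a <- simulate_parclip(ann, n_peaks = 50, seed = 415)$peaks
  b <- simulate_parclip(ann, n_peaks = 50, seed = 415)$peaks
  expect_equal(a, b)
})

test_that("conversion counts track the planted rate", {
  ann <- simulate_genome(seed = 421)
  clip <- simulate_parclip(ann, n_peaks = 400, conversion_rate = 0.1,
                           seed = 422)
  rate <- sum(clip$peaks$conversion_count) / sum(clip$peaks$read_total)
  expect_lt(abs(rate - 0.1), 0.01)
})

test_that("signal matrix simulation matches its planted moments", {
  regions <- tibble::tibble(chrom = "chr1",
                            start = (0:499) * 1000,
                            end = (1:500) * 1000,
                            id = sprintf("r%04d", 1:500))
  # phi = 0: replicate variance tracks the mean (Poisson)
  sim0 <- simulate_signal_matrix(regions, phi = 0, base_mean = 100,
                                 seed = 431)
  wt <- sim0$matrix$values[, sim0$matrix$samples$condition == "WT"]
  disp <- estimate_common_dispersion(wt)
  expect_lt(disp, 0.02)

  # planted fold 4: empirical KO/WT ratio within [3, 5.3]
  fold <- rep(1, 500); fold[1:50] <- 4
  sim <- simulate_signal_matrix(regions, planted_fold = fold,
                                phi = 0.1, base_mean = 100, seed = 432)
  v <- sim$matrix$values
  ko <- rowMeans(v[1:50, sim$matrix$samples$condition == "KO"])
  wt <- rowMeans(v[1:50, sim$matrix$samples$condition == "WT"])
  ratio <- mean(ko) / mean(wt)
  expect_gt(ratio, 3); expect_lt(ratio, 5.3)

  expect_equal(simulate_signal_matrix(regions, seed = 433)$matrix$values,
               simulate_signal_matrix(regions, seed = 433)$matrix$values)
})

test_that("proximity planting hits its expected near-count", {
  ann <- simulate_genome(seed = 441)
  enh <- ann$enhancers[5:6, ]
  ps <- simulate_proximity(enh, ann$genes, planted_fold = 3,
                           n_deg = 40, seed = 442)
  expect_equal(nrow(ps$degs), 40)
  expect_equal(ps$truth$planted_near,
               round(3 * ps$truth$background_near_fraction * 40))
  got <- count_features_within(enh, ps$degs)
  expect_equal(got, ps$truth$planted_near)
  # fold 1 gives a near-count at the uniform expectation
  ps1 <- simulate_proximity(enh, ann$genes, planted_fold = 1,
                            n_deg = 40, seed = 443)
  expect_equal(count_features_within(enh, ps1$degs),
               round(ps1$truth$background_near_fraction * 40))
  expect_error(
    simulate_proximity(enh, ann$genes, planted_fold = 50, n_deg = 40,
                       seed = 444),
    class = "chromclip_argument_error"
  )
  # degenerate window: only overlapping or abutting genes count
  ps0 <- simulate_proximity(enh, ann$genes, planted_fold = 1,
                            window_bp = 0, n_deg = 10, seed = 445)
  expect_lte(count_features_within(enh, ps0$degs, window_bp = 0),
             nrow(ps0$degs))
})

test_that("binding curve simulation is exact at zero noise", {
  sim <- simulate_binding_curve(Bmax = 1, Kd = 10, h = 1,
                                x = c(1, 2, 5, 10, 20, 50, 100),
                                noise_sd = 0, seed = 451)
  x <- sim$curve$concentration_nM
  expect_equal(sim$curve$response, x / (10 + x))
  expect_equal(sim$curve$response[x == 10], 0.5)
  expect_equal(simulate_binding_curve(noise_sd = 0.05, seed = 452),
               simulate_binding_curve(noise_sd = 0.05, seed = 452))
  noisy <- simulate_binding_curve(noise_sd = 0.05, seed = 453)$curve
  expect_true(all(noisy$response >= 0 & noisy$response <= 1.05))
})
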