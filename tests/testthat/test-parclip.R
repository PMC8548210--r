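test_that("conversion rate is conversions per read", {
  pk <- tibble::tibble(chrom = "chr1", start = 0, end = 100,
                       conversion_count = c(10, 0),
                       read_total = c(100, 50))
  out <- peak_conversion_rate(pk)
  expect_equal(out$conversion_rate, c(0.1, 0))
  pk$read_total[1] <- 0
  expect_error(peak_conversion_rate(pk),
               class = "chromclip_undefined_rate_error")
})

test_that("window caller needs both fold and Poisson significance", {
  # IP identical to input: no enrichment anywhere
  flat <- grid_track(rep(10, 20))
  expect_equal(nrow(call_enriched_windows(flat, flat)), 0)

  # scaled expectation 5, IP 50: fold 10 and Poisson tail below 1e-5
  # (equal track totals make the library scale factor exactly 1)
  expect_lt(ppois(49, 5, lower.tail = FALSE), 1e-5)
  ip <- grid_track(c(rep(0, 9), 50))
  inp <- grid_track(rep(5, 10))
  got <- call_enriched_windows(ip, inp, min_fold = 2, alpha = 1e-5)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 900)

  # strong fold but insignificant count: not called
  ip2 <- grid_track(c(rep(0, 9), 4))
  inp2 <- grid_track(rep(0.4, 10))
  expect_equal(nrow(call_enriched_windows(ip2, inp2, min_fold = 2,
                                          alpha = 1e-5)), 0)

  # adjacent called windows merge into one peak
  ip3 <- grid_track(c(rep(5, 8), 60, 60))
  inp3 <- grid_track(rep(sum(ip3$value) / 10, 10))
  got3 <- call_enriched_windows(ip3, inp3)
  expect_equal(nrow(got3), 1)
  expect_equal(c(got3$start, got3$end), c(800, 1000))
  expect_equal(got3$read_total, 120)

  expect_error(call_enriched_windows(grid_track(1:5), grid_track(1:6)),
               class = "chromclip_shape_error")
})

test_that("exchangeable IP and input call at most alpha of windows", {
  set.seed(5)
  alpha <- 0.01
  n <- 4000
  ip <- grid_track(rpois(n, 20))
  inp <- grid_track(rpois(n, 20))
  got <- call_enriched_windows(ip, inp, min_fold = 1, alpha = alpha)
  called_windows <- sum(got$n_windows)
  se <- sqrt(alpha * (1 - alpha) * n)
  expect_lte(called_windows, alpha * n + 3 * se)
})

test_that("stringent set applies the replicate/conversion/RPKM triple rule", {
  rep1 <- tibble::tibble(chrom = "chr1", start = 100, end = 600,
                         id = "p1", rpkm = 12)
  rep2 <- tibble::tibble(chrom = "chr1", start = 150, end = 650)
  cl <- tibble::tibble(chrom = "chr1", start = 300, end = 340,
                       conversion_count = 2)
  kept <- stringent_peak_set(rep1, rep2, cl)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$supporting_clusters[[1]], 1L)

  expect_equal(nrow(stringent_peak_set(
    dplyr::mutate(rep1, rpkm = 5), rep2, cl
  )), 0)
  cl_far <- dplyr::mutate(cl, start = 700, end = 740)
  expect_equal(nrow(stringent_peak_set(rep1, rep2, cl_far)), 0)
  rep2_far <- dplyr::mutate(rep2, start = 800, end = 900)
  expect_equal(nrow(stringent_peak_set(rep1, rep2_far, cl)), 0)
  expect_error(
    stringent_peak_set(rep1, rep2, dplyr::mutate(cl,
                                                 conversion_count = 0)),
    class = "chromclip_validation_error"
  )
})

test_that("stringent set matches the brute-force filter on random inputs", {
  set.seed(41)
  g <- toy_genome()
  for (r in 1:50) {
    rep1 <- random_intervals(sample(3:12, 1), g)
    rep1$rpkm <- runif(nrow(rep1), 0, 25)
    rep2 <- random_intervals(sample(3:12, 1), g)
    cl <- random_intervals(sample(3:12, 1), g, max_len = 60)
    cl$conversion_count <- sample(1:5, nrow(cl), replace = TRUE)
    got <- stringent_peak_set(rep1, rep2, cl)
    want <- bf_stringent(rep1, rep2, cl, 10)
    expect_equal(got$id, want$id)
    # order invariance of the inputs
    got_p <- stringent_peak_set(rep1, rep2[sample(nrow(rep2)), ],
                                cl[sample(nrow(cl)), ])
    expect_equal(got_p$id, got$id)
  }
})

test_that("output subsets rep1 and relaxing the cutoff never shrinks it", {
  set.seed(43)
  g <- toy_genome()
  rep1 <- random_intervals(40, g)
  rep1$rpkm <- runif(40, 0, 30)
  rep2 <- random_intervals(40, g)
  cl <- random_intervals(40, g, max_len = 60)
  cl$conversion_count <- 1
  strict <- stringent_peak_set(rep1, rep2, cl, rpkm_cutoff = 15)
  loose <- stringent_peak_set(rep1, rep2, cl, rpkm_cutoff = 5)
  expect_true(all(strict$id %in% rep1$id))
  expect_true(all(strict$id %in% loose$id))
})

test_that("peak context uses coding > lincRNA > intergenic precedence", {
  genes <- tibble::tibble(
    chrom = "chr1", start = c(100, 150, 600), end = c(300, 400, 800),
    gene_id = c("cod", "lnc", "oth"),
    biotype = c("coding", "lincRNA", "other")
  )
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(200, 320, 650, 900), end = c(250, 380, 700, 950)
  )
  out <- classify_peak_context(peaks, genes)
  # peak 1 overlaps both coding and lincRNA -> coding wins;
  # peak 3 overlaps only an "other" gene -> intergenic for this summary
  expect_equal(out$context,
               c("coding", "lincRNA", "intergenic", "intergenic"))
  cs <- context_summary(out)
  expect_equal(sum(cs$n), nrow(peaks))
  expect_equal(cs$n, c(1L, 1L, 2L))
})

test_that("bound fraction by expression bins genes half-open", {
  expr <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                         rpkm = c(rep(0.5, 5), rep(5, 10), rep(50, 5)))
  bound <- c(sprintf("g%02d", 6:9), "g16")
  out <- bound_fraction_by_expression(expr, bound, c(0, 1, 10, 100))
  expect_equal(out$n_genes, c(5L, 10L, 5L))
  expect_equal(out$fraction, c(0, 0.4, 0.2))
  # empty bin is NA, never 0
  out2 <- bound_fraction_by_expression(expr, bound, c(0, 1, 2, 10, 100))
  expect_true(is.na(out2$fraction[2]))
  expect_error(
    bound_fraction_by_expression(expr, "absent", c(0, 1)),
    class = "chromclip_validation_error"
  )
  expect_error(
    bound_fraction_by_expression(expr, bound, c(1, 1, 2)),
    class = "chromclip_argument_error"
  )
})

test_that("planted monotone binding yields non-decreasing bound fractions", {
  set.seed(47)
  n <- 200 * 4
  rpkm <- rep(c(0.5, 5, 25, 75), each = 200)
  p_bound <- rep(c(0.05, 0.2, 0.5, 0.8), each = 200)
  expr <- tibble::tibble(gene_id = sprintf("g%04d", 1:n), rpkm = rpkm)
  bound <- expr$gene_id[runif(n) < p_bound]
  out <- bound_fraction_by_expression(expr, bound, c(0, 1, 10, 50, 100))
  # monotone up to 3 binomial SEs at n = 200 per bin
  slack <- 3 * sqrt(0.25 / 200)
  expect_true(all(diff(out$fraction) > -slack))
})
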