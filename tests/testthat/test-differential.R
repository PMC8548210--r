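make_sm <- function(values, condition, antibody = "H3K27ac",
                    regions = NULL) {
  n <- nrow(values)
  if (is.null(regions)) {
    regions <- tibble::tibble(
      chrom = "chr1", start = (seq_len(n) - 1) * 1000,
      end = seq_len(n) * 1000, id = sprintf("r%04d", seq_len(n))
    )
  }
  reps <- stats::ave(seq_along(condition), condition, antibody,
                     FUN = seq_along)
  samples <- tibble::tibble(
    sample_id = sprintf("%s_%s_rep%d", antibody, condition, reps),
    condition = condition, antibody = antibody, replicate = reps,
    library_size = 1e6
  )
  signal_matrix(values, regions, samples)
}

test_that("quantile normalization replaces ranks by cross-sample means", {
  sm <- make_sm(cbind(c(1, 2, 3), c(4, 6, 8)), c("WT", "KO"))
  out <- quantile_normalize(sm)
  expect_equal(unname(out$values[, 1]), c(2.5, 4, 5.5))
  expect_equal(unname(out$values[, 2]), c(2.5, 4, 5.5))
  expect_true(out$normalized)

  # identical columns are left unchanged
  sm2 <- make_sm(cbind(c(1, 5, 9), c(1, 5, 9)), c("WT", "KO"))
  expect_equal(unname(quantile_normalize(sm2)$values),
               unname(sm2$values))

  # tied entries get the mean of the reference values they span:
  # reference ranks are (5.5, 10.5, 16); the tie spans ranks 1-2 -> 8
  sm3 <- make_sm(cbind(c(1, 1, 2), c(10, 20, 30)), c("WT", "KO"))
  out3 <- quantile_normalize(sm3)
  expect_equal(unname(out3$values[, 1]), c(8, 8, 16))
  expect_equal(unname(out3$values[, 2]), c(5.5, 10.5, 16))
})

test_that("normalization is per antibody group and warns on singletons", {
  set.seed(91)
  v <- matrix(rexp(40), 10, 4)
  sm <- make_sm(v, c("WT", "WT", "WT", "WT"),
                antibody = c("A", "A", "B", "B"))
  out <- quantile_normalize(sm)
  expect_equal(unname(sort(out$values[, 1])),
               unname(sort(out$values[, 2])))
  expect_equal(unname(sort(out$values[, 3])),
               unname(sort(out$values[, 4])))
  expect_false(isTRUE(all.equal(unname(sort(out$values[, 1])),
                                unname(sort(out$values[, 3])))))
  # within-sample order preserved
  expect_equal(order(out$values[, 1]), order(v[, 1]))

  smx <- make_sm(v[, 1, drop = FALSE], "WT", antibody = "solo")
  expect_warning(quantile_normalize(smx), "single sample")
})

test_that("sorted columns coincide after normalization on random data", {
  set.seed(95)
  sm <- make_sm(matrix(rexp(400, 1 / 50), 50, 8),
                rep(c("WT", "KO"), each = 4))
  out <- quantile_normalize(sm)
  ref <- unname(sort(out$values[, 1]))
  for (j in 2:8) expect_equal(unname(sort(out$values[, j])), ref)
})

test_that("specificity filter keeps present-in-WT, lost-in-KO regions", {
  v <- rbind(
    c(2, 2, 2, 2, 0.5, 0.5, 0.5, 0.5),    # kept: mean 2, FC 2/0.75
    c(0.8, 0.8, 0.8, 0.8, 0.1, 0.1, 0.1, 0.1), # fails min_rpkm
    c(2, 2, 2, 2, 1.6, 1.6, 1.6, 1.6)     # fails fold
  )
  sm <- make_sm(v, rep(c("WT", "KO"), each = 4))
  out <- specificity_filter(sm)
  expect_equal(out$id, "r0001")
  expect_equal(out$wt_ko_fold, 2 / 0.75)
  # monotone in both thresholds
  loose <- specificity_filter(sm, min_rpkm = 0.5, min_fc = 1.1)
  expect_true(all(out$id %in% loose$id))
  expect_error(specificity_filter(sm, ko_condition = "KD"),
               class = "chromclip_argument_error")
})

test_that("common dispersion is near truth for Poisson and NB counts", {
  set.seed(101)
  pois <- matrix(rpois(2000, 100), 500, 4)
  expect_lt(estimate_common_dispersion(pois), 0.02)
  nb <- matrix(rnbinom(2000, size = 10, mu = 100), 500, 4)
  est <- estimate_common_dispersion(nb)
  expect_gt(est, 0.05)
  expect_lt(est, 0.15)
  same <- matrix(rep(c(5, 9, 40), each = 4), 3, 4, byrow = TRUE)
  expect_equal(estimate_common_dispersion(same), 0)
  expect_equal(estimate_common_dispersion(matrix(0, 5, 4)), 0)
  expect_error(estimate_common_dispersion(matrix(1:5, 5, 1)),
               class = "chromclip_argument_error")
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)),
               class = "chromclip_validation_error")
  set.seed(105)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("differential calls recover planted folds and respect thresholds", {
  set.seed(111)
  n <- 300
  fold <- rep(1, n)
  fold[1:12] <- 4
  fold[13:24] <- 0.25
  regions <- tibble::tibble(chrom = "chr1",
                            start = (seq_len(n) - 1) * 1000,
                            end = seq_len(n) * 1000,
                            id = sprintf("r%04d", seq_len(n)))
  sim <- simulate_signal_matrix(regions, planted_fold = fold,
                                phi = 0.05, base_mean = 100,
                                seed = 112)
  d <- differential_regions(sim$matrix, "WT", "KO", min_fc = 1.5,
                            max_fdr = 0.01)
  expect_gt(mean(d$direction[1:12] == "up"), 0.8)
  expect_gt(mean(d$direction[13:24] == "down"), 0.8)
  expect_lt(sum(d$direction[25:n] != "ns"), 5)

  # huge significance but fold below threshold stays ns
  sim2 <- simulate_signal_matrix(regions[1:50, ],
                                 planted_fold = rep(1.4, 50),
                                 phi = 0, base_mean = 20000,
                                 seed = 113)
  d2 <- differential_regions(sim2$matrix, "WT", "KO", min_fc = 1.5,
                             max_fdr = 0.01)
  expect_lt(min(d2$fdr), 0.01)
  expect_true(all(d2$direction == "ns"))

  one_rep <- make_sm(matrix(rpois(20, 50), 10, 2), c("WT", "KO"))
  expect_error(differential_regions(one_rep, "WT", "KO"),
               class = "chromclip_argument_error")
})

test_that("p-values track an edgeR exact test on the same counts", {
  skip_if_not_installed("edgeR")
  set.seed(117)
  n <- 200
  counts <- matrix(rnbinom(n * 8, size = 10, mu = 100), n, 8)
  counts[1:10, 5:8] <- rnbinom(40, size = 10, mu = 400)
  sm <- make_sm(counts, rep(c("WT", "KO"), each = 4))
  d <- differential_regions(sm, "WT", "KO")
  dge <- edgeR::DGEList(counts = counts,
                        group = rep(c("WT", "KO"), each = 4))
  dge <- edgeR::estimateCommonDisp(dge)
  et <- edgeR::exactTest(dge)$table
  expect_gt(cor(-log10(d$p_value), -log10(et$PValue)), 0.9)
  # the planted regions are the top hits under both tests
  expect_true(all(order(d$p_value)[1:10] %in% 1:10))
  expect_true(all(order(et$PValue)[1:10] %in% 1:10))
})

test_that("DEG calls use the twofold/FDR rule", {
  set.seed(121)
  n <- 200
  fold <- rep(1, n); fold[1:10] <- 4; fold[11:20] <- 1.8
  mu <- outer(rep(100, n), rep(1, 8))
  mu[, 5:8] <- mu[, 5:8] * fold
  counts <- matrix(rnbinom(n * 8, size = 20, mu = mu), n, 8)
  tab <- tibble::as_tibble(counts, .name_repair = ~ sprintf("s%d", 1:8))
  tab$gene_id <- sprintf("g%04d", 1:n)
  samples <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    condition = rep(c("WT", "KD"), each = 4),
    antibody = "RNA", replicate = rep(1:4, 2), library_size = 1e6
  )
  d <- call_degs(tab, samples, "WT", "KD")
  expect_gt(mean(d$direction[1:10] == "up"), 0.8)

  # an observed 1.8-fold gene stays ns at min_fc = 2 no matter the
  # p-value (zero replicate variance makes the p essentially 0)
  fixed <- tibble::tibble(
    s1 = 1000, s2 = 1000, s3 = 1000, s4 = 1000,
    s5 = 1800, s6 = 1800, s7 = 1800, s8 = 1800,
    gene_id = "g_fc18"
  )
  d18 <- call_degs(dplyr::bind_rows(fixed, fixed, fixed, fixed),
                   samples, "WT", "KD")
  expect_true(all(d18$p_value < 1e-10))
  expect_true(all(d18$direction == "ns"))
})

test_that("bound fraction compares density to length-scaled background", {
  regions <- tibble::tibble(chrom = "chr1",
                            start = (0:9) * 1000, end = (1:10) * 1000,
                            id = sprintf("r%02d", 1:10))
  # background 0.01 reads/bp -> expectation 10 per 1-kb region
  dens <- c(rep(20, 3), rep(10, 7))
  out <- bound_region_fraction(regions, dens, 0.01, min_fold = 1.5)
  expect_equal(out$fraction, 0.3)
  expect_equal(out$n_bound, 3L)
  out0 <- bound_region_fraction(regions, dens, 0.01, min_fold = 0)
  expect_equal(out0$fraction, 1)
  expect_error(bound_region_fraction(regions, dens, 0),
               class = "chromclip_argument_error")
})

test_that("uniform coverage yields the Poisson tail bound fraction", {
  set.seed(125)
  n <- 2000
  lambda <- 50 # expected reads per region under uniform background
  regions <- tibble::tibble(chrom = "chr1",
                            start = (seq_len(n) - 1) * 1000,
                            end = seq_len(n) * 1000,
                            id = sprintf("r%05d", seq_len(n)))
  dens <- rpois(n, lambda)
  out <- bound_region_fraction(regions, dens, lambda / 1000,
                               min_fold = 1.1)
  expected <- ppois(ceiling(1.1 * lambda) - 1, lambda,
                    lower.tail = FALSE)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(out$fraction - expected), 3 * se + 1e-9)
})

test_that("signal correlation detects dependence and its absence", {
  set.seed(131)
  x <- runif(1000)
  d1 <- tibble::tibble(a = x, b = 2 * x + rnorm(1000, 0, 0.05))
  r1 <- signal_correlation(d1, "a", "b")
  expect_gt(r1$rho, 0.95)
  expect_equal(nrow(r1$bins), 10)
  d2 <- tibble::tibble(a = x, b = runif(1000))
  expect_lt(abs(signal_correlation(d2, "a", "b")$rho), 0.1)
  d3 <- tibble::tibble(a = x[1:10], b = rep(1, 10))
  expect_true(is.na(signal_correlation(d3, "a", "b")$rho))
  expect_error(signal_correlation(d3[1:2, ], "a", "b"),
               class = "chromclip_argument_error")
})

test_that("metaprofiles average bins and honor strand", {
  track <- grid_track(rep(3, 100), window = 10)
  regions <- tibble::tibble(chrom = "chr1", start = 200, end = 400)
  prof <- region_metaprofile(track, regions, flank_bp = 50, n_bins = 10)
  expect_equal(prof, rep(3, 10))

  # signal only in the central bin of a single region
  track2 <- tibble::tibble(chrom = "chr1", start = 240, end = 260,
                           value = 10)
  prof2 <- region_metaprofile(track2, tibble::tibble(
    chrom = "chr1", start = 200, end = 300
  ), n_bins = 5)
  expect_equal(which.max(prof2), 3)
  expect_equal(prof2[c(1, 2, 4, 5)], rep(0, 4))

  # minus-strand region reverses left-loaded signal
  track3 <- tibble::tibble(chrom = "chr1", start = 200, end = 220,
                           value = 8)
  minus <- tibble::tibble(chrom = "chr1", start = 200, end = 300,
                          strand = "-")
  prof3 <- region_metaprofile(track3, minus, n_bins = 5)
  expect_equal(which.max(prof3), 5)

  g <- genome_layout("chr1", 1000)
  expect_warning(
    region_metaprofile(track, tibble::tibble(chrom = "chr1",
                                             start = 900, end = 990),
                       flank_bp = 50, n_bins = 4, genome = g),
    "clipped"
  )
})

test_that("per-copy table reports expression change, overlap and neighbor", {
  loci <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                         start = c(100, 5000, 0),
                         end = c(600, 5600, 400),
                         id = c("h1", "h2", "h3"))
  peaks <- tibble::tibble(chrom = "chr1", start = 50, end = 200)
  genes <- tibble::tibble(chrom = "chr1", start = c(1000, 8000),
                          end = c(2000, 9000),
                          gene_id = c("gA", "gB"))
  out <- hervh_copy_table(loci, wt_rpkm = c(7, 2, 1),
                          kd_rpkm = c(1.5, 2, 1),
                          parclip_peaks = peaks, genes = genes)
  expect_equal(out$log2fc_kd_wt[1], log2(1.75 / 7.25))
  expect_true(out$responsive[1])
  expect_false(out$responsive[2])
  expect_equal(out$parclip_overlap, c("YES", "NO", "NO"))
  expect_equal(out$closest_gene[1:2], c("gA", "gB"))
  expect_equal(out$closest_gene_distance[2], 2400)
  expect_true(is.na(out$closest_gene[3]))
  expect_equal(out$closest_gene_distance[3], Inf)
})
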