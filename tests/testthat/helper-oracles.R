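# Brute-force oracles and tiny fixture builders shared across tests.
# The oracles use only plain arithmetic over all pairs so they stay
# independent of the package's interval machinery.

toy_genome <- function(n = 2, len = 10000) {
  genome_layout(paste0("chr", seq_len(n)), rep(len, n))
}

random_intervals <- function(n, genome, max_len = 500, id_prefix = "iv") {
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (genome$length[ci] - len))
  tibble::tibble(chrom = genome$chrom[ci], start = start,
                 end = start + len,
                 id = sprintf("%s%04d", id_prefix, seq_len(n)))
}

# all-pairs overlap length under half-open semantics
bf_overlap_bp <- function(a, i, b, j) {
  if (a$chrom[i] != b$chrom[j]) return(0)
  min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
}

bf_intersect_flags <- function(a, b, min_overlap = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      bf_overlap_bp(a, i, b, j) >= min_overlap
    }, logical(1)))
  }, logical(1))
}

bf_family_fraction <- function(peaks, repeats) {
  fams <- sort(unique(repeats$family))
  vapply(fams, function(f) {
    r <- repeats[repeats$family == f, ]
    mean(bf_intersect_flags(peaks, r))
  }, numeric(1))
}

bf_distance <- function(a, i, b, j) {
  if (a$chrom[i] != b$chrom[j]) return(Inf)
  max(0, max(a$start[i], b$start[j]) - min(a$end[i], b$end[j]))
}

bf_count_within <- function(enh, genes, w) {
  sum(vapply(seq_len(nrow(genes)), function(j) {
    any(vapply(seq_len(nrow(enh)), function(i) {
      bf_distance(genes, j, enh, i) <= w
    }, logical(1)))
  }, logical(1)))
}

bf_stringent <- function(rep1, rep2, clusters, cutoff) {
  keep <- vapply(seq_len(nrow(rep1)), function(i) {
    in2 <- any(bf_intersect_flags(rep1[i, ], rep2))
    incl <- any(bf_intersect_flags(rep1[i, ], clusters))
    in2 && incl && rep1$rpkm[i] > cutoff
  }, logical(1))
  rep1[keep, ]
}

grid_track <- function(values, window = 100, chrom = "chr1") {
  n <- length(values)
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * window,
                 end = seq_len(n) * window, value = values)
}
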