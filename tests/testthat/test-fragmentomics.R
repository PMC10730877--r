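# 5'-end motifs, NF scores, genome bins, fragment sizes

test_that("end motif profile counts 5' reference 4-mers", {
  g <- toy_genome(c(chr1 = "AAAAAAAACCCCTTTTGGGG"))
  fs <- toy_frags("chr1", c(0L, 2L, 8L), c(14L, 16L, 16L), "+")
  prof <- end_motif_profile(fs, g, ends_mode = "five_prime")
  expect_equal(prof$n_counted, 3L)
  expect_equal(unname(prof$freq["AAAA"]), 2 / 3)
  expect_equal(unname(prof$freq["CCCC"]), 1 / 3)
  expect_equal(sum(prof$freq > 0), 2L)
  expect_equal(sum(prof$freq), 1, tolerance = 1e-9)
  expect_length(prof$freq, 256L)
})

test_that("both-ends mode reverse-complements the minus-template end", {
  g <- toy_genome(c(chr1 = "AAAATTTTGGGGCCCC"))
  fs <- toy_frags("chr1", 0L, 12L, "+")
  prof <- end_motif_profile(fs, g, ends_mode = "both")
  # forward end AAAA; reverse end = revcomp(GGGG) = CCCC
  expect_equal(unname(prof$freq[c("AAAA", "CCCC")]), c(0.5, 0.5))
  expect_equal(prof$n_counted, 2L)
})

test_that("chrY and unidentifiable bases are excluded", {
  g <- toy_genome(c(chr1 = "ACNNGGGGTTTT", chrY = "ACGTACGTACGT"))
  expect_error(end_motif_profile(toy_frags("chrY", 0L, 8L), g),
               "no countable")
  # the ACNN end is skipped; only the GGGG end remains
  fs <- toy_frags("chr1", c(0L, 4L), c(10L, 10L), "+")
  prof <- end_motif_profile(fs, g, ends_mode = "five_prime")
  expect_equal(prof$n_counted, 1L)
  expect_equal(unname(prof$freq["GGGG"]), 1)
  # a fragment on a chromosome missing from the genome is an error
  expect_error(
    end_motif_profile(toy_frags("chr9", 0L, 8L), g, "five_prime"),
    "chr9")
})

test_that("motif profile is invariant to fragment input order", {
  g <- toy_genome(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")))
  set.seed(42)
  start <- sample.int(4000, 200) - 1L
  df <- data.frame(chrom = "chr1", start = start, end = start + 160L,
                   strand = sample(c("+", "-"), 200, TRUE))
  p1 <- end_motif_profile(fragment_set(df), g)
  p2 <- end_motif_profile(fragment_set(df[sample.int(200), ]), g)
  expect_identical(p1$freq, p2$freq)
})

test_that("NF score matches the brute-force per-bp coverage oracle", {
  # fragments tile the two background windows but avoid the promoter
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 5000L,
                      strand = "+")
  starts <- c(seq(2000L, 3900L, by = 100L), seq(6000L, 7900L, by = 100L))
  df <- data.frame(chrom = "chr1", start = starts, end = starts + 100L,
                   strand = "+")
  fs <- fragment_set(df)
  tab <- nf_score(fs, genes)
  scale <- 1e6 / nrow(df)
  expect_equal(tab$promoter_cov,
               oracle_mean_coverage(df, "chr1", 4000, 6000) * scale,
               tolerance = 1e-9)
  expect_equal(tab$bg1_cov,
               oracle_mean_coverage(df, "chr1", 2000, 4000) * scale,
               tolerance = 1e-9)
  expect_equal(tab$bg2_cov,
               oracle_mean_coverage(df, "chr1", 6000, 8000) * scale,
               tolerance = 1e-9)
  expect_gt(tab$nf_score, 0)
  expect_equal(tab$nf_score,
               (tab$bg1_cov + tab$bg2_cov) / 2 - tab$promoter_cov,
               tolerance = 1e-12)
})

test_that("uniform coverage gives NF score zero", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 5000L,
                      strand = "+")
  fs <- toy_frags("chr1", rep(0L, 5), rep(20000L, 5))
  tab <- nf_score(fs, genes)
  expect_equal(tab$nf_score, 0, tolerance = 1e-12)
})

test_that("NF windows are strand-aware and bounds-checked", {
  genes <- data.frame(gene_id = c("gm", "gedge"), chrom = "chr1",
                      tss = c(5000L, 500L), strand = c("-", "+"))
  # coverage only on [6001, 8001), which is background1 for a minus gene
  starts <- seq(6001L, 7901L, by = 100L)
  fs <- fragment_set(data.frame(chrom = "chr1", start = starts,
                                end = starts + 100L, strand = "+"))
  expect_message(tab <- nf_score(fs, genes), "dropped 1")
  expect_identical(tab$gene_id, "gm")
  expect_gt(tab$bg1_cov, 0)
  expect_equal(tab$bg2_cov, 0)
})

test_that("empty fragment set yields all-zero NF scores", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 5000L,
                      strand = "+")
  fs <- fragment_set(data.frame(chrom = character(), start = integer(),
                                end = integer(), strand = character()))
  tab <- nf_score(fs, genes)
  expect_equal(tab$nf_score, 0)
  expect_equal(tab$promoter_cov, 0)
})

test_that("genome binning tiles chromosomes with a truncated last bin", {
  bins <- bin_genome(c(chrA = 2500000), bin_size = 1e6)
  expect_identical(nrow(bins), 3L)
  expect_equal(bins$end - bins$start, c(1e6, 1e6, 5e5))
  # exact tiling: contiguous, non-overlapping, covering the chromosome
  expect_equal(bins$start[-1], bins$end[-nrow(bins)])
  expect_equal(sum(bins$end - bins$start), 2500000)
  # chrY exclusion
  bins2 <- bin_genome(c(chrA = 1e6, chrY = 5e5), bin_size = 1e5)
  expect_false("chrY" %in% bins2$chrom)
  expect_identical(nrow(bins2), 10L)
})

test_that("hg19 1-Mb binning of chr1-22+X gives 3053 bins", {
  sizes <- hg19_chrom_sizes()
  bins <- bin_genome(sizes, bin_size = 1e6, exclude = "chrY")
  expect_identical(nrow(bins), 3053L)
  # per-chromosome tiling is exact
  for (ch in c("chr1", "chr21", "chrX")) {
    b <- bins[bins$chrom == ch, ]
    expect_equal(sum(b$end - b$start), unname(sizes[ch]))
    expect_true(all(b$start[-1] == b$end[-nrow(b)]))
  }
})

test_that("bin features compute short-fragment fractions by midpoint", {
  bins <- bin_genome(c(chrA = 1000), bin_size = 500)
  starts <- c(rep(0L, 4), rep(100L, 6))
  lens <- c(rep(120L, 4), rep(200L, 6))
  fs <- fragment_set(data.frame(chrom = "chrA", start = starts,
                                end = starts + lens, strand = "+"))
  fb <- fragment_bin_features(fs, bins)
  expect_equal(fb$short_frac[1], 0.4)
  expect_identical(fb$n_short[1], 4L)
  expect_identical(fb$n_long[1], 6L)
  expect_true(fb$missing[2])
  expect_equal(fb$short_frac[2], 0)
  expect_error(fragment_bin_features(fs, bins, short_range = c(100, 160),
                                     long_range = c(150, 220)),
               "disjoint")
})

test_that("bin z-scores average zero over non-missing bins", {
  bins <- bin_genome(c(chrA = 4000), bin_size = 1000)
  set.seed(7)
  n <- 400
  start <- sample.int(3500, n, replace = TRUE) - 1L
  len <- sample(c(120L, 200L), n, replace = TRUE)
  fs <- fragment_set(data.frame(chrom = "chrA", start = start,
                                end = start + len, strand = "+"))
  fb <- fragment_bin_features(fs, bins)
  expect_equal(mean(fb$zscore[!fb$missing]), 0, tolerance = 1e-9)
})

test_that("size histogram counts and median agree with raw lengths", {
  fs <- toy_frags("chrA", c(0L, 0L, 0L), c(100L, 150L, 200L))
  h <- size_histogram(fs)
  expect_equal(h$median_size, 150)
  expect_equal(sum(h$counts), 3)
  fs2 <- toy_frags("chrA", rep(0L, 5), rep(166L, 5))
  h2 <- size_histogram(fs2)
  expect_equal(unname(h2$counts["166"]), 5L)
  expect_equal(h2$median_size, 166)
  expect_error(size_histogram(fs, range = c(500, 600)), "no fragments")
})
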