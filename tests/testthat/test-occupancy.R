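test_that("BED parsing validates intervals and preserves half-open semantics", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("track name=demo", "chr1\t100\t200\tp1", "chr1\t250\t300\tp2"),
             path)
  gr <- read_bed(path)
  expect_length(gr, 2L)
  expect_equal(GenomicRanges::start(gr), c(101L, 251L))
  expect_equal(GenomicRanges::end(gr), c(200L, 300L))
  writeLines(c("chr1\t100\t200", "chr1\t300\t300"), path)
  expect_error(read_bed(path), "line 2")
  writeLines("chr1\t100", path)
  expect_error(read_bed(path), "line 1")
  writeLines(character(0), path)
  expect_warning(gr0 <- read_bed(path), "empty")
  expect_length(gr0, 0L)
})

test_that("BED round-trips through write and read without loss", {
  gr <- GenomicRanges::GRanges(c("chr2", "chr1"),
                               IRanges::IRanges(c(11, 101), c(60, 200)))
  S4Vectors::mcols(gr)$name <- c("b", "a")
  path <- tempfile(fileext = ".bed")
  write_bed(gr, path)
  back <- read_bed(path)
  srt <- sort(gr, ignore.strand = TRUE)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(srt))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(srt))
  expect_equal(S4Vectors::mcols(back)$name, S4Vectors::mcols(srt)$name)
})

test_that("abutting half-open intervals do not overlap; nested ones do", {
  p <- promoter_set(GenomicRanges::GRanges("chr1",
                                           IRanges::IRanges(101, 200)))
  abut <- peak_set(GenomicRanges::GRanges("chr1",
                                          IRanges::IRanges(201, 300)), "T", "MET")
  nest <- peak_set(GenomicRanges::GRanges("chr1",
                                          IRanges::IRanges(151, 160)), "T", "MET")
  expect_equal(nrow(overlap_pairs(p, abut)), 0L)
  ov <- overlap_pairs(p, nest)
  expect_equal(nrow(ov), 1L)
  expect_equal(nrow(overlap_pairs(p, nest, min_overlap = 10)), 1L)
  expect_equal(nrow(overlap_pairs(p, nest, min_overlap = 11)), 0L)
})

test_that("the overlap engine matches the quadratic oracle on random instances", {
  set.seed(17)
  for (i in 1:8) {
    inst <- random_interval_instance(sample(5:40, 1), sample(5:60, 1))
    got <- sort_pairs(overlap_pairs(inst$promoters, inst$peaks))
    want <- sort_pairs(brute_force_overlap(inst$promoters, inst$peaks))
    expect_equal(got, want)
  }
})

test_that("occupancy rates use the peak-count denominator in both modes", {
  p <- promoter_set(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101, 501, 901), width = 100)))
  pk <- peak_set(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(110, 120, 505, 2000), width = 10)),
    "T", "MET")
  po <- promoter_occupancy(p, pk)
  expect_equal(po$n_hits, 2L)            # two promoters are hit
  expect_equal(po$rate, 2 / 4)           # of four peaks
  pe <- peak_occupancy(p, pk)
  expect_equal(pe$n_hits, 3L)            # three peaks land in promoters
  expect_equal(pe$rate, 3 / 4)
  empty <- peak_set(GenomicRanges::GRanges(), "T", "MET")
  expect_error(promoter_occupancy(p, empty), "zero peaks")
})

test_that("occupancy comparison is symmetric in p and inverse in fold", {
  a <- occupancy_from_counts("promoter", 277, 75474)
  b <- occupancy_from_counts("promoter", 503, 120679)
  ab <- compare_occupancy(a, b)
  ba <- compare_occupancy(b, a)
  expect_equal(round(ab$fold, 2), 1.14)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$fold, 1 / ba$fold)
  same <- compare_occupancy(a, a)
  expect_equal(same$fold, 1)
  expect_equal(same$p_value, 1)
  expect_error(compare_occupancy(a, occupancy_from_counts("peak", 1, 10)),
               "modes")
  z <- occupancy_from_counts("promoter", 0, 100)
  w <- capture_warnings(zz <- compare_occupancy(z, a))
  expect_true(any(grepl("Inf", w)))  # plus a chi-square small-count warning
  expect_equal(zz$fold, Inf)
})

test_that("promoter-level pair expectation is n_a*n_b/N with Fisher support", {
  r <- promoter_pair_stats(503, 436, 4102, 228)
  expect_equal(round(r$both_expected, 2), 53.46)
  expect_equal(round(r$fold, 2), 4.26)
  expect_lt(r$p_value, 1e-4)
  # expectation bounded by both marginals
  expect_lte(r$both_expected, min(503, 436))
  expect_warning(r0 <- promoter_pair_stats(0, 10, 100, 0), "undefined")
  expect_true(is.na(r0$fold))
  expect_error(promoter_pair_stats(5, 5, 100, 6))
})

test_that("promoter-level expectation equals the permutation-null mean", {
  set.seed(23)
  N <- 60; n_a <- 25; n_b <- 18
  draws <- replicate(10000, {
    a <- sample.int(N, n_a); b <- sample.int(N, n_b)
    length(intersect(a, b))
  })
  expected <- promoter_pair_stats(n_a, n_b, N, 5)$both_expected
  expect_lt(abs(mean(draws) - expected) / expected, 0.02)
})

test_that("peak-level pair expectation is rate_a*rate_b*N and symmetric", {
  r <- peak_pair_stats(796, 120679, 305, 19030, 4102, 152)
  expect_equal(round(r$both_expected, 2), 0.43)
  expect_equal(round(r$fold, 2), 350.51)
  s <- peak_pair_stats(305, 19030, 796, 120679, 4102, 152)
  expect_equal(r$both_expected, s$both_expected)
  expect_equal(r$fold, s$fold)
  expect_warning(z <- peak_pair_stats(0, 10, 5, 10, 100, 0), "undefined")
  expect_true(is.na(z$fold))
})

test_that("interval-level co-occupancy agrees with its count-level arithmetic", {
  g <- gen_genome(small_config(29))
  pr <- g$promoters
  r <- promoter_pair_cooccupancy(pr, g$peaks$A, g$peaks$B)
  hit_a <- GenomicRanges::countOverlaps(pr$ranges, g$peaks$A$ranges) > 0
  hit_b <- GenomicRanges::countOverlaps(pr$ranges, g$peaks$B$ranges) > 0
  expect_equal(r$both_observed, sum(hit_a & hit_b))
  expect_equal(r$both_expected, sum(hit_a) * sum(hit_b) / pr$n)
  pk <- peak_pair_cooccupancy(pr, g$peaks$A, g$peaks$B)
  pk_swap <- peak_pair_cooccupancy(pr, g$peaks$B, g$peaks$A)
  expect_equal(pk$both_expected, pk_swap$both_expected)
  expect_equal(pk$fold, pk_swap$fold)
  # alternative observed-count definition stays within its natural bound
  alt <- peak_pair_cooccupancy(pr, g$peaks$A, g$peaks$B,
                               both_observed_mode = "peaks_in_shared_promoters")
  expect_lte(alt$both_observed,
             sum(GenomicRanges::countOverlaps(
               g$peaks$A$ranges, pr$ranges) > 0) +
               sum(GenomicRanges::countOverlaps(
                 g$peaks$B$ranges, pr$ranges) > 0))
})

test_that("peak aggregation concatenates files without merging", {
  d <- tempfile(); dir.create(d)
  gr1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:10 * 50, width = 30))
  gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:15 * 40, width = 30))
  write_bed(gr1, file.path(d, "a.bed"))
  write_bed(gr2, file.path(d, "b.bed"))
  ps <- aggregate_peaks(file.path(d, c("a.bed", "b.bed")), "JUN", "MET")
  expect_equal(ps$n_peaks, 25L)
  one <- aggregate_peaks(file.path(d, "a.bed"), "JUN", "MET")
  expect_equal(one$n_peaks, length(read_bed(file.path(d, "a.bed"))))
  expect_error(aggregate_peaks(file.path(d, "missing.bed")), "missing.bed")
})
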