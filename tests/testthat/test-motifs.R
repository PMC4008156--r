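simple_pwm <- function(cons = "ACGT", p = 0.97) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(cons)
  m <- matrix((1 - p) / 3, 4, L, dimnames = list(bases, NULL))
  for (j in seq_len(L)) m[substr(cons, j, j), j] <- p
  m
}

# Independent per-position rescoring oracle: score the subsequence (and its
# reverse complement for the minus strand) against the PWM with an explicit
# loop.
oracle_scan <- function(sequence, pwm, threshold) {
  bases <- c("A", "C", "G", "T")
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  score1 <- function(s) {
    tot <- 0
    for (j in seq_len(nchar(s))) {
      ch <- substr(s, j, j)
      if (ch != "N") tot <- tot + log2(pwm[ch, j] / 0.25)
    }
    tot
  }
  L <- ncol(pwm)
  out <- NULL
  for (i in seq_len(nchar(sequence) - L + 1)) {
    win <- substr(sequence, i, i + L - 1)
    for (s in c("+", "-")) {
      sc <- if (s == "+") score1(win) else score1(revcomp(win))
      if (sc >= threshold)
        out <- rbind(out, data.frame(position = i, strand = s, score = sc,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    return(data.frame(position = integer(0), strand = character(0),
                      score = numeric(0)))
  out[order(out$position, out$strand), , drop = FALSE]
}

test_that("a planted consensus is found once, and on the minus strand when reverse-complemented", {
  pwm <- simple_pwm("ACGGT")
  seq_fwd <- paste0("TTTT", "ACGGT", "TTTTT")
  hits <- scan_pwm(seq_fwd, pwm, threshold = 8)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 5L)
  expect_equal(hits$strand, "+")
  seq_rev <- paste0("TTTT", "ACCGT", "TTTTT")  # revcomp of ACGGT
  hits_r <- scan_pwm(seq_rev, pwm, threshold = 8)
  expect_equal(hits_r$strand, "-")
  expect_equal(hits_r$position, 5L)
  expect_equal(hits_r$score, hits$score)
})

test_that("N bases contribute zero log-odds and bad inputs error", {
  pwm <- simple_pwm("ACG")
  full <- scan_pwm("ACG", pwm, threshold = -100)
  withN <- scan_pwm("ANG", pwm, threshold = -100)
  expect_equal(withN$score[withN$strand == "+"],
               full$score[full$strand == "+"] - log2(0.97 / 0.25))
  expect_error(scan_pwm("ACXG", pwm, 0), "alphabet")
  bad <- pwm; bad[1, 1] <- 0.5
  expect_error(scan_pwm("ACGT", bad, 0), "sum to 1")
})

test_that("the scanner matches a brute-force rescoring oracle on random sequences", {
  set.seed(31)
  pwm <- simple_pwm("ACGTAC", p = 0.7)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 300, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    thr <- runif(1, -2, 6)
    got <- scan_pwm(s, pwm, thr)
    want <- oracle_scan(s, pwm, thr)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("single-motif enrichment reproduces the published fold arithmetic", {
  nfkb <- single_motif_enrichment(2386, 4102, 0.498)
  expect_equal(round(100 * nfkb$prop_set, 1), 58.2)
  expect_equal(round(nfkb$fold, 3), 1.168)
  expect_lt(nfkb$p_value, 1e-6)
  ebox <- single_motif_enrichment(2472, 4102, 0.561)
  expect_equal(round(100 * ebox$prop_set, 1), 60.3)
  expect_equal(round(ebox$fold, 3), 1.074)
  # observation at expectation: fold ~ 1, p large
  null <- single_motif_enrichment(round(0.4 * 1000), 1000, 0.4)
  expect_equal(null$fold, 1)
  expect_gt(null$p_value, 0.9)
  expect_error(single_motif_enrichment(5, 10, 0), "expected_prop")
  expect_error(single_motif_enrichment(5, 10, 1), "expected_prop")
})

test_that("pair expectation is the symmetric product of single folds", {
  expect_equal(round(pair_expected_enrichment(0.995, 1.074), 2), 1.07)
  expect_equal(round(pair_expected_enrichment(0.932, 0.870), 2), 0.81)
  expect_equal(pair_expected_enrichment(1, 1), 1)
  expect_equal(pair_expected_enrichment(0.7, 1.3),
               pair_expected_enrichment(1.3, 0.7))
  expect_error(pair_expected_enrichment(0, 1))
})

test_that("pair test counts co-hit promoters and bounds hold", {
  hits <- cbind(a = c(TRUE, TRUE, FALSE, FALSE),
                b = c(FALSE, FALSE, TRUE, TRUE))
  rownames(hits) <- paste0("p", 1:4)
  m <- motif_hit_matrix(hits)
  bg <- motif_background(c(a = 0.5, b = 0.5), c("a|b" = 0.25))
  r <- pair_enrichment_test(m, bg, "a", "b")
  expect_equal(r$n_pair_obs, 0L)
  expect_equal(r$observed_enrichment, 0)
  expect_lte(r$n_pair_obs, min(sum(hits[, "a"]), sum(hits[, "b"])))
  # missing background pair proportion: counts only, with a warning
  bg2 <- motif_background(c(a = 0.5, b = 0.5))
  expect_warning(r2 <- pair_enrichment_test(m, bg2, "a", "b"),
                 "counts only")
  expect_true(is.na(r2$observed_enrichment))
  expect_equal(r2$n_pair_obs, 0L)
})

test_that("independent motif columns give observed enrichment near the product", {
  # mean difference over seeds should be near zero under independence
  diffs <- vapply(1:50, function(s) {
    g <- gen_genome(small_config(s, genome = list(
      n_promoters = 400L, chrom_length = 5e5,
      motif_props = c(m1 = 0.4, m2 = 0.5))))
    r <- pair_enrichment_test(g$motif_matrix, g$motif_background, "m1", "m2")
    r$difference
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * se + 1e-8)
})

test_that("motif hit matrices and JASPAR-style PWMs round-trip from disk", {
  hits <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2,
                 dimnames = list(c("p1", "p2"), c("mA", "mB")))
  m <- motif_hit_matrix(hits)
  path <- tempfile(fileext = ".tsv")
  write_motif_hits(m, path)
  back <- read_motif_hits(path)
  expect_identical(back$hits, m$hits)
  pf <- tempfile(fileext = ".pfm")
  writeLines(c(">M1 test",
               "A [ 10  0  0 ]",
               "C [  0 10  0 ]",
               "G [  0  0 10 ]",
               "T [  0  0  0 ]"), pf)
  pwms <- read_pwm_jaspar(pf, pseudocount = 0)
  expect_equal(dim(pwms$M1), c(4L, 3L))
  expect_equal(colSums(pwms$M1), rep(1, 3))
  expect_equal(unname(pwms$M1["A", 1]), 1)
})

test_that("motif backgrounds load from YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("singles:", "  mA: 0.4", "  mB: 0.5",
               "pairs:", "  mA|mB: 0.2"), path)
  bg <- read_motif_background(path)
  expect_equal(bg$singles[["mA"]], 0.4)
  expect_equal(bg$pairs[["mA|mB"]], 0.2)
})
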