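# Small simulation configurations for fast tests. Sizes are scaled down from
# the study-shaped defaults; the generators themselves are unchanged.

small_config <- function(seed = 11L, expression = list(), literature = list(),
                         genome = list(), network = list()) {
  base <- list(
    expression = list(n_genes = 300L, n_de = c(BC = 40L, PC = 50L),
                      n_shared = 20L, concordance = 0.7),
    literature = list(universe_size = 2000L, set_size = 100L,
                      base_rate = 0.05, enrichment_fold = 3),
    genome = list(n_chroms = 2L, chrom_length = 2e5, n_promoters = 50L,
                  promoter_width = 500L, peak_width = 200L,
                  tfs = list(A = list(n_peaks = 500L, theta = 0.2),
                             B = list(n_peaks = 400L, theta = 0.15))),
    network = list(n_nodes = 40L, edge_density = 0.02))
  sim_config(
    seed = seed,
    expression = utils::modifyList(base$expression, expression),
    literature = utils::modifyList(base$literature, literature),
    genome = utils::modifyList(base$genome, genome),
    network = utils::modifyList(base$network, network))
}

# Random promoter/peak instance for overlap testing (may contain overlapping
# promoters on purpose: the overlap engine must not care).
random_interval_instance <- function(n_prom, n_peak, chrom_len = 10000L,
                                     max_width = 300L) {
  gr <- function(n) {
    s <- sample.int(chrom_len, n, replace = TRUE)
    w <- sample.int(max_width, n, replace = TRUE)
    GenomicRanges::GRanges(sample(c("chr1", "chr2"), n, replace = TRUE),
                           IRanges::IRanges(s, width = w))
  }
  p <- gr(n_prom)
  S4Vectors::mcols(p)$name <- paste0("p", seq_len(n_prom))
  list(promoters = promoter_set(p), peaks = peak_set(gr(n_peak), "T", "MET"))
}

# Quadratic all-vs-all overlap oracle, independent of the interval engine.
brute_force_overlap <- function(promoters, peaks, min_overlap = 1) {
  pr <- promoters$ranges; pk <- peaks$ranges
  out <- NULL
  for (i in seq_along(pr)) {
    for (j in seq_along(pk)) {
      if (as.character(GenomicRanges::seqnames(pr)[i]) !=
          as.character(GenomicRanges::seqnames(pk)[j])) next
      ov <- min(GenomicRanges::end(pr)[i], GenomicRanges::end(pk)[j]) -
        max(GenomicRanges::start(pr)[i], GenomicRanges::start(pk)[j]) + 1L
      if (ov >= min_overlap)
        out <- rbind(out, data.frame(promoter_id = promoters$ids[i],
                                     peak_index = j,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(promoter_id = character(0), peak_index = integer(0))
  out
}

sort_pairs <- function(df) {
  df <- df[order(df$promoter_id, df$peak_index), , drop = FALSE]
  rownames(df) <- NULL
  df
}
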