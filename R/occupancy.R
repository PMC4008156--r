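# ChIP-Seq peak vs promoter interval overlap and co-occupancy statistics.
#
# Coordinates are BED-native on disk (0-based, half-open) and GRanges-native
# (1-based, closed) in memory; read_bed()/write_bed() convert. Overlap means
# at least min_overlap shared base pairs, so abutting half-open intervals do
# not overlap. Strand is ignored: ChIP peaks are unstranded.
#
# Rate conventions follow the study design:
#   promoter occupancy rate = promoters with >= 1 peak / total peaks
#   peak occupancy rate     = peaks overlapping >= 1 promoter / total peaks
# Pair co-occupancy expectations under independent binding:
#   promoter level: n_a * n_b / N_p
#   peak level:     rate_a * rate_b * N_p

OIMET_TISSUE_CLASSES <- c("not_cancer", "MET", "non_MET")

#' Read a BED file of genomic intervals
#'
#' Accepts 3-6 column tab-delimited BED; `track`, `browser` and `#` lines are
#' skipped. Intervals are validated (numeric coordinates, `start < end`,
#' `start >= 0`) with the offending line number in the error message, then
#' converted to a `GRanges` (1-based, closed) sorted within chromosome.
#'
#' @param path BED file path.
#' @return `GRanges` with a `name` metadata column when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(trimws(lines))
  lines <- lines[!skip]; lineno <- lineno[!skip]
  if (!length(lines)) {
    warning("empty BED file: ", path)
    return(GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("line ", lineno[which(nf < 3L)[1]], ": fewer than 3 BED columns")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- is.na(s) | is.na(e) | s < 0 | s >= e
  if (any(bad))
    stop("line ", lineno[which(bad)[1]],
         ": invalid interval (need 0 <= start < end)")
  name <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, character(1)),
    NA_character_)
  str <- vapply(fields, function(f)
    if (length(f) >= 6L && f[[6L]] %in% c("+", "-")) f[[6L]] else "*",
    character(1))
  gr <- GRanges(chrom, IRanges(s + 1, e), strand = str, name = name)
  sort(gr, ignore.strand = TRUE)
}

#' Write intervals to BED (0-based, half-open)
#'
#' @param gr `GRanges`, optionally with a `name` metadata column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  nm <- if ("name" %in% names(mcols(gr))) mcols(gr)$name else NULL
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(nm) && !all(is.na(nm))) df$name <- nm
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Promoter interval set
#'
#' @param x `GRanges` or BED path.
#' @param ids promoter ids (default: `name` column, else `p1..pN`); must be
#'   unique.
#' @return object of class `promoter_set` with `ranges`, `ids`, `n`.
#' @export
promoter_set <- function(x, ids = NULL) {
  gr <- if (is.character(x)) read_bed(x) else x
  if (is.null(ids)) {
    nm <- if ("name" %in% names(mcols(gr))) mcols(gr)$name else NULL
    ids <- if (!is.null(nm) && !anyNA(nm)) nm else paste0("p", seq_along(gr))
  }
  if (length(ids) != length(gr)) stop("ids must match the intervals")
  if (anyDuplicated(ids)) stop("duplicated promoter ids")
  structure(list(ranges = gr, ids = as.character(ids), n = length(gr)),
            class = "promoter_set")
}

#' ChIP-Seq peak set for one transcription factor and tissue class
#'
#' @param x `GRanges` or BED path.
#' @param tf transcription factor label (e.g. `"JUN"`).
#' @param tissue_class tissue/cancer class label; the study classes are
#'   `"not_cancer"`, `"MET"` (solid tumor), `"non_MET"` (leukemia).
#' @return object of class `peak_set` with `ranges`, `tf`, `tissue_class`,
#'   `n_peaks`.
#' @export
peak_set <- function(x, tf = "", tissue_class = "") {
  gr <- if (is.character(x)) read_bed(x) else x
  structure(list(ranges = gr, tf = tf, tissue_class = tissue_class,
                 n_peaks = length(gr)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set [", x$tf, "/", x$tissue_class, "]: ", x$n_peaks, " peaks\n",
      sep = "")
  invisible(x)
}

#' Aggregate per-experiment BED files into one class-level peak set
#'
#' Intervals are concatenated without merging overlapping peaks, so the
#' aggregate peak count is the sum of per-file counts (merging would change
#' the occupancy-rate denominators).
#'
#' @param bed_paths character vector of BED paths (all must exist).
#' @inheritParams peak_set
#' @return [peak_set()].
#' @export
aggregate_peaks <- function(bed_paths, tf = "", tissue_class = "") {
  stopifnot(length(bed_paths) >= 1L)
  missing <- bed_paths[!file.exists(bed_paths)]
  if (length(missing)) stop("missing peak file(s): ",
                            paste(missing, collapse = ", "))
  grs <- lapply(bed_paths, read_bed)
  peak_set(do.call(c, grs), tf = tf, tissue_class = tissue_class)
}

#' All overlapping (promoter, peak) pairs
#'
#' @param promoters a [promoter_set()].
#' @param peaks a [peak_set()].
#' @param min_overlap minimum shared base pairs (default 1).
#' @return data.frame with columns `promoter_id`, `peak_index`.
#' @export
overlap_pairs <- function(promoters, peaks, min_overlap = 1) {
  stopifnot(inherits(promoters, "promoter_set"), inherits(peaks, "peak_set"))
  ov <- findOverlaps(promoters$ranges, peaks$ranges,
                     minoverlap = min_overlap, ignore.strand = TRUE)
  data.frame(promoter_id = promoters$ids[queryHits(ov)],
             peak_index = subjectHits(ov), stringsAsFactors = FALSE)
}

occupancy_result <- function(mode, n_hits, n_peaks) {
  structure(list(mode = mode, n_hits = n_hits, n_peaks = n_peaks,
                 rate = n_hits / n_peaks),
            class = "occupancy_result")
}

#' Occupancy result from pre-computed counts
#'
#' Builds the same result object as [promoter_occupancy()] /
#' [peak_occupancy()] from published or externally computed counts, so that
#' [compare_occupancy()] can be applied to summary tables.
#'
#' @param mode `"promoter"` or `"peak"`.
#' @param n_hits occupied promoters (promoter mode) or overlapping peaks
#'   (peak mode).
#' @param n_peaks total peaks (the rate denominator in both modes).
#' @return `occupancy_result`.
#' @export
occupancy_from_counts <- function(mode = c("promoter", "peak"), n_hits,
                                  n_peaks) {
  mode <- match.arg(mode)
  stopifnot(n_hits >= 0, n_peaks > 0, mode != "peak" || n_hits <= n_peaks)
  occupancy_result(mode, n_hits, n_peaks)
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("%s occupancy: %d / %d peaks (rate %.3f%%)\n",
              x$mode, x$n_hits, x$n_peaks, 100 * x$rate))
  invisible(x)
}

#' Promoter occupancy: promoters overlapped by at least one peak
#'
#' The rate denominator is the total peak count (the study's convention),
#' so the rate is comparable across peak sets of different depth.
#'
#' @inheritParams overlap_pairs
#' @return `occupancy_result` with `mode = "promoter"`, `n_hits`, `n_peaks`,
#'   `rate`.
#' @export
promoter_occupancy <- function(promoters, peaks, min_overlap = 1) {
  stopifnot(inherits(promoters, "promoter_set"), inherits(peaks, "peak_set"))
  if (peaks$n_peaks == 0L) stop("zero peaks: occupancy rate undefined")
  n_hits <- sum(countOverlaps(promoters$ranges, peaks$ranges,
                              minoverlap = min_overlap,
                              ignore.strand = TRUE) > 0L)
  occupancy_result("promoter", n_hits, peaks$n_peaks)
}

#' Peak occupancy: peaks overlapping at least one promoter
#'
#' @inheritParams overlap_pairs
#' @return `occupancy_result` with `mode = "peak"`.
#' @export
peak_occupancy <- function(promoters, peaks, min_overlap = 1) {
  stopifnot(inherits(promoters, "promoter_set"), inherits(peaks, "peak_set"))
  if (peaks$n_peaks == 0L) stop("zero peaks: occupancy rate undefined")
  n_hits <- sum(countOverlaps(peaks$ranges, promoters$ranges,
                              minoverlap = min_overlap,
                              ignore.strand = TRUE) > 0L)
  occupancy_result("peak", n_hits, peaks$n_peaks)
}

#' Compare two occupancy rates
#'
#' Fold change is `test$rate / baseline$rate`; the p-value is a two-sided
#' two-proportion z-test with continuity correction on the (hits, peaks)
#' count pairs.
#'
#' @param baseline,test `occupancy_result` objects of the same mode.
#' @return list with `fold`, `p_value`, `baseline_rate`, `test_rate`.
#' @export
compare_occupancy <- function(baseline, test) {
  stopifnot(inherits(baseline, "occupancy_result"),
            inherits(test, "occupancy_result"))
  if (!identical(baseline$mode, test$mode))
    stop("occupancy results have different modes")
  if (baseline$rate == 0) {
    warning("baseline rate is zero: fold reported as +Inf")
    fold <- Inf
  } else fold <- test$rate / baseline$rate
  p <- prop.test(c(baseline$n_hits, test$n_hits),
                 c(baseline$n_peaks, test$n_peaks))$p.value
  list(fold = fold, p_value = p,
       baseline_rate = baseline$rate, test_rate = test$rate)
}

cooccupancy_result <- function(level, n_only_a, n_only_b, both_expected,
                               both_observed, fold, p_value) {
  structure(list(level = level, n_only_a = n_only_a, n_only_b = n_only_b,
                 both_expected = both_expected, both_observed = both_observed,
                 fold = fold, p_value = p_value),
            class = "cooccupancy_result")
}

#' @export
print.cooccupancy_result <- function(x, ...) {
  cat(sprintf(paste0("%s-level co-occupancy: observed %d, expected %.2f",
                     " (fold %.2f, p %.3g)\n"),
              x$level, x$both_observed, x$both_expected, x$fold, x$p_value))
  invisible(x)
}

#' Promoter-level pair co-occupancy statistics from counts
#'
#' Under independent binding, the expected number of promoters carrying both
#' factors is `n_a * n_b / n_promoters` (the hypergeometric mean). The
#' p-value is Fisher's exact test on the 2x2 classification of promoters
#' (both, a-only, b-only, neither).
#'
#' @param n_a,n_b promoters with at least one peak of each factor.
#' @param n_promoters promoter universe size.
#' @param both_observed promoters with peaks of both factors.
#' @return `cooccupancy_result` with `level = "promoter"`.
#' @export
#' @examples
#' promoter_pair_stats(503, 436, 4102, 228)   # expected 53.46, fold 4.26
promoter_pair_stats <- function(n_a, n_b, n_promoters, both_observed) {
  stopifnot(n_a >= 0, n_b >= 0, n_a <= n_promoters, n_b <= n_promoters,
            both_observed <= min(n_a, n_b),
            n_a + n_b - both_observed <= n_promoters)
  expected <- n_a * n_b / n_promoters
  if (n_a == 0L || n_b == 0L) {
    warning("a factor hits no promoters: fold undefined")
    return(cooccupancy_result("promoter", n_a, n_b, expected, both_observed,
                              NA_real_, NA_real_))
  }
  m <- matrix(c(both_observed, n_a - both_observed,
                n_b - both_observed,
                n_promoters - n_a - n_b + both_observed), nrow = 2L)
  p <- fisher.test(m)$p.value
  cooccupancy_result("promoter", n_a - both_observed, n_b - both_observed,
                     expected, both_observed, both_observed / expected, p)
}

#' Peak-level pair co-occupancy statistics from counts
#'
#' The expectation is `rate_a * rate_b * n_promoters`, with each rate the
#' factor's peak occupancy rate. The p-value is a Poisson test of the
#' observed count against the expectation.
#'
#' @param n_hits_a,n_peaks_a peaks overlapping promoters, and total peaks,
#'   of the first factor.
#' @param n_hits_b,n_peaks_b likewise for the second factor.
#' @param n_promoters promoter universe size.
#' @param both_observed observed pair count (see
#'   [peak_pair_cooccupancy()] for the counting modes).
#' @return `cooccupancy_result` with `level = "peak"`.
#' @export
#' @examples
#' peak_pair_stats(796, 120679, 305, 19030, 4102, 152)  # fold ~ 350.5
peak_pair_stats <- function(n_hits_a, n_peaks_a, n_hits_b, n_peaks_b,
                            n_promoters, both_observed) {
  stopifnot(n_hits_a <= n_peaks_a, n_hits_b <= n_peaks_b, n_promoters > 0)
  rate_a <- n_hits_a / n_peaks_a
  rate_b <- n_hits_b / n_peaks_b
  expected <- rate_a * rate_b * n_promoters
  if (expected == 0) {
    warning("zero expected pair count: fold undefined")
    return(cooccupancy_result("peak", n_hits_a, n_hits_b, expected,
                              both_observed, NA_real_, NA_real_))
  }
  p <- poisson.test(both_observed, expected)$p.value
  cooccupancy_result("peak", n_hits_a, n_hits_b, expected, both_observed,
                     both_observed / expected, p)
}

#' Promoter-level pair co-occupancy from interval sets
#'
#' @param promoters a [promoter_set()].
#' @param peaks_a,peaks_b [peak_set()]s for the two factors.
#' @param min_overlap minimum shared base pairs.
#' @return `cooccupancy_result` (see [promoter_pair_stats()]).
#' @export
promoter_pair_cooccupancy <- function(promoters, peaks_a, peaks_b,
                                      min_overlap = 1) {
  hit_a <- countOverlaps(promoters$ranges, peaks_a$ranges,
                         minoverlap = min_overlap, ignore.strand = TRUE) > 0L
  hit_b <- countOverlaps(promoters$ranges, peaks_b$ranges,
                         minoverlap = min_overlap, ignore.strand = TRUE) > 0L
  promoter_pair_stats(sum(hit_a), sum(hit_b), promoters$n,
                      sum(hit_a & hit_b))
}

#' Peak-level pair co-occupancy from interval sets
#'
#' Two observed-count definitions are available: `"peak_pairs"` (default)
#' counts distinct (peak_a, peak_b) pairs that overlap a common promoter;
#' `"peaks_in_shared_promoters"` counts peaks from either factor lying in
#' promoters occupied by both.
#'
#' @inheritParams promoter_pair_cooccupancy
#' @param both_observed_mode observed-count definition (see above).
#' @return `cooccupancy_result` (see [peak_pair_stats()]).
#' @export
peak_pair_cooccupancy <- function(promoters, peaks_a, peaks_b,
                                  both_observed_mode = c(
                                    "peak_pairs", "peaks_in_shared_promoters"),
                                  min_overlap = 1) {
  both_observed_mode <- match.arg(both_observed_mode)
  ov_a <- overlap_pairs(promoters, peaks_a, min_overlap)
  ov_b <- overlap_pairs(promoters, peaks_b, min_overlap)
  n_hits_a <- length(unique(ov_a$peak_index))
  n_hits_b <- length(unique(ov_b$peak_index))
  if (both_observed_mode == "peak_pairs") {
    j <- merge(ov_a, ov_b, by = "promoter_id")
    both <- nrow(unique(j[, c("peak_index.x", "peak_index.y")]))
  } else {
    shared <- intersect(ov_a$promoter_id, ov_b$promoter_id)
    both <- length(unique(ov_a$peak_index[ov_a$promoter_id %in% shared])) +
      length(unique(ov_b$peak_index[ov_b$promoter_id %in% shared]))
  }
  peak_pair_stats(n_hits_a, peaks_a$n_peaks, n_hits_b, peaks_b$n_peaks,
                  promoters$n, both)
}
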