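# Motif over-representation and motif-pair enrichment.
#
# Motif families (V$AP1F, V$EBOX, ...) are opaque labels; hit matrices record
# whether a promoter carries at least one match for a family. Background
# proportions (genome-wide fraction of promoters with a match) are inputs.
# The pair expectation under independent placement is the product of the two
# single-motif fold enrichments.

#' Read position weight matrices in JASPAR-style format
#'
#' Parses `>name` headers followed by four rows `A [ n n ... ]` (or bare
#' counts) in A, C, G, T order. Counts are converted to per-column
#' frequencies with an optional pseudocount.
#'
#' @param path file path.
#' @param pseudocount added to every count before normalization (default 0.5).
#' @return named list of 4 x L probability matrices (rows A, C, G, T; columns
#'   sum to 1).
#' @export
read_pwm_jaspar <- function(path, pseudocount = 0.5) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' headers found in ", path)
  out <- list()
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    to <- if (i < length(heads)) heads[i + 1] - 1L else length(lines)
    rows <- lines[(heads[i] + 1L):to]
    if (length(rows) < 4L) stop("PWM '", name, "' needs 4 base rows")
    parsed <- lapply(rows[1:4], function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", r)
      r <- gsub("[][]", " ", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    if (length(unique(lengths(parsed))) != 1L)
      stop("PWM '", name, "' has ragged base rows")
    counts <- do.call(rbind, parsed) + pseudocount
    pwm <- sweep(counts, 2L, colSums(counts), "/")
    rownames(pwm) <- c("A", "C", "G", "T")
    out[[name]] <- pwm
  }
  out
}

.revcomp_pwm <- function(pwm) {
  out <- pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

.score_strand <- function(idx, lod, n_pos) {
  # idx: base index per position (NA for N); lod: 4 x L log-odds matrix.
  L <- ncol(lod)
  scores <- numeric(n_pos)
  for (j in seq_len(L)) {
    col <- lod[, j]
    v <- col[idx[j:(j + n_pos - 1L)]]
    v[is.na(v)] <- 0  # N contributes zero log-odds
    scores <- scores + v
  }
  scores
}

#' Scan a sequence with a position weight matrix
#'
#' Scores every window on both strands with the log2-odds of the PWM against
#' a uniform background (0.25 per base); `N` bases contribute zero log-odds.
#' Positions are 1-based window starts on the given (forward) sequence;
#' minus-strand hits are scored with the reverse-complement matrix at the
#' same forward coordinates.
#'
#' @param sequence nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param pwm 4 x L probability matrix, rows named A, C, G, T, columns
#'   summing to 1 (tolerance 1e-9).
#' @param threshold minimum log2-odds score for a reported hit.
#' @return data.frame with columns `position`, `strand`, `score`, ordered by
#'   position.
#' @export
scan_pwm <- function(sequence, pwm, threshold) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!all(rownames(pwm) == c("A", "C", "G", "T")))
    stop("pwm rows must be named A, C, G, T")
  if (any(abs(colSums(pwm) - 1) > 1e-9))
    stop("pwm columns must sum to 1")
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("sequence must be over the A, C, G, T, N alphabet")
  L <- ncol(pwm)
  n_pos <- length(chars) - L + 1L
  if (n_pos < 1L)
    return(data.frame(position = integer(0), strand = character(0),
                      score = numeric(0)))
  idx <- match(chars, c("A", "C", "G", "T"))
  lod <- log2(pwm / 0.25)
  res <- list()
  for (s in c("+", "-")) {
    m <- if (s == "+") lod else log2(.revcomp_pwm(pwm) / 0.25)
    sc <- .score_strand(idx, m, n_pos)
    keep <- which(sc >= threshold)
    if (length(keep))
      res[[s]] <- data.frame(position = keep, strand = s, score = sc[keep],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(position = integer(0), strand = character(0),
                      score = numeric(0)))
  rownames(out) <- NULL
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Construct a promoter-by-motif hit matrix
#'
#' @param hits logical or 0/1 matrix, promoters x motif families; row names
#'   are promoter ids, column names motif labels.
#' @return object of class `motif_hit_matrix`.
#' @export
motif_hit_matrix <- function(hits) {
  hits <- as.matrix(hits)
  storage.mode(hits) <- "logical"
  if (is.null(rownames(hits)) || is.null(colnames(hits)))
    stop("hit matrix needs promoter row names and motif column names")
  structure(list(promoters = rownames(hits), motifs = colnames(hits),
                 hits = hits),
            class = "motif_hit_matrix")
}

#' Read / write a motif hit matrix as TSV (first column `promoter`)
#'
#' @param path TSV file path.
#' @return `motif_hit_matrix` (reader); `path` invisibly (writer).
#' @export
read_motif_hits <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(names(df)[1] == "promoter")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$promoter
  motif_hit_matrix(m)
}

#' @rdname read_motif_hits
#' @param matrix a `motif_hit_matrix`.
#' @export
write_motif_hits <- function(matrix, path) {
  df <- data.frame(promoter = matrix$promoters, matrix$hits + 0L,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Motif background proportions
#'
#' @param singles named numeric vector, motif -> genome-wide proportion of
#'   promoters with at least one match.
#' @param pairs optional named numeric vector, `"A|B"` (labels sorted) ->
#'   genome-wide pair proportion.
#' @return object of class `motif_background`.
#' @export
motif_background <- function(singles, pairs = NULL) {
  stopifnot(all(singles >= 0 & singles <= 1))
  if (!is.null(pairs)) stopifnot(all(pairs >= 0 & pairs <= 1))
  structure(list(singles = singles, pairs = pairs),
            class = "motif_background")
}

#' Read a motif background from YAML (`singles:` and optional `pairs:` maps)
#'
#' @param path YAML file path.
#' @return [motif_background()].
#' @export
read_motif_background <- function(path) {
  cfg <- yaml::read_yaml(path)
  motif_background(unlist(cfg$singles),
                   if (!is.null(cfg$pairs)) unlist(cfg$pairs))
}

.pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Single-motif over-representation against a background proportion
#'
#' Fold enrichment is the observed proportion of promoters carrying the
#' motif over the genome-wide expected proportion; the p-value is a
#' two-sided exact binomial test of `n_with` out of `n_total` at
#' `expected_prop`.
#'
#' @param n_with promoters with at least one match.
#' @param n_total promoters tested.
#' @param expected_prop genome-wide background proportion, in (0, 1).
#' @param motif optional label.
#' @return [enrichment_result()] with `method = "binomial"`.
#' @export
#' @examples
#' single_motif_enrichment(2386, 4102, 0.498)   # fold ~ 1.168
single_motif_enrichment <- function(n_with, n_total, expected_prop,
                                    motif = NA) {
  stopifnot(n_with >= 0, n_with <= n_total)
  if (expected_prop <= 0 || expected_prop >= 1)
    stop("expected_prop must be strictly inside (0, 1)")
  bt <- binom.test(n_with, n_total, expected_prop)
  res <- enrichment_result(motif, n_with, n_total,
                           k_bg = NA_integer_, n_bg = NA_integer_,
                           statistic = unname(bt$statistic),
                           p_value = bt$p.value, method = "binomial")
  res$prop_bg <- expected_prop
  res$fold <- (n_with / n_total) / expected_prop
  res
}

#' Expected pair enrichment under independent motif placement
#'
#' If two motifs fall on promoters independently, the fold enrichment of the
#' pair equals the product of the single-motif fold enrichments.
#'
#' @param fold_i,fold_j single-motif fold enrichments (positive).
#' @return the product (full precision; round to 2 decimals for reporting).
#' @export
#' @examples
#' pair_expected_enrichment(0.995, 1.074)   # 1.07 at 2 decimals
pair_expected_enrichment <- function(fold_i, fold_j) {
  stopifnot(fold_i > 0, fold_j > 0)
  fold_i * fold_j
}

#' Motif-pair enrichment test
#'
#' Counts promoters carrying both motifs, compares the observed pair
#' proportion to the genome-wide background pair proportion
#' (observed enrichment), derives the independence expectation as the
#' product of single-motif folds, and tests the observed pair count against
#' the background-expected count with a 1-df chi-square on
#' (with-pair, without-pair).
#'
#' @param matrix a [motif_hit_matrix()].
#' @param background a [motif_background()]; singles are required for both
#'   motifs, the pair proportion may be missing (counts-only result, with a
#'   warning).
#' @param motif_i,motif_j motif labels.
#' @return data.frame of class `pair_enrichment` with columns `motif_i`,
#'   `motif_j`, `n_pair_obs`, `n_total`, `fold_i`, `fold_j`,
#'   `observed_enrichment`, `expected_enrichment`, `difference`,
#'   `statistic`, `p_value`.
#' @export
pair_enrichment_test <- function(matrix, background, motif_i, motif_j) {
  stopifnot(inherits(matrix, "motif_hit_matrix"),
            inherits(background, "motif_background"))
  for (m in c(motif_i, motif_j)) {
    if (!m %in% matrix$motifs) stop("motif not in hit matrix: ", m)
    if (!m %in% names(background$singles))
      stop("motif not in background: ", m)
  }
  n_total <- length(matrix$promoters)
  hi <- matrix$hits[, motif_i]; hj <- matrix$hits[, motif_j]
  n_pair <- sum(hi & hj)
  fold_i <- mean(hi) / background$singles[[motif_i]]
  fold_j <- mean(hj) / background$singles[[motif_j]]
  expected <- pair_expected_enrichment(fold_i, fold_j)
  key <- .pair_key(motif_i, motif_j)
  bg_pair <- if (!is.null(background$pairs)) background$pairs[[key]] else NULL
  if (is.null(bg_pair) || is.na(bg_pair)) {
    warning("no background pair proportion for ", key,
            ": reporting counts only")
    observed <- NA_real_; difference <- NA_real_
    statistic <- NA_real_; p_value <- NA_real_
  } else {
    observed <- if (bg_pair > 0) (n_pair / n_total) / bg_pair else
      if (n_pair == 0) 0 else Inf
    difference <- observed - expected
    ct <- suppressWarnings(
      chisq.test(c(n_pair, n_total - n_pair), p = c(bg_pair, 1 - bg_pair)))
    statistic <- unname(ct$statistic); p_value <- ct$p.value
  }
  structure(
    data.frame(motif_i = motif_i, motif_j = motif_j, n_pair_obs = n_pair,
               n_total = n_total, fold_i = fold_i, fold_j = fold_j,
               observed_enrichment = observed,
               expected_enrichment = expected, difference = difference,
               statistic = statistic, p_value = p_value,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("pair_enrichment", "data.frame"))
}

#' All-pairs motif enrichment table
#'
#' Runs [pair_enrichment_test()] for every motif pair in the matrix and
#' returns rows ordered by decreasing observed-minus-expected difference.
#'
#' @inheritParams pair_enrichment_test
#' @return data.frame, one row per unordered pair.
#' @export
motif_pair_table <- function(matrix, background) {
  combos <- combn(matrix$motifs, 2L)
  rows <- lapply(seq_len(ncol(combos)), function(k)
    pair_enrichment_test(matrix, background, combos[1, k], combos[2, k]))
  out <- do.call(rbind, rows)
  out[order(-out$difference), , drop = FALSE]
}
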