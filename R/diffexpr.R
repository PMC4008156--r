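# Differential-expression ingestion and signature construction.
#
# Records follow the CuffDiff summary layout: one feature (gene or isoform)
# per condition with a linear fold change (treated/control), a
# Benjamini-Hochberg FDR and a test status flag. Fold changes are linear
# ratios; log2 inputs are converted on ingestion and clamped to [0, 10],
# matching the reporting caps used for ratios with zero numerators or
# denominators.

OIMET_TREATMENTS <- c("OVOL1", "OVOL2", "OVOL1and2")
OIMET_MODELS <- c("BC", "PC")

#' Convert log2 fold changes to clamped linear ratios
#'
#' @param log2fc numeric vector of log2 fold changes; `-Inf`/`Inf` map to the
#'   clamp bounds.
#' @param cap length-2 numeric, reporting clamp for the linear ratio.
#' @return numeric vector of linear ratios in `[cap[1], cap[2]]`.
#' @export
fold_from_log2 <- function(log2fc, cap = c(0, 10)) {
  stopifnot(is.numeric(log2fc), length(cap) == 2L, cap[1] < cap[2])
  pmin(pmax(2^log2fc, cap[1]), cap[2])
}

#' Validate a table of differential-expression records
#'
#' Checks the invariants of the record type: non-negative fold change, FDR in
#' \[0, 1\], and a non-empty gene symbol on isoform-level records. The error
#' message names the offending feature ids.
#'
#' @param records data.frame with columns `feature_id`, `level`
#'   (`"gene"`/`"isoform"`), `gene_symbol`, `model`, `treatment`,
#'   `fold_change`, `fdr`, `status`.
#' @return `records`, invisibly, if valid.
#' @export
validate_diffexpr <- function(records) {
  need <- c("feature_id", "level", "gene_symbol", "model", "treatment",
            "fold_change", "fdr", "status")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  bad_fc <- !is.na(records$fold_change) & records$fold_change < 0
  if (any(bad_fc))
    stop("negative fold_change for feature(s): ",
         paste(head(records$feature_id[bad_fc], 5L), collapse = ", "))
  bad_fdr <- !is.na(records$fdr) & (records$fdr < 0 | records$fdr > 1)
  if (any(bad_fdr))
    stop("fdr outside [0, 1] for feature(s): ",
         paste(head(records$feature_id[bad_fdr], 5L), collapse = ", "))
  iso <- records$level == "isoform"
  bad_sym <- iso & (is.na(records$gene_symbol) | !nzchar(records$gene_symbol))
  if (any(bad_sym))
    stop("isoform record without gene_symbol: ",
         paste(head(records$feature_id[bad_sym], 5L), collapse = ", "))
  bad_level <- !records$level %in% c("gene", "isoform")
  if (any(bad_level))
    stop("level must be 'gene' or 'isoform' for feature(s): ",
         paste(head(records$feature_id[bad_level], 5L), collapse = ", "))
  invisible(records)
}

#' Read a differential-expression table
#'
#' Reads a TSV in the package's record layout, or a CuffDiff-style dialect via
#' `column_map` (a named character vector mapping standard names to the file's
#' column names). Log2 fold changes are converted to clamped linear ratios
#' when `log2_fold = TRUE` or when the mapped fold column is named `log2fc`.
#'
#' @param path TSV file path.
#' @param column_map optional named character vector, e.g.
#'   `c(feature_id = "test_id", gene_symbol = "gene", fold_change = "log2fc")`.
#' @param log2_fold logical; treat the fold column as log2.
#' @param fc_cap clamp bounds for linear ratios (see [fold_from_log2()]).
#' @return validated data.frame of records.
#' @export
read_diffexpr <- function(path, column_map = NULL, log2_fold = FALSE,
                          fc_cap = c(0, 10)) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(df))
        stop("mapped column '", src, "' not found in ", path)
      df[[std]] <- df[[src]]
    }
    if (identical(column_map[["fold_change"]], "log2fc")) log2_fold <- TRUE
  }
  if (!"fold_change" %in% names(df) && "log2fc" %in% names(df)) {
    df$fold_change <- df$log2fc
    log2_fold <- TRUE
  }
  if (log2_fold) df$fold_change <- fold_from_log2(df$fold_change, fc_cap)
  validate_diffexpr(df)
  df
}

#' Select differentially expressed features
#'
#' Applies the three selection clauses jointly: required test status, FDR at
#' or below `fdr_max`, and fold change at or beyond the two-sided band
#' (`>= fc_high` or `<= fc_low`). Ties at thresholds are inclusive.
#'
#' @param records validated record data.frame.
#' @param fdr_max maximum FDR (default 0.05).
#' @param fc_high upper linear fold-change threshold (default 2.0).
#' @param fc_low lower linear fold-change threshold (default 0.5).
#' @param status_required required test status string (default `"OK"`).
#' @param level optional; restrict to `"gene"` or `"isoform"` records.
#' @return character vector of selected feature ids (empty if none).
#' @export
select_de_features <- function(records, fdr_max = 0.05, fc_high = 2.0,
                               fc_low = 0.5, status_required = "OK",
                               level = NULL) {
  stopifnot(fdr_max > 0, fc_high > 0, fc_low > 0, fc_low < 1, fc_high > 1)
  if (nrow(records) == 0L) return(character(0))
  validate_diffexpr(records)
  if (!is.null(level)) records <- records[records$level == level, , drop = FALSE]
  keep <- records$status == status_required &
    records$fdr <= fdr_max &
    (records$fold_change >= fc_high | records$fold_change <= fc_low)
  keep[is.na(keep)] <- FALSE
  unique(records$feature_id[keep])
}

#' Construct a per-model expression signature
#'
#' The signature is the union over the three treatments (OVOL1, OVOL2, both)
#' of the gene symbols mapped from the selected feature ids: a gene enters the
#' signature if it responded to at least one treatment.
#'
#' @param per_treatment_sets named list of three character vectors of feature
#'   ids, keyed by treatment.
#' @param gene_map named character vector, feature id -> gene symbol.
#' @param model label for the model (e.g. `"BC"`).
#' @param thresholds optional list recording the selection thresholds used.
#' @return object of class `signature_set` with elements `model`, `genes`,
#'   `thresholds`.
#' @export
build_model_signature <- function(per_treatment_sets, gene_map, model = "",
                                  thresholds = NULL) {
  stopifnot(is.list(per_treatment_sets), length(per_treatment_sets) == 3L)
  feats <- unique(unlist(per_treatment_sets, use.names = FALSE))
  unmapped <- setdiff(feats, names(gene_map))
  if (length(unmapped))
    stop("feature(s) with no gene mapping: ",
         paste(head(unmapped, 5L), collapse = ", "))
  structure(
    list(model = model,
         genes = sort(unique(unname(gene_map[feats]))),
         thresholds = thresholds),
    class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set [", x$model, "]: ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Intersect two model signatures and score cross-model concordance
#'
#' The cross-model signature is the intersection of the two gene sets.
#' Concordance is the proportion of intersection genes moving in the same
#' direction (both fold changes above 1, or both below 1) under the combined
#' OVOL1-and-OVOL2 treatment; genes with a missing fold pair are excluded
#' from the denominator and counted.
#'
#' @param sig_a,sig_b `signature_set` objects.
#' @param ovol12_folds data.frame with columns `gene`, `fc_a`, `fc_b`
#'   (combined-treatment linear fold changes in the two models), or `NULL`
#'   to skip concordance.
#' @return object of class `intersection_signature` with elements `genes`,
#'   `concordance_fraction`, `n_concordant`, `n_with_folds`,
#'   `n_missing_folds`.
#' @export
intersect_signatures <- function(sig_a, sig_b, ovol12_folds = NULL) {
  stopifnot(inherits(sig_a, "signature_set"), inherits(sig_b, "signature_set"))
  genes <- sort(intersect(sig_a$genes, sig_b$genes))
  conc <- NA_real_; n_conc <- NA_integer_
  n_with <- 0L; n_missing <- length(genes)
  if (!is.null(ovol12_folds) && length(genes)) {
    stopifnot(all(c("gene", "fc_a", "fc_b") %in% names(ovol12_folds)))
    ff <- ovol12_folds[match(genes, ovol12_folds$gene), , drop = FALSE]
    have <- !is.na(ff$fc_a) & !is.na(ff$fc_b)
    n_with <- sum(have)
    n_missing <- length(genes) - n_with
    if (n_missing > 0L)
      message(n_missing, " intersection gene(s) without a complete fold pair",
              " excluded from the concordance denominator")
    if (n_with > 0L) {
      same <- (ff$fc_a[have] > 1 & ff$fc_b[have] > 1) |
              (ff$fc_a[have] < 1 & ff$fc_b[have] < 1)
      n_conc <- sum(same)
      conc <- n_conc / n_with
    }
  }
  structure(
    list(genes = genes, concordance_fraction = conc, n_concordant = n_conc,
         n_with_folds = n_with, n_missing_folds = n_missing),
    class = "intersection_signature")
}

#' @export
print.intersection_signature <- function(x, ...) {
  cat("intersection_signature: ", length(x$genes), " genes",
      if (!is.na(x$concordance_fraction))
        sprintf("; concordance %.1f%% (%d/%d)", 100 * x$concordance_fraction,
                x$n_concordant, x$n_with_folds),
      "\n", sep = "")
  invisible(x)
}

#' Run the two-model signature pipeline on record tables
#'
#' Convenience wrapper: selects gene-level DE features per treatment in each
#' model, builds the two model signatures, and intersects them using the
#' combined-treatment gene-level fold changes.
#'
#' @param records_a,records_b record data.frames for the two models.
#' @param models length-2 character, labels for the two models.
#' @inheritParams select_de_features
#' @return list with `sig_a`, `sig_b`, `intersection`.
#' @export
signature_pipeline <- function(records_a, records_b, models = c("BC", "PC"),
                               fdr_max = 0.05, fc_high = 2.0, fc_low = 0.5,
                               status_required = "OK") {
  thresholds <- list(fdr_max = fdr_max, fc_high = fc_high, fc_low = fc_low,
                     status_required = status_required)
  one <- function(records, model) {
    g <- records[records$level == "gene", , drop = FALSE]
    sets <- lapply(setNames(OIMET_TREATMENTS, OIMET_TREATMENTS), function(tr)
      select_de_features(g[g$treatment == tr, , drop = FALSE],
                         fdr_max, fc_high, fc_low, status_required))
    gmap <- setNames(g$gene_symbol, g$feature_id)
    build_model_signature(sets, gmap, model = model, thresholds = thresholds)
  }
  sig_a <- one(records_a, models[1]); sig_b <- one(records_b, models[2])
  folds12 <- function(records) {
    g <- records[records$level == "gene" &
                   records$treatment == "OVOL1and2", , drop = FALSE]
    setNames(g$fold_change, g$gene_symbol)
  }
  fa <- folds12(records_a); fb <- folds12(records_b)
  genes <- intersect(sig_a$genes, sig_b$genes)
  ff <- data.frame(gene = genes,
                   fc_a = unname(fa[genes]), fc_b = unname(fb[genes]),
                   stringsAsFactors = FALSE)
  list(sig_a = sig_a, sig_b = sig_b,
       intersection = intersect_signatures(sig_a, sig_b, ff))
}

#' Write the cross-model signature table
#'
#' @param pipeline result of [signature_pipeline()].
#' @param records_a,records_b the record tables the pipeline was run on
#'   (used to recover combined-treatment folds).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_signature_table <- function(pipeline, records_a, records_b, path) {
  folds12 <- function(records) {
    g <- records[records$level == "gene" &
                   records$treatment == "OVOL1and2", , drop = FALSE]
    setNames(g$fold_change, g$gene_symbol)
  }
  fa <- folds12(records_a); fb <- folds12(records_b)
  genes <- sort(union(pipeline$sig_a$genes, pipeline$sig_b$genes))
  in_int <- genes %in% pipeline$intersection$genes
  fca <- unname(fa[genes]); fcb <- unname(fb[genes])
  out <- data.frame(
    gene = genes,
    in_a = genes %in% pipeline$sig_a$genes,
    in_b = genes %in% pipeline$sig_b$genes,
    in_intersection = in_int,
    fc_a_ovol12 = fca, fc_b_ovol12 = fcb,
    concordant = in_int & !is.na(fca) & !is.na(fcb) &
      ((fca > 1 & fcb > 1) | (fca < 1 & fcb < 1)),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
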