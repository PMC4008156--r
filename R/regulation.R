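# Regulation pattern calling: up, down, up/down, and isoform switch.
#
# Calls use the relaxed reporting thresholds (>= 1.5 up, <= 0.67 down) rather
# than the signature selection thresholds, and are made from linear fold
# changes observed across the three OVOL treatments.

#' Call the regulation pattern for one feature
#'
#' `Up` if at least one observation is at or above `up_threshold` and none is
#' at or below `down_threshold`; `Down` for the converse; `UpDown` if both
#' rules fire; `none` otherwise. `NA` observations are ignored.
#'
#' @param folds numeric vector of linear fold changes (one per treatment).
#' @param up_threshold fold at or above which an observation counts as up.
#' @param down_threshold fold at or below which an observation counts as down.
#' @return one of `"Up"`, `"Down"`, `"UpDown"`, `"none"`.
#' @export
#' @examples
#' call_regulation(c(1.5, 2.2, 2.1))   # "Up"
#' call_regulation(c(0.0, 0.4, 6.3))   # "UpDown"
call_regulation <- function(folds, up_threshold = 1.5, down_threshold = 0.67) {
  folds <- folds[!is.na(folds)]
  if (!length(folds)) stop("at least one fold observation required")
  if (any(folds < 0)) stop("negative fold change")
  up <- any(folds >= up_threshold)
  down <- any(folds <= down_threshold)
  if (up && down) "UpDown" else if (up) "Up" else if (down) "Down" else "none"
}

#' Call an isoform switch for one gene
#'
#' A switch requires, within a single treatment, one isoform at or above
#' `up_threshold` while a different isoform of the same gene is at or below
#' `down_threshold`. Genes with a single isoform never switch.
#'
#' @param isoform_folds matrix (rows = isoforms, columns = treatments) or list
#'   of per-isoform numeric vectors of equal length.
#' @inheritParams call_regulation
#' @return `"Switch"` or `"none"`.
#' @export
#' @examples
#' call_isoform_switch(rbind(c(10, 10, 10), c(0.7, 0.5, 0.4)))  # "Switch"
call_isoform_switch <- function(isoform_folds, up_threshold = 1.5,
                                down_threshold = 0.67) {
  if (is.list(isoform_folds)) isoform_folds <- do.call(rbind, isoform_folds)
  if (!is.matrix(isoform_folds)) isoform_folds <- matrix(isoform_folds, nrow = 1L)
  if (any(isoform_folds < 0, na.rm = TRUE)) stop("negative fold change")
  if (nrow(isoform_folds) < 2L) return("none")
  for (t in seq_len(ncol(isoform_folds))) {
    col <- isoform_folds[, t]
    if (any(col >= up_threshold, na.rm = TRUE) &&
        any(col <= down_threshold, na.rm = TRUE))
      return("Switch")
  }
  "none"
}

#' Call regulation patterns over a fold-change table
#'
#' Applies [call_regulation()] to every row of a wide per-treatment fold
#' table and [call_isoform_switch()] to every gene x model group of isoform
#' rows. Per-row calls and gene-level switch flags are reported separately;
#' a row's call never overrides the gene's switch flag.
#'
#' @param folds data.frame with columns `gene`, `feature_id`, `level`
#'   (`"gene"`/`"isoform"`), `model`, and fold columns `fc_ovol1`,
#'   `fc_ovol2`, `fc_ovol12`.
#' @inheritParams call_regulation
#' @return list with `calls` (the input plus a `call` column) and `switches`
#'   (data.frame `gene`, `model`, `switch`).
#' @export
regulation_calls <- function(folds, up_threshold = 1.5, down_threshold = 0.67) {
  fc_cols <- c("fc_ovol1", "fc_ovol2", "fc_ovol12")
  stopifnot(all(c("gene", "feature_id", "level", "model", fc_cols) %in%
                  names(folds)))
  fm <- as.matrix(folds[, fc_cols])
  folds$call <- vapply(seq_len(nrow(folds)), function(i)
    call_regulation(fm[i, ], up_threshold, down_threshold), character(1))
  iso <- folds[folds$level == "isoform", , drop = FALSE]
  key <- unique(iso[, c("gene", "model")])
  key$switch <- vapply(seq_len(nrow(key)), function(i) {
    rows <- iso$gene == key$gene[i] & iso$model == key$model[i]
    call_isoform_switch(as.matrix(iso[rows, fc_cols]),
                        up_threshold, down_threshold)
  }, character(1))
  list(calls = folds, switches = key)
}

#' Write a regulation-calls table
#'
#' @param calls result of [regulation_calls()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_regulation_calls <- function(calls, path) {
  out <- calls$calls[, c("gene", "model", "level", "feature_id", "call")]
  sw <- calls$switches
  out$switch <- sw$switch[match(paste(out$gene, out$model),
                                paste(sw$gene, sw$model))]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
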