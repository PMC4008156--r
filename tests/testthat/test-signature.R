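rec <- function(fc, fdr, status = "OK", id = "f1", level = "gene",
                gene = "G", model = "BC", treatment = "OVOL1and2") {
  data.frame(feature_id = id, level = level, gene_symbol = gene,
             model = model, treatment = treatment, fold_change = fc,
             fdr = fdr, status = status, stringsAsFactors = FALSE)
}

test_that("selection applies status, FDR and fold-band clauses jointly and inclusively", {
  expect_equal(select_de_features(rec(2.5, 0.01)), "f1")
  expect_equal(select_de_features(rec(1.9, 0.01)), character(0))
  expect_equal(select_de_features(rec(0.4, 0.01)), "f1")
  # ties at thresholds are inclusive
  expect_equal(select_de_features(rec(2.0, 0.05)), "f1")
  expect_equal(select_de_features(rec(0.5, 0.05)), "f1")
  # any failing clause excludes
  expect_equal(select_de_features(rec(2.5, 0.06)), character(0))
  expect_equal(select_de_features(rec(2.5, 0.01, status = "NOTEST")),
               character(0))
  expect_equal(select_de_features(rec(2.5, 0.01)[0, ]), character(0))
})

test_that("malformed records are rejected with the offending feature named", {
  expect_error(select_de_features(rec(-1, 0.01)), "f1")
  expect_error(select_de_features(rec(2.5, 1.2)), "f1")
  expect_error(validate_diffexpr(rec(2, 0.1, level = "isoform", gene = "")),
               "gene_symbol")
})

test_that("selection is monotone in the thresholds", {
  set.seed(42)
  n <- 200
  recs <- data.frame(feature_id = paste0("f", 1:n), level = "gene",
                     gene_symbol = paste0("g", 1:n), model = "BC",
                     treatment = "OVOL1", fold_change = 2^runif(n, -3, 3),
                     fdr = runif(n), status = "OK", stringsAsFactors = FALSE)
  base <- select_de_features(recs, 0.05, 2.0, 0.5)
  for (i in 1:20) {
    fdr_max <- runif(1, 0.001, 0.05)
    fc_high <- runif(1, 2.0, 6.0)
    fc_low <- runif(1, 0.05, 0.5)
    tighter <- select_de_features(recs, fdr_max, fc_high, fc_low)
    expect_true(all(tighter %in% base))
  }
})

test_that("model signature is the union of treatment responders, mapped to genes", {
  gmap <- c(fA = "A", fB = "B", fC = "C", fD = "D")
  sig <- build_model_signature(list(OVOL1 = c("fA", "fB"),
                                    OVOL2 = c("fB", "fC"),
                                    OVOL1and2 = c("fC", "fD")),
                               gmap, model = "BC")
  expect_equal(sig$genes, c("A", "B", "C", "D"))
  expect_error(build_model_signature(list(OVOL1 = "fX", OVOL2 = character(0),
                                          OVOL1and2 = character(0)), gmap),
               "fX")
})

test_that("intersection and concordance follow the fold-pair sign rule", {
  sa <- build_model_signature(list(OVOL1 = c("a", "b"), OVOL2 = "c",
                                   OVOL1and2 = character(0)),
                              c(a = "A", b = "B", c = "C"), "BC")
  sb <- build_model_signature(list(OVOL1 = c("b", "c"), OVOL2 = "d",
                                   OVOL1and2 = character(0)),
                              c(b = "B", c = "C", d = "D"), "PC")
  folds <- data.frame(gene = c("B", "C"), fc_a = c(2.0, 0.5),
                      fc_b = c(3.0, 2.0))
  int <- intersect_signatures(sa, sb, folds)
  expect_equal(int$genes, c("B", "C"))
  # B concordant (both up), C not (down vs up)
  expect_equal(int$concordance_fraction, 0.5)
  # intersection always contained in both inputs
  expect_true(all(int$genes %in% sa$genes) && all(int$genes %in% sb$genes))
})

test_that("planted DE structure is recovered exactly from synthetic tables", {
  ex <- gen_expression(small_config(3))
  pl <- signature_pipeline(ex$bc, ex$pc)
  expect_identical(pl$sig_a$genes, ex$truth$de_genes$BC)
  expect_identical(pl$sig_b$genes, ex$truth$de_genes$PC)
  expect_identical(pl$intersection$genes, ex$truth$shared_genes)
  expect_equal(pl$intersection$concordance_fraction,
               length(ex$truth$concordant_genes) /
                 length(ex$truth$shared_genes))
  # per-treatment responders recovered from gene-level records
  g <- ex$bc[ex$bc$level == "gene" & ex$bc$treatment == "OVOL1", ]
  expect_identical(sort(select_de_features(g)),
                   ex$truth$responders$BC$OVOL1)
  # planted concordance is inside the binomial 95% CI of its target
  n <- length(ex$truth$shared_genes)
  ci <- binom.test(length(ex$truth$concordant_genes), n, 0.7)$conf.int
  expect_true(ci[1] <= 0.7 && 0.7 <= ci[2])
})

test_that("regulation calls reproduce the canonical fold patterns", {
  expect_equal(call_regulation(c(1.5, 2.2, 2.1)), "Up")
  expect_equal(call_regulation(c(0.7, 0.7, 0.6)), "Down")
  expect_equal(call_regulation(c(1.4, 1.4, 1.4)), "none")
  expect_equal(call_regulation(c(0.0, 0.4, 6.3)), "UpDown")
  expect_equal(call_regulation(c(0.67, 1.5)), "UpDown")  # inclusive ties
  expect_error(call_regulation(c(-0.5, 1)), "negative")
  expect_error(call_regulation(numeric(0)))
})

test_that("isoform switch needs opposite regulation of two isoforms in one treatment", {
  expect_equal(call_isoform_switch(rbind(c(10, 10, 10), c(0.7, 0.5, 0.4))),
               "Switch")
  # up and down observations in different treatments only: no switch
  expect_equal(call_isoform_switch(rbind(c(1.1, 1.4, 1.9),
                                         c(0.8, 1.7, 2.2))), "none")
  expect_equal(call_isoform_switch(rbind(c(0.2, 5.0, 1.0))), "none")
  expect_equal(call_isoform_switch(list(c(2.6, 0.0, 0.0),
                                        c(0.9, 2.3, 1.1))), "Switch")
})

test_that("a switch implies the pooled observations carry both an up and a down", {
  set.seed(9)
  for (i in 1:50) {
    m <- matrix(2^runif(6, -2, 2), nrow = 2)
    if (call_isoform_switch(m) == "Switch")
      expect_equal(call_regulation(as.vector(m)), "UpDown")
  }
})

test_that("regulation_calls separates per-row calls from gene switch flags", {
  folds <- data.frame(
    gene = c("X", "X", "X", "Y"),
    feature_id = c("X", "X.1", "X.2", "Y"),
    level = c("gene", "isoform", "isoform", "gene"),
    model = "BC",
    fc_ovol1 = c(1.2, 2.0, 0.5, 1.0),
    fc_ovol2 = c(1.0, 2.2, 0.6, 1.0),
    fc_ovol12 = c(1.1, 1.8, 0.4, 1.0),
    stringsAsFactors = FALSE)
  out <- regulation_calls(folds)
  expect_equal(out$calls$call, c("none", "Up", "Down", "none"))
  expect_equal(out$switches$switch[out$switches$gene == "X"], "Switch")
})

test_that("log2 ingestion clamps ratios to the reporting caps", {
  expect_equal(fold_from_log2(c(-Inf, 0, 1, 10)), c(0, 1, 2, 10))
})
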