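# oimet

Expression signatures and regulatory enrichment for OVOL-induced
mesenchymal-to-epithelial transition (OI-MET).

The OVOL transcription factors (OVOL1/OVOL2) drive mesenchymal-to-epithelial
transition — the phenotype switch that lets disseminated tumor cells
re-epithelialize at metastatic sites — in both breast-cancer and
prostate-cancer models. Characterizing that system computationally requires a
chain of bespoke statistics that standard differential-expression or peak
callers do not provide: cross-model signature intersection with directional
concordance, gene/isoform regulation-pattern calls, literature co-occurrence
enrichment with a resampling null, motif-pair enrichment against a
product-of-folds expectation, and ChIP-Seq TF co-occupancy against
independence expectations. `oimet` implements that chain as tested, reusable
R functions, together with synthetic-data generators carrying full ground
truth, for computational biologists analyzing TF-driven phenotype switches.

## The statistics at the core

**Signature selection.** A feature is differentially expressed when test
status is `OK`, FDR ≤ 0.05, and linear fold change FC ≥ 2.0 or ≤ 0.5. A
model's signature is the union of responders over the three OVOL treatments;
the cross-model signature is the intersection. Concordance is the fraction
of intersection genes with (FC_BC − 1)(FC_PC − 1) > 0 under the combined
treatment. Regulation calls use FC ≥ 1.5 (up) and FC ≤ 0.67 (down); an
isoform switch needs one isoform ≥ 1.5 while a sibling isoform is ≤ 0.67 in
the same treatment.

**Literature enrichment.** For a gene set of size *n* with *k* genes hitting
a term, against *K* hits among *N* universe symbols: fold = (k/n)/(K/N);
significance by Pearson chi-square on the set-vs-complement 2×2, and by an
empirical p-value p = (1 + r)/(n_iter + 1), where r counts random same-size
sets whose hit proportion reaches the observed one.

**Motif pairs.** Under independent placement, the pair fold enrichment
equals the product of single-motif folds, f_ij = f_i · f_j; the observed
pair count is tested against the background expectation with a 1-df
chi-square.

**Co-occupancy.** With n_a, n_b promoters bound by two factors out of N_p,
the independence expectation for co-bound promoters is n_a·n_b/N_p (Fisher
test); at peak level it is rate_a·rate_b·N_p with each factor's peak
occupancy rate (Poisson test). Occupancy rates use the total peak count as
denominator in both modes.

## Worked example

Published summary counts ship with the package and every derived statistic
is recomputed from them:

```r
library(oimet)

# MET (MeSH) literature enrichment of the 739-gene signature
# against 36,973 HGNC symbols
contingency_enrichment(91, 739, 995, 36973, term = "met_mesh")
#>       term k_set n_set k_bg  n_bg prop_set prop_bg fold statistic  p_value
#> 1 met_mesh    91   739  995 36973    0.123  0.0269 4.58       267 6.13e-60

# AP1/MYC co-occupancy of the 4,102 signature promoters (MET model)
promoter_pair_stats(503, 436, 4102, 228)
#> promoter-level co-occupancy: observed 228, expected 53.46 (fold 4.26, p 1.09e-109)
peak_pair_stats(796, 120679, 305, 19030, 4102, 152)
#> peak-level co-occupancy: observed 152, expected 0.43 (fold 350.51, p 3.46e-323)

# regulation patterns from per-treatment fold changes
call_regulation(c(1.5, 2.2, 2.1))                                  # "Up"
call_isoform_switch(rbind(c(10, 10, 10), c(0.7, 0.5, 0.4)))        # "Switch"
```

The signature genes are 4.6-fold enriched for prior MET literature
association (12.3% vs the 2.7% universe rate), and JUN/MYC co-bind 228
promoters where independent binding predicts ~53 — a 4.3-fold excess,
rising to ~350-fold at the peak-pair level.

The synthetic module generates every input shape with known ground truth:

```r
cfg <- sim_config(seed = 42,
  expression = list(n_genes = 2000, n_de = c(BC = 150, PC = 220),
                    n_shared = 80, concordance = 0.66))
ex <- gen_expression(cfg)
pl <- signature_pipeline(ex$bc, ex$pc)
pl$intersection
#> intersection_signature: 80 genes; concordance 68.8% (55/80)
identical(pl$intersection$genes, ex$truth$shared_genes)
#> [1] TRUE
```

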