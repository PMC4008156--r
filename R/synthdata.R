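# Synthetic data generators with ground-truth bookkeeping.
#
# Each generator emulates the statistical structure one pipeline stage
# consumes: two-model differential-expression tables with a planted shared
# signature, isoform structure and planted switches; Bernoulli gene x term
# literature hit tables with a controllable enrichment fold; promoter and
# peak interval sets with per-TF promoter-targeting rates and optional
# pairwise co-binding coupling; and a directed regulator network with a
# planted fan-in profile. A single root seed expands into per-component
# substreams so stages can be regenerated independently.

#' Simulation configuration
#'
#' Defaults mirror the study system's shapes: a ~20,000-gene transcriptome
#' with 1,622 and 2,692 responsive genes in the two models sharing a
#' 739-gene signature at 66% directional concordance; a 36,973-symbol
#' universe with a 2.7% base literature hit rate and 4.5-fold set
#' enrichment; 4,102 promoters with tens of thousands of ChIP peaks at a
#' ~0.5% promoter-targeting rate. Every size is configurable; tests use
#' much smaller instances.
#'
#' @param seed root integer seed.
#' @param expression,literature,genome,network named lists overriding the
#'   per-component defaults (see the source for the full field list).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, expression = list(), literature = list(),
                       genome = list(), network = list()) {
  defaults <- list(
    expression = list(
      n_genes = 20000L,
      isoform_dist = c("1" = 0.6, "2" = 0.3, "3" = 0.1),
      n_de = c(BC = 1622L, PC = 2692L),
      n_shared = 739L,
      concordance = 0.66,
      treatment_response_prob = 0.7,  # OVOL1/OVOL2 alone; OVOL1and2 always
      switch_fraction = 0.05,
      fdr_max = 0.05, fc_high = 2.0, fc_low = 0.5,
      notest_fraction = 0.02),
    literature = list(
      universe_size = 36973L, set_size = 739L,
      base_rate = 0.027, enrichment_fold = 4.5,
      terms = "term1"),
    genome = list(
      n_chroms = 4L, chrom_length = 5e6,
      n_promoters = 4102L, promoter_width = 600L,
      peak_width = 200L,
      tfs = list(A = list(n_peaks = 20000L, theta = 0.005),
                 B = list(n_peaks = 20000L, theta = 0.005)),
      pair_coupling = NULL,  # e.g. list(a = "A", b = "B", rho = 0.5)
      motif_props = c(m1 = 0.3, m2 = 0.5),
      motif_coupling = NULL),  # e.g. list(a = "m1", b = "m2", rho = 0.3)
    network = list(
      n_nodes = 100L, edge_density = 0.02,
      regulators = paste0("TF", 1:4),
      fanin_hist = c("2" = 20L, "3" = 4L, "4" = 1L)))
  cfg <- list(seed = as.integer(seed),
              expression = utils::modifyList(defaults$expression, expression),
              literature = utils::modifyList(defaults$literature, literature),
              genome = utils::modifyList(defaults$genome, genome),
              network = utils::modifyList(defaults$network, network))
  with(cfg$literature, stopifnot(set_size <= universe_size,
                                 base_rate >= 0, base_rate <= 1))
  with(cfg$expression, stopifnot(n_shared <= min(n_de),
                                 sum(n_de) - n_shared <= n_genes,
                                 concordance >= 0, concordance <= 1))
  structure(cfg, class = "sim_config")
}

# Per-component substream seeds derived from the root seed.
.component_seed <- function(seed, component) {
  offset <- c(expression = 11L, literature = 23L, genome = 37L,
              network = 53L)[[component]]
  (as.integer(seed) * 2654435761 + offset) %% .Machine$integer.max
}

.draw_de_fold <- function(n, direction) {
  # responsive folds: beyond the selection band with margin, capped at 10
  up <- 2^runif(n, 1.05, 3.2)
  ifelse(direction > 0, pmin(up, 10), 1 / up)
}

.draw_null_fold <- function(n) 2^runif(n, -0.55, 0.55)  # inside all bands

#' Generate two-model differential-expression tables with ground truth
#'
#' Plants per-model responsive gene sets with a shared subset at a planted
#' directional concordance, isoform structure, and isoform-switch genes.
#' Responsive records pass the selection thresholds in every responsive
#' treatment (the combined treatment is always responsive); all other
#' records fall inside the null fold band with FDR above the cutoff.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default: the expression substream of
#'   `config$seed`).
#' @return list with `bc`, `pc` (record data.frames, see
#'   [validate_diffexpr()]) and `truth`: `de_genes` (per model),
#'   `shared_genes`, `concordant_genes`, `switch_genes` (per model),
#'   `responders` (per model, per treatment), `ovol12_direction` (per model,
#'   named sign vector).
#' @export
gen_expression <- function(config = sim_config(),
                           seed = .component_seed(config$seed, "expression")) {
  cf <- config$expression
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(cf$n_genes))
    n_iso <- sample(as.integer(names(cf$isoform_dist)), cf$n_genes,
                    replace = TRUE, prob = cf$isoform_dist)
    shared <- sample(genes, cf$n_shared)
    models <- names(cf$n_de)
    rest <- setdiff(genes, shared)
    extra <- list()
    for (m in models) {
      extra[[m]] <- sample(rest, cf$n_de[[m]] - cf$n_shared)
      rest <- setdiff(rest, extra[[m]])
    }
    de_genes <- lapply(setNames(models, models),
                       function(m) sort(c(shared, extra[[m]])))
    # planted directions under the combined treatment
    dir_a <- sample(c(-1, 1), cf$n_shared, replace = TRUE)
    agree <- runif(cf$n_shared) < cf$concordance
    direction <- list()
    direction[[models[1]]] <- setNames(dir_a, shared)
    direction[[models[2]]] <- setNames(ifelse(agree, dir_a, -dir_a), shared)
    concordant <- sort(shared[agree])
    truth_switch <- list(); truth_resp <- list()
    tables <- list()
    for (m in models) {
      de <- de_genes[[m]]
      dir_m <- setNames(sample(c(-1, 1), length(de), replace = TRUE), de)
      dir_m[shared] <- direction[[m]][shared]
      direction[[m]] <- dir_m
      # responsive treatments: OVOL1and2 always, singles with fixed prob
      resp <- list(
        OVOL1 = de[runif(length(de)) < cf$treatment_response_prob],
        OVOL2 = de[runif(length(de)) < cf$treatment_response_prob],
        OVOL1and2 = de)
      truth_resp[[m]] <- lapply(resp, sort)
      multi <- de[n_iso[match(de, genes)] >= 2L]
      n_sw <- max(if (length(multi)) 1L else 0L,
                  round(cf$switch_fraction * length(multi)))
      sw <- sort(sample(multi, min(n_sw, length(multi))))
      truth_switch[[m]] <- sw
      rows <- list()
      for (tr in OIMET_TREATMENTS) {
        is_resp <- genes %in% resp[[tr]]
        fc <- .draw_null_fold(cf$n_genes)
        fc[is_resp] <- .draw_de_fold(sum(is_resp),
                                     dir_m[genes[is_resp]])
        fdr <- runif(cf$n_genes, cf$fdr_max + 0.001, 1)
        fdr[is_resp] <- runif(sum(is_resp), 0, cf$fdr_max - 0.001)
        status <- rep("OK", cf$n_genes)
        status[!is_resp & runif(cf$n_genes) < cf$notest_fraction] <- "NOTEST"
        rows[[paste0("g_", tr)]] <- data.frame(
          feature_id = genes, level = "gene", gene_symbol = genes,
          model = m, treatment = tr, fold_change = fc, fdr = fdr,
          status = status, stringsAsFactors = FALSE)
        # isoform records: follow the gene except for planted switches,
        # where isoform 1 goes up and isoform 2 down in every responsive
        # treatment
        iso_gene <- rep(genes, n_iso)
        iso_rank <- sequence(n_iso)
        iso_id <- paste0(iso_gene, ".", iso_rank)
        iso_resp <- iso_gene %in% resp[[tr]]
        iso_fc <- .draw_null_fold(length(iso_gene))
        iso_fc[iso_resp] <- .draw_de_fold(sum(iso_resp),
                                          dir_m[iso_gene[iso_resp]])
        sw_here <- iso_gene %in% sw & iso_resp
        up1 <- sw_here & iso_rank == 1L
        dn2 <- sw_here & iso_rank == 2L
        iso_fc[up1] <- .draw_de_fold(sum(up1), rep(1, sum(up1)))
        iso_fc[dn2] <- .draw_de_fold(sum(dn2), rep(-1, sum(dn2)))
        iso_fc[sw_here & iso_rank > 2L] <- .draw_null_fold(
          sum(sw_here & iso_rank > 2L))
        iso_fdr <- runif(length(iso_gene), cf$fdr_max + 0.001, 1)
        iso_fdr[iso_resp] <- runif(sum(iso_resp), 0, cf$fdr_max - 0.001)
        rows[[paste0("i_", tr)]] <- data.frame(
          feature_id = iso_id, level = "isoform", gene_symbol = iso_gene,
          model = m, treatment = tr, fold_change = iso_fc, fdr = iso_fdr,
          status = "OK", stringsAsFactors = FALSE)
      }
      tables[[m]] <- do.call(rbind, rows)
      rownames(tables[[m]]) <- NULL
    }
    list(bc = tables[[models[1]]], pc = tables[[models[2]]],
         truth = list(de_genes = de_genes, shared_genes = sort(shared),
                      concordant_genes = concordant,
                      switch_genes = truth_switch,
                      responders = truth_resp,
                      ovol12_direction = direction))
  })
}

#' Generate a Bernoulli gene-by-term hit table with ground truth
#'
#' Background genes hit each term at `base_rate`; genes of the designated
#' set hit at `base_rate * enrichment_fold`, capped at 1 (with a warning
#' when the cap binds).
#'
#' @inheritParams gen_expression
#' @return list with `table` (a [hit_table()]) and `truth`: `gene_set`,
#'   `base_rate`, `set_rate`, `enrichment_fold`.
#' @export
gen_hit_table <- function(config = sim_config(),
                          seed = .component_seed(config$seed, "literature")) {
  cf <- config$literature
  with_seed(seed, {
    universe <- sprintf("H%05d", seq_len(cf$universe_size))
    gene_set <- sort(sample(universe, cf$set_size))
    set_rate <- cf$base_rate * cf$enrichment_fold
    if (set_rate > 1) {
      warning("enriched hit rate capped at 1")
      set_rate <- 1
    }
    hits <- matrix(FALSE, cf$universe_size, length(cf$terms),
                   dimnames = list(universe, cf$terms))
    in_set <- universe %in% gene_set
    for (t in cf$terms) {
      p <- ifelse(in_set, set_rate, cf$base_rate)
      hits[, t] <- runif(cf$universe_size) < p
    }
    list(table = hit_table(universe, hits),
         truth = list(gene_set = gene_set, base_rate = cf$base_rate,
                      set_rate = set_rate,
                      enrichment_fold = cf$enrichment_fold))
  })
}

# Sample peak start positions avoiding promoter overlap, uniform over the
# genome background (rejection sampling; promoter density is low).
.sample_background <- function(n, chroms, chrom_length, peak_width,
                               prom_gr) {
  if (n == 0L)
    return(GRanges())
  out <- NULL
  while (is.null(out) || length(out) < n) {
    m <- max(2L * n, 100L)
    chr <- sample(chroms, m, replace = TRUE)
    s <- floor(runif(m, 1, chrom_length - peak_width))
    gr <- GRanges(chr, IRanges(s, width = peak_width))
    free <- countOverlaps(gr, prom_gr, ignore.strand = TRUE) == 0L
    out <- c(if (is.null(out)) GRanges() else out, gr[free])
  }
  out[seq_len(n)]
}

#' Generate promoters, per-TF peak sets and a motif hit matrix
#'
#' Promoters are placed without overlap on a slot grid. Each TF peak lands
#' inside a uniformly chosen promoter with probability `theta` (uniform
#' start within the promoter, guaranteeing >= 1 bp overlap) and uniformly in
#' the promoter-free background otherwise. For a coupled TF pair, a peak of
#' the second factor is instead co-placed into a promoter already hit by
#' the first with probability `rho`. Motif columns are Bernoulli with an
#' optional pairwise correlation; the returned background carries the true
#' marginals and the independence (product) pair proportion.
#'
#' @inheritParams gen_expression
#' @return list with `promoters` (a [promoter_set()]), `peaks` (named list
#'   of [peak_set()]), `motif_matrix` (a [motif_hit_matrix()]),
#'   `motif_background` (a [motif_background()]) and `truth`: per-TF
#'   `theta`, `pair_coupling`, per-TF `promoters_hit`, and the true motif
#'   pair proportion.
#' @export
gen_genome <- function(config = sim_config(),
                       seed = .component_seed(config$seed, "genome")) {
  cf <- config$genome
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(cf$n_chroms))
    slot <- 2L * cf$promoter_width
    per_chrom <- floor(cf$chrom_length / slot) - 1L
    if (cf$n_promoters > per_chrom * cf$n_chroms)
      stop("promoters do not fit in the genome without overlap")
    slots <- data.frame(
      chrom = rep(chroms, each = per_chrom),
      start = rep(slot * (seq_len(per_chrom) - 1L) + 1L, cf$n_chroms))
    pick <- sort(sample(nrow(slots), cf$n_promoters))
    prom_gr <- GRanges(slots$chrom[pick],
                       IRanges(slots$start[pick],
                               width = cf$promoter_width))
    mcols(prom_gr)$name <- sprintf("prom%05d", seq_len(cf$n_promoters))
    promoters <- promoter_set(prom_gr)
    coup <- cf$pair_coupling
    peaks <- list(); hit_prom <- list()
    for (tf in names(cf$tfs)) {
      tfc <- cf$tfs[[tf]]
      n <- tfc$n_peaks
      coupled <- !is.null(coup) && identical(coup$b, tf) &&
        !is.null(hit_prom[[coup$a]]) && length(hit_prom[[coup$a]]) > 0L
      u <- runif(n)
      if (coupled) {
        take_coup <- u < coup$rho
        take_prom <- !take_coup & (runif(n) < tfc$theta)
      } else {
        take_coup <- rep(FALSE, n)
        take_prom <- u < tfc$theta
      }
      target <- integer(n)
      target[take_prom] <- sample.int(cf$n_promoters, sum(take_prom),
                                      replace = TRUE)
      if (any(take_coup))
        target[take_coup] <- hit_prom[[coup$a]][
          sample.int(length(hit_prom[[coup$a]]), sum(take_coup),
                     replace = TRUE)]
      inprom <- target > 0L
      grs <- GRanges()
      if (any(inprom)) {
        ps <- start(prom_gr)[target[inprom]]
        pe <- end(prom_gr)[target[inprom]]
        s <- floor(runif(sum(inprom), ps, pe))  # start within promoter
        grs <- GRanges(as.character(seqnames(prom_gr))[target[inprom]],
                       IRanges(s, width = cf$peak_width))
      }
      bg <- .sample_background(sum(!inprom), chroms, cf$chrom_length,
                               cf$peak_width, prom_gr)
      all_gr <- sort(c(grs, bg), ignore.strand = TRUE)
      peaks[[tf]] <- peak_set(all_gr, tf = tf,
                              tissue_class = tfc$tissue_class %||% "")
      hit_prom[[tf]] <- sort(unique(target[inprom]))
    }
    # motif matrix
    props <- cf$motif_props
    hits <- matrix(FALSE, cf$n_promoters, length(props),
                   dimnames = list(promoters$ids, names(props)))
    mcoup <- cf$motif_coupling
    done <- character(0)
    if (!is.null(mcoup)) {
      pa <- props[[mcoup$a]]; pb <- props[[mcoup$b]]
      p11 <- pa * pb + mcoup$rho * sqrt(pa * (1 - pa) * pb * (1 - pb))
      stopifnot(p11 <= min(pa, pb), p11 >= max(0, pa + pb - 1))
      a <- runif(cf$n_promoters) < pa
      p_b_given <- ifelse(a, p11 / pa, (pb - p11) / (1 - pa))
      b <- runif(cf$n_promoters) < p_b_given
      hits[, mcoup$a] <- a; hits[, mcoup$b] <- b
      done <- c(mcoup$a, mcoup$b)
      true_pair <- p11
    } else true_pair <- NULL
    for (m in setdiff(names(props), done))
      hits[, m] <- runif(cf$n_promoters) < props[[m]]
    pair_keys <- if (length(props) >= 2L) {
      cmb <- combn(names(props), 2L)
      setNames(props[cmb[1, ]] * props[cmb[2, ]],
               apply(cmb, 2L, function(x) .pair_key(x[1], x[2])))
    } else NULL
    bg <- motif_background(props, pair_keys)
    list(promoters = promoters, peaks = peaks,
         motif_matrix = motif_hit_matrix(hits),
         motif_background = bg,
         truth = list(theta = vapply(cf$tfs, `[[`, numeric(1), "theta"),
                      pair_coupling = coup,
                      promoters_hit = hit_prom,
                      motif_true_pair_prop = true_pair))
  })
}

#' Write a generated genome instance to disk
#'
#' @param genome result of [gen_genome()].
#' @param dir output directory; writes `promoters.bed`, one
#'   `peaks_<tf>.bed` per factor, and `motif_hits.tsv`.
#' @return `dir`, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(genome$promoters$ranges, file.path(dir, "promoters.bed"))
  for (tf in names(genome$peaks))
    write_bed(genome$peaks[[tf]]$ranges,
              file.path(dir, paste0("peaks_", tf, ".bed")))
  write_motif_hits(genome$motif_matrix, file.path(dir, "motif_hits.tsv"))
  invisible(dir)
}

#' Generate a directed edge list with a planted regulator fan-in profile
#'
#' Designated regulator nodes send edges onto disjoint target nodes so that
#' the fan-in histogram (k regulators -> number of targets) is exactly the
#' planted one; additional random edges among non-regulator nodes are added
#' at `edge_density` without touching regulator out-edges.
#'
#' @inheritParams gen_expression
#' @return list with `edges` (data.frame `source`, `target`, `kind`,
#'   `trust`) and `truth`: `fanin_hist`, `per_target`.
#' @export
gen_network <- function(config = sim_config(),
                        seed = .component_seed(config$seed, "network")) {
  cf <- config$network
  with_seed(seed, {
    regs <- cf$regulators
    hist <- cf$fanin_hist
    n_targets <- sum(hist)
    others <- sprintf("N%03d", seq_len(cf$n_nodes))
    others <- setdiff(others, regs)
    if (n_targets > length(others)) stop("fan-in histogram needs more nodes")
    targets <- sample(others, n_targets)
    ks <- rep(as.integer(names(hist)), hist)
    if (any(ks > length(regs))) stop("fan-in exceeds regulator count")
    reg_edges <- do.call(rbind, lapply(seq_len(n_targets), function(i)
      data.frame(source = sample(regs, ks[i]), target = targets[i],
                 stringsAsFactors = FALSE)))
    pool <- others
    m <- round(cf$edge_density * length(pool)^2)
    extra <- NULL
    if (m > 0L) {
      src <- sample(pool, m, replace = TRUE)
      tgt <- sample(pool, m, replace = TRUE)
      keep <- src != tgt
      extra <- unique(data.frame(source = src[keep], target = tgt[keep],
                                 stringsAsFactors = FALSE))
    }
    edges <- rbind(reg_edges, extra)
    if (is.null(edges))
      edges <- data.frame(source = character(0), target = character(0),
                          stringsAsFactors = FALSE)
    edges$kind <- rep("functional", nrow(edges))
    edges$trust <- rep("high", nrow(edges))
    rownames(edges) <- NULL
    per_target <- setNames(ks, targets)
    list(edges = edges,
         truth = list(fanin_hist = hist, per_target = per_target))
  })
}
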