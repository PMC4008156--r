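# Literature co-occurrence enrichment.
#
# A gene/term co-occurrence is counted when at least one publication mentions
# both the gene symbol and the query term. Enrichment of a gene set is tested
# two ways: an empirical p-value from resampling same-sized random sets from
# the symbol universe, and a contingency chi-square of set hits against the
# full-universe hits.

#' Define a literature query term
#'
#' @param label short label for the term (used as a column name in hit
#'   tables).
#' @param phrases character vector of query phrases, OR-ed together.
#' @param fields character vector (recycled) of search fields per phrase:
#'   `"TextWord"` or `"MeSH"`.
#' @param database `"PubMed"` or `"PMC"`.
#' @return object of class `term_spec`.
#' @export
#' @examples
#' term_spec("breast_cancer", c("breast cancer", "breast neoplasms"))
term_spec <- function(label, phrases, fields = "TextWord",
                      database = c("PubMed", "PMC")) {
  database <- match.arg(database)
  stopifnot(length(phrases) >= 1L, all(nzchar(phrases)))
  fields <- rep_len(fields, length(phrases))
  if (!all(fields %in% c("TextWord", "MeSH")))
    stop("fields must be 'TextWord' or 'MeSH'")
  structure(list(label = label,
                 clauses = data.frame(phrase = phrases, field = fields,
                                      stringsAsFactors = FALSE),
                 database = database),
            class = "term_spec")
}

#' Read term specifications from a YAML config
#'
#' The YAML maps term labels to lists with `phrases`, optional `fields`
#' and `database` entries.
#'
#' @param path YAML file path.
#' @return named list of `term_spec` objects.
#' @export
read_term_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(setNames(names(cfg), names(cfg)), function(lab) {
    x <- cfg[[lab]]
    term_spec(lab, phrases = unlist(x$phrases),
              fields = x$fields %||% "TextWord",
              database = x$database %||% "PubMed")
  })
}

.render_field <- function(field) {
  ifelse(field == "MeSH", "[MeSH Terms]", "[Text Word]")
}

#' Build a gene-by-term literature query
#'
#' Three case variants of the gene symbol (as given/upper-case, lower-case,
#' capitalized; duplicates dropped) are OR-ed as Text Word clauses and AND-ed
#' with the term's phrase clauses.
#'
#' @param gene_symbol HGNC gene symbol.
#' @param term a [term_spec()].
#' @return query string.
#' @export
#' @examples
#' build_query("TMEM163",
#'             term_spec("bc", c("breast cancer", "breast neoplasms")))
build_query <- function(gene_symbol, term) {
  stopifnot(nzchar(gene_symbol), inherits(term, "term_spec"))
  low <- tolower(gene_symbol)
  capped <- paste0(toupper(substring(low, 1L, 1L)), substring(low, 2L))
  variants <- unique(c(gene_symbol, toupper(gene_symbol), low, capped))
  gene_clause <- paste0("\"", variants, "\"[Text Word]", collapse = " OR ")
  term_clause <- paste0("\"", term$clauses$phrase, "\"",
                        .render_field(term$clauses$field), collapse = " OR ")
  paste0("(", gene_clause, ") AND (", term_clause, ")")
}

#' Construct a gene-by-term hit table
#'
#' @param universe ordered character vector of gene symbols (the sampling
#'   universe, e.g. all HGNC symbols).
#' @param hits logical or 0/1 matrix, genes x terms, `TRUE` where at least
#'   one publication co-mentions the gene and the term.
#' @return object of class `hit_table`.
#' @export
hit_table <- function(universe, hits) {
  hits <- as.matrix(hits)
  storage.mode(hits) <- "logical"
  if (anyDuplicated(universe)) stop("duplicated gene symbols in universe")
  if (nrow(hits) != length(universe))
    stop("hit matrix rows must match the universe")
  if (is.null(colnames(hits))) stop("hit matrix must have term column names")
  rownames(hits) <- universe
  structure(list(universe = universe, terms = colnames(hits), hits = hits),
            class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat("hit_table: ", length(x$universe), " genes x ", length(x$terms),
      " terms\n", sep = "")
  invisible(x)
}

#' Read / write a hit table as TSV
#'
#' Rows are gene symbols (first column `gene`), remaining columns are term
#' labels with 0/1 cells.
#'
#' @param path TSV file path.
#' @return [hit_table()] object (for the reader); `path` invisibly (writer).
#' @export
read_hit_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(names(df)[1] == "gene")
  hit_table(df$gene, as.matrix(df[, -1, drop = FALSE]))
}

#' @rdname read_hit_table
#' @param table a `hit_table`.
#' @export
write_hit_table <- function(table, path) {
  df <- data.frame(gene = table$universe,
                   table$hits + 0L, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count genes of a set with at least one literature hit for a term
#'
#' @param table a [hit_table()].
#' @param gene_set character vector of gene symbols, a subset of the
#'   universe.
#' @param term term label (column of the hit table).
#' @return integer count in `[0, length(gene_set)]`.
#' @export
count_cooccurrence <- function(table, gene_set, term) {
  stopifnot(inherits(table, "hit_table"))
  if (!term %in% table$terms) stop("unknown term: ", term)
  outside <- setdiff(gene_set, table$universe)
  if (length(outside))
    stop("gene(s) outside the universe: ",
         paste(head(outside, 5L), collapse = ", "))
  sum(table$hits[gene_set, term])
}

#' Empirical resampling p-value for gene-set literature enrichment
#'
#' Draws `n_iter` random gene sets of the observed size from the universe
#' (without replacement within each draw, independently across draws) and
#' ranks the observed hit proportion among the null proportions. The
#' estimator is `(1 + r) / (n_iter + 1)` where `r` counts null proportions
#' at or above the observed one (ties count, the conservative choice), so
#' the smallest attainable p-value is `1 / (n_iter + 1)`.
#'
#' @inheritParams count_cooccurrence
#' @param observed_set the gene set under test.
#' @param n_iter number of resampling iterations (default 100).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return list with `observed_prop`, `p_value`, and `null` (class
#'   `resampling_null`: `n_iter`, `set_size`, `seed`, `null_props`).
#' @export
resampling_pvalue <- function(table, observed_set, term, n_iter = 100,
                              seed = NULL) {
  stopifnot(inherits(table, "hit_table"), n_iter >= 1)
  if (length(observed_set) > length(table$universe))
    stop("observed set larger than the universe")
  k <- count_cooccurrence(table, observed_set, term)
  obs <- k / length(observed_set)
  col <- table$hits[, term]
  null_props <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(length(table$universe), length(observed_set))
      mean(col[idx])
    }, numeric(1))
  })
  p <- (1 + sum(null_props >= obs)) / (n_iter + 1)
  list(observed_prop = obs,
       p_value = p,
       null = structure(list(n_iter = n_iter, set_size = length(observed_set),
                             seed = seed, null_props = null_props),
                        class = "resampling_null"))
}

#' Generic enrichment result container
#'
#' One-row data.frame holding observed/background counts and proportions,
#' the fold enrichment, the test statistic and its p-value, and a method tag.
#'
#' @param term term or motif label.
#' @param k_set,n_set hits and size of the tested set.
#' @param k_bg,n_bg hits and size of the background.
#' @param statistic test statistic.
#' @param p_value p-value.
#' @param method method tag, e.g. `"chisq"`, `"resampling"`, `"binomial"`.
#' @return data.frame of class `enrichment_result`.
#' @export
enrichment_result <- function(term, k_set, n_set, k_bg, n_bg, statistic,
                              p_value, method) {
  prop_set <- k_set / n_set
  prop_bg <- if (!is.na(n_bg) && n_bg > 0) k_bg / n_bg else NA_real_
  fold <- if (is.na(prop_bg)) NA_real_
          else if (prop_bg > 0) prop_set / prop_bg else Inf
  structure(
    data.frame(term = term, k_set = k_set, n_set = n_set, k_bg = k_bg,
               n_bg = n_bg, prop_set = prop_set, prop_bg = prop_bg,
               fold = fold, statistic = statistic, p_value = p_value,
               method = method, stringsAsFactors = FALSE),
    class = c("enrichment_result", "data.frame"))
}

#' Contingency chi-square enrichment of set hits against the background
#'
#' The fold is the ratio of hit proportions, set over whole background
#' (`(k_set/n_set) / (k_bg/n_bg)`). The chi-square is computed on the 2x2
#' table of the set against its complement within the background
#' (`k_bg - k_set` hits in `n_bg - n_set` genes), which avoids counting the
#' set twice; Pearson's statistic without continuity correction, 1 df.
#'
#' @param k_set hits in the tested set.
#' @param n_set size of the tested set.
#' @param k_bg hits in the whole background (which contains the set).
#' @param n_bg size of the whole background.
#' @param term optional label carried into the result.
#' @return [enrichment_result()] with `method = "chisq"`.
#' @export
#' @examples
#' contingency_enrichment(91, 739, 995, 36973)   # fold ~ 4.58
contingency_enrichment <- function(k_set, n_set, k_bg, n_bg, term = NA) {
  stopifnot(k_set >= 0, k_bg >= 0, k_set <= n_set, k_bg <= n_bg,
            n_set <= n_bg, k_set <= k_bg)
  if (k_bg == 0) {
    warning("no background hits: fold undefined, reported as +Inf")
    return(enrichment_result(term, k_set, n_set, k_bg, n_bg,
                             NA_real_, NA_real_, "chisq"))
  }
  m <- matrix(c(k_set, n_set - k_set,
                k_bg - k_set, (n_bg - n_set) - (k_bg - k_set)),
              nrow = 2L, byrow = TRUE)
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  enrichment_result(term, k_set, n_set, k_bg, n_bg,
                    unname(ct$statistic), ct$p.value, "chisq")
}

#' NCBI E-utilities esearch URL for a query
#'
#' Builds the esearch URL for a query string. Fetching is optional and never
#' required by the analysis path: hit tables are the default input.
#'
#' @param query query string from [build_query()].
#' @param database `"pubmed"` or `"pmc"`.
#' @param api_key optional NCBI API key.
#' @param retmax maximum ids to return (0: count only).
#' @return URL string.
#' @export
eutils_esearch_url <- function(query, database = c("pubmed", "pmc"),
                               api_key = NULL, retmax = 0) {
  database <- match.arg(database)
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi",
                "?db=", database,
                "&term=", URLencode(query, reserved = TRUE),
                "&retmax=", retmax)
  if (!is.null(api_key)) url <- paste0(url, "&api_key=", api_key)
  url
}

#' Live E-utilities hit count (optional)
#'
#' Queries esearch and parses the result count. Rate-limited to at most 3
#' requests per second and cached on disk when `cache_dir` is given. Requires
#' network access; intended for refreshing hit tables, not for routine runs.
#'
#' @inheritParams eutils_esearch_url
#' @param cache_dir optional directory for per-query response caching.
#' @return integer count of matching publications.
#' @export
eutils_count <- function(query, database = c("pubmed", "pmc"),
                         api_key = NULL, cache_dir = NULL) {
  database <- match.arg(database)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    key <- paste0(database, "_",
                  paste(as.integer(charToRaw(query)), collapse = ""), ".txt")
    cached <- file.path(cache_dir, substr(key, 1, 200))
    if (file.exists(cached)) return(as.integer(readLines(cached, n = 1L)))
  }
  Sys.sleep(1 / 3)  # <= 3 requests per second
  txt <- paste(readLines(eutils_esearch_url(query, database, api_key),
                         warn = FALSE), collapse = "")
  count <- as.integer(sub(".*<Count>([0-9]+)</Count>.*", "\\1", txt))
  if (!is.null(cache_dir)) writeLines(as.character(count), cached)
  count
}
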