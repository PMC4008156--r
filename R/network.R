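# Parsimonious seed-network construction over a directed interaction edge
# list: direct seed-seed edges plus the smallest set of non-seed
# intermediates, each bridging seed pairs in at most one step. Seeds that
# cannot be connected are kept and reported, mirroring network views that
# show disconnected seed nodes.

#' Read an interaction edge list
#'
#' @param path TSV with columns `source`, `target` and optional `kind`,
#'   `trust`.
#' @return data.frame of edges; self-loops are flagged in a `self_loop`
#'   column.
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("source", "target") %in% names(df)))
  if (!"kind" %in% names(df)) df$kind <- NA_character_
  if (!"trust" %in% names(df)) df$trust <- NA_character_
  df$self_loop <- df$source == df$target
  df
}

# Unordered pair key
.pkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# Minimum set cover: exact subset enumeration by increasing size
# (lexicographic tie-break) for small candidate sets, greedy
# maximum-coverage beyond.
.min_cover <- function(cover_sets, exact_limit) {
  need <- unique(unlist(cover_sets, use.names = FALSE))
  if (!length(need)) return(character(0))
  cands <- sort(names(cover_sets))
  if (length(cands) <= exact_limit) {
    for (k in seq_along(cands)) {
      combos <- combn(cands, k, simplify = FALSE)
      for (cmb in combos) {
        if (all(need %in% unlist(cover_sets[cmb], use.names = FALSE)))
          return(cmb)
      }
    }
    return(cands)
  }
  chosen <- character(0)
  uncovered <- need
  repeat {
    gain <- vapply(cands, function(v)
      sum(uncovered %in% cover_sets[[v]]), integer(1))
    if (!length(gain) || max(gain) == 0L) break
    pick <- cands[gain == max(gain)][1]  # cands sorted: lexicographic tie-break
    chosen <- c(chosen, pick)
    uncovered <- setdiff(uncovered, cover_sets[[pick]])
    cands <- setdiff(cands, pick)
    if (!length(uncovered)) break
  }
  chosen
}

#' Build a parsimonious seed network
#'
#' Includes all direct seed-to-seed edges, then adds the smallest set of
#' non-seed intermediate nodes such that every seed pair connectable through
#' a single intermediate (one maximum step) is connected. The minimum
#' intermediate set is found exactly (subset enumeration) when at most
#' `exact_limit` candidate intermediates exist, and by greedy
#' maximum-coverage with lexicographic tie-breaking otherwise. Seeds left
#' without any connection are reported as disconnected, not dropped.
#'
#' @param seeds character vector of seed gene/TF labels (non-empty).
#' @param edges edge data.frame (see [read_edge_list()]).
#' @param max_intermediate maximum non-seed nodes on a path between two
#'   seeds: 0 (direct edges only) or 1.
#' @param directed if `TRUE` a pair is bridged by `v` when `s -> v -> t` for
#'   some orientation of the pair; if `FALSE` edge direction is ignored.
#' @param exact_limit candidate-count threshold for the exact cover search.
#' @return object of class `tf_network`: `seed_nodes`, `intermediate_nodes`,
#'   `edges`, `disconnected_seeds`, `directed`.
#' @export
build_parsimonious_network <- function(seeds, edges, max_intermediate = 1,
                                       directed = TRUE, exact_limit = 12L) {
  stopifnot(length(seeds) >= 1L, max_intermediate %in% c(0L, 1L))
  seeds <- unique(as.character(seeds))
  if (nrow(edges) == 0L)
    return(structure(list(seed_nodes = seeds,
                          intermediate_nodes = character(0),
                          edges = edges, disconnected_seeds = seeds,
                          directed = directed),
                     class = "tf_network"))
  src <- as.character(edges$source); tgt <- as.character(edges$target)
  direct <- which(src %in% seeds & tgt %in% seeds & src != tgt)
  keep_edges <- direct
  intermediates <- character(0)
  if (max_intermediate >= 1L) {
    covered_direct <- unique(.pkey(src[direct], tgt[direct]))
    in_from_seed <- split(src[src %in% seeds & !tgt %in% seeds],
                          tgt[src %in% seeds & !tgt %in% seeds])
    out_to_seed <- split(tgt[tgt %in% seeds & !src %in% seeds],
                         src[tgt %in% seeds & !src %in% seeds])
    cand <- if (directed) intersect(names(in_from_seed), names(out_to_seed))
            else unique(c(names(in_from_seed), names(out_to_seed)))
    cover_sets <- list()
    for (v in cand) {
      if (directed) {
        froms <- unique(in_from_seed[[v]]); tos <- unique(out_to_seed[[v]])
        pairs <- expand.grid(a = froms, b = tos, stringsAsFactors = FALSE)
      } else {
        adj <- unique(c(in_from_seed[[v]], out_to_seed[[v]]))
        if (length(adj) < 2L) next
        pairs <- as.data.frame(t(combn(adj, 2L)), stringsAsFactors = FALSE)
        names(pairs) <- c("a", "b")
      }
      pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
      keys <- setdiff(unique(.pkey(pairs$a, pairs$b)), covered_direct)
      if (length(keys)) cover_sets[[v]] <- keys
    }
    intermediates <- .min_cover(cover_sets, exact_limit)
    for (v in intermediates) {
      # shortest-path edges only: seed->v kept iff v reaches a seed, and
      # v->seed kept iff a seed reaches v (directed case)
      if (directed) {
        keep_edges <- c(keep_edges,
                        which(tgt == v & src %in% seeds),
                        which(src == v & tgt %in% seeds))
      } else {
        keep_edges <- c(keep_edges,
                        which((tgt == v & src %in% seeds) |
                                (src == v & tgt %in% seeds)))
      }
    }
  }
  keep_edges <- sort(unique(keep_edges))
  net_edges <- edges[keep_edges, , drop = FALSE]
  touched <- unique(c(net_edges$source, net_edges$target))
  connected <- seeds[seeds %in% touched]
  structure(list(seed_nodes = seeds,
                 intermediate_nodes = sort(intermediates),
                 edges = net_edges,
                 disconnected_seeds = setdiff(seeds, connected),
                 directed = directed),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  cat("tf_network: ", length(x$seed_nodes), " seeds, ",
      length(x$intermediate_nodes), " intermediates, ",
      nrow(x$edges), " edges, ",
      length(x$disconnected_seeds), " disconnected seed(s)\n", sep = "")
  invisible(x)
}

#' Regulator fan-out histogram
#'
#' For every non-regulator target node, counts the distinct regulators with
#' a direct edge onto it, and summarizes how many targets are regulated by
#' k regulators.
#'
#' @param x a `tf_network` or an edge data.frame.
#' @param regulators character vector of regulator labels; regulators absent
#'   from the edge list produce a warning.
#' @return list with `per_target` (named integer vector, targets with >= 1
#'   regulator) and `histogram` (named integer vector, k -> number of
#'   targets).
#' @export
regulator_fanout <- function(x, regulators) {
  edges <- if (inherits(x, "tf_network")) x$edges else x
  nodes <- unique(c(edges$source, edges$target))
  missing <- setdiff(regulators, nodes)
  if (length(missing))
    warning("regulator(s) not present: ", paste(missing, collapse = ", "))
  reg_edges <- edges[edges$source %in% regulators &
                       !edges$target %in% regulators, , drop = FALSE]
  reg_edges <- unique(reg_edges[, c("source", "target")])
  per_target <- table(reg_edges$target)
  per_target <- setNames(as.integer(per_target), names(per_target))
  hist <- table(per_target)
  list(per_target = per_target,
       histogram = setNames(as.integer(hist), names(hist)))
}

#' Convert a network to igraph / write node-edge tables and GraphML
#'
#' @param network a `tf_network`.
#' @return an `igraph` graph with a `role` vertex attribute
#'   (`seed`/`intermediate`).
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "tf_network"))
  nodes <- unique(c(network$seed_nodes, network$intermediate_nodes,
                    network$edges$source, network$edges$target))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "target")],
    directed = network$directed,
    vertices = data.frame(
      name = nodes,
      role = ifelse(nodes %in% network$seed_nodes, "seed", "intermediate"),
      stringsAsFactors = FALSE))
  g
}

#' @rdname as_igraph
#' @param dir output directory (created if needed); writes `nodes.tsv`,
#'   `edges.tsv` and `network.graphml`.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- unique(c(network$seed_nodes, network$intermediate_nodes,
                    network$edges$source, network$edges$target))
  nd <- data.frame(
    node = nodes,
    role = ifelse(nodes %in% network$seed_nodes, "seed", "intermediate"),
    disconnected = nodes %in% network$disconnected_seeds,
    stringsAsFactors = FALSE)
  write.table(nd, file.path(dir, "nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(network$edges, file.path(dir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  igraph::write_graph(as_igraph(network),
                      file.path(dir, "network.graphml"), format = "graphml")
  invisible(dir)
}
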