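#' Leaf-removal iteration index on an acyclic topology
#'
#' Iteration 1 removes every node with zero out-degree; each subsequent
#' iteration removes the nodes whose remaining out-neighbours have all been
#' removed. The index is the bottom-up level of a node: the maximum index
#' equals the length of the longest directed path plus one.
#'
#' @param topo an acyclic `kpnet_topology` (typically a condensation DAG).
#' @return named integer vector of iteration indices (>= 1) per node.
#' @export
leaf_removal <- function(topo) {
  topo <- topology(topo)
  n <- length(topo$nodes)
  if (n == 0) {
    stop_kpnet("empty topology", class = "kpnet_argument_error")
  }
  from <- match(topo$arcs$from, topo$nodes)
  to <- match(topo$arcs$to, topo$nodes)
  outdeg <- tabulate(from, nbins = n)
  in_nbrs <- split(from, to)          # predecessors keyed by target index
  level <- integer(n)
  frontier <- which(outdeg == 0)
  it <- 0L
  remaining <- n
  while (length(frontier) > 0) {
    it <- it + 1L
    level[frontier] <- it
    remaining <- remaining - length(frontier)
    preds <- unlist(in_nbrs[as.character(frontier)], use.names = FALSE)
    nxt <- integer(0)
    if (length(preds) > 0) {
      cnt <- table(preds)
      idx <- as.integer(names(cnt))
      outdeg[idx] <- outdeg[idx] - as.integer(cnt)
      nxt <- idx[outdeg[idx] == 0 & level[idx] == 0L]
    }
    frontier <- nxt
  }
  if (remaining > 0) {
    stop_kpnet("topology is cyclic: leaf removal requires a DAG",
               class = "kpnet_cycle_error")
  }
  setNames(level, topo$nodes)
}

#' Vertex sort: level spans from leaf removal on the condensation
#'
#' Collapses each strongly connected component to a super node, runs leaf
#' removal on the resulting DAG (bottom-up index `b`) and on its transpose
#' (top-down index `t`), and reports per-node level spans. `D` is the total
#' number of levels (`max(b)`); spans are reported top-first (level 1 = apex):
#' `level_min = t`, `level_max = D - b + 1`. All members of one SCC share
#' their super node's span. A node spanning several levels reflects the
#' freedom the data leave in placing it.
#'
#' @param topo a `kpnet_topology` (self-loops must already be dropped, the
#'   default of [topology()]).
#' @return `kpnet_levels`: data.frame with columns `id`, `b`, `t`,
#'   `level_min`, `level_max`, plus attributes `D` and `condensation`.
#' @examples
#' topo <- new_toy_topology(c("a b", "b c"))
#' vertex_sort(topo)
#' @export
vertex_sort <- function(topo) {
  topo <- topology(topo)
  if (length(topo$nodes) == 0) {
    stop_kpnet("empty network", class = "kpnet_argument_error")
  }
  cond <- scc(topo)
  b_sup <- leaf_removal(cond$dag)
  t_sup <- leaf_removal(transpose_topology(cond$dag))
  D <- max(b_sup)
  b <- unname(b_sup[cond$membership[topo$nodes]])
  tt <- unname(t_sup[cond$membership[topo$nodes]])
  out <- data.frame(id = topo$nodes, b = as.integer(b), t = as.integer(tt),
                    level_min = as.integer(tt),
                    level_max = as.integer(D - b + 1L),
                    stringsAsFactors = FALSE)
  attr(out, "D") <- as.integer(D)
  attr(out, "condensation") <- cond
  class(out) <- c("kpnet_levels", "data.frame")
  out
}

#' Number of levels of a vertex sort
#' @param levels a `kpnet_levels` object.
#' @return integer `D`.
#' @export
n_levels <- function(levels) attr(levels, "D")

#' Classify enzymes into bow-tie layers
#'
#' The core layer is the largest strongly connected component (ties broken by
#' internal arc count, then by smallest member id, so the choice is
#' deterministic); the top layer contains the enzymes that regulate the core
#' and the bottom layer those regulated by it. The remaining sorted enzymes
#' are peripheral. `mode = "path"` (default) uses any directed path,
#' `mode = "direct"` only one-arc neighbours of the core.
#'
#' @param topo the enzyme subgraph (see [enzyme_subgraph()]); any
#'   `kpnet_topology` is accepted.
#' @param mode `"path"` or `"direct"`.
#' @return `kpnet_partition`: list of sorted id vectors `$top`, `$core`,
#'   `$bottom`, `$peripheral`; plus `$substrates` when `topo` carries
#'   `isolated_enzymes` (then equal to them -- non-enzyme substrates are added
#'   by [sort_network()]).
#' @export
classify_layers <- function(topo, mode = c("path", "direct")) {
  mode <- match.arg(mode)
  topo <- topology(topo)
  cond <- scc(topo)
  core <- pick_core(cond, topo)
  if (length(core) == 1) {
    warning("largest SCC has a single node: degenerate bow tie")
  }
  if (mode == "path") {
    rs <- reach_sets(topo, core)
    top <- rs$ancestors
    bottom <- rs$descendants
  } else {
    top <- sort(setdiff(topo$arcs$from[topo$arcs$to %in% core], core))
    bottom <- sort(setdiff(topo$arcs$to[topo$arcs$from %in% core], core))
  }
  peripheral <- sort(setdiff(topo$nodes, c(core, top, bottom)))
  out <- list(top = top, core = sort(core), bottom = bottom,
              peripheral = peripheral)
  if (!is.null(topo$isolated_enzymes)) {
    out$substrates <- topo$isolated_enzymes
  }
  structure(out, class = "kpnet_partition")
}

# Largest SCC with deterministic tie-breaking: size, then internal arc
# count, then lexicographically smallest member id.
pick_core <- function(cond, topo) {
  sizes <- lengths(cond$supernodes)
  cand <- names(sizes)[sizes == max(sizes)]
  if (length(cand) > 1) {
    internal <- vapply(cand, function(lab) {
      members <- cond$supernodes[[lab]]
      sum(topo$arcs$from %in% members & topo$arcs$to %in% members)
    }, integer(1))
    cand <- cand[internal == max(internal)]
    cand <- sort(cand)[1]  # label is the smallest member id
  }
  cond$supernodes[[cand[1]]]
}

#' @export
print.kpnet_partition <- function(x, ...) {
  cat("kpnet_partition:",
      paste(sprintf("%s=%d", names(x), lengths(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Global reaching centrality
#'
#' The local reaching centrality of node i is the proportion of the other
#' nodes it can reach, `C_R(i) = |descendants(i)| / (N - 1)`; the GRC is the
#' normalized average gap below the best reacher,
#' `GRC = sum(max C_R - C_R(i)) / (N - 1)`. 1 for an out-star (autocratic),
#' 0 for a cycle (democratic).
#'
#' @param x a [kpnet_network()] or `kpnet_topology` with at least 2 nodes.
#'   For a network, GRC is computed on the full topology (enzymes plus
#'   substrates) with self-loops dropped.
#' @return `kpnet_grc`: list with `$cr` (named numeric per node), `$grc`,
#'   `$n`.
#' @export
grc <- function(x) {
  topo <- topology(x)
  n <- length(topo$nodes)
  if (n < 2) {
    stop_kpnet("GRC requires at least 2 nodes", class = "kpnet_argument_error")
  }
  g <- as_igraph(topo)
  dm <- igraph::distances(g, mode = "out")
  reach <- rowSums(is.finite(dm)) - 1  # exclude self
  cr <- setNames(reach / (n - 1), topo$nodes)
  val <- sum(max(cr) - cr) / (n - 1)
  structure(list(cr = cr, grc = unname(val), n = n), class = "kpnet_grc")
}

#' @export
print.kpnet_grc <- function(x, ...) {
  cat(sprintf("GRC = %.4f over %d nodes (max C_R = %.4f)\n",
              x$grc, x$n, max(x$cr)))
  invisible(x)
}

#' Distinct proteins regulated by each layer
#'
#' For each layer, the number of distinct proteins (of any role) targeted by
#' at least one enzyme of that layer in the full signed network.
#'
#' @param network a [kpnet_network()].
#' @param partition a `kpnet_partition`.
#' @param layers which layers to count.
#' @return named integer vector.
#' @export
layer_regulation_counts <- function(network, partition,
                                    layers = c("top", "core", "bottom")) {
  vapply(layers, function(l) {
    length(unique(network$edges$target[network$edges$source %in%
                                         partition[[l]]]))
  }, integer(1))
}

#' Sort a network into its bow-tie hierarchy
#'
#' One-call pipeline: build the enzyme subgraph, vertex-sort it, classify
#' bow-tie layers, and attach the substrates layer (non-enzyme nodes plus
#' isolated enzymes).
#'
#' @param network a [kpnet_network()].
#' @param mode passed to [classify_layers()].
#' @return list with `$levels` (`kpnet_levels`), `$partition`
#'   (`kpnet_partition` incl. `$substrates`), `$D`, `$isolated_enzymes`,
#'   `$enzyme_topology`.
#' @export
sort_network <- function(network, mode = c("path", "direct")) {
  mode <- match.arg(mode)
  es <- enzyme_subgraph(network)
  if (length(es$nodes) == 0) {
    stop_kpnet("enzyme subgraph is empty: nothing to sort",
               class = "kpnet_argument_error")
  }
  levels <- vertex_sort(es)
  part <- classify_layers(es, mode = mode)
  non_enz <- setdiff(network$nodes$id, enzyme_ids(network))
  part$substrates <- sort(unique(c(es$isolated_enzymes, non_enz)))
  list(levels = levels, partition = part, D = n_levels(levels),
       isolated_enzymes = es$isolated_enzymes, enzyme_topology = es)
}

#' Build a small topology from "from to" arc strings (testing/examples)
#'
#' @param arcs character vector, each element `"u v"` for an arc u -> v.
#' @param nodes optional extra isolated nodes.
#' @return a `kpnet_topology`.
#' @export
new_toy_topology <- function(arcs = character(), nodes = character()) {
  if (length(arcs) > 0) {
    parts <- strsplit(arcs, "[[:space:]]+")
    af <- vapply(parts, `[`, character(1), 1)
    at <- vapply(parts, `[`, character(1), 2)
    arcs <- data.frame(from = af, to = at, stringsAsFactors = FALSE)
  } else {
    arcs <- data.frame(from = character(), to = character())
  }
  new_topology(unique(c(nodes, arcs$from, arcs$to)), arcs)
}
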