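#' Topology view of a signed network
#'
#' Collapses the signed multi-edge set to plain directed arcs for all
#' topological computations. Phosphorylation and dephosphorylation edges
#' between the same ordered pair collapse to one arc by default (the layer
#' logic treats "both" as a single arrow class), and self-loops
#' (autophosphorylation) are dropped by default because a self-loop would make
#' any node trivially cyclic.
#'
#' @param network a [kpnet_network()], or an existing `kpnet_topology`
#'   (returned unchanged).
#' @param collapse_types collapse P/D parallel edges to one arc.
#' @param drop_self_loops remove arcs u -> u.
#' @return `kpnet_topology`: list with sorted character `$nodes`, data.frame
#'   `$arcs` (`from`, `to`) and `$self_loops_included`.
#' @export
topology <- function(network, collapse_types = TRUE, drop_self_loops = TRUE) {
  if (inherits(network, "kpnet_topology")) return(network)
  arcs <- data.frame(from = network$edges$source, to = network$edges$target,
                     stringsAsFactors = FALSE)
  # Arcs are unique ordered pairs by construction; a P and a D edge between
  # the same pair always collapse to one arc once the sign is discarded, so
  # collapse_types = FALSE differs only in keeping the signs retrievable from
  # the owning network, never in the arc set.
  arcs <- unique(arcs)
  if (drop_self_loops) arcs <- arcs[arcs$from != arcs$to, , drop = FALSE]
  new_topology(network$nodes$id, arcs, self_loops = !drop_self_loops)
}

new_topology <- function(nodes, arcs, self_loops = FALSE) {
  nodes <- sort(unique(as.character(nodes)))
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (nrow(arcs) > 0) {
    arcs$from <- as.character(arcs$from)
    arcs$to <- as.character(arcs$to)
    arcs <- unique(arcs[c("from", "to")])
    arcs <- arcs[order(arcs$from, arcs$to), , drop = FALSE]
  } else {
    arcs <- data.frame(from = character(), to = character(),
                       stringsAsFactors = FALSE)
  }
  rownames(arcs) <- NULL
  structure(list(nodes = nodes, arcs = arcs, self_loops_included = self_loops),
            class = "kpnet_topology")
}

#' @export
print.kpnet_topology <- function(x, ...) {
  cat(sprintf("kpnet_topology: %d nodes, %d arcs\n",
              length(x$nodes), nrow(x$arcs)))
  invisible(x)
}

as_igraph <- function(topo) {
  igraph::graph_from_data_frame(topo$arcs, directed = TRUE,
                                vertices = data.frame(name = topo$nodes))
}

#' Strongly connected components and condensation
#'
#' Collapses each strongly connected component (SCC) into a super node; the
#' arcs between distinct super nodes form an acyclic condensation graph.
#' Super nodes are labelled by their lexicographically smallest member, so the
#' output is deterministic.
#'
#' @param topo a `kpnet_topology` (or anything [topology()] accepts).
#' @return `kpnet_condensation`: list with `$membership` (named character:
#'   node -> super-node label), `$supernodes` (named list of member vectors),
#'   `$dag` (`kpnet_topology` over super-node labels).
#' @export
scc <- function(topo) {
  topo <- topology(topo)
  g <- as_igraph(topo)
  comp <- igraph::components(g, mode = "strong")$membership
  labs <- vapply(split(names(comp), comp), min, character(1))
  membership <- setNames(labs[as.character(comp)], names(comp))
  supernodes <- split(names(membership), membership)
  supernodes <- supernodes[order(names(supernodes))]
  arcs <- topo$arcs
  darcs <- data.frame(from = unname(membership[arcs$from]),
                      to = unname(membership[arcs$to]),
                      stringsAsFactors = FALSE)
  darcs <- darcs[darcs$from != darcs$to, , drop = FALSE]
  dag <- new_topology(names(supernodes), darcs)
  structure(list(membership = membership, supernodes = supernodes, dag = dag),
            class = "kpnet_condensation")
}

#' @export
print.kpnet_condensation <- function(x, ...) {
  sizes <- lengths(x$supernodes)
  cat(sprintf("kpnet_condensation: %d super nodes (largest SCC: %d), %d dag arcs\n",
              length(x$supernodes), max(sizes), nrow(x$dag$arcs)))
  invisible(x)
}

transpose_topology <- function(topo) {
  new_topology(topo$nodes,
               data.frame(from = topo$arcs$to, to = topo$arcs$from,
                          stringsAsFactors = FALSE),
               self_loops = topo$self_loops_included)
}

#' Ancestors and descendants of a node set
#'
#' Path semantics: ancestors are nodes outside `S` with a directed path to
#' some member of `S`; descendants are nodes outside `S` reachable from some
#' member of `S`.
#'
#' @param topo a `kpnet_topology`.
#' @param S character vector of node ids, non-empty subset of `topo$nodes`.
#' @return list with sorted character vectors `$ancestors`, `$descendants`.
#' @export
reach_sets <- function(topo, S) {
  topo <- topology(topo)
  if (length(S) == 0) {
    stop_kpnet("S must be non-empty", class = "kpnet_argument_error")
  }
  if (!all(S %in% topo$nodes)) {
    stop_kpnet("S contains nodes outside the topology",
               class = "kpnet_argument_error")
  }
  g <- as_igraph(topo)
  anc <- unique(unlist(lapply(S, function(v) {
    names(igraph::subcomponent(g, v, mode = "in"))
  })))
  des <- unique(unlist(lapply(S, function(v) {
    names(igraph::subcomponent(g, v, mode = "out"))
  })))
  list(ancestors = sort(setdiff(anc, S)), descendants = sort(setdiff(des, S)))
}

#' Induced enzyme subgraph
#'
#' Keeps only kinase/phosphatase nodes and the arcs with both endpoints
#' enzymes. Enzymes that lose all their arcs (e.g. those targeting only
#' non-enzyme substrates, or targeted by nobody) are excluded from the
#' subgraph and reported as isolated enzymes: they belong to the substrates
#' layer of the bow tie.
#'
#' @param network a [kpnet_network()].
#' @inheritParams topology
#' @return a `kpnet_topology` over the connected enzymes, with the vector of
#'   isolated enzymes in `$isolated_enzymes`.
#' @export
enzyme_subgraph <- function(network, collapse_types = TRUE,
                            drop_self_loops = TRUE) {
  enz <- enzyme_ids(network)
  topo <- topology(network, collapse_types, drop_self_loops)
  arcs <- topo$arcs[topo$arcs$from %in% enz & topo$arcs$to %in% enz, ,
                    drop = FALSE]
  connected <- sort(unique(c(arcs$from, arcs$to)))
  out <- new_topology(connected, arcs, self_loops = topo$self_loops_included)
  out$isolated_enzymes <- sort(setdiff(enz, connected))
  out
}

# In/out degrees on the collapsed topology, named by node id.
topology_degrees <- function(topo) {
  topo <- topology(topo)
  indeg <- table(factor(topo$arcs$to, levels = topo$nodes))
  outdeg <- table(factor(topo$arcs$from, levels = topo$nodes))
  list(in_degree = setNames(as.integer(indeg), topo$nodes),
       out_degree = setNames(as.integer(outdeg), topo$nodes))
}

#' Node degrees of a network or topology
#'
#' @param x a [kpnet_network()] or `kpnet_topology`.
#' @param mode `"in"`, `"out"` or `"total"`.
#' @return named integer vector over all nodes.
#' @export
node_degrees <- function(x, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  d <- topology_degrees(topology(x))
  switch(mode,
         "in" = d$in_degree,
         "out" = d$out_degree,
         total = d$in_degree + d$out_degree)
}
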