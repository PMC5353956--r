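#' Construct a directed signed kinase-phosphatase network
#'
#' The central container of the package: a set of typed nodes (kinase,
#' phosphatase or other) plus a set of unique signed directed edges, each a
#' phosphorylation (`"P"`) or dephosphorylation (`"D"`) interaction from an
#' enzyme to a substrate.
#'
#' @param edges data.frame with character columns `source`, `target`, `itype`
#'   (`"P"` or `"D"`). Duplicate `(source, target, itype)` triples are dropped
#'   with a warning.
#' @param nodes optional data.frame with columns `id`, `role`
#'   (`"kinase"`, `"phosphatase"` or `"other"`). Nodes appearing only in
#'   `edges` are added with role `"other"`.
#' @param validate_sources if `TRUE` (default), every edge source must have
#'   role kinase or phosphatase; randomized networks produced by the null
#'   models relax this.
#' @return an object of class `kpnet_network`: a list with sorted data.frames
#'   `$nodes` (id, role) and `$edges` (source, target, itype).
#' @examples
#' net <- kpnet_network(
#'   data.frame(source = "CDC28", target = "SIC1", itype = "P"),
#'   data.frame(id = "CDC28", role = "kinase")
#' )
#' net
#' @export
kpnet_network <- function(edges, nodes = NULL, validate_sources = TRUE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("source", "target", "itype")
  if (!all(need %in% names(edges))) {
    stop_kpnet("edge table must have columns %s", paste(need, collapse = ", "),
               class = "kpnet_format_error")
  }
  edges <- edges[need]
  for (cl in need) edges[[cl]] <- as.character(edges[[cl]])
  if (nrow(edges) > 0) {
    if (any(!nzchar(edges$source)) || any(!nzchar(edges$target))) {
      stop_kpnet("empty node identifier in edge table",
                 class = "kpnet_format_error")
    }
    bad <- !edges$itype %in% c("P", "D")
    if (any(bad)) {
      stop_kpnet("invalid interaction type '%s' (must be P or D)",
                 edges$itype[which(bad)[1]], class = "kpnet_format_error")
    }
    dup <- duplicated(edges)
    if (any(dup)) {
      warning(sprintf("dropping %d duplicate edge triple(s)", sum(dup)))
      edges <- edges[!dup, , drop = FALSE]
    }
  }

  if (is.null(nodes)) {
    nodes <- data.frame(id = character(), role = character(),
                        stringsAsFactors = FALSE)
  } else {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    if (!all(c("id", "role") %in% names(nodes))) {
      stop_kpnet("node table must have columns id, role",
                 class = "kpnet_format_error")
    }
    nodes <- nodes[c("id", "role")]
    nodes$id <- as.character(nodes$id)
    nodes$role <- as.character(nodes$role)
    if (anyDuplicated(nodes$id)) {
      stop_kpnet("duplicated node id '%s' in node table",
                 nodes$id[duplicated(nodes$id)][1],
                 class = "kpnet_format_error")
    }
    badrole <- !nodes$role %in% c("kinase", "phosphatase", "other")
    if (any(badrole)) {
      stop_kpnet("invalid role '%s' (kinase/phosphatase/other)",
                 nodes$role[which(badrole)[1]], class = "kpnet_format_error")
    }
  }
  extra <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(extra) > 0) {
    nodes <- rbind(nodes, data.frame(id = extra, role = "other",
                                     stringsAsFactors = FALSE))
  }

  if (validate_sources && nrow(edges) > 0) {
    role_of <- setNames(nodes$role, nodes$id)
    off <- role_of[edges$source] == "other"
    if (any(off)) {
      i <- which(off)[1]
      stop_kpnet(
        "edge %s -> %s (%s): source has role 'other' (must be an enzyme)",
        edges$source[i], edges$target[i], edges$itype[i],
        class = "kpnet_validation_error")
    }
  }

  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target, edges$itype), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "kpnet_network")
}

#' @export
print.kpnet_network <- function(x, ...) {
  roles <- table(factor(x$nodes$role,
                        levels = c("kinase", "phosphatase", "other")))
  cat(sprintf(
    "kpnet_network: %d nodes (%d kinases, %d phosphatases, %d other), %d signed edges\n",
    nrow(x$nodes), roles[["kinase"]], roles[["phosphatase"]],
    roles[["other"]], nrow(x$edges)))
  invisible(x)
}

enzyme_ids <- function(network) {
  network$nodes$id[network$nodes$role %in% c("kinase", "phosphatase")]
}

node_roles <- function(network) {
  setNames(network$nodes$role, network$nodes$id)
}

#' Read a network from edge-list and node-role TSV files
#'
#' The edge table is a TSV with header columns `source`, `target`, `itype`
#' (P = phosphorylation, D = dephosphorylation); the node table has columns
#' `id`, `role`. Row order is irrelevant: the in-memory network is sorted.
#' Supplementary XLSX tables can be exported to this format with one line,
#' e.g. in R: `openxlsx`-free via
#' `write.table(readxl_or_python_export, "edges.tsv", sep="\t", ...)`, or
#' `python -c "import pandas; pandas.read_excel('file.xlsx').to_csv('edges.tsv', sep='\t', index=False)"`.
#' A column-mapping can be supplied when the source table uses other headers.
#'
#' @param edge_path path to the edge TSV.
#' @param node_path optional path to the node-role TSV; when omitted all edge
#'   sources are assigned role `"kinase"` is *not* assumed -- instead an error
#'   is raised unless `validate_sources = FALSE`, because enzyme roles cannot
#'   be guessed.
#' @param edge_columns named character vector mapping the canonical names
#'   `source`, `target`, `itype` to the file's column names.
#' @param validate_sources passed to [kpnet_network()].
#' @return a [kpnet_network()].
#' @export
read_network <- function(edge_path, node_path = NULL,
                         edge_columns = c(source = "source",
                                          target = "target",
                                          itype = "itype"),
                         validate_sources = TRUE) {
  ed <- read.delim(edge_path, stringsAsFactors = FALSE,
                   colClasses = "character")
  miss <- setdiff(unname(edge_columns), names(ed))
  if (length(miss) > 0) {
    stop_kpnet("edge file misses column(s): %s", paste(miss, collapse = ", "),
               class = "kpnet_format_error")
  }
  ed <- data.frame(source = ed[[edge_columns[["source"]]]],
                   target = ed[[edge_columns[["target"]]]],
                   itype = ed[[edge_columns[["itype"]]]],
                   stringsAsFactors = FALSE)
  nd <- NULL
  if (!is.null(node_path)) {
    nd <- read.delim(node_path, stringsAsFactors = FALSE,
                     colClasses = "character")
    if (!all(c("id", "role") %in% names(nd))) {
      stop_kpnet("node file must have columns id, role",
                 class = "kpnet_format_error")
    }
  } else if (validate_sources) {
    # Roles are needed to enforce the enzyme-source rule; infer the weakest
    # consistent assignment: every source is an enzyme of unknown class.
    nd <- data.frame(id = unique(ed$source), role = "kinase",
                     stringsAsFactors = FALSE)
  }
  kpnet_network(ed, nd, validate_sources = validate_sources)
}

#' Write a network to edge-list (and optionally node-role) TSV files
#'
#' Output is sorted, so `write_network()` followed by [read_network()] is a
#' byte-identical round trip.
#'
#' @param network a [kpnet_network()].
#' @param edge_path,node_path output paths; `node_path = NULL` skips roles.
#' @export
write_network <- function(network, edge_path, node_path = NULL) {
  write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(node_path)) {
    write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(network)
}

#' Read a node property table
#'
#' TSV with first column `id` and remaining columns numeric; `0/1`-only
#' columns are flagged binary (categorical). Empty cells are missing values.
#'
#' @param path path to the TSV.
#' @return data.frame with character `id` plus numeric columns; binary
#'   columns are marked in `attr(, "binary_columns")`.
#' @export
read_property_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE)
  if (ncol(raw) < 2 || names(raw)[1] != "id") {
    stop_kpnet("property table must start with an 'id' column",
               class = "kpnet_format_error")
  }
  if (anyDuplicated(raw$id)) {
    stop_kpnet("duplicated id '%s' in property table",
               raw$id[duplicated(raw$id)][1], class = "kpnet_format_error")
  }
  out <- data.frame(id = raw$id, stringsAsFactors = FALSE)
  binary <- character()
  for (cl in names(raw)[-1]) {
    v <- raw[[cl]]
    v[!nzchar(v)] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0) {
      stop_kpnet("non-numeric value '%s' in column '%s', row %d",
                 v[bad[1]], cl, bad[1], class = "kpnet_format_error")
    }
    if (all(num %in% c(0, 1) | is.na(num))) binary <- c(binary, cl)
    out[[cl]] <- num
  }
  attr(out, "binary_columns") <- binary
  out
}

#' Extract one property as a named vector
#'
#' @param tab a table from [read_property_table()] (or any data.frame with an
#'   `id` column).
#' @param column property column name.
#' @return named numeric vector (names = ids), `NA` for missing.
#' @export
property_vector <- function(tab, column) {
  if (!column %in% names(tab)) {
    stop_kpnet("no property column '%s'", column, class = "kpnet_format_error")
  }
  setNames(tab[[column]], tab$id)
}

#' Write a layer assignment with level spans to TSV
#'
#' @param partition a `kpnet_partition` from [classify_layers()] or
#'   [sort_network()].
#' @param levels a `kpnet_levels` data.frame from [vertex_sort()]; may omit
#'   substrate-layer nodes (their levels are written empty).
#' @param path output path.
#' @return the written data.frame, invisibly. Rows are ordered by layer
#'   (top, core, bottom, peripheral, substrates) then id, so re-runs are
#'   byte-identical.
#' @export
write_layers <- function(partition, levels, path) {
  layer_names <- c("top", "core", "bottom", "peripheral", "substrates")
  present <- layer_names[layer_names %in% names(partition)]
  rows <- do.call(rbind, lapply(present, function(l) {
    ids <- partition[[l]]
    if (length(ids) == 0) return(NULL)
    data.frame(id = sort(ids), layer = l, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(id = character(), layer = character(),
                       stringsAsFactors = FALSE)
  }
  span_ids <- levels$id
  orphan <- setdiff(span_ids, rows$id)
  if (length(orphan) > 0) {
    stop_kpnet("node '%s' has a level span but no layer", orphan[1],
               class = "kpnet_consistency_error")
  }
  idx <- match(rows$id, span_ids)
  rows$level_min <- levels$level_min[idx]
  rows$level_max <- levels$level_max[idx]
  rows <- rows[order(match(rows$layer, layer_names), rows$id), , drop = FALSE]
  rownames(rows) <- NULL
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(rows)
}
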