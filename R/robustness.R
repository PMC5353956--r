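#' Perturb a network by adding or deleting edges
#'
#' `mode = "delete"` removes `k` uniformly chosen rows of the signed edge
#' list (subsampled network, emulating false positives removed);
#' `mode = "add"` inserts `k` new arcs with enzyme sources and any-node
#' targets (noisy network, emulating missing interactions), never duplicating
#' an existing source-target pair nor creating a self-loop.
#'
#' @param network a [kpnet_network()].
#' @param mode `"add"` or `"delete"`.
#' @param k number of edges to add/remove.
#' @param seed RNG seed.
#' @param sources candidate sources for added edges (default: enzymes).
#' @return a perturbed [kpnet_network()].
#' @export
perturb_edges <- function(network, mode = c("add", "delete"), k,
                          seed = NULL, sources = NULL) {
  mode <- match.arg(mode)
  m <- nrow(network$edges)
  if (k < 0) stop_kpnet("k must be >= 0", class = "kpnet_argument_error")
  if (mode == "delete") {
    if (k > m) {
      stop_kpnet("cannot delete %d of %d edges", k, m,
                 class = "kpnet_argument_error")
    }
    with_seed(seed, {
      keep <- if (k == 0) seq_len(m) else
        setdiff(seq_len(m), sample.int(m, k))
      kpnet_network(network$edges[keep, , drop = FALSE], network$nodes,
                    validate_sources = FALSE)
    })
  } else {
    src_pool <- sources %||% enzyme_ids(network)
    if (length(src_pool) == 0) {
      stop_kpnet("no candidate sources for added edges",
                 class = "kpnet_argument_error")
    }
    nodes <- network$nodes$id
    existing <- arc_key(network$edges$source, network$edges$target)
    capacity <- length(src_pool) * (length(nodes) - 1) -
      length(unique(existing[network$edges$source %in% src_pool]))
    if (k > capacity) {
      stop_kpnet("cannot add %d edges (capacity %d)", k, capacity,
                 class = "kpnet_argument_error")
    }
    with_seed(seed, {
      keys <- new.env(hash = TRUE, parent = emptyenv())
      for (kk in unique(existing)) assign(kk, TRUE, envir = keys)
      add_from <- character(k); add_to <- character(k)
      placed <- 0L; attempts <- 0L
      while (placed < k) {
        attempts <- attempts + 1L
        if (attempts > 1000 * max(k, 1) + 10000) {
          stop_kpnet("edge-addition budget exhausted",
                     class = "kpnet_rigid_error")
        }
        s <- src_pool[sample.int(length(src_pool), 1)]
        t <- nodes[sample.int(length(nodes), 1)]
        if (s == t) next
        ky <- arc_key(s, t)
        if (exists(ky, envir = keys, inherits = FALSE)) next
        assign(ky, TRUE, envir = keys)
        placed <- placed + 1L
        add_from[placed] <- s; add_to[placed] <- t
      }
      edges <- rbind(network$edges,
                     data.frame(source = add_from, target = add_to,
                                itype = rep("P", length(add_from)),
                                stringsAsFactors = FALSE))
      kpnet_network(edges, network$nodes, validate_sources = FALSE)
    })
  }
}

#' Layer stability between two partitions
#'
#' Per layer, the Jaccard similarity `|intersection| / |union|` and a
#' hypergeometric overlap p-value with `k = |intersection|`,
#' `K = |original layer|`, `n = |perturbed layer|` and universe `N` the
#' sorted enzymes (top, core, bottom) present in both partitions.
#'
#' @param original,perturbed `kpnet_partition` objects.
#' @param layers layers to compare.
#' @return data.frame with columns `layer`, `jaccard`, `overlap`,
#'   `size_original`, `size_perturbed`, `p_overlap`.
#' @export
layer_stability <- function(original, perturbed,
                            layers = c("top", "core", "bottom")) {
  sorted_orig <- unlist(original[c("top", "core", "bottom")],
                        use.names = FALSE)
  sorted_pert <- unlist(perturbed[c("top", "core", "bottom")],
                        use.names = FALSE)
  universe <- intersect(sorted_orig, sorted_pert)
  N <- length(universe)
  out <- lapply(layers, function(l) {
    A <- original[[l]] %||% character(0)
    B <- perturbed[[l]] %||% character(0)
    if (length(A) == 0 || length(B) == 0) {
      warning(sprintf("layer '%s' empty in one partition", l))
      return(data.frame(layer = l, jaccard = 0, overlap = 0L,
                        size_original = length(A), size_perturbed = length(B),
                        p_overlap = NA_real_, stringsAsFactors = FALSE))
    }
    ov <- length(intersect(A, B))
    jac <- ov / length(union(A, B))
    Au <- intersect(A, universe)
    Bu <- intersect(B, universe)
    ovu <- length(intersect(Au, Bu))
    p <- if (N == 0) NA_real_ else {
      hypergeom_test(ovu, length(Au), length(Bu), N, "enrichment")$p
    }
    data.frame(layer = l, jaccard = jac, overlap = ov,
               size_original = length(A), size_perturbed = length(B),
               p_overlap = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Layer robustness suite against edge noise
#'
#' For every mode (add, delete) and perturbation size `k`, generates `reps`
#' perturbed networks, re-sorts each, and scores its layers against the
#' original with [layer_stability()]. Mean Jaccard per layer should decay
#' with `k`, and deletion should be gentler than addition on real signalling
#' networks.
#'
#' @param network a [kpnet_network()].
#' @param ks perturbation sizes (default 40, 80, 120, 160, 200 edges).
#' @param reps replicates per mode and size (default 100).
#' @param seed base seed.
#' @param modes subset of `c("add", "delete")`.
#' @param mode passed to [classify_layers()].
#' @return `kpnet_robustness`: list with `$per_replicate` (data.frame mode,
#'   k, rep, layer, jaccard, p_overlap) and `$summary` (mean Jaccard and mean
#'   p per mode x k x layer).
#' @export
robustness_suite <- function(network, ks = c(40, 80, 120, 160, 200),
                             reps = 100, seed = NULL,
                             modes = c("add", "delete"),
                             mode = c("path", "direct")) {
  mode <- match.arg(mode)
  base <- suppressWarnings(sort_network(network, mode = mode))$partition
  rows <- list()
  ri <- 0L
  for (pmode in modes) {
    for (k in ks) {
      for (r in seq_len(reps)) {
        ri <- ri + 1L
        s <- derive_seed(seed %||% 0, ri)
        pert <- perturb_edges(network, pmode, k, seed = s)
        part <- tryCatch(
          suppressWarnings(sort_network(pert, mode = mode))$partition,
          error = function(e) NULL)
        st <- if (is.null(part)) {
          data.frame(layer = c("top", "core", "bottom"), jaccard = 0,
                     overlap = 0L, size_original = NA, size_perturbed = 0L,
                     p_overlap = NA_real_, stringsAsFactors = FALSE)
        } else {
          suppressWarnings(layer_stability(base, part))
        }
        st$mode <- pmode; st$k <- k; st$rep <- r
        rows[[ri]] <- st
      }
    }
  }
  per <- do.call(rbind, rows)
  per <- per[c("mode", "k", "rep", "layer", "jaccard", "overlap",
               "size_original", "size_perturbed", "p_overlap")]
  summ <- aggregate(cbind(jaccard, p_overlap) ~ mode + k + layer, data = per,
                    FUN = function(v) mean(v, na.rm = TRUE), na.action = NULL)
  summ <- summ[order(summ$mode, summ$k, summ$layer), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(per_replicate = per, summary = summ, ks = ks, reps = reps,
                 seed = seed), class = "kpnet_robustness")
}

#' @export
print.kpnet_robustness <- function(x, ...) {
  cat(sprintf("robustness suite: ks = %s, %d reps\n",
              paste(x$ks, collapse = ","), x$reps))
  print(x$summary)
  invisible(x)
}
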