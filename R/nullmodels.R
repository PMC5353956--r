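# All randomizers take a kpnet_network and return a kpnet_network over the
# same node set (roles preserved). Randomization operates on the collapsed
# topology (unique arcs, no self-loops); regenerated edges that no longer
# carry a meaningful sign are written as "P" -- the sign plays no role in any
# topological statistic. Sources of randomized networks need not be enzymes
# (DNPR/ER deliberately ignore roles), so validation is relaxed.

arcs_to_network <- function(template, from, to, itype = NULL) {
  if (is.null(itype)) itype <- rep("P", length(from))
  kpnet_network(data.frame(source = from, target = to, itype = itype,
                           stringsAsFactors = FALSE),
                template$nodes, validate_sources = FALSE)
}

arc_key <- function(from, to) paste(from, to, sep = "\r")

#' Degree-preserving randomization (DPR)
#'
#' Repeatedly picks two arcs (a->b, c->d) and exchanges their ends to
#' (a->d, c->b). A proposal creating a self-loop or a duplicate arc is
#' rejected and does not count, so every node's in- and out-degree is
#' preserved exactly and the network stays simple. `n_swaps` accepted swaps
#' are performed.
#'
#' @param network a [kpnet_network()] with >= 2 arcs.
#' @param n_swaps accepted swap count (default 10000).
#' @param seed RNG seed.
#' @return a randomized [kpnet_network()].
#' @export
dpr <- function(network, n_swaps = 10000, seed = NULL) {
  topo <- topology(network)
  m <- nrow(topo$arcs)
  if (m < 2) {
    stop_kpnet("need at least 2 arcs to swap", class = "kpnet_argument_error")
  }
  with_seed(seed, {
    from <- topo$arcs$from
    to <- topo$arcs$to
    keys <- new.env(hash = TRUE, parent = emptyenv())
    for (k in arc_key(from, to)) assign(k, TRUE, envir = keys)
    accepted <- 0L
    attempts <- 0L
    max_attempts <- max(1000L, 200L * n_swaps)
    while (accepted < n_swaps) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop_kpnet(
          "network too rigid: %d swaps accepted after %d attempts",
          accepted, attempts - 1L, class = "kpnet_rigid_error")
      }
      ij <- sample.int(m, 2)
      i <- ij[1]; j <- ij[2]
      a <- from[i]; b <- to[i]; c_ <- from[j]; d <- to[j]
      if (a == d || c_ == b) next                 # self-loop
      k1 <- arc_key(a, d); k2 <- arc_key(c_, b)
      if (exists(k1, envir = keys, inherits = FALSE) ||
          exists(k2, envir = keys, inherits = FALSE)) next  # duplicate
      rm(list = c(arc_key(a, b), arc_key(c_, d)), envir = keys)
      assign(k1, TRUE, envir = keys)
      assign(k2, TRUE, envir = keys)
      to[i] <- d; to[j] <- b
      accepted <- accepted + 1L
    }
    arcs_to_network(network, from, to)
  })
}

#' Similar-degree-preserving randomization (SDPR)
#'
#' Draws a target degree sequence per node (independently for in and out)
#' uniformly from {d, d+1, max(d-1, 0)}, balances the stub totals, builds a
#' network with the squared-remaining-stubs matching algorithm, and finally
#' DPR-switches it. Every realized degree is within +-1 of the original.
#'
#' @inheritParams dpr
#' @param n_swaps accepted DPR swaps applied after matching.
#' @param max_restarts pairing-phase restarts before giving up.
#' @return a randomized [kpnet_network()].
#' @export
sdpr <- function(network, n_swaps = 10000, seed = NULL, max_restarts = 50) {
  topo <- topology(network)
  if (nrow(topo$arcs) == 0) {
    stop_kpnet("empty network", class = "kpnet_argument_error")
  }
  deg <- topology_degrees(topo)
  with_seed(seed, {
    nodes <- topo$nodes
    draw <- function(d) {
      vapply(d, function(di) {
        max(di + sample(c(0L, 1L, -1L), 1), 0L)
      }, integer(1))
    }
    repeat {
      din <- draw(deg$in_degree)
      dout <- draw(deg$out_degree)
      din <- balance_sequence(din, deg$in_degree, sum(dout))
      if (!is.null(din)) break
    }
    arcs <- NULL
    for (r in seq_len(max_restarts)) {
      arcs <- match_stubs(nodes, dout, din)
      if (!is.null(arcs)) break
    }
    if (is.null(arcs)) {
      stop_kpnet("matching failed after %d restarts", max_restarts,
                 class = "kpnet_rigid_error")
    }
    net <- arcs_to_network(network, arcs$from, arcs$to)
    if (nrow(net$edges) >= 2 && n_swaps > 0) {
      net <- dpr(net, n_swaps = n_swaps,
                 seed = sample.int(2147483587, 1))
    }
    net
  })
}

# Nudge `target` (each entry within +-1 of `orig`, >= 0) until it sums to
# `total`; NULL if impossible in a bounded number of moves.
balance_sequence <- function(target, orig, total) {
  for (step in seq_len(10000)) {
    diff <- sum(target) - total
    if (diff == 0) return(target)
    dir <- if (diff > 0) -1L else 1L
    ok <- which(abs(target + dir - orig) <= 1 & target + dir >= 0)
    if (length(ok) == 0) return(NULL)
    i <- ok[sample.int(length(ok), 1)]
    target[i] <- target[i] + dir
  }
  NULL
}

# Pair out-stubs with in-stubs, selection probability proportional to the
# square of each node's remaining stubs; rejects self-loops and duplicate
# arcs; NULL when it dead-ends (caller restarts).
match_stubs <- function(nodes, out_stubs, in_stubs) {
  rem_out <- out_stubs
  rem_in <- in_stubs
  n_arcs <- min(sum(rem_out), sum(rem_in))
  from <- character(n_arcs)
  to <- character(n_arcs)
  keys <- new.env(hash = TRUE, parent = emptyenv())
  for (e in seq_len(n_arcs)) {
    placed <- FALSE
    for (try in seq_len(500)) {
      src <- sample.int(length(nodes), 1, prob = rem_out^2)
      dst <- sample.int(length(nodes), 1, prob = rem_in^2)
      if (src == dst) next
      k <- arc_key(nodes[src], nodes[dst])
      if (exists(k, envir = keys, inherits = FALSE)) next
      assign(k, TRUE, envir = keys)
      from[e] <- nodes[src]; to[e] <- nodes[dst]
      rem_out[src] <- rem_out[src] - 1L
      rem_in[dst] <- rem_in[dst] - 1L
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  list(from = from, to = to)
}

#' In- or out-degree-preserving randomization (IDPR / ODPR)
#'
#' IDPR (`column = "from"`): keeps the target column (in-degrees exact) and
#' resamples sources with replacement from the enzymes. ODPR
#' (`column = "to"`): keeps the source column (out-degrees exact) and
#' resamples targets with replacement from all nodes. Duplicate arcs and
#' self-loops created by resampling are resolved by end-exchanges with
#' randomly chosen arcs (which leave both columns' multisets intact), and the
#' result is DPR-switched.
#'
#' @inheritParams dpr
#' @param column `"from"` (IDPR) or `"to"` (ODPR).
#' @param sources candidate sources for IDPR (default: the network's
#'   enzymes).
#' @param targets candidate targets for ODPR (default: all nodes).
#' @param n_swaps accepted DPR swaps applied afterwards.
#' @return a randomized [kpnet_network()].
#' @export
column_randomize <- function(network, column = c("from", "to"),
                             seed = NULL, sources = NULL, targets = NULL,
                             n_swaps = 10000) {
  column <- match.arg(column)
  topo <- topology(network)
  m <- nrow(topo$arcs)
  if (m == 0) stop_kpnet("empty network", class = "kpnet_argument_error")
  if (column == "from") {
    pool <- sources %||% enzyme_ids(network)
    if (length(pool) == 0) {
      stop_kpnet("no enzymes to sample sources from",
                 class = "kpnet_argument_error")
    }
  } else {
    pool <- targets %||% topo$nodes
  }
  with_seed(seed, {
    from <- topo$arcs$from
    to <- topo$arcs$to
    if (column == "from") {
      from <- sample(pool, m, replace = TRUE)
    } else {
      to <- sample(pool, m, replace = TRUE)
    }
    fixed <- resolve_conflicts(from, to)
    if (is.null(fixed)) {
      stop_kpnet("could not resolve duplicate arcs after resampling",
                 class = "kpnet_rigid_error")
    }
    net <- arcs_to_network(network, fixed$from, fixed$to)
    if (nrow(net$edges) >= 2 && n_swaps > 0) {
      net <- dpr(net, n_swaps = n_swaps, seed = sample.int(2147483587, 1))
    }
    net
  })
}

# Exchange ends of offending arcs (duplicates/self-loops) with random
# partners until the arc list is simple; preserves the multiset of each
# column. NULL when the retry budget is exhausted.
resolve_conflicts <- function(from, to, max_rounds = 200) {
  m <- length(from)
  for (round in seq_len(max_rounds)) {
    keys <- arc_key(from, to)
    bad <- which(duplicated(keys) | from == to)
    if (length(bad) == 0) return(list(from = from, to = to))
    for (i in bad) {
      j <- sample.int(m, 1)
      if (j == i) next
      tmp <- to[i]; to[i] <- to[j]; to[j] <- tmp
    }
  }
  NULL
}

#' Degree-non-preserving randomization (DNPR)
#'
#' Rebuilds the network from scratch: both endpoints of every arc are drawn
#' with replacement from the node set; collisions (duplicate arcs,
#' self-loops) are resampled until the original arc count is met. Node set
#' and arc count are preserved, degree sequences are not.
#'
#' @inheritParams dpr
#' @param sources optional restriction of candidate sources (e.g. enzymes
#'   only); default all nodes.
#' @return a randomized [kpnet_network()].
#' @export
dnpr <- function(network, seed = NULL, sources = NULL) {
  topo <- topology(network)
  nodes <- topo$nodes
  n <- length(nodes)
  m <- nrow(topo$arcs)
  if (n < 2) stop_kpnet("need >= 2 nodes", class = "kpnet_argument_error")
  src_pool <- sources %||% nodes
  max_m <- length(src_pool) * (n - 1)
  if (m > max_m) {
    stop_kpnet("arc count %d exceeds capacity %d", m, max_m,
               class = "kpnet_argument_error")
  }
  with_seed(seed, {
    from <- character(m); to <- character(m)
    keys <- new.env(hash = TRUE, parent = emptyenv())
    placed <- 0L
    attempts <- 0L
    while (placed < m) {
      attempts <- attempts + 1L
      if (attempts > 1000 * m + 10000) {
        stop_kpnet("DNPR resampling budget exhausted",
                   class = "kpnet_rigid_error")
      }
      s <- src_pool[sample.int(length(src_pool), 1)]
      t <- nodes[sample.int(n, 1)]
      if (s == t) next
      k <- arc_key(s, t)
      if (exists(k, envir = keys, inherits = FALSE)) next
      assign(k, TRUE, envir = keys)
      placed <- placed + 1L
      from[placed] <- s; to[placed] <- t
    }
    arcs_to_network(network, from, to)
  })
}

#' Uniform Erdos-Renyi directed graph with a fixed arc count
#'
#' Samples exactly `n_arcs` distinct ordered pairs (no self-loops) uniformly
#' among all simple directed graphs with `n_nodes` nodes and `n_arcs` arcs.
#'
#' @param n_nodes node count (nodes are named `v001`, ... unless `nodes` is
#'   given).
#' @param n_arcs arc count, at most `n_nodes * (n_nodes - 1)`.
#' @param seed RNG seed.
#' @param nodes optional node id vector (length `n_nodes`).
#' @param roles optional role vector aligned with `nodes`.
#' @return a [kpnet_network()] (roles default to `"kinase"` so the graph is
#'   its own enzyme subgraph).
#' @export
erdos_renyi <- function(n_nodes, n_arcs, seed = NULL, nodes = NULL,
                        roles = NULL) {
  if (n_arcs > n_nodes * (n_nodes - 1)) {
    stop_kpnet("arc count %d infeasible for %d nodes", n_arcs, n_nodes,
               class = "kpnet_argument_error")
  }
  if (is.null(nodes)) {
    nodes <- sprintf("v%0*d", nchar(as.character(n_nodes)), seq_len(n_nodes))
  }
  if (is.null(roles)) roles <- rep("kinase", n_nodes)
  with_seed(seed, {
    idx <- sample.int(n_nodes * (n_nodes - 1), n_arcs)
    # Enumerate ordered pairs (i, j), i != j: row i owns n_nodes - 1 slots.
    i <- (idx - 1) %/% (n_nodes - 1) + 1
    jj <- (idx - 1) %% (n_nodes - 1) + 1
    j <- ifelse(jj >= i, jj + 1, jj)
    kpnet_network(
      data.frame(source = nodes[i], target = nodes[j], itype = "P",
                 stringsAsFactors = FALSE),
      data.frame(id = nodes, role = roles, stringsAsFactors = FALSE),
      validate_sources = FALSE)
  })
}

#' Generate one randomized replicate under a named scheme
#'
#' @param network a [kpnet_network()].
#' @param scheme one of `"DPR"`, `"SDPR"`, `"IDPR"`, `"ODPR"`, `"DNPR"`,
#'   `"ER"` (case-insensitive).
#' @param seed RNG seed.
#' @param n_swaps swap budget for the DPR-based schemes.
#' @return a randomized [kpnet_network()].
#' @export
randomize_network <- function(network, scheme, seed = NULL, n_swaps = 10000) {
  scheme <- toupper(scheme)
  topo <- topology(network)
  switch(scheme,
    DPR = dpr(network, n_swaps = n_swaps, seed = seed),
    SDPR = sdpr(network, n_swaps = n_swaps, seed = seed),
    IDPR = column_randomize(network, "from", seed = seed, n_swaps = n_swaps),
    ODPR = column_randomize(network, "to", seed = seed, n_swaps = n_swaps),
    DNPR = dnpr(network, seed = seed),
    ER = erdos_renyi(length(topo$nodes), nrow(topo$arcs), seed = seed,
                     nodes = topo$nodes,
                     roles = node_roles(network)[topo$nodes]),
    stop_kpnet("unknown randomization scheme '%s'", scheme,
               class = "kpnet_argument_error"))
}

#' Empirical p-value of a network statistic against a null-model ensemble
#'
#' Generates `n_reps` randomized replicates under `scheme` (replicate i uses
#' a seed derived deterministically from `seed` and i) and reports
#' `p = #{replicates with statistic >= observed} / n_reps` for `tail = "ge"`
#' (`<=` for `"le"`), plus a null summary.
#'
#' @param network a [kpnet_network()].
#' @param statistic function network -> single numeric.
#' @param scheme passed to [randomize_network()].
#' @param n_reps replicate count (>= 1).
#' @param seed base seed.
#' @param tail `"ge"` or `"le"`.
#' @param n_swaps swap budget for DPR-based schemes.
#' @return `kpnet_empirical_p`: list with `$observed`, `$p`, `$tail`,
#'   `$null_values`, `$null_mean`, `$null_sd`, `$null_quantiles`, `$scheme`,
#'   `$n_reps`, `$seed`.
#' @export
empirical_pvalue <- function(network, statistic, scheme, n_reps = 1000,
                             seed = NULL, tail = c("ge", "le"),
                             n_swaps = 10000) {
  tail <- match.arg(tail)
  if (n_reps < 1) {
    stop_kpnet("n_reps must be >= 1", class = "kpnet_argument_error")
  }
  observed <- statistic(network)
  null_values <- vapply(seq_len(n_reps), function(i) {
    statistic(randomize_network(network, scheme,
                                seed = derive_seed(seed %||% 0, i),
                                n_swaps = n_swaps))
  }, numeric(1))
  p <- if (tail == "ge") mean(null_values >= observed)
       else mean(null_values <= observed)
  structure(list(observed = observed, p = p, tail = tail,
                 null_values = null_values,
                 null_mean = mean(null_values), null_sd = sd(null_values),
                 null_quantiles = quantile(null_values,
                                           c(0.025, 0.5, 0.975)),
                 scheme = toupper(scheme), n_reps = n_reps, seed = seed),
            class = "kpnet_empirical_p")
}

#' @export
print.kpnet_empirical_p <- function(x, ...) {
  cat(sprintf(
    "empirical p (%s, %d reps, tail %s): observed=%.4g, null %.4g +- %.4g, p=%.4g\n",
    x$scheme, x$n_reps, x$tail, x$observed, x$null_mean, x$null_sd, x$p))
  invisible(x)
}
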