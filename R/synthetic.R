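# Generators for self-contained testing: planted bow-tie networks with a
# known ground-truth partition, scale-free directed networks, and
# layer-structured Gaussian property tables.

#' Specification of a planted bow-tie network
#'
#' @param n_top,n_core,n_bottom,n_peripheral,n_substrates layer sizes
#'   (core >= 1; peripheral nodes need bottom or substrate nodes to attach
#'   to).
#' @param p_core_extra probability of each extra core-internal arc beyond the
#'   Hamiltonian cycle.
#' @param p_top_core,p_core_bottom probability of each optional extra
#'   top->core / core->bottom arc beyond the guaranteed one per node.
#' @param p_substrate probability that a given enzyme targets a given
#'   substrate.
#' @param p_phosphatase probability that an enzyme is a phosphatase rather
#'   than a kinase.
#' @return `kpnet_planted_spec` list.
#' @export
planted_spec <- function(n_top = 10, n_core = 6, n_bottom = 10,
                         n_peripheral = 3, n_substrates = 20,
                         p_core_extra = 0.3, p_top_core = 0.15,
                         p_core_bottom = 0.15, p_substrate = 0.1,
                         p_phosphatase = 0.25) {
  if (n_core < 1) stop_kpnet("n_core must be >= 1",
                             class = "kpnet_argument_error")
  if (n_peripheral > 0 && n_bottom == 0 && n_substrates == 0) {
    stop_kpnet("peripheral nodes need bottom or substrate nodes to attach to",
               class = "kpnet_argument_error")
  }
  probs <- c(p_core_extra, p_top_core, p_core_bottom, p_substrate,
             p_phosphatase)
  if (any(probs < 0 | probs > 1)) {
    stop_kpnet("probabilities must be in [0, 1]",
               class = "kpnet_argument_error")
  }
  structure(list(n_top = n_top, n_core = n_core, n_bottom = n_bottom,
                 n_peripheral = n_peripheral, n_substrates = n_substrates,
                 p_core_extra = p_core_extra, p_top_core = p_top_core,
                 p_core_bottom = p_core_bottom, p_substrate = p_substrate,
                 p_phosphatase = p_phosphatase),
            class = "kpnet_planted_spec")
}

#' Generate a planted bow-tie network with its ground-truth partition
#'
#' The core is arranged on a directed Hamiltonian cycle (strong connectivity
#' guaranteed) plus random extra internal arcs. Deterministic base
#' attachments -- top node i targets core node ((i-1) mod n_core)+1, bottom
#' node j is targeted by core node (j mod n_core)+1, peripheral node j
#' targets bottom node ((j-1) mod n_bottom)+1 -- guarantee every top node a
#' path into the core and every bottom node a path from it; random extra arcs
#' are layered on top. With all probabilities 0 the construction is fully
#' deterministic: `planted_spec(2, 3, 2, 1, 0, 0, 0, 0, 0, 0)` is the
#' T1->C1, T2->C2, C1->C2->C3->C1, C2->B1, C3->B2, X1->B1 toy.
#'
#' @param spec a [planted_spec()].
#' @param seed RNG seed.
#' @return list with `$network` ([kpnet_network()]) and `$truth`
#'   (`kpnet_partition` with `$top`, `$core`, `$bottom`, `$peripheral`,
#'   `$substrates`).
#' @export
gen_planted_bowtie <- function(spec = planted_spec(), seed = NULL) {
  stopifnot(inherits(spec, "kpnet_planted_spec"))
  ids <- function(prefix, n) if (n > 0) paste0(prefix, seq_len(n))
                             else character(0)
  top <- ids("T", spec$n_top)
  core <- ids("C", spec$n_core)
  bottom <- ids("B", spec$n_bottom)
  peri <- ids("X", spec$n_peripheral)
  subs <- ids("S", spec$n_substrates)
  enz <- c(top, core, bottom, peri)
  with_seed(seed, {
    from <- character(0); to <- character(0)
    add <- function(f, t) {
      from <<- c(from, f); to <<- c(to, t)
    }
    nc <- spec$n_core
    if (nc > 1) {
      add(core, core[c(2:nc, 1)])                       # Hamiltonian cycle
      extra <- expand.grid(f = core, t = core, stringsAsFactors = FALSE)
      extra <- extra[extra$f != extra$t, ]
      pick <- runif(nrow(extra)) < spec$p_core_extra
      add(extra$f[pick], extra$t[pick])
    }
    if (spec$n_top > 0) {
      add(top, core[(seq_len(spec$n_top) - 1) %% nc + 1])
      extra <- expand.grid(f = top, t = core, stringsAsFactors = FALSE)
      pick <- runif(nrow(extra)) < spec$p_top_core
      add(extra$f[pick], extra$t[pick])
    }
    if (spec$n_bottom > 0) {
      add(core[seq_len(spec$n_bottom) %% nc + 1], bottom)
      extra <- expand.grid(f = core, t = bottom, stringsAsFactors = FALSE)
      pick <- runif(nrow(extra)) < spec$p_core_bottom
      add(extra$f[pick], extra$t[pick])
    }
    if (spec$n_peripheral > 0) {
      anchors <- if (spec$n_bottom > 0) {
        bottom[(seq_len(spec$n_peripheral) - 1) %% spec$n_bottom + 1]
      } else {
        subs[(seq_len(spec$n_peripheral) - 1) %% spec$n_substrates + 1]
      }
      add(peri, anchors)
    }
    if (spec$n_substrates > 0) {
      extra <- expand.grid(f = enz, t = subs, stringsAsFactors = FALSE)
      pick <- runif(nrow(extra)) < spec$p_substrate
      add(extra$f[pick], extra$t[pick])
    }
    roles <- c(
      ifelse(runif(length(enz)) < spec$p_phosphatase, "phosphatase",
             "kinase"),
      rep("other", length(subs)))
    itype <- ifelse(
      setNames(roles[seq_along(enz)], enz)[from] == "phosphatase", "D", "P")
    edges <- unique(data.frame(source = from, target = to, itype = itype,
                               stringsAsFactors = FALSE))
    net <- kpnet_network(edges,
                         data.frame(id = c(enz, subs), role = roles,
                                    stringsAsFactors = FALSE))
    truth <- structure(list(top = sort(top), core = sort(core),
                            bottom = sort(bottom), peripheral = sort(peri),
                            substrates = sort(subs)),
                       class = "kpnet_partition")
    list(network = net, truth = truth)
  })
}

#' Generate a scale-free directed network
#'
#' Out-degrees are drawn from the discrete power law P(k) ~ k^-gamma
#' (k >= 1, truncated at n-1); targets are uniform, with duplicate arcs and
#' self-loops resampled. Nodes are all kinases, so the graph is its own
#' enzyme subgraph.
#'
#' @param n_nodes node count (>= 10).
#' @param gamma power-law exponent (> 1).
#' @param seed RNG seed.
#' @return a [kpnet_network()].
#' @export
gen_powerlaw_network <- function(n_nodes, gamma, seed = NULL) {
  if (n_nodes < 10) stop_kpnet("n_nodes must be >= 10",
                               class = "kpnet_argument_error")
  if (gamma <= 1) stop_kpnet("gamma must be > 1",
                             class = "kpnet_argument_error")
  nodes <- sprintf("n%0*d", nchar(as.character(n_nodes)), seq_len(n_nodes))
  with_seed(seed, {
    degs <- rpowerlaw(n_nodes, gamma, xmin = 1, cap = n_nodes - 1)
    from <- character(0); to <- character(0)
    for (i in seq_len(n_nodes)) {
      k <- degs[i]
      tries <- 0
      targets <- character(0)
      while (length(targets) < k && tries < 100) {
        tries <- tries + 1
        cand <- nodes[sample.int(n_nodes, k - length(targets),
                                 replace = TRUE)]
        cand <- setdiff(unique(cand), c(nodes[i], targets))
        targets <- c(targets, cand)
      }
      from <- c(from, rep(nodes[i], length(targets)))
      to <- c(to, targets)
    }
    kpnet_network(
      data.frame(source = from, target = to, itype = "P",
                 stringsAsFactors = FALSE),
      data.frame(id = nodes, role = "kinase", stringsAsFactors = FALSE))
  })
}

#' Generate a layer-structured Gaussian property table
#'
#' Draws one property value per enzyme from a Gaussian with layer-specific
#' mean and standard deviation, then masks a fraction of values as missing --
#' a stylized stand-in for the incomplete biological property compilations
#' the randomization and profile tests consume.
#'
#' @param partition a `kpnet_partition`.
#' @param means,sds named numeric vectors (per layer); unnamed scalars
#'   recycle.
#' @param missing_fraction fraction of values set to `NA`.
#' @param seed RNG seed.
#' @param column property column name.
#' @return property data.frame (as from [read_property_table()]).
#' @export
gen_layer_properties <- function(partition,
                                 means = c(top = 1, core = 0, bottom = -1),
                                 sds = 1, missing_fraction = 0,
                                 seed = NULL, column = "property") {
  layers <- intersect(c("top", "core", "bottom", "peripheral"),
                      names(partition))
  get_par <- function(par, l, default) {
    if (length(par) == 1 && is.null(names(par))) return(par)
    if (l %in% names(par)) return(par[[l]])
    default
  }
  if (any(unlist(sds) < 0)) {
    stop_kpnet("negative standard deviation", class = "kpnet_argument_error")
  }
  if (missing_fraction < 0 || missing_fraction > 1) {
    stop_kpnet("missing_fraction must be in [0, 1]",
               class = "kpnet_argument_error")
  }
  with_seed(seed, {
    ids <- character(0); vals <- numeric(0)
    for (l in layers) {
      nodes <- partition[[l]]
      if (length(nodes) == 0) next
      ids <- c(ids, nodes)
      vals <- c(vals, stats::rnorm(length(nodes), get_par(means, l, 0),
                                   get_par(sds, l, 1)))
    }
    if (missing_fraction > 0 && length(vals) > 0) {
      nmiss <- round(missing_fraction * length(vals))
      if (nmiss > 0) vals[sample.int(length(vals), nmiss)] <- NA_real_
    }
    out <- data.frame(id = ids, stringsAsFactors = FALSE)
    out[[column]] <- vals
    out <- out[order(out$id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
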