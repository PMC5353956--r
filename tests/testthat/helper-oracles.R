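# Brute-force oracles, written independently of the package internals (and
# of igraph): adjacency matrices and explicit enumeration throughout.

# Random simple directed topology (no self-loops) as a kpnet_topology.
rand_topo <- function(n, p, seed) {
  set.seed(seed)
  M <- matrix(runif(n * n) < p, n, n)
  diag(M) <- FALSE
  ids <- sprintf("n%02d", seq_len(n))
  arcs <- which(M, arr.ind = TRUE)
  new_toy_topology(sprintf("%s %s", ids[arcs[, 1]], ids[arcs[, 2]]),
                   nodes = ids)
}

topo_adjacency <- function(topo) {
  n <- length(topo$nodes)
  M <- matrix(0L, n, n, dimnames = list(topo$nodes, topo$nodes))
  if (nrow(topo$arcs) > 0) M[cbind(topo$arcs$from, topo$arcs$to)] <- 1L
  M
}

# Floyd-Warshall boolean transitive closure (reachability by >= 1 arc).
closure_oracle <- function(topo) {
  M <- topo_adjacency(topo) > 0
  n <- nrow(M)
  for (k in seq_len(n)) {
    M <- M | (M[, k] %o% M[k, ])
  }
  M
}

# SCCs as equivalence classes of pairwise mutual reachability.
scc_oracle <- function(topo) {
  R <- closure_oracle(topo)
  n <- nrow(R)
  mutual <- (R & t(R)) | diag(TRUE, n)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[mutual[i, ]] <- cid
    }
  }
  split(topo$nodes, comp)
}

# Longest directed path length in a DAG (DP over adjacency powers: the
# largest L with any walk of length L; in a DAG walks are paths).
longest_path_oracle <- function(topo) {
  A <- topo_adjacency(topo)
  if (sum(A) == 0) return(0)
  P <- A
  L <- 0
  repeat {
    if (sum(P) == 0) return(L)
    L <- L + 1
    P <- P %*% A
    if (L > nrow(A)) stop("not a DAG")
  }
}

# Min-plus shortest distances; Inf when unreachable.
dist_oracle <- function(topo) {
  A <- topo_adjacency(topo)
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

# Betweenness by explicit shortest-path counting: walks of length d(s, t)
# are exactly the shortest paths, so sigma = (A^d)[s, t].
betweenness_oracle <- function(topo) {
  A <- topo_adjacency(topo)
  n <- nrow(A)
  D <- dist_oracle(topo)
  maxd <- max(D[is.finite(D)])
  powers <- vector("list", maxd + 1)
  powers[[1]] <- diag(1, n)                       # A^0
  for (L in seq_len(maxd)) powers[[L + 1]] <- powers[[L]] %*% A
  sigma <- function(s, t) {
    d <- D[s, t]
    if (!is.finite(d)) return(0)
    powers[[d + 1]][s, t]
  }
  bw <- setNames(numeric(n), topo$nodes)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(D[s, t])) next
    st <- sigma(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        bw[v] <- bw[v] + sigma(s, v) * sigma(v, t) / st
      }
    }
  }
  bw
}

# Motif counts by exhaustive enumeration over ordered tuples.
motif_oracle <- function(topo) {
  A <- topo_adjacency(topo) > 0
  n <- nrow(A)
  ffl <- 0L; fbl2 <- 0L; bifan <- 0L
  if (n >= 3) {
    for (a in 1:n) for (b in 1:n) for (c in 1:n) {
      if (a != b && b != c && a != c &&
          A[a, b] && A[b, c] && A[a, c]) ffl <- ffl + 1L
    }
  }
  if (n >= 2) {
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (A[a, b] && A[b, a]) fbl2 <- fbl2 + 1L
    }
  }
  if (n >= 4) {
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      for (c in 1:(n - 1)) for (d in (c + 1):n) {
        if (length(unique(c(a, b, c, d))) == 4 &&
            A[a, c] && A[a, d] && A[b, c] && A[b, d]) bifan <- bifan + 1L
      }
    }
  }
  list(ffl = ffl, fbl2 = fbl2, bifan = bifan)
}

# Hypergeometric tail by exact combinatorial summation.
hyper_oracle <- function(k, K, n, N, direction) {
  js <- max(0, n + K - N):min(n, K)
  mass <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  if (direction == "enrichment") sum(mass[js >= k]) else sum(mass[js <= k])
}

# Exact permutation p for a difference of means, by bitmask enumeration.
perm_oracle <- function(a, b, alternative) {
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  obs <- mean(a) - mean(b)
  diffs <- numeric(0)
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) != na) next
    diffs <- c(diffs, mean(pool[sel]) - mean(pool[-sel]))
  }
  eps <- 1e-12
  switch(alternative,
         greater = mean(diffs >= obs - eps),
         less = mean(diffs <= obs + eps),
         two_sided = mean(abs(diffs) >= abs(obs) - eps))
}

# Degrees straight off the arc table.
degree_oracle <- function(net) {
  topo <- topology(net)
  list(
    in_deg = vapply(topo$nodes,
                    function(v) sum(topo$arcs$to == v), integer(1)),
    out_deg = vapply(topo$nodes,
                     function(v) sum(topo$arcs$from == v), integer(1)))
}

expect_simple_arcs <- function(net) {
  topo <- topology(net, drop_self_loops = FALSE)
  expect_false(any(topo$arcs$from == topo$arcs$to))
  expect_false(any(duplicated(topo$arcs[c("from", "to")])))
}
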