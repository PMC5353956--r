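#' Randomization (permutation) test for a difference of group means
#'
#' Pools the two groups, redraws groups of the original sizes without
#' replacement `n_resamples` times, and reports the fraction of resampled
#' mean differences at least as extreme as the observed one. With
#' `alternative = "auto"` (default) the test is one-sided in the direction of
#' the observed difference, which is recorded in the result. `exact = TRUE`
#' (or small pools, see `exact_limit`) enumerates every split instead of
#' sampling, giving the exact permutation p-value.
#'
#' @param values_a,values_b numeric vectors; `NA`s are dropped.
#' @param n_resamples resample count (default 10000).
#' @param alternative `"auto"`, `"greater"`, `"less"` or `"two_sided"`
#'   (difference = mean(A) - mean(B)).
#' @param seed RNG seed.
#' @param exact force exhaustive enumeration of all splits.
#' @param exact_limit enumerate automatically when the number of splits is at
#'   most this (default 5000).
#' @return `kpnet_rt`: list with `$observed` (mean difference), `$p`,
#'   `$alternative` (resolved direction), `$n_resamples` (actual), `$exact`,
#'   `$n_a`, `$n_b`, `$seed`.
#' @export
randomization_test <- function(values_a, values_b, n_resamples = 10000,
                               alternative = c("auto", "greater", "less",
                                               "two_sided"),
                               seed = NULL, exact = FALSE,
                               exact_limit = 5000) {
  alternative <- match.arg(alternative)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) == 0 || length(b) == 0) {
    side <- if (length(a) == 0) "first" else "second"
    stop_kpnet("%s group is empty after removing missing values", side,
               class = "kpnet_argument_error")
  }
  obs <- mean(a) - mean(b)
  if (alternative == "auto") {
    alternative <- if (obs >= 0) "greater" else "less"
  }
  pool <- c(a, b)
  na <- length(a)
  n <- length(pool)
  total <- sum(pool)
  n_splits <- choose(n, na)
  use_exact <- exact || n_splits <= exact_limit
  diffs <- if (use_exact) {
    idx <- combn(n, na)
    sa <- colSums(matrix(pool[idx], nrow = na))
    sa / na - (total - sa) / (n - na)
  } else {
    with_seed(seed, {
      vapply(seq_len(n_resamples), function(i) {
        s <- sample.int(n, na)
        sa <- sum(pool[s])
        sa / na - (total - sa) / (n - na)
      }, numeric(1))
    })
  }
  eps <- 1e-12 * (1 + abs(obs))   # guard |a-b| float noise in comparisons
  p <- switch(alternative,
    greater = mean(diffs >= obs - eps),
    less = mean(diffs <= obs + eps),
    two_sided = mean(abs(diffs) >= abs(obs) - eps))
  structure(list(observed = obs, p = p, alternative = alternative,
                 n_resamples = length(diffs), exact = use_exact,
                 n_a = na, n_b = n - na, seed = seed),
            class = "kpnet_rt")
}

#' @export
print.kpnet_rt <- function(x, ...) {
  cat(sprintf("RT (%s, %s%d resamples): diff=%.4g, p=%.4g\n",
              x$alternative, if (x$exact) "exact, " else "", x$n_resamples,
              x$observed, x$p))
  invisible(x)
}

#' Hypergeometric enrichment / depletion test
#'
#' With `k` successes in a selection of size `n`, `K` successes in a universe
#' of size `N`, enrichment is `P(X >= k)` and depletion `P(X <= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k successes in selection.
#' @param K successes in universe.
#' @param n selection size.
#' @param N universe size.
#' @param direction `"enrichment"` or `"depletion"`.
#' @return `kpnet_ht`: list with `$k`, `$K`, `$n`, `$N`, `$direction`, `$p`,
#'   `$expected` (n*K/N).
#' @export
hypergeom_test <- function(k, K, n, N,
                           direction = c("enrichment", "depletion")) {
  direction <- match.arg(direction)
  if (K < 0 || K > N || n < 0 || n > N ||
      k < max(0, n + K - N) || k > min(n, K)) {
    stop_kpnet("infeasible hypergeometric configuration (k=%d K=%d n=%d N=%d)",
               k, K, n, N, class = "kpnet_argument_error")
  }
  p <- if (direction == "enrichment") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    phyper(k, K, N - K, n)
  }
  structure(list(k = k, K = K, n = n, N = N, direction = direction, p = p,
                 expected = n * K / N), class = "kpnet_ht")
}

#' @export
print.kpnet_ht <- function(x, ...) {
  cat(sprintf("HT %s: k=%d (expected %.2f), K=%d, n=%d, N=%d, p=%.4g\n",
              x$direction, x$k, x$expected, x$K, x$n, x$N, x$p))
  invisible(x)
}

#' Spearman association between a node property and node degree
#'
#' Rank correlation with a permutation p-value (two-sided): the property is
#' permuted against the degrees `n_perm` times.
#'
#' @param property,degree numeric vectors; paired by name when both are
#'   named, positionally otherwise. Pairs with a missing value are dropped.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return `kpnet_assoc`: list with `$rho`, `$p`, `$n`, `$n_perm`.
#' @export
degree_association <- function(property, degree, n_perm = 10000,
                               seed = NULL) {
  if (!is.null(names(property)) && !is.null(names(degree))) {
    common <- intersect(names(property), names(degree))
    property <- property[common]
    degree <- degree[common]
  }
  keep <- !is.na(property) & !is.na(degree)
  x <- property[keep]
  y <- degree[keep]
  if (length(x) < 5) {
    stop_kpnet("need >= 5 paired observations", class = "kpnet_argument_error")
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop_kpnet("constant input: rank correlation undefined",
               class = "kpnet_argument_error")
  }
  rho <- cor(x, y, method = "spearman")
  ry <- rank(y)
  p <- with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) {
      cor(rank(sample(x)), ry)
    }, numeric(1))
    mean(abs(perm) >= abs(rho) - 1e-12)
  })
  structure(list(rho = rho, p = p, n = length(x), n_perm = n_perm),
            class = "kpnet_assoc")
}

#' @export
print.kpnet_assoc <- function(x, ...) {
  cat(sprintf("Spearman rho=%.3f (n=%d), permutation p=%.4g (%d perms)\n",
              x$rho, x$n, x$p, x$n_perm))
  invisible(x)
}

#' Layer profile of a property over a randomized-network ensemble
#'
#' For each replicate: randomize the network under `scheme`, sort it,
#' classify its bow-tie layers, and average the property over each layer's
#' enzymes. Reports the across-replicate mean and percentile 95% confidence
#' interval per layer, next to the observed network's layer means. A flat
#' profile under DNPR is the signature of a property the vertex sort itself
#' does not impose.
#'
#' @param network a [kpnet_network()].
#' @param property named numeric vector over (at least the) enzymes; `NA`
#'   allowed. Special strings `"in_degree"` / `"out_degree"` use the
#'   replicate's own degrees (degree-type properties follow the randomized
#'   topology, biological properties follow the node id).
#' @param scheme passed to [randomize_network()].
#' @param n_reps replicate count (default 1000).
#' @param seed base seed.
#' @param layers layers to profile.
#' @param n_swaps swap budget for DPR-based schemes.
#' @return `kpnet_layer_profile`: list with `$summary` (data.frame layer,
#'   null_mean, ci_lo, ci_hi, observed), `$replicates` (matrix reps x
#'   layers), `$scheme`, `$n_reps`, `$seed`.
#' @export
layer_profile <- function(network, property, scheme, n_reps = 1000,
                          seed = NULL, layers = c("top", "core", "bottom"),
                          n_swaps = 10000) {
  degree_prop <- is.character(property) && length(property) == 1 &&
    property %in% c("in_degree", "out_degree")
  prop_of <- function(net) {
    if (!degree_prop) return(property)
    node_degrees(net, mode = sub("_degree", "", property))
  }
  layer_means <- function(net) {
    part <- tryCatch(
      suppressWarnings(sort_network(net)$partition),
      error = function(e) NULL)
    pv <- prop_of(net)
    vapply(layers, function(l) {
      ids <- intersect(part[[l]] %||% character(0), names(pv))
      v <- pv[ids]
      if (length(v) == 0 || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  observed <- layer_means(network)
  reps <- t(vapply(seq_len(n_reps), function(i) {
    layer_means(randomize_network(network, scheme,
                                  seed = derive_seed(seed %||% 0, i),
                                  n_swaps = n_swaps))
  }, numeric(length(layers))))
  colnames(reps) <- layers
  summ <- data.frame(
    layer = layers,
    null_mean = colMeans(reps, na.rm = TRUE),
    ci_lo = apply(reps, 2, quantile, 0.025, na.rm = TRUE),
    ci_hi = apply(reps, 2, quantile, 0.975, na.rm = TRUE),
    observed = unname(observed),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  structure(list(summary = summ, replicates = reps,
                 scheme = toupper(scheme), n_reps = n_reps, seed = seed),
            class = "kpnet_layer_profile")
}

#' @export
print.kpnet_layer_profile <- function(x, ...) {
  cat(sprintf("layer profile (%s, %d reps):\n", x$scheme, x$n_reps))
  print(x$summary)
  invisible(x)
}
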