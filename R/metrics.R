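#' Directed shortest-path betweenness
#'
#' For each node v, the sum over ordered pairs (s, t), s != t != v, of the
#' fraction of shortest s -> t paths passing through v. The raw sum is what
#' the bottleneck definition uses; a normalized version (divided by
#' (n-1)(n-2)) is also returned.
#'
#' @param x a [kpnet_network()] or `kpnet_topology`.
#' @return data.frame with columns `id`, `betweenness` (raw), `normalized`.
#' @export
betweenness_scores <- function(x) {
  topo <- topology(x)
  g <- as_igraph(topo)
  raw <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  n <- length(topo$nodes)
  norm <- if (n > 2) raw / ((n - 1) * (n - 2)) else raw * 0
  data.frame(id = topo$nodes, betweenness = unname(raw[topo$nodes]),
             normalized = unname(norm[topo$nodes]),
             stringsAsFactors = FALSE)
}

#' Select the top fraction of nodes by score
#'
#' Hubs are the top 20% of enzymes by degree; bottlenecks the top 20% by
#' betweenness. The selection size is `floor(fraction * n)`; ties at the cut
#' are broken by smaller id so the selection is deterministic.
#'
#' @param scores named numeric vector (names = node ids).
#' @param fraction in (0, 1].
#' @return sorted character vector of selected ids.
#' @export
select_top_fraction <- function(scores, fraction = 0.2) {
  if (length(scores) == 0) {
    stop_kpnet("empty score table", class = "kpnet_argument_error")
  }
  if (!(fraction > 0 && fraction <= 1)) {
    stop_kpnet("fraction must be in (0, 1]", class = "kpnet_argument_error")
  }
  k <- floor(fraction * length(scores))
  if (k == 0) return(character(0))
  ord <- order(-scores, names(scores))
  sort(names(scores)[ord][seq_len(k)])
}

#' Count feed-forward loops, 2-node feedback loops and bi-fans
#'
#' FFL: ordered triples (A, B, C) of distinct nodes with arcs A->B, B->C,
#' A->C. 2-node feedback loop: unordered pairs with arcs both ways. Bi-fan:
#' unordered source pairs {A, B} times unordered target pairs {C, D}, four
#' distinct nodes, with all of A->C, A->D, B->C, B->D.
#'
#' @param x a [kpnet_network()] or `kpnet_topology`; self-loops are dropped.
#' @return `kpnet_motifs`: list with integer `$ffl`, `$fbl2`, `$bifan`.
#' @export
count_motifs <- function(x) {
  topo <- topology(x)
  n <- length(topo$nodes)
  M <- matrix(0L, n, n)
  if (nrow(topo$arcs) > 0) {
    M[cbind(match(topo$arcs$from, topo$nodes),
            match(topo$arcs$to, topo$nodes))] <- 1L
  }
  diag(M) <- 0L
  M2 <- M %*% M
  ffl <- sum(M2 * M)
  fbl2 <- sum(M * t(M)) / 2
  common <- M %*% t(M)                 # common out-neighbours per source pair
  cu <- common[upper.tri(common)]
  bifan <- sum(choose(cu, 2))
  structure(list(ffl = as.integer(ffl), fbl2 = as.integer(fbl2),
                 bifan = as.integer(round(bifan))), class = "kpnet_motifs")
}

#' @export
print.kpnet_motifs <- function(x, ...) {
  cat(sprintf("motifs: ffl=%d, fbl2=%d, bifan=%d\n", x$ffl, x$fbl2, x$bifan))
  invisible(x)
}

# Hurwitz zeta sum_{k>=a} k^-s via truncated sum plus Euler-Maclaurin tail.
hurwitz_zeta <- function(s, a) {
  L <- a + 2000
  k <- a:(L - 1)
  sum(k^(-s)) + L^(1 - s) / (s - 1) + 0.5 * L^(-s) -
    (s / 12) * L^(-s - 1)
}

# Discrete power-law log-likelihood for the tail x >= xmin.
pl_loglik <- function(gamma, x, xmin) {
  -length(x) * log(hurwitz_zeta(gamma, xmin)) - gamma * sum(log(x))
}

# KS distance between the tail empirical CDF and the fitted discrete law.
pl_ks <- function(x, xmin, gamma) {
  tail_x <- x[x >= xmin]
  support <- xmin:max(tail_x)
  z <- hurwitz_zeta(gamma, xmin)
  pmf <- support^(-gamma) / z
  cdf_fit <- cumsum(pmf)
  cdf_emp <- ecdf_at(tail_x, support)
  max(abs(cdf_emp - cdf_fit))
}

ecdf_at <- function(x, support) {
  cumsum(tabulate(factor(x, levels = support))) / length(x)
}

# Sample n values from the discrete power law P(X = k) ~ k^-gamma, k >= xmin,
# truncated at `cap` (inverse-CDF on the tabulated pmf).
rpowerlaw <- function(n, gamma, xmin = 1, cap = 100000) {
  support <- xmin:cap
  pmf <- support^(-gamma)
  sample(support, n, replace = TRUE, prob = pmf)
}

#' Fit a discrete power law to a degree sequence
#'
#' Clauset-style recipe: for each candidate lower cut-off `xmin` the exponent
#' is estimated by discrete maximum likelihood (numerical optimisation of the
#' zeta likelihood) and the `xmin` minimising the Kolmogorov-Smirnov distance
#' between the tail data and the fit is kept. The goodness-of-fit probability
#' comes from a semi-parametric bootstrap: synthetic samples draw the tail
#' from the fitted law and the head from the empirical data below `xmin`,
#' are refitted, and `gof_p` is the fraction with a KS distance at least as
#' large as observed (high p = plausible power law).
#'
#' @param degrees integer vector of positive degrees (>= 10 values).
#' @param xmin fixed lower cut-off; `NULL` (default) selects it by KS.
#' @param gof_reps bootstrap replicates for `gof_p`; 0 skips the bootstrap.
#' @param seed RNG seed for the bootstrap.
#' @return `kpnet_powerlaw`: list with `$gamma`, `$xmin`, `$gof_p` (NA when
#'   skipped), `$n_tail`, `$ks`.
#' @export
powerlaw_fit <- function(degrees, xmin = NULL, gof_reps = 100, seed = NULL) {
  x <- as.integer(degrees)
  if (length(x) < 10) {
    stop_kpnet("need at least 10 degrees", class = "kpnet_argument_error")
  }
  if (any(x < 1)) {
    stop_kpnet("degrees must be positive integers",
               class = "kpnet_argument_error")
  }
  if (length(unique(x)) == 1) {
    stop_kpnet("all degrees equal: power-law fit undefined",
               class = "kpnet_fit_error")
  }
  fit <- pl_fit_once(x, xmin)
  gof_p <- NA_real_
  if (gof_reps > 0) {
    gof_p <- with_seed(seed, {
      head_x <- x[x < fit$xmin]
      p_tail <- fit$n_tail / length(x)
      cap <- max(10000, 10 * max(x))
      hits <- vapply(seq_len(gof_reps), function(i) {
        tail_n <- stats::rbinom(1, length(x), p_tail)
        syn <- c(
          if (tail_n > 0) rpowerlaw(tail_n, fit$gamma, fit$xmin, cap),
          if (length(x) - tail_n > 0 && length(head_x) > 0)
            sample(head_x, length(x) - tail_n, replace = TRUE)
          else if (length(x) - tail_n > 0)
            rpowerlaw(length(x) - tail_n, fit$gamma, fit$xmin, cap)
        )
        refit <- try(pl_fit_once(syn, xmin), silent = TRUE)
        if (inherits(refit, "try-error")) return(NA_real_)
        as.numeric(refit$ks >= fit$ks)
      }, numeric(1))
      mean(hits, na.rm = TRUE)
    })
  }
  structure(list(gamma = fit$gamma, xmin = fit$xmin, gof_p = gof_p,
                 n_tail = fit$n_tail, ks = fit$ks),
            class = "kpnet_powerlaw")
}

pl_fit_once <- function(x, xmin = NULL) {
  cands <- if (is.null(xmin)) sort(unique(x)) else as.integer(xmin)
  # Need a non-trivial tail to fit against.
  cands <- cands[vapply(cands, function(m) sum(x >= m), integer(1)) >= 5]
  cands <- cands[cands <= stats::quantile(x, 0.99)]
  if (length(cands) == 0) {
    stop_kpnet("no viable xmin candidate", class = "kpnet_fit_error")
  }
  best <- NULL
  for (m in cands) {
    tail_x <- x[x >= m]
    if (length(unique(tail_x)) < 2) next
    opt <- optimize(function(g) -pl_loglik(g, tail_x, m),
                    interval = c(1.01, 8))
    ks <- pl_ks(x, m, opt$minimum)
    if (is.null(best) || ks < best$ks) {
      best <- list(gamma = opt$minimum, xmin = m, ks = ks,
                   n_tail = length(tail_x))
    }
  }
  if (is.null(best)) {
    stop_kpnet("degenerate tail: power-law fit failed", class = "kpnet_fit_error")
  }
  best
}

#' @export
print.kpnet_powerlaw <- function(x, ...) {
  cat(sprintf("power law: gamma=%.3f, xmin=%d, n_tail=%d, KS=%.4f, gof_p=%s\n",
              x$gamma, x$xmin, x$n_tail, x$ks,
              ifelse(is.na(x$gof_p), "NA", sprintf("%.3f", x$gof_p))))
  invisible(x)
}
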