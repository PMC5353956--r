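test_that("randomization test matches exact enumeration oracles", {
  rt <- randomization_test(c(10, 11, 12), c(0, 1, 2),
                           alternative = "greater")
  expect_true(rt$exact)
  expect_equal(rt$p, 1 / 20)

  # constant pools -> p = 1 for any alternative
  for (alt in c("greater", "less", "two_sided")) {
    expect_equal(randomization_test(c(3, 3, 3), c(3, 3, 3),
                                    alternative = alt)$p, 1)
  }

  # bitmask oracle on random small pools
  set.seed(31)
  for (i in 1:12) {
    a <- round(rnorm(sample(2:5, 1)), 2)
    b <- round(rnorm(sample(2:5, 1)), 2)
    for (alt in c("greater", "less", "two_sided")) {
      expect_equal(randomization_test(a, b, alternative = alt)$p,
                   perm_oracle(a, b, alt))
    }
  }

  expect_error(randomization_test(c(NA, NA), 1:3), "empty",
               class = "kpnet_argument_error")
})

test_that("sampled RT agrees with exact p on moderate pools", {
  set.seed(5)
  a <- rnorm(8, 1)
  b <- rnorm(8)
  exact <- randomization_test(a, b, exact = TRUE,
                              alternative = "greater")$p
  sampled <- randomization_test(a, b, n_resamples = 4000, seed = 2,
                                alternative = "greater",
                                exact_limit = 0)$p
  expect_lt(abs(sampled - exact), 0.03)
})

test_that("RT p-values are uniform under exchangeability", {
  set.seed(99)
  alphas <- c(0.01, 0.05, 0.1)
  n_trials <- 2000
  ps <- vapply(seq_len(n_trials), function(i) {
    z <- rnorm(12)
    randomization_test(z[1:6], z[7:12], alternative = "greater")$p
  }, numeric(1))
  for (a in alphas) {
    expect_lt(abs(mean(ps <= a) - a), 0.02)
  }
})

test_that("hypergeometric test equals exhaustive enumeration", {
  ht <- hypergeom_test(4, 5, 4, 10, "enrichment")
  expect_equal(ht$p, 5 / 210)

  pick <- function(v) v[sample.int(length(v), 1)]
  for (N in c(6, 9, 12)) {
    for (i in 1:15) {
      K <- pick(0:N)
      n <- pick(0:N)
      k <- pick(max(0, n + K - N):min(n, K))
      for (dir in c("enrichment", "depletion")) {
        expect_equal(hypergeom_test(k, K, n, N, dir)$p,
                     hyper_oracle(k, K, n, N, dir), tolerance = 1e-12)
      }
    }
  }

  expect_equal(hypergeom_test(0, 3, 4, 10, "depletion")$p,
               hyper_oracle(0, 3, 4, 10, "depletion"))
  expect_equal(hypergeom_test(3, 3, 10, 10, "enrichment")$p, 1)  # n = N
  expect_equal(hypergeom_test(3, 3, 10, 10, "depletion")$p, 1)
  expect_error(hypergeom_test(5, 3, 4, 10), "infeasible",
               class = "kpnet_argument_error")
})

test_that("degree association hits the rank extremes and rejects junk", {
  x <- c(a = 1, b = 2, c = 3, d = 4, e = 5, f = 6)
  expect_equal(degree_association(x, x, n_perm = 200, seed = 1)$rho, 1)
  expect_equal(degree_association(x, rev(unname(x)) * 2, n_perm = 200,
                                  seed = 1)$rho, -1)
  expect_error(degree_association(rep(1, 6), x), "constant",
               class = "kpnet_argument_error")
  expect_error(degree_association(1:3, 1:3), ">= 5",
               class = "kpnet_argument_error")

  set.seed(6)
  res <- degree_association(rnorm(60), rnorm(60), n_perm = 400, seed = 2)
  expect_lt(abs(res$rho), 0.35)
  expect_gt(res$p, 0.01)
})

test_that("layer profiles are flat for constant properties", {
  bt <- gen_planted_bowtie(planted_spec(5, 4, 5, 1, 10), seed = 21)
  enz <- bt$network$nodes$id[bt$network$nodes$role != "other"]
  const <- setNames(rep(7, length(enz)), enz)
  lp <- layer_profile(bt$network, const, "DPR", n_reps = 8, seed = 3,
                      n_swaps = 50)
  expect_true(all(lp$summary$null_mean == 7))
  expect_true(all(lp$summary$ci_lo == 7 & lp$summary$ci_hi == 7))
  expect_true(all(lp$summary$observed == 7))
  expect_true(all(lp$summary$ci_lo <= lp$summary$null_mean &
                    lp$summary$null_mean <= lp$summary$ci_hi))
})

test_that("observed out-degree means fall inside the DPR profile CI", {
  bt <- gen_planted_bowtie(planted_spec(6, 5, 6, 1, 12, 0.3, 0.2, 0.2, 0.15),
                           seed = 22)
  lp <- layer_profile(bt$network, "out_degree", "DPR", n_reps = 30,
                      seed = 4, n_swaps = 60)
  s <- lp$summary
  ok <- s$observed >= s$ci_lo - 1e-9 & s$observed <= s$ci_hi + 1e-9
  expect_gte(sum(ok), 2)   # DPR preserves degrees: self-consistency
})
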