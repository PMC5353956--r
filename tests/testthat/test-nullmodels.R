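# The scheme constraint matrix, checked on every generated replicate:
#   DPR  preserves (in, out) exactly       SDPR within +-1
#   IDPR preserves in only                 ODPR preserves out only
#   DNPR preserves neither
# All preserve node count; all but SDPR preserve arc count; none produce
# self-loops or duplicate arcs.

base_net <- gen_planted_bowtie(planted_spec(6, 5, 6, 2, 15, 0.3, 0.2, 0.2,
                                            0.15), seed = 77)$network

test_that("dpr preserves both degree sequences and actually rewires", {
  d0 <- degree_oracle(base_net)
  for (i in 1:10) {
    r <- dpr(base_net, n_swaps = 200, seed = i)
    d1 <- degree_oracle(r)
    expect_equal(d1$in_deg, d0$in_deg)
    expect_equal(d1$out_deg, d0$out_deg)
    expect_simple_arcs(r)
  }
  a0 <- topology(base_net)$arcs
  a1 <- topology(dpr(base_net, n_swaps = 500, seed = 1))$arcs
  expect_gt(nrow(unique(rbind(a0, a1))), nrow(a0))  # arc sets differ
})

test_that("a single swap on a 2-arc graph exchanges the ends", {
  net <- kpnet_network(data.frame(source = c("a", "c"),
                                  target = c("b", "d"), itype = "P"),
                       data.frame(id = c("a", "c"), role = "kinase"))
  r <- dpr(net, n_swaps = 1, seed = 3)
  expect_setequal(paste(r$edges$source, r$edges$target),
                  c("a d", "c b"))
  tiny <- kpnet_network(data.frame(source = "a", target = "b", itype = "P"),
                        data.frame(id = "a", role = "kinase"))
  expect_error(dpr(tiny), "2 arcs", class = "kpnet_argument_error")
})

test_that("sdpr keeps every degree within +-1 and arc count within +-n", {
  d0 <- degree_oracle(base_net)
  n <- nrow(base_net$nodes)
  m <- nrow(topology(base_net)$arcs)
  for (i in 1:10) {
    r <- sdpr(base_net, n_swaps = 100, seed = i)
    d1 <- degree_oracle(r)
    expect_true(all(abs(d1$in_deg - d0$in_deg) <= 1))
    expect_true(all(abs(d1$out_deg - d0$out_deg) <= 1))
    expect_lte(abs(nrow(topology(r)$arcs) - m), n)
    expect_simple_arcs(r)
    expect_identical(r$nodes$id, base_net$nodes$id)
  }
})

test_that("idpr/odpr preserve exactly one degree sequence", {
  d0 <- degree_oracle(base_net)
  enz <- base_net$nodes$id[base_net$nodes$role != "other"]
  out_changed <- FALSE
  in_changed <- FALSE
  for (i in 1:10) {
    ri <- column_randomize(base_net, "from", seed = i, n_swaps = 100)
    di <- degree_oracle(ri)
    expect_equal(di$in_deg, d0$in_deg)
    expect_true(all(topology(ri)$arcs$from %in% enz))  # sources stay enzymes
    if (!identical(di$out_deg, d0$out_deg)) out_changed <- TRUE
    expect_simple_arcs(ri)

    ro <- column_randomize(base_net, "to", seed = i, n_swaps = 100)
    do <- degree_oracle(ro)
    expect_equal(do$out_deg, d0$out_deg)
    if (!identical(do$in_deg, d0$in_deg)) in_changed <- TRUE
    expect_simple_arcs(ro)
  }
  expect_true(out_changed)   # non-preserved sequence does change
  expect_true(in_changed)
})

test_that("dnpr preserves node and arc counts only", {
  m <- nrow(topology(base_net)$arcs)
  degs_differ <- FALSE
  d0 <- degree_oracle(base_net)
  for (i in 1:10) {
    r <- dnpr(base_net, seed = i)
    expect_identical(r$nodes$id, base_net$nodes$id)
    expect_equal(nrow(topology(r)$arcs), m)
    expect_simple_arcs(r)
    if (!identical(degree_oracle(r)$out_deg, d0$out_deg)) degs_differ <- TRUE
  }
  expect_true(degs_differ)

  # 2-node 2-arc case is forced by exhaustion
  two <- kpnet_network(data.frame(source = c("a", "b"), target = c("b", "a"),
                                  itype = "P"),
                       data.frame(id = c("a", "b"), role = "kinase"))
  r2 <- dnpr(two, seed = 1)
  expect_setequal(paste(r2$edges$source, r2$edges$target), c("a b", "b a"))
})

test_that("erdos_renyi hits exact arc counts and bounds", {
  r <- erdos_renyi(20, 50, seed = 4)
  expect_equal(nrow(r$edges), 50)
  expect_simple_arcs(r)
  full <- erdos_renyi(4, 12, seed = 1)
  expect_equal(nrow(full$edges), 12)      # complete digraph
  expect_error(erdos_renyi(4, 13), "infeasible",
               class = "kpnet_argument_error")
  expect_true(nrow(erdos_renyi(616, 1087, seed = 2)$edges) == 1087)
})

test_that("generators are seed-deterministic and vary across seeds", {
  for (scheme in c("DPR", "SDPR", "IDPR", "ODPR", "DNPR", "ER")) {
    a <- randomize_network(base_net, scheme, seed = 11, n_swaps = 50)
    b <- randomize_network(base_net, scheme, seed = 11, n_swaps = 50)
    c_ <- randomize_network(base_net, scheme, seed = 12, n_swaps = 50)
    expect_identical(a$edges, b$edges)
    expect_false(identical(a$edges, c_$edges))
  }
})

test_that("empirical p-values behave at the extremes", {
  arc_count <- function(net) nrow(topology(net)$arcs)
  res <- empirical_pvalue(base_net, arc_count, "DPR", n_reps = 20, seed = 1,
                          n_swaps = 50)
  expect_equal(res$p, 1)                  # statistic invariant under DPR

  star <- kpnet_network(
    data.frame(source = "h", target = paste0("s", 1:8), itype = "P"),
    data.frame(id = "h", role = "kinase"))
  res2 <- empirical_pvalue(star, function(n) grc(n)$grc, "ER",
                           n_reps = 50, seed = 2, tail = "ge")
  expect_equal(res2$observed, 1)
  expect_equal(res2$p, 0)                 # GRC = 1 unbeatable by ER nulls
  expect_error(empirical_pvalue(base_net, arc_count, "DPR", n_reps = 0),
               "n_reps", class = "kpnet_argument_error")
})
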