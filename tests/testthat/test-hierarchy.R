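test_that("leaf removal indexes hand-traced DAGs", {
  expect_equal(leaf_removal(new_toy_topology(c("a b", "b c"))),
               c(a = 3L, b = 2L, c = 1L))
  expect_equal(leaf_removal(new_toy_topology(nodes = letters[1:4])),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_equal(leaf_removal(new_toy_topology(c("h x", "h y", "h z"))),
               c(h = 2L, x = 1L, y = 1L, z = 1L))
  expect_error(leaf_removal(new_toy_topology(c("a b", "b a"))),
               "cyclic", class = "kpnet_cycle_error")
})

test_that("leaf removal max index equals longest path length + 1", {
  for (seed in 1:10) {
    topo <- rand_topo(12, 0.1, seed + 300)
    cond <- scc(topo)
    idx <- leaf_removal(cond$dag)
    expect_equal(max(idx), longest_path_oracle(cond$dag) + 1)
  }
})

test_that("vertex sort reproduces hand-traced spans", {
  vs <- vertex_sort(new_toy_topology(c("a b", "b c")))
  expect_equal(vs$level_min, 1:3)
  expect_equal(vs$level_max, 1:3)
  expect_equal(n_levels(vs), 3L)

  vs2 <- vertex_sort(new_toy_topology(c("a b", "a c", "c d")))
  spans <- setNames(Map(c, vs2$level_min, vs2$level_max), vs2$id)
  expect_equal(spans$a, c(1L, 1L))
  expect_equal(spans$b, c(2L, 3L))
  expect_equal(spans$c, c(2L, 2L))
  expect_equal(spans$d, c(3L, 3L))
  expect_equal(n_levels(vs2), 3L)
  expect_error(vertex_sort(new_toy_topology()), "empty",
               class = "kpnet_argument_error")
})

test_that("span invariants hold and SCC members share spans", {
  for (seed in 1:20) {
    topo <- rand_topo(sample(6:25, 1), runif(1, 0.05, 0.3), seed + 400)
    vs <- vertex_sort(topo)
    D <- n_levels(vs)
    expect_true(all(vs$level_min >= 1 & vs$level_min <= vs$level_max &
                      vs$level_max <= D))
    expect_true(all(vs$b + vs$t <= D + 1))
    cond <- scc(topo)
    for (members in cond$supernodes) {
      sub <- vs[vs$id %in% members, ]
      expect_equal(length(unique(sub$level_min)), 1)
      expect_equal(length(unique(sub$level_max)), 1)
    }
  }
})

test_that("classify_layers recovers the planted toy exactly", {
  bt <- gen_planted_bowtie(planted_spec(2, 3, 2, 1, 0, 0, 0, 0, 0, 0))
  part <- classify_layers(enzyme_subgraph(bt$network), mode = "path")
  expect_equal(part$top, c("T1", "T2"))
  expect_equal(part$core, c("C1", "C2", "C3"))
  expect_equal(part$bottom, c("B1", "B2"))
  expect_equal(part$peripheral, "X1")

  # direct mode uses one-arc neighbours only
  topo <- new_toy_topology(c("t1 t2", "t2 c1", "c1 c2", "c2 c1",
                             "c2 b1", "b1 b2"))
  pd <- classify_layers(topo, mode = "direct")
  expect_equal(pd$top, "t2")
  expect_equal(pd$bottom, "b1")
  pp <- classify_layers(topo, mode = "path")
  expect_equal(pp$top, c("t1", "t2"))
  expect_equal(pp$bottom, c("b1", "b2"))
})

test_that("degenerate bow tie warns but still classifies", {
  expect_warning(part <- classify_layers(new_toy_topology(c("a b", "b c"))),
                 "degenerate")
  expect_length(c(part$top, part$core, part$bottom, part$peripheral), 3)
})

test_that("grc matches closed forms and the brute-force oracle", {
  star <- new_toy_topology(c("h a", "h b", "h c", "h d"))
  expect_equal(grc(star)$grc, 1)
  cycle <- new_toy_topology(c("a b", "b c", "c d", "d a"))
  expect_equal(grc(cycle)$grc, 0)
  chain <- grc(new_toy_topology(c("a b", "b c")))
  expect_equal(unname(chain$cr), c(1, 0.5, 0))
  expect_equal(chain$grc, 0.75)
  expect_error(grc(new_toy_topology(nodes = "a")), "at least 2",
               class = "kpnet_argument_error")

  # oracle equivalence on random graphs <= 7 nodes
  for (seed in 1:30) {
    topo <- rand_topo(sample(3:7, 1), runif(1, 0.1, 0.5), seed + 500)
    R <- closure_oracle(topo)
    diag(R) <- FALSE
    n <- length(topo$nodes)
    cr <- rowSums(R) / (n - 1)
    expect_equal(grc(topo)$grc, sum(max(cr) - cr) / (n - 1))
  }
})

test_that("grc is label-invariant; arcs from the apex cannot raise it", {
  topo <- rand_topo(10, 0.15, 601)
  g0 <- grc(topo)
  map <- setNames(rev(letters[1:10]), topo$nodes)
  relabel <- new_toy_topology(sprintf("%s %s", map[topo$arcs$from],
                                      map[topo$arcs$to]),
                              nodes = unname(map))
  expect_equal(grc(relabel)$grc, g0$grc)

  apex <- names(which.max(g0$cr))[1]
  others <- setdiff(topo$nodes, apex)
  for (tgt in others[1:3]) {
    arcs <- unique(rbind(topo$arcs, data.frame(from = apex, to = tgt)))
    aug <- grc(new_toy_topology(sprintf("%s %s", arcs$from, arcs$to),
                                nodes = topo$nodes))
    expect_lte(aug$grc, g0$grc + 1e-12)
  }
})

test_that("layer regulation counts follow the edge list", {
  net <- kpnet_network(
    data.frame(source = c("C1", "C1", "T1", "C1"),
               target = c("S1", "S2", "C1", "T1"),
               itype = "P"),
    data.frame(id = c("C1", "T1"), role = "kinase"))
  part <- structure(list(top = "T1", core = "C1", bottom = character()),
                    class = "kpnet_partition")
  counts <- layer_regulation_counts(net, part)
  expect_equal(counts[["core"]], 3)  # S1, S2 and enzyme T1 all count
  expect_equal(counts[["top"]], 1)
  expect_equal(counts[["bottom"]], 0)
})

test_that("sort_network assembles levels, partition and substrate layer", {
  bt <- gen_planted_bowtie(planted_spec(4, 3, 4, 2, 6), seed = 9)
  sn <- sort_network(bt$network)
  expect_s3_class(sn$levels, "kpnet_levels")
  expect_setequal(
    c(sn$partition$top, sn$partition$core, sn$partition$bottom,
      sn$partition$peripheral, sn$partition$substrates),
    bt$network$nodes$id)
  expect_true(all(startsWith(sn$partition$substrates, "S")))
})
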