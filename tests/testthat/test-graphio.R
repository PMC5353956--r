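test_that("network construction deduplicates, defaults roles, validates", {
  edges <- data.frame(source = c("K1", "K1", "K1"),
                      target = c("S1", "S2", "S1"),
                      itype = c("P", "P", "P"))
  nodes <- data.frame(id = "K1", role = "kinase")
  expect_warning(net <- kpnet_network(edges, nodes), "duplicate")
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$nodes$id, c("K1", "S1", "S2"))
  expect_equal(net$nodes$role[net$nodes$id == "S1"], "other")

  expect_error(
    kpnet_network(data.frame(source = "K1", target = "S1", itype = "P"),
                  data.frame(id = "K1", role = "other")),
    "K1 -> S1", class = "kpnet_validation_error")
  expect_error(
    kpnet_network(data.frame(source = "K1", target = "S1", itype = "Z"),
                  nodes),
    "interaction type", class = "kpnet_format_error")
  expect_error(
    kpnet_network(edges[0, ], data.frame(id = c("K1", "K1"),
                                         role = "kinase")),
    "duplicated", class = "kpnet_format_error")
})

test_that("read/write round trip is byte-identical and order-independent", {
  bt <- gen_planted_bowtie(planted_spec(3, 3, 3, 1, 5), seed = 11)
  e1 <- file.path(tempdir(), "e1.tsv"); n1 <- file.path(tempdir(), "n1.tsv")
  e2 <- file.path(tempdir(), "e2.tsv"); n2 <- file.path(tempdir(), "n2.tsv")
  write_network(bt$network, e1, n1)
  net2 <- read_network(e1, n1)
  expect_identical(net2$edges, bt$network$edges)
  expect_identical(net2$nodes, bt$network$nodes)
  write_network(net2, e2, n2)
  expect_identical(readLines(e1), readLines(e2))

  # permuting input rows yields the same in-memory network
  ed <- read.delim(e1, colClasses = "character")
  set.seed(1)
  ed <- ed[sample(nrow(ed)), ]
  e3 <- file.path(tempdir(), "e3.tsv")
  write.table(ed, e3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_network(e3, n1)$edges, bt$network$edges)
})

test_that("read_network validates columns and supports column mapping", {
  f <- file.path(tempdir(), "bad.tsv")
  writeLines(c("a\tb", "x\ty"), f)
  expect_error(read_network(f), "column", class = "kpnet_format_error")

  g <- file.path(tempdir(), "mapped.tsv")
  writeLines(c("Kinase\tSubstrate\tType", "K1\tS1\tP"), g)
  net <- read_network(g, edge_columns = c(source = "Kinase",
                                          target = "Substrate",
                                          itype = "Type"))
  expect_equal(net$edges$source, "K1")
})

test_that("property tables type, mask missing and reject bad cells", {
  f <- file.path(tempdir(), "prop.tsv")
  writeLines(c("id\tabundance\tessential",
               "P1\t5.5\t1", "P2\t\t0", "P3\t2.0\t1"), f)
  tab <- read_property_table(f)
  expect_true(is.na(tab$abundance[tab$id == "P2"]))
  expect_equal(attr(tab, "binary_columns"), "essential")
  v <- property_vector(tab, "abundance")
  expect_equal(unname(v["P1"]), 5.5)

  writeLines(c("id\tx", "P1\tfoo"), f)
  expect_error(read_property_table(f), "row 1",
               class = "kpnet_format_error")
  writeLines(c("id\tx", "P1\t1", "P1\t2"), f)
  expect_error(read_property_table(f), "duplicated",
               class = "kpnet_format_error")
})

test_that("write_layers orders rows, handles chains and inconsistencies", {
  topo <- new_toy_topology(c("a b", "b c"))
  levels <- vertex_sort(topo)
  part <- suppressWarnings(classify_layers(topo))
  f <- file.path(tempdir(), "layers.tsv")
  rows <- write_layers(part, levels, f)
  expect_equal(nrow(rows), 3)
  expect_equal(sort(rows$level_min), 1:3)
  expect_identical(readLines(f), {
    write_layers(part, levels, f); readLines(f)  # determinism
  })

  # span without layer -> consistency error
  part2 <- part
  part2$top <- setdiff(part2$top, "a")
  part2$peripheral <- setdiff(part2$peripheral, "a")
  part2$core <- setdiff(part2$core, "a")
  part2$bottom <- setdiff(part2$bottom, "a")
  expect_error(write_layers(part2, levels, f), "no layer",
               class = "kpnet_consistency_error")

  # empty network -> header-only file
  empty <- structure(list(top = character(), core = character(),
                          bottom = character(), peripheral = character()),
                     class = "kpnet_partition")
  write_layers(empty, data.frame(id = character(), level_min = integer(),
                                 level_max = integer()), f)
  expect_equal(length(readLines(f)), 1)
})
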