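test_that("construction validates node and edge integrity", {
  nodes <- data.frame(id = c("a", "b"), name = c("a", "b"), category = "gene")

  expect_error(
    metapathway(nodes, data.frame(source = "a", target = "z", weight = 1)),
    "not in node table"
  )
  expect_error(
    metapathway(nodes, data.frame(source = "a", target = "b", weight = 2)),
    "\\+1 or -1"
  )
  expect_error(
    metapathway(nodes, data.frame(
      source = c("a", "a"), target = c("b", "b"), weight = c(1, 1)
    )),
    "duplicate edge"
  )
  expect_error(
    metapathway(
      data.frame(id = c("a", "a"), name = "a", category = "gene"),
      data.frame(source = character(), target = character(), weight = numeric())
    ),
    "duplicate node"
  )
  expect_error(
    metapathway(
      data.frame(id = "a", name = "a", category = "protein"),
      data.frame(source = character(), target = character(), weight = numeric())
    ),
    "category"
  )
  expect_error(
    metapathway(
      nodes,
      data.frame(source = "a", target = "b", weight = 1),
      membership = data.frame(pathway_id = "p", pathway_name = "p", node_id = "z")
    ),
    "membership"
  )
})

test_that("a written network reloads identically", {
  g <- tiny_fork()
  g$membership <- tibble::tibble(
    pathway_id = "p1", pathway_name = "fork", node_id = c("a", "b", "c")
  )
  dir <- withr::local_tempdir()
  e <- file.path(dir, "e.tsv")
  n <- file.path(dir, "n.tsv")
  m <- file.path(dir, "m.tsv")
  write_network(g, e, n, m)
  g2 <- read_network(e, n, m)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$membership, g$membership)
  expect_equal(n_nodes(g2), 3)
})

test_that("read_network rejects malformed files with location info", {
  dir <- withr::local_tempdir()
  nodes_path <- file.path(dir, "n.tsv")
  writeLines(c("id\tname\tcategory", "a\ta\tgene", "b\tb\tgene"), nodes_path)

  bad_weight <- file.path(dir, "e1.tsv")
  writeLines(c("source\ttarget\tweight", "a\tb\t2"), bad_weight)
  expect_error(read_network(bad_weight, nodes_path), "e1.tsv.*weight|weight.*e1.tsv")

  unknown <- file.path(dir, "e2.tsv")
  writeLines(c("source\ttarget\tweight", "a\tz\t1"), unknown)
  expect_error(read_network(unknown, nodes_path), "z")

  truncated <- file.path(dir, "e3.tsv")
  writeLines(c("source\ttarget\tweight", "a\tb"), truncated)
  expect_error(suppressWarnings(read_network(truncated, nodes_path)), "malformed|missing")
})

test_that("merge_graphs unions by id and keeps memberships", {
  g1 <- metapathway(
    data.frame(id = c("a", "b"), name = c("a", "b"), category = "gene"),
    data.frame(source = "a", target = "b", weight = 1),
    membership = data.frame(pathway_id = "p1", pathway_name = "p1", node_id = c("a", "b"))
  )
  g2 <- metapathway(
    data.frame(id = c("c", "d"), name = c("c", "d"), category = "gene"),
    data.frame(source = "c", target = "d", weight = -1),
    membership = data.frame(pathway_id = "p2", pathway_name = "p2", node_id = c("c", "d"))
  )
  merged <- merge_graphs(list(g1, g2))
  expect_equal(n_nodes(merged), 4)
  expect_equal(nrow(merged$edges), 2)
  expect_setequal(unique(merged$membership$pathway_id), c("p1", "p2"))

  # shared node counted once; identical edge idempotent
  g3 <- metapathway(
    data.frame(id = c("b", "c"), name = c("b", "c"), category = "gene"),
    data.frame(source = "b", target = "c", weight = 1)
  )
  merged2 <- merge_graphs(list(g1, g3))
  expect_equal(n_nodes(merged2), 3)

  # self-merge is the identity up to membership labels
  self <- merge_graphs(list(g1, g1))
  expect_equal(self$nodes, g1$nodes)
  expect_equal(self$edges, g1$edges)

  # a sign conflict is an error, never a silent preference
  g4 <- metapathway(
    data.frame(id = c("a", "b"), name = c("a", "b"), category = "gene"),
    data.frame(source = "a", target = "b", weight = -1)
  )
  expect_error(merge_graphs(list(g1, g4)), "conflict")
})

test_that("upstream and downstream report signed-edge neighbours", {
  g <- tiny_fork()
  expect_setequal(downstream(g, "a"), c("b", "c"))
  expect_equal(upstream(g, "b"), "a")
  expect_equal(upstream(g, "a"), character(0))
  expect_equal(downstream(g, "c"), character(0))

  g2 <- graph_from_edges(data.frame(
    source = c("a", "c"), target = c("b", "b"), weight = 1
  ))
  expect_setequal(upstream(g2, "b"), c("a", "c"))
  expect_error(upstream(g, "zz"), "unknown")
})

test_that("non-expressed nodes are deleted with their incident edges", {
  g <- chain3()
  reduced <- apply_nonexpressed(g, "b")
  expect_setequal(reduced$nodes$id, c("a", "c"))
  expect_equal(nrow(reduced$edges), 0)
  # c can no longer receive anything from a
  p <- propagate(reduced, c(a = 3))
  expect_equal(unname(p$values["c"]), 0)

  expect_equal(apply_nonexpressed(g, character()), g)
  expect_equal(n_nodes(apply_nonexpressed(g, c("a", "b", "c"))), 0)
  expect_warning(apply_nonexpressed(g, c("a", "nope")), "nope")
})

test_that("dependency groups become virtual regulator nodes", {
  g <- graph_from_edges(
    data.frame(source = "V1", target = "V4", weight = 1),
    extra_nodes = c("V2", "V3")
  )
  inp <- sim_input(
    c(V1 = 1, V2 = 1, V3 = -1),
    groups = list(grp = c("V1", "V2", "V3"))
  )
  out <- add_dependency_nodes(g, inp)

  vid <- setdiff(out$graph$nodes$id, g$nodes$id)
  expect_length(vid, 1)
  expect_equal(out$graph$nodes$category[out$graph$nodes$id == vid], "virtual")
  ve <- out$graph$edges[out$graph$edges$source == vid, ]
  expect_setequal(ve$target, c("V1", "V2", "V3"))
  expect_equal(
    ve$weight[match(c("V1", "V2", "V3"), ve$target)],
    c(1, 1, -1)
  )
  # rewritten input is {V* = +1} only; original objects untouched
  expect_equal(out$input$directions$node_id, vid)
  expect_equal(out$input$directions$direction, 1)
  expect_false(vid %in% g$nodes$id)
  expect_length(out$input$groups, 0)

  expect_error(
    add_dependency_nodes(g, sim_input(c(V1 = 1, V2 = 1), groups = list(g1 = "V1"))),
    "at least 2"
  )
  expect_error(
    add_dependency_nodes(
      g,
      sim_input(c(V1 = 1, Vx = -1), groups = list(g1 = c("V1", "Vx")))
    ),
    "Vx"
  )

  # two groups get two distinct virtual nodes with their own edges
  inp2 <- sim_input(
    c(V1 = 1, V2 = 1, V3 = -1, V4 = -1),
    groups = list(ga = c("V1", "V2"), gb = c("V3", "V4"))
  )
  out2 <- add_dependency_nodes(g, inp2)
  vids <- setdiff(out2$graph$nodes$id, g$nodes$id)
  expect_length(vids, 2)
  expect_equal(sum(out2$graph$edges$source %in% vids), 4)
  expect_setequal(out2$input$directions$node_id, vids)
})

test_that("sim_input enforces direction and non-expressed consistency", {
  expect_error(sim_input(c(a = 2)), "-1, 0, or \\+1")
  expect_error(sim_input(c(a = 1), nonexpressed = "a"), "non-expressed")
  expect_error(sim_input(c(a = 1, b = 0), groups = list(g = c("a", "b"))), "deregulated")
  inp <- sim_input(c(a = 1, b = -1), nonexpressed = "c")
  expect_s3_class(inp, "sim_input")
  expect_equal(inp$nonexpressed, "c")
})
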