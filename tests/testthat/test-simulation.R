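test_that("state probabilities are count ratios with guarded input", {
  expect_equal(
    unname(state_probabilities(600, 300, 100, T = 1000)),
    c(0.6, 0.3, 0.1)
  )
  expect_equal(unname(state_probabilities(0, 0, 5)), c(0, 0, 1))
  expect_equal(unname(state_probabilities(1000, 0, 0)), c(1, 0, 0))
  expect_error(state_probabilities(0, 0, 0, T = 0), "positive")
  expect_error(state_probabilities(1, 1, 1, T = 5), "sum to T")
})

test_that("activity scores are signed log-odds of the majority state", {
  expect_equal(activity_score(c(0.998, 0.002, 0)), log2(499))
  expect_equal(activity_score(c(0.2, 0.7, 0.1)), -log2(7 / 3))
  expect_equal(activity_score(c(0.1, 0.1, 0.8)), 0)
  expect_equal(activity_score(c(0.4, 0.4, 0.2)), 0) # no majority, no score
  # boundary: a unanimous tally is continuity-corrected, capped by T
  expect_equal(activity_score(c(1, 0, 0), T = 1000), log2(999.5 / 0.5))
  expect_equal(activity_score(c(0, 1, 0), T = 10), -log2(9.5 / 0.5))
  expect_identical(activity_score(c(1, 0, 0)), Inf)
  expect_error(activity_score(c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("confidence grows with the majority probability", {
  p <- seq(0.51, 0.999, length.out = 40)
  scores <- vapply(p, function(q) activity_score(c(q, (1 - q) / 2, (1 - q) / 2)), numeric(1))
  expect_true(all(diff(scores) > 0))
  neg <- vapply(p, function(q) activity_score(c((1 - q) / 2, q, (1 - q) / 2)), numeric(1))
  expect_equal(neg, -scores)
})

test_that("an always-perturbed isolated node tallies up or zero only", {
  g <- graph_from_edges(
    data.frame(source = "x", target = "y", weight = 1),
    extra_nodes = "a"
  )
  res <- run_simulation(g, sim_input(c(a = 1)), T = 10, seed = 2)
  row <- res$results[res$results$id == "a", ]
  expect_equal(row$n_down, 0)
  expect_equal(row$n_up + row$n_zero, 10)
  expect_equal(row$prob_up + row$prob_down + row$prob_zero, 1)
  expect_gte(row$avg_perturbation, 0)
})

test_that("an empty input leaves every node unchanged", {
  g <- tiny_fork()
  empty <- sim_input(tibble::tibble(node_id = character(), direction = numeric()))
  res <- run_simulation(g, empty, T = 5, seed = 1)
  expect_true(all(res$results$n_zero == 5))
  expect_true(all(res$results$activity_score == 0))
  expect_true(all(res$results$avg_perturbation == 0))
})

test_that("perfect transmission gives identical tallies downstream", {
  g <- graph_from_edges(data.frame(source = "a", target = "b", weight = 1))
  res <- run_simulation(g, sim_input(c(a = 1)), T = 1000, seed = 9)
  ra <- res$results[res$results$id == "a", ]
  rb <- res$results[res$results$id == "b", ]
  expect_equal(rb$n_up, ra$n_up)
  expect_equal(rb$n_zero, ra$n_zero)
  expect_equal(rb$activity_score, ra$activity_score)
  expect_gt(rb$activity_score, 0)
})

test_that("tallies always sum to T and runs are deterministic under a seed", {
  g <- random_network(25, 0.1, acyclic = TRUE, n_pathways = 2, seed = 31)
  inp <- sim_input(setNames(c(1, -1), g$nodes$id[c(1, 2)]))
  r1 <- run_simulation(g, inp, T = 50, seed = 77)
  expect_true(all(r1$results$n_up + r1$results$n_down + r1$results$n_zero == 50))
  r2 <- run_simulation(g, inp, T = 50, seed = 77)
  expect_identical(r1$results, r2$results)
})

test_that("non-expressed placeholders are reported as permanently unchanged", {
  g <- chain3()
  reduced <- apply_nonexpressed(g, "b")
  res <- run_simulation(
    reduced, sim_input(c(a = 1)),
    T = 20, seed = 4, nonexpressed = "b"
  )
  row <- res$results[res$results$id == "b", ]
  expect_equal(c(row$n_up, row$n_down, row$n_zero), c(0, 0, 20))
  expect_equal(row$activity_score, 0)
  expect_equal(row$avg_perturbation, 0)
})

test_that("pathway perturbation aggregates member nodes per step", {
  p <- c(a = 1, b = -1, c = 4)
  mem <- data.frame(
    pathway_id = c("p1", "p1", "p2"), node_id = c("a", "b", "c")
  )
  expect_equal(
    pathway_perturbation(p, mem),
    c(p1 = 0, p2 = 4)
  )
  expect_equal(
    pathway_perturbation(p, mem, aggregation = "mean"),
    c(p1 = 0, p2 = 4)
  )
  mem2 <- data.frame(pathway_id = "p", node_id = c("a", "c"))
  expect_equal(pathway_perturbation(p, mem2, "mean"), c(p = 2.5))
  expect_error(pathway_perturbation(p, data.frame(pathway_id = "p", node_id = "zz")), "zz")
})

test_that("pathway rows go through the same tally pipeline as nodes", {
  g <- toy_cascade(depth = 2, branching = 2)
  res <- run_simulation(g, sim_input(c(root = 1)), T = 500, seed = 12)
  pw <- res$results[res$results$level == "pathway", ]
  expect_equal(nrow(pw), 1)
  expect_equal(pw$n_up + pw$n_down + pw$n_zero, 500)
  # all member contributions are positive, so the pathway mirrors the root
  root <- res$results[res$results$id == "root", ]
  expect_equal(pw$n_up, root$n_up)
  expect_gt(pw$activity_score, 0)

  # mean aggregation rescales per-step values, not the tallies
  res_m <- run_simulation(
    g, sim_input(c(root = 1)),
    T = 500, seed = 12, pathway_aggregation = "mean"
  )
  pw_m <- res_m$results[res_m$results$level == "pathway", ]
  expect_equal(pw_m$n_up, pw$n_up)
  expect_lt(pw_m$avg_perturbation, pw$avg_perturbation)
})

test_that("average perturbation agrees in sign with a confident majority", {
  g <- toy_cascade(depth = 2, branching = 2, inhibit_last = TRUE)
  res <- run_simulation(g, sim_input(c(root = 1)), T = 1000, seed = 6)
  confident <- res$results[pmax(res$results$prob_up, res$results$prob_down) > 0.95, ]
  expect_gt(nrow(confident), 0)
  expect_equal(
    sign(confident$avg_perturbation),
    sign(confident$activity_score)
  )
})

test_that("a run aborts when most steps cannot reach a steady state", {
  g <- graph_from_edges(data.frame(
    source = c("a", "b"), target = c("b", "a"), weight = 1
  ))
  expect_error(
    run_simulation(g, sim_input(c(a = 1)), T = 10, seed = 1, max_iter = 20),
    "steady state"
  )
})

test_that("dependency groups must be resolved before simulating", {
  g <- tiny_fork()
  inp <- sim_input(c(a = 1, b = 1), groups = list(g1 = c("a", "b")))
  expect_error(run_simulation(g, inp, T = 5), "add_dependency_nodes")
})

test_that("tidy, glance and autoplot expose the result", {
  g <- tiny_fork()
  res <- run_simulation(g, sim_input(c(a = 1)), T = 10, seed = 1)
  expect_s3_class(tidy(res), "tbl_df")
  gl <- glance(res)
  expect_equal(gl$T, 10L)
  expect_equal(gl$n_nodes, 3L)
  expect_s3_class(autoplot(res), "ggplot")
})
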