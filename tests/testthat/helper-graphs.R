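# Small graphs built in code and shared across test files.

# a -> b (+1), a -> c (-1): splits a's perturbation over two signed edges
tiny_fork <- function() {
  metapathway(
    nodes = data.frame(
      id = c("a", "b", "c"), name = c("a", "b", "c"), category = "gene"
    ),
    edges = data.frame(
      source = c("a", "a"), target = c("b", "c"), weight = c(1, -1)
    )
  )
}

# a -> b -> c, unit out-degrees: perturbation passes through unchanged
chain3 <- function() {
  metapathway(
    nodes = data.frame(
      id = c("a", "b", "c"), name = c("a", "b", "c"), category = "gene"
    ),
    edges = data.frame(
      source = c("a", "b"), target = c("b", "c"), weight = c(1, 1)
    )
  )
}

graph_from_edges <- function(edges, extra_nodes = character()) {
  ids <- unique(c(edges$source, edges$target, extra_nodes))
  metapathway(
    nodes = data.frame(id = ids, name = ids, category = "gene"),
    edges = edges
  )
}

# Calibration fixture for the empirical null: a hub fed by two leaf classes
# whose steady-state contribution weights are 1 ("full") and 1/2 ("half",
# diluted by a negative parallel path through a pass-through mid node).
# Every node contributes to the hub with a positive weight, so a balanced
# up/down input keeps the hub's per-step sign genuinely stochastic for any
# random choice of input nodes — the property the null-calibration check
# needs from its fixture.
dilution_star <- function(n_full = 16, n_half = 16, n_mid = 4) {
  full <- sprintf("f%02d", seq_len(n_full))
  half <- sprintf("h%02d", seq_len(n_half))
  mids <- sprintf("m%02d", seq_len(n_mid))
  pick <- function(i) mids[((i + 0:2) %% n_mid) + 1]
  nodes <- data.frame(
    id = c("hub", mids, full, half),
    name = c("hub", mids, full, half), category = "gene"
  )
  edges <- dplyr::bind_rows(
    data.frame(source = mids, target = "hub", weight = 1),
    purrr::map(seq_along(full), function(i) {
      data.frame(source = full[i], target = c("hub", pick(i)), weight = 1)
    }) |> purrr::list_rbind(),
    purrr::map(seq_along(half), function(i) {
      data.frame(
        source = half[i], target = c("hub", pick(i)),
        weight = c(1, 1, 1, -1)
      )
    }) |> purrr::list_rbind()
  )
  metapathway(nodes, edges)
}

# Mean and standard deviation of max(0, N(mean, sd)): closed-form oracle for
# the rectified-Gaussian generator.
rectified_normal_moments <- function(mean = 5, sd = 2) {
  r <- mean / sd
  m1 <- mean * pnorm(r) + sd * dnorm(r)
  m2 <- (mean^2 + sd^2) * pnorm(r) + mean * sd * dnorm(r)
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# Write the TSV file set for a graph + input into a temp dir; returns paths.
write_run_fixture <- function(graph, input_tbl, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- list(
    edges = file.path(dir, "edges.tsv"),
    nodes = file.path(dir, "nodes.tsv"),
    membership = file.path(dir, "membership.tsv"),
    input = file.path(dir, "input.tsv"),
    out = file.path(dir, "out.tsv")
  )
  write_network(graph, paths$edges, paths$nodes, paths$membership)
  readr::write_tsv(input_tbl, paths$input, progress = FALSE)
  paths
}
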