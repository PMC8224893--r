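#' Random signed directed test network
#'
#' Erdős–Rényi-style generator used to exercise every stage of the pipeline
#' without any external pathway database: each ordered node pair receives an
#' edge independently with probability `edge_probability`; a drawn edge is
#' inhibiting with probability `inhibition_fraction`. With `acyclic = TRUE`
#' edges only run from lower to higher node index, guaranteeing a DAG.
#' Pathways are random connected subsets grown by breadth-first search from
#' random seed nodes (ignoring edge direction), so pathway aggregates overlap
#' the way merged pathway maps do.
#'
#' @param n_nodes Number of nodes.
#' @param edge_probability Per-pair edge probability in `[0, 1)`.
#' @param inhibition_fraction Probability that an edge is inhibiting.
#' @param acyclic Forbid directed cycles?
#' @param n_pathways Number of random pathways to annotate (0 for none).
#' @param seed Optional integer seed; the generator is a pure function of
#'   its arguments when given.
#' @return A [metapathway()] object.
#' @examples
#' random_network(10, 0.2, seed = 1)
#' @export
random_network <- function(n_nodes, edge_probability,
                           inhibition_fraction = 0.25, acyclic = FALSE,
                           n_pathways = 0, seed = NULL) {
  stopifnot(
    n_nodes >= 1, edge_probability >= 0, edge_probability < 1,
    inhibition_fraction >= 0, inhibition_fraction <= 1, n_pathways >= 0
  )
  if (!is.null(seed)) {
    withr::local_seed(seed)
  }
  ids <- sprintf("n%03d", seq_len(n_nodes))
  nodes <- tibble(id = ids, name = ids, category = "gene")

  pairs <- expand.grid(
    source = seq_len(n_nodes), target = seq_len(n_nodes),
    KEEP.OUT.ATTRS = FALSE
  )
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  if (acyclic) {
    pairs <- pairs[pairs$source < pairs$target, , drop = FALSE]
  }
  keep <- stats::runif(nrow(pairs)) < edge_probability
  pairs <- pairs[keep, , drop = FALSE]
  weight <- ifelse(stats::runif(nrow(pairs)) < inhibition_fraction, -1, 1)
  edges <- tibble(
    source = ids[pairs$source], target = ids[pairs$target], weight = weight
  )

  membership <- NULL
  if (n_pathways > 0) {
    adj <- lapply(seq_len(n_nodes), function(i) {
      unique(c(
        pairs$target[pairs$source == i],
        pairs$source[pairs$target == i]
      ))
    })
    grow <- function(start, size) {
      members <- start
      frontier <- start
      while (length(members) < size && length(frontier) > 0) {
        nxt <- setdiff(unique(unlist(adj[frontier])), members)
        if (length(nxt) == 0) break
        take <- head(sample(nxt), size - length(members))
        members <- c(members, take)
        frontier <- take
      }
      members
    }
    membership <- purrr::map(seq_len(n_pathways), function(p) {
      size <- sample(2:max(2, ceiling(n_nodes / 3)), 1)
      members <- grow(sample(n_nodes, 1), size)
      tibble(
        pathway_id = sprintf("pw%02d", p),
        pathway_name = sprintf("random pathway %d", p),
        node_id = ids[members]
      )
    }) |> purrr::list_rbind()
  }
  metapathway(nodes, edges, membership)
}

#' Rooted activation cascade with a closed-form steady state
#'
#' A tree of activating edges rooted at `"root"`, `branching` children per
#' node, `depth` levels. Every internal node spreads its perturbation evenly
#' over its children, so an imposed expression change `x` at the root yields
#' exactly `x / branching^d` at depth `d` — a closed form against which the
#' solvers can be checked to machine precision. With `inhibit_last = TRUE`
#' the edge into the last leaf is inhibiting, flipping that leaf's sign.
#'
#' Node ids are `"root"` and `"d<level>_<index>"`.
#'
#' @param depth Number of levels below the root (at least 1).
#' @param branching Children per node (at least 1).
#' @param inhibit_last Make the final leaf edge inhibiting?
#' @return A [metapathway()] object with one pathway spanning all nodes.
#' @examples
#' toy_cascade(depth = 2, branching = 2)
#' @export
toy_cascade <- function(depth, branching, inhibit_last = FALSE) {
  stopifnot(depth >= 1, branching >= 1)
  nodes <- tibble(id = "root", name = "root", category = "gene")
  edges <- tibble(source = character(), target = character(), weight = numeric())
  parents <- "root"
  for (d in seq_len(depth)) {
    kids <- sprintf("d%d_%d", d, seq_len(length(parents) * branching))
    nodes <- dplyr::bind_rows(
      nodes,
      tibble(id = kids, name = kids, category = "gene")
    )
    edges <- dplyr::bind_rows(
      edges,
      tibble(
        source = rep(parents, each = branching), target = kids, weight = 1
      )
    )
    parents <- kids
  }
  if (inhibit_last) {
    edges$weight[nrow(edges)] <- -1
  }
  membership <- tibble(
    pathway_id = "cascade", pathway_name = "toy cascade", node_id = nodes$id
  )
  metapathway(nodes, edges, membership)
}

#' Pseudo-observed log-fold-changes with ground truth
#'
#' Emulates an observed differential-expression table for benchmarking: a
#' single synthetic log-fold-change draw per input node is propagated once
#' through the network, then independent Gaussian noise of standard
#' deviation `noise_sd` is added to every node. With `noise_sd = 0` the
#' observed values equal the propagated truth exactly; raising the noise
#' degrades downstream classification continuously.
#'
#' @param graph A [metapathway()] object.
#' @param input A [sim_input()] (dependency groups must be resolved).
#' @param noise_sd Non-negative noise standard deviation (log2 fold change
#'   units).
#' @param seed Optional integer seed.
#' @param logfc_mean,logfc_sd Parameters of the input draw.
#' @return A tibble with columns `node_id`, `logfc` (noisy observation), and
#'   `true_perturbation` (the noiseless propagated value).
#' @export
synth_observed_logfc <- function(graph, input, noise_sd = 0, seed = NULL,
                                 logfc_mean = 5, logfc_sd = 2) {
  stopifnot(inherits(graph, "metapathway"), noise_sd >= 0)
  if (!is.null(seed)) {
    withr::local_seed(seed)
  }
  de <- build_delta_e(graph, input, mean = logfc_mean, sd = logfc_sd)
  truth <- propagate(graph, de, tol = 1e-10, max_iter = 5000)$values
  noise <- if (noise_sd > 0) noise_sd * rnorm_polar(length(truth)) else 0
  tibble(
    node_id = names(truth),
    logfc = unname(truth + noise),
    true_perturbation = unname(truth)
  )
}
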