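#' Draw a random input of the same size and direction multiset
#'
#' The empirical null for activity scores is built by re-running the
#' simulation with the same number of deregulated nodes, the same up/down
#' direction values, and the same non-expressed constraints, but with node
#' identities drawn uniformly at random (without replacement) from the
#' network. Virtual regulator nodes are never drawn.
#'
#' @param graph A [metapathway()] object.
#' @param input The observed [sim_input()].
#' @return A new [sim_input()] with random node ids and the original
#'   direction values assigned in order.
#' @export
randomize_input <- function(graph, input) {
  stopifnot(inherits(graph, "metapathway"), inherits(input, "sim_input"))
  dirs <- input$directions[input$directions$direction != 0, , drop = FALSE]
  candidates <- graph$nodes$id[graph$nodes$category != "virtual"]
  if (length(candidates) < nrow(dirs)) {
    abort(sprintf(
      "graph has %d candidate node(s) but the input needs %d",
      length(candidates), nrow(dirs)
    ))
  }
  picked <- sample(candidates, nrow(dirs), replace = FALSE)
  sim_input(
    tibble(node_id = picked, direction = dirs$direction),
    nonexpressed = input$nonexpressed
  )
}

#' Empirical p-values from a randomization ensemble
#'
#' A node (or pathway) alteration is specific to the simulated input if
#' random inputs of the same shape rarely produce a score at least as
#' extreme. The p-value is the fraction of randomizations whose score
#' exceeds the observed one: strictly, with no add-one smoothing, so `p = 0`
#' is possible. By default scores are compared in absolute value (two-sided:
#' strong inhibition is as extreme as strong activation); `mode = "raw"`
#' compares signed scores one-sidedly.
#'
#' @param observed Named numeric vector of observed activity scores.
#' @param random_scores Matrix of null scores with one row per randomization
#'   and one named column per scored entity (superset of `observed`'s names).
#' @param mode `"abs"` (two-sided, default) or `"raw"` (one-sided).
#' @return A tibble with columns `id` and `p_value`.
#' @export
empirical_pvalues <- function(observed, random_scores, mode = c("abs", "raw")) {
  mode <- match.arg(mode)
  if (is.null(dim(random_scores))) {
    random_scores <- matrix(random_scores,
      ncol = length(random_scores),
      dimnames = list(NULL, names(random_scores))
    )
  }
  R <- nrow(random_scores)
  if (R == 0) {
    abort("the randomization ensemble is empty")
  }
  miss <- setdiff(names(observed), colnames(random_scores))
  if (length(miss) > 0) {
    abort(sprintf(
      "ensemble lacks score(s) for: %s",
      paste(head(miss, 5), collapse = ", ")
    ))
  }
  rnd <- random_scores[, names(observed), drop = FALSE]
  p <- if (mode == "abs") {
    colMeans(abs(rnd) > rep(abs(observed), each = R))
  } else {
    colMeans(rnd > rep(observed, each = R))
  }
  tibble(id = names(observed), p_value = unname(p))
}

#' Storey q-values
#'
#' False-discovery-rate adjustment of empirical p-values. The proportion of
#' true nulls is estimated as `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) m))`
#' and the q-value of the i-th smallest p is
#' `min_{j >= i} pi0 * m * p_(j) / j`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param lambda Tuning point for the `pi0` estimate (default 0.5; the
#'   single-point estimator is stable on the small score sets produced by
#'   desk-scale networks).
#' @param pi0 Optional override of the estimated null proportion.
#' @return Numeric vector of q-values, in the order of `p`.
#' @examples
#' qvalues(c(0.01, 0.02, 0.9), pi0 = 1)
#' @export
qvalues <- function(p, lambda = 0.5, pi0 = NULL) {
  if (length(p) == 0) {
    return(numeric(0))
  }
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
    if (pi0 == 0) pi0 <- 1 / m # all p small: keep the adjustment non-degenerate
  }
  ord <- order(p)
  q_sorted <- pi0 * m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Attach empirical significance to a simulation result
#'
#' Runs the full input-randomization procedure: `R` random inputs of the
#' observed shape are simulated with `T_inner` repetitions each, their
#' activity scores form the null ensemble, and every node and pathway of the
#' observed run receives an empirical p-value and a Storey q-value
#' (q-values are computed separately within the node and pathway families).
#'
#' @param graph The [metapathway()] used for the observed run.
#' @param input The observed [sim_input()].
#' @param observed A `simulation_result` from [run_simulation()] on the same
#'   graph and input.
#' @param R Number of input randomizations (default 1000).
#' @param T_inner Monte-Carlo repetitions per randomization (default 100).
#' @param seed Optional integer seed for the whole procedure.
#' @param pvalue_mode `"abs"` or `"raw"`; see [empirical_pvalues()].
#' @param lambda Passed to [qvalues()].
#' @param tol,max_iter Propagation solver settings for the null runs.
#' @return A `simulation_result` whose `results` tibble gains `p_value` and
#'   `q_value` columns (`NA` for non-expressed placeholder rows).
#' @export
run_significance <- function(graph, input, observed, R = 1000, T_inner = 100,
                             seed = NULL, pvalue_mode = c("abs", "raw"),
                             lambda = 0.5, tol = 1e-6, max_iter = 2000) {
  stopifnot(
    inherits(graph, "metapathway"), inherits(input, "sim_input"),
    inherits(observed, "simulation_result"), R >= 1, T_inner >= 1
  )
  pvalue_mode <- match.arg(pvalue_mode)
  if (!is.null(seed)) {
    withr::local_seed(seed)
  }

  scored <- observed$results[observed$results$id %in%
    c(graph$nodes$id, graph$membership$pathway_id), , drop = FALSE]
  obs_scores <- setNames(scored$activity_score, scored$id)

  M <- propagation_operator(graph)
  if (nrow(M) <= 512) {
    M <- as.matrix(M) # dense matvec is faster on desk-scale graphs
  }
  B <- membership_operator(graph, observed$pathway_aggregation)
  ent_ids <- c(graph$nodes$id, if (!is.null(B)) rownames(B))

  random_scores <- matrix(
    NA_real_, nrow = R, ncol = length(ent_ids),
    dimnames = list(NULL, ent_ids)
  )
  for (r in seq_len(R)) {
    rnd_input <- randomize_input(graph, input)
    random_scores[r, ] <- simulate_scores(
      graph, rnd_input, T_inner, M, B,
      tol = tol, max_iter = max_iter,
      logfc_mean = observed$logfc_mean, logfc_sd = observed$logfc_sd
    )
  }

  pv <- empirical_pvalues(obs_scores, random_scores, mode = pvalue_mode)
  res <- observed$results
  res$p_value <- pv$p_value[match(res$id, pv$id)]
  res$q_value <- NA_real_
  for (lev in unique(res$level)) {
    sel <- res$level == lev & !is.na(res$p_value)
    if (any(sel)) {
      res$q_value[sel] <- qvalues(res$p_value[sel], lambda = lambda)
    }
  }
  observed$results <- res
  observed$significance <- list(R = R, T_inner = T_inner, pvalue_mode = pvalue_mode)
  observed
}
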