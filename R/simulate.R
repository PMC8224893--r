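#' State probabilities from Monte-Carlo tallies
#'
#' Each node is treated as a discrete random variable with states activated
#' (`+1`), inhibited (`-1`), or unchanged (`0`); its distribution is
#' estimated empirically by counting the sign of the propagated perturbation
#' across repetitions.
#'
#' @param n_up,n_down,n_zero Non-negative counts summing to `T`.
#' @param T Total number of repetitions (positive).
#' @return A named numeric triple `(prob_up, prob_down, prob_zero)` summing
#'   to 1.
#' @examples
#' state_probabilities(600, 300, 100, T = 1000)
#' @export
state_probabilities <- function(n_up, n_down, n_zero, T = n_up + n_down + n_zero) {
  stopifnot(length(T) == 1)
  if (T <= 0) {
    abort("T must be positive")
  }
  if (any(c(n_up, n_down, n_zero) < 0) || any(n_up + n_down + n_zero != T)) {
    abort("counts must be non-negative and sum to T")
  }
  c(prob_up = n_up / T, prob_down = n_down / T, prob_zero = n_zero / T)
}

#' Log-odds activity score of the majority state
#'
#' The activity score condenses a node's empirical state distribution into a
#' single signed confidence value: `+log2(p/(1-p))` when activation is the
#' majority state (`p = Pr(+1) > 1/2`), `-log2(p/(1-p))` when inhibition is,
#' and `0` when the unchanged state dominates or no state exceeds one half.
#' The sign is the predicted direction of effect; the magnitude is the
#' log-likelihood that the effect occurs.
#'
#' A majority probability of exactly 1 would give an infinite score; when the
#' tally size `T` is supplied, a continuity correction replaces the count `T`
#' by `T - 1/2` in the odds, capping the magnitude at `log2((T - 1/2) / (1/2))`
#' so scores stay finite and ranked by `T`. Without `T` the score is infinite
#' in that case.
#'
#' @param prob Probability triple `(up, down, zero)` summing to 1, e.g. from
#'   [state_probabilities()]. A 3-column matrix is handled row-wise.
#' @param T Optional tally size behind the probabilities, used for the
#'   continuity correction at the boundary.
#' @return A numeric score (vector for matrix input).
#' @examples
#' activity_score(c(0.998, 0.002, 0))
#' activity_score(c(0.2, 0.7, 0.1))
#' @export
activity_score <- function(prob, T = NULL) {
  if (is.matrix(prob)) {
    return(apply(prob, 1, activity_score, T = T))
  }
  if (length(prob) != 3 || any(prob < 0) || abs(sum(prob) - 1) > 1e-8) {
    abort("prob must be a non-negative triple summing to 1")
  }
  p_up <- prob[[1]]
  p_down <- prob[[2]]
  if (p_up > 0.5) {
    sgn <- 1
    p <- p_up
  } else if (p_down > 0.5) {
    sgn <- -1
    p <- p_down
  } else {
    return(0) # unchanged majority, or no majority at all
  }
  if (p == 1) {
    if (is.null(T)) {
      return(sgn * Inf)
    }
    p <- (T - 0.5) / T
  }
  sgn * log2(p / (1 - p))
}

#' Aggregate node perturbations to pathway level
#'
#' A pathway's perturbation at one simulation step is the sum (default) or
#' mean of its member nodes' perturbations at that step; the per-step pathway
#' values then go through the same tally / probability / score pipeline as
#' nodes.
#'
#' @param perturbation A named numeric vector of node perturbations (or a
#'   `perturbation` object from [propagate()]).
#' @param membership Data frame with columns `pathway_id` and `node_id` (as
#'   in a [metapathway()]'s `membership` slot).
#' @param aggregation `"sum"` or `"mean"`.
#' @return A named numeric vector, one entry per pathway. Pathways with no
#'   members get 0 with a warning.
#' @export
pathway_perturbation <- function(perturbation, membership, aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  if (inherits(perturbation, "perturbation")) {
    perturbation <- perturbation$values
  }
  pw <- unique(membership$pathway_id)
  if (length(pw) == 0) {
    return(setNames(numeric(0), character(0)))
  }
  unknown <- setdiff(stats::na.omit(membership$node_id), names(perturbation))
  if (length(unknown) > 0) {
    abort(sprintf(
      "membership node id(s) missing from perturbation: %s",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  agg <- if (aggregation == "sum") sum else mean
  out <- vapply(pw, function(p) {
    members <- membership$node_id[membership$pathway_id == p]
    members <- members[!is.na(members)]
    if (length(members) == 0) {
      warn(sprintf("pathway '%s' has no member nodes; value set to 0", p))
      return(0)
    }
    agg(perturbation[members])
  }, numeric(1))
  out
}

# 0/1 membership matrix (pathways x nodes) matching the graph's node order,
# scaled for the chosen aggregation so pathway values are one matrix product.
membership_operator <- function(graph, aggregation) {
  pw <- unique(graph$membership$pathway_id)
  ids <- graph$nodes$id
  if (length(pw) == 0) {
    return(NULL)
  }
  i <- match(graph$membership$pathway_id, pw)
  j <- match(graph$membership$node_id, ids)
  B <- Matrix::sparseMatrix(
    i = i, j = j, x = 1, dims = c(length(pw), length(ids)),
    dimnames = list(pw, ids)
  )
  if (aggregation == "mean") {
    sizes <- Matrix::rowSums(B)
    B <- B / pmax(sizes, 1)
  }
  B
}

#' Run the Monte-Carlo phenotype simulation
#'
#' Repeats `T` times: draw a fresh synthetic log-fold-change for every input
#' node, propagate it through the network to a steady state, and classify
#' every node (and every pathway aggregate) as activated, inhibited, or
#' unchanged by the sign of its perturbation. The tallies yield empirical
#' state probabilities, a log-odds activity score, and the average
#' perturbation for each node and pathway.
#'
#' Dependency groups must already be resolved via [add_dependency_nodes()]
#' and non-expressed nodes removed via [apply_nonexpressed()]; ids passed in
#' `nonexpressed` are reported as permanently unchanged (counts `(0, 0, T)`,
#' score 0).
#'
#' @param graph A [metapathway()] object.
#' @param input A [sim_input()] with no unresolved dependency groups.
#' @param T Number of Monte-Carlo repetitions (default 1000).
#' @param seed Optional integer; when given, the run is a pure function of
#'   its arguments.
#' @param tol,max_iter Passed to the propagation solver.
#' @param pathway_aggregation `"sum"` or `"mean"` per-step pathway summary.
#' @param logfc_mean,logfc_sd Rectified-Gaussian parameters for the synthetic
#'   log-fold-changes.
#' @param nonexpressed Optional ids of nodes that were removed from the graph
#'   as non-expressed, to be included in the output as unchanged.
#' @param max_divergent_fraction Abort when more than this fraction of steps
#'   fails to reach the steady state (such steps are solved by least squares
#'   and flagged).
#' @return An object of class `simulation_result`; see [tidy.simulation_result()]
#'   for the per-entity table and [glance.simulation_result()] for the run
#'   summary.
#' @examples
#' g <- toy_cascade(depth = 2, branching = 2)
#' res <- run_simulation(g, sim_input(c(root = 1)), T = 100, seed = 7)
#' tidy(res)
#' @export
run_simulation <- function(graph, input, T = 1000, seed = NULL,
                           tol = 1e-6, max_iter = 2000,
                           pathway_aggregation = c("sum", "mean"),
                           logfc_mean = 5, logfc_sd = 2,
                           nonexpressed = NULL,
                           max_divergent_fraction = 0.1) {
  stopifnot(inherits(graph, "metapathway"), inherits(input, "sim_input"), T >= 1)
  pathway_aggregation <- match.arg(pathway_aggregation)
  if (length(input$groups) > 0) {
    abort("resolve dependency groups with add_dependency_nodes() before simulating")
  }
  if (!is.null(seed)) {
    withr::local_seed(seed)
  }
  T <- as.integer(T)
  ids <- graph$nodes$id
  nonexpressed <- as.character(nonexpressed %||% input$nonexpressed)
  nonexpressed <- setdiff(nonexpressed, ids)

  DE <- draw_delta_e_matrix(graph, input, T, mean = logfc_mean, sd = logfc_sd)
  M <- propagation_operator(graph)
  sol <- jacobi_solve(M, DE, tol = tol, max_iter = max_iter)
  P <- sol$P
  divergent <- !sol$converged
  if (any(divergent)) {
    ls <- lstsq_solve(M, DE[, divergent, drop = FALSE])
    P[, divergent] <- ls$P
    if (mean(divergent) > max_divergent_fraction) {
      abort(sprintf(
        "%d of %d simulation steps (%.0f%%) did not reach a steady state",
        sum(divergent), T, 100 * mean(divergent)
      ))
    }
    warn(sprintf(
      "%d of %d simulation steps did not reach a steady state; least-squares values used",
      sum(divergent), T
    ))
  }

  node_tbl <- tally_states(P, ids, graph$nodes$name, level = "node", T = T)

  B <- membership_operator(graph, pathway_aggregation)
  pathway_tbl <- NULL
  if (!is.null(B)) {
    PP <- as.matrix(B %*% P)
    pw_names <- graph$membership$pathway_name[match(rownames(B), graph$membership$pathway_id)]
    pathway_tbl <- tally_states(PP, rownames(B), pw_names, level = "pathway", T = T)
  }

  ne_tbl <- NULL
  if (length(nonexpressed) > 0) {
    ne_tbl <- tibble(
      id = nonexpressed, name = nonexpressed, level = "node",
      n_up = 0L, n_down = 0L, n_zero = T,
      prob_up = 0, prob_down = 0, prob_zero = 1,
      avg_perturbation = 0, activity_score = 0
    )
  }

  results <- dplyr::bind_rows(node_tbl, ne_tbl, pathway_tbl)
  structure(
    list(
      results = results, T = T, seed = seed,
      pathway_aggregation = pathway_aggregation,
      n_divergent_steps = sum(divergent),
      logfc_mean = logfc_mean, logfc_sd = logfc_sd,
      input = input
    ),
    class = "simulation_result"
  )
}

# Vectorised activity scores straight from tallies, continuity-corrected at
# the boundary (count T enters the odds as T - 1/2).
score_from_counts <- function(n_up, n_down, T) {
  p_up <- pmin(n_up / T, (T - 0.5) / T)
  p_down <- pmin(n_down / T, (T - 0.5) / T)
  score <- numeric(length(n_up))
  up <- n_up / T > 0.5
  dn <- n_down / T > 0.5
  score[up] <- log2(p_up[up] / (1 - p_up[up]))
  score[dn] <- -log2(p_down[dn] / (1 - p_down[dn]))
  score
}

# Sign tallies, probabilities, scores, and mean perturbation for the rows of
# a values-by-steps matrix.
tally_states <- function(P, ids, names, level, T) {
  n_up <- as.integer(rowSums(P > 0)) # exact zero keeps the unchanged state
  n_down <- as.integer(rowSums(P < 0))
  n_zero <- T - n_up - n_down
  tibble(
    id = ids, name = names, level = level,
    n_up = n_up, n_down = n_down, n_zero = n_zero,
    prob_up = n_up / T, prob_down = n_down / T, prob_zero = n_zero / T,
    avg_perturbation = unname(rowMeans(P)),
    activity_score = score_from_counts(n_up, n_down, T)
  )
}

# Lean one-run scorer for the randomization null: same draw order and solver
# semantics as run_simulation, but returns only the score vector.
simulate_scores <- function(graph, input, T, M, B, tol, max_iter,
                            logfc_mean, logfc_sd,
                            max_divergent_fraction = 0.1) {
  DE <- draw_delta_e_matrix(graph, input, T, mean = logfc_mean, sd = logfc_sd)
  sol <- jacobi_solve(M, DE, tol = tol, max_iter = max_iter)
  P <- sol$P
  divergent <- !sol$converged
  if (any(divergent)) {
    if (mean(divergent) > max_divergent_fraction) {
      abort(sprintf(
        "%d of %d simulation steps (%.0f%%) did not reach a steady state",
        sum(divergent), T, 100 * mean(divergent)
      ))
    }
    P[, divergent] <- lstsq_solve(M, DE[, divergent, drop = FALSE])$P
  }
  if (!is.null(B)) {
    P <- rbind(P, as.matrix(B %*% P))
  }
  score_from_counts(rowSums(P > 0), rowSums(P < 0), T)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result: %d node(s), %d pathway(s), T = %d%s>\n",
    sum(x$results$level == "node"), sum(x$results$level == "pathway"),
    x$T,
    if (x$n_divergent_steps > 0) {
      sprintf(", %d divergent step(s)", x$n_divergent_steps)
    } else {
      ""
    }
  ))
  print(head(x$results, 10))
  invisible(x)
}

#' Tidy a simulation result
#'
#' @param x A `simulation_result` from [run_simulation()].
#' @param ... Unused.
#' @return A tibble with one row per node and pathway: state counts,
#'   probabilities, average perturbation, activity score, and (after
#'   [run_significance()]) `p_value` and `q_value`.
#' @export
tidy.simulation_result <- function(x, ...) {
  x$results
}

#' @rdname tidy.simulation_result
#' @export
glance.simulation_result <- function(x, ...) {
  tibble(
    T = x$T,
    n_nodes = sum(x$results$level == "node"),
    n_pathways = sum(x$results$level == "pathway"),
    n_divergent_steps = x$n_divergent_steps,
    pathway_aggregation = x$pathway_aggregation,
    seed = x$seed %||% NA_integer_
  )
}

#' Plot activity scores from a simulation result
#'
#' Horizontal bars of the per-node (and per-pathway) log-odds activity
#' scores, coloured by predicted direction.
#'
#' @param object A `simulation_result`.
#' @param level `"node"`, `"pathway"`, or `"both"`.
#' @param top Keep only the `top` entities by absolute score (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.simulation_result <- function(object, level = c("both", "node", "pathway"),
                                       top = Inf, ...) {
  level <- match.arg(level)
  df <- object$results
  if (level != "both") {
    df <- dplyr::filter(df, .data$level == !!level)
  }
  df <- df |>
    dplyr::arrange(dplyr::desc(abs(.data$activity_score))) |>
    head(if (is.finite(top)) top else nrow(df)) |>
    dplyr::mutate(
      direction = dplyr::case_when(
        .data$activity_score > 0 ~ "activated",
        .data$activity_score < 0 ~ "inhibited",
        TRUE ~ "unchanged"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$activity_score,
    y = stats::reorder(.data$id, abs(.data$activity_score)),
    fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$level), scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_manual(values = c(
      activated = "#b2182b", inhibited = "#2166ac", unchanged = "grey70"
    )) +
    ggplot2::labs(
      x = "activity score (log2 odds of majority state)",
      y = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}
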