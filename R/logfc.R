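#' Standard Gaussian variates by the Marsaglia polar method
#'
#' The package's single source of normal variates. Pairs of uniforms on the
#' unit square are mapped to the unit disc by rejection (pairs with squared
#' radius `>= 1` or `== 0` are discarded) and transformed to two independent
#' standard normals; variates are emitted in pair order. Uniforms come from
#' R's global random stream, so `set.seed()` makes the sequence reproducible.
#' Each call draws its own pairs: a spare half-pair is never carried between
#' calls, so `rnorm_polar(2 * n)` is not the concatenation of two calls of
#' size `n`.
#'
#' @param n Number of variates to return.
#' @return A numeric vector of length `n`.
#' @examples
#' set.seed(1)
#' rnorm_polar(5)
#' @export
rnorm_polar <- function(n) {
  stopifnot(length(n) == 1, n >= 0)
  n <- as.integer(n)
  if (n == 0) {
    return(numeric(0))
  }
  out <- numeric(0)
  while (length(out) < n) {
    # disc acceptance rate is pi/4 and each pair yields 2 variates
    m <- max(16L, ceiling((n - length(out)) * 0.7))
    u <- matrix(stats::runif(2 * m, -1, 1), nrow = 2)
    s <- u[1, ]^2 + u[2, ]^2
    keep <- s < 1 & s > 0
    f <- sqrt(-2 * log(s[keep]) / s[keep])
    out <- c(out, as.vector(u[, keep, drop = FALSE] * rep(f, each = 2)))
  }
  out[seq_len(n)]
}

#' Draw synthetic log-fold-changes for deregulated nodes
#'
#' The magnitude of an imposed up-/down-regulation is modelled as a rectified
#' Gaussian: a normal with mean `+mean` (up) or `-mean` (down) and standard
#' deviation `sd`, with the mass on the wrong side of zero mapped to exactly
#' zero — `max(0, sd*z + mean)` for direction `+1`, `min(0, sd*z - mean)` for
#' `-1`, and exactly `0` for direction `0`. The defaults (mean 5, sd 2 on the
#' log2 scale) describe the spread of strong deregulation events in tumour
#' expression data.
#'
#' @param v Vector of directions in `{-1, 0, +1}`; one draw is returned per
#'   element. Entries with `v = 0` consume no randomness.
#' @param mean,sd Distribution parameters (log2 fold change units).
#' @return Numeric vector, same length as `v`; non-negative where `v = +1`,
#'   non-positive where `v = -1`, zero where `v = 0`.
#' @examples
#' set.seed(1)
#' sample_logfc(c(1, 1, -1, 0))
#' @export
sample_logfc <- function(v, mean = 5, sd = 2) {
  v <- as.numeric(v)
  if (!all(v %in% c(-1, 0, 1))) {
    abort("directions must be -1, 0, or +1")
  }
  out <- numeric(length(v))
  live <- v != 0
  if (any(live)) {
    z <- rnorm_polar(sum(live))
    vv <- v[live]
    out[live] <- ifelse(
      vv > 0,
      pmax(0, sd * z + mean),
      pmin(0, sd * z - mean)
    )
  }
  out
}

#' Assemble one expression-change vector for a simulation step
#'
#' Every node of the graph gets an entry: a fresh rectified-Gaussian draw for
#' each input node (in order of sorted node id, so the random stream is
#' consumed in a documented order) and exactly zero elsewhere.
#'
#' @param graph A [metapathway()] object.
#' @param input A [sim_input()] whose node ids all exist in the graph.
#' @param mean,sd Passed to [sample_logfc()].
#' @return A named numeric vector over all graph nodes, in the graph's node
#'   order.
#' @export
build_delta_e <- function(graph, input, mean = 5, sd = 2) {
  stopifnot(inherits(graph, "metapathway"), inherits(input, "sim_input"))
  dirs <- input$directions[input$directions$direction != 0, , drop = FALSE]
  check_known_ids(graph, dirs$node_id, "input node id")
  ids <- graph$nodes$id
  de <- setNames(numeric(length(ids)), ids)
  if (nrow(dirs) > 0) {
    ord <- order(dirs$node_id)
    de[dirs$node_id[ord]] <- sample_logfc(dirs$direction[ord], mean = mean, sd = sd)
  }
  de
}

# Draw the full n_input x T matrix of rectified LogFCs for one simulation run.
# Column t holds step t; within a step, input nodes are taken in sorted-id
# order so the stream order matches repeated build_delta_e() calls in intent
# (a single vectorised polar call is used for efficiency).
draw_delta_e_matrix <- function(graph, input, T, mean = 5, sd = 2) {
  ids <- graph$nodes$id
  dirs <- input$directions[input$directions$direction != 0, , drop = FALSE]
  check_known_ids(graph, dirs$node_id, "input node id")
  DE <- matrix(0, nrow = length(ids), ncol = T, dimnames = list(ids, NULL))
  if (nrow(dirs) == 0 || T == 0) {
    return(DE)
  }
  ord <- order(dirs$node_id)
  in_ids <- dirs$node_id[ord]
  v <- dirs$direction[ord]
  z <- matrix(rnorm_polar(length(v) * T), nrow = length(v))
  up <- v > 0
  lfc <- z
  lfc[up, ] <- pmax(0, sd * z[up, , drop = FALSE] + mean)
  lfc[!up, ] <- pmin(0, sd * z[!up, , drop = FALSE] - mean)
  DE[match(in_ids, ids), ] <- lfc
  DE
}
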