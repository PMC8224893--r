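# Sparse propagation operator M with M[i, u] = w(u, i) / sum_{d in D(u)} |w(u, d)|:
# each upstream node u spreads its perturbation over its outgoing edges,
# normalised by its total absolute out-weight; the edge sign decides whether
# the contribution activates or inhibits the receiver.
propagation_operator <- function(graph) {
  ids <- graph$nodes$id
  n <- length(ids)
  e <- graph$edges
  src <- match(e$source, ids)
  tgt <- match(e$target, ids)
  out_abs <- tabulate(src, nbins = n) # |w| = 1 for every edge
  Matrix::sparseMatrix(
    i = tgt, j = src, x = e$weight / out_abs[src],
    dims = c(n, n), dimnames = list(ids, ids)
  )
}

# Jacobi iteration P <- DE + M P from P = DE, simultaneous update, on an
# n x k matrix of right-hand sides. Per-column convergence is tracked so a
# Monte-Carlo run can flag individual divergent steps.
jacobi_solve <- function(M, DE, tol, max_iter) {
  P <- DE
  if (ncol(DE) == 0 || nrow(DE) == 0) {
    return(list(P = P, converged = logical(ncol(DE)), iterations = 0L))
  }
  delta <- rep(Inf, ncol(DE))
  iterations <- max_iter
  for (it in seq_len(max_iter)) {
    P_new <- as.matrix(DE + M %*% P)
    d <- abs(P_new - P)
    delta <- if (nrow(d) == 1) as.numeric(d) else apply(d, 2, max)
    P <- P_new
    if (all(delta < tol)) {
      iterations <- it
      break
    }
  }
  # a column counts as converged only if its final sweep moved less than tol
  list(P = P, converged = delta < tol, iterations = iterations)
}

# Minimum-norm least-squares solve of (I - M) P = DE via SVD pseudoinverse;
# fallback for systems where the fixed-point iteration does not settle.
lstsq_solve <- function(M, DE, rcond_tol = 1e-10) {
  A <- diag(nrow(M)) - as.matrix(M)
  sv <- svd(A)
  keep <- sv$d > rcond_tol * max(sv$d, .Machine$double.eps)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  P <- sv$v %*% (dinv * (t(sv$u) %*% DE))
  dimnames(P) <- dimnames(DE)
  list(P = P, singular = !all(keep))
}

as_delta_e <- function(graph, delta_e) {
  ids <- graph$nodes$id
  if (is.data.frame(delta_e)) {
    if (!all(c("node_id", "value") %in% names(delta_e))) {
      abort("a data-frame delta_e needs columns node_id and value")
    }
    delta_e <- setNames(delta_e$value, delta_e$node_id)
  }
  if (is.null(names(delta_e))) {
    if (length(delta_e) != length(ids)) {
      abort("unnamed delta_e must have one entry per graph node")
    }
    names(delta_e) <- ids
  }
  check_known_ids(graph, names(delta_e), "delta_e node id")
  full <- setNames(numeric(length(ids)), ids)
  full[names(delta_e)] <- as.numeric(delta_e)
  if (any(!is.finite(full))) {
    abort("delta_e entries must be finite")
  }
  full
}

new_perturbation <- function(values, converged, iterations, method) {
  structure(
    list(
      values = values, converged = converged,
      iterations = iterations, method = method
    ),
    class = "perturbation"
  )
}

#' Propagate expression changes to a steady-state perturbation
#'
#' Solves the steady-state balance `P(i) = dE(i) + sum_{u in U(i)}
#' w(u, i) / |out(u)| * P(u)`: every node's perturbation is its own imposed
#' expression change plus the signed, out-degree-normalised contributions of
#' its upstream neighbours. The fixed point is found by Jacobi iteration
#' (simultaneous update, starting from `P = dE`), which keeps nodes that
#' receive no signal at exactly zero. If the iteration has not settled below
#' `tol` in max-norm within `max_iter` sweeps — possible on cycles where the
#' operator is not a contraction — the minimum-norm least-squares solution is
#' returned instead and `converged` is set to `FALSE`.
#'
#' @param graph A [metapathway()] object.
#' @param delta_e Expression changes: a named numeric vector (missing nodes
#'   are zero), an unnamed vector in graph node order, or a data frame with
#'   columns `node_id` and `value`. Entries must be finite.
#' @param tol Convergence tolerance on the max-norm change per sweep.
#' @param max_iter Maximum number of Jacobi sweeps.
#' @return An object of class `perturbation` with fields `values` (named
#'   numeric over all nodes), `converged`, `iterations`, and `method`
#'   (`"jacobi"` or `"lstsq"`).
#' @examples
#' g <- toy_cascade(depth = 1, branching = 2)
#' propagate(g, c(root = 2))
#' @export
propagate <- function(graph, delta_e, tol = 1e-6, max_iter = 2000) {
  stopifnot(inherits(graph, "metapathway"), tol > 0, max_iter >= 1)
  de <- as_delta_e(graph, delta_e)
  if (length(de) == 0) {
    return(new_perturbation(de, TRUE, 0L, "jacobi"))
  }
  M <- propagation_operator(graph)
  res <- jacobi_solve(M, matrix(de, ncol = 1, dimnames = list(names(de), NULL)),
    tol = tol, max_iter = max_iter
  )
  if (res$converged[1]) {
    return(new_perturbation(
      setNames(res$P[, 1], names(de)), TRUE, res$iterations, "jacobi"
    ))
  }
  ls <- lstsq_solve(M, matrix(de, ncol = 1))
  new_perturbation(
    setNames(ls$P[, 1], names(de)), FALSE, res$iterations, "lstsq"
  )
}

#' Exact linear-algebra solution of the propagation balance
#'
#' Direct solve of `(I - M) P = dE`, where `M` is the signed out-degree
#' normalised adjacency operator. Serves as an independent check on the
#' iterative solver: on any acyclic graph the two agree to numerical
#' precision. When `I - M` is singular (some cycles make the steady state
#' non-unique) the minimum-norm least-squares solution is returned and
#' `converged` is set to `FALSE`.
#'
#' @inheritParams propagate
#' @return An object of class `perturbation`; `method` is `"exact"` or
#'   `"lstsq"`.
#' @export
propagate_exact <- function(graph, delta_e) {
  stopifnot(inherits(graph, "metapathway"))
  de <- as_delta_e(graph, delta_e)
  if (length(de) == 0) {
    return(new_perturbation(de, TRUE, 0L, "exact"))
  }
  M <- propagation_operator(graph)
  A <- diag(length(de)) - as.matrix(M)
  P <- tryCatch(solve(A, de), error = function(e) NULL)
  if (!is.null(P) && rcond(A) > 1e-10) {
    return(new_perturbation(setNames(P, names(de)), TRUE, 1L, "exact"))
  }
  ls <- lstsq_solve(M, matrix(de, ncol = 1, dimnames = list(names(de), NULL)))
  new_perturbation(setNames(ls$P[, 1], names(de)), FALSE, 1L, "lstsq")
}

#' @export
print.perturbation <- function(x, ...) {
  cat(sprintf(
    "<perturbation: %d nodes, %s (%s, %d iteration(s))>\n",
    length(x$values),
    if (x$converged) "converged" else "NOT converged",
    x$method, x$iterations
  ))
  invisible(x)
}

#' @rdname propagate
#' @param x A `perturbation` object.
#' @param ... Unused.
#' @export
tidy.perturbation <- function(x, ...) {
  tibble(node_id = names(x$values), perturbation = unname(x$values))
}
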