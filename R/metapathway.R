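#' Construct a meta-pathway graph
#'
#' A meta-pathway is a single signed directed graph obtained by merging many
#' pathway maps on their shared nodes. Nodes are biological elements (genes,
#' miRNAs, metabolites); each edge carries a weight of `+1` (activation) or
#' `-1` (inhibition). Pathway membership is kept alongside the merged graph so
#' that results can be aggregated back to pathway level.
#'
#' @param nodes A data frame with columns `id`, `name`, `category`. Categories
#'   are one of `"gene"`, `"mirna"`, `"metabolite"`; `"virtual"` is reserved
#'   for regulator nodes created by [add_dependency_nodes()].
#' @param edges A data frame with columns `source`, `target`, `weight`
#'   (`weight` in `{+1, -1}`). `(source, target)` pairs must be unique.
#' @param membership Optional data frame with columns `pathway_id`,
#'   `pathway_name`, `node_id` mapping pathways to their member nodes.
#'
#' @return An object of class `metapathway`: a list of the three validated
#'   tibbles.
#' @examples
#' g <- metapathway(
#'   nodes = data.frame(id = c("a", "b"), name = c("a", "b"), category = "gene"),
#'   edges = data.frame(source = "a", target = "b", weight = 1)
#' )
#' g
#' @export
metapathway <- function(nodes, edges, membership = NULL) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (is.null(membership)) {
    membership <- tibble(
      pathway_id = character(), pathway_name = character(),
      node_id = character()
    )
  }
  membership <- as_tibble(membership)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      abort(sprintf("%s table lacks column(s): %s", what, paste(miss, collapse = ", ")))
    }
  }
  need(nodes, c("id", "name", "category"), "nodes")
  need(edges, c("source", "target", "weight"), "edges")
  need(membership, c("pathway_id", "pathway_name", "node_id"), "membership")

  nodes$id <- as.character(nodes$id)
  nodes$name <- as.character(nodes$name)
  nodes$category <- as.character(nodes$category)
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)

  g <- structure(
    list(nodes = nodes, edges = edges, membership = membership),
    class = "metapathway"
  )
  validate_metapathway(g)
}

validate_metapathway <- function(g) {
  nodes <- g$nodes
  edges <- g$edges
  membership <- g$membership

  if (any(!nzchar(nodes$id)) || anyNA(nodes$id)) {
    abort("node ids must be non-empty strings")
  }
  if (anyDuplicated(nodes$id)) {
    dup <- unique(nodes$id[duplicated(nodes$id)])
    abort(sprintf("duplicate node id(s): %s", paste(head(dup, 5), collapse = ", ")))
  }
  bad_cat <- setdiff(unique(nodes$category), c("gene", "mirna", "metabolite", "virtual"))
  if (length(bad_cat) > 0) {
    abort(sprintf("unknown node category: %s", paste(bad_cat, collapse = ", ")))
  }
  if (!all(edges$weight %in% c(-1, 1))) {
    abort("edge weights must be exactly +1 or -1")
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- edges[duplicated(key), , drop = FALSE]
    abort(sprintf(
      "duplicate edge(s): %s",
      paste(head(paste0(dup$source, "->", dup$target), 5), collapse = ", ")
    ))
  }
  unknown <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "edge endpoint(s) not in node table: %s",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  unknown_m <- setdiff(membership$node_id, nodes$id)
  if (length(unknown_m) > 0) {
    abort(sprintf(
      "membership node id(s) not in node table: %s",
      paste(head(unknown_m, 5), collapse = ", ")
    ))
  }
  g
}

#' @export
print.metapathway <- function(x, ...) {
  cat(sprintf(
    "<metapathway: %d nodes, %d edges, %d pathways>\n",
    nrow(x$nodes), nrow(x$edges),
    length(unique(x$membership$pathway_id))
  ))
  invisible(x)
}

#' Number of nodes in a meta-pathway graph
#'
#' @param graph A [metapathway()] object.
#' @return Integer node count.
#' @export
n_nodes <- function(graph) {
  stopifnot(inherits(graph, "metapathway"))
  nrow(graph$nodes)
}

#' Upstream and downstream neighbours of a node
#'
#' `upstream()` returns the sources of a node's incoming edges; `downstream()`
#' the targets of its outgoing edges. These are the neighbour sets over which
#' perturbation contributions are accumulated and normalised during
#' propagation.
#'
#' @param graph A [metapathway()] object.
#' @param id A single node identifier present in the graph.
#' @return A character vector of node ids (possibly empty).
#' @examples
#' g <- toy_cascade(depth = 1, branching = 2)
#' downstream(g, "root")
#' @export
upstream <- function(graph, id) {
  stopifnot(inherits(graph, "metapathway"))
  check_known_ids(graph, id)
  unique(graph$edges$source[graph$edges$target == id])
}

#' @rdname upstream
#' @export
downstream <- function(graph, id) {
  stopifnot(inherits(graph, "metapathway"))
  check_known_ids(graph, id)
  unique(graph$edges$target[graph$edges$source == id])
}

check_known_ids <- function(graph, ids, what = "node id") {
  unknown <- setdiff(ids, graph$nodes$id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown %s(s): %s", what,
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  invisible(ids)
}

#' Merge meta-pathway graphs on their shared nodes
#'
#' Builds a single meta-pathway from a list of pathway graphs: nodes are
#' unioned by id, edges by `(source, target)` pair, and each source graph's
#' pathway membership is retained. An edge annotated with weight `+1` in one
#' graph and `-1` in another is an irreconcilable sign conflict and raises an
#' error, since a silently flipped sign would invert every downstream
#' prediction.
#'
#' @param graphs A list of [metapathway()] objects sharing one identifier
#'   namespace.
#' @return A merged [metapathway()] object.
#' @export
merge_graphs <- function(graphs) {
  stopifnot(is.list(graphs), length(graphs) >= 1)
  purrr::walk(graphs, function(g) stopifnot(inherits(g, "metapathway")))

  nodes <- purrr::map(graphs, "nodes") |>
    purrr::list_rbind() |>
    dplyr::distinct(.data$id, .keep_all = TRUE)
  edges <- purrr::map(graphs, "edges") |>
    purrr::list_rbind() |>
    dplyr::distinct()
  conflict <- edges |>
    dplyr::count(.data$source, .data$target) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    abort(sprintf(
      "conflicting edge sign(s) during merge: %s",
      paste(head(paste0(conflict$source, "->", conflict$target), 5), collapse = ", ")
    ))
  }
  membership <- purrr::map(graphs, "membership") |>
    purrr::list_rbind() |>
    dplyr::distinct()
  metapathway(nodes, edges, membership)
}

#' Remove non-expressed nodes from a graph
#'
#' A node declared silent in the studied cell line is removed together with
#' every incident edge, so it neither receives nor transmits perturbation.
#' Deletion (rather than clamping the node's value to zero) also shrinks the
#' out-degree normalisation of its upstream neighbours, redistributing their
#' signal over the edges that remain.
#'
#' @param graph A [metapathway()] object.
#' @param nonexpressed Character vector of node ids to remove. Ids not present
#'   in the graph are ignored with a warning.
#' @return A reduced [metapathway()] object.
#' @examples
#' g <- toy_cascade(depth = 2, branching = 1)
#' apply_nonexpressed(g, "d1_1")
#' @export
apply_nonexpressed <- function(graph, nonexpressed) {
  stopifnot(inherits(graph, "metapathway"))
  nonexpressed <- as.character(nonexpressed)
  unknown <- setdiff(nonexpressed, graph$nodes$id)
  if (length(unknown) > 0) {
    warn(sprintf(
      "ignoring %d non-expressed id(s) absent from the graph: %s",
      length(unknown), paste(head(unknown, 5), collapse = ", ")
    ))
  }
  drop <- intersect(nonexpressed, graph$nodes$id)
  if (length(drop) == 0) {
    return(graph)
  }
  metapathway(
    nodes = dplyr::filter(graph$nodes, !.data$id %in% drop),
    edges = dplyr::filter(
      graph$edges,
      !.data$source %in% drop & !.data$target %in% drop
    ),
    membership = dplyr::filter(graph$membership, !.data$node_id %in% drop)
  )
}

#' Simulation input: deregulated nodes, silenced nodes, dependency groups
#'
#' @param directions A data frame with columns `node_id` and `direction`
#'   (`+1` up-regulation, `-1` down-regulation), or a named numeric vector.
#' @param nonexpressed Character vector of node ids silent in the studied
#'   system; must be disjoint from the deregulated nodes.
#' @param groups Optional named list of character vectors; each vector names
#'   input nodes whose deregulations are dependent and should be driven by a
#'   common virtual regulator (see [add_dependency_nodes()]).
#'
#' @return An object of class `sim_input`.
#' @examples
#' sim_input(c(TP53 = -1, MYC = 1))
#' @export
sim_input <- function(directions, nonexpressed = character(), groups = list()) {
  if (is.numeric(directions) && !is.null(names(directions))) {
    directions <- tibble(node_id = names(directions), direction = unname(directions))
  }
  directions <- as_tibble(directions)
  if (!all(c("node_id", "direction") %in% names(directions))) {
    abort("directions needs columns node_id and direction")
  }
  directions$node_id <- as.character(directions$node_id)
  directions$direction <- as.numeric(directions$direction)
  if (!all(directions$direction %in% c(-1, 0, 1))) {
    abort("directions must be -1, 0, or +1")
  }
  if (anyDuplicated(directions$node_id)) {
    abort("duplicate node ids in input directions")
  }
  nonexpressed <- as.character(nonexpressed)
  active <- directions$node_id[directions$direction != 0]
  clash <- intersect(nonexpressed, active)
  if (length(clash) > 0) {
    abort(sprintf(
      "node(s) both deregulated and non-expressed: %s",
      paste(head(clash, 5), collapse = ", ")
    ))
  }
  if (length(groups) > 0) {
    if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
      names(groups) <- paste0("group", seq_along(groups))
    }
    for (nm in names(groups)) {
      members <- as.character(groups[[nm]])
      missing <- setdiff(members, active)
      if (length(missing) > 0) {
        abort(sprintf(
          "dependency group '%s' member(s) not among deregulated inputs: %s",
          nm, paste(missing, collapse = ", ")
        ))
      }
    }
  }
  structure(
    list(directions = directions, nonexpressed = nonexpressed, groups = groups),
    class = "sim_input"
  )
}

#' @export
print.sim_input <- function(x, ...) {
  cat(sprintf(
    "<sim_input: %d node(s) [%d up, %d down], %d non-expressed, %d dependency group(s)>\n",
    nrow(x$directions),
    sum(x$directions$direction == 1), sum(x$directions$direction == -1),
    length(x$nonexpressed), length(x$groups)
  ))
  invisible(x)
}

#' Resolve dependency groups with virtual regulator nodes
#'
#' Input deregulations are sampled independently; when two or more input nodes
#' are biologically dependent, that assumption is wrong. Instead of modelling
#' how the dependency reshapes the log-fold-change distribution, each group is
#' replaced by a fresh virtual node `V*` added to the graph with one signed
#' edge `V* -> member` per group member (edge weight = the member's
#' deregulation direction). The returned input up-regulates `V*` and drops the
#' members, so a single draw drives the whole group coherently.
#'
#' @param graph A [metapathway()] object; not mutated.
#' @param input A [sim_input()] with one or more dependency groups of at least
#'   two members each.
#' @return A list with elements `graph` (extended) and `input` (rewritten,
#'   with no remaining groups).
#' @export
add_dependency_nodes <- function(graph, input) {
  stopifnot(inherits(graph, "metapathway"), inherits(input, "sim_input"))
  if (length(input$groups) == 0) {
    return(list(graph = graph, input = input))
  }
  nodes <- graph$nodes
  edges <- graph$edges
  dirs <- input$directions
  for (nm in names(input$groups)) {
    members <- as.character(input$groups[[nm]])
    if (length(members) < 2) {
      abort(sprintf("dependency group '%s' needs at least 2 members", nm))
    }
    check_known_ids(graph, members, "dependency group member")
    mdir <- dirs$direction[match(members, dirs$node_id)]
    if (anyNA(mdir) || any(mdir == 0)) {
      abort(sprintf("dependency group '%s' members must have direction +1 or -1", nm))
    }
    vid <- paste0("virtual_", nm)
    k <- 0
    while (vid %in% nodes$id) {
      k <- k + 1
      vid <- paste0("virtual_", nm, "_", k)
    }
    nodes <- dplyr::bind_rows(
      nodes,
      tibble(id = vid, name = paste("virtual regulator", nm), category = "virtual")
    )
    edges <- dplyr::bind_rows(
      edges,
      tibble(source = vid, target = members, weight = mdir)
    )
    dirs <- dirs |>
      dplyr::filter(!.data$node_id %in% members) |>
      dplyr::bind_rows(tibble(node_id = vid, direction = 1))
  }
  list(
    graph = metapathway(nodes, edges, graph$membership),
    input = sim_input(dirs, nonexpressed = input$nonexpressed)
  )
}
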