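#' Read a meta-pathway graph from TSV tables
#'
#' Expects the plain tab-separated dialects used throughout the package:
#' an edge table (`source`, `target`, `weight` with weight in `{+1, -1, 1}`),
#' a node table (`id`, `name`, `category`) and an optional pathway-membership
#' table (`pathway_id`, `pathway_name`, `node_id`). Lines starting with `#`
#' are ignored. Duplicate edges and edges referencing unknown node ids are
#' errors, not silently resolved.
#'
#' @param edges_path,nodes_path,membership_path Paths to the TSV files;
#'   `membership_path` may be `NULL`.
#' @return A [metapathway()] object.
#' @seealso [write_network()]
#' @export
read_network <- function(edges_path, nodes_path, membership_path = NULL) {
  edges <- read_tsv_strict(edges_path, c("source", "target", "weight"))
  nodes <- read_tsv_strict(nodes_path, c("id", "name", "category"))
  weight <- suppressWarnings(as.numeric(edges$weight))
  bad <- which(is.na(weight) | !weight %in% c(-1, 1))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: invalid edge weight '%s' (data row %d); must be +1 or -1",
      edges_path, edges$weight[bad[1]], bad[1]
    ))
  }
  edges$weight <- weight
  membership <- NULL
  if (!is.null(membership_path)) {
    membership <- read_tsv_strict(
      membership_path,
      c("pathway_id", "pathway_name", "node_id")
    )
  }
  metapathway(nodes, edges, membership)
}

read_tsv_strict <- function(path, expected_cols) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  df <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  miss <- setdiff(expected_cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf(
      "%s: missing column(s) %s (header must be %s)",
      path, paste(miss, collapse = ", "), paste(expected_cols, collapse = "\\t")
    ))
  }
  incomplete <- which(apply(is.na(df[expected_cols]), 1, any))
  if (length(incomplete) > 0) {
    abort(sprintf("%s: malformed row at data line %d", path, incomplete[1]))
  }
  df
}

#' Write a meta-pathway graph to TSV tables
#'
#' Inverse of [read_network()]; a written graph reloads identically.
#'
#' @param graph A [metapathway()] object.
#' @param edges_path,nodes_path,membership_path Output paths;
#'   `membership_path` may be `NULL` to skip the membership table.
#' @return `graph`, invisibly.
#' @export
write_network <- function(graph, edges_path, nodes_path, membership_path = NULL) {
  stopifnot(inherits(graph, "metapathway"))
  readr::write_tsv(graph$edges, edges_path, progress = FALSE)
  readr::write_tsv(graph$nodes, nodes_path, progress = FALSE)
  if (!is.null(membership_path)) {
    readr::write_tsv(graph$membership, membership_path, progress = FALSE)
  }
  invisible(graph)
}

#' Read a simulation input file
#'
#' The input TSV has header `node_id<TAB>direction` with direction
#' `OVEREXPRESSION` or `UNDEREXPRESSION` (mapped to `+1`/`-1`), and an
#' optional third column `group` labelling dependency groups. An optional
#' companion file lists non-expressed node ids, one per line.
#'
#' @param input_path Path to the input TSV.
#' @param nonexpressed_path Optional path to the non-expressed id list.
#' @return A [sim_input()] object.
#' @export
read_sim_input <- function(input_path, nonexpressed_path = NULL) {
  df <- read_tsv_strict(input_path, c("node_id", "direction"))
  dirmap <- c(OVEREXPRESSION = 1, UNDEREXPRESSION = -1)
  bad <- which(!df$direction %in% names(dirmap))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: invalid direction '%s' (data row %d); must be OVEREXPRESSION or UNDEREXPRESSION",
      input_path, df$direction[bad[1]], bad[1]
    ))
  }
  directions <- tibble(
    node_id = df$node_id,
    direction = unname(dirmap[df$direction])
  )
  groups <- list()
  if ("group" %in% names(df)) {
    lab <- df$group
    has <- !is.na(lab) & nzchar(lab)
    if (any(has)) {
      groups <- split(df$node_id[has], lab[has])
    }
  }
  nonexpressed <- character()
  if (!is.null(nonexpressed_path)) {
    nonexpressed <- read_nonexpressed(nonexpressed_path)
  }
  sim_input(directions, nonexpressed = nonexpressed, groups = groups)
}

#' @rdname read_sim_input
#' @export
read_nonexpressed <- function(nonexpressed_path) {
  if (!file.exists(nonexpressed_path)) {
    abort(sprintf("file not found: %s", nonexpressed_path))
  }
  x <- readr::read_lines(nonexpressed_path, progress = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read an observed log-fold-change table
#'
#' Two-column TSV with header `node_id<TAB>logfc`, as produced by an upstream
#' differential-expression analysis.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `node_id` (character) and `logfc` (numeric).
#' @export
read_logfc <- function(path) {
  df <- read_tsv_strict(path, c("node_id", "logfc"))
  logfc <- suppressWarnings(as.numeric(df$logfc))
  bad <- which(is.na(logfc))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-numeric logfc at data row %d", path, bad[1]))
  }
  tibble(node_id = df$node_id, logfc = logfc)
}

#' Read an expression matrix for non-expressed detection
#'
#' Wide TSV: first column `node_id`, remaining columns one numeric
#' measurement per sample.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `node_id` plus numeric sample columns.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!"node_id" %in% names(df) || ncol(df) < 2) {
    abort(sprintf("%s: expected node_id plus at least one sample column", path))
  }
  df$node_id <- as.character(df$node_id)
  df
}
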