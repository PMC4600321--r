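#' Build an undirected weighted network
#'
#' The basic container for targets, queries and references: a set of node
#' identifiers (opaque, case-sensitive strings) plus undirected weighted edges
#' with weights in \[0, 1\]. Self-loops are dropped and duplicate edges are
#' collapsed keeping the maximum weight (with a warning), so the stored edge
#' set always satisfies the class invariants.
#'
#' @param nodes character vector of node identifiers (may be empty; endpoints
#'   of `edges` are added automatically).
#' @param edges data frame with columns `u`, `v` and optionally `w`
#'   (default weight 1.0).
#' @param id short label for the network.
#' @return an object of class `rnq_network` with fields `id`, `nodes`
#'   (sorted character vector) and `edges` (data frame `u`, `v`, `w` with
#'   `u < v`, sorted).
#' @export
network <- function(nodes = character(), edges = NULL, id = "net") {
  nodes <- as.character(nodes)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(u = character(), v = character(), w = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("u", "v") %in% names(edges)))
      abort_validation("edges must have columns 'u' and 'v'")
    if (is.null(edges$w)) edges$w <- 1.0
    edges$u <- as.character(edges$u)
    edges$v <- as.character(edges$v)
    edges$w <- as.numeric(edges$w)
    if (anyNA(edges$w)) abort_validation("edge weights must be numeric")
    if (any(edges$w < 0 | edges$w > 1))
      abort_validation("edge weights must lie in [0, 1]")
    nodes <- c(nodes, edges$u, edges$v)   # endpoints count even if dropped
    self <- edges$u == edges$v
    if (any(self)) {
      warning(sprintf("dropping %d self-loop(s)", sum(self)), call. = FALSE)
      edges <- edges[!self, , drop = FALSE]
    }
    if (nrow(edges) > 0) {
      swap <- edges$u > edges$v
      tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
      key <- paste(edges$u, edges$v, sep = "\r")
      if (anyDuplicated(key)) {
        warning("collapsing duplicate edges (keeping maximum weight)",
                call. = FALSE)
        w <- tapply(edges$w, key, max)
        parts <- strsplit(names(w), "\r", fixed = TRUE)
        edges <- data.frame(u = vapply(parts, `[`, "", 1L),
                            v = vapply(parts, `[`, "", 2L),
                            w = as.numeric(w), stringsAsFactors = FALSE)
      }
      edges <- edges[order(edges$u, edges$v), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  nodes <- sort(unique(c(nodes, edges$u, edges$v)))
  structure(list(id = id, nodes = nodes, edges = edges),
            class = "rnq_network")
}

#' Build a tree-topology query network
#'
#' Queries and references must be trees (connected, acyclic): the alignment
#' engine only supports tree queries.
#'
#' @inheritParams network
#' @return an object of classes `rnq_query_tree`, `rnq_network`.
#' @export
query_tree <- function(nodes = character(), edges = NULL, id = "query") {
  net <- network(nodes, edges, id)
  assert_tree(net)
  class(net) <- c("rnq_query_tree", class(net))
  net
}

assert_tree <- function(net) {
  n <- length(net$nodes)
  if (n < 1) abort_validation("a query tree needs at least one node")
  if (nrow(net$edges) != n - 1)
    abort_validation("not a tree: |edges| != |nodes| - 1")
  if (n > 1) {
    g <- as_igraph(net)
    if (igraph::components(g)$no != 1)
      abort_validation("not a tree: network is disconnected")
  }
  invisible(net)
}

is_tree <- function(net) {
  ok <- tryCatch({ assert_tree(net); TRUE },
                 rnq_validation_error = function(e) FALSE)
  ok
}

as_igraph <- function(net) {
  if (nrow(net$edges) == 0)
    return(igraph::make_empty_graph(directed = FALSE) +
             igraph::vertices(net$nodes))
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$u, to = net$edges$v, weight = net$edges$w),
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

#' @export
print.rnq_network <- function(x, ...) {
  cat(sprintf("<%s '%s': %d nodes, %d edges>\n",
              if (inherits(x, "rnq_query_tree")) "query tree" else "network",
              x$id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# adjacency list (character node ids -> character neighbours), deterministic
adjacency_list <- function(net) {
  adj <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (i in seq_along(adj)) adj[[i]] <- character()
  if (nrow(net$edges) > 0) {
    sp_u <- split(net$edges$v, net$edges$u)
    sp_v <- split(net$edges$u, net$edges$v)
    for (nm in names(sp_u)) adj[[nm]] <- c(adj[[nm]], sp_u[[nm]])
    for (nm in names(sp_v)) adj[[nm]] <- c(adj[[nm]], sp_v[[nm]])
    adj <- lapply(adj, sort)
  }
  adj
}

edge_weight_env <- function(net) {
  env <- new.env(parent = emptyenv(), size = max(16L, nrow(net$edges)))
  if (nrow(net$edges) > 0)
    for (i in seq_len(nrow(net$edges)))
      assign(paste(net$edges$u[i], net$edges$v[i], sep = "\r"),
             net$edges$w[i], envir = env)
  env
}

edge_weight <- function(wenv, a, b) {
  key <- if (a < b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
  val <- get0(key, envir = wenv, ifnotfound = NA_real_)
  val
}

# remove nodes and incident edges (used when extracting non-overlapping
# mappings); keeps remaining isolated nodes
network_delete_nodes <- function(net, drop) {
  keep_nodes <- setdiff(net$nodes, drop)
  keep <- !(net$edges$u %in% drop | net$edges$v %in% drop)
  out <- net
  out$nodes <- keep_nodes
  out$edges <- net$edges[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' Read a network from an edge-list TSV file
#'
#' Each line is `u<TAB>v[<TAB>w]` (any whitespace separator is accepted); a
#' missing weight defaults to 1.0. Lines starting with `#` are comments,
#' except a `#nodes:` header which declares isolated nodes (as written by
#' [write_network()]). Self-loops and duplicate edges are dropped with a
#' warning.
#'
#' @param path file path.
#' @param id label for the network.
#' @param tree if `TRUE`, validate the result as a tree and return a
#'   [query_tree()].
#' @return an `rnq_network` (or `rnq_query_tree`).
#' @export
read_network <- function(path, id = basename(path), tree = FALSE) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  extra_nodes <- character()
  hdr <- grepl("^#nodes:", lines)
  for (h in lines[hdr]) {
    extra_nodes <- c(extra_nodes,
                     strsplit(trimws(sub("^#nodes:", "", h)), "[ \t]+")[[1]])
  }
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  us <- character(0); vs <- character(0); ws <- numeric(0)
  for (i in body_idx) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 2 || length(f) > 3)
      abort_parse(sprintf("line %d: expected 'u v [w]', got %d field(s)",
                          i, length(f)))
    w <- if (length(f) == 3) suppressWarnings(as.numeric(f[3])) else 1.0
    if (is.na(w)) abort_parse(sprintf("line %d: weight '%s' is not numeric",
                                      i, f[3]))
    if (w < 0 || w > 1)
      abort_validation(sprintf("line %d: weight %g outside [0, 1]", i, w))
    us <- c(us, f[1]); vs <- c(vs, f[2]); ws <- c(ws, w)
  }
  edges <- data.frame(u = us, v = vs, w = ws, stringsAsFactors = FALSE)
  net <- network(nodes = extra_nodes[nzchar(extra_nodes)], edges = edges,
                 id = id)
  if (tree) net <- query_tree(net$nodes, net$edges, id)
  net
}

#' Write a network to an edge-list TSV file
#'
#' Weights are written at full precision so that a read/write round trip
#' reproduces the network exactly. Isolated nodes are recorded in a
#' `#nodes:` header comment.
#'
#' @param net an `rnq_network`.
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  isolated <- setdiff(net$nodes, c(net$edges$u, net$edges$v))
  lines <- character()
  if (length(isolated) > 0)
    lines <- c(lines, paste("#nodes:", paste(isolated, collapse = " ")))
  if (nrow(net$edges) > 0)
    lines <- c(lines, sprintf("%s\t%s\t%s", net$edges$u, net$edges$v,
                              formatC(net$edges$w, format = "g", digits = 17)))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write to %s", path))
  invisible(path)
}

# Order-independent checksum of the node set and weighted edge set,
# used to detect a stale index.
network_checksum <- function(net) {
  canon <- c(sort(net$nodes),
             sprintf("%s\t%s\t%.12g", net$edges$u, net$edges$v, net$edges$w))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canon, tf)
  unname(tools::md5sum(tf))
}
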