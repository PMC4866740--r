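# Graph container: undirected, unweighted, simple. Nodes are arbitrary string
# identifiers held in canonical order (numeric when every identifier parses as
# an integer, else C-locale lexicographic); all internal work uses the integer
# index into that order so results cannot depend on input line order.

looks_integerish <- function(x) {
  all(grepl("^[+-]?[0-9]+$", x))
}

canonical_node_order <- function(ids) {
  if (looks_integerish(ids)) {
    order(as.numeric(ids), method = "radix")
  } else {
    order(ids, method = "radix")
  }
}

new_cd_graph <- function(nodes, edges) {
  n <- length(nodes)
  m <- nrow(edges)
  if (m > 0L) {
    ii <- c(edges[, 1L], edges[, 2L])
    jj <- c(edges[, 2L], edges[, 1L])
    ord <- order(ii, jj, method = "radix")
    adj <- unname(split(jj[ord], factor(ii[ord], levels = seq_len(n))))
  } else {
    adj <- rep(list(integer(0)), n)
  }
  structure(
    list(
      nodes = nodes,
      edges = edges,
      adj = adj,
      degree = lengths(adj),
      n = n,
      m = m
    ),
    class = "cd_graph"
  )
}

#' Build a graph from an edge table
#'
#' Constructs an undirected, unweighted simple graph from a two-column edge
#' table. Self-loops are dropped and duplicate edges collapsed, each with a
#' warning. Node identifiers may be arbitrary strings; the node order is
#' canonicalized (numeric when all identifiers parse as integers, otherwise
#' lexicographic) so that the resulting graph — and every downstream detection
#' result — is independent of the row order of `edges`.
#'
#' @param edges A data frame (or two-column matrix) whose first two columns
#'   give the endpoints of each edge.
#' @param nodes Optional character vector of additional node identifiers to
#'   include (e.g. isolated nodes that appear in no edge).
#' @return An object of class `cd_graph` with elements `nodes` (canonical
#'   identifiers), `edges` (integer index pairs, each row `i < j`), `adj`
#'   (adjacency lists), `degree`, `n` and `m`.
#' @examples
#' g <- cd_graph(data.frame(from = c(1, 2, 3), to = c(2, 3, 1)))
#' g$n # 3
#' g$m # 3
#' @export
cd_graph <- function(edges, nodes = NULL) {
  if (is.matrix(edges)) edges <- as.data.frame(edges)
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  ids <- unique(c(a, b, as.character(nodes %||% character(0))))
  if (length(ids) == 0L) stop("graph has no nodes", call. = FALSE)
  ids <- ids[canonical_node_order(ids)]
  ia <- match(a, ids)
  ib <- match(b, ids)
  loops <- ia == ib
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)), call. = FALSE)
    ia <- ia[!loops]
    ib <- ib[!loops]
  }
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  key <- (lo - 1) * length(ids) + hi
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate edge(s)", sum(dup)), call. = FALSE)
    lo <- lo[!dup]
    hi <- hi[!dup]
    key <- key[!dup]
  }
  ord <- order(key, method = "radix")
  new_cd_graph(ids, cbind(lo[ord], hi[ord], deparse.level = 0))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

as_cd_graph <- function(x) {
  if (inherits(x, "cd_graph")) return(x)
  if (is.data.frame(x) || is.matrix(x)) return(cd_graph(x))
  if (is.character(x) && length(x) == 1L) return(read_edge_list(x))
  stop("cannot interpret `x` as a graph; supply a cd_graph, an edge data ",
       "frame, or an edge-list file path", call. = FALSE)
}

#' @export
print.cd_graph <- function(x, ...) {
  cat(sprintf("<cd_graph> undirected simple graph: %d nodes, %d edges\n",
              x$n, x$m))
  invisible(x)
}

#' Read a plain-text edge list
#'
#' One edge per line, two whitespace-separated node identifiers. Text from a
#' `#` to the end of a line is treated as a comment; blank lines are skipped.
#' Malformed lines raise an error naming the line number. Self-loops and
#' duplicate edges are handled as in [cd_graph()].
#'
#' @param file Path to the edge-list file (or a connection).
#' @param comment_prefix Comment marker, default `"#"`.
#' @return A [cd_graph()] object.
#' @export
read_edge_list <- function(file, comment_prefix = "#") {
  lines <- readLines(file, warn = FALSE)
  stripped <- sub(paste0(comment_prefix, ".*$"), "", lines)
  stripped <- trimws(stripped)
  keep <- which(nzchar(stripped))
  if (length(keep) == 0L) stop("edge list is empty", call. = FALSE)
  toks <- strsplit(stripped[keep], "[[:space:]]+")
  bad <- lengths(toks) != 2L
  if (any(bad)) {
    stop(sprintf("malformed edge-list line %d: expected two identifiers",
                 keep[which(bad)[1L]]), call. = FALSE)
  }
  mat <- do.call(rbind, toks)
  cd_graph(data.frame(from = mat[, 1L], to = mat[, 2L]))
}

#' Extract the subgraph induced by a node set
#'
#' Returns the graph on exactly the requested nodes with every edge whose two
#' endpoints both belong to the set.
#'
#' @param graph A [cd_graph()].
#' @param nodes Character vector of node identifiers (must all be in `graph`).
#' @return A [cd_graph()] on `nodes`.
#' @export
induced_subgraph <- function(graph, nodes) {
  graph <- as_cd_graph(graph)
  nodes <- as.character(nodes)
  idx <- match(nodes, graph$nodes)
  if (anyNA(idx)) {
    stop("unknown node(s): ", paste(nodes[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  keep <- logical(graph$n)
  keep[idx] <- TRUE
  e <- graph$edges
  sel <- keep[e[, 1L]] & keep[e[, 2L]]
  sub_ids <- graph$nodes[sort(idx)]
  remap <- integer(graph$n)
  remap[sort(idx)] <- seq_along(sub_ids)
  new_cd_graph(sub_ids, cbind(remap[e[sel, 1L]], remap[e[sel, 2L]],
                              deparse.level = 0))
}

#' @export
as.data.frame.cd_graph <- function(x, ...) {
  data.frame(from = x$nodes[x$edges[, 1L]], to = x$nodes[x$edges[, 2L]],
             stringsAsFactors = FALSE)
}

# ---- partitions -------------------------------------------------------------

# Internal representation: integer vector over graph node index, one community
# id per node (>= 1). Public representation: tibble(node, community).

partition_vector <- function(graph, partition) {
  if (is.data.frame(partition)) {
    nd <- as.character(partition[[1L]])
    cm <- partition[[2L]]
  } else if (!is.null(names(partition))) {
    nd <- names(partition)
    cm <- unname(partition)
  } else {
    stop("partition must be a data frame (node, community) or a named vector",
         call. = FALSE)
  }
  idx <- match(graph$nodes, nd)
  if (anyNA(idx)) {
    stop("partition is missing node(s): ",
         paste(utils::head(graph$nodes[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  cm <- as.character(cm)[idx]
  if (anyNA(cm)) stop("partition contains missing community labels", call. = FALSE)
  canonicalize_labels(match(cm, unique(cm)))
}

# Renumber community ids 1..k by first appearance in canonical node order.
canonicalize_labels <- function(lab) {
  match(lab, unique(lab))
}

partition_tibble <- function(graph, lab) {
  tibble::tibble(node = graph$nodes, community = canonicalize_labels(lab))
}

#' Write a membership table
#'
#' Writes one `node<TAB>community` line per node, in canonical node order with
#' community identifiers renumbered by first appearance, so output is
#' bit-exact across runs.
#'
#' @param partition A data frame with columns `node` and `community` (or a
#'   named vector of community labels).
#' @param file Path or connection to write to.
#' @param header Logical; write a `node\tcommunity` header line.
#' @export
write_membership <- function(partition, file, header = FALSE) {
  if (!is.data.frame(partition)) {
    partition <- tibble::tibble(node = names(partition),
                                community = unname(partition))
  }
  nd <- as.character(partition[[1L]])
  ord <- canonical_node_order(nd)
  nd <- nd[ord]
  cm <- canonicalize_labels(as.character(partition[[2L]])[ord])
  lines <- paste(nd, cm, sep = "\t")
  if (header) lines <- c("node\tcommunity", lines)
  writeLines(lines, file)
  invisible(NULL)
}

#' Read a membership table
#'
#' Inverse of [write_membership()]: reads a TSV of `node<TAB>community` lines.
#'
#' @param file Path or connection.
#' @param header Logical; whether the first line is a header.
#' @return A tibble with columns `node` (character) and `community` (integer,
#'   renumbered by first appearance in canonical node order).
#' @export
read_membership <- function(file, header = FALSE) {
  df <- utils::read.table(file, header = header, sep = "\t",
                          colClasses = "character", col.names = c("node", "community"))
  ord <- canonical_node_order(df$node)
  tibble::tibble(node = df$node[ord],
                 community = canonicalize_labels(df$community[ord]))
}
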