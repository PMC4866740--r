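# Mutual-neighbour scores (MNS) and the two-phase initial grouping. The MNS of
# an adjacent node pair is the number of neighbours they share; pairs that are
# each other's best-scoring neighbour seed the initial communities.

#' Mutual-neighbour score of a node pair
#'
#' The number of neighbours the two nodes share.
#'
#' @param graph A graph ([cd_graph()], edge data frame, or edge-list path).
#' @param x,y Node identifiers (must differ).
#' @return Non-negative integer count.
#' @export
mutual_neighbour_score <- function(graph, x, y) {
  graph <- as_cd_graph(graph)
  i <- match(as.character(x), graph$nodes)
  j <- match(as.character(y), graph$nodes)
  if (is.na(i)) stop("unknown node: ", x, call. = FALSE)
  if (is.na(j)) stop("unknown node: ", y, call. = FALSE)
  if (i == j) stop("x and y must differ", call. = FALSE)
  sum(graph$adj[[i]] %in% graph$adj[[j]])
}

#' Mutual-neighbour scores for every edge
#'
#' Computes the MNS for every adjacent pair of the graph. Restricting the
#' table to adjacent pairs keeps the construction linear in the edge count and
#' matches how the scores are consumed: both grouping phases only ever compare
#' a node with its neighbours.
#'
#' @inheritParams mutual_neighbour_score
#' @return A tibble with columns `from`, `to` (canonical identifiers,
#'   `from` before `to`) and `score`.
#' @export
build_mns_table <- function(graph) {
  graph <- as_cd_graph(graph)
  sc <- i_mns_scores(graph)
  tibble::tibble(from = graph$nodes[graph$edges[, 1L]],
                 to = graph$nodes[graph$edges[, 2L]],
                 score = sc)
}

# Integer vector of per-edge scores, aligned with graph$edges rows.
i_mns_scores <- function(graph) {
  if (graph$m == 0L) return(integer(0))
  vapply(seq_len(graph$m), function(e) {
    sum(graph$adj[[graph$edges[e, 1L]]] %in% graph$adj[[graph$edges[e, 2L]]])
  }, integer(1))
}

# Per-node list of edge scores aligned with the adjacency lists, plus the
# per-node maximum incident score.
i_mns_adjacency <- function(graph, scores) {
  n <- graph$n
  if (graph$m == 0L) {
    return(list(score = rep(list(integer(0)), n), best = integer(n)))
  }
  ii <- c(graph$edges[, 1L], graph$edges[, 2L])
  jj <- c(graph$edges[, 2L], graph$edges[, 1L])
  ss <- c(scores, scores)
  ord <- order(ii, jj, method = "radix")
  per <- unname(split(ss[ord], factor(ii[ord], levels = seq_len(n))))
  best <- vapply(per, function(s) if (length(s)) max(s) else 0L, integer(1))
  list(score = per, best = best)
}

# Minimal union-find for phase-1 transitive grouping.
uf_find <- function(parent, x) {
  while (parent[x] != x) {
    parent[x] <- parent[parent[x]]
    x <- parent[x]
  }
  x
}

#' Seed initial communities from mutual-neighbour scores
#'
#' Two-phase initial grouping. Phase 1: every adjacent pair with positive MNS
#' that is mutually best-scoring (the score equals both endpoints' maximum
#' incident score) is grouped, transitively. Phase 2: the remaining unlabeled
#' nodes are swept once, asynchronously, in ascending-degree order; each
#' adopts the label of the neighbour with which it shares the highest MNS.
#' When several neighbours tie at the highest score, the node adopts the label
#' held by most of those tied neighbours (remaining ties go to the smallest
#' community identifier). Nodes whose incident scores are all zero, or whose
#' tied best neighbours are all unlabeled, stay solo.
#'
#' @inheritParams mutual_neighbour_score
#' @return A membership tibble `(node, community)` with `NA` for solo nodes.
#' @export
seed_groups <- function(graph) {
  graph <- as_cd_graph(graph)
  st <- st_new(graph)
  i_seed_groups(graph, st)
  state_to_membership(graph, st)
}

i_seed_groups <- function(graph, st, mns = NULL) {
  scores <- mns %||% i_mns_scores(graph)
  madj <- i_mns_adjacency(graph, scores)
  n <- graph$n

  # phase 1: mutual-highest pairs, grouped transitively via union-find
  parent <- seq_len(n)
  if (graph$m > 0L) {
    e1 <- graph$edges[, 1L]
    e2 <- graph$edges[, 2L]
    sel <- which(scores > 0L & scores == madj$best[e1] & scores == madj$best[e2])
    for (e in sel) {
      r1 <- uf_find(parent, e1[e])
      r2 <- uf_find(parent, e2[e])
      if (r1 != r2) parent[max(r1, r2)] <- min(r1, r2)
    }
    roots <- vapply(seq_len(n), function(v) uf_find(parent, v), integer(1))
    # a root with at least two members forms a community
    sizes <- tabulate(roots, nbins = n)
    comm_roots <- which(sizes >= 2L)
    for (r in comm_roots) {
      id <- st_fresh_id(st)
      for (v in which(roots == r)) st_set_label(graph, st, v, id)
    }
  }

  # phase 2: single asynchronous adoption sweep, ascending degree
  solo <- st_solo(st)
  if (length(solo)) {
    solo <- solo[order(graph$degree[solo], solo, method = "radix")]
    for (v in solo) {
      sc <- madj$score[[v]]
      if (length(sc) == 0L) next
      mx <- max(sc)
      if (mx == 0L) next
      tied <- graph$adj[[v]][sc == mx]
      labs <- st$label[tied]
      labs <- labs[labs > 0L]
      if (length(labs) == 0L) next
      u <- sort(unique(labs))
      cntv <- tabulate(match(labs, u))
      st_set_label(graph, st, v, u[which.max(cntv)])
    }
  }
  invisible(NULL)
}
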