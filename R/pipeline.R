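# End-to-end CLPA-GNR detection: seed communities from mutual-neighbour
# scores, grow them with constrained propagation passes under gradually
# relaxed admission rules, recurse once on the residual solo subgraph, force
# totality, then merge under a descending-alpha schedule guided by modularity.
# Every stage is deterministic, so the whole pipeline is.

#' Detect communities with the deterministic constrained-LPA pipeline
#'
#' Runs the full six-part detection pipeline on an undirected, unweighted
#' simple graph:
#'
#' 1. every node starts solo;
#' 2. mutual-neighbour-score seeding ([seed_groups()]), merging at
#'    `alpha = 1`, then GNR 1;
#' 3. CLPA 1, 2 and 3, each followed by GNR 2 (GNR 3 on the re-run after
#'    part 4);
#' 4. if at least `subgraph_threshold` solo nodes remain, parts 1–3 run
#'    recursively on the subgraph induced by the solo nodes, the resulting
#'    communities are imported, and part 3 re-runs on the full graph;
#' 5. CLPA 4, 5, 6 and 7, each followed by GNR 4; any node still solo joins
#'    the adjacent community with the highest [acceptance_capability()]
#'    (nodes with no grouped neighbour become singleton communities);
#' 6. merging at `alpha` descending over `alpha_grid`, each round followed by
#'    the final GNR; the sweep stops when modularity drops and the best-
#'    modularity state seen is returned.
#'
#' @param x A graph: a [cd_graph()], a two-column edge data frame, or the
#'   path to an edge-list file.
#' @param alpha_grid Strictly decreasing merge thresholds in `(0, 1]` for
#'   part 6.
#' @param subgraph_threshold Minimum residual solo count that triggers the
#'   part-4 recursion (default 10).
#' @param final_gnr GNR variant used after each part-6 merge round (4 or 5;
#'   default 5, which preserves totality of the partition).
#' @param part5_clpa Ordered CLPA variants used in part 5.
#' @param trace Logical; record per-stage snapshots.
#' @return An object of class `clpagnr` with elements `membership` (tibble
#'   `node`, `community`), `modularity`, `n_communities`, `trivial`, `n`,
#'   `m`, and (when requested) `trace`.
#' @examples
#' edges <- data.frame(from = c("a", "a", "b", "d", "d", "e", "c"),
#'                     to   = c("b", "c", "c", "e", "f", "f", "d"))
#' fit <- detect_communities(edges)
#' glance(fit)
#' @export
detect_communities <- function(x,
                               alpha_grid = seq(1, 0.1, by = -0.1),
                               subgraph_threshold = 10,
                               final_gnr = 5,
                               part5_clpa = c(4, 5, 6, 7),
                               trace = FALSE) {
  graph <- as_cd_graph(x)
  if (graph$n == 0L) stop("empty graph", call. = FALSE)
  stopifnot(all(alpha_grid > 0), all(alpha_grid <= 1),
            all(diff(alpha_grid) < 0), subgraph_threshold >= 1)
  final_gnr <- as.integer(final_gnr)
  stopifnot(final_gnr %in% 1:5)

  tracer <- if (trace) make_tracer(graph) else NULL
  st <- st_new(graph)                                     # part 1
  snap(tracer, st, "part1_init")

  mns_scores <- i_mns_scores(graph)
  mnsadj <- i_mns_adjacency(graph, mns_scores)

  i_seed_groups(graph, st, mns = mns_scores)              # part 2
  snap(tracer, st, "part2_seed")
  i_merge_pass(graph, st, alpha = 1)
  snap(tracer, st, "part2_merge")
  i_gnr(graph, st, 1L)
  snap(tracer, st, "part2_gnr1")

  run_part3(graph, st, gnr_variant = 2L, tracer = tracer) # part 3

  if (length(st_solo(st)) >= subgraph_threshold) {        # part 4, at most once
    solo_idx <- st_solo(st)
    sub <- induced_subgraph(graph, graph$nodes[solo_idx])
    sub_st <- st_new(sub)
    sub_scores <- i_mns_scores(sub)
    i_seed_groups(sub, sub_st, mns = sub_scores)
    i_merge_pass(sub, sub_st, alpha = 1)
    i_gnr(sub, sub_st, 1L)
    run_part3(sub, sub_st, gnr_variant = 2L, tracer = NULL)
    import_subgraph_communities(graph, st, sub, sub_st)
    snap(tracer, st, "part4_import")
    run_part3(graph, st, gnr_variant = 3L, tracer = tracer, label = "part4_re")
  }

  if (length(st_solo(st)) > 0L) {                         # part 5
    for (v in part5_clpa) {
      i_clpa(graph, st, as.integer(v), mnsadj = mnsadj)
      i_gnr(graph, st, 4L)
      snap(tracer, st, sprintf("part5_clpa%d_gnr4", as.integer(v)))
    }
    assign_residual_solos(graph, st)
    snap(tracer, st, "part5_residual")
  } else {
    assign_residual_solos(graph, st)  # isolated nodes become singletons
  }

  best_lab <- st$label                                    # part 6
  best_q <- i_modularity(graph, total_labels(st))
  for (alpha in alpha_grid) {
    i_merge_pass(graph, st, alpha)
    i_gnr(graph, st, final_gnr)
    assign_residual_solos(graph, st)  # only needed when final_gnr < 5
    q <- i_modularity(graph, total_labels(st))
    snap(tracer, st, sprintf("part6_alpha%.1f", alpha))
    if (q > best_q) {
      best_q <- q
      best_lab <- st$label
    } else if (q < best_q) {
      break
    }
  }
  st$label <- best_lab
  st$intra <- st_recount_intra(graph, best_lab)
  snap(tracer, st, "final")

  membership <- partition_tibble(graph, st$label)
  k <- length(unique(membership$community))
  structure(
    list(
      membership = membership,
      modularity = best_q,
      n_communities = k,
      trivial = k == 1L,
      n = graph$n,
      m = graph$m,
      alpha_grid = alpha_grid,
      trace = if (trace) tracer$rows() else NULL
    ),
    class = "clpagnr"
  )
}

run_part3 <- function(graph, st, gnr_variant, tracer, label = "part3") {
  for (v in 1:3) {
    i_clpa(graph, st, v)
    i_gnr(graph, st, gnr_variant)
    snap(tracer, st, sprintf("%s_clpa%d_gnr%d", label, v, gnr_variant))
  }
}

import_subgraph_communities <- function(graph, st, sub, sub_st) {
  for (c in st_comm_ids(sub_st)) {
    id <- st_fresh_id(st)
    mem <- match(sub$nodes[st_members(sub_st, c)], graph$nodes)
    for (v in mem) st_set_label(graph, st, v, id)
  }
}

# Force totality: remaining solo nodes join the adjacent community with the
# highest acceptance capability (ties to the smallest identifier); solo nodes
# with no grouped neighbour (including isolated nodes) become singletons.
assign_residual_solos <- function(graph, st) {
  solo <- st_solo(st)
  if (length(solo) == 0L) return(invisible(NULL))
  for (v in solo) {
    if (st$label[v] != 0L) next
    nl <- st$label[graph$adj[[v]]]
    cands <- sort(unique(nl[nl > 0L]))
    if (length(cands) == 0L) {
      st_set_label(graph, st, v, st_fresh_id(st))
    } else {
      st_set_label(graph, st, v, resolve_by_capability(graph, st, v, cands))
    }
  }
  invisible(NULL)
}

# Labels with solo nodes replaced by unique singleton ids (for modularity on
# partially assigned states).
total_labels <- function(st) {
  lab <- st$label
  solo <- lab == 0L
  if (any(solo)) {
    lab[solo] <- max(lab) + seq_len(sum(solo))
  }
  lab
}

make_tracer <- function(graph) {
  env <- new.env(parent = emptyenv())
  env$stage <- character(0)
  env$k <- integer(0)
  env$solo <- integer(0)
  env$q <- numeric(0)
  env$graph <- graph
  env$rows <- function() {
    tibble::tibble(stage = env$stage, n_communities = env$k,
                   n_solo = env$solo, modularity = env$q)
  }
  env
}

snap <- function(tracer, st, stage) {
  if (is.null(tracer)) return(invisible(NULL))
  tracer$stage <- c(tracer$stage, stage)
  tracer$k <- c(tracer$k, length(st_comm_ids(st)))
  tracer$solo <- c(tracer$solo, length(st_solo(st)))
  tracer$q <- c(tracer$q, i_modularity(tracer$graph, total_labels(st)))
  invisible(NULL)
}

#' Is a partition trivial (one community)?
#'
#' @param partition A membership data frame `(node, community)` or a fitted
#'   `clpagnr` object.
#' @return `TRUE` iff the partition has exactly one community.
#' @export
trivial_detection <- function(partition) {
  if (inherits(partition, "clpagnr")) return(partition$trivial)
  length(unique(partition[[2L]])) == 1L
}

# ---- S3 surface ------------------------------------------------------------

#' @export
print.clpagnr <- function(x, ...) {
  cat(sprintf("<clpagnr> deterministic community detection\n"))
  cat(sprintf("  graph: %d nodes, %d edges\n", x$n, x$m))
  cat(sprintf("  communities: %d  modularity: %.4f  trivial: %s\n",
              x$n_communities, x$modularity, x$trivial))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Membership table of a fitted detection
#'
#' @param x A `clpagnr` object.
#' @param ... Unused.
#' @return A tibble with columns `node` and `community`.
#' @export
tidy.clpagnr <- function(x, ...) {
  x$membership
}

#' One-row summary of a fitted detection
#'
#' @param x A `clpagnr` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `m`, `n_communities`, `modularity`,
#'   `trivial`.
#' @export
glance.clpagnr <- function(x, ...) {
  tibble::tibble(n = x$n, m = x$m, n_communities = x$n_communities,
                 modularity = x$modularity, trivial = x$trivial)
}

#' Community-size profile of a fitted detection
#'
#' @param object A `clpagnr` object.
#' @param ... Unused.
#' @return A ggplot bar chart of community sizes, largest first.
#' @export
autoplot.clpagnr <- function(object, ...) {
  sizes <- dplyr::count(object$membership, .data$community, name = "size")
  sizes <- dplyr::arrange(sizes, dplyr::desc(.data$size))
  sizes$rank <- seq_len(nrow(sizes))
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$rank, y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "community (by size rank)", y = "nodes",
                  title = sprintf("%d communities, Q = %.3f",
                                  object$n_communities, object$modularity)) +
    ggplot2::theme_minimal()
}
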