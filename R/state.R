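# Label state: per-node community label (0L = solo) over the canonical node
# index of a cd_graph, plus the per-node intra-community link count, which is
# kept incrementally in sync with every label change. Mutable by design (an
# environment) because every propagation pass is an asynchronous sweep.

st_new <- function(graph, label = NULL) {
  st <- new.env(parent = emptyenv())
  st$label <- if (is.null(label)) integer(graph$n) else as.integer(label)
  stopifnot(length(st$label) == graph$n)
  st$intra <- st_recount_intra(graph, st$label)
  st$nextid <- max(0L, st$label) + 1L
  st
}

st_recount_intra <- function(graph, label) {
  vapply(seq_len(graph$n), function(v) {
    l <- label[v]
    if (l == 0L) return(0L)
    nb <- graph$adj[[v]]
    if (length(nb) == 0L) return(0L)
    sum(label[nb] == l)
  }, integer(1))
}

# Change node v's label (0L solos it); keeps intra counts consistent.
st_set_label <- function(graph, st, v, new) {
  old <- st$label[v]
  if (old == new) return(invisible(NULL))
  nb <- graph$adj[[v]]
  if (old != 0L && length(nb)) {
    in_old <- nb[st$label[nb] == old]
    st$intra[in_old] <- st$intra[in_old] - 1L
  }
  st$label[v] <- new
  if (new != 0L && length(nb)) {
    in_new <- nb[st$label[nb] == new]
    st$intra[in_new] <- st$intra[in_new] + 1L
    st$intra[v] <- length(in_new)
  } else {
    st$intra[v] <- 0L
  }
  invisible(NULL)
}

st_fresh_id <- function(st) {
  id <- st$nextid
  st$nextid <- id + 1L
  id
}

st_members <- function(st, c) which(st$label == c)

st_comm_ids <- function(st) sort(unique(st$label[st$label > 0L]))

st_solo <- function(st) which(st$label == 0L)

# Sorted-by-(size, id) community ids; ascending size, ties by id.
st_comms_by_size <- function(st) {
  ids <- st_comm_ids(st)
  if (length(ids) == 0L) return(integer(0))
  sizes <- tabulate(st$label, nbins = max(ids))[ids]
  ids[order(sizes, ids, method = "radix")]
}

# ---- public label-state wrappers -------------------------------------------

# A membership data frame may mark solo nodes with NA community.
state_from_membership <- function(graph, membership) {
  if (is.null(membership)) return(st_new(graph))
  nd <- as.character(membership[[1L]])
  cm <- as.character(membership[[2L]])
  idx <- match(graph$nodes, nd)
  if (anyNA(idx)) stop("membership is missing node(s)", call. = FALSE)
  cm <- cm[idx]
  lab <- integer(graph$n)
  known <- !is.na(cm)
  lab[known] <- match(cm[known], unique(cm[known]))
  st_new(graph, lab)
}

state_to_membership <- function(graph, st) {
  lab <- st$label
  com <- rep(NA_integer_, graph$n)
  grouped <- lab > 0L
  if (any(grouped)) {
    com[grouped] <- match(lab[grouped], unique(lab[grouped]))
  }
  tibble::tibble(node = graph$nodes, community = com)
}

comm_id_for <- function(graph, st, community) {
  # Public community handles are the canonical (first-appearance) numbers of
  # state_to_membership; map one back to the internal label id.
  lab <- st$label
  grouped <- which(lab > 0L)
  ids <- unique(lab[grouped])
  community <- as.integer(community)
  if (community < 1L || community > length(ids)) {
    stop("no such community: ", community, call. = FALSE)
  }
  ids[community]
}

#' Per-node capacity to accept newcomers
#'
#' The capacity of a grouped node is its number of inter-community links
#' divided by its degree (links to solo nodes count as inter-community).
#' Nodes whose whole neighbourhood lies in their own community have capacity
#' 0; degree-0 nodes are defined to have capacity 0.
#'
#' @param graph A graph ([cd_graph()], edge data frame, or edge-list path).
#' @param membership Data frame `(node, community)`; `NA` marks solo nodes.
#' @param node Node identifier.
#' @return A number in `[0, 1]`.
#' @export
node_capacity <- function(graph, membership, node) {
  graph <- as_cd_graph(graph)
  st <- state_from_membership(graph, membership)
  v <- match(as.character(node), graph$nodes)
  if (is.na(v)) stop("unknown node: ", node, call. = FALSE)
  if (st$label[v] == 0L) stop("node is solo; capacity is defined for grouped nodes",
                              call. = FALSE)
  i_capacity(graph, st, v)
}

i_capacity <- function(graph, st, v) {
  d <- graph$degree[v]
  if (d == 0L) return(0)
  (d - st$intra[v]) / d
}

#' Capability of a community to accept a node
#'
#' The sum of [node_capacity()] over the node's neighbours that belong to the
#' community; used to break ties between equally plausible communities.
#'
#' @inheritParams node_capacity
#' @param community Community number (as in `membership`).
#' @return Sum of member capacities (0 when no neighbour is in the community).
#' @export
acceptance_capability <- function(graph, membership, node, community) {
  graph <- as_cd_graph(graph)
  st <- state_from_membership(graph, membership)
  v <- match(as.character(node), graph$nodes)
  if (is.na(v)) stop("unknown node: ", node, call. = FALSE)
  i_capability(graph, st, v, comm_id_for(graph, st, community))
}

i_capability <- function(graph, st, v, c) {
  nb <- graph$adj[[v]]
  nb <- nb[st$label[nb] == c]
  if (length(nb) == 0L) return(0)
  sum((graph$degree[nb] - st$intra[nb]) / graph$degree[nb])
}

#' Number of links from a node into a community
#'
#' @inheritParams acceptance_capability
#' @return Count of edges from `node` to members of `community`.
#' @export
links_into <- function(graph, membership, node, community) {
  graph <- as_cd_graph(graph)
  st <- state_from_membership(graph, membership)
  v <- match(as.character(node), graph$nodes)
  if (is.na(v)) stop("unknown node: ", node, call. = FALSE)
  i_links_into(graph, st, v, comm_id_for(graph, st, community))
}

i_links_into <- function(graph, st, v, c) {
  nb <- graph$adj[[v]]
  if (length(nb) == 0L) return(0L)
  sum(st$label[nb] == c)
}

# Minimum per-member intra-link count of community c.
i_qmin <- function(st, c) {
  mem <- st_members(st, c)
  min(st$intra[mem])
}

#' Community-admission conditions
#'
#' Evaluates one of the four progressively relaxed admission rules comparing
#' `l`, the number of links the node has into the community, against `q`, the
#' observed minimum per-member intra-community link count: condition 1 is
#' `l > q`, condition 2 `l >= q`, condition 3 `l > q/2`, condition 4
#' `l >= q/2` (`q/2` kept exact, not rounded).
#'
#' @inheritParams acceptance_capability
#' @param condition Integer 1–4.
#' @return Logical.
#' @export
condition_satisfied <- function(graph, membership, node, community, condition) {
  graph <- as_cd_graph(graph)
  st <- state_from_membership(graph, membership)
  v <- match(as.character(node), graph$nodes)
  if (is.na(v)) stop("unknown node: ", node, call. = FALSE)
  c <- comm_id_for(graph, st, community)
  i_condition(i_links_into(graph, st, v, c), i_qmin(st, c), condition)
}

i_condition <- function(l, q, condition) {
  switch(as.integer(condition),
         l > q,          # 1
         l >= q,         # 2
         2 * l > q,      # 3: l > q/2, exact
         2 * l >= q)     # 4
}

# ---- community statistics ---------------------------------------------------

#' Per-community statistics
#'
#' Sizes, intra- and inter-community link counts for every community of a
#' membership table (links to solo nodes count as inter-community).
#'
#' @inheritParams node_capacity
#' @return A tibble with one row per community: `community`, `size`,
#'   `intra_links`, `inter_links`.
#' @export
community_stats <- function(graph, membership) {
  graph <- as_cd_graph(graph)
  st <- state_from_membership(graph, membership)
  ids <- st_comm_ids(st)
  rows <- lapply(seq_along(ids), function(k) {
    mem <- st_members(st, ids[k])
    intra <- sum(st$intra[mem]) / 2
    tibble::tibble(community = k, size = length(mem),
                   intra_links = as.integer(intra),
                   inter_links = as.integer(sum(graph$degree[mem]) - 2 * intra))
  })
  dplyr::bind_rows(rows)
}

# ---- merging ---------------------------------------------------------------

#' Merge criterion for two communities
#'
#' A target community is absorbed by a neighbouring community when the
#' neighbour-normalized inter-link count exceeds `alpha` times the target's
#' intra-link density: `inter_links / size_neighbour > alpha * intra_target /
#' size_target` (strict). Smaller `alpha` makes merging easier.
#'
#' @param intra_target,size_target Intra-link count and node count of the
#'   community considered for absorption.
#' @param inter_links Links between the two communities.
#' @param size_neighbour Node count of the candidate absorbing community.
#' @param alpha Threshold in `(0, 1]`.
#' @return Logical.
#' @examples
#' should_merge(10, 5, 16, 7, alpha = 1) # 16/7 = 2.286 > 10/5 = 2 -> TRUE
#' @export
should_merge <- function(intra_target, size_target, inter_links,
                         size_neighbour, alpha = 1) {
  stopifnot(alpha > 0, alpha <= 1)
  inter_links * size_target > alpha * intra_target * size_neighbour
}

# One full merging stage at a given alpha on the internal state. Scans
# communities ascending by size (ties by id); for the current target, candidate
# absorbers are its neighbouring communities by descending inter-link count
# (ties by id); on the first satisfied criterion the target's members adopt the
# absorber's label and the scan restarts. Stops when a scan performs no merge.
i_merge_pass <- function(graph, st, alpha) {
  repeat {
    ids <- st_comms_by_size(st)
    if (length(ids) <= 1L) return(invisible(NULL))
    sizes <- tabulate(st$label, nbins = max(ids))
    intra <- vapply(ids, function(c) sum(st$intra[st_members(st, c)]) %/% 2L,
                    integer(1))
    names(intra) <- as.character(ids)
    # inter-community link counts from the edge list
    l1 <- st$label[graph$edges[, 1L]]
    l2 <- st$label[graph$edges[, 2L]]
    cross <- l1 > 0L & l2 > 0L & l1 != l2
    ca <- pmin(l1[cross], l2[cross])
    cb <- pmax(l1[cross], l2[cross])
    key <- paste(ca, cb)
    cnt <- table(key)
    merged <- FALSE
    for (a in ids) {
      mem_a <- st_members(st, a)
      if (length(mem_a) == 0L) next
      intra_a <- intra[[as.character(a)]]
      size_a <- sizes[a]
      # neighbouring communities of a with their inter-link counts
      pref <- ifelse(ids < a, paste(ids, a), paste(a, ids))
      inter <- as.integer(cnt[pref])
      inter[is.na(inter)] <- 0L
      nbr <- ids[ids != a & inter > 0L]
      if (length(nbr) == 0L) next
      inter_n <- inter[match(nbr, ids)]
      ordn <- order(-inter_n, nbr, method = "radix")
      nbr <- nbr[ordn]
      inter_n <- inter_n[ordn]
      for (k in seq_along(nbr)) {
        b <- nbr[k]
        if (should_merge(intra_a, size_a, inter_n[k], sizes[b], alpha)) {
          for (v in mem_a) st_set_label(graph, st, v, b)
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(invisible(NULL))
  }
}

#' Run one community-merging stage
#'
#' Applies the merge criterion of [should_merge()] repeatedly under a fixed,
#' deterministic scan order until no further merge is possible.
#'
#' @inheritParams node_capacity
#' @param alpha Merge threshold in `(0, 1]`.
#' @return The updated membership tibble (`NA` community = solo, unchanged).
#' @export
merge_pass <- function(graph, membership, alpha = 1) {
  stopifnot(alpha > 0, alpha <= 1)
  graph <- as_cd_graph(graph)
  st <- state_from_membership(graph, membership)
  i_merge_pass(graph, st, alpha)
  state_to_membership(graph, st)
}
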