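# Partition-agreement and partition-quality metrics. Entropy-based metrics
# use natural logarithms throughout; both NVI and NMI are invariant to the
# base, so the choice is cosmetic.

contingency_counts <- function(lx, ly) {
  ux <- unique(lx)
  uy <- unique(ly)
  tab <- table(factor(lx, levels = ux), factor(ly, levels = uy))
  matrix(as.numeric(tab), nrow = length(ux))
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' Variation of information between two partitions
#'
#' `VI(X, Y) = H(X) + H(Y) - 2 I(X, Y)`; the normalized form divides by
#' `log n`, the maximum attainable on `n` nodes, so `nvi` is 0 for identical
#' partitions and 1 between the all-singletons and the one-community
#' partition.
#'
#' @param x,y Membership data frames `(node, community)` over the same node
#'   set (or named community vectors).
#' @return A tibble with columns `vi` and `nvi`.
#' @export
variation_of_information <- function(x, y) {
  al <- aligned_labels(x, y)
  n <- length(al$x)
  nxy <- contingency_counts(al$x, al$y) / n
  px <- rowSums(nxy)
  py <- colSums(nxy)
  hx <- -sum(xlogx(px))
  hy <- -sum(xlogx(py))
  hxy <- -sum(xlogx(nxy))
  mi <- hx + hy - hxy
  vi <- hx + hy - 2 * mi
  vi <- max(vi, 0)  # clamp tiny negative rounding residue
  tibble::tibble(vi = vi, nvi = if (n > 1) vi / log(n) else 0)
}

#' Normalized mutual information between two partitions
#'
#' The confusion-matrix form: `-2 sum_ij N_ij log(N_ij N / (N_i. N_.j))`
#' divided by `sum_i N_i. log(N_i./N) + sum_j N_.j log(N_.j/N)`. Equals 1 for
#' identical partitions and 0 when one partition is a single community while
#' the other is not.
#'
#' @inheritParams variation_of_information
#' @return A number in `[0, 1]`.
#' @export
normalized_mutual_information <- function(x, y) {
  al <- aligned_labels(x, y)
  n <- length(al$x)
  nij <- contingency_counts(al$x, al$y)
  ni <- rowSums(nij)
  nj <- colSums(nij)
  if (length(ni) == 1L && length(nj) == 1L) return(1)  # identical trivial
  outer_exp <- outer(ni, nj) / n
  terms <- ifelse(nij > 0, nij * log(nij / outer_exp), 0)
  num <- -2 * sum(terms)
  den <- sum(xlogx(ni / n)) * n + sum(xlogx(nj / n)) * n
  if (den == 0) return(0)
  num / den
}

aligned_labels <- function(x, y) {
  as_named <- function(p) {
    if (is.data.frame(p)) {
      stats::setNames(as.character(p[[2L]]), as.character(p[[1L]]))
    } else if (!is.null(names(p))) {
      stats::setNames(as.character(p), names(p))
    } else {
      stop("partitions must be data frames (node, community) or named vectors",
           call. = FALSE)
    }
  }
  px <- as_named(x)
  py <- as_named(y)
  if (length(px) != length(py) || !setequal(names(px), names(py))) {
    stop("partitions must cover the same node set", call. = FALSE)
  }
  nodes <- names(px)
  list(x = unname(px), y = unname(py[nodes]))
}

#' Modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - d_i d_j / 2m) delta(c_i, c_j)`: the fraction
#' of intra-community edges minus its expectation under the degree-preserving
#' null model. A single all-node community has `Q = 0`; `Q <= 1` always (it
#' can be negative for adversarial partitions).
#'
#' @param graph A graph ([cd_graph()], edge data frame, or edge-list path).
#' @param partition Membership data frame `(node, community)`, total.
#' @return A number `<= 1`.
#' @export
modularity_q <- function(graph, partition) {
  graph <- as_cd_graph(graph)
  i_modularity(graph, partition_vector(graph, partition))
}

i_modularity <- function(graph, lab) {
  m <- graph$m
  if (m == 0L) return(0)
  l1 <- lab[graph$edges[, 1L]]
  l2 <- lab[graph$edges[, 2L]]
  ids <- unique(lab)
  m_in <- vapply(ids, function(c) sum(l1 == c & l2 == c), numeric(1))
  d_c <- vapply(ids, function(c) sum(graph$degree[lab == c]), numeric(1))
  sum(m_in / m - (d_c / (2 * m))^2)
}

#' Modularity density of a partition
#'
#' A density-weighted modularity variant that counteracts the resolution
#' limit and the tendency to split large communities. For each community
#' `c` with `n_c` nodes, `m_in` intra-links, `m_out` inter-links and internal
#' density `d_c = 2 m_in / (n_c (n_c - 1))` (defined as 0 for singletons),
#' the contribution is `(m_in/m) d_c - ((2 m_in + m_out) d_c / (2m))^2 -
#' sum_{c' != c} (m_cc' / 2m) d_cc'` with pairwise density
#' `d_cc' = m_cc' / (n_c n_c')`.
#'
#' @inheritParams modularity_q
#' @return A number.
#' @export
modularity_density <- function(graph, partition) {
  graph <- as_cd_graph(graph)
  i_modularity_density(graph, partition_vector(graph, partition))
}

i_modularity_density <- function(graph, lab) {
  m <- graph$m
  if (m == 0L) return(0)
  l1 <- lab[graph$edges[, 1L]]
  l2 <- lab[graph$edges[, 2L]]
  ids <- sort(unique(lab))
  k <- length(ids)
  li1 <- match(l1, ids)
  li2 <- match(l2, ids)
  n_c <- as.numeric(tabulate(match(lab, ids), nbins = k))
  m_in <- numeric(k)
  cross <- matrix(0, k, k)
  intra <- li1 == li2
  if (any(intra)) {
    tin <- tapply(rep(1, sum(intra)), li1[intra], sum)
    m_in[as.integer(names(tin))] <- as.numeric(tin)
  }
  if (any(!intra)) {
    a <- pmin(li1[!intra], li2[!intra])
    b <- pmax(li1[!intra], li2[!intra])
    for (e in seq_along(a)) {
      cross[a[e], b[e]] <- cross[a[e], b[e]] + 1
      cross[b[e], a[e]] <- cross[b[e], a[e]] + 1
    }
  }
  m_out <- rowSums(cross)
  d_c <- ifelse(n_c > 1, 2 * m_in / (n_c * (n_c - 1)), 0)
  total <- 0
  for (i in seq_len(k)) {
    pair_term <- 0
    if (k > 1L) {
      others <- setdiff(seq_len(k), i)
      d_cc <- cross[i, others] / (n_c[i] * n_c[others])
      pair_term <- sum(cross[i, others] / (2 * m) * d_cc)
    }
    total <- total + m_in[i] / m * d_c[i] -
      ((2 * m_in[i] + m_out[i]) / (2 * m) * d_c[i])^2 - pair_term
  }
  total
}

#' Evaluate a partition against a graph (and optionally a reference)
#'
#' Computes modularity and modularity density of the partition and, when a
#' reference partition is supplied, the normalized variation of information
#' and normalized mutual information against it.
#'
#' @inheritParams modularity_q
#' @param truth Optional reference membership data frame.
#' @return A one-row tibble: `n`, `m`, `n_communities`, `q`, `q_ds` and (with
#'   `truth`) `nvi`, `nmi`.
#' @export
evaluate_partition <- function(graph, partition, truth = NULL) {
  graph <- as_cd_graph(graph)
  if (inherits(partition, "clpagnr")) partition <- partition$membership
  lab <- partition_vector(graph, partition)
  out <- tibble::tibble(
    n = graph$n,
    m = graph$m,
    n_communities = length(unique(lab)),
    q = i_modularity(graph, lab),
    q_ds = i_modularity_density(graph, lab)
  )
  if (!is.null(truth)) {
    out$nvi <- variation_of_information(partition, truth)$nvi
    out$nmi <- normalized_mutual_information(partition, truth)
  }
  out
}
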