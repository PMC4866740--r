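# Fixture builders and independent brute-force oracles used across the suite.

clique_edges <- function(prefix, k) {
  pr <- t(utils::combn(paste0(prefix, seq_len(k)), 2L))
  data.frame(from = pr[, 1L], to = pr[, 2L])
}

triangle <- function() data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"))

two_cliques <- function(k, bridge = TRUE) {
  e <- rbind(clique_edges("a", k), clique_edges("b", k))
  if (bridge) e <- rbind(e, data.frame(from = "a1", to = "b1"))
  e
}

# Erdos-Renyi edge table on nodes "1".."n" (may leave isolated nodes out of
# the edge table; pass nodes= to cd_graph when they matter).
er_edges <- function(n, p, seed) {
  set.seed(seed)
  pr <- t(utils::combn(seq_len(n), 2L))
  keep <- stats::runif(nrow(pr)) < p
  data.frame(from = as.character(pr[keep, 1L]), to = as.character(pr[keep, 2L]))
}

random_partition <- function(nodes, k, seed) {
  set.seed(seed)
  data.frame(node = nodes, community = sample.int(k, length(nodes), replace = TRUE))
}

# --- brute-force oracles -----------------------------------------------------

brute_degree <- function(graph) {
  df <- as.data.frame(graph)
  vapply(graph$nodes, function(v) sum(df$from == v) + sum(df$to == v), integer(1))
}

brute_mns <- function(graph, x, y) {
  df <- as.data.frame(graph)
  nbr <- function(v) unique(c(df$to[df$from == v], df$from[df$to == v]))
  length(intersect(nbr(x), nbr(y)))
}

# Direct entropy-sum evaluation of VI from the joint label distribution.
brute_vi <- function(x, y) {
  merged <- merge(x, y, by = 1)
  n <- nrow(merged)
  joint <- table(merged[[2L]], merged[[3L]]) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (joint[i, j] > 0) {
        mi <- mi + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
      }
    }
  }
  as.numeric(h(px) + h(py) - 2 * mi)
}

brute_nmi <- function(x, y) {
  merged <- merge(x, y, by = 1)
  n <- nrow(merged)
  nij <- table(merged[[2L]], merged[[3L]])
  ni <- rowSums(nij)
  nj <- colSums(nij)
  num <- 0
  for (i in seq_along(ni)) {
    for (j in seq_along(nj)) {
      if (nij[i, j] > 0) {
        num <- num - 2 * nij[i, j] * log(nij[i, j] * n / (ni[i] * nj[j]))
      }
    }
  }
  den <- sum(ni * log(ni / n)) + sum(nj * log(nj / n))
  if (den == 0) return(if (identical(unname(as.vector(nij)), n)) 1 else 0)
  as.numeric(num / den)
}

# Edge-loop evaluation of modularity straight from its double-sum definition.
brute_modularity <- function(graph, partition) {
  lab <- setNames(partition[[2L]], partition[[1L]])
  df <- as.data.frame(graph)
  m <- nrow(df)
  deg <- brute_degree(graph)
  q <- 0
  for (i in graph$nodes) {
    for (j in graph$nodes) {
      if (lab[[i]] != lab[[j]]) next
      a_ij <- sum((df$from == i & df$to == j) | (df$from == j & df$to == i))
      q <- q + a_ij - deg[[i]] * deg[[j]] / (2 * m)
    }
  }
  as.numeric(q / (2 * m))
}

# Term-by-term modularity density from per-community counts.
brute_modularity_density <- function(graph, partition) {
  lab <- setNames(partition[[2L]], partition[[1L]])
  df <- as.data.frame(graph)
  m <- nrow(df)
  comms <- unique(partition[[2L]])
  el <- cbind(lab[df$from], lab[df$to])
  total <- 0
  for (c in comms) {
    nc <- sum(partition[[2L]] == c)
    m_in <- sum(el[, 1L] == c & el[, 2L] == c)
    m_out <- sum(xor(el[, 1L] == c, el[, 2L] == c))
    d_c <- if (nc > 1) 2 * m_in / (nc * (nc - 1)) else 0
    pair <- 0
    for (c2 in setdiff(comms, c)) {
      n2 <- sum(partition[[2L]] == c2)
      m_cc <- sum((el[, 1L] == c & el[, 2L] == c2) | (el[, 1L] == c2 & el[, 2L] == c))
      pair <- pair + m_cc / (2 * m) * (m_cc / (nc * n2))
    }
    total <- total + m_in / m * d_c - ((2 * m_in + m_out) / (2 * m) * d_c)^2 - pair
  }
  as.numeric(total)
}

karate_path <- function() {
  p <- system.file("extdata", "karate.edges", package = "clpagnr")
  if (nzchar(p)) p else testthat::test_path("..", "..", "inst", "extdata", "karate.edges")
}

expect_valid_membership <- function(graph, membership) {
  expect_setequal(membership$node, graph$nodes)
  expect_false(any(duplicated(membership$node)))
}
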