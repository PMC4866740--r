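test_that("node capacity reproduces the worked four-neighbour scenario", {
  ex <- example_capacity_graph()
  expect_equal(node_capacity(ex$graph, ex$membership, "K"), 0.500)
  expect_equal(node_capacity(ex$graph, ex$membership, "N"), 4 / 12)
  # the printed 3-d.p. values are 1.063 and 0.958
  expect_equal(acceptance_capability(ex$graph, ex$membership, "J", 1), 5 / 10 + 9 / 16)
  expect_equal(acceptance_capability(ex$graph, ex$membership, "J", 2), 5 / 8 + 4 / 12)
})

test_that("capacity is 0 for fully internal nodes and lies in [0, 1]", {
  g <- cd_graph(clique_edges("c", 5))
  mem <- data.frame(node = g$nodes, community = 1L)
  for (v in g$nodes) {
    cap <- node_capacity(g, mem, v)
    expect_equal(cap, 0)
  }
  g2 <- cd_graph(two_cliques(4))
  mem2 <- data.frame(node = g2$nodes,
                     community = ifelse(grepl("^a", g2$nodes), 1L, 2L))
  caps <- vapply(g2$nodes, function(v) node_capacity(g2, mem2, v), numeric(1))
  expect_true(all(caps >= 0 & caps <= 1))
})

test_that("links_into matches a brute-force edge filter", {
  g <- cd_graph(er_edges(30, 0.2, seed = 12))
  mem <- random_partition(g$nodes, 4, seed = 13)
  df <- as.data.frame(g)
  for (v in g$nodes[1:10]) {
    for (c in 1:2) {
      comm_nodes <- mem$node[match(mem$community, unique(mem$community)) == c]
      expected <- sum((df$from == v & df$to %in% comm_nodes) |
                        (df$to == v & df$from %in% comm_nodes))
      expect_equal(links_into(g, mem, v, c), expected)
    }
  }
  tri <- cd_graph(rbind(triangle(), data.frame(from = "v", to = c("a", "b"))))
  mem_tri <- data.frame(node = tri$nodes,
                        community = ifelse(tri$nodes == "v", NA, 1L))
  expect_equal(links_into(tri, mem_tri, "v", 1), 2L)
})

test_that("the four admission conditions bracket the minimum intra count", {
  tri <- cd_graph(rbind(triangle(), data.frame(from = "v", to = c("a", "b"))))
  mem <- data.frame(node = tri$nodes, community = ifelse(tri$nodes == "v", NA, 1L))
  # q = 2 (a and b have 2 intra links... a also links v but v is solo)
  expect_false(condition_satisfied(tri, mem, "v", 1, 1)) # 2 > 2 fails
  expect_true(condition_satisfied(tri, mem, "v", 1, 2))  # 2 >= 2
  expect_true(condition_satisfied(tri, mem, "v", 1, 3))  # 2 > 1
  expect_true(condition_satisfied(tri, mem, "v", 1, 4))

  # a freshly seeded pair: q = 1, one link in
  pair <- cd_graph(data.frame(from = c("p", "p"), to = c("q", "v")))
  memp <- data.frame(node = pair$nodes,
                     community = ifelse(pair$nodes == "v", NA, 1L))
  expect_false(condition_satisfied(pair, memp, "v", 1, 1))
  expect_true(condition_satisfied(pair, memp, "v", 1, 2))
  expect_true(condition_satisfied(pair, memp, "v", 1, 3))  # 1 > 0.5, exact halving
  expect_true(condition_satisfied(pair, memp, "v", 1, 4))

  # zero links fail everything when q > 0
  g2 <- cd_graph(rbind(triangle(), data.frame(from = "x", to = "y")))
  mem2 <- data.frame(node = g2$nodes,
                     community = ifelse(g2$nodes %in% c("a", "b", "c"), 1L, NA))
  expect_false(any(vapply(1:4, function(k)
    condition_satisfied(g2, mem2, "x", 1, k), logical(1))))
})

test_that("community stats agree with a from-scratch recount", {
  g <- cd_graph(er_edges(30, 0.2, seed = 21))
  mem <- random_partition(g$nodes, 3, seed = 22)
  stats <- community_stats(g, mem)
  df <- as.data.frame(g)
  lab <- setNames(mem$community, mem$node)
  for (i in seq_len(nrow(stats))) {
    c <- unique(mem$community[order(match(mem$node, g$nodes))])[i]
    nodes_c <- mem$node[mem$community == c]
    intra <- sum(lab[df$from] == c & lab[df$to] == c)
    inter <- sum(xor(lab[df$from] == c, lab[df$to] == c))
    expect_equal(stats$size[i], length(nodes_c))
    expect_equal(stats$intra_links[i], intra)
    expect_equal(stats$inter_links[i], inter)
  }
  expect_equal(sum(stats$size), g$n)
})

test_that("the merge criterion matches its worked ratio and is strict", {
  expect_true(should_merge(10, 5, 16, 7, alpha = 1))   # 2.286 > 2
  expect_false(should_merge(10, 5, 10, 5, alpha = 1))  # equal densities
  expect_false(should_merge(10, 5, 0, 7, alpha = 0.5)) # no inter links
})

test_that("merging is monotone in alpha", {
  for (seed in 1:20) {
    set.seed(seed)
    intra <- sample(0:20, 1); st <- sample(1:10, 1)
    inter <- sample(0:20, 1); sn <- sample(1:10, 1)
    alphas <- sort(runif(5))
    res <- vapply(alphas, function(a) should_merge(intra, st, inter, sn, a), logical(1))
    # once FALSE at some alpha, FALSE at every larger alpha
    expect_true(all(diff(as.integer(res)) <= 0))
  }
})

test_that("a merge pass absorbs sparse fragments but spares dense cliques", {
  # worked pair: A (5 nodes, 10 intra) vs B (7 nodes, 16 inter links to A)
  a_nodes <- paste0("a", 1:5)
  b_nodes <- paste0("b", 1:7)
  set.seed(31)
  a_intra <- t(utils::combn(a_nodes, 2))[sample(10, 10), ]   # all 10 pairs
  b_intra <- t(utils::combn(b_nodes, 2))
  cross <- expand.grid(from = a_nodes, to = b_nodes, stringsAsFactors = FALSE)
  cross <- cross[sample(nrow(cross), 16), ]
  edges <- rbind(data.frame(from = a_intra[, 1], to = a_intra[, 2]),
                 data.frame(from = b_intra[, 1], to = b_intra[, 2]),
                 cross)
  g <- cd_graph(edges)
  mem <- data.frame(node = g$nodes,
                    community = ifelse(grepl("^a", g$nodes), 1L, 2L))
  merged <- merge_pass(g, mem, alpha = 1)
  expect_equal(length(unique(merged$community)), 1L)

  g2 <- cd_graph(two_cliques(4))
  mem2 <- data.frame(node = g2$nodes,
                     community = ifelse(grepl("^a", g2$nodes), 1L, 2L))
  expect_equal(merge_pass(g2, mem2, alpha = 1), dplyr::as_tibble(mem2))

  one <- data.frame(node = g2$nodes, community = 1L)
  expect_equal(merge_pass(g2, one, alpha = 0.5)$community, one$community)
})
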