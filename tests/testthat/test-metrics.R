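test_that("variation of information hits its closed-form anchors", {
  nodes <- as.character(1:12)
  p <- data.frame(node = nodes, community = rep(1:3, each = 4))
  expect_equal(variation_of_information(p, p)$nvi, 0)
  singletons <- data.frame(node = nodes, community = seq_along(nodes))
  whole <- data.frame(node = nodes, community = 1L)
  expect_equal(variation_of_information(singletons, whole)$nvi, 1)
})

test_that("NVI and NMI match brute-force entropy evaluation on random partitions", {
  for (seed in 1:25) {
    nodes <- as.character(seq_len(10 + (seed %% 20)))
    x <- random_partition(nodes, 2 + seed %% 4, seed)
    y <- random_partition(nodes, 2 + (seed + 3) %% 4, seed + 100)
    got <- variation_of_information(x, y)
    expect_equal(got$vi, brute_vi(x, y), tolerance = 1e-12)
    expect_equal(normalized_mutual_information(x, y), brute_nmi(x, y),
                 tolerance = 1e-12)
  }
})

test_that("VI behaves as a metric on partitions", {
  nodes <- as.character(1:15)
  for (seed in 1:10) {
    x <- random_partition(nodes, 3, seed)
    y <- random_partition(nodes, 3, seed + 40)
    z <- random_partition(nodes, 4, seed + 80)
    vxy <- variation_of_information(x, y)$vi
    vyx <- variation_of_information(y, x)$vi
    expect_equal(vxy, vyx, tolerance = 1e-12)
    vxz <- variation_of_information(x, z)$vi
    vzy <- variation_of_information(z, y)$vi
    expect_lte(vxy, vxz + vzy + 1e-12)
  }
  x <- random_partition(nodes, 3, 7)
  expect_equal(variation_of_information(x, x)$vi, 0)
})

test_that("NVI and NMI are invariant to community relabeling", {
  nodes <- as.character(1:20)
  x <- random_partition(nodes, 4, 5)
  y <- random_partition(nodes, 3, 6)
  y2 <- y
  y2$community <- match(y$community, c(3, 1, 2))  # permuted labels
  expect_equal(variation_of_information(x, y), variation_of_information(x, y2))
  expect_equal(normalized_mutual_information(x, y),
               normalized_mutual_information(x, y2))
})

test_that("NMI anchors: identical partitions give 1, a trivial side gives 0", {
  nodes <- as.character(1:10)
  p <- data.frame(node = nodes, community = rep(1:2, 5))
  expect_equal(normalized_mutual_information(p, p), 1)
  whole <- data.frame(node = nodes, community = 1L)
  expect_equal(normalized_mutual_information(whole, p), 0)
})

test_that("modularity matches its definition and closed-form anchors", {
  g <- cd_graph(two_cliques(3, bridge = FALSE))
  p <- data.frame(node = g$nodes, community = ifelse(grepl("^a", g$nodes), 1, 2))
  expect_equal(modularity_q(g, p), 0.5)
  expect_equal(modularity_q(g, data.frame(node = g$nodes, community = 1L)), 0)
  for (seed in 1:10) {
    gr <- cd_graph(er_edges(18, 0.25, seed = seed))
    pr <- random_partition(gr$nodes, 3, seed + 7)
    expect_equal(modularity_q(gr, pr), brute_modularity(gr, pr),
                 tolerance = 1e-12)
  }
})

test_that("modularity density matches the per-community closed form", {
  g <- cd_graph(two_cliques(3, bridge = FALSE))
  p <- data.frame(node = g$nodes, community = ifelse(grepl("^a", g$nodes), 1, 2))
  # per triangle: (3/6)*1 - (6/12*1)^2 = 0.25
  expect_equal(modularity_density(g, p), 0.5)
  clique <- cd_graph(clique_edges("k", 5))
  one <- data.frame(node = clique$nodes, community = 1L)
  expect_equal(modularity_density(clique, one),
               brute_modularity_density(clique, one), tolerance = 1e-12)
  for (seed in 1:10) {
    gr <- cd_graph(er_edges(16, 0.3, seed = seed + 30))
    pr <- random_partition(gr$nodes, 3, seed + 60)
    expect_equal(modularity_density(gr, pr),
                 brute_modularity_density(gr, pr), tolerance = 1e-12)
  }
})

test_that("singleton communities contribute finite modularity-density terms", {
  g <- cd_graph(rbind(triangle(), data.frame(from = "a", to = "d")))
  p <- data.frame(node = g$nodes, community = c(1, 1, 1, 2))  # d alone
  expect_true(is.finite(modularity_density(g, p)))
  expect_equal(modularity_density(g, p), brute_modularity_density(g, p),
               tolerance = 1e-12)
})

test_that("evaluate_partition assembles all applicable metrics", {
  g <- cd_graph(two_cliques(4, bridge = FALSE))
  p <- data.frame(node = g$nodes, community = ifelse(grepl("^a", g$nodes), 1, 2))
  rep1 <- evaluate_partition(g, p, truth = p)
  expect_equal(rep1$nvi, 0)
  expect_equal(rep1$nmi, 1)
  expect_equal(rep1$n_communities, 2L)
  rep2 <- evaluate_partition(g, data.frame(node = g$nodes, community = 1L))
  expect_equal(rep2$q, 0)
  expect_false("nmi" %in% names(rep2))
})

test_that("ground truth of an unmixed benchmark has positive modularity", {
  inst <- generate_gn(0, seed = 2)
  expect_gt(modularity_q(inst$graph, inst$truth), 0.5)
})
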