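# Benchmark graph generators with planted ground truth: LFR (power-law
# degrees and community sizes), Girvan-Newman (128 nodes, four groups of 32,
# degree 16), and relaxed caveman (16 cliques of heterogeneous sizes,
# degraded by rewiring). All generation is seeded and implemented as a stub
# (configuration) model with rejection/repair of self-loops, duplicate edges
# and constraint-violating pairs.

round_half_up <- function(x) floor(x + 0.5)

# Discrete truncated power-law sampler: P(s) proportional to s^-expo on
# lo..hi (uniform when expo == 0).
sample_power_law <- function(n, expo, lo, hi) {
  support <- lo:hi
  w <- if (expo == 0) rep(1, length(support)) else support^(-expo)
  support[sample.int(length(support), n, replace = TRUE, prob = w)]
}

# Degree sampler whose expectation equals `mean_k` exactly: support kmin..maxk
# with power-law weights d^-gamma, where kmin and a fractional weight on the
# boundary degree solve the mean constraint.
sample_degrees <- function(n, mean_k, maxk, gamma) {
  stopifnot(mean_k >= 1, mean_k <= maxk)
  e_mean <- function(kmin) {
    d <- kmin:maxk
    sum(d^(1 - gamma)) / sum(d^(-gamma))
  }
  kmin <- 1L
  while (kmin < maxk && e_mean(kmin + 1L) <= mean_k) kmin <- kmin + 1L
  d <- kmin:maxk
  w <- d^(-gamma)
  if (e_mean(kmin) < mean_k && kmin < maxk) {
    # scale the boundary weight so the expectation is exactly mean_k
    a0 <- sum(w[-1L])
    a1 <- sum((d^(1 - gamma))[-1L])
    frac <- (mean_k * a0 - a1) / (kmin^(-gamma) * (kmin - mean_k))
    w[1L] <- frac * kmin^(-gamma)
  }
  d[sample.int(length(d), n, replace = TRUE, prob = w)]
}

# Community sizes from a truncated power law, adjusted to sum exactly to N.
sample_community_sizes <- function(n_total, expo, minc, maxc) {
  sizes <- integer(0)
  while (sum(sizes) < n_total) {
    sizes <- c(sizes, sample_power_law(1L, expo, minc, maxc))
  }
  excess <- sum(sizes) - n_total
  while (excess > 0L) {
    i <- which.max(sizes)
    cut <- min(excess, sizes[i] - minc)
    if (cut == 0L) {
      # every community at minc: drop one and restart the trim
      sizes <- sizes[-length(sizes)]
      excess <- sum(sizes) - n_total
      if (excess < 0L) {
        sizes <- c(sizes, sample_power_law(1L, expo, minc, maxc))
        excess <- sum(sizes) - n_total
      }
      next
    }
    sizes[i] <- sizes[i] - cut
    excess <- excess - cut
  }
  sizes
}

# Assign nodes to communities so each node's intra-degree fits (community
# size > d_in). Random placement with kick-outs, as in standard LFR builders.
assign_to_communities <- function(d_in, sizes) {
  n <- length(d_in)
  k <- length(sizes)
  comm <- integer(n)           # 0 = unassigned
  fill <- integer(k)
  queue <- sample.int(n)
  guard <- 0L
  while (length(queue) > 0L) {
    guard <- guard + 1L
    if (guard > 200L * n) {
      # stubborn leftovers: cap their intra-degree to the largest community
      v <- queue[1L]
      d_in[v] <- max(0L, max(sizes) - 1L)
      guard <- 0L
    }
    v <- queue[1L]
    queue <- queue[-1L]
    big_enough <- which(sizes > d_in[v])
    if (length(big_enough) == 0L) {
      d_in[v] <- max(sizes) - 1L
      big_enough <- which(sizes > d_in[v])
    }
    open <- big_enough[fill[big_enough] < sizes[big_enough]]
    if (length(open) > 0L) {
      c <- if (length(open) == 1L) open else sample(open, 1L)
      comm[v] <- c
      fill[c] <- fill[c] + 1L
    } else {
      c <- if (length(big_enough) == 1L) big_enough else sample(big_enough, 1L)
      kick <- sample(which(comm == c), 1L)
      comm[kick] <- 0L
      fill[c] <- fill[c] - 1L
      comm[v] <- c
      fill[c] <- fill[c] + 1L
      queue <- c(queue, kick)
    }
  }
  list(comm = comm, d_in = d_in)
}

# Random matching of a stub multiset into simple edges. `bad_pair(a, b)`
# flags forbidden pairs (beyond self-loops and duplicates, which are always
# forbidden). Unmatchable leftovers are dropped after `max_rounds`.
match_stubs <- function(stubs, n, existing_keys = numeric(0),
                        bad_pair = NULL, max_rounds = 300L) {
  edges <- matrix(integer(0), ncol = 2)
  keys <- existing_keys
  pool <- stubs
  rounds <- 0L
  while (length(pool) >= 2L && rounds < max_rounds) {
    rounds <- rounds + 1L
    pool <- pool[sample.int(length(pool))]
    if (length(pool) %% 2L == 1L) {
      odd <- pool[length(pool)]
      pool <- pool[-length(pool)]
    } else {
      odd <- integer(0)
    }
    a <- pmin(pool[c(TRUE, FALSE)], pool[c(FALSE, TRUE)])
    b <- pmax(pool[c(TRUE, FALSE)], pool[c(FALSE, TRUE)])
    key <- (a - 1) * n + b
    bad <- a == b | key %in% keys | duplicated(key)
    if (!is.null(bad_pair)) bad <- bad | bad_pair(a, b)
    if (any(!bad)) {
      edges <- rbind(edges, cbind(a[!bad], b[!bad]))
      keys <- c(keys, key[!bad])
    }
    pool <- c(rbind(a[bad], b[bad]), odd)
    if (all(bad) && length(odd) == 0L && rounds > 50L) {
      # stalled: try edge swaps against accepted edges to free up stubs
      if (nrow(edges) > 0L && length(pool) >= 2L) {
        e <- sample.int(nrow(edges), 1L)
        pool <- c(pool, edges[e, ])
        keys <- keys[-match((edges[e, 1L] - 1) * n + edges[e, 2L], keys)]
        edges <- edges[-e, , drop = FALSE]
      } else {
        break
      }
    }
  }
  list(edges = edges, keys = keys, dropped = length(pool))
}

new_benchmark_instance <- function(graph, truth_comm, spec) {
  truth <- tibble::tibble(node = graph$nodes,
                          community = canonicalize_labels(truth_comm))
  l1 <- truth_comm[graph$edges[, 1L]]
  l2 <- truth_comm[graph$edges[, 2L]]
  structure(
    list(graph = graph, truth = truth, spec = spec,
         realized_mixing = if (graph$m > 0) mean(l1 != l2) else 0),
    class = "benchmark_instance"
  )
}

#' @export
print.benchmark_instance <- function(x, ...) {
  cat(sprintf("<benchmark_instance> %s: %d nodes, %d edges, %d communities, realized mixing %.3f\n",
              x$spec$family, x$graph$n, x$graph$m,
              length(unique(x$truth$community)), x$realized_mixing))
  invisible(x)
}

#' @export
tidy.benchmark_instance <- function(x, ...) x$truth

#' @export
glance.benchmark_instance <- function(x, ...) {
  tibble::tibble(family = x$spec$family, n = x$graph$n, m = x$graph$m,
                 n_communities = length(unique(x$truth$community)),
                 realized_mixing = x$realized_mixing)
}

# Shared LFR-style stub construction once nodes carry (community, d_in,
# d_out). Returns the edge index matrix.
build_mixed_edges <- function(comm, d_in, d_out, n) {
  sizes <- tabulate(comm)
  # intra-degree cannot exceed community size - 1
  over <- d_in > sizes[comm] - 1L
  d_out[over] <- d_out[over] + d_in[over] - (sizes[comm[over]] - 1L)
  d_in[over] <- sizes[comm[over]] - 1L

  keys <- numeric(0)
  edges <- matrix(integer(0), ncol = 2)
  for (c in seq_along(sizes)) {
    mem <- which(comm == c)
    kin <- d_in[mem]
    if (sum(kin) %% 2L == 1L) {
      # drop the odd stub rather than converting it to an inter-community
      # stub, so mu = 0 keeps every edge intra-community
      i <- which.max(kin)
      kin[i] <- kin[i] - 1L
    }
    res <- match_stubs(rep(mem, kin), n, existing_keys = keys)
    edges <- rbind(edges, res$edges)
    keys <- res$keys
  }
  if (sum(d_out) %% 2L == 1L) {
    i <- which.max(d_out)
    d_out[i] <- d_out[i] - 1L
  }
  res <- match_stubs(rep(seq_len(n), d_out), n, existing_keys = keys,
                     bad_pair = function(a, b) comm[a] == comm[b])
  rbind(edges, res$edges)
}

#' Generate an LFR benchmark instance
#'
#' Standard LFR construction: node degrees from a truncated power law with
#' exponent `gamma` (mean `avg_degree`, maximum `max_degree`); community
#' sizes from a truncated power law with exponent `beta` on
#' `[min_comm, max_comm]` summing to `n`; each node spends a fraction
#' `1 - mu` of its degree on intra-community stubs (rounded half-up, the
#' remainder inter-community); stubs are matched randomly with repair. The
#' defaults are the small/small-degree/small-community configuration
#' (n = 1000, average degree 10, maximum degree 50, community sizes 10–50,
#' gamma = 2, beta = 1).
#'
#' @param mu Mixing parameter in `[0, 1]`: average fraction of a node's edges
#'   leaving its community.
#' @param n Number of nodes.
#' @param avg_degree,max_degree Mean and maximum node degree.
#' @param min_comm,max_comm Community-size bounds.
#' @param gamma,beta Power-law exponents for degrees and community sizes.
#' @param seed RNG seed; the same spec and seed always give the same
#'   instance.
#' @return A `benchmark_instance`: a list with `graph` ([cd_graph()]),
#'   `truth` (membership tibble), `spec`, and `realized_mixing`.
#' @export
generate_lfr <- function(mu, n = 1000, avg_degree = 10, max_degree = 50,
                         min_comm = 10, max_comm = 50, gamma = 2, beta = 1,
                         seed = 1L) {
  stopifnot(mu >= 0, mu <= 1, min_comm <= max_comm, max_comm <= n,
            avg_degree <= max_degree)
  with_preserved_rng({
    set.seed(as.integer(seed))
    deg <- sample_degrees(n, avg_degree, max_degree, gamma)
    sizes <- sample_community_sizes(n, beta, min_comm, max_comm)
    d_in <- as.integer(round_half_up((1 - mu) * deg))
    asg <- assign_to_communities(d_in, sizes)
    d_in <- asg$d_in
    d_out <- deg - d_in
    edges <- build_mixed_edges(asg$comm, d_in, d_out, n)
    graph <- cd_graph(data.frame(from = as.character(edges[, 1L]),
                                 to = as.character(edges[, 2L])),
                      nodes = as.character(seq_len(n)))
    truth <- asg$comm[match(graph$nodes, as.character(seq_len(n)))]
    new_benchmark_instance(graph, truth,
                           list(family = "lfr", mu = mu, n = n,
                                avg_degree = avg_degree,
                                max_degree = max_degree,
                                min_comm = min_comm, max_comm = max_comm,
                                gamma = gamma, beta = beta, seed = seed))
  })
}

#' Generate a Girvan-Newman benchmark instance
#'
#' 128 nodes in four planted groups of 32; every node has 16 edge stubs, of
#' which `round((1 - mu) * 16)` are intra-group and the rest inter-group;
#' stubs are matched uniformly at random avoiding self-loops and duplicate
#' edges.
#'
#' @inheritParams generate_lfr
#' @return A `benchmark_instance`.
#' @export
generate_gn <- function(mu, seed = 1L) {
  stopifnot(mu >= 0, mu <= 1)
  with_preserved_rng({
    set.seed(as.integer(seed))
    n <- 128L
    comm <- rep(1:4, each = 32L)
    kin <- as.integer(round_half_up((1 - mu) * 16))
    d_in <- rep(kin, n)
    d_out <- rep(16L - kin, n)
    edges <- build_mixed_edges(comm, d_in, d_out, n)
    graph <- cd_graph(data.frame(from = as.character(edges[, 1L]),
                                 to = as.character(edges[, 2L])),
                      nodes = as.character(seq_len(n)))
    truth <- comm[match(graph$nodes, as.character(seq_len(n)))]
    new_benchmark_instance(graph, truth,
                           list(family = "gn", mu = mu, seed = seed))
  })
}

# Default relaxed-caveman size vector: 16 draws from a truncated power law
# on [2, 157] with exponent 1, resampled until they sum exactly to 512. With
# exponent 1 the expected sum of 16 draws is ~570, so the rejection loop
# terminates quickly while the realized sizes stay highly heterogeneous,
# typically spanning the whole [2, 157] range. A bounded fallback repairs
# the last draw if the rejection budget is ever exhausted.
rc_default_sizes <- function() {
  for (try in seq_len(100000L)) {
    sizes <- sample_power_law(16L, 1, 2L, 157L)
    if (sum(sizes) == 512L) return(sizes)
  }
  while (sum(sizes) != 512L) {
    i <- which.max(sizes)
    sizes[i] <- min(157L, max(2L, sizes[i] + (512L - sum(sizes))))
  }
  sizes
}

#' Generate a relaxed-caveman benchmark instance
#'
#' Starts from 16 disjoint cliques on 512 nodes with highly heterogeneous
#' sizes, then weakens the structure by removing a fraction `degradation` of
#' each clique's edges and rewiring each removed edge from one retained
#' endpoint to a uniformly chosen node of another community (avoiding
#' duplicates).
#'
#' @param degradation Fraction `D` in `[0, 1]` of each clique's internal
#'   edges to rewire.
#' @param sizes Optional explicit vector of 16 community sizes (each in
#'   `[2, 157]`, summing to 512); by default sizes are drawn from a rescaled
#'   truncated power law.
#' @inheritParams generate_lfr
#' @return A `benchmark_instance`.
#' @export
generate_rc <- function(degradation, sizes = NULL, seed = 1L) {
  stopifnot(degradation >= 0, degradation <= 1)
  with_preserved_rng({
    set.seed(as.integer(seed))
    if (is.null(sizes)) sizes <- rc_default_sizes()
    stopifnot(length(sizes) == 16L, sum(sizes) == 512L,
              min(sizes) >= 2L, max(sizes) <= 157L)
    n <- 512L
    comm <- rep(seq_along(sizes), sizes)
    members <- split(seq_len(n), comm)
    edge_a <- integer(0)
    edge_b <- integer(0)
    for (mem in members) {
      pr <- utils::combn(mem, 2L)
      edge_a <- c(edge_a, pr[1L, ])
      edge_b <- c(edge_b, pr[2L, ])
    }
    keys <- (edge_a - 1) * n + edge_b
    alive <- rep(TRUE, length(keys))
    keyset <- new.env(parent = emptyenv(), size = 4L * length(keys))
    for (k in keys) assign(as.character(k), TRUE, envir = keyset)
    new_a <- integer(0)
    new_b <- integer(0)
    # rewire round(D * m_clique) edges of each clique
    for (c in seq_along(sizes)) {
      in_c <- which(comm[edge_a] == c)
      nrem <- as.integer(round_half_up(degradation * length(in_c)))
      if (nrem == 0L) next
      rem <- if (length(in_c) == 1L) in_c else sample(in_c, nrem)
      for (e in rem) {
        alive[e] <- FALSE
        rm(list = as.character(keys[e]), envir = keyset)
        keep <- if (stats::runif(1) < 0.5) edge_a[e] else edge_b[e]
        for (try in 1:100) {
          t <- sample.int(n, 1L)
          if (comm[t] == c) next
          a2 <- min(keep, t)
          b2 <- max(keep, t)
          k2 <- as.character((a2 - 1) * n + b2)
          if (exists(k2, envir = keyset, inherits = FALSE)) next
          assign(k2, TRUE, envir = keyset)
          new_a <- c(new_a, a2)
          new_b <- c(new_b, b2)
          break
        }
        # if no target found the edge stays removed
      }
    }
    edges <- cbind(c(edge_a[alive], new_a), c(edge_b[alive], new_b))
    graph <- cd_graph(data.frame(from = as.character(edges[, 1L]),
                                 to = as.character(edges[, 2L])),
                      nodes = as.character(seq_len(n)))
    truth <- comm[match(graph$nodes, as.character(seq_len(n)))]
    new_benchmark_instance(graph, truth,
                           list(family = "rc", degradation = degradation,
                                sizes = sizes, seed = seed))
  })
}
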