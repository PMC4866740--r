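# Constrained label propagation (CLPA 1-7), grouped-node reallocation
# (GNR 1-5), dual removal, and the baseline randomized LPA. Every constrained
# pass is an asynchronous sweep under a fixed update sequence with explicit
# tie-breaking (final key: ascending canonical node / community identifier),
# repeated until a sweep changes no label. Only solo->grouped transitions
# happen in CLPA; GNR switches nodes between communities or (variants 1-3)
# removes them back to solo.

MAX_SWEEPS_FACTOR <- 100L

sweep_cap <- function(graph, max_sweeps) {
  if (!is.null(max_sweeps)) return(as.integer(max_sweeps))
  MAX_SWEEPS_FACTOR * max(graph$n, 1L)
}

check_converged <- function(sweeps, cap, what) {
  if (sweeps >= cap) {
    stop(sprintf("%s did not converge within %d sweeps", what, cap),
         call. = FALSE)
  }
}

# ---- CLPA ------------------------------------------------------------------

#' Run one constrained label-propagation pass
#'
#' Allocates solo nodes into existing communities under one of seven
#' progressively relaxed admission schemes; sweeps repeat until no label
#' changes. Variants:
#' * 1 — communities ascending by size; their solo neighbours descending by
#'   degree; join under condition 1.
#' * 2 — as 1 under condition 2.
#' * 3 — solo nodes descending by degree; candidate community = where most
#'   grouped neighbours reside; a tied candidate set blocks the move; join
#'   under condition 3.
#' * 4 — as 3 but a tie is resolved toward the community with the highest
#'   [acceptance_capability()].
#' * 5 — community sweep order of variant 1; candidate = plurality community;
#'   join under condition 3 and only if modularity (solo nodes counted as
#'   singleton communities) strictly increases.
#' * 6 — grouped nodes descending by number of solo neighbours; each adjacent
#'   solo node sharing at least one mutual neighbour with the grouped node
#'   joins its community under condition 4.
#' * 7 — as 4 under condition 4.
#'
#' @param graph A graph ([cd_graph()], edge data frame, or edge-list path).
#' @param membership Data frame `(node, community)`, `NA` = solo.
#' @param variant Integer 1–7.
#' @param max_sweeps Safety cap on sweeps (default `100 * n`); exceeding it is
#'   an error rather than a silent return.
#' @return The updated membership tibble.
#' @export
run_clpa <- function(graph, membership, variant, max_sweeps = NULL) {
  graph <- as_cd_graph(graph)
  st <- state_from_membership(graph, membership)
  i_clpa(graph, st, variant, max_sweeps = max_sweeps)
  state_to_membership(graph, st)
}

i_clpa <- function(graph, st, variant, mnsadj = NULL, max_sweeps = NULL) {
  variant <- as.integer(variant)
  if (is.na(variant) || variant < 1L || variant > 7L) {
    stop("unknown CLPA variant: ", variant, call. = FALSE)
  }
  cap <- sweep_cap(graph, max_sweeps)
  if (variant == 6L && is.null(mnsadj)) {
    mnsadj <- i_mns_adjacency(graph, i_mns_scores(graph))
  }
  sweeps <- 0L
  repeat {
    changed <- switch(variant,
                      clpa_sweep_12(graph, st, cond = 1L),
                      clpa_sweep_12(graph, st, cond = 2L),
                      clpa_sweep_347(graph, st, cond = 3L, tie_capability = FALSE),
                      clpa_sweep_347(graph, st, cond = 3L, tie_capability = TRUE),
                      clpa_sweep_5(graph, st),
                      clpa_sweep_6(graph, st, mnsadj),
                      clpa_sweep_347(graph, st, cond = 4L, tie_capability = TRUE))
    if (!changed) break
    sweeps <- sweeps + 1L
    check_converged(sweeps, cap, paste0("CLPA ", variant))
  }
  invisible(NULL)
}

# Solo neighbours of a community's members, descending degree, ties by index.
solo_neighbours_of <- function(graph, st, members) {
  nb <- unique(unlist(graph$adj[members], use.names = FALSE))
  nb <- nb[st$label[nb] == 0L]
  if (length(nb) == 0L) return(integer(0))
  nb[order(-graph$degree[nb], nb, method = "radix")]
}

clpa_sweep_12 <- function(graph, st, cond) {
  changed <- FALSE
  for (c in st_comms_by_size(st)) {
    mem <- st_members(st, c)
    if (length(mem) == 0L) next
    for (v in solo_neighbours_of(graph, st, mem)) {
      if (st$label[v] != 0L) next
      l <- i_links_into(graph, st, v, c)
      if (i_condition(l, i_qmin(st, c), cond)) {
        st_set_label(graph, st, v, c)
        changed <- TRUE
      }
    }
  }
  changed
}

# Plurality community among a node's grouped neighbours. Returns list(comms,
# counts) of the tied top labels (empty when no grouped neighbour).
plurality_communities <- function(graph, st, v) {
  nl <- st$label[graph$adj[[v]]]
  nl <- nl[nl > 0L]
  if (length(nl) == 0L) return(list(comms = integer(0), count = 0L))
  u <- sort(unique(nl))
  cntv <- tabulate(match(nl, u))
  mx <- max(cntv)
  list(comms = u[cntv == mx], count = mx)
}

# Resolve a tied candidate set by strict highest acceptance capability,
# remaining ties by smallest community id.
resolve_by_capability <- function(graph, st, v, comms) {
  caps <- vapply(comms, function(c) i_capability(graph, st, v, c), numeric(1))
  comms[which.max(caps)]
}

clpa_sweep_347 <- function(graph, st, cond, tie_capability) {
  changed <- FALSE
  solo <- st_solo(st)
  if (length(solo) == 0L) return(FALSE)
  solo <- solo[order(-graph$degree[solo], solo, method = "radix")]
  for (v in solo) {
    if (st$label[v] != 0L) next
    pl <- plurality_communities(graph, st, v)
    if (length(pl$comms) == 0L) next
    if (length(pl$comms) > 1L) {
      if (!tie_capability) next
      c <- resolve_by_capability(graph, st, v, pl$comms)
    } else {
      c <- pl$comms
    }
    l <- i_links_into(graph, st, v, c)
    if (i_condition(l, i_qmin(st, c), cond)) {
      st_set_label(graph, st, v, c)
      changed <- TRUE
    }
  }
  changed
}

clpa_sweep_5 <- function(graph, st) {
  changed <- FALSE
  m <- graph$m
  if (m == 0L) return(FALSE)
  for (c0 in st_comms_by_size(st)) {
    mem <- st_members(st, c0)
    if (length(mem) == 0L) next
    for (v in solo_neighbours_of(graph, st, mem)) {
      if (st$label[v] != 0L) next
      pl <- plurality_communities(graph, st, v)
      if (length(pl$comms) != 1L) next
      c <- pl$comms
      l <- i_links_into(graph, st, v, c)
      if (!i_condition(l, i_qmin(st, c), 3L)) next
      # modularity delta of moving the singleton v into c (solo nodes are
      # treated as singleton communities, so only v's own term moves):
      # dQ = l/m - deg(v) * D_c / (2 m^2), strict increase required
      d_c <- sum(graph$degree[st_members(st, c)])
      dq <- l / m - graph$degree[v] * d_c / (2 * m^2)
      if (dq > 0) {
        st_set_label(graph, st, v, c)
        changed <- TRUE
      }
    }
  }
  changed
}

clpa_sweep_6 <- function(graph, st, mnsadj) {
  changed <- FALSE
  grouped <- which(st$label > 0L)
  if (length(grouped) == 0L) return(FALSE)
  n_solo_nb <- vapply(grouped, function(g) {
    nb <- graph$adj[[g]]
    if (length(nb) == 0L) 0L else sum(st$label[nb] == 0L)
  }, integer(1))
  keep <- n_solo_nb > 0L
  grouped <- grouped[keep]
  n_solo_nb <- n_solo_nb[keep]
  grouped <- grouped[order(-n_solo_nb, grouped, method = "radix")]
  for (g in grouped) {
    c <- st$label[g]
    if (c == 0L) next
    nb <- graph$adj[[g]]
    sc <- mnsadj$score[[g]]
    cand <- nb[st$label[nb] == 0L & sc > 0L]
    for (v in cand) {
      if (st$label[v] != 0L) next
      l <- i_links_into(graph, st, v, c)
      if (i_condition(l, i_qmin(st, c), 4L)) {
        st_set_label(graph, st, v, c)
        changed <- TRUE
      }
    }
  }
  changed
}

# ---- dual removal ----------------------------------------------------------

#' Dissolve every two-node community
#'
#' Two-node communities rarely grow in later stages and create undesirable
#' ties, so they are disbanded: both members become solo.
#'
#' @inheritParams run_clpa
#' @return The updated membership tibble.
#' @export
dual_removal <- function(graph, membership) {
  graph <- as_cd_graph(graph)
  st <- state_from_membership(graph, membership)
  i_dual_removal(graph, st)
  state_to_membership(graph, st)
}

i_dual_removal <- function(graph, st) {
  ids <- st_comm_ids(st)
  if (length(ids) == 0L) return(FALSE)
  sizes <- tabulate(st$label, nbins = max(ids))
  changed <- FALSE
  for (c in ids[sizes[ids] == 2L]) {
    for (v in st_members(st, c)) st_set_label(graph, st, v, 0L)
    changed <- TRUE
  }
  changed
}

# ---- GNR -------------------------------------------------------------------

#' Run one grouped-node reallocation pass
#'
#' Refines an existing assignment by switching grouped nodes to the community
#' where most of their neighbours reside, or removing them back to solo.
#' Variants:
#' * 1 — one-shot quartile pruning (members whose intra-community link count
#'   is below the first quartile of their community's counts are removed;
#'   executed exactly once), then the reallocation loop under condition 1.
#' * 2 — the reallocation loop under condition 1 (no pruning).
#' * 3 — the reallocation loop under condition 3.
#' * 4 — as 3 but a node failing the condition stays put (no removals).
#' * 5 — as 4 with dual removal also disabled.
#'
#' The reallocation loop sweeps grouped nodes in ascending-degree order and
#' classifies each against its neighbours' labels: (1) its own label is the
#' strict plurality — keep; (2) another label is the strict plurality — switch
#' when the condition holds, otherwise remove (variants 1–3) or keep (4–5);
#' (3) tied plurality — when exactly one tied community has the strictly
#' highest [acceptance_capability()], switch under the condition, otherwise
#' remove/keep; a capability tie removes (1–3) or keeps (4–5). Situations 1–2
#' are handled before situation 3 within each sweep, each sweep ends with
#' [dual_removal()] (variants 1–4), and sweeps repeat until nothing changes.
#'
#' @inheritParams run_clpa
#' @param variant Integer 1–5.
#' @return The updated membership tibble.
#' @export
run_gnr <- function(graph, membership, variant, max_sweeps = NULL) {
  graph <- as_cd_graph(graph)
  st <- state_from_membership(graph, membership)
  i_gnr(graph, st, variant, max_sweeps = max_sweeps)
  state_to_membership(graph, st)
}

i_gnr <- function(graph, st, variant, max_sweeps = NULL) {
  variant <- as.integer(variant)
  if (is.na(variant) || variant < 1L || variant > 5L) {
    stop("unknown GNR variant: ", variant, call. = FALSE)
  }
  if (variant == 1L) gnr_quartile_prune(graph, st)
  cond <- if (variant <= 2L) 1L else 3L
  removal <- variant <= 3L
  duals <- variant <= 4L
  cap <- sweep_cap(graph, max_sweeps)
  sweeps <- 0L
  seen <- character(0)
  repeat {
    changed <- gnr_sweep(graph, st, cond, removal)
    if (duals && i_dual_removal(graph, st)) changed <- TRUE
    if (!changed) break
    # asynchronous switching can enter a short limit cycle (e.g. two nodes
    # trading places every sweep); a revisited labeling carries no new
    # information, so it is treated as convergence
    h <- paste(st$label, collapse = ",")
    if (h %in% seen) break
    seen <- c(seen, h)
    sweeps <- sweeps + 1L
    check_converged(sweeps, cap, paste0("GNR ", variant))
  }
  invisible(NULL)
}

# First-quartile pruning (GNR 1 only). Quantile convention: linear
# interpolation with the lower hinge at position (n+2)/4 (stats::quantile
# type 5), under which the multiset 1..8 has Q1 = 2.5. All communities are
# pruned against a snapshot of the counts so the step is genuinely one-shot.
gnr_quartile_prune <- function(graph, st) {
  snapshot <- st$intra
  for (c in st_comm_ids(st)) {
    mem <- st_members(st, c)
    if (length(mem) < 2L) next
    q1 <- stats::quantile(snapshot[mem], probs = 0.25, type = 5, names = FALSE)
    for (v in mem[snapshot[mem] < q1]) st_set_label(graph, st, v, 0L)
  }
  invisible(NULL)
}

# Classify node v against its grouped neighbours' labels. Returns a list:
# situation 1 (keep), 2 (single foreign plurality), 3 (tied plurality), or
# 0 when the node has no grouped neighbour (kept untouched).
gnr_classify <- function(graph, st, v) {
  pl <- plurality_communities(graph, st, v)
  if (length(pl$comms) == 0L) return(list(sit = 0L))
  if (length(pl$comms) == 1L) {
    if (pl$comms == st$label[v]) return(list(sit = 1L))
    return(list(sit = 2L, target = pl$comms))
  }
  list(sit = 3L, tied = pl$comms)
}

gnr_apply_switch <- function(graph, st, v, target, cond, removal) {
  l <- i_links_into(graph, st, v, target)
  if (i_condition(l, i_qmin(st, target), cond)) {
    st_set_label(graph, st, v, target)
    TRUE
  } else if (removal) {
    st_set_label(graph, st, v, 0L)
    TRUE
  } else {
    FALSE
  }
}

gnr_handle <- function(graph, st, v, cls, cond, removal) {
  switch(cls$sit + 1L,
         FALSE,                                   # 0: no grouped neighbour
         FALSE,                                   # 1: keep
         gnr_apply_switch(graph, st, v, cls$target, cond, removal),  # 2
         {                                        # 3: tied plurality
           caps <- vapply(cls$tied, function(c) i_capability(graph, st, v, c),
                          numeric(1))
           top <- which(caps == max(caps))
           if (length(top) == 1L) {
             target <- cls$tied[top]
             if (target == st$label[v]) {
               FALSE
             } else {
               gnr_apply_switch(graph, st, v, target, cond, removal)
             }
           } else if (removal) {
             st_set_label(graph, st, v, 0L)
             TRUE
           } else {
             FALSE
           }
         })
}

gnr_sweep <- function(graph, st, cond, removal) {
  changed <- FALSE
  grouped <- which(st$label > 0L)
  if (length(grouped) == 0L) return(FALSE)
  grouped <- grouped[order(graph$degree[grouped], grouped, method = "radix")]
  deferred <- integer(0)
  for (v in grouped) {
    if (st$label[v] == 0L) next
    cls <- gnr_classify(graph, st, v)
    if (cls$sit == 3L) {
      deferred <- c(deferred, v)
    } else if (gnr_handle(graph, st, v, cls, cond, removal)) {
      changed <- TRUE
    }
  }
  for (v in deferred) {
    if (st$label[v] == 0L) next
    cls <- gnr_classify(graph, st, v)  # situation may have changed meanwhile
    if (gnr_handle(graph, st, v, cls, cond, removal)) changed <- TRUE
  }
  changed
}

# ---- baseline randomized LPA ------------------------------------------------

#' Baseline (randomized) label propagation
#'
#' The classic asynchronous label propagation algorithm: every node starts
#' with a unique label; nodes are visited in a fresh random order each
#' iteration and adopt the most frequent label among their neighbours, ties
#' broken uniformly at random; the process stops once every node's label is
#' among its neighbours' most frequent labels. Included as the non-
#' deterministic baseline the constrained pipeline is designed to replace.
#'
#' @inheritParams run_clpa
#' @param seed Integer seed controlling update order and tie-breaks.
#' @return A membership tibble `(node, community)` (total partition).
#' @export
run_simple_lpa <- function(graph, seed = 1L) {
  graph <- as_cd_graph(graph)
  with_preserved_rng({
    set.seed(as.integer(seed))
    n <- graph$n
    lab <- seq_len(n)
    repeat {
      ord <- sample.int(n)
      changed <- FALSE
      for (v in ord) {
        nb <- graph$adj[[v]]
        if (length(nb) == 0L) next
        nl <- lab[nb]
        u <- unique(nl)
        cntv <- tabulate(match(nl, u))
        top <- u[cntv == max(cntv)]
        if (!(lab[v] %in% top)) {
          lab[v] <- if (length(top) == 1L) top else sample(top, 1L)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    partition_tibble(graph, lab)
  })
}

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}
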