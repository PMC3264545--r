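# Shared fixtures and independent brute-force oracles.

# The 9-node toy tree: hub b with three branch neighbors, one bare (g1),
# one carrying three leaves (g2), one carrying two (g3).
fig1_network <- function() {
  read_edgelist(system.file("extdata", "fig1_toy_edgelist.tsv",
                            package = "multicent"), quiet = TRUE)
}

named_graph <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_edgelist(el, directed = FALSE)
}

path3 <- function() named_graph("a", "b", "b", "c")

# all connected simple graphs on <= 7 nodes, one per isomorphism class,
# via igraph's graph atlas (names assigned for the package's API)
atlas_connected <- function(min_nodes = 2L) {
  out <- list()
  for (i in 1:1252) {
    g <- igraph::graph_from_atlas(i)
    if (igraph::vcount(g) < min_nodes) next
    if (!igraph::is_connected(g)) next
    igraph::V(g)$name <- sprintf("v%02d", seq_len(igraph::vcount(g)))
    out[[length(out) + 1L]] <- g
  }
  out
}

# ---- independent oracles (no igraph centralities, no matrix powers) ----

adj_list <- function(g) {
  nms <- igraph::V(g)$name
  lapply(stats::setNames(seq_along(nms), nms), function(i) {
    nms[as.integer(igraph::neighbors(g, i))]
  })
}

bfs_dist <- function(adj, src) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[src] <- 0
  frontier <- src
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (!is.finite(d[v])) {
          d[v] <- d[u] + 1
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# all geodesics from s to t, enumerated recursively over the distance field
all_geodesics <- function(adj, d_to_t, s, t) {
  if (s == t) return(list(t))
  paths <- list()
  for (v in adj[[s]]) {
    if (d_to_t[v] == d_to_t[s] - 1) {
      for (p in all_geodesics(adj, d_to_t, v, t)) {
        paths[[length(paths) + 1L]] <- c(s, p)
      }
    }
  }
  paths
}

oracle_betweenness <- function(g) {
  adj <- adj_list(g)
  nms <- names(adj)
  b <- stats::setNames(rep(0, length(nms)), nms)
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (i >= j) next
      d_to_t <- bfs_dist(adj, nms[j])
      paths <- all_geodesics(adj, d_to_t, nms[i], nms[j])
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner)) {
        tab <- table(inner) / length(paths)
        b[names(tab)] <- b[names(tab)] + as.numeric(tab)
      }
    }
  }
  b
}

oracle_closeness <- function(g) {
  adj <- adj_list(g)
  n <- length(adj)
  vapply(names(adj), function(u) (n - 1) / sum(bfs_dist(adj, u)), numeric(1))
}

# TI oracle: enumerate all q-step walks explicitly; the effect of i on j
# along a walk j = v0, v1, ..., vq = i is prod_t 1/deg(v_t), t < q.
oracle_ti <- function(g, m) {
  adj <- adj_list(g)
  deg <- vapply(adj, length, numeric(1))
  walk_effect <- function(from, to, q) {
    # summed weight of q-step walks from `from` to `to`
    if (q == 0) return(as.numeric(from == to))
    sum(vapply(adj[[from]], function(v) (1 / deg[from]) * walk_effect(v, to, q - 1),
               numeric(1)))
  }
  nms <- names(adj)
  ti <- stats::setNames(rep(0, length(nms)), nms)
  for (i in nms) {
    total <- 0
    for (q in seq_len(m)) {
      for (j in setdiff(nms, i)) total <- total + walk_effect(j, i, q)
    }
    ti[i] <- total / m
  }
  ti
}

# small centrality table with hand-set columns, for clustering /
# redundancy units
toy_table <- function(n = 60, n_hi = 8, seed = 42) {
  set.seed(seed)
  ids <- sprintf("p%03d", seq_len(n))
  hi <- seq_len(n_hi)
  mk <- function(lo_mean, hi_mean) {
    x <- abs(stats::rnorm(n, lo_mean, 0.05))
    x[hi] <- abs(stats::rnorm(n_hi, hi_mean, 0.05))
    x
  }
  tab <- data.frame(protein_id = ids,
                    D = mk(0.1, 0.9), EC = mk(0.1, 0.9), TI1 = mk(0.1, 0.9),
                    TI4 = mk(0.1, 0.9), B = mk(0.1, 0.9), C = mk(0.4, 0.95),
                    stringsAsFactors = FALSE)
  normalize_max1(tab)
}

# run detect_hubs over generator seeds; returns a precision/recall matrix
recovery_run <- function(seeds, k_max = 9L, spec_args = list()) {
  t(vapply(seeds, function(s) {
    spec <- do.call(synthetic_spec, c(list(seed = s), spec_args))
    gen <- generate_network(spec)
    tab <- centrality_table(gen$network)
    hr <- suppressWarnings(
      detect_hubs(tab, config = hub_config(k_max = k_max, seed = s))
    )
    recovery_metrics(hr$hubs, gen$truth)
  }, numeric(3)))
}
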