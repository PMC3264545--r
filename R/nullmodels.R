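#' Uniform random graph with fixed node and edge counts
#'
#' G(n, m): a simple undirected graph drawn uniformly among all graphs
#' with exactly \code{n} nodes and \code{m} edges.
#'
#' @param n node count.
#' @param m edge count; must satisfy \eqn{m \le n(n-1)/2}.
#' @param seed integer seed (\code{NULL} leaves the RNG state alone).
#' @return an \code{igraph} graph with vertex names \code{n0001, ...}.
#' @export
gnm_random <- function(n, m, seed = NULL) {
  if (m > n * (n - 1) / 2) stop(sprintf("m = %d infeasible for n = %d nodes", m, n))
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- igraph::sample_gnm(n, m, directed = FALSE)
  igraph::V(g)$name <- sprintf("n%04d", seq_len(n))
  g
}

#' Degree-preserving rewiring (double edge swaps)
#'
#' Randomizes the wiring of a network while keeping every node's degree
#' exactly as in the input, by repeated double-edge swaps that never
#' introduce self-loops or duplicate edges (infeasible swaps are simply
#' skipped).
#'
#' @param net an \code{igraph} network with at least 2 edges.
#' @param swap_factor attempted swaps per edge (default 10).
#' @param seed integer seed.
#' @return a rewired \code{igraph} network with the identical degree
#'   sequence.
#' @export
rewire_preserving_degree <- function(net, swap_factor = 10, seed = NULL) {
  if (igraph::ecount(net) < 2L) stop("need at least 2 edges to rewire")
  if (!is.null(seed)) set.seed(as.integer(seed))
  niter <- ceiling(swap_factor * igraph::ecount(net))
  igraph::rewire(net, with = igraph::keeping_degseq(loops = FALSE, niter = niter))
}

#' Watts-Strogatz small-world graph with exact edge-count conservation
#'
#' Starts from a ring lattice of \code{n} nodes each tied to its
#' \code{mean_degree} nearest neighbors, then visits every lattice edge
#' once and, with probability \code{p}, re-attaches its far endpoint to a
#' uniformly chosen node, rejecting self-loops and duplicate edges (the
#' edge is left in place when no admissible target exists). The edge
#' count is therefore exactly \eqn{n \cdot mean\_degree / 2} for any
#' \code{p}.
#'
#' @param n node count.
#' @param mean_degree even lattice degree, \eqn{< n}.
#' @param p rewiring probability in \eqn{[0, 1]}.
#' @param seed integer seed.
#' @return an \code{igraph} graph.
#' @export
small_world <- function(n, mean_degree, p, seed = NULL) {
  if (mean_degree %% 2 != 0) stop("mean_degree must be even")
  if (mean_degree >= n) stop("mean_degree must be smaller than n")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  half <- mean_degree / 2
  from <- rep(seq_len(n), each = half)
  to <- (from + rep(seq_len(half), times = n) - 1L) %% n + 1L
  adj <- matrix(FALSE, n, n)
  adj[cbind(from, to)] <- TRUE
  adj[cbind(to, from)] <- TRUE
  rewire_flag <- stats::runif(length(from)) < p
  for (e in which(rewire_flag)) {
    u <- from[e]
    candidates <- which(!adj[u, ])
    candidates <- setdiff(candidates, u)
    if (!length(candidates)) next
    v_new <- if (length(candidates) == 1L) candidates else sample(candidates, 1L)
    v_old <- to[e]
    adj[u, v_old] <- adj[v_old, u] <- FALSE
    adj[u, v_new] <- adj[v_new, u] <- TRUE
    to[e] <- v_new
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("n%04d", seq_len(igraph::vcount(g)))
  g
}

#' Specification of one null-model family
#'
#' @param model \code{"gnm"}, \code{"rewired"} or \code{"smallworld"}.
#' @param n,m node/edge counts (\code{gnm}; default: matched to the
#'   reference network).
#' @param mean_degree,p small-world lattice degree and rewiring
#'   probability.
#' @param swap_factor swaps per edge for \code{"rewired"}.
#' @param replicates number of independent replicates.
#' @param seed integer seed; replicate r uses a seed derived from it.
#' @return a list of class \code{null_model_spec}.
#' @export
null_model_spec <- function(model = c("gnm", "rewired", "smallworld"),
                            n = NULL, m = NULL, mean_degree = NULL, p = 0.05,
                            swap_factor = 10, replicates = 1L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(replicates >= 1L)
  if (!is.null(n) && !is.null(m) && m > n * (n - 1) / 2) {
    stop("infeasible edge count for the given node count")
  }
  structure(list(model = model, n = n, m = m, mean_degree = mean_degree,
                 p = p, swap_factor = swap_factor,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "null_model_spec")
}

# internal: realize one replicate of a null model matched to `net`
generate_null <- function(net, spec, seed) {
  n <- spec$n %||% igraph::vcount(net)
  m <- spec$m %||% igraph::ecount(net)
  switch(spec$model,
    gnm = gnm_random(n, m, seed = seed),
    rewired = rewire_preserving_degree(net, swap_factor = spec$swap_factor, seed = seed),
    smallworld = {
      k <- spec$mean_degree %||% {
        kk <- round(2 * m / n)
        kk + kk %% 2
      }
      small_world(n, k, spec$p, seed = seed)
    })
}

#' Centrality-redundancy analysis on null models
#'
#' For each null-model specification, generates the requested replicates
#' matched to the reference network, extracts each replicate's giant
#' component, computes the six-index centrality table and its
#' rank-association matrix, and reports the entrywise mean matrix across
#' replicates together with its index dendrogram. Comparing these against
#' the empirical matrix shows which parts of the redundancy structure are
#' forced by degree sequence or density alone.
#'
#' @param net the reference \code{igraph} network.
#' @param specs a list of \code{\link{null_model_spec}} objects.
#' @return a named list (one entry per spec) of lists with \code{model},
#'   \code{matrix} (replicate-mean \code{rank_association}),
#'   \code{dendrogram}, \code{replicates}, \code{seeds}.
#' @export
null_redundancy_suite <- function(net, specs) {
  if (inherits(specs, "null_model_spec")) specs <- list(specs)
  out <- list()
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    seeds <- vapply(seq_len(spec$replicates),
                    function(r) stage_seed(spec$seed, 100L * s + r), integer(1))
    acc <- NULL
    for (r in seq_len(spec$replicates)) {
      g <- giant_component(generate_null(net, spec, seeds[r]))
      mat <- association_matrix(centrality_table(g))
      acc <- if (is.null(acc)) unclass(mat) else acc + unclass(mat)
    }
    mean_mat <- structure(acc / spec$replicates,
                          class = c("rank_association", "matrix"))
    name <- if (is.null(names(specs)[s]) || !nzchar(names(specs)[s] %||% "")) {
      spec$model
    } else {
      names(specs)[s]
    }
    out[[name]] <- list(model = spec$model, matrix = mean_mat,
                        dendrogram = index_dendrogram(mean_mat),
                        replicates = spec$replicates, seeds = seeds)
  }
  out
}

#' Write a null-model suite result bundle
#'
#' One TSV matrix and one Newick dendrogram per model, plus a JSON
#' manifest of the specifications and seeds used.
#'
#' @param suite result of \code{\link{null_redundancy_suite}}.
#' @param dir output directory (created if absent).
#' @export
write_null_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (name in names(suite)) {
    res <- suite[[name]]
    write_association_matrix(res$matrix, file.path(dir, paste0(name, "_association.tsv")))
    write_dendrogram_newick(res$dendrogram, file.path(dir, paste0(name, "_dendrogram.nwk")))
    manifest[[name]] <- list(model = res$model, replicates = res$replicates,
                             seeds = res$seeds)
  }
  write_json_flat(manifest, file.path(dir, "null_manifest.json"))
  invisible(dir)
}
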