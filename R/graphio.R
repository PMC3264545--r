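#' Read a protein interaction network from a tab-separated edgelist
#'
#' Each non-empty line names one undirected interaction as two
#' whitespace/tab-separated protein identifiers. Identifiers are opaque,
#' case-sensitive strings (UniProt accessions in practice). A header line
#' is skipped automatically when its first two tokens match
#' \code{header_labels} (case-insensitively). Self-loops and duplicate
#' interactions are dropped with a message reporting how many; the graph
#' returned is always simple and undirected.
#'
#' @param path path to the edgelist file, or a character vector of lines.
#' @param header_labels column labels that identify an optional header line.
#' @param quiet suppress the dropped-edge message.
#' @return an undirected simple \code{igraph} graph whose vertex names are
#'   the protein identifiers.
#' @export
read_edgelist <- function(path, header_labels = c("protein1", "protein2"),
                          quiet = FALSE) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty edgelist input")
  idx <- which(keep)
  toks <- strsplit(trimws(lines[idx]), "[ \t]+")
  first <- tolower(toks[[1L]][1:2])
  if (all(!is.na(first)) && setequal(first, tolower(header_labels))) {
    idx <- idx[-1L]
    toks <- toks[-1L]
    if (!length(toks)) stop("edgelist contains only a header line")
  }
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed edgelist line %d: fewer than 2 identifiers", idx[bad[1L]]))
  }
  ends <- t(vapply(toks, function(x) x[1:2], character(2)))
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  raw <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dropped <- raw - igraph::ecount(g)
  if (dropped > 0L && !quiet) {
    message(sprintf("read_edgelist: dropped %d duplicate/self-loop interaction(s)", dropped))
  }
  g
}

#' Write an interaction network as a tab-separated edgelist
#'
#' @param net an \code{igraph} network with named vertices.
#' @param path output file path.
#' @param header write the \code{protein1}/\code{protein2} header line.
#' @export
write_edgelist <- function(net, path, header = TRUE) {
  el <- igraph::as_edgelist(net, names = TRUE)
  df <- data.frame(protein1 = el[, 1], protein2 = el[, 2])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Extract the giant component of a network
#'
#' Returns the induced subgraph on the largest connected component. When
#' several components tie for the largest size, the one containing the
#' lexicographically smallest vertex name wins (C-locale ordering), so the
#' result never depends on vertex order.
#'
#' @param net an \code{igraph} network with named vertices.
#' @return a connected \code{igraph} subgraph.
#' @export
giant_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("cannot take the giant component of an empty network")
  comp <- igraph::components(net)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    firsts <- vapply(big, function(k) {
      sort(igraph::V(net)$name[comp$membership == k], method = "radix")[1L]
    }, character(1))
    big <- big[order(firsts, method = "radix")][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == big))
}

#' Whole-network descriptive statistics
#'
#' Density, global clustering coefficient (transitivity: three times the
#' triangle count over the connected-triple count), the mean of the local
#' clustering coefficients as a separate field, diameter and average
#' shortest-path length over unordered vertex pairs. On a disconnected
#' network the path-based fields are \code{NA} with a warning; take
#' \code{\link{giant_component}} first.
#'
#' @param net an \code{igraph} network.
#' @return an object of class \code{network_stats}: a list with fields
#'   \code{n_nodes}, \code{n_edges}, \code{density},
#'   \code{clustering_coefficient}, \code{clustering_local_mean},
#'   \code{diameter}, \code{avg_path_length}, \code{connected}.
#' @export
global_stats <- function(net) {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  dens <- if (n >= 2L) 2 * m / (n * (n - 1)) else NA_real_
  trans <- igraph::transitivity(net, type = "global")
  local_mean <- igraph::transitivity(net, type = "average", isolates = "zero")
  connected <- n > 0L && igraph::is_connected(net)
  if (connected && n >= 2L) {
    diam <- igraph::diameter(net, unconnected = FALSE)
    apl <- igraph::mean_distance(net, unconnected = FALSE)
  } else {
    if (!connected) warning("network is disconnected: diameter and average path length undefined")
    diam <- NA_real_
    apl <- NA_real_
  }
  structure(list(n_nodes = n, n_edges = m, density = dens,
                 clustering_coefficient = ifelse(is.nan(trans), NA_real_, trans),
                 clustering_local_mean = local_mean,
                 diameter = diam, avg_path_length = apl,
                 connected = connected),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("Network statistics\n")
  cat(sprintf("  nodes: %d   edges: %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  density: %.6f   clustering (transitivity): %.4f\n",
              x$density, x$clustering_coefficient))
  if (x$connected) {
    cat(sprintf("  diameter: %d   average path length: %.4f\n",
                x$diameter, x$avg_path_length))
  } else {
    cat("  disconnected: diameter and average path length undefined\n")
  }
  invisible(x)
}

#' Serialize network statistics to a flat JSON object
#'
#' @param stats a \code{network_stats} object.
#' @param path output path.
#' @export
write_network_stats <- function(stats, path) {
  write_json_flat(unclass(stats), path)
  invisible(path)
}
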