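#' Degree centrality
#'
#' Number of interaction partners of each protein.
#'
#' @param net an \code{igraph} network with named vertices.
#' @return named numeric vector of degrees.
#' @export
degree_centrality <- function(net) {
  d <- igraph::degree(net, loops = FALSE)
  d[order(names(d), method = "radix")]
}

#' Eigenvector centrality, max-rescaled
#'
#' Dominant eigenvector of the 0/1 adjacency structure, rescaled so the
#' maximum score is exactly 1. Requires a connected network (on a
#' disconnected one the dominant eigenvector concentrates on one component
#' and is not comparable across proteins); extract the giant component
#' first. The eigen-relation residual \eqn{\max_i |(Av)_i - \lambda v_i|}
#' is checked against \code{tol} after convergence.
#'
#' @param net connected \code{igraph} network.
#' @param tol residual tolerance for the eigen-relation.
#' @param max_iter iteration cap passed to the Lanczos solver.
#' @return named numeric vector of scores in \eqn{[0, 1]} with maximum 1.
#' @export
eigenvector_centrality <- function(net, tol = 1e-8, max_iter = 3000L) {
  if (!igraph::is_connected(net)) {
    stop("eigenvector centrality requires a connected network; extract the giant component first")
  }
  opts <- igraph::arpack_defaults()
  opts$maxiter <- as.integer(max_iter)
  opts$tol <- min(tol, 1e-10)
  # the Lanczos start vector comes from R's RNG; pin it locally so the
  # scores are bit-reproducible, then restore the caller's RNG state
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(20011L)
  ec <- igraph::eigen_centrality(net, options = opts)
  v <- ec$vector
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  resid <- max(abs(as.numeric(A %*% v) - ec$value * v))
  if (!is.finite(resid) || resid > max(tol, tol * abs(ec$value))) {
    stop(sprintf("eigenvector iteration did not converge within %d iterations (residual %.3e)",
                 max_iter, resid))
  }
  v[order(names(v), method = "radix")]
}

#' Closeness centrality
#'
#' Reciprocal of the mean shortest-path distance to every other protein:
#' \eqn{C_i = (n - 1) / \sum_j d(i, j)}, so a star center scores exactly 1.
#'
#' @param net connected \code{igraph} network.
#' @return named numeric vector of scores in \eqn{(0, 1]}.
#' @export
closeness_centrality <- function(net) {
  if (!igraph::is_connected(net)) {
    stop("closeness requires a connected network; extract the giant component first")
  }
  cl <- igraph::closeness(net, normalized = TRUE)
  cl[order(names(cl), method = "radix")]
}

#' Betweenness centrality (raw, endpoints excluded)
#'
#' For every unordered pair of other proteins, the fraction of that pair's
#' geodesics passing through the focal protein, summed over pairs. Raw
#' (unnormalized) counts: a pure broker on a tree counts whole pairs.
#'
#' @param net an \code{igraph} network.
#' @return named numeric vector of pair counts.
#' @export
betweenness_centrality <- function(net) {
  b <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  b[order(names(b), method = "radix")]
}

#' One-step effect matrix
#'
#' Row-stochastic matrix whose \eqn{(i, j)} entry is the one-step effect of
#' protein \eqn{j} on protein \eqn{i}: \eqn{a_{ij} / D_i}, i.e. each
#' protein divides its unit of influence received equally among its
#' interaction partners. Powers of this matrix propagate effects along
#' walks (multiplicative along a walk, additive across walks), the
#' propagation model behind the topological importance index.
#'
#' @param net an \code{igraph} network with no isolated vertices.
#' @return a sparse row-stochastic \code{Matrix} with dimnames in
#'   lexicographic vertex order.
#' @export
effect_matrix <- function(net) {
  ord <- order(igraph::V(net)$name, method = "radix")
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)[ord, ord, drop = FALSE]
  d <- Matrix::rowSums(A)
  if (any(d == 0)) {
    stop("isolated node(s) with no interactions: ",
         paste(rownames(A)[d == 0], collapse = ", "))
  }
  A / d
}

#' Topological importance index
#'
#' The effect a protein exerts on the rest of the network through walks of
#' up to \code{m} steps. With \eqn{E} the one-step \code{\link{effect_matrix}},
#' the \eqn{q}-step effect of protein \eqn{i} on \eqn{j} is the
#' \eqn{(j, i)} entry of \eqn{E^q}; \eqn{\phi_{q,i}} sums these over all
#' \eqn{j \ne i}, and \eqn{TI^m_i = \sum_{q=1}^{m} \phi_{q,i} / m}.
#' At \eqn{m = 1} this is the sum of reciprocal neighbor degrees, a
#' short-range extension of degree; at larger \eqn{m} it measures
#' meso-scale influence. Walks may revisit vertices: effects compose
#' multiplicatively along a walk with no exclusion rule, and only the
#' diagonal (self-effect) of each power is discarded.
#'
#' @param net an \code{igraph} network with no isolated vertices.
#' @param m maximum number of steps (integer \eqn{\ge} 1).
#' @return named numeric vector of TI scores.
#' @export
topological_importance <- function(net, m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 || m != floor(m)) {
    stop("m must be a single integer >= 1")
  }
  E <- effect_matrix(net)
  P <- E
  phi <- Matrix::colSums(P) - Matrix::diag(P)
  if (m > 1) {
    for (q in 2:m) {
      P <- P %*% E
      phi <- phi + Matrix::colSums(P) - Matrix::diag(P)
    }
  }
  ti <- as.numeric(phi / m)
  names(ti) <- colnames(E)
  ti
}

INDEX_LABELS <- c("D", "EC", "TI1", "TI4", "B", "C")

#' Six-index centrality table
#'
#' Computes degree (D), eigenvector score (EC), topological importance at
#' one and four steps (TI1, TI4), betweenness (B) and closeness (C) for
#' every protein of a connected network, covering local, meso-scale and
#' global prominence, and appends max-normalized columns
#' (\code{*_norm}, each index divided by its own maximum so all indices
#' share the upper limit 1).
#'
#' @param net connected \code{igraph} network with no isolated vertices.
#' @param ti_steps step limits for the two topological-importance columns.
#' @return a \code{data.frame} with columns \code{protein_id}, the six raw
#'   indices, and their \code{_norm} counterparts; one row per protein in
#'   lexicographic identifier order.
#' @export
centrality_table <- function(net, ti_steps = c(1L, 4L)) {
  if (!igraph::is_connected(net)) {
    stop("centrality_table requires a connected network; extract the giant component first")
  }
  tab <- data.frame(
    protein_id = sort(igraph::V(net)$name, method = "radix"),
    D = as.numeric(degree_centrality(net)),
    EC = as.numeric(eigenvector_centrality(net)),
    TI1 = as.numeric(topological_importance(net, ti_steps[1L])),
    TI4 = as.numeric(topological_importance(net, ti_steps[2L])),
    B = as.numeric(betweenness_centrality(net)),
    C = as.numeric(closeness_centrality(net)),
    stringsAsFactors = FALSE
  )
  normalize_max1(tab)
}

#' Max-normalize the centrality columns of a table
#'
#' Divides each index column by its own maximum so every index has upper
#' limit exactly 1, writing the result into \code{_norm} columns. An
#' all-zero column cannot be rescaled and is left as zeros with a warning.
#' Idempotent: normalizing an already-normalized table changes nothing.
#'
#' @param tab a centrality table with some of the columns
#'   \code{D, EC, TI1, TI4, B, C}.
#' @return the table with refreshed \code{_norm} columns.
#' @export
normalize_max1 <- function(tab) {
  if (!is.data.frame(tab) || nrow(tab) == 0L) stop("empty centrality table")
  idx <- intersect(INDEX_LABELS, names(tab))
  if (!length(idx)) stop("no centrality index columns found")
  for (lab in idx) {
    mx <- max(tab[[lab]])
    if (mx <= 0) {
      warning(sprintf("column %s has no positive values; left unscaled", lab))
      tab[[paste0(lab, "_norm")]] <- tab[[lab]]
    } else {
      tab[[paste0(lab, "_norm")]] <- tab[[lab]] / mx
    }
  }
  tab
}

# internal: rows = proteins, cols = requested normalized indices
norm_matrix <- function(tab, indices = NULL) {
  indices <- indices %||% intersect(INDEX_LABELS, sub("_norm$", "", grep("_norm$", names(tab), value = TRUE)))
  cols <- paste0(indices, "_norm")
  missing <- setdiff(cols, names(tab))
  if (length(missing)) stop("missing normalized columns: ", paste(missing, collapse = ", "))
  x <- as.matrix(tab[, cols, drop = FALSE])
  rownames(x) <- tab$protein_id
  colnames(x) <- indices
  x
}

#' Write / read a centrality table as TSV
#'
#' One row per protein; columns \code{protein_id}, the six raw indices and
#' their normalized counterparts.
#'
#' @param tab a centrality table.
#' @param path file path.
#' @export
write_centrality_table <- function(tab, path) {
  write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_centrality_table
#' @export
read_centrality_table <- function(path) {
  read_tsv(path)
}
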