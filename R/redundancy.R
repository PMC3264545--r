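#' Goodman-Kruskal rank concordance (gamma)
#'
#' Signed rank association between two per-protein score vectors:
#' \eqn{\gamma = (C - D) / (C + D)} over all unordered protein pairs,
#' where C counts pairs ordered the same way by both scores and D pairs
#' ordered oppositely. Pairs tied in either input are excluded from both
#' counts (classical gamma; no average-rank pre-processing), which makes
#' the score invariant under any strictly monotone transform of either
#' input. Returns \code{NA} with a warning when every pair is tied.
#'
#' @param x,y numeric vectors over the same proteins; if both are named,
#'   \code{y} is aligned to \code{x} by name.
#' @return a score in \eqn{[-1, 1]}, or \code{NA} if undefined.
#' @export
gk_gamma <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y))) stop("x and y cover different protein sets")
    y <- y[names(x)]
  }
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 proteins")
  conc <- disc <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    conc <- conc + sum(s > 0)
    disc <- disc + sum(s < 0)
  }
  if (conc + disc == 0) {
    warning("all pairs tied in at least one ranking; gamma undefined")
    return(NA_real_)
  }
  (conc - disc) / (conc + disc)
}

#' Pairwise rank-association matrix of the six centrality indices
#'
#' \code{\link{gk_gamma}} for each unordered pair of index columns,
#' symmetrized, diagonal 1. Raw columns are used; the score only depends
#' on rank order, so max-normalization cannot change it.
#'
#' @param tab a centrality table.
#' @param indices index labels to include (default the six).
#' @return a symmetric numeric matrix of class \code{rank_association}.
#' @export
association_matrix <- function(tab, indices = INDEX_LABELS) {
  missing <- setdiff(indices, names(tab))
  if (length(missing)) stop("table lacks index columns: ", paste(missing, collapse = ", "))
  k <- length(indices)
  m <- diag(1, k)
  dimnames(m) <- list(indices, indices)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      g <- gk_gamma(tab[[indices[i]]], tab[[indices[j]]])
      m[i, j] <- m[j, i] <- g
    }
  }
  structure(m, class = c("rank_association", "matrix"))
}

#' Dendrogram of similarities between centrality indices
#'
#' Agglomerative clustering of the indices where the dissimilarity
#' between two indices is the Euclidean distance between their rows of
#' the rank-association matrix, with both indices' self/cross entries
#' removed pairwise — so indices group together when they relate to all
#' the other indices the same way, not merely when they agree with each
#' other.
#'
#' @param mat a \code{rank_association} matrix.
#' @param linkage agglomeration method: \code{"average"} (default),
#'   \code{"single"}, \code{"complete"} or \code{"ward.D2"}.
#' @return an \code{hclust} tree over the index labels.
#' @export
index_dendrogram <- function(mat, linkage = c("average", "single", "complete", "ward.D2")) {
  linkage <- match.arg(linkage)
  labs <- rownames(mat)
  k <- length(labs)
  d <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      keep <- setdiff(seq_len(k), c(i, j))
      d[i, j] <- d[j, i] <- sqrt(sum((mat[i, keep] - mat[j, keep])^2))
    }
  }
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Export an index dendrogram in Newick format
#'
#' Branch lengths carry the merge heights.
#'
#' @param dend an \code{hclust} tree.
#' @param path output file path.
#' @export
write_dendrogram_newick <- function(dend, path) {
  phy <- ape::as.phylo(dend)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write a rank-association matrix as TSV
#'
#' @param mat a \code{rank_association} matrix.
#' @param path output file path.
#' @export
write_association_matrix <- function(mat, path) {
  df <- data.frame(index = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Evaluate a reduced centrality subset against a reference hub set
#'
#' Reruns the two-round model-based clustering using only the given
#' indices and reports how many reference hubs land in the top one and
#' top two round-2 components (components ranked by decreasing mean of
#' their normalized-centrality means), together with the sizes of those
#' component unions.
#'
#' @param tab a centrality table with normalized columns.
#' @param subset index labels to cluster on (typically 4 of the 6).
#' @param reference_hubs protein identifiers of the reference hub set.
#' @param config a \code{\link{hub_config}}.
#' @return an object of class \code{subset_evaluation}: list with
#'   \code{subset}, per-round fit summaries, \code{overlap_1cluster} and
#'   \code{overlap_2clusters} (each \code{c(recovered, size)}),
#'   \code{reference_size}.
#' @export
evaluate_subset <- function(tab, subset, reference_hubs, config = hub_config()) {
  stopifnot(length(reference_hubs) > 0L)
  bad <- setdiff(subset, INDEX_LABELS)
  if (length(bad)) stop("unknown index label(s): ", paste(bad, collapse = ", "))
  hr <- detect_hubs(tab, config = config, indices = subset)
  fit <- hr$round2 %||% hr$round1
  ord <- rank_components(fit)
  members <- function(ks) names(fit$assignments)[fit$assignments %in% ks]
  top1 <- members(ord[1L])
  top2 <- members(ord[seq_len(min(2L, fit$K))])
  structure(list(
    subset = subset,
    round1_fit = list(family = hr$round1$family, K = hr$round1$K,
                      central_size = length(hr$round1_central_cluster)),
    round2_fit = if (is.null(hr$round2)) NULL else
      list(family = hr$round2$family, K = hr$round2$K),
    overlap_1cluster = c(recovered = length(intersect(top1, reference_hubs)),
                         size = length(top1)),
    overlap_2clusters = c(recovered = length(intersect(top2, reference_hubs)),
                          size = length(top2)),
    reference_size = length(reference_hubs),
    hub_result = hr
  ), class = "subset_evaluation")
}

#' @export
print.subset_evaluation <- function(x, ...) {
  cat(sprintf("Subset {%s}: round-1 %s K=%d (central %d)",
              paste(x$subset, collapse = ","), x$round1_fit$family,
              x$round1_fit$K, x$round1_fit$central_size))
  if (!is.null(x$round2_fit)) {
    cat(sprintf("; round-2 %s K=%d", x$round2_fit$family, x$round2_fit$K))
  }
  cat("\n")
  cat(sprintf("  top 1 cluster: %d/%d reference hubs in %d proteins\n",
              x$overlap_1cluster["recovered"], x$reference_size,
              x$overlap_1cluster["size"]))
  cat(sprintf("  top 2 clusters: %d/%d reference hubs in %d proteins\n",
              x$overlap_2clusters["recovered"], x$reference_size,
              x$overlap_2clusters["size"]))
  invisible(x)
}
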