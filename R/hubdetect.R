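#' Clustering settings for hub detection
#'
#' @param k_min,k_max inclusive range of mixture component counts tried.
#' @param families candidate covariance families (mclust model names, e.g.
#'   \code{"EII"} spherical, \code{"VVI"} diagonal, \code{"VEV"}
#'   ellipsoidal equal shape, \code{"VVV"} unconstrained). \code{NULL}
#'   tries the full multivariate set.
#' @param n_init accepted for interface compatibility; the fitter
#'   initializes EM from deterministic model-based agglomerative
#'   clustering, so restarts are not used (see the methods vignette).
#' @param seed integer seed for the fitting stage.
#' @param min_central_cluster if round 1 isolates fewer proteins than
#'   this, round 2 is skipped and the round-1 selection is returned.
#' @return a list of class \code{hub_config}.
#' @export
hub_config <- function(k_min = 1L, k_max = 20L, families = NULL, n_init = 10L,
                       seed = 1L, min_central_cluster = 10L) {
  stopifnot(k_min >= 1L, k_max >= k_min, min_central_cluster >= 1L)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 families = families, n_init = as.integer(n_init),
                 seed = as.integer(seed),
                 min_central_cluster = as.integer(min_central_cluster)),
            class = "hub_config")
}

# internal: coerce a centrality table (or matrix) to the fitting matrix,
# rows in lexicographic id order so results are row-permutation invariant
fit_input <- function(table, indices = NULL) {
  x <- if (is.matrix(table)) table else norm_matrix(table, indices)
  if (is.null(rownames(x))) rownames(x) <- sprintf("row%06d", seq_len(nrow(x)))
  x[order(rownames(x), method = "radix"), , drop = FALSE]
}

#' Fit a Gaussian mixture over centrality profiles, selecting K and the
#' covariance family by BIC
#'
#' Every combination of candidate covariance family and component count in
#' \code{k_range} is fitted by EM (initialized from model-based
#' hierarchical agglomeration); the fit maximizing
#' \eqn{BIC = 2 \log L - k \log n} is returned. Candidates whose EM
#' degenerates (singular covariance) are skipped; if every candidate
#' fails, the fit is retried once with a light conjugate prior that floors
#' the covariance eigenvalues, and an error is raised only if that also
#' fails. Rows are internally ordered by identifier, so the result does
#' not depend on input row order.
#'
#' @param table a centrality table (its \code{_norm} columns are used) or
#'   a numeric matrix with row names.
#' @param k_range integer vector of component counts to try.
#' @param families candidate covariance family names, \code{NULL} for all.
#' @param n_init see \code{\link{hub_config}}.
#' @param seed integer seed set before fitting.
#' @param indices optional subset of index labels to cluster on.
#' @return an object of class \code{mixture_fit}: list with \code{family}
#'   (selected covariance structure and its description), \code{K},
#'   \code{bic}, \code{loglik}, \code{assignments} (named integer vector),
#'   \code{component_means} (K x d matrix), \code{component_sizes},
#'   \code{bic_convention}.
#' @import mclust
#' @export
fit_mixture_bic <- function(table, k_range = 1:20, families = NULL,
                            n_init = 10L, seed = NULL, indices = NULL) {
  x <- fit_input(table, indices)
  if (nrow(x) < 2L) stop("need at least 2 rows to fit a mixture")
  k_range <- k_range[k_range <= nrow(x)]
  if (!length(k_range)) stop("k_range exceeds the number of rows")
  if (!is.null(seed)) set.seed(as.integer(seed))
  fit <- suppressWarnings(
    mclust::Mclust(x, G = k_range, modelNames = families, verbose = FALSE)
  )
  if (is.null(fit)) {
    warning("all unregularized mixture candidates degenerated; refitting with a covariance prior")
    fit <- suppressWarnings(
      mclust::Mclust(x, G = k_range, modelNames = families, verbose = FALSE,
                     prior = mclust::priorControl())
    )
  }
  if (is.null(fit) && 1L %in% k_range) {
    # zero-variance data (e.g. identical rows) defeats even the prior;
    # the one-component spherical fit with a floored variance is exact
    warning("data are degenerate; returning a regularized single-component fit")
    sigma2 <- max(mean(apply(x, 2, stats::var)), 1e-6)
    d <- ncol(x)
    ll <- sum(vapply(seq_len(d), function(j) {
      sum(stats::dnorm(x[, j], mean(x[, j]), sqrt(sigma2), log = TRUE))
    }, numeric(1)))
    fit <- list(modelName = "EII", G = 1L,
                bic = 2 * ll - (d + 1) * log(nrow(x)), loglik = ll,
                classification = rep(1L, nrow(x)),
                parameters = list(mean = matrix(colMeans(x), ncol = 1)))
  }
  if (is.null(fit)) stop("mixture fitting failed for every (family, K) candidate")
  assignments <- fit$classification
  names(assignments) <- rownames(x)
  means <- t(fit$parameters$mean)
  if (is.null(dim(means))) means <- matrix(means, nrow = fit$G)
  colnames(means) <- colnames(x)
  rownames(means) <- seq_len(fit$G)
  structure(list(
    family = fit$modelName,
    family_description = unname(mclust::mclustModelNames(fit$modelName)$type),
    K = fit$G,
    bic = unname(fit$bic),
    loglik = fit$loglik,
    assignments = assignments,
    component_means = means,
    component_sizes = as.integer(table(factor(assignments, levels = seq_len(fit$G)))),
    bic_convention = "2*loglik - npar*log(n) (maximized)"
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: %s (%s), K = %d, BIC = %.3f\n",
              x$family, x$family_description, x$K, x$bic))
  cat("component sizes:", paste(x$component_sizes, collapse = ", "), "\n")
  invisible(x)
}

# internal: rank components by decreasing centrality (mean of the
# component means across indices); ties by mean betweenness, then by
# smaller component size
rank_components <- function(fit) {
  score <- rowMeans(fit$component_means)
  b <- if ("B" %in% colnames(fit$component_means)) fit$component_means[, "B"] else rep(0, fit$K)
  order(-score, -b, fit$component_sizes)
}

#' Members of the most central mixture component
#'
#' The component whose mean vector, averaged across the normalized
#' indices, is largest; ties go to the larger mean betweenness, then to
#' the smaller component.
#'
#' @param fit a \code{mixture_fit}.
#' @param table the table the fit was computed on (consistency check).
#' @return character vector of protein identifiers.
#' @export
select_central_cluster <- function(fit, table = NULL) {
  if (!is.null(table)) {
    ids <- if (is.matrix(table)) rownames(table) else table$protein_id
    if (!setequal(ids, names(fit$assignments))) {
      stop("fit and table cover different protein sets")
    }
  }
  top <- rank_components(fit)[1L]
  names(fit$assignments)[fit$assignments == top]
}

#' Detect multi-centrality hubs by two rounds of model-based clustering
#'
#' Round 1 clusters all proteins on their normalized centrality profiles
#' and keeps the most central component; round 2 re-clusters that subset
#' and again keeps the most central component, which is the hub set. If
#' round 1 already isolates fewer than \code{min_central_cluster}
#' proteins, that selection is returned directly with a warning (round 2
#' would be fitting noise).
#'
#' @param table a centrality table with normalized columns.
#' @param config a \code{\link{hub_config}}.
#' @param indices optional subset of index labels to cluster on (all
#'   available normalized indices by default).
#' @return an object of class \code{hub_result}: list with \code{round1},
#'   \code{round1_central_cluster}, \code{round2} (NULL when skipped),
#'   \code{hubs}, and \code{audit} (per-round component-mean tables).
#' @export
detect_hubs <- function(table, config = hub_config(), indices = NULL) {
  kr <- config$k_min:config$k_max
  fit1 <- fit_mixture_bic(table, k_range = kr, families = config$families,
                          n_init = config$n_init,
                          seed = stage_seed(config$seed, 1L), indices = indices)
  central1 <- select_central_cluster(fit1)
  audit <- list(round1 = fit1$component_means)
  if (length(central1) < config$min_central_cluster) {
    warning(sprintf(paste0("round-1 central cluster has only %d protein(s) ",
                           "(< %d); returning it directly, round 2 skipped"),
                    length(central1), config$min_central_cluster))
    res <- list(round1 = fit1, round1_central_cluster = central1,
                round2 = NULL, hubs = central1, audit = audit)
    return(structure(res, class = "hub_result"))
  }
  sub <- if (is.matrix(table)) {
    table[central1, , drop = FALSE]
  } else {
    table[table$protein_id %in% central1, , drop = FALSE]
  }
  fit2 <- fit_mixture_bic(sub, k_range = kr[kr <= length(central1)],
                          families = config$families, n_init = config$n_init,
                          seed = stage_seed(config$seed, 2L), indices = indices)
  hubs <- select_central_cluster(fit2)
  audit$round2 <- fit2$component_means
  structure(list(round1 = fit1, round1_central_cluster = central1,
                 round2 = fit2, hubs = hubs, audit = audit),
            class = "hub_result")
}

#' @export
print.hub_result <- function(x, ...) {
  cat(sprintf("Round 1: %s, K = %d -> central cluster of %d proteins\n",
              x$round1$family, x$round1$K, length(x$round1_central_cluster)))
  if (is.null(x$round2)) {
    cat("Round 2: skipped (round-1 central cluster below minimum size)\n")
  } else {
    cat(sprintf("Round 2: %s, K = %d -> %d multi-centrality hubs\n",
                x$round2$family, x$round2$K, length(x$hubs)))
  }
  cat("hubs:", paste(sort(x$hubs), collapse = " "), "\n")
  invisible(x)
}

#' Serialize a hub-detection result to JSON
#'
#' @param result a \code{hub_result}.
#' @param path output path.
#' @export
write_hub_result <- function(result, path) {
  round_summary <- function(f) {
    if (is.null(f)) return(NULL)
    list(family = f$family, family_description = f$family_description,
         K = f$K, bic = f$bic, component_sizes = f$component_sizes,
         component_means = apply(f$component_means, 1, as.list))
  }
  write_json_flat(list(
    hubs = sort(result$hubs),
    n_hubs = length(result$hubs),
    round1 = round_summary(result$round1),
    round1_central_cluster = sort(result$round1_central_cluster),
    round2 = round_summary(result$round2)
  ), path)
  invisible(path)
}
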