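#' Specification for the synthetic vitamin-network generator
#'
#' Emulates the statistical structure the analysis assumes: a sparse
#' network (density near 0.002) in which a small set of planted hubs
#' forms a densely interconnected (assortative) backbone, the remaining
#' seed proteins hang off the backbone in short branches, and a large
#' periphery attaches preferentially, yielding short average path
#' lengths; annotations enrich one vitamin label (D) among the planted
#' hubs.
#'
#' @param n_total total node count.
#' @param n_seed number of seed ("vitamin protein") analogs, hubs
#'   included.
#' @param n_hubs planted hub count (\eqn{\le} n_seed).
#' @param backbone_p edge probability between hub pairs.
#' @param periphery_attach mean attachments of a periphery node
#'   (\eqn{\ge} 1).
#' @param hub_d_prob probability a planted hub carries label D.
#' @param background_probs per-class label probabilities for non-hub
#'   seeds (default uniform over the 13 classes).
#' @param hub_tf_prob probability a hub is a transcription factor;
#'   non-hub seeds use \code{bg_tf_prob}.
#' @param bg_tf_prob see above.
#' @param pub_meanlog,pub_sdlog log-normal parameters for publication
#'   counts.
#' @param seed RNG seed.
#' @return a list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_total = 1600L, n_seed = 200L, n_hubs = 20L,
                           backbone_p = 0.4, periphery_attach = 1.6,
                           hub_d_prob = 0.85, background_probs = NULL,
                           hub_tf_prob = 0.8, bg_tf_prob = 0.15,
                           pub_meanlog = 3, pub_sdlog = 1, seed = 1L) {
  stopifnot(n_hubs <= n_seed, n_seed <= n_total, n_hubs >= 0L,
            backbone_p >= 0, backbone_p <= 1, periphery_attach >= 1,
            hub_d_prob >= 0, hub_d_prob <= 1)
  classes <- vitamin_classes("13-class")
  background_probs <- background_probs %||%
    stats::setNames(rep(1 / length(classes), length(classes)), classes)
  if (!setequal(names(background_probs), classes)) {
    stop("background_probs must be named by the 13 vitamin classes")
  }
  exp_edges <- choose(n_hubs, 2) * backbone_p +
    (n_seed - n_hubs) * 1.5 + (n_total - n_seed) * periphery_attach
  exp_density <- 2 * exp_edges / (n_total * (n_total - 1))
  if (exp_density < 0.001 || exp_density > 0.01) {
    stop(sprintf("expected density %.4f outside the sparse regime [0.001, 0.01]",
                 exp_density))
  }
  structure(list(n_total = as.integer(n_total), n_seed = as.integer(n_seed),
                 n_hubs = as.integer(n_hubs), backbone_p = backbone_p,
                 periphery_attach = periphery_attach, hub_d_prob = hub_d_prob,
                 background_probs = background_probs, hub_tf_prob = hub_tf_prob,
                 bg_tf_prob = bg_tf_prob, pub_meanlog = pub_meanlog,
                 pub_sdlog = pub_sdlog, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic network with a planted hub backbone
#'
#' Three growth phases: (1) hub backbone — each hub pair is linked with
#' probability \code{backbone_p}; (2) non-hub seeds join one by one,
#' each attaching to 1 or 2 uniformly chosen existing seed/hub nodes,
#' forming the short branches; (3) periphery nodes join one by one, each
#' attaching to \code{1 + Poisson(periphery_attach - 1)} distinct
#' existing nodes chosen with probability proportional to current degree
#' (preferential attachment, which concentrates periphery load on the
#' backbone). The giant component is returned with the planted ground
#' truth.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{network} (connected \code{igraph}) and
#'   \code{truth} (list: \code{hub_ids}, \code{seed_ids}).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(stage_seed(spec$seed, 11L))
  hubs <- if (spec$n_hubs > 0L) sprintf("HUB%03d", seq_len(spec$n_hubs)) else character(0)
  seeds <- if (spec$n_seed > spec$n_hubs) {
    sprintf("SEED%03d", seq_len(spec$n_seed - spec$n_hubs))
  } else {
    character(0)
  }
  periph <- if (spec$n_total > spec$n_seed) {
    sprintf("PER%04d", seq_len(spec$n_total - spec$n_seed))
  } else {
    character(0)
  }
  all_ids <- c(hubs, seeds, periph)
  deg <- stats::setNames(integer(length(all_ids)), all_ids)
  ef <- character(0); et <- character(0)
  add_edges <- function(u, vs) {
    ef <<- c(ef, rep(u, length(vs))); et <<- c(et, vs)
    deg[u] <<- deg[u] + length(vs)
    deg[vs] <<- deg[vs] + 1L
  }
  if (spec$n_hubs >= 2L) {
    pairs <- utils::combn(hubs, 2L)
    keep <- stats::runif(ncol(pairs)) < spec$backbone_p
    if (any(keep)) {
      kept <- pairs[, keep, drop = FALSE]
      ef <- c(ef, kept[1L, ]); et <- c(et, kept[2L, ])
      tab <- table(c(kept))
      deg[names(tab)] <- deg[names(tab)] + as.integer(tab)
    }
  }
  pool <- hubs
  for (s in seeds) {
    if (!length(pool)) { pool <- s; next }
    k <- min(sample(1:2, 1L), length(pool))
    targets <- if (length(pool) == 1L) pool else sample(pool, k)
    add_edges(s, targets)
    pool <- c(pool, s)
  }
  for (p in periph) {
    k <- min(1L + stats::rpois(1L, spec$periphery_attach - 1), length(pool))
    w <- deg[pool] + 1e-9
    targets <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), k, prob = w)]
    add_edges(p, targets)
    pool <- c(pool, p)
  }
  g <- igraph::graph_from_edgelist(cbind(ef, et), directed = FALSE)
  g <- igraph::simplify(g)
  g <- giant_component(g)
  truth <- list(hub_ids = intersect(hubs, igraph::V(g)$name),
                seed_ids = intersect(c(hubs, seeds), igraph::V(g)$name))
  list(network = g, truth = truth)
}

#' Generate annotations matched to a synthetic ground truth
#'
#' Planted hubs carry label D with probability \code{hub_d_prob}
#' (otherwise a background draw) and are transcription factors with
#' probability \code{hub_tf_prob}; non-hub seeds draw one label from
#' \code{background_probs}. Publication counts are log-normal. Only seed
#' proteins are annotated, mirroring a curated reference list.
#'
#' @param truth ground truth from \code{\link{generate_network}}.
#' @param spec the \code{\link{synthetic_spec}} used.
#' @return an annotation table (see \code{\link{annotation_table}}).
#' @export
generate_annotations <- function(truth, spec) {
  set.seed(stage_seed(spec$seed, 12L))
  ids <- sort(truth$seed_ids, method = "radix")
  is_hub <- ids %in% truth$hub_ids
  classes <- names(spec$background_probs)
  draw_bg <- function(n) sample(classes, n, replace = TRUE, prob = spec$background_probs)
  labels <- draw_bg(length(ids))
  hub_d <- is_hub & stats::runif(length(ids)) < spec$hub_d_prob
  labels[hub_d] <- "D"
  is_tf <- stats::runif(length(ids)) <
    ifelse(is_hub, spec$hub_tf_prob, spec$bg_tf_prob)
  pubs <- pmax(0L, as.integer(round(stats::rlnorm(length(ids), spec$pub_meanlog,
                                                  spec$pub_sdlog))))
  annotation_table(ids, as.list(labels), is_tf, pubs)
}

#' Precision, recall and F1 of a detected hub set against ground truth
#'
#' @param detected character vector of detected protein identifiers.
#' @param truth ground truth from \code{\link{generate_network}}.
#' @return named numeric vector \code{c(precision, recall, f1)} (zero
#'   when undefined).
#' @export
recovery_metrics <- function(detected, truth) {
  tp <- length(intersect(detected, truth$hub_ids))
  precision <- if (length(detected)) tp / length(detected) else 0
  recall <- if (length(truth$hub_ids)) tp / length(truth$hub_ids) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}
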