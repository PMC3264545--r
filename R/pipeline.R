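#' Configuration for a full analysis run
#'
#' @param edgelist path to the interaction edgelist TSV (or \code{NULL}
#'   to pass a network directly to \code{\link{run_pipeline}}).
#' @param annotations optional path to the annotation TSV; annotation
#'   statistics are skipped when absent.
#' @param out_dir output directory for the report bundle.
#' @param seed master seed propagated (via \code{\link{stage_seed}}) to
#'   every stochastic stage.
#' @param clustering a \code{\link{hub_config}}; its seed field is
#'   overridden by the master seed.
#' @param null_specs list of \code{\link{null_model_spec}} objects
#'   (\code{NULL} for the default gnm / rewired / small-world trio;
#'   an empty list skips the stage).
#' @param subsets list of 4-index label vectors to evaluate against the
#'   detected hubs (default: the four informative combinations).
#' @param verbose log stage progress and timings.
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(edgelist = NULL, annotations = NULL,
                            out_dir = tempfile("multicent_run_"), seed = 1L,
                            clustering = hub_config(), null_specs = NULL,
                            subsets = NULL, verbose = TRUE) {
  subsets <- subsets %||% list(c("D", "EC", "TI1", "TI4"),
                               c("TI1", "TI4", "B", "C"),
                               c("EC", "TI1", "TI4", "B"),
                               c("D", "TI1", "TI4", "C"))
  structure(list(edgelist = edgelist, annotations = annotations,
                 out_dir = out_dir, seed = as.integer(seed),
                 clustering = clustering, null_specs = null_specs,
                 subsets = subsets, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full multi-centrality analysis
#'
#' Stages, in order: read the edgelist and extract the giant component;
#' whole-network statistics; six-index centrality table with
#' max-normalization; two-round model-based hub detection; Goodman-Kruskal
#' rank-association matrix and index dendrogram; 4-index subset
#' evaluations against the detected hubs; null-model redundancy suite;
#' annotation statistics (solubility and transcription-factor chi-squared,
#' enrichment profiles, KS comparisons) when an annotation table is
#' available. Stages whose inputs are absent are marked skipped with a
#' reason. Identical configuration and seed give an identical report; on a
#' stage failure the partial report bundle is written before the error
#' propagates.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param network optional \code{igraph} network overriding
#'   \code{config$edgelist}.
#' @return a list of class \code{pipeline_report} (also written to
#'   \code{config$out_dir} as TSV/JSON/Newick files).
#' @export
run_pipeline <- function(config = pipeline_config(), network = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(provenance = list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("multicent")),
    r_version = R.version.string,
    config = config[setdiff(names(config), "verbose")]
  ))
  say <- function(fmt, ...) if (config$verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      report$error <<- list(stage = name, message = conditionMessage(e))
      write_json_flat(report$error, file.path(config$out_dir, "error.json"))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("stage %-12s %6.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  net <- stage("network", {
    if (is.null(network)) {
      if (is.null(config$edgelist)) stop("no edgelist path and no network object given")
      network <- read_edgelist(config$edgelist, quiet = !config$verbose)
    }
    giant_component(network)
  })

  report$network_stats <- stage("stats", {
    st <- global_stats(net)
    write_network_stats(st, file.path(config$out_dir, "network_stats.json"))
    st
  })

  tab <- stage("centrality", {
    tb <- centrality_table(net)
    write_centrality_table(tb, file.path(config$out_dir, "centrality_table.tsv"))
    tb
  })
  report$centrality_table <- file.path(config$out_dir, "centrality_table.tsv")

  hubs <- stage("hubs", {
    cfg <- config$clustering
    cfg$seed <- stage_seed(config$seed, 21L)
    hr <- detect_hubs(tab, config = cfg)
    write_hub_result(hr, file.path(config$out_dir, "hub_result.json"))
    hr
  })
  report$hub_result <- hubs

  report$redundancy <- stage("redundancy", {
    mat <- association_matrix(tab)
    dend <- index_dendrogram(mat)
    write_association_matrix(mat, file.path(config$out_dir, "association_matrix.tsv"))
    write_dendrogram_newick(dend, file.path(config$out_dir, "index_dendrogram.nwk"))
    list(matrix = mat, dendrogram = dend)
  })

  report$subset_evaluations <- stage("subsets", {
    if (!length(config$subsets)) {
      list(skipped = "no subsets configured")
    } else {
      cfg <- config$clustering
      cfg$seed <- stage_seed(config$seed, 31L)
      evs <- lapply(config$subsets, evaluate_subset, tab = tab,
                    reference_hubs = hubs$hubs, config = cfg)
      names(evs) <- vapply(config$subsets, paste, character(1), collapse = "-")
      summ <- data.frame(
        subset = names(evs),
        round1_family = vapply(evs, function(e) e$round1_fit$family, character(1)),
        round1_K = vapply(evs, function(e) e$round1_fit$K, numeric(1)),
        central_size = vapply(evs, function(e) e$round1_fit$central_size, numeric(1)),
        top1_recovered = vapply(evs, function(e) e$overlap_1cluster[["recovered"]], numeric(1)),
        top1_size = vapply(evs, function(e) e$overlap_1cluster[["size"]], numeric(1)),
        top2_recovered = vapply(evs, function(e) e$overlap_2clusters[["recovered"]], numeric(1)),
        top2_size = vapply(evs, function(e) e$overlap_2clusters[["size"]], numeric(1)))
      write_tsv(summ, file.path(config$out_dir, "subset_evaluation.tsv"))
      evs
    }
  })

  report$null_models <- stage("nulls", {
    specs <- config$null_specs %||% {
      s0 <- stage_seed(config$seed, 41L)
      list(null_model_spec("gnm", replicates = 3L, seed = s0),
           null_model_spec("rewired", replicates = 3L, seed = s0),
           null_model_spec("smallworld",
                           n = max(3L, round(igraph::vcount(net) / 2.5)),
                           replicates = 3L, seed = s0))
    }
    if (!length(specs)) {
      list(skipped = "no null-model specs configured")
    } else {
      suite <- null_redundancy_suite(net, specs)
      write_null_suite(suite, file.path(config$out_dir, "null_models"))
      suite
    }
  })

  report$annotation_stats <- stage("annotation", {
    if (is.null(config$annotations)) {
      list(skipped = "no annotation table supplied")
    } else {
      annot <- read_annotations(config$annotations)
      annotated_hubs <- intersect(hubs$hubs, annot$accession)
      if (!length(annotated_hubs)) {
        list(skipped = "no detected hub is annotated")
      } else {
        background <- setdiff(annot$accession, annotated_hubs)
        sol_h <- solubility_split(annot, annotated_hubs)
        sol_b <- solubility_split(annot, background)
        tf_tab <- rbind(hubs = c(tf = sum(annot$is_tf[annot$accession %in% annotated_hubs]),
                                 non_tf = sum(!annot$is_tf[annot$accession %in% annotated_hubs])),
                        background = c(sum(annot$is_tf[annot$accession %in% background]),
                                       sum(!annot$is_tf[annot$accession %in% background])))
        prof13 <- enrichment_profile(annot, annotated_hubs, "13-class")
        prof6 <- enrichment_profile(annot, annotated_hubs, "6-class")
        deg <- degree_centrality(giant_component(net))
        shared <- intersect(names(deg), annot$accession)
        res <- list(
          solubility = list(hubs = as.list(sol_h), background = as.list(sol_b),
                            chi2 = chi2_test(rbind(sol_h, sol_b))),
          transcription_factor = list(table = tf_tab, chi2 = chi2_test(tf_tab)),
          enrichment_13class = prof13,
          enrichment_6class = prof6,
          ks_13class = ks_two_sample(prof13$subset_prop, prof13$background_prop),
          ks_6class = ks_two_sample(prof6$subset_prop, prof6$background_prop),
          ks_degree_vs_publications = if (length(shared) >= 2L) {
            ks_two_sample(deg[shared], annot$publications[match(shared, annot$accession)])
          } else {
            list(skipped = "fewer than 2 annotated proteins in the network")
          })
        write_tsv(prof13, file.path(config$out_dir, "enrichment_13class.tsv"))
        write_tsv(prof6, file.path(config$out_dir, "enrichment_6class.tsv"))
        res
      }
    }
  })

  strip_classes <- function(x) if (is.list(x)) lapply(unclass(x), strip_classes) else x
  write_json_flat(strip_classes(report$provenance),
                  file.path(config$out_dir, "provenance.json"))
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("multicent pipeline report\n")
  print(x$network_stats)
  print(x$hub_result)
  skipped <- function(s) is.list(s) && !is.null(s$skipped)
  cat(sprintf("redundancy matrix: %dx%d; subsets: %s; nulls: %s; annotation: %s\n",
              nrow(x$redundancy$matrix), ncol(x$redundancy$matrix),
              if (skipped(x$subset_evaluations)) "skipped" else length(x$subset_evaluations),
              if (skipped(x$null_models)) "skipped" else paste(names(x$null_models), collapse = ","),
              if (skipped(x$annotation_stats)) "skipped" else "done"))
  invisible(x)
}
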