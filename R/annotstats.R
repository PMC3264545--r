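#' Vitamin label schemes
#'
#' The 13-class scheme keeps each B vitamin separate; the 6-class scheme
#' collapses the B complex into a single \code{B} label. Fat-soluble
#' vitamins are A, D, E and K; the B complex and C are water-soluble.
#'
#' @param scheme \code{"13-class"} or \code{"6-class"}.
#' @return character vector of class labels.
#' @export
vitamin_classes <- function(scheme = c("13-class", "6-class")) {
  scheme <- match.arg(scheme)
  if (scheme == "13-class") {
    c("A", "B1", "B2", "B3", "B5", "B6", "B7", "B9", "B12", "C", "D", "E", "K")
  } else {
    c("A", "B", "C", "D", "E", "K")
  }
}

FAT_SOLUBLE <- c("A", "D", "E", "K")

#' Build a protein annotation table
#'
#' @param accession protein identifiers.
#' @param vitamins list of character vectors (or single
#'   semicolon-separated strings) of vitamin labels per protein, drawn
#'   from the 13-class scheme.
#' @param is_tf logical: annotated with regulation of transcription.
#' @param publications nonnegative publication counts.
#' @return a \code{data.frame} with columns \code{accession},
#'   \code{vitamins} (semicolon-separated), \code{is_tf},
#'   \code{publications}.
#' @export
annotation_table <- function(accession, vitamins, is_tf, publications) {
  if (is.character(vitamins)) vitamins <- strsplit(vitamins, ";", fixed = TRUE)
  valid <- vitamin_classes("13-class")
  bad <- setdiff(unique(unlist(vitamins)), c(valid, ""))
  if (length(bad)) stop("unknown vitamin label(s): ", paste(bad, collapse = ", "))
  if (any(publications < 0)) stop("publication counts must be nonnegative")
  data.frame(accession = as.character(accession),
             vitamins = vapply(vitamins, paste, character(1), collapse = ";"),
             is_tf = as.logical(is_tf),
             publications = as.integer(publications),
             stringsAsFactors = FALSE)
}

#' Read / write an annotation table
#'
#' TSV with columns \code{accession}, \code{vitamins} (semicolon-separated
#' labels), \code{is_tf} (0/1), \code{publications}.
#'
#' @param path file path.
#' @export
read_annotations <- function(path) {
  df <- read_tsv(path, colClasses = c(vitamins = "character"))
  annotation_table(df$accession, df$vitamins, df$is_tf == 1 | df$is_tf == TRUE,
                   df$publications)
}

#' @rdname read_annotations
#' @param annot an annotation table.
#' @export
write_annotations <- function(annot, path) {
  out <- annot
  out$is_tf <- as.integer(out$is_tf)
  write_tsv(out, path)
  invisible(path)
}

# internal: list of label vectors
vitamin_sets <- function(annot) strsplit(annot$vitamins, ";", fixed = TRUE)

#' Fat- versus water-soluble association counts
#'
#' Counts how many of the given proteins are associated with at least one
#' fat-soluble vitamin (A, D, E, K) and how many with at least one
#' water-soluble vitamin (the B complex, C). A protein carrying both kinds
#' contributes to both counts (reported via a message); proteins with no
#' vitamin label are excluded from both.
#'
#' @param annot an annotation table.
#' @param ids protein identifiers, all of which must be annotated.
#' @return named integer vector \code{c(fat, water)}.
#' @export
solubility_split <- function(annot, ids) {
  missing <- setdiff(ids, annot$accession)
  if (length(missing)) {
    stop("unannotated protein(s): ", paste(missing, collapse = ", "))
  }
  sets <- vitamin_sets(annot[match(ids, annot$accession), , drop = FALSE])
  fat <- vapply(sets, function(v) any(v %in% FAT_SOLUBLE), logical(1))
  water <- vapply(sets, function(v) any(v %in% setdiff(vitamin_classes("13-class"), FAT_SOLUBLE)),
                  logical(1))
  both <- sum(fat & water)
  if (both > 0) message(sprintf("%d protein(s) associated with both solubility classes", both))
  c(fat = sum(fat), water = sum(water))
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Both the Yates-corrected and the uncorrected statistic are always
#' reported; \code{correction} selects which one the headline
#' \code{statistic}/\code{p} fields carry (corrected by default, the
#' standard behaviour for 2x2 tables in R).
#'
#' @param table a 2x2 matrix of nonnegative counts.
#' @param correction apply the continuity correction to the headline
#'   result.
#' @return list with \code{statistic}, \code{df}, \code{p},
#'   \code{statistic_corrected}, \code{statistic_uncorrected},
#'   \code{p_corrected}, \code{p_uncorrected}.
#' @export
chi2_test <- function(table, correction = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("expected a 2x2 table")
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal: chi-squared test undefined")
  }
  corr <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  unc <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  head <- if (correction) corr else unc
  list(statistic = unname(head$statistic), df = unname(head$parameter),
       p = head$p.value,
       statistic_corrected = unname(corr$statistic),
       statistic_uncorrected = unname(unc$statistic),
       p_corrected = corr$p.value, p_uncorrected = unc$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Maximum empirical-CDF gap between two samples, with the asymptotic
#' p-value. Alternatives follow the usual convention: "greater" tests
#' whether the CDF of \code{x} lies above that of \code{y}.
#'
#' @param x,y nonempty numeric samples.
#' @param alternative \code{"two-sided"}, \code{"one-sided-greater"} or
#'   \code{"one-sided-less"}.
#' @return list with \code{statistic} (D) and \code{p}.
#' @export
ks_two_sample <- function(x, y, alternative = c("two-sided", "one-sided-greater",
                                                "one-sided-less")) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  alternative <- match.arg(alternative)
  alt <- c(`two-sided` = "two.sided", `one-sided-greater` = "greater",
           `one-sided-less` = "less")[[alternative]]
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = alt, exact = FALSE))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Per-class vitamin association profile of a protein subset
#'
#' For every class of the chosen scheme, the proportion of subset
#' proteins associated with it, side by side with the proportion among
#' all annotated proteins (the background). A multi-labelled protein
#' counts once in every class it carries, so a group's proportions may
#' sum above 1.
#'
#' @param annot an annotation table.
#' @param subset protein identifiers (must be annotated).
#' @param scheme \code{"13-class"} or \code{"6-class"}.
#' @return a \code{data.frame} with columns \code{class},
#'   \code{subset_prop}, \code{background_prop}.
#' @export
enrichment_profile <- function(annot, subset, scheme = c("13-class", "6-class")) {
  scheme <- match.arg(scheme)
  missing <- setdiff(subset, annot$accession)
  if (length(missing)) stop("unannotated protein(s): ", paste(missing, collapse = ", "))
  classes <- vitamin_classes(scheme)
  collapse_b <- function(v) if (scheme == "6-class") unique(sub("^B[0-9]+$", "B", v)) else v
  prop <- function(ids) {
    sets <- lapply(vitamin_sets(annot[match(ids, annot$accession), , drop = FALSE]),
                   collapse_b)
    vapply(classes, function(cl) mean(vapply(sets, function(v) cl %in% v, logical(1))),
           numeric(1))
  }
  data.frame(class = classes,
             subset_prop = unname(prop(subset)),
             background_prop = unname(prop(annot$accession)),
             stringsAsFactors = FALSE)
}
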