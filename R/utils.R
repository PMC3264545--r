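`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible per-stage seed from a master seed
#'
#' Stochastic stages of the pipeline (mixture fitting, null-model
#' generation, synthetic data) each receive their own seed derived
#' deterministically from the master seed, so any stage can be rerun in
#' isolation with an identical random stream.
#'
#' @param seed master integer seed.
#' @param stage integer stage offset (>= 0).
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  ((as.integer(seed) %% 100000L) * 10007L + as.integer(stage) * 97L) %% 2147483647L
}

# writes a data.frame as plain TSV, no quoting, no row names
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_json_flat <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
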