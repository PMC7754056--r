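# Classed conditions so callers (and the CLI) can map failures to exit codes.

gendulf_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "gendulf_error"), call = call))
}

abort_format      <- function(msg) gendulf_abort(msg, "gendulf_format_error")
abort_duplicate   <- function(msg) gendulf_abort(msg, "gendulf_duplicate_id_error")
abort_value       <- function(msg) gendulf_abort(msg, "gendulf_value_error")
abort_label       <- function(msg) gendulf_abort(msg, "gendulf_label_error")
abort_composition <- function(msg) gendulf_abort(msg, "gendulf_composition_error")
abort_domain      <- function(msg) gendulf_abort(msg, "gendulf_domain_error")
abort_argument    <- function(msg) gendulf_abort(msg, "gendulf_argument_error")
abort_missing_gene  <- function(msg) gendulf_abort(msg, "gendulf_missing_gene_error")
abort_eligibility   <- function(msg) gendulf_abort(msg, "gendulf_eligibility_error")
abort_sample_size   <- function(msg) gendulf_abort(msg, "gendulf_sample_size_error")
abort_partition     <- function(msg) gendulf_abort(msg, "gendulf_partition_error")
abort_spec          <- function(msg) gendulf_abort(msg, "gendulf_spec_error")
abort_io            <- function(msg) gendulf_abort(msg, "gendulf_io_error")

#' Derive a reproducible substream seed from a master seed and a string key
#'
#' Per-gene and per-replicate random draws use seeds derived deterministically
#' from one master seed, so neither gene order nor parallel scheduling can
#' change results. All arithmetic stays below 2^53 and the result below 2^31,
#' so the value is exact in double precision and valid for [set.seed()].
#'
#' @param master integer master seed.
#' @param key character key naming the substream (e.g. a gene identifier).
#' @return An integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, key) {
  if (!is.numeric(master) || length(master) != 1L || is.na(master))
    abort_argument("master seed must be a single number")
  h <- 0
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(((master %% 97561) * 21503 + h * 7919 + 13) %% 2147483647)
}
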