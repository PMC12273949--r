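# Deterministic per-operation RNG substreams. All stochastic operations in
# the package take a single user-facing seed; each operation derives its own
# substream from (seed, label) so runs are reproducible bit-for-bit and
# operations do not perturb each other's draws or the caller's RNG state.

rng_stream <- function(seed, label) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  set.seed((as.integer(seed) %% 1000003L) * 2011L + h %% 100003L)
  invisible(old)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' E. coli K-12 MG1655 genome size in bp
#'
#' Used as the default genome size for beneficial-supply and deleterious-load
#' arithmetic.
#' @export
ECOLI_GENOME_SIZE <- 4641652
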