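#' Write a DFE to JSON
#'
#' Serializes bin edges, raw counts, corrected weights, class fractions and
#' the median selection coefficient.
#'
#' @param dfe an object of class `dfe`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dfe_json <- function(dfe, path) {
  stopifnot(inherits(dfe, "dfe"))
  obj <- list(strain_id = dfe$strain_id, environment = dfe$environment,
              bin_edges = dfe$bin_edges, raw_counts = dfe$raw_counts,
              corrected_weights = dfe$corrected_weights,
              n_mutations = dfe$n_mutations,
              f_b = dfe$f_b, f_n = dfe$f_n, f_d = dfe$f_d,
              median_s = dfe$median_s)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
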