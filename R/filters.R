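#' Variant filter configuration
#'
#' Read-support and frequency thresholds applied to called variants before any
#' downstream analysis. The defaults implement the standard stringent MA
#' calling rules: support on both strands, at least 4 reads per strand, and
#' allele frequency strictly above 80%.
#'
#' @param min_reads_per_strand minimum reads supporting the variant on each of
#'   the plus and minus strands (default 4).
#' @param min_frequency allele-frequency threshold; variants must exceed it
#'   strictly (default 0.80).
#' @param require_both_strands if TRUE, variants must be represented by at
#'   least one read on each strand regardless of `min_reads_per_strand`.
#' @return An object of class `variant_filter_config`.
#' @export
variant_filter_config <- function(min_reads_per_strand = 4,
                                  min_frequency = 0.80,
                                  require_both_strands = TRUE) {
  stopifnot(min_reads_per_strand >= 0,
            min_frequency >= 0, min_frequency <= 1,
            is.logical(require_both_strands))
  structure(list(min_reads_per_strand = as.integer(min_reads_per_strand),
                 min_frequency = min_frequency,
                 require_both_strands = isTRUE(require_both_strands)),
            class = "variant_filter_config")
}

#' Filter called variants and subtract ancestral mutations
#'
#' Applies the three MA calling filters -- (i) representation on both strands,
#' (ii) a minimum per-strand read count, (iii) allele frequency strictly above
#' the threshold -- then removes any variant also present in the ancestor
#' (matched exactly on position, ref and alt). Ancestor variants are matched
#' at any frequency: the frequency filter is deliberately not applied on the
#' ancestor side, so that low-frequency ancestral segregants are still
#' subtracted from the offspring lists.
#'
#' @param variants data.frame of called variants. Must carry numeric columns
#'   `reads_plus`, `reads_minus` and `freq`, plus `position`, `ref`, `alt`
#'   (1-based, fully closed coordinates).
#' @param ancestor_variants optional data.frame of variants called in the
#'   corresponding ancestor, same coordinate convention; NULL to skip
#'   subtraction.
#' @param config a [variant_filter_config()].
#' @return The rows of `variants` passing all filters, ancestor-subtracted.
#'   The operation is idempotent and order-independent over input rows.
#' @export
apply_filters <- function(variants, ancestor_variants = NULL,
                          config = variant_filter_config()) {
  stopifnot(inherits(config, "variant_filter_config"))
  needed <- c("position", "ref", "alt", "freq", "reads_plus", "reads_minus")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols) > 0) {
    stop("variant table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(variants$reads_plus < 0, na.rm = TRUE) ||
      any(variants$reads_minus < 0, na.rm = TRUE)) {
    stop("negative per-strand read counts")
  }
  if (any(variants$freq < 0 | variants$freq > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  keep <- variants$reads_plus >= config$min_reads_per_strand &
    variants$reads_minus >= config$min_reads_per_strand &
    variants$freq > config$min_frequency
  if (config$require_both_strands) {
    keep <- keep & variants$reads_plus > 0 & variants$reads_minus > 0
  }
  keep[is.na(keep)] <- FALSE
  out <- variants[keep, , drop = FALSE]
  if (!is.null(ancestor_variants) && nrow(out) > 0 &&
      nrow(ancestor_variants) > 0) {
    key <- function(df) paste(df$position, df$ref, df$alt, sep = "\r")
    out <- out[!(key(out) %in% key(ancestor_variants)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a tab-separated mutation table
#'
#' Expected header: strain, block, line, position, ref, alt, class, freq,
#' reads_plus, reads_minus, region, coding_effect, gene.
#'
#' @param path file path.
#' @return data.frame of mutation records.
#' @export
read_mutation_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a tab-separated mutation table
#'
#' @param x data.frame of mutation records.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
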