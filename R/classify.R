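#' Classify a base-pair substitution
#'
#' Assigns each single-nucleotide substitution to the transition/transversion
#' dichotomy and to a GC-content direction. Classification is strand-symmetric:
#' a call and its reverse complement fall in the same class (G>A and C>T are
#' both transitions and both GC->AT), so reverse-strand calls fold into the six
#' canonical substitution types.
#'
#' @param ref_allele character vector of single-nucleotide reference alleles
#'   (A, C, G or T).
#' @param alt_allele character vector of single-nucleotide alternate alleles,
#'   recycled against `ref_allele`; `ref != alt` elementwise.
#' @return A data.frame with one row per substitution and columns
#'   `ts_tv` ("transition" or "transversion") and `gc_direction`
#'   ("AT->GC", "GC->AT" or "no_change"; A<->T and G<->C substitutions do not
#'   alter GC content).
#' @examples
#' classify_bps(c("A", "G", "A"), c("G", "T", "T"))
#' @export
classify_bps <- function(ref_allele, alt_allele) {
  ref <- toupper(as.character(ref_allele))
  alt <- toupper(as.character(alt_allele))
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases)) {
    stop("ref and alt alleles must be single unambiguous bases (A/C/G/T)")
  }
  if (any(ref == alt)) {
    stop("ref and alt alleles must differ")
  }
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts_tv <- ifelse(purine[ref] == purine[alt], "transition", "transversion")
  gc <- c(A = FALSE, T = FALSE, G = TRUE, C = TRUE)
  gc_direction <- ifelse(gc[ref] == gc[alt], "no_change",
                         ifelse(gc[ref], "GC->AT", "AT->GC"))
  data.frame(ts_tv = unname(ts_tv), gc_direction = unname(gc_direction),
             stringsAsFactors = FALSE)
}
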