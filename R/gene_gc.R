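#' Per-gene GC content from a genome and annotation
#'
#' Computes the GC fraction of every annotated gene and classifies genes as
#' low or high GC relative to the genome-wide median gene GC, for testing
#' whether mutational effects associate with local base composition.
#'
#' @param genome_fasta path to a genome FASTA file.
#' @param gff3 path to a GFF3 annotation; features of type `gene` are used.
#' @return data.frame with columns `gene_id`, `gc_fraction`, and `gc_class`
#'   ("low"/"high" relative to the median gc_fraction).
#' @export
gene_gc_table <- function(genome_fasta, gff3) {
  if (!requireNamespace("Biostrings", quietly = TRUE) ||
      !requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("gene_gc_table requires the Biostrings and rtracklayer packages")
  }
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ann <- rtracklayer::import(gff3)
  ann <- ann[ann$type == "gene"]
  if (length(ann) == 0) stop("annotation contains no gene features")
  seq_ids <- as.character(GenomicRanges::seqnames(ann))
  if (!all(seq_ids %in% names(genome))) {
    stop("annotation references sequences absent from the FASTA")
  }
  starts <- GenomicRanges::start(ann)
  ends <- GenomicRanges::end(ann)
  lens <- Biostrings::width(genome)[match(seq_ids, names(genome))]
  if (any(starts < 1) || any(ends > lens)) {
    stop("gene coordinates fall outside the sequence bounds")
  }
  ids <- ann$ID
  if (is.null(ids)) ids <- ann$gene_id
  if (is.null(ids)) ids <- paste0("gene", seq_along(ann))
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(ann), function(i) {
    Biostrings::subseq(genome[[seq_ids[i]]], starts[i], ends[i])
  }))
  gc <- Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE)[, 1]
  out <- data.frame(gene_id = as.character(ids), gc_fraction = unname(gc),
                    stringsAsFactors = FALSE)
  med <- stats::median(out$gc_fraction)
  out$gc_class <- ifelse(out$gc_fraction <= med, "low", "high")
  out
}
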