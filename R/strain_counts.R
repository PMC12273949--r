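#' Published mutation-spectrum counts for seven E. coli MA strains
#'
#' Per-strain mutation counts from a large mutation-accumulation study of
#' E. coli K-12 DNA-repair deletion strains spanning a wide range of
#' transition/transversion biases: the wild type, three mismatch-repair
#' knockouts (mutS, mutL, mutH), a damaged-pyrimidine repair double knockout
#' (nth-nei), and two 8-oxo-dGTP pathway knockouts (mutY, mutT). These counts
#' are the inputs for bias, rate and bookkeeping arithmetic; biases derived
#' from them are proportions of the form a/(a+b) (see [compute_bias()]).
#'
#' `generations_per_line` is the per-line generation count for strains whose
#' MA blocks all ran the same number of days at ~27 generations per day; it is
#' `NA` for the wild type and the mutY knockout, whose blocks differed in
#' length (their rate arithmetic needs per-block accounting not carried here).
#'
#' @return data.frame with one row per strain and columns: `strain`,
#'   `lines_evolved`, `lines_sequenced`, `total_mutations`,
#'   `single_mutation_lines`, `bps`, `indel`, `coding`, `noncoding`,
#'   `nonsynonymous`, `synonymous`, `transitions`, `transversions`,
#'   `at_gc`, `gc_at`, `no_change`, `generations_per_line`.
#' @examples
#' counts <- mutator_spectrum_counts()
#' wt <- counts[counts$strain == "WT", ]
#' compute_bias(wt$transversions, wt$transitions, wt$lines_sequenced)
#' @export
mutator_spectrum_counts <- function() {
  data.frame(
    strain = c("mutS", "mutL", "mutH", "nth-nei", "WT", "mutY", "mutT"),
    lines_evolved = c(350L, 350L, 350L, 300L, 98L, 430L, 300L),
    lines_sequenced = c(345L, 344L, 346L, 285L, 97L, 424L, 271L),
    total_mutations = c(616L, 603L, 908L, 502L, 426L, 798L, 789L),
    single_mutation_lines = c(91L, 97L, 100L, 102L, 94L, 113L, 97L),
    bps = c(508L, 509L, 809L, 482L, 387L, 787L, 783L),
    indel = c(108L, 94L, 99L, 20L, 39L, 11L, 6L),
    coding = c(440L, 437L, 710L, 400L, 282L, 684L, 657L),
    noncoding = c(68L, 72L, 99L, 82L, 105L, 103L, 126L),
    nonsynonymous = c(290L, 274L, 433L, 273L, 183L, 489L, 462L),
    synonymous = c(150L, 163L, 277L, 127L, 99L, 195L, 195L),
    transitions = c(491L, 491L, 774L, 430L, 206L, 69L, 12L),
    transversions = c(17L, 18L, 35L, 52L, 178L, 644L, 771L),
    at_gc = c(339L, 361L, 568L, 22L, 118L, 24L, 775L),
    gc_at = c(162L, 143L, 229L, 438L, 206L, 746L, 5L),
    no_change = c(7L, 5L, 12L, 22L, 60L, 17L, 3L),
    generations_per_line = c(27, 27, 27, 216, NA, NA, 27),
    stringsAsFactors = FALSE
  )
}
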