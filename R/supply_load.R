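#' Genome-wide beneficial mutation supply
#'
#' S_b = f_b x mu x genome size: the expected number of beneficial mutations
#' arising per genome per generation. The 95% CI propagates the binomial
#' uncertainty of f_b at the DFE's sample size, treating mu as fixed:
#' sd(S_b) = sqrt(f_b (1 - f_b) / n) x mu x genome size, CI = 1.96 sd.
#'
#' @param f_b beneficial fraction of the (corrected) DFE, in [0, 1].
#' @param mu mutation rate per bp per generation.
#' @param genome_size genome length in bp (default the E. coli K-12 value).
#' @param n_dfe number of mutations in the DFE; NULL drops the CI.
#' @return list with `S_b` and `ci_half_width` (NA without `n_dfe`).
#' @examples
#' beneficial_supply(0.1, 1e-8, 4641652)
#' @export
beneficial_supply <- function(f_b, mu, genome_size = ECOLI_GENOME_SIZE,
                              n_dfe = NULL) {
  stopifnot(f_b >= 0, f_b <= 1, mu >= 0, genome_size > 0)
  ci <- NA_real_
  if (!is.null(n_dfe)) {
    ci <- 1.96 * sqrt(f_b * (1 - f_b) / n_dfe) * mu * genome_size
  }
  list(S_b = f_b * mu * genome_size, ci_half_width = ci)
}

#' Genome-wide deleterious load
#'
#' L_d = f_d x mu x genome size, the mirror of [beneficial_supply()] for the
#' deleterious fraction; same CI propagation.
#'
#' @param f_d deleterious fraction of the (corrected) DFE, in [0, 1].
#' @param mu mutation rate per bp per generation.
#' @param genome_size genome length in bp.
#' @param n_dfe number of mutations in the DFE; NULL drops the CI.
#' @return list with `L_d` and `ci_half_width`.
#' @export
deleterious_load <- function(f_d, mu, genome_size = ECOLI_GENOME_SIZE,
                             n_dfe = NULL) {
  stopifnot(f_d >= 0, f_d <= 1, mu >= 0, genome_size > 0)
  ci <- NA_real_
  if (!is.null(n_dfe)) {
    ci <- 1.96 * sqrt(f_d * (1 - f_d) / n_dfe) * mu * genome_size
  }
  list(L_d = f_d * mu * genome_size, ci_half_width = ci)
}

#' Beneficial supply and deleterious load across strains
#'
#' Computes, for every strain, the observed supply and load from its own DFE
#' fractions, the counterfactual values under the reference (wild-type) DFE
#' (isolating the effect of mutation rate alone), and ratios to the
#' reference strain. By construction the counterfactual columns scale
#' linearly with mu across strains, and
#' rel_S_b / rel_S_b_wt_dfe = f_b(strain) / f_b(WT).
#'
#' @param strains data.frame with columns `strain`, `environment`, `mu`,
#'   `f_b`, `f_d`, and optionally `n_dfe` (for CIs).
#' @param wt_id label of the reference strain, present in `strains` for
#'   every environment.
#' @param genome_size genome length in bp.
#' @return data.frame with columns `strain`, `environment`, `S_b`,
#'   `S_b_ci`, `S_b_wt_dfe`, `L_d`, `L_d_ci`, `L_d_wt_dfe`, `rel_S_b`,
#'   `rel_S_b_wt_dfe`, `rel_L_d`, `rel_L_d_wt_dfe`.
#' @export
supply_load_table <- function(strains, wt_id = "WT",
                              genome_size = ECOLI_GENOME_SIZE) {
  needed <- c("strain", "mu", "f_b", "f_d")
  if (!all(needed %in% names(strains))) {
    stop("strains must carry columns: ", paste(needed, collapse = ", "))
  }
  if (!("environment" %in% names(strains))) strains$environment <- "default"
  if (!(wt_id %in% strains$strain)) {
    stop("reference strain '", wt_id, "' missing from the table")
  }
  out <- lapply(split(strains, strains$environment), function(d) {
    wt <- d[d$strain == wt_id, ]
    if (nrow(wt) != 1) {
      stop("reference strain must appear exactly once per environment")
    }
    n_dfe <- if ("n_dfe" %in% names(d)) d$n_dfe else rep(list(NULL), nrow(d))
    sb <- mapply(function(f, m, n) beneficial_supply(f, m, genome_size,
                                                     if (is.na(n)) NULL else n),
                 d$f_b, d$mu,
                 if ("n_dfe" %in% names(d)) d$n_dfe else NA,
                 SIMPLIFY = FALSE)
    ld <- mapply(function(f, m, n) deleterious_load(f, m, genome_size,
                                                    if (is.na(n)) NULL else n),
                 d$f_d, d$mu,
                 if ("n_dfe" %in% names(d)) d$n_dfe else NA,
                 SIMPLIFY = FALSE)
    res <- data.frame(
      strain = d$strain, environment = d$environment,
      S_b = vapply(sb, `[[`, numeric(1), "S_b"),
      S_b_ci = vapply(sb, `[[`, numeric(1), "ci_half_width"),
      S_b_wt_dfe = wt$f_b * d$mu * genome_size,
      L_d = vapply(ld, `[[`, numeric(1), "L_d"),
      L_d_ci = vapply(ld, `[[`, numeric(1), "ci_half_width"),
      L_d_wt_dfe = wt$f_d * d$mu * genome_size,
      stringsAsFactors = FALSE)
    wt_row <- res[res$strain == wt_id, ]
    res$rel_S_b <- res$S_b / wt_row$S_b
    res$rel_S_b_wt_dfe <- res$S_b_wt_dfe / wt_row$S_b_wt_dfe
    res$rel_L_d <- res$L_d / wt_row$L_d
    res$rel_L_d_wt_dfe <- res$L_d_wt_dfe / wt_row$L_d_wt_dfe
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
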