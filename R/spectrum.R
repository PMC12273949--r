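#' Mutation-class bias with binomial 95% confidence interval
#'
#' The bias between two mutation classes is the proportion
#' `count_a / (count_a + count_b)` (e.g. transversion bias =
#' Tv / (Ts + Tv)). The 95% CI half-width is the normal-approximation
#' binomial form `1.96 * sqrt(p (1 - p) / n_lines)`, with the number of
#' successfully sequenced MA lines as the sample size; this convention
#' was reverse-engineered from published per-strain CIs and reproduces
#' them to 3 decimal places.
#'
#' @param count_a mutations of the focal class (numerator).
#' @param count_b mutations of the contrasting class.
#' @param n_lines number of sequenced MA lines the counts came from.
#' @return Object of class `bias_estimate`: list with `value`,
#'   `ci_half_width`, `count_a`, `count_b`, `n_lines`. When
#'   `count_a + count_b == 0` the value is `NA` and `undefined` is TRUE.
#'   The CI half-width is 0 when the bias is exactly 0 or 1.
#' @examples
#' compute_bias(178, 206, 97)  # transversion bias of a wild-type strain
#' @export
compute_bias <- function(count_a, count_b, n_lines) {
  stopifnot(length(count_a) == 1, length(count_b) == 1, length(n_lines) == 1)
  if (is.na(n_lines) || n_lines < 1) stop("n_lines must be >= 1")
  if (count_a < 0 || count_b < 0) stop("counts must be non-negative")
  total <- count_a + count_b
  if (total == 0) {
    out <- list(value = NA_real_, ci_half_width = NA_real_, undefined = TRUE)
  } else {
    p <- count_a / total
    out <- list(value = p,
                ci_half_width = 1.96 * sqrt(p * (1 - p) / n_lines),
                undefined = FALSE)
  }
  structure(c(out, list(count_a = count_a, count_b = count_b,
                        n_lines = n_lines)),
            class = "bias_estimate")
}

#' @export
print.bias_estimate <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("bias undefined (0 mutations in both classes)\n")
  } else {
    cat(sprintf("bias %.3f +/- %.3f (95%% CI), %d/%d mutations over %d lines\n",
                x$value, x$ci_half_width, x$count_a,
                x$count_a + x$count_b, x$n_lines))
  }
  invisible(x)
}

#' Per-bp per-generation mutation rate
#'
#' mu = total mutations / (genome size x total line-generations), with total
#' line-generations the sum over lines of the generations each line evolved.
#' When per-line mutation counts are supplied, a 95% CI is attached as the
#' t-distribution margin of error over per-line rates:
#' `t[0.975, n-1] * sd(rates) / sqrt(n)`. With only a strain total the CI
#' cannot be formed and is reported as `NA` rather than approximated.
#'
#' @param total_mutations total mutations called in the strain.
#' @param genome_size genome length in bp.
#' @param line_generations numeric vector of generations evolved, one entry
#'   per sequenced line (a single value is recycled only if `n_lines` given).
#' @param per_line_counts optional per-line mutation counts, same length as
#'   `line_generations`; must sum to `total_mutations`.
#' @param n_lines optional number of lines, used to recycle a scalar
#'   `line_generations`.
#' @return list with `mu` and `mu_ci_half_width` (NA when per-line counts are
#'   unavailable).
#' @examples
#' mutation_rate(789, 4.6e6, rep(27, 271))  # ~2.3e-8
#' @export
mutation_rate <- function(total_mutations, genome_size, line_generations,
                          per_line_counts = NULL, n_lines = NULL) {
  if (!is.null(n_lines) && length(line_generations) == 1) {
    line_generations <- rep(line_generations, n_lines)
  }
  if (length(line_generations) == 0) stop("line_generations must be non-empty")
  if (genome_size <= 0) stop("genome_size must be positive")
  total_gen <- sum(line_generations)
  if (total_gen <= 0) stop("total generations must be positive")
  mu <- total_mutations / (genome_size * total_gen)
  ci <- NA_real_
  if (!is.null(per_line_counts)) {
    if (length(per_line_counts) != length(line_generations)) {
      stop("per_line_counts and line_generations lengths differ")
    }
    if (sum(per_line_counts) != total_mutations) {
      stop("per_line_counts do not sum to total_mutations")
    }
    n <- length(per_line_counts)
    if (n >= 2) {
      rates <- per_line_counts / (genome_size * line_generations)
      ci <- stats::qt(0.975, df = n - 1) * stats::sd(rates) / sqrt(n)
    }
  }
  list(mu = mu, mu_ci_half_width = ci)
}

#' Tally the mutation spectrum of one strain
#'
#' Counts mutations by class and computes the per-bp per-generation mutation
#' rate. BPS are split into transitions/transversions and GC-direction
#' classes; coding/noncoding and synonymous/nonsynonymous partitions are
#' counted over BPS records (so coding + noncoding = BPS and
#' synonymous + nonsynonymous = coding).
#'
#' @param mutations data.frame of mutation records (columns `strain`, `class`,
#'   `ref`, `alt`, `region`, `coding_effect`; all rows must share one strain).
#'   May be empty.
#' @param n_lines number of successfully sequenced lines.
#' @param total_generations total line-generations over all lines and blocks.
#' @param genome_size genome length in bp (default the E. coli K-12 value used
#'   for rate arithmetic, 4.6e6).
#' @param per_line_counts optional per-line mutation counts for the rate CI.
#' @param line_generations optional per-line generations matching
#'   `per_line_counts`; defaults to `total_generations / n_lines` each.
#' @return Object of class `ma_spectrum`: `strain_id`, `n_lines`,
#'   `total_generations`, a named integer vector `counts`, `mu`,
#'   `mu_ci_half_width`, and a list `biases` of [compute_bias()] results
#'   (transversion, indel, noncoding, synonymous, gc_at).
#' @export
tally_spectrum <- function(mutations, n_lines, total_generations,
                           genome_size = 4.6e6, per_line_counts = NULL,
                           line_generations = NULL) {
  strain <- NA_character_
  if (nrow(mutations) > 0) {
    strains <- unique(as.character(mutations$strain))
    if (length(strains) > 1) {
      stop("tally_spectrum expects a single strain; got: ",
           paste(strains, collapse = ", "))
    }
    strain <- strains
  }
  is_bps <- nrow(mutations) > 0 & mutations$class == "BPS"
  bps <- mutations[is_bps, , drop = FALSE]
  indels <- sum(!is_bps)
  cls <- if (nrow(bps) > 0) classify_bps(bps$ref, bps$alt) else
    data.frame(ts_tv = character(0), gc_direction = character(0))
  counts <- c(
    transitions    = sum(cls$ts_tv == "transition"),
    transversions  = sum(cls$ts_tv == "transversion"),
    BPS            = nrow(bps),
    indels         = indels,
    coding         = sum(bps$region == "coding"),
    noncoding      = sum(bps$region == "noncoding"),
    synonymous     = sum(bps$coding_effect == "synonymous"),
    nonsynonymous  = sum(bps$coding_effect == "nonsynonymous"),
    "AT->GC"       = sum(cls$gc_direction == "AT->GC"),
    "GC->AT"       = sum(cls$gc_direction == "GC->AT"),
    no_change      = sum(cls$gc_direction == "no_change")
  )
  total <- counts[["BPS"]] + counts[["indels"]]
  rate <- if (total == 0) {
    list(mu = 0, mu_ci_half_width = NA_real_)
  } else {
    lg <- if (is.null(line_generations)) {
      rep(total_generations / n_lines, n_lines)
    } else line_generations
    mutation_rate(total, genome_size, lg, per_line_counts = per_line_counts)
  }
  biases <- list(
    transversion = compute_bias(counts[["transversions"]],
                                counts[["transitions"]], n_lines),
    indel = compute_bias(counts[["indels"]], counts[["BPS"]], n_lines),
    noncoding = compute_bias(counts[["noncoding"]], counts[["coding"]],
                             n_lines),
    synonymous = compute_bias(counts[["synonymous"]],
                              counts[["nonsynonymous"]], n_lines),
    gc_at = compute_bias(counts[["GC->AT"]], counts[["AT->GC"]], n_lines)
  )
  structure(list(strain_id = strain, n_lines = n_lines,
                 total_generations = total_generations,
                 counts = counts, mu = rate$mu,
                 mu_ci_half_width = rate$mu_ci_half_width,
                 biases = biases),
            class = "ma_spectrum")
}

#' @export
print.ma_spectrum <- function(x, ...) {
  cat("Mutation spectrum for strain", x$strain_id,
      sprintf("(%d lines, %.0f line-generations)\n",
              x$n_lines, x$total_generations))
  print(x$counts)
  cat(sprintf("mutation rate mu = %.3g per bp per generation", x$mu))
  if (!is.na(x$mu_ci_half_width)) {
    cat(sprintf(" +/- %.3g", x$mu_ci_half_width))
  }
  cat("\nbiases:\n")
  for (nm in names(x$biases)) {
    b <- x$biases[[nm]]
    if (!isTRUE(b$undefined)) {
      cat(sprintf("  %-12s %.2f +/- %.3f\n", nm, b$value, b$ci_half_width))
    }
  }
  invisible(x)
}

#' Poisson goodness of fit for per-line mutation counts
#'
#' Under the MA design, mutations should accrue independently at a constant
#' rate, so the number of mutations per line is Poisson. This compares the
#' observed frequency distribution against Poisson(lambda-hat) with a
#' chi-squared test. Categories are 0, 1, 2, ... with the right tail pooled
#' until every expected count is at least 5 (standard chi-squared validity);
#' degrees of freedom are `categories - 2` (one for totals, one for the
#' estimated mean). Blocks that evolved for different numbers of generations
#' should be tested separately.
#'
#' @param per_line_counts integer vector, mutations called per MA line.
#' @return Object of class `poisson_gof`: `lambda_hat`, `observed`,
#'   `expected` (both named by category, tail category "k+"), `chisq_stat`,
#'   `dof`, `p_value`, `n_lines`.
#' @export
poisson_gof <- function(per_line_counts) {
  x <- as.integer(per_line_counts)
  if (length(x) < 2) stop("need at least 2 lines")
  if (all(x == 0)) stop("degenerate input: no mutations in any line")
  n <- length(x)
  lambda <- mean(x)
  kmax <- max(x)
  probs <- stats::dpois(0:kmax, lambda)
  probs <- c(probs, 1 - sum(probs))  # open right tail
  expected <- n * probs
  # pool the right tail until every expected count >= 5
  k <- length(expected)
  while (k > 2 && expected[k] < 5) {
    expected[k - 1] <- expected[k - 1] + expected[k]
    expected <- expected[-k]
    k <- k - 1
  }
  n_cat <- length(expected)
  observed <- tabulate(pmin(x, n_cat - 1) + 1L, nbins = n_cat)
  labels <- as.character(0:(n_cat - 1))
  labels[n_cat] <- paste0(n_cat - 1, "+")
  names(observed) <- names(expected) <- labels
  stat <- sum((observed - expected)^2 / expected)
  dof <- max(n_cat - 2, 1)
  structure(list(lambda_hat = lambda, observed = observed,
                 expected = expected, chisq_stat = stat, dof = dof,
                 p_value = stats::pchisq(stat, dof, lower.tail = FALSE),
                 n_lines = n),
            class = "poisson_gof")
}

#' @export
print.poisson_gof <- function(x, ...) {
  cat(sprintf(
    "Poisson GOF: lambda-hat = %.3f over %d lines; X2 = %.3f, df = %d, p = %.3g\n",
    x$lambda_hat, x$n_lines, x$chisq_stat, x$dof, x$p_value))
  print(rbind(observed = x$observed, expected = round(x$expected, 2)))
  invisible(x)
}

#' Recall of known background mutations across MA lines
#'
#' Checks, line by line, whether each expected (position, ref, alt) mutation
#' was called, and at what frequency; used to estimate the false-negative rate
#' of a calling pipeline from mutations known to be present in the ancestor.
#'
#' @param mutation_lists named list of per-line mutation data.frames (columns
#'   `position`, `ref`, `alt`, `freq`).
#' @param expected data.frame with columns `position`, `ref`, `alt`.
#' @return list with `per_line` (one row per line per expected mutation:
#'   `line`, `position`, `ref`, `alt`, `found`, `frequency`) and `recall`
#'   (per-mutation fraction of lines in which it was found).
#' @export
recall_check <- function(mutation_lists, expected) {
  stopifnot(is.list(mutation_lists), nrow(expected) >= 1)
  lines <- names(mutation_lists)
  if (is.null(lines)) lines <- as.character(seq_along(mutation_lists))
  rows <- lapply(seq_along(mutation_lists), function(i) {
    ml <- mutation_lists[[i]]
    hit <- vapply(seq_len(nrow(expected)), function(j) {
      m <- which(ml$position == expected$position[j] &
                 ml$ref == expected$ref[j] & ml$alt == expected$alt[j])
      if (length(m) == 0) NA_real_ else ml$freq[m[1]]
    }, numeric(1))
    data.frame(line = lines[i], position = expected$position,
               ref = expected$ref, alt = expected$alt,
               found = !is.na(hit), frequency = hit,
               stringsAsFactors = FALSE)
  })
  per_line <- do.call(rbind, rows)
  recall <- tapply(per_line$found,
                   paste(per_line$position, per_line$ref, per_line$alt),
                   mean)
  key <- paste(expected$position, expected$ref, expected$alt)
  list(per_line = per_line, recall = as.numeric(recall[key]))
}
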