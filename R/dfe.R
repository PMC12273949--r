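#' Relative colony-sampling probability of a mutation of effect s
#'
#' In an MA experiment each daily bottleneck picks one colony; a mutation
#' arising during colony growth is carried by the sampled cell with a
#' probability that increases with its growth advantage, so beneficial
#' mutations are slightly over-represented among the mutations recovered.
#' This models the bias with a deterministic colony-growth expectation: a
#' mutation arises at division generation t (t = 0..G-1) with probability
#' proportional to the number of divisions at t (2^t); the mutant sub-lineage
#' then doubles (1+s) times per ancestral doubling, giving a final mutant
#' fraction
#'   f(s, t) = 2^((1+s)(G-t)) / (2^G - 2^(G-t) + 2^((1+s)(G-t)))
#' and the relative sampling probability is
#'   r(s) = E_t[f(s, t)] / E_t[f(0, t)].
#' r(0) = 1 and r is strictly increasing in s. DFE correction weights each
#' recovered mutation by 1/r(s) (see [build_dfe()]); a user-supplied weight
#' function can replace this model there.
#'
#' @param s selection coefficient(s), each > -1.
#' @param G generations of colony growth between bottlenecks (default 27).
#' @return numeric vector of relative sampling probabilities.
#' @examples
#' colony_sampling_weight(c(-0.1, 0, 0.1))
#' @export
colony_sampling_weight <- function(s, G = 27) {
  if (any(!is.finite(s)) || any(s <= -1)) {
    stop("selection coefficients must be finite and > -1")
  }
  if (G < 1) stop("G must be >= 1")
  t <- 0:(G - 1)
  wt <- 2^t
  wt <- wt / sum(wt)
  ef <- function(si) {
    num <- 2^((1 + si) * (G - t))
    sum(wt * num / (2^G - 2^(G - t) + num))
  }
  e0 <- ef(0)
  vapply(s, function(si) ef(si) / e0, numeric(1))
}

#' DFE construction configuration
#'
#' @param neutral_half_width half-width of the neutral zone around s = 0,
#'   chosen to absorb experimental measurement error (0.05 for rich LB
#'   medium, 0.025 for minimal glucose).
#' @param bin_width histogram bin width; defaults to the neutral half-width
#'   so the neutral zone is exactly the two central bins. Bins are aligned on
#'   multiples of `bin_width`, so `neutral_half_width` must be a whole number
#'   of bins.
#' @param colony_generations generations per colony bottleneck used by the
#'   sampling-bias model (default 27).
#' @param apply_correction correct for colony-sampling bias (default TRUE).
#' @param weight_fun function(s) giving relative sampling probabilities;
#'   defaults to [colony_sampling_weight()] with `colony_generations`.
#'   Supplying a weight table of the reference correction procedure is
#'   supported through this hook.
#' @param per_mutation if TRUE (default) each mutation carries weight
#'   1/r(s_i) before binning; if FALSE the correction is applied to binned
#'   fractions at the bin midpoints instead.
#' @return object of class `dfe_config`.
#' @export
dfe_config <- function(neutral_half_width = 0.05,
                       bin_width = if (neutral_half_width > 0)
                         neutral_half_width else 0.05,
                       colony_generations = 27,
                       apply_correction = TRUE,
                       weight_fun = NULL,
                       per_mutation = TRUE) {
  stopifnot(bin_width > 0, neutral_half_width >= 0)
  if (neutral_half_width > 0) {
    k <- neutral_half_width / bin_width
    if (abs(k - round(k)) > 1e-8) {
      stop("neutral_half_width must be a whole number of bins")
    }
  }
  if (is.null(weight_fun)) {
    G <- colony_generations
    weight_fun <- function(s) colony_sampling_weight(s, G)
  }
  structure(list(neutral_half_width = neutral_half_width,
                 bin_width = bin_width,
                 colony_generations = as.integer(colony_generations),
                 apply_correction = isTRUE(apply_correction),
                 weight_fun = weight_fun,
                 per_mutation = isTRUE(per_mutation)),
            class = "dfe_config")
}

#' Build a (bias-corrected) distribution of fitness effects
#'
#' Bins measured selection coefficients into a histogram and, by default,
#' corrects for colony-sampling bias by weighting each mutation by the
#' reciprocal of its relative sampling probability r(s) (renormalized).
#' The correction changes weights only, never the measured s values, so raw
#' and corrected DFEs share the same support. Beneficial, neutral and
#' deleterious fractions are the corrected weight with s above, within, and
#' below the neutral zone. Lethal records (s = -1, no growth) are placed in
#' the most deleterious bin and take the correction weight of the most
#' deleterious viable mutation rather than entering the r(s) model.
#'
#' @param s_values finite selection coefficients, n >= 1 (s = -1 allowed for
#'   lethals; s < -1 is an error).
#' @param config a [dfe_config()].
#' @param strain_id,environment optional labels carried through.
#' @return Object of class `dfe`: `bin_edges`, `raw_counts`,
#'   `corrected_weights` (sum to 1), `s_values`, `weights` (per-mutation,
#'   sum to 1), `n_mutations`, `f_b`, `f_n`, `f_d`, `median_s` (weighted
#'   median of the corrected distribution), plus the labels and config.
#' @examples
#' dfe <- build_dfe(c(-0.2, -0.06, 0.01, 0.08, 0.12),
#'                  dfe_config(neutral_half_width = 0.05))
#' dfe$f_b
#' @export
build_dfe <- function(s_values, config = dfe_config(),
                      strain_id = NA_character_,
                      environment = NA_character_) {
  stopifnot(inherits(config, "dfe_config"))
  s <- as.numeric(s_values)
  if (length(s) == 0) stop("empty selection-coefficient input")
  if (any(!is.finite(s))) stop("selection coefficients must be finite")
  if (any(s < -1)) stop("selection coefficients below -1 are not meaningful")
  lethal <- s <= -1
  w <- rep(1, length(s))
  if (config$apply_correction && config$per_mutation) {
    if (any(!lethal)) {
      r <- config$weight_fun(s[!lethal])
      w[!lethal] <- 1 / r
      if (any(lethal)) {
        # lethal class inherits the weight of the deleterious floor
        w[lethal] <- 1 / min(r[s[!lethal] == min(s[!lethal])])
      }
    }
  }
  w <- w / sum(w)

  bw <- config$bin_width
  lo <- floor(min(s) / bw) * bw
  hi <- ceiling(max(s) / bw) * bw
  if (hi <= lo) hi <- lo + bw
  edges <- seq(lo, hi, by = bw)
  bin <- findInterval(s, edges, rightmost.closed = TRUE, left.open = TRUE)
  bin[bin == 0] <- 1  # s exactly at the lowest edge
  raw_counts <- tabulate(bin, nbins = length(edges) - 1)
  corrected <- vapply(seq_len(length(edges) - 1),
                      function(b) sum(w[bin == b]), numeric(1))
  if (config$apply_correction && !config$per_mutation) {
    # bin-level mode: reweight binned fractions at bin midpoints
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    mids <- pmax(mids, -0.999)
    cw <- raw_counts / config$weight_fun(mids)
    corrected <- cw / sum(cw)
    nh <- config$neutral_half_width
    f_b <- sum(corrected[mids > nh])
    f_d <- sum(corrected[mids < -nh])
    w <- corrected[bin] / raw_counts[bin]
    w <- w / sum(w)
  } else {
    corrected <- corrected / sum(corrected)
    nh <- config$neutral_half_width
    f_b <- sum(w[s > nh])
    f_d <- sum(w[s < -nh])
  }
  f_n <- 1 - f_b - f_d
  ord <- order(s)
  cum <- cumsum(w[ord])
  median_s <- s[ord][which(cum >= 0.5)[1]]
  structure(list(strain_id = strain_id, environment = environment,
                 bin_edges = edges, raw_counts = raw_counts,
                 corrected_weights = corrected,
                 s_values = s, weights = w,
                 n_mutations = length(s),
                 f_b = f_b, f_n = f_n, f_d = f_d,
                 median_s = median_s, config = config),
            class = "dfe")
}

#' @export
print.dfe <- function(x, ...) {
  lab <- if (!is.na(x$strain_id)) paste0(" [", x$strain_id,
                                         if (!is.na(x$environment))
                                           paste0(", ", x$environment), "]")
         else ""
  cat(sprintf("DFE%s: %d mutations%s\n", lab, x$n_mutations,
              if (x$config$apply_correction)
                " (colony-sampling bias corrected)" else " (raw)"))
  cat(sprintf("  f_b = %.3f  f_n = %.3f  f_d = %.3f  median s = %+.3f\n",
              x$f_b, x$f_n, x$f_d, x$median_s))
  invisible(x)
}

#' @export
summary.dfe <- function(object, ...) {
  print(object)
  df <- data.frame(bin_lo = object$bin_edges[-length(object$bin_edges)],
                   bin_hi = object$bin_edges[-1],
                   raw_count = object$raw_counts,
                   corrected_weight = round(object$corrected_weights, 4))
  print(df, row.names = FALSE)
  invisible(df)
}

#' @export
plot.dfe <- function(x, ..., main = NULL) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  if (is.null(main)) {
    main <- sprintf("DFE%s", if (!is.na(x$strain_id))
      paste0(" of ", x$strain_id) else "")
  }
  graphics::barplot(x$corrected_weights, names.arg = sprintf("%.2f", mids),
                    xlab = "selection coefficient s",
                    ylab = "corrected fraction", main = main, ...)
  invisible(x)
}

# round half away from zero, then repair the largest remainder so the
# rounded counts sum to n
effective_counts <- function(fractions, n) {
  x <- fractions * n
  r <- floor(x + 0.5)
  diff <- n - sum(r)
  if (diff != 0) {
    rem <- x - r
    ord <- order(if (diff > 0) -rem else rem)
    for (i in seq_len(abs(diff))) {
      j <- ord[(i - 1) %% length(r) + 1]
      r[j] <- r[j] + sign(diff)
    }
  }
  r
}

#' Chi-squared comparison of two DFEs' class fractions
#'
#' Converts each DFE's beneficial/neutral/deleterious fractions back to
#' effective counts (n x fraction, rounded half away from zero with a
#' largest-remainder repair so counts sum to n) and runs a 3x2 chi-squared
#' test. When any expected cell falls below 1 a warning is raised and
#' Fisher's exact test is used instead (flagged in the result).
#'
#' @param dfe_a,dfe_b objects of class `dfe`.
#' @return object of class `dfe_comparison`: `strain_pair`, `counts`
#'   (2x3 matrix), `chisq_stat`, `dof`, `p_raw`, `exact_fallback`,
#'   `p_adjusted` (NA until set by [compare_dfe_batch()]).
#' @export
compare_dfe_fractions <- function(dfe_a, dfe_b) {
  stopifnot(inherits(dfe_a, "dfe"), inherits(dfe_b, "dfe"))
  tab <- rbind(effective_counts(c(dfe_a$f_b, dfe_a$f_n, dfe_a$f_d),
                                dfe_a$n_mutations),
               effective_counts(c(dfe_b$f_b, dfe_b$f_n, dfe_b$f_d),
                                dfe_b$n_mutations))
  dimnames(tab) <- list(c(dfe_a$strain_id, dfe_b$strain_id),
                        c("beneficial", "neutral", "deleterious"))
  keep <- colSums(tab) > 0
  tab2 <- tab[, keep, drop = FALSE]
  expected <- outer(rowSums(tab2), colSums(tab2)) / sum(tab2)
  fallback <- any(expected < 1)
  if (fallback) {
    warning("expected cell below 1; falling back to Fisher's exact test")
    p <- stats::fisher.test(tab2)$p.value
    stat <- NA_real_
    dof <- NA_integer_
  } else if (identical(tab2[1, ], tab2[2, ])) {
    stat <- 0
    dof <- ncol(tab2) - 1L
    p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab2, correct = FALSE))
    stat <- unname(ct$statistic)
    dof <- unname(ct$parameter)
    p <- ct$p.value
  }
  structure(list(strain_pair = rownames(tab), counts = tab,
                 chisq_stat = stat, dof = dof, p_raw = p,
                 exact_fallback = fallback, p_adjusted = NA_real_),
            class = "dfe_comparison")
}

#' All pairwise DFE comparisons with Benjamini-Hochberg correction
#'
#' @param dfes list of `dfe` objects (>= 2).
#' @return data.frame with one row per pair: `strain_a`, `strain_b`,
#'   `chisq_stat`, `p_raw`, `p_adjusted` (BH across all pairs),
#'   `exact_fallback`.
#' @export
compare_dfe_batch <- function(dfes) {
  stopifnot(length(dfes) >= 2)
  pairs <- utils::combn(length(dfes), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    cmp <- compare_dfe_fractions(dfes[[pairs[1, k]]], dfes[[pairs[2, k]]])
    data.frame(strain_a = cmp$strain_pair[1], strain_b = cmp$strain_pair[2],
               chisq_stat = cmp$chisq_stat, p_raw = cmp$p_raw,
               exact_fallback = cmp$exact_fallback,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

#' Subsampling robustness of the beneficial fraction
#'
#' Repeatedly subsamples the selection coefficients without replacement at a
#' reduced sample size, rebuilds the DFE each time, and summarizes the
#' resulting f_b values with a percentile interval — the standard check that
#' a smaller filtered data set would not have changed the estimated
#' beneficial fraction.
#'
#' @param s_values full set of selection coefficients.
#' @param target_n subsample size, <= length(s_values).
#' @param iterations number of subsamples (default 100).
#' @param seed RNG seed; fixed seed gives bitwise-identical output.
#' @param config a [dfe_config()].
#' @return list with `f_b` (per-iteration values), `mean`, `ci` (2.5% and
#'   97.5% percentiles), `target_n`, `iterations`, `seed`.
#' @export
subsample_dfe <- function(s_values, target_n, iterations = 100, seed = 1,
                          config = dfe_config()) {
  n <- length(s_values)
  if (target_n > n) stop("target_n exceeds available sample size")
  if (target_n < 1) stop("target_n must be >= 1")
  rng <- rng_stream(seed, "subsample_dfe")
  fb <- vapply(seq_len(iterations), function(i) {
    idx <- sample.int(n, target_n)
    build_dfe(s_values[idx], config)$f_b
  }, numeric(1))
  restore_rng(rng)
  list(f_b = fb, mean = mean(fb),
       ci = stats::quantile(fb, c(0.025, 0.975), names = FALSE),
       target_n = target_n, iterations = iterations, seed = seed)
}

# insert-and-absorb compact letter display from a logical "differs" matrix
compact_letters <- function(differs) {
  g <- nrow(differs)
  sets <- list(seq_len(g))
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      if (!differs[i, j]) next
      for (k in seq_along(sets)) {
        if (all(c(i, j) %in% sets[[k]])) {
          s <- sets[[k]]
          sets[[k]] <- setdiff(s, i)
          sets[[length(sets) + 1]] <- setdiff(s, j)
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(sets))
      for (a in seq_along(sets)) {
        for (b in seq_along(sets)) {
          if (a != b && keep[a] && keep[b] &&
              all(sets[[a]] %in% sets[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- sets[keep]
    }
  }
  # letter sets in the order of the best-ranked group they contain
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letters_out <- rep("", g)
  for (k in seq_along(sets)) {
    for (m in sets[[k]]) {
      letters_out[m] <- paste0(letters_out[m], letters[k])
    }
  }
  letters_out
}

#' Wilcoxon rank-sum comparisons of fitness effects across mutation classes
#'
#' Runs pairwise Wilcoxon rank-sum tests between groups of selection
#' coefficients (for example transition versus transversion mutations, or a
#' class within each strain), adjusts p-values with Benjamini-Hochberg over
#' the declared family, and assigns a compact-letter grouping: groups sharing
#' a letter are not significantly different at `alpha`.
#'
#' @param s selection coefficients.
#' @param group group label per observation.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list with `pairs` (data.frame: group_a, group_b, statistic,
#'   p_raw, p_adjusted), `letters` (named by group), and `excluded` (groups
#'   with fewer than 2 observations, dropped with a warning).
#' @export
class_fitness_tests <- function(s, group, alpha = 0.05) {
  group <- as.character(group)
  sizes <- table(group)
  excluded <- names(sizes)[sizes < 2]
  if (length(excluded) > 0) {
    warning("excluding group(s) with < 2 observations: ",
            paste(excluded, collapse = ", "))
    keep <- !(group %in% excluded)
    s <- s[keep]
    group <- group[keep]
  }
  groups <- names(sort(tapply(s, group, stats::median), decreasing = TRUE))
  if (length(groups) < 2) stop("need at least 2 groups with >= 2 observations")
  pairs <- utils::combn(groups, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- s[group == pairs[1, k]]
    b <- s[group == pairs[2, k]]
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
               statistic = unname(wt$statistic), p_raw = wt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = "BH")
  differs <- matrix(FALSE, length(groups), length(groups),
                    dimnames = list(groups, groups))
  for (k in seq_len(nrow(res))) {
    sig <- res$p_adjusted[k] < alpha
    differs[res$group_a[k], res$group_b[k]] <- sig
    differs[res$group_b[k], res$group_a[k]] <- sig
  }
  lets <- compact_letters(differs)
  names(lets) <- groups
  list(pairs = res, letters = lets, excluded = excluded)
}

#' Regression of the beneficial fraction on a mutation-bias axis
#'
#' Ordinary least squares of per-strain f_b (or f_d) on a per-strain bias
#' value, e.g. the transversion bias; also used for f_b against ancestral
#' growth rate.
#'
#' @param bias per-strain predictor values (>= 3 strains).
#' @param f_b per-strain response values.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, and the
#'   underlying `fit` (an lm object).
#' @export
bias_fb_regression <- function(bias, f_b) {
  stopifnot(length(bias) == length(f_b))
  if (length(bias) < 3) stop("need at least 3 strains")
  fit <- stats::lm(f_b ~ bias)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) < 2 || sm$sigma == 0) {
    NA_real_
  } else {
    sm$coefficients["bias", "Pr(>|t|)"]
  }
  list(slope = unname(stats::coef(fit)["bias"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared, p_value = p, fit = fit)
}
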