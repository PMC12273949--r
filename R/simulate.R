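#' Configuration for a synthetic MA experiment
#'
#' Defines the generative model of a mutation-accumulation experiment: each
#' line accrues Poisson(mu x genome size x generations) mutations; mutation
#' types are drawn from a multinomial spectrum; read support and allele
#' frequencies are synthesized so that the default variant filters pass,
#' with an optional fraction of planted filter-failing decoys.
#'
#' `spectrum_probs` gives the probability of each of the six canonical
#' (pyrimidine-normalized) base-substitution types plus the indel class; the
#' seven entries must sum to 1. Strand is randomized, so the complementary
#' representation of each type is emitted half the time. Names:
#' `C>T`, `A>G` (transitions), `C>A`, `C>G`, `A>C`, `A>T` (transversions),
#' `indel`.
#'
#' @param strain_id strain label.
#' @param mu mutation rate per bp per generation.
#' @param genome_size genome length in bp.
#' @param n_lines number of MA lines.
#' @param generations_per_line generations each line evolves (default 27,
#'   one daily colony bottleneck).
#' @param spectrum_probs named numeric vector over the 7 classes (see
#'   Details); default is a mild transition bias.
#' @param p_coding probability a BPS lands in coding sequence (default 0.88,
#'   roughly the coding density of a bacterial genome).
#' @param p_syn_given_coding probability a coding BPS is synonymous
#'   (default 0.25).
#' @param background_mutations data.frame of mutations planted in the
#'   ancestor (columns `position`, `ref`, `alt`), present in the ancestor
#'   table and all offspring lines; NULL for none.
#' @param decoy_fraction expected decoy mutations per line, as a fraction of
#'   the Poisson mean, synthesized to fail the default filters (default 0).
#' @param seed RNG seed for [simulate_ma()].
#' @return object of class `ma_sim_config`.
#' @export
ma_sim_config <- function(strain_id = "sim",
                          mu = 5e-10,
                          genome_size = 4.6e6,
                          n_lines = 100,
                          generations_per_line = 27,
                          spectrum_probs = c("C>T" = 0.35, "A>G" = 0.19,
                                             "C>A" = 0.14, "C>G" = 0.08,
                                             "A>C" = 0.12, "A>T" = 0.07,
                                             "indel" = 0.05),
                          p_coding = 0.88,
                          p_syn_given_coding = 0.25,
                          background_mutations = NULL,
                          decoy_fraction = 0,
                          seed = 1) {
  need <- c("C>T", "A>G", "C>A", "C>G", "A>C", "A>T", "indel")
  if (!all(need %in% names(spectrum_probs))) {
    stop("spectrum_probs must name all of: ", paste(need, collapse = ", "))
  }
  spectrum_probs <- spectrum_probs[need]
  if (any(spectrum_probs < 0) || abs(sum(spectrum_probs) - 1) > 1e-8) {
    stop("spectrum_probs must be non-negative and sum to 1")
  }
  stopifnot(mu >= 0, genome_size >= 1, n_lines >= 1,
            generations_per_line >= 1,
            p_coding >= 0, p_coding <= 1,
            p_syn_given_coding >= 0, p_syn_given_coding <= 1,
            decoy_fraction >= 0)
  structure(list(strain_id = strain_id, mu = mu, genome_size = genome_size,
                 n_lines = as.integer(n_lines),
                 generations_per_line = generations_per_line,
                 spectrum_probs = spectrum_probs, p_coding = p_coding,
                 p_syn_given_coding = p_syn_given_coding,
                 background_mutations = background_mutations,
                 decoy_fraction = decoy_fraction, seed = as.integer(seed)),
            class = "ma_sim_config")
}

# the six canonical substitution types with their strand representations
canonical_types <- list(
  "C>T" = list(c("C", "T"), c("G", "A")),
  "A>G" = list(c("A", "G"), c("T", "C")),
  "C>A" = list(c("C", "A"), c("G", "T")),
  "C>G" = list(c("C", "G"), c("G", "C")),
  "A>C" = list(c("A", "C"), c("T", "G")),
  "A>T" = list(c("A", "T"), c("T", "A"))
)

#' Simulate a mutation-accumulation experiment
#'
#' Draws per-line mutation counts from Poisson(mu x genome size x
#' generations), mutation types from the configured multinomial spectrum,
#' and positions uniformly without collision within each line. Read support
#' (>= 4 reads on each strand) and allele frequencies (> 0.8) are
#' synthesized so every true mutation passes the default filters; decoy
#' mutations, when requested, are synthesized to fail exactly one filter
#' each. Background mutations are present in the ancestor table and every
#' offspring line. A truth ledger records every draw so downstream
#' estimates can be scored without re-simulation.
#'
#' @param config an [ma_sim_config()].
#' @return list with `mutations` (data.frame in the standard mutation-table
#'   layout: strain, block, line, position, ref, alt, class, freq,
#'   reads_plus, reads_minus, region, coding_effect, gene), `ancestor`
#'   (ancestor variant table), and `truth` (list: per-line counts, class
#'   draws, spectrum probabilities, decoy count, the config and seed).
#' @export
simulate_ma <- function(config = ma_sim_config()) {
  stopifnot(inherits(config, "ma_sim_config"))
  old <- rng_stream(config$seed, "simulate_ma")
  on.exit(restore_rng(old))
  lambda <- config$mu * config$genome_size * config$generations_per_line
  n_mut <- stats::rpois(config$n_lines, lambda)
  classes <- names(config$spectrum_probs)

  make_rows <- function(line, k, decoy = FALSE) {
    if (k == 0) return(NULL)
    cls <- sample(classes, k, replace = TRUE,
                  prob = config$spectrum_probs)
    pos <- sample.int(config$genome_size, k)  # without replacement: no collisions
    ref <- alt <- character(k)
    for (i in seq_len(k)) {
      if (cls[i] == "indel") {
        ref[i] <- "A"
        alt[i] <- "AT"
      } else {
        strand <- sample(1:2, 1)
        ra <- canonical_types[[cls[i]]][[strand]]
        ref[i] <- ra[1]
        alt[i] <- ra[2]
      }
    }
    is_bps <- cls != "indel"
    region <- ifelse(is_bps & stats::runif(k) < config$p_coding,
                     "coding", "noncoding")
    region[!is_bps] <- ifelse(stats::runif(sum(!is_bps)) < config$p_coding,
                              "coding", "noncoding")
    effect <- rep("not_applicable", k)
    coding_bps <- is_bps & region == "coding"
    effect[coding_bps] <- ifelse(
      stats::runif(sum(coding_bps)) < config$p_syn_given_coding,
      "synonymous", "nonsynonymous")
    if (!decoy) {
      reads_plus <- 4L + stats::rpois(k, 16)
      reads_minus <- 4L + stats::rpois(k, 16)
      freq <- stats::runif(k, 0.85, 1)
    } else {
      # each decoy fails exactly one filter
      mode <- sample(3, k, replace = TRUE)
      reads_plus <- 4L + stats::rpois(k, 16)
      reads_minus <- 4L + stats::rpois(k, 16)
      freq <- stats::runif(k, 0.85, 1)
      reads_plus[mode == 1] <- sample(0:3, sum(mode == 1), replace = TRUE)
      reads_minus[mode == 2] <- sample(0:3, sum(mode == 2), replace = TRUE)
      freq[mode == 3] <- stats::runif(sum(mode == 3), 0.2, 0.8)
    }
    data.frame(strain = config$strain_id, block = "block1", line = line,
               position = pos, ref = ref, alt = alt,
               class = ifelse(is_bps, "BPS", "insertion"),
               freq = freq, reads_plus = reads_plus,
               reads_minus = reads_minus, region = region,
               coding_effect = effect, gene = NA_character_,
               true_class = cls, decoy = decoy,
               stringsAsFactors = FALSE)
  }

  rows <- lapply(seq_len(config$n_lines), function(i) {
    line <- sprintf("L%03d", i)
    true <- make_rows(line, n_mut[i])
    dec <- if (config$decoy_fraction > 0) {
      make_rows(line, stats::rpois(1, lambda * config$decoy_fraction),
                decoy = TRUE)
    } else NULL
    rbind(true, dec)
  })
  mutations <- do.call(rbind, rows)
  if (is.null(mutations)) {
    mutations <- make_rows("L000", 0)
    mutations <- data.frame(strain = character(0), block = character(0),
                            line = character(0), position = integer(0),
                            ref = character(0), alt = character(0),
                            class = character(0), freq = numeric(0),
                            reads_plus = integer(0), reads_minus = integer(0),
                            region = character(0),
                            coding_effect = character(0),
                            gene = character(0), true_class = character(0),
                            decoy = logical(0), stringsAsFactors = FALSE)
  }

  ancestor <- data.frame(position = integer(0), ref = character(0),
                         alt = character(0), freq = numeric(0),
                         stringsAsFactors = FALSE)
  if (!is.null(config$background_mutations)) {
    bg <- config$background_mutations
    ancestor <- data.frame(position = bg$position, ref = bg$ref,
                           alt = bg$alt, freq = 1.0,
                           stringsAsFactors = FALSE)
    bg_rows <- do.call(rbind, lapply(seq_len(config$n_lines), function(i) {
      data.frame(strain = config$strain_id, block = "block1",
                 line = sprintf("L%03d", i), position = bg$position,
                 ref = bg$ref, alt = bg$alt,
                 class = ifelse(nchar(bg$ref) == 1 & nchar(bg$alt) == 1,
                                "BPS", "insertion"),
                 freq = 1.0, reads_plus = 20L, reads_minus = 20L,
                 region = "noncoding", coding_effect = "not_applicable",
                 gene = NA_character_, true_class = "background",
                 decoy = FALSE, stringsAsFactors = FALSE)
    }))
    mutations <- rbind(mutations, bg_rows)
  }
  rownames(mutations) <- NULL
  truth <- list(per_line_counts = n_mut,
                lambda = lambda,
                class_counts = table(factor(
                  mutations$true_class[!mutations$decoy &
                                       mutations$true_class != "background"],
                  levels = classes)),
                n_decoys = sum(mutations$decoy),
                spectrum_probs = config$spectrum_probs,
                seed = config$seed, config = config)
  list(mutations = mutations, ancestor = ancestor, truth = truth)
}

#' Configuration of the fitness-effect generator
#'
#' Class-conditional mixture of fitness effects: with the given weights a
#' mutation is deleterious (negative gamma draw), beneficial (exponential
#' draw) or exactly neutral. An additive shift for transversions emulates a
#' right-shifted transversion DFE relative to transitions. The parameters
#' are generative choices for testing estimator behavior, not empirical
#' estimates.
#'
#' @param w_del,w_ben,w_neutral mixture weights (must sum to 1).
#' @param del_shape,del_scale gamma shape/scale of the magnitude of
#'   deleterious effects.
#' @param ben_mean mean of the exponential beneficial effects.
#' @param ben_max truncation of the beneficial tail (default 0.15): single
#'   point mutations conferring more than a ~15% growth-rate gain are not
#'   biologically plausible in this setting, and an unbounded tail would
#'   occasionally hand one simulated mutation an astronomical
#'   colony-sampling advantage that no real MA cohort exhibits.
#' @param tv_shift additive offset applied to transversion effects
#'   (default 0).
#' @param noise_sd sd of optional additive measurement noise on s
#'   (default 0; plate-reader noise is modelled separately in
#'   [simulate_plate()]).
#' @return object of class `effect_gen_config`.
#' @export
effect_gen_config <- function(w_del = 0.4, w_ben = 0.15, w_neutral = 0.45,
                              del_shape = 1.5, del_scale = 0.06,
                              ben_mean = 0.05, ben_max = 0.15, tv_shift = 0,
                              noise_sd = 0) {
  if (abs(w_del + w_ben + w_neutral - 1) > 1e-8) {
    stop("mixture weights must sum to 1")
  }
  stopifnot(w_del >= 0, w_ben >= 0, w_neutral >= 0,
            del_shape > 0, del_scale > 0, ben_mean > 0, ben_max > 0,
            noise_sd >= 0, is.finite(tv_shift))
  structure(list(w_del = w_del, w_ben = w_ben, w_neutral = w_neutral,
                 del_shape = del_shape, del_scale = del_scale,
                 ben_mean = ben_mean, ben_max = ben_max,
                 tv_shift = tv_shift, noise_sd = noise_sd),
            class = "effect_gen_config")
}

#' Draw true selection coefficients for simulated mutations
#'
#' Each mutation receives s from the class-conditional mixture of
#' [effect_gen_config()]: deleterious draws are -gamma (truncated at -0.999
#' so s > -1), beneficial draws are exponential, neutral draws are exactly
#' 0; transversions get the configured additive shift.
#'
#' @param classes character vector of mutation classes; entries containing
#'   the transversion types (`C>A`, `C>G`, `A>C`, `A>T`) or equal to
#'   "transversion" receive the shift.
#' @param config an [effect_gen_config()].
#' @param seed RNG seed.
#' @return list with `s` (numeric vector), `component` (del/ben/neutral per
#'   draw), and `true_fractions` (realized fractions of s > 0, s == 0,
#'   s < 0).
#' @export
simulate_effects <- function(classes, config = effect_gen_config(),
                             seed = 1) {
  stopifnot(inherits(config, "effect_gen_config"))
  n <- length(classes)
  old <- rng_stream(seed, "simulate_effects")
  on.exit(restore_rng(old))
  comp <- sample(c("del", "ben", "neutral"), n, replace = TRUE,
                 prob = c(config$w_del, config$w_ben, config$w_neutral))
  s <- numeric(n)
  nd <- sum(comp == "del")
  nb <- sum(comp == "ben")
  s[comp == "del"] <- -pmin(stats::rgamma(nd, shape = config$del_shape,
                                          scale = config$del_scale), 0.999)
  # exponential truncated at ben_max by inverse-CDF sampling
  u <- stats::runif(nb)
  s[comp == "ben"] <- -config$ben_mean *
    log(1 - u * (1 - exp(-config$ben_max / config$ben_mean)))
  tv <- classes %in% c("C>A", "C>G", "A>C", "A>T", "transversion", "Tv")
  s[tv] <- s[tv] + config$tv_shift
  if (config$noise_sd > 0) s <- s + stats::rnorm(n, 0, config$noise_sd)
  s <- pmax(s, -0.999)
  list(s = s, component = comp,
       true_fractions = c(f_b = mean(s > 0), f_n = mean(s == 0),
                          f_d = mean(s < 0)))
}

#' Thin a mutation cohort by colony-sampling bias
#'
#' Forward model of the selection bias the DFE correction removes: each
#' mutation is retained with probability proportional to its relative
#' colony-sampling probability r(s, G) (normalized by the maximum), so the
#' retained cohort is enriched for beneficial mutations. Correcting the
#' retained cohort with weights 1/r(s) recovers the generative class
#' fractions in expectation.
#'
#' @param s true selection coefficients (> -1).
#' @param G colony generations (G = 0 gives uniform retention).
#' @param seed RNG seed.
#' @return list with `retained` (logical vector), `s_retained`, and
#'   `retention_prob`.
#' @export
inject_colony_bias <- function(s, G = 27, seed = 1) {
  if (any(s <= -1)) stop("selection coefficients must be > -1")
  old <- rng_stream(seed, "inject_colony_bias")
  on.exit(restore_rng(old))
  if (G == 0) {
    p <- rep(1, length(s))
  } else {
    r <- colony_sampling_weight(s, G)
    p <- r / max(r)
  }
  keep <- stats::runif(length(s)) < p
  list(retained = keep, s_retained = s[keep], retention_prob = p)
}

#' Plate-reader simulation configuration
#'
#' @param interval_min sampling interval in minutes (default 15).
#' @param duration_h run length in hours (default 16).
#' @param K carrying capacity in OD units (default 1.0).
#' @param od0 initial OD of the inoculum (default 0.04, a 1:100 dilution of
#'   a dense overnight culture).
#' @param lag_h lag time in hours before growth starts (default 1).
#' @param noise_sd additive Gaussian noise on each OD reading (default
#'   2.5e-4, a flash-averaged reader; chosen so that single-clone selection
#'   coefficients are repeatable to well within the neutral zones, +/-0.025
#'   to +/-0.05, that the downstream analysis treats as measurement error).
#' @param baseline media background OD added to every well (default 0.04).
#' @param replicates technical replicates per clone (default 3).
#' @return object of class `plate_sim_config`.
#' @export
plate_sim_config <- function(interval_min = 15, duration_h = 16, K = 1.0,
                             od0 = 0.04, lag_h = 1, noise_sd = 2.5e-4,
                             baseline = 0.04, replicates = 3) {
  stopifnot(interval_min > 0, duration_h * 60 / interval_min >= 10,
            K > od0, od0 > 0, lag_h >= 0, noise_sd >= 0, replicates >= 1)
  structure(list(interval_min = interval_min, duration_h = duration_h,
                 K = K, od0 = od0, lag_h = lag_h, noise_sd = noise_sd,
                 baseline = baseline, replicates = as.integer(replicates)),
            class = "plate_sim_config")
}

# logistic growth trajectory, flat at od0 before the lag
logistic_od <- function(t_h, r, config) {
  if (r <= 0) return(rep(config$od0, length(t_h)))
  tt <- pmax(t_h - config$lag_h, 0)
  config$K / (1 + ((config$K - config$od0) / config$od0) * exp(-r * tt))
}

#' Simulate a plate of growth curves
#'
#' Generates logistic OD600 trajectories with additive Gaussian noise for a
#' set of clones with known true growth rates, plus ancestor, reference and
#' blank wells, in the long plate format consumed by [plate_fitness()].
#'
#' @param clone_rates named numeric vector of true maximum growth rates
#'   (per hour) of the evolved clones.
#' @param ancestor_rate true growth rate of the ancestor.
#' @param config a [plate_sim_config()].
#' @param seed RNG seed.
#' @param environment environment label (default "LB").
#' @param n_blanks,n_reference numbers of blank and reference wells.
#' @param reference_rate true rate of the reference strain (defaults to the
#'   ancestor rate).
#' @return list with `data` (long-format data.frame: plate, well, clone,
#'   role, environment, time_min, od600, replicate) and `truth` (the input
#'   rates and seed).
#' @export
simulate_plate <- function(clone_rates, ancestor_rate,
                           config = plate_sim_config(), seed = 1,
                           environment = "LB", n_blanks = 3,
                           n_reference = 1,
                           reference_rate = ancestor_rate) {
  stopifnot(inherits(config, "plate_sim_config"))
  old <- rng_stream(seed, "simulate_plate")
  on.exit(restore_rng(old))
  t_min <- seq(0, config$duration_h * 60, by = config$interval_min)
  t_h <- t_min / 60
  if (is.null(names(clone_rates))) {
    names(clone_rates) <- sprintf("clone%03d", seq_along(clone_rates))
  }
  wells <- list()
  widx <- 0
  add_well <- function(clone, role, rate, rep_i) {
    widx <<- widx + 1
    od <- if (role == "blank") rep(0, length(t_h)) else
      logistic_od(t_h, rate, config)
    reading <- config$baseline + od +
      stats::rnorm(length(t_h), 0, config$noise_sd)
    data.frame(plate = "simplate", well = sprintf("W%03d", widx),
               clone = clone, role = role, environment = environment,
               time_min = t_min, od600 = reading, replicate = rep_i,
               stringsAsFactors = FALSE)
  }
  for (cl in names(clone_rates)) {
    for (r in seq_len(config$replicates)) {
      wells[[length(wells) + 1]] <- add_well(cl, "evolved",
                                             clone_rates[[cl]], r)
    }
  }
  for (r in seq_len(config$replicates)) {
    wells[[length(wells) + 1]] <- add_well("ancestor", "ancestor",
                                           ancestor_rate, r)
  }
  for (r in seq_len(n_reference)) {
    wells[[length(wells) + 1]] <- add_well("reference", "reference",
                                           reference_rate, r)
  }
  for (r in seq_len(n_blanks)) {
    wells[[length(wells) + 1]] <- add_well("blank", "blank", 0, r)
  }
  data <- do.call(rbind, wells)
  rownames(data) <- NULL
  list(data = data,
       truth = list(clone_rates = clone_rates,
                    ancestor_rate = ancestor_rate,
                    reference_rate = reference_rate,
                    true_s = clone_rates / ancestor_rate - 1,
                    seed = seed, config = config))
}
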