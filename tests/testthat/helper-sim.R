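# Shared fixtures and independent oracles, built in code at test time.

# hand-enumerable variant table: rows 1-2 fail read-support filters, row 3
# fails the frequency filter, rows 4-8 pass, rows 7-8 match the ancestor
toy_variant_table <- function() {
  data.frame(
    position = c(100, 200, 300, 400, 500, 600, 700, 800),
    ref = c("A", "C", "G", "T", "A", "C", "G", "A"),
    alt = c("G", "T", "A", "C", "C", "A", "T", "T"),
    freq = c(0.95, 0.99, 0.80, 0.90, 0.85, 0.92, 0.88, 0.97),
    reads_plus = c(3, 10, 12, 8, 6, 9, 11, 7),
    reads_minus = c(10, 2, 15, 9, 5, 12, 6, 8),
    stringsAsFactors = FALSE
  )
}

toy_ancestor_table <- function() {
  data.frame(position = c(700, 800), ref = c("G", "A"), alt = c("T", "T"),
             freq = c(0.35, 0.99), stringsAsFactors = FALSE)
}

# stochastic pure-birth colony oracle for the relative sampling probability:
# draws the mutation generation t with P(t) proportional to 2^t, grows the
# mutant sub-lineage as a Yule (pure-birth) process for the remaining G - t
# ancestral doublings at rate (1+s) doublings per doubling -- whose size is
# geometric with mean 2^((1+s)(G-t)) and never goes extinct -- and averages
# the final mutant fraction; independent of the closed-form expectation it
# checks
simulate_colony_r <- function(s, G, n_rep = 2e5, seed = 1) {
  set.seed(seed)
  sample_prob <- function(si) {
    t <- sample(0:(G - 1), n_rep, replace = TRUE, prob = 2^(0:(G - 1)))
    m <- stats::rgeom(n_rep, 2^(-(1 + si) * (G - t))) + 1
    nonmutant <- 2^G - 2^(G - t)
    mean(m / (m + nonmutant))
  }
  sample_prob(s) / sample_prob(0)
}

# Monte-Carlo average over random arising times with deterministic
# sub-lineage growth: an independent numerical route to the same
# expectation the closed form implements
simulate_colony_r_det <- function(s, G, n_rep = 2e5, seed = 1) {
  set.seed(seed)
  avg_f <- function(si) {
    t <- sample(0:(G - 1), n_rep, replace = TRUE, prob = 2^(0:(G - 1)))
    num <- 2^((1 + si) * (G - t))
    mean(num / (2^G - 2^(G - t) + num))
  }
  avg_f(s) / avg_f(0)
}

# one end-to-end synthetic strain: MA mutations -> class-conditional effects
# -> colony-bias thinning -> plate measurement -> corrected DFE
run_sim_strain <- function(bias = c("tv", "ts"), seed, n_lines = 100,
                           tv_shift = 0.05, neutral_half_width = 0.05) {
  bias <- match.arg(bias)
  probs <- if (bias == "tv") {
    c("C>T" = 0.01, "A>G" = 0.01, "C>A" = 0.49, "C>G" = 0,
      "A>C" = 0.49, "A>T" = 0, "indel" = 0)
  } else {
    c("C>T" = 0.49, "A>G" = 0.49, "C>A" = 0.005, "C>G" = 0.005,
      "A>C" = 0.005, "A>T" = 0.005, "indel" = 0)
  }
  sim <- simulate_ma(ma_sim_config(strain_id = bias, mu = 1 / (4.6e6 * 27),
                                   n_lines = n_lines,
                                   spectrum_probs = probs, seed = seed))
  eff <- simulate_effects(sim$mutations$true_class,
                          effect_gen_config(tv_shift = tv_shift),
                          seed = seed + 1)
  inj <- inject_colony_bias(eff$s, G = 27, seed = seed + 2)
  pl <- simulate_plate(pmax(1 + inj$s_retained, 0.02), 1.0,
                       plate_sim_config(), seed = seed + 3)
  fr <- plate_fitness(pl$data)
  build_dfe(fr$s, dfe_config(neutral_half_width = neutral_half_width),
            strain_id = bias)
}
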