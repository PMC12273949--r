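test_that("colony_sampling_weight is 1 at neutrality and strictly increasing", {
  for (G in c(1, 12, 27, 40)) {
    expect_equal(colony_sampling_weight(0, G), 1, tolerance = 1e-12)
  }
  s_grid <- seq(-0.5, 0.5, by = 0.05)
  r <- colony_sampling_weight(s_grid, 27)
  expect_true(all(diff(r) > 0))
  expect_true(all(r[s_grid > 0] > 1))
  expect_true(all(r[s_grid < 0] < 1))
  expect_error(colony_sampling_weight(-1, 27), "> -1")
})

test_that("the sampling weight matches independent colony simulations at G = 12", {
  for (s in c(-0.15, 0.1, 0.25)) {
    r_closed <- colony_sampling_weight(s, 12)
    # Monte-Carlo over arising times, deterministic lineage growth: an
    # independent route to the same expectation; the estimate is dominated
    # by rare early-arising mutations, so its relative SE is ~0.5% at 2e6
    # draws and the tolerance covers ~4 SE
    r_mc <- simulate_colony_r_det(s, 12, n_rep = 2e6, seed = 42)
    expect_equal(r_mc, r_closed, tolerance = 0.02)
    # fully stochastic Yule colony: the deterministic expectation tracks
    # it within a few percent (the model's documented approximation gap)
    r_yule <- simulate_colony_r(s, 12, n_rep = 2e5, seed = 42)
    expect_equal(r_yule, r_closed, tolerance = 0.08)
  }
})

test_that("build_dfe handles the all-neutral and uncorrected edge cases exactly", {
  d0 <- build_dfe(rep(0, 25))
  expect_equal(d0$f_n, 1)
  expect_equal(d0$f_b, 0)
  expect_equal(d0$f_d, 0)
  expect_equal(d0$median_s, 0)

  # no correction, no neutral zone: f_b is the empirical fraction of s > 0
  set.seed(8)
  s <- rnorm(200, 0, 0.1)
  d <- build_dfe(s, dfe_config(neutral_half_width = 0,
                               apply_correction = FALSE))
  expect_equal(d$f_b, mean(s > 0))
  expect_equal(d$f_d, mean(s < 0))

  expect_error(build_dfe(numeric(0)), "empty")
  expect_error(build_dfe(c(0.1, NA)), "finite")
  expect_error(build_dfe(-1.5), "-1")
})

test_that("DFE invariants hold over random inputs and correction shrinks f_b", {
  set.seed(19)
  for (i in 1:20) {
    s <- c(rnorm(80, -0.05, 0.1), rexp(20, 20))
    cfg_raw <- dfe_config(apply_correction = FALSE)
    cfg_cor <- dfe_config()
    d_raw <- build_dfe(s, cfg_raw)
    d_cor <- build_dfe(s, cfg_cor)
    expect_equal(d_cor$f_b + d_cor$f_n + d_cor$f_d, 1, tolerance = 1e-9)
    expect_equal(sum(d_cor$corrected_weights), 1, tolerance = 1e-9)
    expect_equal(sum(d_raw$raw_counts), d_raw$n_mutations)
    # identical support: correction changes weights, never s values or bins
    expect_equal(d_cor$bin_edges, d_raw$bin_edges)
    expect_equal(d_cor$s_values, d_raw$s_values)
    expect_equal(d_cor$raw_counts, d_raw$raw_counts)
    # down-weighting beneficial mutations can only reduce f_b
    expect_lte(d_cor$f_b, d_raw$f_b + 1e-12)
  }
})

test_that("lethal records sit in the most deleterious bin without entering r(s)", {
  s <- c(-1, -0.4, -0.1, 0, 0.1)
  d <- build_dfe(s)
  expect_equal(sum(d$corrected_weights), 1, tolerance = 1e-9)
  expect_equal(d$raw_counts[1], 1)  # the lethal occupies the lowest bin
  # its weight equals that of the most deleterious viable mutation
  expect_equal(d$weights[s == -1], d$weights[s == -0.4])
})

test_that("bin-level correction mode renormalizes binned fractions", {
  set.seed(5)
  s <- rnorm(150, 0, 0.08)
  d <- build_dfe(s, dfe_config(per_mutation = FALSE))
  expect_equal(sum(d$corrected_weights), 1, tolerance = 1e-9)
  expect_equal(d$f_b + d$f_n + d$f_d, 1, tolerance = 1e-9)
})

test_that("correcting a bias-injected cohort recovers the generative fractions", {
  eff <- simulate_effects(rep("C>T", 400), effect_gen_config(), seed = 77)
  inj <- inject_colony_bias(eff$s, G = 27, seed = 78)
  raw <- build_dfe(inj$s_retained,
                   dfe_config(neutral_half_width = 0,
                              apply_correction = FALSE))
  cor <- build_dfe(inj$s_retained, dfe_config(neutral_half_width = 0))
  fb_true <- eff$true_fractions[["f_b"]]
  # the enriched cohort overshoots; the corrected estimate lands closer
  expect_gte(raw$f_b, fb_true)
  expect_lt(abs(cor$f_b - fb_true), abs(raw$f_b - fb_true) + 1e-12)
})

test_that("compare_dfe_fractions matches the closed-form chi-squared", {
  cfg <- dfe_config(neutral_half_width = 0.05, apply_correction = FALSE)
  mk <- function(nb, nn, nd, id) {
    build_dfe(c(runif(nb, 0.06, 0.3), runif(nn, -0.04, 0.04),
                runif(nd, -0.5, -0.06)), cfg, strain_id = id)
  }
  set.seed(2)
  a <- mk(50, 25, 25, "a")
  b <- mk(10, 45, 45, "b")
  cmp <- compare_dfe_fractions(a, b)
  # independent closed form from the 2x3 table
  tab <- rbind(c(50, 25, 25), c(10, 45, 45))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  expect_equal(cmp$chisq_stat, stat, tolerance = 1e-9)
  expect_equal(cmp$p_raw, pchisq(stat, 2, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_lt(cmp$p_raw, 0.001)

  same <- compare_dfe_fractions(a, a)
  expect_equal(same$chisq_stat, 0)
  expect_equal(same$p_raw, 1)

  tiny <- mk(1, 1, 0, "tiny")
  expect_warning(cmp2 <- compare_dfe_fractions(tiny, mk(0, 2, 0, "t2")),
                 "exact")
  expect_true(cmp2$exact_fallback)
})

test_that("batch DFE comparison applies BH across the declared family", {
  cfg <- dfe_config(apply_correction = FALSE)
  set.seed(14)
  dfes <- lapply(1:4, function(i) {
    build_dfe(rnorm(60, -0.02 * i, 0.08), cfg, strain_id = paste0("s", i))
  })
  out <- compare_dfe_batch(dfes)
  expect_equal(nrow(out), 6)
  expect_equal(out$p_adjusted, p.adjust(out$p_raw, method = "BH"))
  expect_true(all(out$p_adjusted >= out$p_raw))
})

test_that("subsample_dfe is deterministic, degenerate at full n, and tightens with n", {
  set.seed(23)
  s <- c(rnorm(150, -0.03, 0.08), rexp(50, 15))
  full <- build_dfe(s)$f_b

  a <- subsample_dfe(s, 200, seed = 6)
  expect_equal(a$ci[1], full)
  expect_equal(a$ci[2], full)
  expect_equal(a$f_b, rep(full, 100))

  b1 <- subsample_dfe(s, 40, seed = 6)
  b2 <- subsample_dfe(s, 40, seed = 6)
  expect_identical(b1, b2)

  wide <- diff(subsample_dfe(s, 30, seed = 6)$ci)
  narrow <- diff(subsample_dfe(s, 150, seed = 6)$ci)
  expect_lt(narrow, wide)
  expect_error(subsample_dfe(s, 500, seed = 1), "exceeds")
})

test_that("class_fitness_tests separates shifted classes and letters groups", {
  # identical samples are indistinguishable
  x <- c(0.01, -0.02, 0.03, 0, -0.01)
  same <- class_fitness_tests(c(x, x), rep(c("A", "B"), each = 5))
  expect_equal(same$pairs$p_raw, 1, tolerance = 1e-9)
  expect_equal(unname(same$letters), c("a", "a"))

  # power: Ts ~ N(-0.05, 0.02) vs Tv ~ N(+0.02, 0.02), n = 100
  set.seed(55)
  rejections <- sum(replicate(100, {
    out <- class_fitness_tests(c(rnorm(100, -0.05, 0.02),
                                 rnorm(100, 0.02, 0.02)),
                               rep(c("Ts", "Tv"), each = 100))
    out$pairs$p_adjusted < 0.001
  }))
  expect_gte(rejections, 99)

  # three groups with A ~ B, A != C, B != C get letters {a, a, b}:
  # C (highest median, lettered first) stands alone
  set.seed(9)
  vals <- c(rnorm(30, 0, 0.01), rnorm(30, 0.001, 0.01), rnorm(30, 1, 0.01))
  lt <- class_fitness_tests(vals, rep(c("A", "B", "C"), each = 30))$letters
  expect_equal(unname(lt[["C"]]), "a")
  expect_equal(unname(lt[c("A", "B")]), c("b", "b"))

  # a group with a single observation is dropped with a warning
  expect_warning(
    out <- class_fitness_tests(c(1, 2, 3, 9, 10, 11, 99),
                               c("A", "A", "A", "B", "B", "B", "C")),
    "excluding")
  expect_equal(out$excluded, "C")
  expect_equal(sort(names(out$letters)), c("A", "B"))
})

test_that("bias_fb_regression gives exact fits and calibrated null p-values", {
  # perfectly collinear points (lm warns about the perfect fit)
  r <- suppressWarnings(
    bias_fb_regression(c(0.1, 0.3, 0.5, 0.9),
                       0.05 + 0.2 * c(0.1, 0.3, 0.5, 0.9)))
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_equal(r$slope, 0.2, tolerance = 1e-9)

  # under a zero-slope null the p-value is approximately uniform
  set.seed(41)
  ps <- replicate(200, bias_fb_regression(runif(7), runif(7))$p_value)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # a planted positive relation is recovered
  set.seed(12)
  bias <- runif(7)
  fb <- 0.05 + 0.3 * bias + rnorm(7, 0, 0.02)
  expect_gt(bias_fb_regression(bias, fb)$slope, 0)

  expect_error(bias_fb_regression(c(1, 2), c(1, 2)), "at least 3")
})
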