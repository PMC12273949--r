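test_that("apply_filters enforces strand support, frequency and ancestor subtraction", {
  v <- toy_variant_table()
  anc <- toy_ancestor_table()

  # strand-support failures (3 reads on one strand) and the exact 0.80
  # frequency boundary are removed; ancestor matches drop regardless of the
  # ancestor's own frequency
  out <- apply_filters(v, anc)
  expect_equal(out$position, c(400, 500, 600))

  # without ancestor subtraction five rows pass
  expect_equal(nrow(apply_filters(v)), 5)

  # idempotent and order-independent
  expect_equal(apply_filters(out, anc), out)
  shuffled <- v[c(5, 1, 8, 3, 7, 2, 6, 4), ]
  out2 <- apply_filters(shuffled, anc)
  expect_equal(sort(out2$position), sort(out$position))

  # a variant supported by 3 reads on one strand is removed even at high freq
  one <- data.frame(position = 1, ref = "A", alt = "G", freq = 0.95,
                    reads_plus = 3, reads_minus = 10)
  expect_equal(nrow(apply_filters(one)), 0)
})

test_that("apply_filters validates its input", {
  v <- toy_variant_table()
  expect_error(apply_filters(v[, setdiff(names(v), "reads_plus")]),
               "required column")
  v$reads_minus[2] <- -1
  expect_error(apply_filters(v), "negative")
  v2 <- toy_variant_table()
  v2$freq[1] <- 1.2
  expect_error(apply_filters(v2), "frequencies")
})

test_that("require_both_strands acts independently of the read-count floor", {
  v <- data.frame(position = 1:2, ref = "A", alt = "G", freq = 0.95,
                  reads_plus = c(9, 5), reads_minus = c(0, 5))
  cfg <- variant_filter_config(min_reads_per_strand = 0)
  expect_equal(apply_filters(v, config = cfg)$position, 2)
  cfg2 <- variant_filter_config(min_reads_per_strand = 0,
                                require_both_strands = FALSE)
  expect_equal(nrow(apply_filters(v, config = cfg2)), 2)
})

test_that("classify_bps follows the transition/transversion and GC definitions", {
  expect_equal(classify_bps("A", "G"),
               data.frame(ts_tv = "transition", gc_direction = "AT->GC"))
  expect_equal(classify_bps("G", "T"),
               data.frame(ts_tv = "transversion", gc_direction = "GC->AT"))
  expect_equal(classify_bps("A", "T"),
               data.frame(ts_tv = "transversion", gc_direction = "no_change"))
  expect_equal(classify_bps("G", "C")$gc_direction, "no_change")

  # strand symmetry: every substitution classifies like its complement
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- names(comp)
  for (r in bases) for (a in setdiff(bases, r)) {
    expect_equal(classify_bps(r, a), classify_bps(comp[[r]], comp[[a]]),
                 info = paste(r, a))
  }

  expect_error(classify_bps("N", "A"), "unambiguous")
  expect_error(classify_bps("A", "A"), "differ")
})

test_that("compute_bias reproduces published bias values and their CIs", {
  wt <- compute_bias(178, 206, 97)
  expect_equal(round(wt$value, 2), 0.46)
  expect_equal(round(wt$ci_half_width, 3), 0.099)

  # complementarity: a/(a+b) + b/(a+b) = 1
  set.seed(4)
  for (i in 1:25) {
    a <- sample(0:500, 1); b <- sample(0:500, 1)
    if (a + b == 0) next
    n <- sample(1:400, 1)
    expect_equal(compute_bias(a, b, n)$value + compute_bias(b, a, n)$value, 1)
  }

  z <- compute_bias(0, 7, 50)
  expect_equal(z$value, 0)
  expect_equal(z$ci_half_width, 0)
  expect_true(compute_bias(0, 0, 10)$undefined)
  expect_error(compute_bias(1, 1, 0), "n_lines")
})

test_that("mutation_rate implements the per-line-generation formula and t CI", {
  r <- mutation_rate(789, 4.6e6, rep(27, 271))
  expect_equal(signif(r$mu, 2), 2.3e-8)
  expect_true(is.na(r$mu_ci_half_width))

  r2 <- mutation_rate(908, 4.6e6, 27, n_lines = 346)
  expect_equal(signif(r2$mu, 2), 2.1e-8)

  expect_equal(mutation_rate(0, 4.6e6, rep(27, 10))$mu, 0)

  # CI equals the hand-written t margin over per-line rates
  counts <- c(2, 0, 1, 3, 1, 0, 2, 1)
  gens <- rep(27, 8)
  r3 <- mutation_rate(sum(counts), 1e6, gens, per_line_counts = counts)
  rates <- counts / (1e6 * gens)
  expect_equal(r3$mu_ci_half_width, qt(0.975, 7) * sd(rates) / sqrt(8))

  expect_error(mutation_rate(5, 1e6, numeric(0)), "non-empty")
  expect_error(mutation_rate(5, 0, rep(27, 3)), "positive")
  expect_error(mutation_rate(5, 1e6, c(0, 0)), "positive")
})

test_that("tally_spectrum partitions counts and matches generator bookkeeping", {
  sim <- simulate_ma(ma_sim_config(strain_id = "tally", mu = 8e-9,
                                   n_lines = 120, seed = 21))
  sp <- tally_spectrum(sim$mutations, n_lines = 120,
                       total_generations = 120 * 27)
  ct <- sp$counts
  expect_equal(ct[["transitions"]] + ct[["transversions"]], ct[["BPS"]])
  expect_equal(ct[["coding"]] + ct[["noncoding"]], ct[["BPS"]])
  expect_equal(ct[["synonymous"]] + ct[["nonsynonymous"]], ct[["coding"]])
  expect_equal(ct[["AT->GC"]] + ct[["GC->AT"]] + ct[["no_change"]],
               ct[["BPS"]])
  expect_equal(ct[["BPS"]] + ct[["indels"]], nrow(sim$mutations))

  # class counts equal the truth ledger's multinomial draws
  truth <- sim$truth$class_counts
  expect_equal(ct[["indels"]], unname(truth[["indel"]]))
  expect_equal(ct[["transitions"]],
               unname(truth[["C>T"]] + truth[["A>G"]]))
  expect_equal(ct[["transversions"]],
               unname(sum(truth[c("C>A", "C>G", "A>C", "A>T")])))

  # mu consistent with the direct formula
  expect_equal(sp$mu, nrow(sim$mutations) / (4.6e6 * 120 * 27))

  empty <- sim$mutations[0, ]
  sp0 <- tally_spectrum(empty, n_lines = 10, total_generations = 270)
  expect_true(all(sp0$counts == 0))
  expect_equal(sp0$mu, 0)

  mixed <- sim$mutations
  mixed$strain[1] <- "other"
  expect_error(tally_spectrum(mixed, 120, 120 * 27), "single strain")
})

test_that("poisson_gof pools the tail, detects underdispersion, and validates", {
  set.seed(11)
  g <- poisson_gof(rpois(300, 2))
  expect_true(all(g$expected >= 5))
  expect_equal(sum(g$observed), 300)
  expect_equal(sum(g$expected), 300, tolerance = 1e-9)
  expect_equal(g$dof, length(g$observed) - 2)

  # constant counts have variance 0, grossly non-Poisson
  expect_lt(poisson_gof(rep(8, 120))$p_value, 1e-6)

  expect_error(poisson_gof(c(3)), "at least 2")
  expect_error(poisson_gof(c(0, 0, 0)), "degenerate")
})

test_that("recall_check scores planted background mutations per line", {
  expected <- data.frame(position = c(2845011, 4296380),
                         ref = c("G", "A"), alt = c("A", "AT"))
  make_line <- function(with_first) {
    pos <- c(if (with_first) 2845011, 4296380, 12345)
    data.frame(position = pos,
               ref = c(if (with_first) "G", "A", "C"),
               alt = c(if (with_first) "A", "AT", "T"),
               freq = c(if (with_first) 0.99, 0.95, 0.9))
  }
  lists <- lapply(1:10, function(i) make_line(i <= 9))
  names(lists) <- paste0("L", 1:10)
  rc <- recall_check(lists, expected)
  expect_equal(rc$recall, c(0.9, 1.0))
  expect_equal(nrow(rc$per_line), 20)
  expect_equal(sum(rc$per_line$found), 19)

  absent <- data.frame(position = 99, ref = "A", alt = "C")
  expect_equal(recall_check(lists, absent)$recall, 0)
})

test_that("gene_gc_table recovers planted per-gene GC fractions", {
  skip_if_not_installed("Biostrings")
  skip_if_not_installed("rtracklayer")
  # ten 40-bp genes with GC fractions 0, 1/9, ..., 1 on one contig
  fracs <- seq(0, 1, length.out = 10)
  genes <- vapply(fracs, function(f) {
    n_gc <- round(40 * f)
    paste(c(rep("G", n_gc), rep("A", 40 - n_gc)), collapse = "")
  }, character(1))
  genome <- paste(genes, collapse = "")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 synthetic", genome), fa)
  gff <- tempfile(fileext = ".gff3")
  starts <- seq(1, by = 40, length.out = 10)
  writeLines(c("##gff-version 3",
               sprintf("chr1\tsim\tgene\t%d\t%d\t.\t+\t.\tID=g%02d",
                       starts, starts + 39, 1:10)), gff)
  tab <- gene_gc_table(fa, gff)
  expect_equal(tab$gene_id, sprintf("g%02d", 1:10))
  expect_equal(tab$gc_fraction, round(40 * fracs) / 40)
  expect_equal(tab$gc_class, rep(c("low", "high"), each = 5))

  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsim\tgene\t390\t450\t.\t+\t.\tID=over"), bad)
  expect_error(gene_gc_table(fa, bad), "bounds")
})
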