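---
title: "Mutation-accumulation spectra and bias-corrected DFEs with madfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation-accumulation spectra and bias-corrected DFEs with madfe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(madfe)
```

## The analysis this package implements

A mutation-accumulation (MA) experiment propagates many replicate lines of a
microbe through daily single-colony bottlenecks. The bottleneck of one cell
per day makes selection almost powerless, so mutations accumulate nearly at
the rate and in the proportions at which they arise. Sequencing the evolved
lines and measuring the growth of single-mutation clones then gives two
things: the *mutation spectrum* of the strain (how often each class of
mutation arises) and the *distribution of fitness effects* (DFE) of new
mutations. madfe covers the full path from filtered variant calls and
plate-reader OD600 series to spectra, rates, bias-corrected DFEs, and the
genome-wide beneficial supply and deleterious load, plus a synthetic
MA-experiment generator so every step can be validated end to end against
known truth.

The scientific question the pipeline serves: *E. coli* is transition-biased
(~54% of its single-nucleotide mutations are transitions). Deleting DNA
repair genes produces strains whose bias ranges from 97% transitions to 98%
transversions. Because a historically well-sampled mutational class is
depleted of beneficial mutations, strains that reverse the ancestral bias
are expected to show right-shifted DFEs with more beneficial mutations —
and they do, which is what the acceptance checks of this package probe with
synthetic cohorts.

## Variant filtering

`apply_filters()` keeps a called variant only if it is (i) represented on
both strands, (ii) supported by at least 4 reads per strand, and (iii) at
allele frequency strictly above 80%; variants matching an ancestor call
(same position, ref, alt — exact matching, no fuzzy indel matching) are then
subtracted. Two conventions worth making explicit:

* the 80% boundary is read strictly: a variant at exactly 0.80 is removed;
* ancestor variants match at *any* frequency — ancestral mutations can
  segregate below 80% in the deeply sequenced ancestor stock and must still
  be subtracted from offspring.

Coordinates are 1-based and fully closed, following the VCF convention of
upstream callers. The filter is idempotent and order-independent, which the
test suite checks by property.

## Spectra, biases and rates

A mutation-class bias is the proportion `a / (a + b)` between two classes:
transversion bias Tv/(Ts+Tv), indel bias indel/(indel+BPS), and so on.
Classification of base-pair substitutions is strand-symmetric (`G>A` and its
complement `C>T` are the same event), so every BPS folds into six canonical
types; `A<->T` and `G<->C` changes leave GC content unchanged and form their
own "no change" class in the GC-direction partition.

The 95% CI convention for a bias is the normal-approximation binomial form

    1.96 * sqrt(p (1 - p) / n_lines)

with *n* the number of successfully sequenced MA lines, not the number of
mutations. The source data we validate against print only "1.96 times the
standard deviation of calculated bias"; this binomial form with n = lines
was reverse-engineered and reproduces all seven published transversion-bias
CIs to 3 decimal places, which the acceptance tests re-verify.

The mutation rate is

    mu = total mutations / (genome size x total line-generations)

with line-generations summed over lines (days x ~27 generations per day on
LB agar; per-block overrides are supported because real blocks differ in
length). Its CI is the t-distribution margin of error over per-line rates
and therefore *requires per-line counts*: when only a strain total is
available the CI is reported as `NA` rather than approximated.

`poisson_gof()` checks the per-line counts against a Poisson law, the
diagnostic that accumulation was uniform across lines. Categories 0, 1, 2,
... pool the right tail until every expected count is at least 5 (the
standard chi-squared validity rule; the source analysis does not state its
pooling), with dof = categories − 2. Blocks with different generation counts
must be tested separately, since their means differ by construction.

## Growth rates and selection coefficients

The maximum growth rate is the steepest slope of log OD600 versus time over
any contiguous window of 5 readings (1 h at 15-min sampling) whose linear
fit has R² ≥ 0.99, after subtracting the per-plate mean blank and clipping
readings to a detection floor of 0.01. The window length, floor, R²
threshold and blank policy are all configurable (`growth_fit_config()`);
the defaults mirror common practice for 15-min plate-reader series. The
estimate is invariant to uniform OD scaling, exact on a noiseless
exponential, and recovers a logistic intrinsic rate within 5% from a dilute
start — the early-phase logistic bias (the instantaneous rate is r(1−OD/K))
is documented rather than corrected, because it largely cancels in the
fitness *ratio* below.

Relative fitness is the mean rate of three technical replicates divided by
the matched same-plate ancestor rate, and the selection coefficient is

    s = relative fitness − 1.

Replicate aggregation is a plain arithmetic mean with no outlier rejection.
`plate_qc()` flags rising blanks (contamination), reports the
reference-strain rate against cross-plate statistics, and lists evolved
clones lacking a matched ancestor.

## The colony-sampling bias and its correction

Each MA bottleneck picks one colony cell. A beneficial mutation that arises
during colony growth overrepresents itself among the colony's cells, so the
recovered mutations are slightly enriched for beneficial effects. The
default model is a deterministic colony-growth expectation: a mutation
arises at division generation t (t = 0..G−1) with probability proportional
to the number of divisions at t (2^t); its sub-lineage then grows at (1+s)
doublings per ancestral doubling, giving the final mutant fraction

    f(s, t) = 2^((1+s)(G−t)) / (2^G − 2^(G−t) + 2^((1+s)(G−t)))

and the relative sampling probability r(s) = E_t[f(s,t)] / E_t[f(0,t)],
with G = 27 generations per daily colony. r(0) = 1 and r is strictly
increasing, so weighting each recovered mutation by 1/r(s) down-weights
beneficial and up-weights deleterious mutations. Two properties the tests
pin down: a Monte-Carlo evaluation of the same expectation agrees with the
closed form to its sampling error, and a *fully stochastic* pure-birth
(Yule) colony agrees with the deterministic expectation only to within a
few percent — the model is an expectation approximation, and r(s) is
therefore pluggable (`weight_fun` in `dfe_config()`) so a reference weight
table can be swapped in.

`build_dfe()` applies the correction per mutation before binning: weights
1/r(s_i), renormalized. An alternative bin-level mode (reweighting binned
fractions at bin midpoints) is available behind `per_mutation = FALSE`,
because the verbal description "binning ... then down-weighting" is
ambiguous between the two; per-mutation weighting is the default as the
better-defined operation. The correction changes weights only — never the
measured s values or the bin support.

Bins are aligned on multiples of the bin width, and the neutral zone
[−w, +w] must be a whole number of bins; by default the bin width *equals*
the neutral half-width, so the neutral zone is exactly the two central
bins. The neutral half-widths are an environment property reflecting
measurement error: ±0.05 in rich medium (LB), ±0.025 in minimal glucose.
f_b, f_n and f_d are the corrected weight above, inside and below the
neutral zone; the median s is the weighted median of the corrected
distribution. Lethal records (s = −1, no growth) are placed in the most
deleterious bin and inherit the correction weight of the most deleterious
viable mutation instead of entering r(s), which is undefined at −1.

DFE class fractions are compared between strains by converting fractions
back to effective counts (n × fraction, rounded half away from zero, then
repairing the largest remainder so counts sum to n) and running a 3×2
chi-squared test, with Benjamini–Hochberg adjustment across all pairs in
the declared family and a Fisher-exact fallback (flagged) when an expected
cell drops below 1. Class-wise fitness contrasts use pairwise Wilcoxon
rank-sum tests with BH adjustment and a compact-letter display assigned in
order of decreasing group median.

## Beneficial supply and deleterious load

    S_b = f_b x mu x genome size        L_d = f_d x mu x genome size

with genome size 4,641,652 bp for *E. coli* K-12. (Rate arithmetic against
the published per-strain tables uses the rounder 4.6e6 those calculations
were printed with.) CIs propagate the binomial sd of the fraction at the
DFE's sample size, treating mu as fixed — the source convention is
unstated, so this propagation is documented as the package's choice.
Counterfactual columns computed with the wild-type DFE isolate the effect
of the mutation rate alone, and satisfy
`rel_S_b / rel_S_b_wt_dfe = f_b(strain) / f_b(WT)` exactly.

## What the synthetic generator emulates — and what it does not

`simulate_ma()` draws per-line mutation counts Poisson(mu × genome ×
generations), classes from a multinomial over the six canonical BPS types
plus indels, and positions uniformly without collision; read support and
frequencies are synthesized so true mutations pass the default filters,
with optional decoys each failing exactly one filter. Mutational hotspots,
sequence context, selection during MA (other than the colony-sampling bias
injected separately) and read-level artifacts are deliberately *not*
modelled — passing tests say the estimators are correct under the stated
generative assumptions, not that real data meet them.

`simulate_effects()` draws s from a class-conditional mixture: point mass
at 0 (neutral), negative gamma (deleterious), exponential truncated at
+0.15 (beneficial), with an additive shift for transversions emulating the
right-shifted transversion DFE. The truncation is a realism constraint:
single point mutations conferring >15% growth-rate gains do not occur in
these assays, and an unbounded tail would hand a single simulated mutation
an astronomical colony-sampling advantage no real cohort exhibits. Default
weights give class fractions of the magnitude seen in real MA DFEs (f_b
roughly 0.05–0.4). These are generative choices, not empirical estimates.

`simulate_plate()` produces logistic trajectories OD(t) = K / (1 +
((K−OD0)/OD0) e^{−r(t−lag)}) with baseline 0.04, inoculum OD0 = 0.04 (a
1:100 dilution of a dense overnight culture), 1 h lag, 15-min sampling for
16 h, and additive Gaussian reading noise of sd 2.5e-4, a flash-averaged
reader. The noise default was chosen so that single-clone selection
coefficients are repeatable to a few thousandths — well inside the
±0.025/±0.05 neutral zones the analysis treats as measurement error, as a
usable assay must be.

`inject_colony_bias()` thins a cohort with retention probability
r(s)/max(r), the forward model of the bias the correction removes;
correcting the thinned cohort with 1/r(s) recovers the generative class
fractions in expectation (the round-trip property at the heart of the test
suite). All generators derive per-operation RNG substreams from a single
seed and are reproducible bit for bit.

## Problem sizes used by the test suite

The suite validates the round-trip property over 100 seeded replicates of
100-mutation cohorts, the Poisson GOF type-I rate over 1,000 null
simulations of 300 lines, the colony-weight oracles at G = 12 with 2×10^5
to 2×10^6 Monte-Carlo draws, and the transversion-versus-transition
headline end to end (mutations → effects → colony bias → plates → DFEs)
over 100 seed pairs of 100-line strains. These sizes give the binomial
envelopes quoted in the tests while keeping the default run in the minutes
range.

## Known limitations

* The colony-sampling model is a deterministic expectation; fully
  stochastic colony growth deviates by a few percent in r(s), and the
  published corrected DFEs it approximates cannot be reproduced exactly
  without per-clone fitness supplements.
* The growth fitter's max-window estimator is an order statistic and
  inherits upward noise sensitivity when curves are noisy near the
  detection floor; the defaults assume reasonably clean reader data.
* Published per-strain mutation rates for blocks of unequal length (the
  wild type and the mutY knockout in the shipped count table) are not
  reproducible from per-line generation totals alone and are excluded from
  rate checks; their `generations_per_line` is `NA`.
* Parametric DFE fitting (gamma/displaced-gamma likelihoods), epistasis and
  multi-step trajectories are out of scope.
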