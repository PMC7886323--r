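---
title: "Models and methods: multilevel selection and nontransitive fitness in killer yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: multilevel selection and nontransitive fitness in killer yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the parameters that matter, and the choices made
where the design was genuinely open. Everything quantitative stated here is
computed by the test suite or by `scripts/acceptance.R`; nothing is asserted
beyond what that code checks.

## The system

Budding yeast can carry the M1 cytoplasmic satellite virus, which encodes
the K1 preprotoxin. Cells carrying functional virus secrete a toxin that
kills susceptible neighbours; the unprocessed preprotoxin confers immunity
on the carrier, so immunity can survive mutations that abolish the secreted
toxin. A cell contains on the order of 10^2 viral genomes, so there are two
nested arenas of selection: among host cells (nuclear fitness differences
plus toxin-mediated killing) and among viral variants within each cell
(replication competition for the per-cell copy quota). The package
simulates both arenas under a daily serial-transfer protocol and implements
the statistics used to analyse the resulting data.

## Serial-transfer demography

`serial_transfer_protocol()` encodes a daily 1:D dilution with regrowth to
saturation. The default D = 2^10 implies exactly `log2(D)` = 10 doublings
(generations) per transfer; the post-dilution bottleneck is Nb = 1e5 cells.
D must be an exact power of two so that "generations per transfer" is an
integer — a deliberate validity constraint, not a numerical convenience.

## Fitness convention

All selection coefficients are Malthusian (log-scale) per-generation rates:
a genotype with coefficient `s` multiplies its count by `2 exp(s)` per
generation. With this convention the log count ratio of two competitors
changes by exactly `s_a - s_b` per generation, so the log-ratio-slope
estimator is unbiased and exact on noise-free data — a competition with a
0.05 gap moves `ln(N_a/N_b)` by exactly 0.5 per 10 generations. The
alternative convention (multiplicative `1 + s`) would make the slope
`ln((1+s_a)/(1+s_b))`, blurring the correspondence between the simulated
truth and the estimator; for the coefficients used here (|s| <= 0.05) the
two differ by under 3%.

## Toxin kinetics

Killing is well-mixed and memoryless: each generation a susceptible
(non-immune) cell dies with probability `kappa * f_killer`, where
`f_killer` is the current frequency of toxin-producing cells and `kappa`
(per generation, per unit killer frequency) is the kill coefficient. With
`saturating = TRUE` the probability is capped at 1; otherwise exceeding 1
is an error. No toxin accumulation or spatial structure is modelled — this
is the simplest kinetics that produces positive frequency dependence, which
is the phenomenon of interest. `kappa` is a free parameter of the model,
not a measured quantity; the default 0.2 is chosen so that killing
dominates nuclear advantages of a few percent when killers are common
(`kappa * 0.9 > 0.05`) but not when they are rare, which places the
bistable threshold in the interior of (0, 1).

Under this model the deterministic per-generation fitness of a sensitive
clone at frequency `f` against a killer is `s + ln(1 - kappa (1 - f))`, an
increasing function of `f` with a single root — the unstable equilibrium
that `frequency_dependence()` estimates as `f* = -intercept/beta` from a
linear fit. The linear fit is a first-order approximation to a mildly
concave response; with the default parameters the approximation error on
`f*` is small compared to sampling noise, and no nonlinear model is fitted.

## Within-cell viral dynamics

Each cell carries `viral_copy_number` (Nv, default 100) viral genomes. At a
cell division the pool is doubled by weighted sampling — variant `v` with
within-cell advantage `a_v` is drawn proportionally to `count_v (1 + a_v)`
— mutated at `viral_mutation_rate` per copy, and each daughter inherits Nv
copies sampled without replacement. This is a Wright-Fisher process of size
~Nv per division, so a new neutral copy fixes within a cell lineage with
probability 1/Nv and an advantaged one with probability
`(1 - exp(-2a)) / (1 - exp(-2 a Nv))` (`wf_fixation_prob()`).

Two simulators expose these dynamics at different resolutions:

* `simulate_heteroplasmic_lines()` is fully explicit. Because bottleneck
  founders are drawn uniformly (the experimental design minimises
  among-cell selection), the sampled cell is exchangeable with any other
  lineage, and it suffices to simulate a single cell lineage per line —
  exact, and O(divisions) instead of O(2^divisions). The recorded
  per-bottleneck frequency is the founder cell's composition.
* `simulate_population_evolution()` is cohort-based: cells are grouped by
  their resident viral variant, and heteroplasmic transients are collapsed.
  The justification is separation of timescales: an advantaged variant
  sweeps a cell lineage in tens of divisions, fast relative to the
  1000-generation population process. Within-cell dynamics enter through a
  per-division conversion hazard `mu_v * Nv * P_fix`; converted cells found
  a cohort of the new variant. Cohort members are exchangeable given the
  variant's effect class, so de novo conversions are pooled into one cohort
  per (effect class, mutation kind) — this keeps the state bounded at any
  mutation rate without changing the distribution of any recorded quantity.
  Drift acts through the multinomial transfer bottleneck.

The default `viral_mutation_rate = 1e-6` per copy per replication is a
placeholder of a biologically plausible magnitude for an RNA virus; no
measured value is available for this system, and the rate is exposed in
`sim_config()`. At this default, de novo conversion alone is too slow to
erode killing within 1000 generations — population-scale phenotype loss on
that timescale requires standing heteroplasmic variation
(`standing_variants`), which is opt-in because whether founding cultures
carry it is an empirical property of the experiment being emulated, not of
the model.

Mutation effects are drawn from `default_effect_table()`: synonymous
changes (neutral, phenotype-preserving), missense toxin-null changes that
keep immunity (K-I+), nonsense/frameshift changes that abolish both
(K-I-), and internal deletions behaving as defective-interfering-like
genomes with a larger replication advantage. A mutation can break toxin or
immunity function but never restore it: the effective flags of a de novo
variant are the AND of its parent's and its class's flags. This asymmetry
is what makes the forbidden-transition audit (`transition_audit()`) pass by
construction at the model level — immunity outlasts killing because every
toxin-producing genome also confers immunity.

Point mutations are labelled transitions or transversions with odds
`ts_tv_bias : 2` (one transition vs two transversion classes per site,
weight `ts_tv_bias` on the transition). Note the distinction between the
weight and the observed ratio: a weight of `b` yields an expected observed
transition:transversion count ratio of `b/2`.

## Phenotype thresholds and grading

A cell produces toxin iff the fraction of toxin-functional copies in its
pool is at least `theta_K` (default 0.5), and is immune iff the fraction of
immunity-functional copies is at least `theta_I` (default 0.05). The
asymmetry encodes the biology: toxin secretion requires substantial
functional dosage, while immunity is conferred by the preprotoxin itself,
so sparse functional copies suffice. Both are configurable.

Population-level grades (`full`/`weak`/`none`) discretise the fraction of
cells with the property at `grade_hi = 0.75` and `grade_lo = 0.25`,
emulating the coarse scoring of plate halo assays. The retention threshold
in `phenotype_trajectory()` defaults to `full`, so any weakening counts as
loss.

## Estimation choices

* **Zero counts.** A zero count in a competition time course signals
  fixation or loss of a competitor. Pseudocounts would bias small-sample
  slopes, so the usable window ends at the first zero and a boundary
  outcome (`fixed`/`lost` at generation g) is reported alongside the
  pre-boundary slope; per-interval estimates flag rather than silently drop
  affected intervals.
* **Significance conventions.** `frequency_dependence()` uses the slope's
  two-sided t-test at `alpha` (default 0.01). `classify_triple()` calls a
  direct competition "lost" only when the estimate is negative and exceeds
  twice its standard error in magnitude; ties are conservatively
  transitive. A sign change of the direct outcome across tested starting
  frequencies gives the `frequency_dependent_nontransitive` verdict.
  Deviations from expectation are reported against the sum of stepwise
  gains (`mode = "sum"`), with the compound product available.
* **Read counting.** Allele assignment is exact substring matching of the
  site +/- 5 nt probe (and its reverse complement); reads with sequencing
  errors inside the probe land in `n_unmatched`, which is reported, not
  hidden. For substitution probes with any flank the two probes differ at
  the centre, so ambiguity is impossible on error-free reads. Wilson score
  intervals are used for the frequency because they behave at the
  boundaries (f near 0 or 1) where these data live.
* **dN/dS.** Nei-Gojobori proportion counting without multiple-hit
  correction: per-gene variant counts here are far too small for the
  correction to matter, and the uncorrected version is exactly auditable
  by hand. Mutations to stop codons count as nonsynonymous. Recurrent
  changes are counted per-occurrence via the `n` column.
* **Spectrum null.** `ts_tv_stats()` tests observed transition and
  transversion counts against the unbiased 1:2 expectation with a df = 1
  Pearson chi-squared, uncorrected. Observed counts of 32:5 give R = 6.4
  and chi-squared 47.0 under this convention.
* **Contingency tests.** `contingency_chisq()` defaults to the uncorrected
  Pearson statistic (Yates correction available); validity requires all
  marginals positive, enforced as an error.

## Reproducibility

Every stochastic entry point derives an independent stream from the root
seed and a stream index via a fixed integer recurrence
(`derive_seed(seed, index)`), restoring the caller's RNG state afterwards.
Identical configuration and seed give bit-identical outputs, including the
data files written by `run_pipeline()`.

## What the generator does and does not emulate

The simulator reproduces the structure of the experiment: serial dilution
demography, flow-cytometry-like binomial sampling of competitor counts,
frequency-dependent killing, within-cell replication competition with a
single-cell-bottleneck design, and amplicon reads with uniform substitution
errors at Phred+33 qualities. It does not model spatial structure (plate
colonies concentrate toxin locally and should strengthen frequency
dependence), toxin accumulation or decay, host physiology (copy-number
regulation, curing), sequence-level viral genomes (variants are effect
classes, not nucleotide strings; `synthetic_k1_orf()` is an explicitly
synthetic stand-in used only by the sequence utilities), read-quality
variation, or nuclear genome evolution beyond fixed clone coefficients.
Passing tests therefore validate the analysis chain and the qualitative
regime structure — sign flips, bistability, transition ordering — not
quantitative agreement with any particular wet-lab measurement.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which the Monte-Carlo checks have useful power: 100
replicate competitions for estimator recovery and for the
frequency-dependence false-positive rate (each replicate pooling intervals
from five starting frequencies); 500 heteroplasmic lines over 30
bottlenecks of 20 divisions for the neutral fixation check (enough
divisions that residual heterozygosity at Nv = 100 is below 1%); 20-50
populations over 300-1000 generations for the population-scale properties;
1000 random instances for each oracle-equivalence check.

## Known limitations

* The kill coefficient, the within-cell advantages and the viral mutation
  rate are model parameters without measured values; conclusions that
  depend on their magnitudes (e.g. the time to population-scale phenotype
  loss) are illustrative.
* The cohort approximation ignores the transient during a within-cell
  sweep; phenotype changes appear atomically at conversion. At the recorded
  resolutions (tens of generations) this is invisible, but sub-sweep
  dynamics are out of reach.
* `f*` from the linear fit inherits the first-order approximation above;
  with strong killing (`kappa` near 1) the concavity of
  `s + ln(1 - kappa(1-f))` would bias it noticeably.
* The frequency estimator's exact-match rule discards error-bearing reads;
  at high error rates or long probes this loses depth (reported via
  `n_unmatched`) though it does not bias the estimate.
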