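---
title: "Estimating condition-specific translation elongation dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating condition-specific translation elongation dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ribodyn)
```

# The problem

Ribosome profiling measures where ribosomes sit on mRNAs, at codon
resolution, by sequencing ribosome-protected fragments. A footprint-count
(RC) profile is therefore shaped simultaneously by how abundant the mRNA
is, how often ribosomes initiate on it, how fast each codon is decoded, and
by substantial technical noise — and footprints map densely only on highly
expressed genes. `ribodyn` implements a pipeline that extracts the
*elongation* component of this signal per codon and per condition (time
point), aggregates it per gene, and couples the resulting rates to a
mechanistic translation simulator.

# The decoding-rate model

## Normalization

Within each profile, the first and last 20 codons are masked (they carry
initiation- and termination-proximal biases), and profiles where fewer than
40% of the remaining positions carry footprints are discarded; both
thresholds are configurable (`pipeline_config()`), and the coverage
comparison is inclusive (a profile at exactly 40% is kept). Each retained
profile is divided by its average count, yielding normalized footprint
counts (NFC) that are comparable across genes with very different
expression. Under steady-state translation the expected footprint count at
a codon is proportional to the time a ribosome dwells there, so a codon's
NFC is a relative dwell-time observation.

A choice the data force on us: a zero count at a position can mean "decoded
too fast to catch" or "not sampled deeply enough", and at realistic depths
the second dominates. The package therefore computes the profile average
over *covered* (count > 0) unmasked positions and collects NFC observations
only at covered positions. `include_zeros = TRUE` switches to averaging
over all unmasked positions for sensitivity analyses.

## The EMG decomposition

Pooling the NFC values of one codon across the reference set gives its
dwell-time histogram: approximately normal with a heavy right tail.
Simulations of translation without pausing produce normally distributed
decoding rates, which motivates reading the tail as *non-typical* events —
pauses, ribosome collisions, mapping artefacts. The histogram is therefore
fitted with an exponentially modified Gaussian, the convolution

$$X = N(\mu, \sigma^2) + \mathrm{Exp}(\lambda),$$

with the exponential component parameterized by rate $\lambda$ (tail mean
$1/\lambda$). The normal mean $\mu$ is the codon's typical decoding time
and $\mathrm{TDR} = 1/\mu$ its typical decoding rate — a relative,
dimensionless quantity (absolute time calibration is out of scope).

Numerics worth noting:

* the log density is evaluated through the scaled complementary error
  function, with an asymptotic expansion above $u = 25$ (where
  `pracma::erfcx` overflows) and a direct exponential-tail branch for
  $u < 0$, so likelihoods stay finite for arbitrarily sharp components;
* the likelihood is maximized by Nelder–Mead on $(\mu, \log\sigma,
  \log\lambda)$ from a method-of-moments start plus a deterministic
  perturbation grid (5 starts by default). The EMG likelihood is multimodal
  when the tail is heavy, hence the multi-start; determinism of the start
  grid makes refits of the same sample bit-identical;
* fitting is admitted only for codons with at least 100 pooled
  observations at the time point.

After the first fit, points whose fitted survival probability $p_i$
satisfies $p_i \cdot n_i < 0.001$ — i.e. values so extreme that fewer than
0.001 of them are expected in the whole sample — are removed and the codon
is refitted exactly once. No iteration: one removal pass is what the
procedure defines, and the monotonicity of the rule (a lower threshold
never removes more) is property-tested.

A distribution-free companion estimator, $1/\mathrm{median}(\mathrm{NFC})$,
is provided (`median_based_rates()`) to check that conclusions do not hinge
on the parametric form.

## From codons to genes

A gene's MTDR is the geometric mean of the TDRs of its codons, every codon
position counted with its multiplicity (a gene that uses a slow codon ten
times is slowed ten times). When a codon is unfitted at a time point the
gene's value is imputed with the time point's mean log-TDR and the gene is
flagged (`unfitted = "drop"` drops it instead) — lowly expressed genes
must remain scoreable, but visibly so. Column z-scores (sample sd,
$n - 1$) make values comparable across time points with different coverage;
the MTDR co-score of two genes is the Pearson correlation of their MTDR
trajectories, computed pairwise-complete with at least 3 shared time
points.

# Codon metrics

* **tAI** weights follow the relative-adaptiveness construction: each codon
  sums $(1 - s) \cdot \mathrm{tGCN}$ over the anticodons that read it
  (Watson–Crick plus one wobble pairing determined by its third base), and
  weights are normalized by the maximum. The wobble constraints are shipped
  as `inst/extdata/tai_s_values.tsv` (G:U 0.41, I:C 0.28, I:A 0.9999,
  U:G 0.68); codons with zero adaptiveness receive the geometric-mean
  fallback and are flagged.
* **CAI groups**: per amino acid, the codons with extreme CAI form the
  High/Low sets; methionine and tryptophan are excluded (no synonymous
  counterpart), leaving 18 codons per set under the standard code. Ties
  break lexicographically and are recorded.
* **Rank CV**: TDRs are ranked 1–61 per time point and a codon's
  variability across time is $\mathrm{CV} = 100 \cdot
  \mathrm{sd}(\mathrm{ranks})/\mathrm{mean}(\mathrm{ranks})$ (sample sd, a
  population-sd switch exists). The Low-vs-High CAI comparison uses a
  right-tailed Wilcoxon rank-sum test, and the equal-sample-size control
  resamples every codon down to max(100, minimal admitted sample size)
  before refitting, removing the frequency–histogram-size confound.
* **Demand**: codon occurrences weighted by transcript level (RPKM),
  summed over genes, then normalized within each synonymous family (the
  fractions sum to 1 per amino acid); ratios against the vegetative time
  point are standardized per codon by the codon's own mean ratio.

# The TASEP simulator

Translation is simulated as a continuous-time totally asymmetric simple
exclusion process with extended particles: a ribosome at codon $i$ covers
codons $[i, i + \ell - 1]$ with $\ell = 10$, advances at the codon's rate
when codon $i + \ell$ is vacant, terminates at the last codon, and
initiates at codon 1 at rate IR when the first $\ell$ codons are vacant.
The implementation is an exact Gillespie simulation in C++ with its own
`mt19937_64` stream, so results are deterministic given the seed across
platforms. Exclusion is assertable at every event (`check_exclusion`), and
a deterministic low-density mean-field fixed point
(`mean_field_single_mrna()`) cross-checks occupancy and flux in tests.

The whole-cell mode couples all mRNA copies to one finite ribosome pool:
each mRNA's effective initiation propensity is IR scaled by the free-pool
fraction (`free/total`; a mass-action alternative is available), a
terminating ribosome re-joins the pool, and `free + bound = total` is
integer bookkeeping verified at every event. Averaging uses a fixed,
configurable burn-in followed by a measurement window — a fixed window was
preferred over an adaptive stationarity test because it keeps runtimes
deterministic, and the flux-balance tests confirm the window sits in steady
state for the regimes used.

Whole-cell defaults are 200,000 ribosomes and 60,000 mRNAs; tests and the
bundled experiments run a 1/100-scale cell (2,000 ribosomes, 600 mRNAs)
with the footprint kept at 10 codons — scaling the pool and the mRNA count
together preserves the per-mRNA regime while keeping a simulation to
seconds.

## Synonymous recoding

`randomize_cluster_codons()` rewrites each amino acid of a gene cluster by
a draw from the demand distribution (genomic codon usage × transcript
copies), preserving the protein exactly. The bundled experiment
(`run_recoding_experiment()`) builds a 100-gene desk-scale cell, optimizes
a 50-gene cluster to each family's fastest codon, recodes it 20 times, and
compares free pool and mean translation rate via percent change and
z-score. The direction of the effect (both decrease) is the reproducible
claim; its magnitude depends on the cell's composition and is reported, not
asserted.

# Initiation-rate inference

Observed footprint density only constrains the *product* of initiation and
elongation; to separate them, an occupancy anchor maps density (RPKM-like)
to an expected ribosome count by monotone piecewise-linear interpolation
(queries outside the anchors extrapolate from the nearest segment and are
flagged). The initiation rate whose simulated mean occupancy matches the
target is then found by binary search: the upper bracket grows
geometrically until the simulated count exceeds the target or a jamming
plateau is detected (doubling IR no longer raises occupancy), and every
evaluation reuses the same RNG seed — common random numbers make the
simulated count effectively monotone in IR, which bisection needs.
Tolerance defaults to 0.05 × target with a floor of 0.1 ribosomes, 40
iterations maximum. Genes without a footprint profile at a time point
propagate a `no_profile` status instead of a rate. Anchors are built from
the vegetative time point and applied to all time points — an explicit
assumption, since occupancy data exist only for vegetative growth.

# Statistics

Empirical p-values throughout use the add-one convention
$p = (1 + \#\{\text{rand} \ge \text{obs}\})/(n_{\text{rand}} + 1)$, which
cannot return 0 at finite $n$. The direction test draws size-matched gene
sets uniformly without replacement from all scored genes; the
protein-similarity test compares a cluster's mean pairwise Smith–Waterman
score (BLOSUM62, gap open 11 / extend 1 — standard protein defaults, and
configurable, since no scheme is canonical for this use) with size-matched
random groups. The PPI association test contrasts edge and non-edge
co-score distributions (one-sided Wilcoxon) and correlates edge co-scores
with confidence (Spearman); the non-edge background is capped at $10^6$
sampled pairs with a fixed seed.

# What the synthetic generator does and does not emulate

The generator reproduces the statistical structure the estimators assume:
log-normal transcript levels spanning orders of magnitude (hence genes with
sparse profiles), per-position dwell signals of $1/\mathrm{rate}$ plus a
Bernoulli–exponential pause excess (the mixture the EMG decomposition
expects), Poisson count noise, stage-specific rate perturbations including
rank inversions for rare codons, and PPI edges enriched among co-patterned
genes. It does **not** emulate sequence-dependent biases (ligation,
nuclease, P-site ambiguity), mRNA secondary structure effects on local
rates, codon autocorrelation along real ORFs, or traffic-jam feedback on
the observed footprints. Passing recovery tests therefore demonstrates the
estimators invert the stated generative model at realistic depths — not
that every bias of a real library is handled.

The chosen study conditions (fixed once): 300 genes of 150–400 codons, 4
time points, mean depth 40 reads/codon for the recovery experiment;
`pause_prob = 0.05`, `pause_scale = 1.0` NFC units; two rare codons
(0.25× usage weight) carrying the inversion. The EMG recovery grid spans
$\mu \in \{0.5, 1, 2\}$, $\lambda\mu \in \{0.5, 2, 5\}$,
$\sigma = 0.2\mu$ at $n = 10{,}000$ — the regime where per-codon samples
live after pooling. The null-calibration experiments use a 300-gene scored
universe with sets of 30 (direction test) and a 40-protein universe with
clusters of 5 (alignment test), 100 randomizations inside each test and
500 replicates outside.

# Known limitations

* TDR is relative; comparing absolute speeds across data sets needs an
  external calibration.
* The EMG separates "typical" from "non-typical" but cannot attribute the
  tail to pauses versus mapping artefacts.
* The mean-field solver is reliable only below saturation and is used
  accordingly (as a cross-check, not a result).
* IR inference inherits the TASEP's relative time scale and saturates at
  the jamming plateau: targets above it return `unconverged` by design.
* The pool-proportional whole-cell coupling is one defensible choice; the
  mass-action alternative is provided, and conclusions in the bundled
  experiments are direction-level, not magnitude-level.
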