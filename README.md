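# ribodyn

Condition-specific translation **elongation** dynamics from ribosome
profiling, separated from initiation and transcript abundance.

Ribosome profiling counts footprints of translating ribosomes at codon
resolution, but a raw footprint-count (RC) profile superimposes mRNA level,
initiation rate, elongation speed and noise. `ribodyn` implements the
decomposition pipeline that isolates the elongation component and the
simulation machinery to reason about its consequences:

1. **Typical decoding rates (TDR).** Each gene's RC profile is trimmed
   (first/last 20 codons), filtered by coverage (≥ 40% of positions with
   footprints), and normalized by its average count into an NFC profile.
   Per codon and time point, the pooled NFC values (≥ 100 occurrences) are
   fitted by maximum likelihood to an **exponentially modified Gaussian**

   *X* = *N*(μ, σ²) + Exp(λ),

   whose normal component captures the typical decoding time and whose
   exponential tail absorbs pauses, traffic jams and biases. After one
   outlier-removal pass (points with *p*ᵢ·*n*ᵢ < 0.001 under the fitted
   survival function) and a refit, the codon's typical decoding rate is
   TDR = 1/μ.
2. **MTDR.** A gene's elongation efficiency is the geometric mean of the
   TDRs of its codons; per-time-point z-scores make genes comparable across
   conditions, and the Pearson correlation of two genes' MTDR trajectories
   (the *co-score*) quantifies co-patterned elongation dynamics.
3. **Codon metrics.** tRNA adaptation index from tRNA gene copy numbers
   with wobble constraints, High/Low-CAI codon groups, the coefficient of
   variation of a codon's TDR *ranks* across time points
   (CV = 100·sd/mean), transcript-weighted codon demand, per-amino-acid
   weighted TDR, and an equal-sample-size control.
4. **TASEP simulation.** A continuous-time (Gillespie) totally asymmetric
   simple exclusion process with 10-codon ribosome footprints, for single
   mRNAs and for a whole cell in which 60,000 mRNAs compete for a finite
   pool of 200,000 ribosomes (tests and examples run a 1/100-scale cell).
   Synonymous-recoding experiments rewrite a gene cluster by
   demand-weighted codon draws and measure the effect on the free ribosome
   pool and mean translation rate.
5. **Initiation-rate inference.** Footprint density is mapped to an
   expected ribosome count through monotone linear interpolation of
   occupancy anchors; the initiation rate whose simulated occupancy matches
   the target is found by binary search with common random numbers.
6. **Synthetic data.** A first-class generator produces genomes, dynamic
   ground-truth codon rates (including programmed rare-codon rank
   inversions), log-normal transcript levels, Poisson ribo-seq-like
   profiles with Bernoulli/exponential pause mixtures, and PPI networks
   coupled to MTDR co-patterns — so every stage is testable end to end.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_fit_tdr.R
```

prints

```
simulated 300 genes x 4 time points, 1200 profiles, depth 40
rank inversion programmed for CGG/CCG at t3
t1: 61 codons fitted, Spearman vs truth 0.999, vs median-based 0.999
t2: 61 codons fitted, Spearman vs truth 0.999, vs median-based 0.999
t3: 61 codons fitted, Spearman vs truth 0.998, vs median-based 0.999
t4: 61 codons fitted, Spearman vs truth 0.998, vs median-based 0.998
estimated ranks of CGG/CCG:
    t1 t2 t3 t4
CGG  2  2 57  3
CCG  1  1 60  1
```

i.e. the EMG-based estimator recovers the generating decoding rates almost
perfectly (rank correlation ≥ 0.998 per time point) and reproduces the
programmed behaviour of the two rare codons, which sit at the very bottom
of the rank scale except at `t3`, where their decoding rate jumps above the
90th percentile. The remaining drivers compute MTDR/z-scores and co-scores
(`03`), codon metrics and demand (`04`), initiation rates (`05`), the
whole-cell recoding experiment (`06`; demand-weighted recoding of a 50-gene
codon-optimized cluster shrank the free ribosome pool by 6.1% with z = 8.4
and the mean translation rate by 8.2% with z = 8.9 on the default seed),
and the network/gene-set statistics (`07`).

Programmatic use mirrors the drivers:

```r
library(ribodyn)
genome   <- generate_genome(300, c(150, 400), seed = 1)
stage1   <- profiles_to_samples(profiles, genome, pipeline_config())
tdr      <- estimate_tdr_table(stage1$samples)
mtdr     <- mtdr_matrix(genome, tdr$tdr)
z        <- standardize_mtdr(mtdr$mtdr)
```

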