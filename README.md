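# replinoise

Replicate-concordance diagnostics for low-biomass 16S rRNA gene profiling.

When bacterial biomass is very low, amplicon sequencing still returns a
lane full of classifiable reads. Some of that is **reagent (kit)
contamination** — real DNA, reproduced faithfully across technical
replicates of the same kit. Some of it is **stochastic sequencing
noise** — reads that are *not* reproduced between technical replicates of
the same DNA extract, yet can make a single replicate look like a rich
community that even tests as significantly different from its negative
controls. `replinoise` is for microbiome researchers working with
low-biomass sample types (lavage fluid, breath condensate, reagent
controls, dilution series) who need to decide which of those they are
looking at before interpreting a community profile.

## What it computes

For an OTU table with technical-replicate structure (mothur `.shared` +
design TSV, or simulated), the package:

* partitions Bray-Curtis dissimilarities
  (`d(x,y) = Σ|x_i − y_i| / Σ(x_i + y_i)` on relative abundances) into
  **intra-replicate** and **inter-replicate** sets with bounded-support
  kernel density estimates and their overlap coefficient
  (`intraInterDistances`);
* classifies each specimen or kit into **signal- / contamination- /
  noise-dominated / indeterminate** from that evidence (`classifyRegime`);
* fits the **biomass–reproducibility transition** — a four-parameter
  logistic of mean intra-replicate distance against log10(16S copies per
  specimen, ddPCR) — and reports its midpoint and 10–90% range
  (`transitionFit`), plus the practical screening rule that flags
  specimens below 1e5 copies (`flagLowBiomass`);
* builds **mean-of-replicate-medians** consensus profiles that zero out
  OTUs seen in a minority of replicates (`meanOfReplicateMedians`),
  identifies contaminant OTUs from replicated negative controls, and
  removes them with read-retention accounting (`identifyContaminants`,
  `removeContaminants`);
* runs a one-factor **PERMANOVA** (pseudo-F permutation test, optional
  block permutation of whole specimens) to demonstrate that "significantly
  different from controls" does not imply "reproducible" (`bcPermanova`);
* ships a **generative simulator** of the noise process — Poisson template
  sampling plus a per-replicate random noise pool competing for fixed read
  depth with weight λ — that reproduces the dilution-series behavior and
  provides ground truth for calibration (`simConfig`,
  `simulateDilutionSeries`, `simulateControls`, `simulateSpecimens`);
* orchestrates everything into a TSV report bundle (`runPipeline`).

## Worked example

Simulate the benchmark dilution-series experiment — a single-strain
community at 1e8 16S copies, five tenfold dilutions, 3 extraction kits ×
4 technical replicates, depth 10,000, noise scale λ = 5000 — and run the
core analyses:

```r
library(replinoise)
cfg <- simConfig(seed = 7, noiseScale = 5e3, readDepth = 10000L)
x <- simulateDilutionSeries(cfg)
x
#> ReplicateExperiment: 72 samples x 2001 OTUs
#>   specimens: 18  kits: 3  controls: 0
#>   biomass records: 18 specimens

s <- intraInterDistances(x, stratum = "kit")
mi <- tapply(s@intra$distance, s@intra$level, mean)
round(mi, 3)
#> D1_1e+00 D2_1e-01 D3_1e-02 D4_1e-03 D5_1e-04 D6_1e-05
#>    0.000    0.001    0.005    0.049    0.334    0.834
```

Replicates agree almost perfectly down to 1e5 copies, then fall apart:
by the last dilution (1e3 copies) the mean within-kit Bray-Curtis
distance is 0.83 — replicates of the *same extract* no longer resemble
each other. Fitting the transition:

```r
bm <- biomassCopies(x); d <- replicateDesign(x)
copies <- vapply(names(mi), function(lv)
  bm[[d$specimen_id[match(lv, d$dilution)]]], numeric(1))
transitionFit(copies, mi)
#> TransitionFit: midpoint 5.01e+03 copies, range 557-4.5e+04, span 0.00-1.00

table(flagLowBiomass(x)$status)
#> flagged      ok
#>       6      12
```

The fitted midpoint (≈5,000 copies) recovers the simulator's noise scale
λ: samples cross from reproducible to noise-dominated within a narrow
copy-number window, and the 6 specimens below 1e5 copies are flagged as
noise-vulnerable. Reagent controls show the two contrasting failure
modes — contaminated kits are internally reproducible but unlike every
other kit, clean kits are pure irreproducible noise:

```r
ctl <- simulateControls(simConfig(seed = 7, noiseScale = 1e3, readDepth = 10000L))
classifyRegimes(ctl, stratum = "kit")
#>      group                  regime median_intra median_inter   overlap
#> 1 CtlKit01 contamination_dominated       0.0252      1.00000 0.0000000
#> 2 CtlKit02 contamination_dominated       0.0221      1.00000 0.0000000
#> 3 CtlKit03         noise_dominated       1.0000      0.99945 0.9202174
#> 4 CtlKit04         noise_dominated       0.9994      0.99970 0.9837417
#> 5 CtlKit05         noise_dominated       0.9903      0.99980 0.7487573
#> 6 CtlKit06         noise_dominated       0.9968      1.00000 0.9229946
#> 7 CtlKit07         noise_dominated       0.9962      0.99980 0.7245040
```

The two planted contaminated kits (01, 02) are called exactly: near-zero
median intra-replicate distance, maximal distance to other kits, zero
density overlap. See the vignette
(`vignettes/replicate-noise-qc.Rmd`) for the models, parameter meanings
and numerical choices.

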