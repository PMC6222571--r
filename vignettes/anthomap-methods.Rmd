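---
title: "Methods: simulating and mapping anthocyanin acylation QTL in F2 maize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and mapping anthocyanin acylation QTL in F2 maize}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthomap)
```

`anthomap` packages the statistical machinery of a small-population F2 QTL
study of the maize reduced-acylation trait: a synthetic population
generator with a known causal architecture, the genotype/phenotype
processing used on GBS + HPLC data, single-marker and stepwise regression
scans, Type-3 variance decomposition, and a subsampling power experiment.
This vignette records the models, their assumptions, the tunable
parameters, and the design choices that were genuinely open.

## The population model

**Genome and marker map.** Ten chromosomes with RefGen_v3-scale lengths
(chromosome 1 ends at 301,476,924 bp, total ≈ 2.06 Gb). Markers are placed
by sampling positions from a piecewise-uniform density whose terminal
`end_fraction` (default 0.2) of each chromosome is weighted
`end_density_boost`-fold (default 2), reflecting the end-of-chromosome
enrichment of reduced-representation SNP sets. With the default 8,062
markers the mean adjacent gap is ≈255 kb. Marker counts are allocated to
chromosomes proportionally to physical length by a largest-remainder rule
with a one-marker floor, so a 10-marker map gets one marker per chromosome.

**Meiosis.** Gametes are simulated under the Haldane (no-interference)
model: the genetic map is linear at `cm_per_mb` (default 0.7 cM/Mb,
≈1,500 cM genome — a round figure in the maize range; the rate is
configurable because the study design supplies no genetic map), crossover
counts per chromosome are Poisson with mean equal to the map length in
Morgans, and crossover positions are uniform on the genetic map. The
recombination fraction between positions d cM apart is therefore exactly
`(1 − exp(−2d/100))/2`, which the test suite verifies against simulation.
Each F2 receives two independent F1 gametes, so marker classes segregate
1:2:1.

**Founders.** Founder A is fully inbred; founder B is a genetic stock that
is *not* fully inbred: at a `residual_founder_het` fraction of markers
(default 0.05) it carries a third allele, so each F2's B-lineage allele at
such a site is one of two symbols. Population-wise these sites behave as
tri-allelic, exercising the coding rule that collapses third and fourth
alleles with the minors.

**Causal architecture.** Five loci ride the same simulated haplotypes as
pseudo-markers (they need not coincide with a marker; nearest-marker
linkage carries the signal, the design this emulates had its top SNP near, not inside, the candidate gene): the reduced-acylation locus at
chr1:300,173,138; an AC intensifier on chromosome 7; the two aleurone
transcription-factor loci on chromosomes 9 and 10 (mid-arm defaults, configurable: only their chromosomes, not their
coordinates, are part of the emulated design); and an inert pericarp-color locus carried with zero effect.

## The phenotype model

**Acylation percentage** is bimodal: homozygous mutants at the
reduced-acylation locus draw from N(15.0, 5²) percent and all others from
N(70.8, 6²), clipped to [0, 100]. The class means are part of the emulated
study conditions; the within-class standard deviations are not, so they
were chosen once to reproduce a cleanly separated bimodal histogram
around the 50% classification valley (mutant and wild-type tails ≥5 SD
from the cutoff) and are exposed as `acyl_sd_mutant` / `acyl_sd_wildtype`.

**Anthocyanin content** (mg/kg) is additive in scored locus classes:
`baseline_ac` plus +105.4 (intensifier, homozygous), −23.3 (reduced
acylation, homozygous), −24.2 and −29.1 (the two kernel-scored loci), plus
a mean-zero right-skewed residual. The baseline default 102.3 mg/kg makes
the expected population mean ≈96 mg/kg, the emulated population mean.
The residual is a shifted log-normal — `scale·LN(0, sdlog) − E[·]` with
`ac_noise_sd` = 25 mg/kg and `ac_noise_sdlog` = 0.6 — because the observed
AC distribution is right-skewed (which is also why the scans map AC on the
log scale). The 25 mg/kg default puts the residual share of AC variance
near ~25%, the residual share the emulated design exhibits. AC is floored at
1 mg/kg so log transforms are always defined.

**Peak areas.** Each sample's total chromatogram area is
`AC / standard_ac × standard_total_area` (external-standard proportionality,
1000 mg/kg standard), split between acylated and non-acylated compounds by
the sample's acylation percentage and fixed within-class shares (the
malonylated cyanidin peak dominating the acylated fraction). Two replicate
injections scale the whole chromatogram by independent factors
`1 + N(0, σ)`, with σ calibrated as `(cv/100)/sqrt(2/π)` so that the
*expected two-replicate CV* equals `replicate_cv_pct` (default 3.09%): the
sample SD of two such draws is `|d|/√2` with `d ~ N(0, 2σ²)`, whose mean is
`σ·sqrt(2/π)`. With noise disabled the derived traits reproduce the
generating values to numerical precision (a tested round-trip).

**Kernel scores.** The speckling and colorless scores are emitted from the
heterozygous class of their loci (expected 50%). The scored-class frequencies observed in populations of this design
(~56–58%) sit between the Mendelian 50% and 75% classes, and ear-level
imprinting genetics cannot be reduced to a clean
plant-genotype rule; the heterozygous class is the closest Mendelian class
and — importantly — the AC effects attach to the *scored* class exactly as the 0/1 regression coding of such studies does, so the fixed-effects and
variance-component machinery sees the same design structure either way.

## Genotype processing

Raw calls are two-letter allele pairs, order-insensitive. The major allele
at a marker is the most frequent allele (ties broken lexicographically);
codes are the dosage of the major allele (2/1/0), with third/fourth-allele
homozygotes collapsing to 0. MAF is `min(f_major, 1 − f_major)` so it stays
in [0, 0.5] even at collapsed multi-allelic sites where the single most
frequent allele can fall below 0.5. The MAF filter keeps markers *at* the
threshold (boundary semantics are rarely stated for this cutoff; ≥ is the
documented, configurable choice here); the sample filter removes samples *strictly
above* the missing fraction, and MAF is recomputed after sample filtering
(sample filter first, then the MAF filter). Missing codes
are never imputed — imputation is out of scope and the scans drop missing
pairs per marker instead.

The genotype TSV writes A/H/B symbols with A fixed to the major allele at
write time; the reader therefore decodes directly rather than re-inferring
the major allele (re-inference can flip codes at collapsed tri-allelic
sites where the pooled minors outnumber the major allele).

## Scans and thresholds

Each marker is tested by OLS of the phenotype on its code plus any
covariate markers; the p-value is the two-sided t-test of the marker slope
with df = n_used − rank. On complete data the scan residualises the
phenotype and all markers on the covariates once (Frisch–Waugh), which is
algebraically identical to per-marker full fits and is verified against a
brute-force normal-equations oracle to 1e-10. Markers monomorphic among
used samples, or collinear with the covariate set, get p = 1 and a flag; a
constant phenotype aborts the scan. p-values are computed on the log scale
and floored at the smallest positive double so extreme signals remain
ordered (top-marker selection uses −log10(p), ties broken by genomic
coordinate — chromosome then position).

The genome-wide threshold is Bonferroni α/n (−log10 ≈ 5.21 at α = 0.05,
n = 8,062); a relaxed exploratory constructor (`fixed_threshold`, default
1e-4) is provided for conditional scans of weaker QTL. Stepwise selection
adds the top marker as a covariate while it clears the per-test threshold,
capped at `max_qtl` (default 10) as a runaway guard.

## Variance components

`decompose_variance` implements a Type-3 method of moments: each factor's
Type-III sum of squares (the fit reduction from dropping it from the full
main-effects model) and the residual SS are equated to their expectations
under the all-random model, `E[y'Ay] = Σ_j σ_j² tr(A Z_j Z_j') +
σ_e² tr(A)`, and the linear system is solved. The model is main-effects
only, matching the per-locus summary it reproduces (no interaction terms
are partitioned). Negative solutions are truncated to
zero before proportions are renormalised to 100 (raw solutions are kept as
an attribute); a singular expected-mean-square system falls back to a
sequential Type-I decomposition with a warning. On balanced one-factor
data the estimate equals the classical one-way ANOVA
`(MSA − MSE)/n₀` closed form, which the tests assert to 1e-10.
Fixed-effect shifts and their significance come from a joint OLS fit that
reports aliased (perfectly confounded) scores instead of silently dropping
them.

## Power simulation

For each subsample size, individuals are drawn without replacement,
independently across replicates; each subsample is scanned and its top
marker classified by two rules: *significant* (p below α divided by the
full marker count — constant across replicates, with monomorphic markers
still counted as tested at p = 1) and *within window* (default 10 Mb of
the true locus). Distances are measured on the cumulative genome
coordinate — identical to within-chromosome bp distance when the top
marker is on the right chromosome, finite across chromosomes — so that a
genome-length window yields zero false positives by construction. Per-size summary
averages follow the usual table conventions: −log10(p) averaged over
significant replicates, distance over detected replicates, and the scored
phenotype-class proportion over all replicates (labelled explicitly as the scored-class proportion of
whichever trait is being summarised).

With the default architecture the fully penetrant binary trait (25%
scored class) detects at ~90–100% across seeds at subsample size 40 and
the bimodal acylation trait at ~97–100% at size 60; class balance is the
binding constraint at small sizes, so traits with a near-even scored class
reach 100% earlier.

## Candidate filtering

Motifs are scanned as position patterns: HXXXD (fixed H/D, three arbitrary
residues), DFGWG (exact), and XY[F/L]GNC (one arbitrary residue, then
fixed Y, F or L, then GNC). Wildcard positions match any residue including
the unknown letter X; fixed positions match only their residue, so X never
satisfies them. All overlapping matches are reported, 0-based in the data
model and 1-based in reports. The filter criterion is Motif-3 presence
only; homology pre-screening (identity/coverage against a reference
malonyltransferase) requires alignment infrastructure and external
databases and is deliberately out of scope — the shipped candidate
coordinate table is a documentation fixture, and the example FASTA is
synthetic (labelled as such). The segregation chi-square is the Pearson
statistic against expected ratio counts with an upper-tail p; for small N
it is an approximation to the exact multinomial tail (the tests document
the gap without asserting equality).

## Reproducibility and problem sizes

Every stochastic function takes a seed; the pipeline derives fixed
per-stage offsets from one master seed so re-running a stage does not
perturb another's draws, and a seeded run is byte-identical. The test
suite works at two scales chosen for quick, stable statistics: a
600-marker/128-individual population for module tests and the full
8,062-marker/128-individual scale for detection-power and end-to-end
checks; Monte-Carlo assertions use 3-standard-error bands (or fixed-seed
determinism) throughout. Recovery of the generating AC effects is judged
by 95% confidence-interval coverage (±2 SE) pooled over the four effects.

## Limitations

The generator emulates a *post-imputation* matrix: sequencing reads,
variant calling and imputation are not modelled, so imputation artefacts
(block-wise errors, allele-frequency shrinkage) are absent, and the
missing/miscall degradation it can apply is independent per entry rather
than coverage-driven. Crossover interference is ignored (Haldane), kernel
scores are plant-genotype simplifications of ear-level imprinting
phenotypes, compound shares within the acylated and non-acylated fractions
are fixed rather than genotype-dependent, and the variance decomposition is
method-of-moments, not REML (no confidence intervals on components).
Passing tests on this generator therefore demonstrate correctness of the
statistical machinery under the stated design, not robustness to every
pathology of real GBS/HPLC data.
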