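---
title: "Models and methods: coupling demographic history to paleoclimate niche dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: coupling demographic history to paleoclimate niche dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoterrapin)
```

`paleoterrapin` couples three classical comparative-genomics analyses into
one tested pipeline: (i) inference of effective-population-size (Ne)
trajectories from single diploid genomes with a pairwise
sequentially-Markovian-coalescent (SMC) hidden Markov model, (ii)
reconstruction of suitable-habitat area through paleoclimate periods with a
Maxent-style presence–background niche model, and (iii) the statistics that
connect them — trend coding with chi-squared/Phi association tests,
phylogenetic generalized least squares (PGLS) of heterozygosity and mean Ne
on conservation status and habitat area, and a position-representation-ratio
(PRR) statistic for assigning assembly scaffolds to micro-dissected
chromosomes. Every stage can be exercised on synthetic data with known
ground truth, which is how the package tests itself.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data tests do and do
not establish about real data.

## The pairwise SMC model

A single diploid genome is a pair of haplotypes whose common ancestor at
each position lived some time T(x) ago (the TMRCA). Recombination makes
T(x) a piecewise-constant process along the chromosome; mutation turns T
into observable heterozygosity, since the expected density of heterozygous
sites at a position with TMRCA t is 2&mu;t per bp. The classical pairwise
SMC approach discretizes T into intervals and treats the binned genome
(100-bp bins coded heterozygous / homozygous / missing) as the emission
sequence of a hidden Markov chain over those intervals.

**Time discretization.** Coalescent time (units of 2N&#8320; generations)
is cut into 64 atomic intervals with log spacing
t&#8342; = 0.1(exp((k/n)·ln(1 + 10·t&#8337;&#8336;&#8339;)) − 1) up to
t&#8337;&#8336;&#8339; = 15; the last interval absorbs deeper coalescences.
Atomic intervals share coalescence-intensity parameters in "free" groups
written in the upstream pattern dialect: the default `"2+2+25*2+4+6"`
expands to free-interval sizes (2, 2, 2×25, 4, 6). A token `m*a` means *m*
free intervals of *a* atomic intervals each, the convention required by the
main pattern itself (25*2 = fifty atomic intervals grouped in pairs); note
that this expansion yields 29 free parameters.

**Emission and transition.** Emission is
P(HET | state k) = 1 − exp(−&theta;·t&#772;&#8342;) with &theta; the scaled
mutation rate per bin and t&#772;&#8342; the interval's representative time
(interval midpoint; the last interval uses the midpoint of its finite
part). Missing bins emit with probability 1 in every state. Transitions use
the SMC' kernel: with probability exp(−&rho;t) no recombination occurs in
the bin gap; otherwise a recombination point u is uniform on (0, t), and
the detached lineage re-coalesces upward — below t it meets two partners
(total rate 2&lambda;(v)), and rejoining its own stub (probability 1/2 of
those events) leaves the TMRCA unchanged, which is the "back-coalescence"
mass that distinguishes SMC' from plain SMC; above t a single ancestral
lineage remains (rate &lambda;(v)). With piecewise-constant &lambda; every
segment integrates in closed form, and each row of the 64×64 transition
matrix is assembled in one O(K) sweep; the recombination-height integral
uses midpoint quadrature per atomic segment. The same kernel (in natural
units, exact exponential races rather than quadrature) drives the
synthetic-data simulator, so the inference model and the generator match by
construction; a `variant = "smc"` flag switches the simulator to the plain
SMC kernel.

**Fitting.** The E-step is a scaled forward–backward pass per scaffold
(compiled code); the M-step maximizes the expected complete-data
log-likelihood over (log &theta;, log &rho;, log &lambda;&#8321;..&#8342;)
with L-BFGS-B, capped at 30 quasi-Newton iterations. Because the M-step
starts from the current parameters and only accepts improvements, this is a
generalized EM and the observed log-likelihood is non-decreasing — a
property the tests assert at tolerance 1e-8. Defaults: 25 EM iterations
with relative-likelihood stopping at 1e-6; &theta; initialized from the
observed heterozygous-bin fraction h as h/(1−h) and &rho; = &theta;/5 (the
conventional −t 15 / −r 5 settings); &lambda; initialized flat at 1. A
track with no heterozygous bins is returned flagged `degenerate` rather
than fit.

**Scaling and summaries.** N&#8320; = &theta;/(4&mu;·bin) converts the
relative trajectory to diploid Ne and years (times × 2N&#8320;g). The
per-generation mutation rate comes from the calibration
&mu; = d·g/(2T&#8325;) with generation time g = age at maturity + half the
reproductive longevity; when the calibrating node spans several species, d
is the mean pairwise distance. The per-year rate &mu;/g = d/(2T&#8325;) does
not depend on g. Mean Ne for comparative analyses excludes the four most
recent trajectory points, where SMC estimates are noisy. Group-mean curves
min-max normalize each species' trajectory over the 10 kya–10 Mya window on
a common log-time grid (64 points by default); a `mode = "max"` option
divides by the maximum only, the per-period display convention. A constant
trajectory normalizes to 0.5 with a warning.

**Uncertainty.** The block bootstrap splits scaffolds into 5-Mb segments
(configurable), resamples with replacement to the original total length and
refits; 30 replicates is the study-scale default. Year-scaling commutes
with the bootstrap, which is tested.

**What the recovery tests mean.** On a 10-Mb constant-Ne simulation the
per-interval estimates oscillate around the truth — the familiar wiggle of
unregularized SMC fits with 29 free parameters — while the TMRCA-mass-
weighted mean over the central intervals (those covering the interquartile
range of the true coalescence-time distribution) is stable; the acceptance
check asserts that weighted central estimate within ±20%. Real analyses use
whole genomes (hundreds of Mb), where both the wiggle and the rare
megabase-scale recent-coalescence blocks that make 10-Mb windows fat-tailed
average out. The 10-Mb problem size was chosen to keep the full property
suite within minutes on one CPU while still leaving ~4,000 recombination
segments of signal.

## Heterozygosity and track preparation

Genome-wide heterozygosity H is the count of heterozygous genotypes passing
the base-quality (≥ 20) and mapping-quality (≥ 30) filters divided by the
*genome size* — not by the number of callable sites; a flag exposes the
callable-sites denominator, which is the more common convention. Depth
filtering keeps sites with DOC within [mean/3, 2·mean], boundaries
inclusive (the filter removes sites with *less than* one-third and *more
than* double the mean), and is idempotent. Binning codes a bin HET if it
contains at least one passing heterozygous site and MISSING when more than
90% of its positions are explicitly missing (configurable); coordinates are
1-based inclusive in genotype tables and 0-based half-open in bins. The
psmcfa-style text format (FASTA-like records, alphabet T/K/N, 60 characters
per line) round-trips bit-exactly through the writer/reader. Computing H
"from the folded site frequency spectrum" of a single diploid genome is
operationally identical to counting heterozygous genotypes, which is what
the implementation does.

## The niche model

**Preprocessing.** Occurrences are spatially thinned to a minimum pairwise
distance of 4.5 km. Thinning is a maximum-independent-set problem on the
graph of too-close pairs: connected conflict components of up to 20 records
are solved exactly by branch and bound, larger components by repeated
randomized greedy deletion (most-neighbours first), keeping the best of 25
passes — so on small instances the result provably matches exhaustive
search, which the tests exploit. Rasters are cropped to the occurrence
bounding box plus a 10° buffer. Collinear climate layers are reduced by PCA
on standardized cell values, retaining the first components that explain
more than 90% of variance, capped at 6. Species with fewer than 15
occurrences are excluded (the generator enforces the same rule unless
explicitly overridden).

**Model family.** The Maxent suitability model is fit in its
penalized-logistic form: an L1-penalized binomial regression of presence
cells against 10,000 uniformly drawn background cells on a feature
expansion of the PC scores — linear (L), quadratic (Q) and pairwise-product
(P) classes; hinge and threshold features are deliberately out of scope.
The penalty is &lambda; = multiplier × √(log p / n) with per-feature weight
1 on internally standardized features, so the regularization multipliers
{1, 2, 5} span light to near-total shrinkage; the solver is glmnet at a
fixed &lambda; inside a short path, and an independent quasi-Newton solver
reproduces the coefficients to 1e-4 in the tests. The candidate grid is
configurable and defaults to the 7 non-empty feature-class subsets × 3
multipliers: the documented "nine combinations" of three classes cannot be
enumerated as exactly nine non-empty subsets, so the grid is exposed as
configuration rather than guessed at.

**Output transform.** Predictions default to the cloglog transform
1 − exp(−e^H&#8320;·raw), with raw the density relative to the training
background and H&#8320; its entropy (the current Maxent default); a
logistic option exists. Suitability is therefore in [0, 1] and the
suitable-area rule counts cells with suitability ≥ 0.36 (inclusive, the
"medium to high probability 0.36–1.00" band), times the cell area — exact
cell areas on the synthetic planar grids, a cosine-latitude approximation
for lon/lat grids. Ice-masked cells are excluded. The normalized area
series divides by the maximum across periods.

**Selection.** Each candidate is evaluated by random 4-fold
cross-validation of the presences (AUC of held-out presences against the
background, computed by the rank statistic, which equals trapezoidal ROC
integration) and by AICc on the full fit, with K the number of non-zero
coefficients and the likelihood the product of normalized raw suitabilities
at presences. The selected model minimizes AICc among candidates with mean
test AUC above 0.7; ties prefer fewer non-zero coefficients, then the lower
multiplier. If nothing passes the gate the result is an explicit "no valid
model", mirroring species exclusion. Selection is deterministic given the
seed (folds and background draw).

**Spatial autocorrelation.** Moran's I with binary distance-band weights at
21 bands between 0 and 10 km, permutation p-values (999 permutations,
seeded); bands with fewer than two pairs report NA. The residuals tested
are presence-cell observed-minus-predicted values — the residual definition
is not fixed by convention, so the function accepts any point/residual
table and the choice is documented here rather than hidden.

**Synthetic worlds.** The generator draws smooth gradient-plus-noise
climate layers on a planar grid (4.5-km cells, matching the thinning
radius), defines true suitability as a logistic transform of a stated
linear predictor, samples occurrences proportional to suitability, and
shifts layers additively per period so the true suitable area moves in a
known direction. The defaults (intercept −4, strong positive and moderate
negative linear coefficients on two of four layers) make suitable habitat
occupy roughly a third of the region, which puts the best achievable AUC
near 0.84 under proportional sampling — a realistic regime for widespread
species and comfortably above the 0.7 gate. What these tests establish is
that the pipeline recovers a known data-generating process of its own model
family on an idealized planar grid; they do not address sampling bias,
spatially structured detection, non-equilibrium occupancy or geodesic
effects in real occurrence data.

## Trend coding and association

For the period pairs MIS19 (~787 kya) → LIG (~130 kya) and LIG → LGM
(~20 kya), changes are coded from &Delta; = earlier − later: negative →
increasing, positive → decreasing, zero → stable. Ne enters at the
trajectory value at the period's nominal age (a configurable choice; the
alternative of a span mean is not implied by the coding rule), area at the
period's suitable-area value, and temperature from a supplied global
mean-surface-temperature series applied uniformly across species. The
package ships a synthetic temperature curve for demonstrations and expects
a published reconstruction as CSV input in real analyses.

Associations are Pearson chi-squared tests of the cross-tabulated codes;
for 2×2 tables both the Yates-corrected and uncorrected statistics are
always reported (the corrected one is the headline default), since
n·&phi;² equals only the *uncorrected* statistic — an identity the tests
assert to 1e-12. Phi requires binomial data, so species carrying a
"stable" code are excluded from the Phi table (but retained for
chi-squared); subsets by habitat and climate zone reuse the same machinery.

## Comparative PGLS

The Brownian covariance C has entries equal to shared root-to-MRCA path
lengths (`ape::vcv.phylo`; an independent path-sum traversal is the test
oracle). The GLS estimate &beta;&#770; = (X'C&#8315;¹X)&#8315;¹X'C&#8315;¹y
is computed in closed form via Cholesky whitening, with
&sigma;² = r'C&#8315;¹r/(n − p) and standard errors from
&sigma;²(X'C&#8315;¹X)&#8315;¹ — the plain PGLS, with no Pagel's-&lambda;
optimization, which keeps C = I star trees exactly equal to OLS and makes
estimates invariant to uniform branch-length rescaling (both tested; the
closed form is also cross-checked against `nlme::gls` with Brownian
correlation). The model set: (1) H ~ status + current area and
mean Ne ~ status + mean past area over all species, (2) the same restricted
to at-risk species, and (3) the status/habitat-availability relationship.
Status is categorical, so model 3 is fit as area regressed on the binary
status — the direction that makes "a correlation between habitat
availability and conservation status" estimable in a linear model; both
current and past-mean area are reported. Tukey HSD contrasts compare
adjusted group means (covariates at their sample means) with
studentized-range p-values from the GLS covariance; on balanced
identity-covariance designs this reproduces the textbook procedure exactly.

## Chromosome assignment (PRR)

For each micro-dissected chromosome sample, a scaffold's position
representation ratio is
PRR = (positions on scaffold / positions genome-wide) /
(scaffold length / genome length); since PRR is distributed lognormally the
log form is thresholded. Enrichment calls require logPRR > 0, a one-sided
binomial p ≤ 0.01 (one-sided because only enrichment is thresholded), and
at least 2 mapped positions (the smallest count with a defined mean
pairwise distance); an optional minimum mean-pairwise-distance filter (off
by default) addresses clustered amplification artefacts. Per-scaffold
summaries (position count, mean pairwise distance, mean reads per position)
mirror the usual reporting table.

## Orchestration and reproducibility

`run_demo()` wires every stage over a synthetic multi-species world at demo
scale (6 species, 0.5-Mb genomes, 10 EM iterations, 40×40 rasters, 150
occurrences, 2,000 background points) and completes in well under two
minutes on one CPU; all stage seeds derive from one global seed by stable
hashing, so a fixed seed reproduces the result exactly. The full study-scale
settings (pattern `"2+2+25*2+4+6"`, t&#8337;&#8336;&#8339; 15, &theta;/&rho;
5, 30 bootstraps, 4.5-km thinning, 10° buffer, 10,000 background points,
k = 4, AUC > 0.7, threshold 0.36, p ≤ 0.01) are the defaults of
`pipeline_config()`, which rejects unknown keys. The command-line surface
of the package is `Rscript scripts/acceptance.R --seed N --out path`, which
re-runs the property suite and the demo pipeline from scratch and writes
the headline numbers as JSON.

## Known limitations

* The SMC fit estimates 29 free intensities without smoothing; per-interval
  estimates at 10-Mb scale oscillate (±30–50% in unlucky seeds) even though
  window-averaged estimates are accurate. Real whole-genome inputs or fewer
  free intervals reduce this.
* Synthetic rasters are planar with exact cell areas; lon/lat inputs use a
  cosine-latitude cell-area approximation, not geodesic cell geometry.
* The Maxent penalty scaling is a single analytic default
  (&lambda;&#8320; = √(log p / n)) rather than the feature-class-specific
  empirical tables some implementations ship; the multiplier grid spans the
  same light-to-heavy range.
* Temperature coding applies one global series to all species; a
  per-species column is accepted but not synthesized.
* The VCF reader takes the first sample's genotypes and DP field; multi-
  sample VCFs or likelihood-based genotype calling are out of scope.
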