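---
title: "Benchmarking GWAS methods across genetic architectures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking GWAS methods across genetic architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtnbench)
```

## Why this package exists

Single-marker mixed-model GWAS works well for traits controlled by a
handful of loci, but its power collapses as the number of causal variants
grows and heritability falls. Multi-locus methods (FarmCPU-style
iterative scans) and Bayesian whole-genome regression (BayesCpi) were
developed for exactly that regime, yet they report evidence on different
scales (p-values versus posterior model frequencies), which makes naive
comparisons meaningless. `qtnbench` provides the full machinery to
compare such engines fairly: a phenotype simulator with exact
heritability calibration, three association engines implemented under one
interface, an evaluation layer that matches calls to simulated truth
through linkage disequilibrium and compares engines at equal numbers of
accepted positives, and a synthetic population generator so the whole
benchmark runs from nothing but a seed.

## The trait model

Phenotypes follow a strictly additive model,

$$Y_j = \sum_{i=1}^{m} a_i S_{ij} + e_j,$$

where $S_{ij} \in \{0, 1, 2\}$ is the dosage of causal marker $i$ in
individual $j$, effects $a_i$ are standard normal (a geometric series
$a_i = r^i$ with random signs is available as an alternative), and
$e_j \sim N(0, \sigma_e)$ with

$$\sigma_e = \sqrt{\widehat{\mathrm{Var}}(g)\,(1/h^2 - 1)},
\qquad g_j = \sum_i a_i S_{ij}.$$

Two calibration choices deserve a note. First,
$\widehat{\mathrm{Var}}(g)$ is the *realized sample variance*
(denominator $n-1$) of the genetic values on the genotyped individuals,
not a population quantity, so the expected realized heritability
$\mathrm{Var}(g)/\mathrm{Var}(Y)$ equals the target $h^2$ in finite
samples; the test suite verifies recovery within $\pm 0.02$ over
thousands of replicates at $h^2 \in \{0.1, 0.5, 0.9\}$. Second, the
residual stream is seeded from the architecture seed plus a fixed
offset, so the same architecture can be re-noised independently — each
replicate recomputes $\mathrm{Var}(g)$ and redraws the residuals. At
$h^2 = 1$ residuals are exactly zero. Epistasis, dominance, and
MAF-dependent effect sizes are deliberately out of scope; real traits
that violate these assumptions (e.g., selected traits with skewed effect
distributions) will show lower absolute power than these simulations
suggest.

## The synthetic population

No external genotype data are required. `generate_population()` draws a
Balding–Nichols structured population: ancestral allele frequencies come
from one of two presets — `"u-shaped"` (Beta(0.2, 0.2) truncated to
[0.01, 0.99]), imitating the rare-allele-heavy spectra of
genotyping-by-sequencing panels, or `"common-filtered"`
(MAF ~ Uniform(0.1, 0.5)), imitating array-designed or pre-filtered
marker sets — and each subpopulation's frequencies are Beta-dispersed
around them with differentiation $F$:
$p_s \sim \mathrm{Beta}\left(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\right)$.

Linkage disequilibrium comes from a founder-haplotype copying model
rather than a coalescent: each subpopulation owns a finite pool of
founder haplotypes, and every individual's haplotype is a mosaic of the
pool with per-bp copy-switch probability `switch_rate_per_bp`
(geometric tract lengths). The LD decay length is therefore directly
tunable, roughly $1/\texttt{switch\_rate\_per\_bp}$, spanning the range
from near-zero LD (array-like) to hundreds of kb (low-recombination
panels). Individuals are fully inbred by default (one mosaic haplotype
doubled), matching the inbred crop panels this benchmark emulates.

What the generator does *not* reproduce: demographic history, selection,
recombination-rate variation, genotyping error, and the empirical
relatedness structure of real breeding programs. Consequences worth
keeping in mind:

* the two MAF presets plus finite founder pools leave a substantial
  fraction of generated markers monomorphic or rare — exactly like raw
  GBS data — so every analysis here first applies
  `filter_markers(min_maf = 0.05)`, as the four real datasets this
  design emulates all did;
* within a subpopulation individuals are exchangeable, so after the
  leading principal components are regressed out the kinship matrix is
  close to isotropic. REML variance-ratio estimates on *null* traits
  are therefore noisy (the likelihood is nearly flat in the
  variance split); this is a property of the study conditions, not of
  the estimator, whose correctness is checked against an independent
  no-rotation two-dimensional grid oracle.

Passing tests on these populations show the engines and the scoring
machinery behave as designed; they do not certify power numbers for any
particular real crop panel.

## The three engines

**Mixed linear model (Q+K).** $y = W\beta + u + e$ with
$u \sim N(0, \sigma_g^2 K)$, $W$ = intercept + first three PCs of the
standardized dosage matrix, and $K$ the centered genomic relationship
matrix. One eigendecomposition of $K$ turns REML into a one-dimensional
profile in $\lambda = \sigma_g^2/\sigma_e^2$, optimized on
$\log_{10}\lambda \in [-5, 5]$ (tolerance $10^{-6}$; boundary solutions
are flagged, not rejected). The scan reuses the null variance components
for every marker (the standard fast approximation) and reports two-sided
Wald t-tests; an `exact` mode re-optimizes $\lambda$ per marker and is
used in tests to bound the approximation error (within 15% on
$-\log_{10} p$ for top signals). With $K = I$ the scan reduces exactly
to covariate-adjusted OLS, which the tests exploit as a closed-form
oracle. The centered and VanRaden kinship estimators differ only by the
global scalar $M / (2\sum_k p_k(1-p_k))$, so their entries correlate
perfectly — the package's quickest end-to-end sanity check.

**FarmCPU-style iterative scan.** Alternates (i) an OLS scan with
intercept, three PCs, and the current pseudo-QTNs as fixed covariates
with (ii) pseudo-QTN reselection: the best-p marker per genomic bin is a
candidate, candidate sets of size $t$ are scored by the REML likelihood
of an intercept-only model whose random-effect covariance is the
VanRaden kinship built from the candidate markers alone, over the grid
bin sizes $\{5 \times 10^5, 5 \times 10^6, 5 \times 10^7\}$ bp and
$t \in \{10, 20, \ldots, 100\}$ (the reference implementation's
defaults). Design choices that were genuinely open:

* *Entry threshold.* The iteration only starts if the first scan's
  minimum p-value passes $0.01/M$ — the reference tool's safeguard.
  Without it, pseudo-QTN selection on a null trait always finds
  apparent support, because candidates are chosen as the markers most
  correlated with the noise (a selection bias the likelihood scoring
  cannot undo); with it, null traits simply return the plain
  covariate-adjusted scan.
* *P-value substitution.* A marker serving as a pseudo-QTN is reported
  with its covariate's own t-test from the joint fit. We substitute
  only at the pseudo-QTN's position; spreading its p-value across its
  whole bin would clone one value over hundreds of markers when the
  50-Mb bin wins, flooding the top of the ranked list and corrupting
  matched-K comparisons.
* *Collinearity.* Selected sets are pruned at pairwise $r^2 > 0.7$
  (better p-value kept); residual collinear covariates are dropped at
  fit time with a warning.
* *Convergence* is exact set repetition (catching cycles), capped at 10
  iterations; hitting the cap returns the last scan with a flag. On
  polygenic traits the selected set keeps churning at the margins, so
  the cap is the practical stopping rule — the final scans differ
  negligibly.

**BayesCpi.** Whole-genome regression
$y = \mu + \sum_j x_j \beta_j \delta_j + e$ with a common slab variance
$\sigma_\beta^2$, inclusion indicators
$\delta_j \sim \mathrm{Bern}(1-\pi)$, and $\pi$ itself sampled
(Beta(1, 1) prior) — $\pi = 0.9999$ is the chain's *starting point*, not
a fixed prior. The Gibbs sweep (compiled, residual-update form) samples
each $\delta_j$ with $\beta_j$ integrated out, then $\beta_j$ given
inclusion, then both variances from scaled-inverse-$\chi^2$ full
conditionals with 4 degrees of freedom; the marker-effect scale is
derived from the genetic-variance prior divided by the expected number
of included markers times the mean marker variance. The production
defaults are 11 000 iterations / 1000 burn-in behind a 1000/100 pilot
chain whose posterior variances seed the production priors (the
"two-step" guard against mis-scaled defaults); the factorial benchmark
and the acceptance checks use 2000/200 chains, which the
chain-doubling stability test shows are adequate at these problem
sizes. The sampler's stationary distribution is validated against
exhaustive enumeration of all $2^3$ models on a toy instance (maximum
inclusion-probability error < 0.03). No population-structure control is
applied inside the sampler, reproducing the benchmark's design; an
optional PC pre-adjustment of the phenotype exists but is off by
default. Markers are ranked by posterior model frequency with ties
broken by the genetic variance attributed to each marker, then marker
index.

Architecture estimation reads $\hat m = (1-\hat\pi)M$ and
$\hat h^2$ = posterior mean of
$\mathrm{Var}(g)/(\mathrm{Var}(g) + \sigma_e^2)$ (realized-variance
definition, matching the simulator). The documented bias — causal-count
overestimation for complex, low-heritability traits, as the model
recruits noncausal markers to absorb residual noise — is reproduced and
asserted in the test suite, and is the reason the method
recommendation flags low confidence in that regime.

## Scoring: LD-aware power, FDR, Type-I error

Engines are compared by the increasing-rank method: at each accepted-
positive count $K$, the top-$K$ ranked markers are positives. A positive
is a true positive if it is causal or has $r^2 > 0.6$ (strict) with a
causal marker on the same chromosome within 10 Mb; positives linked to
the same causal variant merge into a single true positive, shrinking the
effective positive count. Then

$$\mathrm{power} = \frac{TP}{m}, \qquad
\mathrm{FDR} = \frac{FP}{TP + FP}, \qquad
\text{Type I} = \frac{FP}{M - m}.$$

Choices made where the rules were open: a positive linked to several
causal variants credits only the one with the highest $r^2$; FDR at
$K = 0$ is reported as 0 with a flag rather than NaN; the Type-I
denominator is literally $M - m$, with no exclusion of markers in LD
with causal variants. Varying the LD threshold across 0.6–0.9 moves
power by less than 0.1 absolute on these populations (a soft regression
check in the suite).

## The factorial benchmark

`sweep_config()` defaults to the full design: QTN counts $2^1 \ldots
2^{10}$, heritabilities 0.1–1.0 in steps of 0.1, 10 replicates — exactly
1000 phenotype datasets per population. Per-cell seeds come from a
multiplicative integer mix of the base seed and the cell coordinates
(collision-free across the grid, stable under grid extension, folded
into R's 31-bit seed range). Sweeps are resumable through per-cell
artifacts, engine failures flag the cell and continue, and
`summarize_report()` renders power/FDR-versus-K and
power-versus-architecture summaries with standard errors over
replicates.

Problem sizes: the package's reference population for development and
for the automated checks is 500 individuals x 5000 generated markers
(about 2000 after the MAF filter), 3 subpopulations at $F = 0.25$,
u-shaped frequencies, switch rate $10^{-6}$/bp — chosen as the smallest
configuration on which all the qualitative orderings the benchmark is
about (power falling with architecture complexity and falling
heritability; multi-locus engines beating the single-marker scan at
matched K; Bayesian architecture estimates accurate for simple
high-$h^2$ traits and upward-biased for complex low-$h^2$ ones) are
reproducible in minutes on a laptop. The full $10^3$-cell factorial at
this size is an overnight run.

## Numerical notes and degenerate inputs

* Monomorphic markers: flagged with $p = 1$ in scans, excluded from
  pairwise LD (logged), rejected as the sole content of a kinship.
* All-missing markers error by name; imputation requires at least one
  observed call per marker.
* Kinship PSD is enforced up to $10^{-8} \cdot \mathrm{trace}/N$; tiny
  negative eigenvalues are clipped to zero.
* Variance-ratio search bounds ($10^{\pm 5}$) are accepted as solutions
  but flagged; the REML objective at the optimum is test-verified
  against grid ends.
* The dosage-matrix text dialect uses `NA` as its missing sentinel and
  round-trips bit-identically; positions are 1-based and distances are
  plain $|p_i - p_j|$.

## Known limitations

Beyond the generator's realism limits above: no epistasis or dominance
in the simulator; no multi-trait or GxE models; BayesCpi has no
principled significance cutoff (rankings only, as in the benchmark it
reimplements); the FarmCPU iteration's set-equality convergence
usually terminates at the iteration cap on highly polygenic traits; and
the architecture-based method recommendation is a coarse decision rule
distilled from the benchmark's orderings, not a fitted classifier.
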